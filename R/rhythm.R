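# Core cosinor engine: OLS fit of y = m + a*cos(w t) + b*sin(w t) for every
# row of Y at once, via one QR decomposition of the shared design.
# Returns the per-gene parameter table without multiple-testing columns.
.fit_harmonic_matrix <- function(Y, t, period = 24) {
  n <- length(t)
  if (ncol(Y) != n) stop("time vector does not match the sample count")
  if (n < 6) stop("need at least 6 samples for a cosinor fit")
  if (length(unique(round(t %% period, 9))) < 3)
    stop("need at least 3 distinct times modulo the period; ",
         "the cosinor model is unidentifiable")
  w <- 2 * pi / period
  X <- cbind(mesor = 1, cosw = cos(w * t), sinw = sin(w * t))
  qrX <- qr(X)
  Yt <- t(Y)
  B <- qr.coef(qrX, Yt)
  fitted <- qr.fitted(qrX, Yt)
  rss <- colSums((Yt - fitted)^2)
  tss <- colSums(sweep(Yt, 2, colMeans(Yt), `-`)^2)
  df2 <- n - 3
  mss <- pmax(tss - rss, 0)
  Fstat <- (mss / 2) / (rss / df2)
  p <- stats::pf(Fstat, 2, df2, lower.tail = FALSE)
  # constant series: no variance to explain -> null fit by convention
  flat <- tss <= .Machine$double.eps * n * (1 + colMeans(Yt)^2)
  Fstat[flat] <- 0
  p[flat] <- 1
  # exact fits: rss = 0 with signal -> p = 0
  exact <- !flat & rss <= .Machine$double.eps * n * pmax(tss, 1)
  Fstat[exact] <- Inf
  p[exact] <- 0
  m <- B["mesor", ]
  a <- B["cosw", ]
  b <- B["sinw", ]
  A <- sqrt(a^2 + b^2)
  A[flat] <- 0
  phase <- (atan2(b, a) * period / (2 * pi)) %% period
  relamp <- ifelse(m > 0, A / m, NA_real_)
  data.frame(gene_id = rownames(Y),
             mesor = m, coef_cos = a, coef_sin = b,
             amplitude = A, relamp = relamp, phase_h = phase,
             Fstat = Fstat, pvalue = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Harmonic (cosinor) regression of a single abundance series
#'
#' Ordinary least-squares fit of the fixed-period cosinor model
#' `y(t) = m + a*cos(w t) + b*sin(w t)` with `w = 2*pi/period`, equivalent
#' to `m + A*cos(w*(t - phi))` with amplitude `A = sqrt(a^2 + b^2)` and peak
#' phase `phi = atan2(b, a)/w mod period`. Significance comes from the F
#' statistic of the harmonic model against the intercept-only model with
#' `(2, n - 3)` degrees of freedom. Replicate observations at equal times
#' enter as independent measurements. Relative amplitude `A/m` is reported
#' as `NA` when the fitted mesor is not positive.
#'
#' @param y Positive linear abundance values.
#' @param t Sampling times in hours (same length as `y`, at least 6 points
#'   with 3 or more distinct times modulo the period).
#' @param period Fixed oscillation period in hours (default 24).
#' @return A one-row `data.frame` with columns `gene_id`, `mesor`,
#'   `coef_cos`, `coef_sin`, `amplitude`, `relamp`, `phase_h`, `Fstat`,
#'   `pvalue`.
#' @examples
#' t <- seq(0, 42, by = 3)
#' y <- 10 + 3 * cos(2 * pi * (t - 8) / 24)
#' harmonic_fit(y, t)
#' @export
harmonic_fit <- function(y, t, period = 24) {
  stopifnot(length(y) == length(t))
  Y <- matrix(y, nrow = 1, dimnames = list("y", NULL))
  .fit_harmonic_matrix(Y, t, period)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (via [stats::p.adjust()]),
#' preserving the input order. Input p-values must lie in `[0, 1]`.
#'
#' @param p Numeric vector of p-values.
#' @return Vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Genome-wide rhythmicity table with BH control and amplitude filter
#'
#' Fits the fixed-period cosinor model to every gene of a linear-scale
#' matrix, adjusts p-values across all tested genes by Benjamini-Hochberg,
#' and flags genes as significantly 24-h rhythmic when `q < q_cut` AND the
#' relative amplitude is at least `relamp_cut`. Input must be on an
#' untransformed scale (`"linear"` or `"linear-normalized"`): single
#' platforms are analyzed on their original linear abundances, the
#' concatenated series on its normalized values. Output is sorted by
#' q-value, then gene id.
#'
#' @param em An [expression_matrix()] or [concatenate_series()] output on a
#'   linear scale.
#' @param period Fixed period in hours (default 24).
#' @param q_cut FDR threshold (default 0.05, strict inequality).
#' @param relamp_cut Relative-amplitude threshold (default 0.1, inclusive).
#' @return A `data.frame` of class `RhythmTable`: one row per gene with the
#'   cosinor parameters plus `qvalue` and `significant`.
#' @export
rhythmicity_table <- function(em, period = 24, q_cut = 0.05,
                              relamp_cut = 0.1) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (!em$scale %in% c("linear", "linear-normalized"))
    stop("rhythmicity is fitted on linear-scale values; got '", em$scale,
         "'. Use to_linear() to de-log the matrix first.")
  fits <- .fit_harmonic_matrix(em$values, em$time_h, period)
  fits$qvalue <- bh_adjust(fits$pvalue)
  fits$significant <- fits$qvalue < q_cut &
    !is.na(fits$relamp) & fits$relamp >= relamp_cut
  fits <- fits[order(fits$qvalue, fits$gene_id), ]
  rownames(fits) <- NULL
  attr(fits, "period") <- period
  attr(fits, "q_cut") <- q_cut
  attr(fits, "relamp_cut") <- relamp_cut
  class(fits) <- c("RhythmTable", "data.frame")
  fits
}

#' Write / read a rhythmicity table as TSV
#'
#' @param fits A [rhythmicity_table()] result.
#' @param file Path of the TSV.
#' @return `write_rhythm_table` returns `file` invisibly; `read_rhythm_table`
#'   returns the table.
#' @export
write_rhythm_table <- function(fits, file) {
  utils::write.table(fits, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_rhythm_table
#' @export
read_rhythm_table <- function(file) {
  fits <- utils::read.delim(file, stringsAsFactors = FALSE)
  class(fits) <- c("RhythmTable", "data.frame")
  fits
}
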