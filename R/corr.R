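#' Mean per-time-point expression correlation between two platforms
#'
#' For every shared sampling time, the Pearson correlation across common
#' genes is computed between the samples of the two matrices taken at that
#' time (replicate samples at a time are correlated pairwise and averaged),
#' and the per-time coefficients are averaged. Times at which either sample
#' has zero variance are skipped with a warning.
#'
#' @param a,b [expression_matrix()] objects with at least 3 common genes.
#' @param shared_times Optional set of times (hours) to use; defaults to the
#'   intersection of the two time grids.
#' @return A list with `mean_pearson`, the per-time coefficients `by_time`,
#'   and `n_genes`.
#' @export
expression_correlation <- function(a, b, shared_times = NULL) {
  stopifnot(inherits(a, "ExpressionMatrix"), inherits(b, "ExpressionMatrix"))
  genes <- intersect(rownames(a$values), rownames(b$values))
  if (length(genes) < 3) stop("need at least 3 common genes")
  if (is.null(shared_times)) shared_times <- intersect(a$time_h, b$time_h)
  if (length(shared_times) == 0) stop("no shared time points")
  av <- a$values[genes, , drop = FALSE]
  bv <- b$values[genes, , drop = FALSE]
  by_time <- stats::setNames(rep(NA_real_, length(shared_times)),
                             shared_times)
  for (k in seq_along(shared_times)) {
    tt <- shared_times[k]
    ia <- which(a$time_h == tt)
    ib <- which(b$time_h == tt)
    if (!length(ia) || !length(ib)) next
    rs <- c()
    for (i in ia) for (j in ib) {
      x <- av[, i]
      y <- bv[, j]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        warning(sprintf("zero-variance sample at t = %g h; pair skipped", tt))
        next
      }
      rs <- c(rs, stats::cor(x, y))
    }
    if (length(rs)) by_time[k] <- mean(rs)
  }
  if (all(is.na(by_time))) stop("no usable shared time point")
  list(mean_pearson = mean(by_time, na.rm = TRUE), by_time = by_time,
       n_genes = length(genes))
}

# circular mean direction of angles (radians)
.circ_mean_angle <- function(theta) {
  atan2(mean(sin(theta)), mean(cos(theta)))
}

#' Circular correlation of two phase vectors
#'
#' The Jammalamadaka-SenGupta circular correlation coefficient of two phase
#' vectors on the 24-h circle:
#' `r = sum(sin(x - mx) * sin(y - my)) / sqrt(sum(sin(x - mx)^2) * sum(sin(y - my)^2))`
#' with `mx`, `my` the circular means. Significance comes from the
#' asymptotic normal statistic `z = r * sqrt(n * l20 * l02 / l22)`, where
#' `lij` are the mixed sine moments `mean(sin^i(x - mx) * sin^j(y - my))`.
#' The coefficient is invariant under rotation of either vector and flips
#' sign under reflection.
#'
#' @param phases_x,phases_y Phase vectors in hours, equal length `n >= 3`.
#' @param period Period in hours (default 24).
#' @return A list with `r` (in `[-1, 1]`, `NA` when either vector is
#'   degenerate, i.e. all angles equal), `p` (two-sided asymptotic p-value)
#'   and `n`.
#' @examples
#' x <- c(1, 5, 9, 16, 22)
#' circular_correlation(x, (x + 6) %% 24)$r  # 1: rotation invariance
#' @export
circular_correlation <- function(phases_x, phases_y, period = 24) {
  n <- length(phases_x)
  if (length(phases_y) != n) stop("phase vectors must have equal length")
  if (n < 3) stop("need at least 3 phase pairs")
  tx <- 2 * pi * phases_x / period
  ty <- 2 * pi * phases_y / period
  sx <- sin(tx - .circ_mean_angle(tx))
  sy <- sin(ty - .circ_mean_angle(ty))
  den <- sqrt(sum(sx^2) * sum(sy^2))
  if (den < 1e-12)
    return(list(r = NA_real_, p = NA_real_, n = n))
  r <- sum(sx * sy) / den
  l20 <- mean(sx^2)
  l02 <- mean(sy^2)
  l22 <- mean(sx^2 * sy^2)
  z <- r * sqrt(n * l20 * l02 / l22)
  list(r = r, p = 2 * stats::pnorm(-abs(z)), n = n)
}

#' Pearson correlation of relative amplitudes
#'
#' Standard Pearson correlation with a two-sided t-test (via
#' [stats::cor.test()]); returns `NA` coefficients when either vector has
#' zero variance.
#'
#' @param ra_x,ra_y Relative-amplitude vectors, equal length `n >= 3`.
#' @return A list with `r`, `p` and `n`.
#' @export
amplitude_correlation <- function(ra_x, ra_y) {
  n <- length(ra_x)
  if (length(ra_y) != n) stop("vectors must have equal length")
  if (n < 3) stop("need at least 3 pairs")
  if (stats::sd(ra_x) == 0 || stats::sd(ra_y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n))
  ct <- stats::cor.test(ra_x, ra_y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Cross-platform comparison report of circadian parameters
#'
#' Restricts two rhythmicity tables to the genes significantly 24-h rhythmic
#' in both, then reports the circular correlation of their phases and the
#' Pearson correlation of their relative amplitudes; optionally also the
#' mean per-time-point expression correlation of the underlying matrices
#' over the shared time window.
#'
#' @param fits_a,fits_b [rhythmicity_table()] results.
#' @param expr_a,expr_b Optional [expression_matrix()] pair for the
#'   expression correlation.
#' @param shared_window Hours interval defining the shared times for the
#'   expression correlation (default `c(12, 24)`).
#' @return A `CorrelationReport` list: `circular_r`, `circular_p`, `amp_r`,
#'   `amp_p`, `n_genes` (commonly significant genes), and `mean_pearson`
#'   (`NA` unless matrices were given).
#' @export
correlation_report <- function(fits_a, fits_b, expr_a = NULL, expr_b = NULL,
                               shared_window = c(12, 24)) {
  common <- intersect(fits_a$gene_id[fits_a$significant],
                      fits_b$gene_id[fits_b$significant])
  circ <- list(r = NA_real_, p = NA_real_)
  amp <- list(r = NA_real_, p = NA_real_)
  if (length(common) >= 3) {
    ia <- match(common, fits_a$gene_id)
    ib <- match(common, fits_b$gene_id)
    circ <- circular_correlation(fits_a$phase_h[ia], fits_b$phase_h[ib])
    amp <- amplitude_correlation(fits_a$relamp[ia], fits_b$relamp[ib])
  }
  mean_pearson <- NA_real_
  if (!is.null(expr_a) && !is.null(expr_b)) {
    st <- intersect(expr_a$time_h, expr_b$time_h)
    st <- st[st >= shared_window[1] & st <= shared_window[2]]
    mean_pearson <- expression_correlation(expr_a, expr_b, st)$mean_pearson
  }
  structure(list(mean_pearson = mean_pearson,
                 circular_r = circ$r, circular_p = circ$p,
                 amp_r = amp$r, amp_p = amp$p,
                 n_genes = length(common)),
            class = "CorrelationReport")
}
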