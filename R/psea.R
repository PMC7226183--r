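#' Kuiper statistic for circular uniformity
#'
#' The Kuiper statistic `V = D+ + D-` of a sample against the uniform
#' distribution on `[0, 1)`, with `D+ = max_i(i/n - u_(i))` and
#' `D- = max_i(u_(i) - (i-1)/n)` over the sorted sample. Unlike the
#' Kolmogorov-Smirnov statistic, `V` is invariant under rotation of the
#' sample on the circle, which makes it the appropriate uniformity statistic
#' for circadian phases.
#'
#' @param u Numeric vector in `[0, 1)`, `n >= 1`.
#' @return The statistic `V`.
#' @examples
#' kuiper_statistic((2 * (1:10) - 1) / 20)  # evenly spread: V = 1/n = 0.1
#' @export
kuiper_statistic <- function(u) {
  n <- length(u)
  if (n < 1) stop("need at least one value")
  if (any(!is.finite(u)) || any(u < 0) || any(u >= 1))
    stop("values must lie in [0, 1)")
  us <- sort(u)
  i <- seq_len(n)
  dplus <- max(i / n - us)
  dminus <- max(us - (i - 1) / n)
  dplus + dminus
}

#' Asymptotic Kuiper test p-value
#'
#' Upper-tail probability of the Kuiper statistic under uniformity, from the
#' asymptotic series `p = 2 * sum_j (4 j^2 lambda^2 - 1) exp(-2 j^2 lambda^2)`
#' evaluated at the Stephens small-sample effective statistic
#' `lambda = (sqrt(n) + 0.155 + 0.24/sqrt(n)) * V`. The series is truncated
#' once terms fall below 1e-12 and the result is clamped to `[0, 1]`; small
#' effective statistics (`lambda < 0.4`), where the series loses accuracy,
#' return 1 (the statistic carries no evidence against uniformity there).
#'
#' @param V Kuiper statistic in `[0, 2]` (at most 1 for a sample of distinct
#'   values).
#' @param n Sample size (`>= 1`; the approximation is intended for
#'   `n >= 8`-ish sizes and works well at the set sizes of enrichment
#'   testing).
#' @return The p-value in `[0, 1]`.
#' @export
kuiper_pvalue <- function(V, n) {
  stopifnot(V >= 0, n >= 1)
  lambda <- (sqrt(n) + 0.155 + 0.24 / sqrt(n)) * V
  if (lambda < 0.4) return(1)
  l2 <- lambda^2
  p <- 0
  for (j in 1:100) {
    term <- (4 * j^2 * l2 - 1) * exp(-2 * j^2 * l2)
    p <- p + term
    if (abs(term) < 1e-12) break
  }
  min(max(2 * p, 0), 1)
}

#' Circular (vector-average) mean of phases
#'
#' Phases are mapped to angles on the 24-h circle, their mean resultant
#' vector is formed, and its direction mapped back to hours. Perfectly
#' balanced phase sets (resultant length below 1e-9, e.g. two antipodal
#' points) have no defined mean and return `NA`.
#'
#' @param phases Phases in hours, non-empty.
#' @param period Period in hours (default 24).
#' @return The circular mean in `[0, period)`, or `NA` if degenerate.
#' @examples
#' circular_mean_phase(c(23, 1))  # 0: wraps around midnight
#' @export
circular_mean_phase <- function(phases, period = 24) {
  if (!length(phases)) stop("`phases` must be non-empty")
  theta <- 2 * pi * phases / period
  C <- mean(cos(theta))
  S <- mean(sin(theta))
  if (sqrt(C^2 + S^2) <= 1e-9) return(NA_real_)
  out <- (atan2(S, C) * period / (2 * pi)) %% period
  # floating-point wrap: a hair below the period is phase zero
  if (period - out < 1e-9) out <- 0
  out
}

#' Phase Set Enrichment Analysis
#'
#' Tests, for every gene set, whether the circadian phases of its
#' significantly rhythmic members cluster on the 24-h circle, using the
#' Kuiper test against a uniform background distribution. Member phases are
#' rounded to the full hour (half-up, 24 mapping to 0) before testing when
#' `round_phase = TRUE`; sets with fewer than `min_genes` rhythmic members
#' are excluded from testing. Benjamini-Hochberg adjustment is applied
#' across the tested sets only, and a set is called enriched when
#' `q < q_cut`. The vector-average (circular mean) phase of each tested
#' set's members is reported from the unrounded phases.
#'
#' @param fits A [rhythmicity_table()] result (needs `gene_id`, `phase_h`,
#'   `significant`).
#' @param sets A [gene_set_collection()].
#' @param min_genes Minimum number of rhythmic members for a set to be
#'   tested (default 5).
#' @param q_cut FDR threshold for enrichment (default 0.05).
#' @param round_phase Round phases to the full hour before testing
#'   (default `TRUE`).
#' @return A `data.frame` of class `PseaTable`, one row per set in input
#'   order: `set`, `n_rhythmic`, `kuiper_V`, `kuiper_lambda`, `pvalue`,
#'   `qvalue`, `mean_phase_h`, `tested`, `enriched`, and `label` when the
#'   collection carries truth labels.
#' @export
run_psea <- function(fits, sets, min_genes = 5, q_cut = 0.05,
                     round_phase = TRUE) {
  stopifnot(is.data.frame(fits),
            all(c("gene_id", "phase_h", "significant") %in% names(fits)))
  if (!inherits(sets, "GeneSetCollection") || length(sets) == 0)
    stop("`sets` must be a non-empty GeneSetCollection")
  sig <- fits[fits$significant & !is.na(fits$phase_h), ]
  phase_of <- stats::setNames(sig$phase_h, sig$gene_id)

  res <- data.frame(set = names(sets), n_rhythmic = 0L,
                    kuiper_V = NA_real_, kuiper_lambda = NA_real_,
                    pvalue = NA_real_, qvalue = NA_real_,
                    mean_phase_h = NA_real_, tested = FALSE,
                    enriched = FALSE, stringsAsFactors = FALSE)
  for (k in seq_along(sets$sets)) {
    ph <- phase_of[intersect(sets$sets[[k]], names(phase_of))]
    res$n_rhythmic[k] <- length(ph)
    if (length(ph) < min_genes) next
    res$tested[k] <- TRUE
    ph_test <- if (round_phase) floor(ph + 0.5) %% 24 else ph
    u <- (ph_test %% 24) / 24
    V <- kuiper_statistic(u)
    res$kuiper_V[k] <- V
    res$kuiper_lambda[k] <-
      (sqrt(length(u)) + 0.155 + 0.24 / sqrt(length(u))) * V
    res$pvalue[k] <- kuiper_pvalue(V, length(u))
    res$mean_phase_h[k] <- circular_mean_phase(ph)
  }
  if (any(res$tested)) {
    res$qvalue[res$tested] <- bh_adjust(res$pvalue[res$tested])
    res$enriched <- res$tested & !is.na(res$qvalue) & res$qvalue < q_cut
  }
  if (!is.null(sets$label)) res$label <- unname(sets$label[res$set])
  class(res) <- c("PseaTable", "data.frame")
  res
}
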