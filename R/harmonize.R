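#' Fit Training Distribution Matching parameters
#'
#' Training Distribution Matching (TDM) makes a wide-dynamic-range dataset
#' (log2 CPM from sequencing) comparable to a reference dataset (bounded
#' log2 microarray intensities) by a single monotone map fitted on the
#' pooled values of each matrix. The reference's inter-quartile range (IQR)
#' and the relative spread of its tails,
#' `spread_low = (q1 - min)/iqr` and `spread_high = (max - q3)/iqr`,
#' define clamp bounds on the target,
#' `clamp_low = target_q1 - spread_low * target_iqr` and
#' `clamp_high = target_q3 + spread_high * target_iqr`; [apply_tdm()] then
#' clamps and linearly rescales into the reference range.
#'
#' Both matrices should be restricted to the commonly expressed genes before
#' fitting.
#'
#' @param reference An [expression_matrix()] on a log2 scale (the intensity
#'   platform).
#' @param target An [expression_matrix()] on the `"log2-cpm"` scale.
#' @return A `TDMParams` list with the reference extremes/quartiles, tail
#'   spreads, target quartiles and clamp bounds.
#' @export
fit_tdm <- function(reference, target) {
  stopifnot(inherits(reference, "ExpressionMatrix"),
            inherits(target, "ExpressionMatrix"))
  rv <- as.numeric(reference$values)
  tv <- as.numeric(target$values)
  rq <- stats::quantile(rv, c(0.25, 0.75), names = FALSE)
  tq <- stats::quantile(tv, c(0.25, 0.75), names = FALSE)
  ref_iqr <- rq[2] - rq[1]
  target_iqr <- tq[2] - tq[1]
  if (ref_iqr <= 0) stop("degenerate reference distribution (IQR = 0)")
  if (target_iqr <= 0) stop("degenerate target distribution (IQR = 0)")
  spread_low <- (rq[1] - min(rv)) / ref_iqr
  spread_high <- (max(rv) - rq[2]) / ref_iqr
  structure(list(
    ref_min = min(rv), ref_max = max(rv),
    ref_q1 = rq[1], ref_q3 = rq[2], ref_iqr = ref_iqr,
    spread_low = spread_low, spread_high = spread_high,
    target_q1 = tq[1], target_q3 = tq[2], target_iqr = target_iqr,
    clamp_low = tq[1] - spread_low * target_iqr,
    clamp_high = tq[2] + spread_high * target_iqr),
    class = "TDMParams")
}

#' Apply a fitted TDM transform
#'
#' Every value is clamped into `[clamp_low, clamp_high]` and the clamped
#' matrix is linearly rescaled so that its observed extremes map onto
#' `[ref_min, ref_max]` — one global map for the whole matrix, preserving
#' rank order (and hence within-gene and within-sample dependencies) among
#' unclamped values. When values reach both clamp bounds, the output
#' extremes equal the reference extremes exactly.
#'
#' @param target An [expression_matrix()] on the `"log2-cpm"` scale.
#' @param params A [fit_tdm()] object fitted on the same gene universe.
#' @return An `ExpressionMatrix` on scale `"log2-intensity-matched"`.
#' @export
apply_tdm <- function(target, params) {
  stopifnot(inherits(target, "ExpressionMatrix"),
            inherits(params, "TDMParams"))
  v <- pmin(pmax(target$values, params$clamp_low), params$clamp_high)
  lo <- min(v)
  hi <- max(v)
  if (hi <= lo) stop("clamped target is constant; cannot rescale")
  out <- target
  out$values <- (v - lo) / (hi - lo) * (params$ref_max - params$ref_min) +
    params$ref_min
  out$scale <- "log2-intensity-matched"
  out
}

#' Pooled Kolmogorov-Smirnov distance between two matrices
#'
#' Supremum distance between the empirical CDFs of all pooled values of two
#' matrices; used to quantify how closely the transformed count platform
#' matches the intensity platform's distribution.
#'
#' @param a,b [expression_matrix()] objects or numeric vectors/matrices.
#' @return The KS distance in `[0, 1]`.
#' @export
ks_distance <- function(a, b) {
  va <- if (inherits(a, "ExpressionMatrix")) as.numeric(a$values) else
    as.numeric(a)
  vb <- if (inherits(b, "ExpressionMatrix")) as.numeric(b$values) else
    as.numeric(b)
  grid <- sort(c(va, vb))
  Fa <- stats::ecdf(va)
  Fb <- stats::ecdf(vb)
  max(abs(Fa(grid) - Fb(grid)))
}

#' Normalize each gene to its mean over a shared time window
#'
#' Maps the matrix to the linear scale (`2^x` for log2 scales) and divides
#' each gene's values by that gene's mean over the samples whose time lies
#' inside `shared_window` (boundaries inclusive; default 12-24 h, the window
#' covered by both platform designs). After this, both platforms have
#' per-gene shared-window mean 1, so their concatenation carries no platform
#' offset in the window.
#'
#' @param em An [expression_matrix()].
#' @param shared_window Two-element hours interval (default `c(12, 24)`).
#' @return An `ExpressionMatrix` on scale `"linear-normalized"` with
#'   attribute `shared_window`.
#' @export
normalize_to_shared <- function(em, shared_window = c(12, 24)) {
  stopifnot(inherits(em, "ExpressionMatrix"), length(shared_window) == 2,
            shared_window[1] <= shared_window[2])
  lin <- to_linear(em)
  in_win <- lin$time_h >= shared_window[1] & lin$time_h <= shared_window[2]
  if (!any(in_win))
    stop("no samples inside the shared window [",
         shared_window[1], ", ", shared_window[2], "] h")
  mu <- rowMeans(lin$values[, in_win, drop = FALSE])
  bad <- !(mu > 0)
  if (any(bad))
    stop("non-positive shared-window mean for gene(s): ",
         paste(utils::head(rownames(lin$values)[bad], 5), collapse = ", "))
  out <- lin
  out$values <- lin$values / mu
  out$scale <- "linear-normalized"
  attr(out, "shared_window") <- shared_window
  out
}

#' Concatenate two shared-window-normalized platforms into one time series
#'
#' Pools the samples of both matrices over the union time grid, restricted
#' to the genes present in both; samples taken at equal wall times form
#' replicate groups and enter downstream harmonic regression as independent
#' replicate measurements. Platform provenance is retained per sample.
#'
#' @param ref_norm,target_norm [normalize_to_shared()] outputs (scale
#'   `"linear-normalized"`) sharing the same window.
#' @return A `ConcatenatedSeries` (also an `ExpressionMatrix`) ordered by
#'   time, with attributes `replicate_groups` (samples per time point) and
#'   `shared_window`.
#' @export
concatenate_series <- function(ref_norm, target_norm) {
  stopifnot(inherits(ref_norm, "ExpressionMatrix"),
            inherits(target_norm, "ExpressionMatrix"))
  if (ref_norm$scale != "linear-normalized" ||
      target_norm$scale != "linear-normalized")
    stop("both inputs must be normalized to the shared window first")
  genes <- intersect(rownames(ref_norm$values), rownames(target_norm$values))
  if (length(genes) == 0) stop("disjoint gene sets; nothing to concatenate")
  v <- cbind(ref_norm$values[genes, , drop = FALSE],
             target_norm$values[genes, , drop = FALSE])
  time_h <- c(ref_norm$time_h, target_norm$time_h)
  platform <- c(ref_norm$platform, target_norm$platform)
  ord <- order(time_h, names(time_h))
  out <- expression_matrix(v[, ord, drop = FALSE], time_h = time_h[ord],
                           platform = platform[ord],
                           scale = "linear-normalized")
  class(out) <- c("ConcatenatedSeries", class(out))
  attr(out, "replicate_groups") <- split(colnames(out$values), out$time_h)
  attr(out, "shared_window") <- attr(ref_norm, "shared_window")
  out
}

#' Harmonize two platforms end to end
#'
#' Convenience wrapper for the whole cross-platform stage on commonly
#' expressed genes: fit and apply TDM (count platform onto the intensity
#' platform), normalize each platform to the shared-window mean, and
#' concatenate.
#'
#' @param intensity A filtered [expression_matrix()] on scale
#'   `"log2-intensity"`.
#' @param counts_log_cpm A filtered `ExpressionMatrix` on scale
#'   `"log2-cpm"`.
#' @param shared_window Hours interval shared by both designs (default
#'   `c(12, 24)`).
#' @return A list with elements `concat` (the [concatenate_series()]
#'   output), `tdm` (the fitted [fit_tdm()] parameters), and the two
#'   normalized platform matrices `ref_norm` and `target_norm`.
#' @export
harmonize_platforms <- function(intensity, counts_log_cpm,
                                shared_window = c(12, 24)) {
  genes <- intersect(rownames(intensity$values),
                     rownames(counts_log_cpm$values))
  if (length(genes) == 0) stop("no commonly expressed genes")
  ref <- intensity[genes, ]
  tgt <- counts_log_cpm[genes, ]
  tdm <- fit_tdm(ref, tgt)
  tgt_matched <- apply_tdm(tgt, tdm)
  ref_norm <- normalize_to_shared(ref, shared_window)
  tgt_norm <- normalize_to_shared(tgt_matched, shared_window)
  list(concat = concatenate_series(ref_norm, tgt_norm),
       tdm = tdm, ref_norm = ref_norm, target_norm = tgt_norm)
}
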