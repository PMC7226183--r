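#' Collapse feature-level rows to gene level
#'
#' When several measured features (e.g. transcript clusters or probe sets)
#' annotate the same gene, the feature with the highest mean value over all
#' samples represents the gene. Ties are broken toward the lexicographically
#' smallest feature id so the choice is deterministic. Features absent from
#' the mapping are dropped.
#'
#' @param em An [expression_matrix()] keyed by feature ids.
#' @param feature_to_gene Data frame with columns `feature_id` and `gene_id`
#'   (each feature maps to at most one gene), or a named character vector
#'   (names = feature ids, values = gene ids).
#' @return An `ExpressionMatrix` keyed by gene ids, one row per mapped gene.
#' @export
collapse_features <- function(em, feature_to_gene) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (is.character(feature_to_gene) && !is.null(names(feature_to_gene))) {
    feature_to_gene <- data.frame(feature_id = names(feature_to_gene),
                                  gene_id = unname(feature_to_gene),
                                  stringsAsFactors = FALSE)
  }
  if (!is.data.frame(feature_to_gene) ||
      !all(c("feature_id", "gene_id") %in% names(feature_to_gene)) ||
      nrow(feature_to_gene) == 0)
    stop("`feature_to_gene` must be a non-empty feature_id/gene_id mapping")
  if (anyDuplicated(feature_to_gene$feature_id))
    stop("each feature must map to at most one gene")

  map <- feature_to_gene[feature_to_gene$feature_id %in% rownames(em$values), ]
  if (nrow(map) == 0) stop("no mapped features present in the matrix")
  means <- rowMeans(em$values)[map$feature_id]
  # order: gene, then decreasing mean, then feature id; first row per gene wins
  ord <- order(map$gene_id, -means, map$feature_id)
  map <- map[ord, ]
  keep <- map[!duplicated(map$gene_id), ]
  out <- em
  out$values <- em$values[keep$feature_id, , drop = FALSE]
  rownames(out$values) <- keep$gene_id
  out
}

#' TMM scaling factors for a count matrix
#'
#' Computes trimmed-mean-of-M-values normalization factors through
#' [edgeR::calcNormFactors()]: M- and A-values against a reference sample
#' (by default the sample whose upper quartile is closest to the mean upper
#' quartile), 30 percent two-sided trim on M and 5 percent on A, weighted
#' mean of the retained M-values, and centering so the factors have
#' geometric mean 1.
#'
#' @param counts An [expression_matrix()] on the `"counts"` scale with at
#'   least two samples.
#' @param reference_sample Optional sample id to use as the TMM reference.
#' @return A `NormFactors` list with elements `factors` (named, geometric
#'   mean 1), `lib_size` (column totals) and `effective_lib_size`
#'   (`lib_size * factors`).
#' @export
tmm_factors <- function(counts, reference_sample = NULL) {
  stopifnot(inherits(counts, "ExpressionMatrix"))
  if (counts$scale != "counts") stop("`counts` must be on the counts scale")
  if (ncol(counts$values) < 2) stop("TMM needs at least two samples")
  zero <- colSums(counts$values) == 0
  if (any(zero))
    stop("all-zero sample(s): ",
         paste(colnames(counts$values)[zero], collapse = ", "))
  ref_col <- NULL
  if (!is.null(reference_sample)) {
    ref_col <- match(reference_sample, colnames(counts$values))
    if (is.na(ref_col)) stop("unknown reference sample: ", reference_sample)
  }
  f <- edgeR::calcNormFactors(counts$values, method = "TMM",
                              refColumn = ref_col)
  lib <- colSums(counts$values)
  structure(list(factors = stats::setNames(f, colnames(counts$values)),
                 lib_size = lib,
                 effective_lib_size = lib * f),
            class = "NormFactors")
}

# linear CPM on effective library sizes (no pseudo-count)
.cpm_linear <- function(counts, factors) {
  sweep(counts$values, 2, factors$effective_lib_size, `/`) * 1e6
}

#' log2 counts per million with a library-scaled pseudo-count
#'
#' Follows the standard CPM convention (as in [edgeR::cpm()]): the
#' pseudo-count is scaled per sample by the effective library size relative
#' to the average library, then
#' `log2((count + prior_s) / (lib_s + 2 * prior_s) * 1e6)`.
#' With `prior_count = 0` this is plain `log2(CPM)` (zero counts map to
#' `-Inf`).
#'
#' @param counts An [expression_matrix()] on the `"counts"` scale.
#' @param factors A [tmm_factors()] object aligned with the samples.
#' @param prior_count Non-negative pseudo-count (default 0.5).
#' @return An `ExpressionMatrix` on scale `"log2-cpm"`.
#' @export
log_cpm <- function(counts, factors, prior_count = 0.5) {
  stopifnot(inherits(counts, "ExpressionMatrix"),
            inherits(factors, "NormFactors"))
  if (counts$scale != "counts") stop("`counts` must be on the counts scale")
  if (prior_count < 0) stop("`prior_count` must be non-negative")
  if (!identical(names(factors$factors), colnames(counts$values)))
    stop("`factors` are not aligned with the samples")
  eff <- factors$effective_lib_size
  prior <- prior_count * eff / mean(eff)
  v <- log2(sweep(sweep(counts$values, 2, prior, `+`),
                  2, eff + 2 * prior, `/`) * 1e6)
  out <- counts
  out$values <- v
  out$scale <- "log2-cpm"
  out
}

#' Filter genes by mean expression
#'
#' Retains genes whose mean value over all samples is at least `cutoff`
#' (boundary inclusive). For count matrices the mean is evaluated on linear
#' CPM (computed with TMM factors, no pseudo-count) and the returned matrix
#' still holds the retained raw counts, ready for renormalization on the
#' reduced gene set; for any other scale the mean is taken on the values as
#' given.
#'
#' @param em An [expression_matrix()].
#' @param cutoff Threshold on the per-gene mean (CPM for counts, matrix
#'   units otherwise); `-Inf` disables the filter.
#' @param factors Optional [tmm_factors()] for counts input; computed when
#'   missing.
#' @return The filtered `ExpressionMatrix` (same scale as the input).
#' @export
filter_expressed <- function(em, cutoff, factors = NULL) {
  stopifnot(inherits(em, "ExpressionMatrix"), !is.na(cutoff), cutoff < Inf)
  if (em$scale == "counts") {
    if (is.null(factors)) factors <- tmm_factors(em)
    means <- rowMeans(.cpm_linear(em, factors))
  } else {
    means <- rowMeans(em$values)
  }
  keep <- means >= cutoff
  if (!any(keep))
    stop(sprintf("expression filter at %g removed all %d genes", cutoff,
                 nrow(em$values)))
  em[keep, ]
}

#' Preprocess a count platform: TMM, CPM filter, renormalized log2 CPM
#'
#' The full count-side preprocessing chain: compute TMM factors, drop genes
#' below `cpm_cutoff` mean CPM over all samples, then renormalize using only
#' the retained genes (TMM factors and CPM recomputed on the reduced
#' matrix) and return log2 CPM.
#'
#' @param counts An [expression_matrix()] on the `"counts"` scale.
#' @param cpm_cutoff Mean-CPM expression cut-off (default 0.5).
#' @param prior_count Pseudo-count for the final log transform (default 0.5).
#' @return A list with elements `log_cpm` (`ExpressionMatrix`, scale
#'   `"log2-cpm"`), `counts` (retained raw counts) and `factors` (the
#'   recomputed [tmm_factors()]).
#' @export
preprocess_counts <- function(counts, cpm_cutoff = 0.5, prior_count = 0.5) {
  f0 <- tmm_factors(counts)
  kept <- filter_expressed(counts, cpm_cutoff, factors = f0)
  f1 <- tmm_factors(kept)
  list(log_cpm = log_cpm(kept, f1, prior_count = prior_count),
       counts = kept, factors = f1)
}

#' Preprocess an intensity platform: mean-intensity filter
#'
#' Retains genes whose mean log2 intensity over all samples is at least
#' `cutoff` (default 3, boundary inclusive).
#'
#' @param intensity An [expression_matrix()] on the `"log2-intensity"` scale.
#' @param cutoff Mean log2-intensity cut-off (default 3).
#' @return The filtered `ExpressionMatrix`.
#' @export
preprocess_intensity <- function(intensity, cutoff = 3) {
  stopifnot(inherits(intensity, "ExpressionMatrix"))
  if (intensity$scale != "log2-intensity")
    stop("`intensity` must be on the log2-intensity scale")
  filter_expressed(intensity, cutoff)
}
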