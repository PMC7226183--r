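#' Expression matrix with per-sample time and platform metadata
#'
#' The central data container of the package: a numeric genes x samples
#' matrix together with the hours-since-synchronization and platform label of
#' every sample, and a scale tag saying what the numbers mean. All pipeline
#' stages consume and produce this container.
#'
#' @param values Numeric matrix, genes in rows (unique rownames = gene ids),
#'   samples in columns (unique colnames = sample ids). No missing values.
#' @param time_h Numeric vector of sampling times in hours after
#'   synchronization, one per column of `values`, all `>= 0`.
#' @param platform Character scalar or vector: platform label per sample
#'   (e.g. `"microarray"`, `"rnaseq"`).
#' @param scale One of `"counts"`, `"log2-cpm"`, `"log2-intensity"`,
#'   `"log2-intensity-matched"`, `"linear"`, `"linear-normalized"`. On the
#'   `"counts"` scale values must be non-negative integers.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `time_h`, `platform`, `scale`.
#' @examples
#' m <- matrix(1:12, 3, 4, dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' em <- expression_matrix(m, time_h = c(0, 3, 6, 9), platform = "demo",
#'                         scale = "counts")
#' dim(em)
#' @export
expression_matrix <- function(values, time_h, platform, scale) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("`values` must have unique rownames (gene ids)")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("`values` must have unique colnames (sample ids)")
  if (anyNA(values)) stop("`values` must not contain missing values")
  scale <- match.arg(scale, c("counts", "log2-cpm", "log2-intensity",
                              "log2-intensity-matched", "linear",
                              "linear-normalized"))
  if (scale == "counts") {
    if (any(values < 0)) stop("counts must be non-negative")
    if (any(abs(values - round(values)) > 1e-8))
      stop("counts must be integer-valued")
  }
  if (length(time_h) != ncol(values))
    stop("`time_h` must have one entry per sample")
  if (any(!is.finite(time_h)) || any(time_h < 0))
    stop("`time_h` must be finite and >= 0")
  if (length(platform) == 1L) platform <- rep(platform, ncol(values))
  if (length(platform) != ncol(values))
    stop("`platform` must have one entry per sample")
  structure(
    list(values = values,
         time_h = stats::setNames(as.numeric(time_h), colnames(values)),
         platform = stats::setNames(as.character(platform), colnames(values)),
         scale = scale),
    class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
dimnames.ExpressionMatrix <- function(x) dimnames(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat(sprintf("  platforms: %s\n",
              paste(unique(x$platform), collapse = ", ")))
  tt <- sort(unique(x$time_h))
  cat(sprintf("  times (h): %s\n", paste(tt, collapse = ", ")))
  invisible(x)
}

#' Subset an ExpressionMatrix by genes and/or samples
#'
#' @param x An [expression_matrix()].
#' @param i Gene (row) index: integer, logical or character.
#' @param j Sample (column) index.
#' @param ... Ignored.
#' @return An `ExpressionMatrix` restricted to the selected rows/columns.
#' @export
`[.ExpressionMatrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  out <- x
  out$values <- x$values[i, j, drop = FALSE]
  out$time_h <- x$time_h[j]
  out$platform <- x$platform[j]
  out
}

#' Map an ExpressionMatrix to the linear abundance scale
#'
#' Rhythm fitting operates on untransformed (linear, positive) abundances:
#' relative amplitude is only meaningful there. log2 scales are exponentiated
#' (`2^x`); counts and linear scales pass through unchanged apart from the
#' scale tag.
#'
#' @param x An [expression_matrix()].
#' @return The same matrix on scale `"linear"` (or `"linear-normalized"`,
#'   which is left untouched).
#' @export
to_linear <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$scale == "linear-normalized") return(x)
  if (startsWith(x$scale, "log2")) x$values <- 2^x$values
  x$scale <- "linear"
  x
}

#' Write / read an ExpressionMatrix as TSV
#'
#' The matrix file has a `gene_id` first column followed by one column per
#' sample; the companion sample sheet has columns `sample_id`, `time_h`,
#' `platform`. Plain tab-separated text, no quoting.
#'
#' @param em An [expression_matrix()].
#' @param file Path of the matrix TSV.
#' @param sample_file Optional path of the sample sheet TSV (written by
#'   `write_expression_matrix` when given; required by
#'   `read_expression_matrix`).
#' @param scale Scale tag to assign on reading.
#' @return `write_expression_matrix` returns `file` invisibly;
#'   `read_expression_matrix` returns an `ExpressionMatrix`.
#' @export
write_expression_matrix <- function(em, file, sample_file = NULL) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  df <- data.frame(gene_id = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sample_file)) write_sample_sheet(em, sample_file)
  invisible(file)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(file, sample_file, scale) {
  df <- utils::read.delim(file, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  ss <- utils::read.delim(sample_file, stringsAsFactors = FALSE)
  need <- c("sample_id", "time_h", "platform")
  if (!all(need %in% names(ss)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  miss <- setdiff(colnames(m), ss$sample_id)
  if (length(miss))
    stop("samples missing from sample sheet: ", paste(miss, collapse = ", "))
  ss <- ss[match(colnames(m), ss$sample_id), ]
  expression_matrix(m, time_h = ss$time_h, platform = ss$platform,
                    scale = scale)
}

#' @rdname write_expression_matrix
#' @export
write_sample_sheet <- function(em, file) {
  utils::write.table(
    data.frame(sample_id = colnames(em$values), time_h = em$time_h,
               platform = em$platform, stringsAsFactors = FALSE),
    file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Circular distance between clock times
#'
#' Shortest distance on the 24-h circle (or an arbitrary period), i.e.
#' `min(|a - b| mod T, T - |a - b| mod T)`.
#'
#' @param a,b Numeric vectors of times (hours); recycled.
#' @param period Period in hours (default 24).
#' @return Numeric vector of distances in `[0, period/2]`.
#' @examples
#' circular_distance(23, 1)  # 2
#' @export
circular_distance <- function(a, b, period = 24) {
  d <- abs(a - b) %% period
  pmin(d, period - d)
}
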