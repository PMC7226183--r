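#' Named gene-set collection (GMT semantics)
#'
#' Holds named sets of gene ids, with optional per-set descriptions and, for
#' simulated collections, ground-truth labels (`"clustered"`/`"null"`).
#'
#' @param sets Named list of character vectors of gene ids; set names must be
#'   unique and members unique within each set.
#' @param description Optional named character vector of descriptions.
#' @param label Optional named character vector of truth labels.
#' @return A `GeneSetCollection` object.
#' @export
gene_set_collection <- function(sets, description = NULL, label = NULL) {
  if (!is.list(sets) || length(sets) == 0)
    stop("`sets` must be a non-empty named list")
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("set names must be present and unique")
  if (any(vapply(sets, anyDuplicated, 1L) > 0))
    stop("members must be unique within a set")
  structure(list(sets = sets, description = description, label = label),
            class = "GeneSetCollection")
}

#' @export
length.GeneSetCollection <- function(x) length(x$sets)

#' @export
names.GeneSetCollection <- function(x) names(x$sets)

#' @export
print.GeneSetCollection <- function(x, ...) {
  sz <- lengths(x$sets)
  cat(sprintf("GeneSetCollection: %d sets (sizes %d-%d)\n",
              length(x$sets), min(sz), max(sz)))
  if (!is.null(x$label)) print(table(x$label))
  invisible(x)
}

#' Read / write gene sets in GMT format
#'
#' GMT is the tab-separated gene-set format: one set per line, fields
#' `name`, `description`, then the member gene ids. Reading is delegated to
#' [fgsea::gmtPathways()] (which discards the description field); writing
#' emits standard GMT lines.
#'
#' @param file Path to a `.gmt` file.
#' @param x A [gene_set_collection()].
#' @return `read_gmt` returns a `GeneSetCollection`; `write_gmt` returns
#'   `file` invisibly.
#' @export
read_gmt <- function(file) {
  sets <- fgsea::gmtPathways(file)
  gene_set_collection(sets)
}

#' @rdname read_gmt
#' @export
write_gmt <- function(x, file) {
  stopifnot(inherits(x, "GeneSetCollection"))
  desc <- x$description
  if (is.null(desc)) desc <- stats::setNames(rep("na", length(x$sets)),
                                             names(x$sets))
  lines <- vapply(names(x$sets), function(nm) {
    paste(c(nm, desc[[nm]], x$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, file)
  invisible(file)
}
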