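#' Protein quantification table
#'
#' A `quant_table` bundles a protein-group x sample LFQ intensity matrix with
#' the parallel matrix of unique-precursor counts and protein-group
#' annotation, in the spirit of the list-based expression containers used by
#' mainstream omics packages. Intensities are stored either on the linear
#' scale (as produced by the search engine) or on the log2 scale; the `scale`
#' flag guards against double transformation.
#'
#' Missing quantifications are `NA` cells in `lfq`; by convention a missing
#' cell always carries a precursor count of 0. Precursor counts may be `NA`
#' when the input dialect does not report them (see [read_report()]); such
#' cells pass the precursor filter unexamined.
#'
#' @param lfq numeric matrix, proteins in rows, samples in columns. Column
#'   names are sample ids, row names protein-group ids.
#' @param precursors integer matrix of unique-precursor counts, same shape as
#'   `lfq`, or `NULL` for all-unknown counts.
#' @param proteins data.frame with columns `protein_id` and `gene`
#'   (semicolon-joined symbols for shared groups), one row per `lfq` row, or
#'   `NULL` to derive it from the row names.
#' @param scale `"linear"` or `"log2"`.
#' @return An object of class `quant_table`: a list with elements `lfq`,
#'   `precursors`, `proteins` and `scale`.
#' @export
quant_table <- function(lfq, precursors = NULL, proteins = NULL,
                        scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(lfq) || !is.numeric(lfq)) {
    stop("'lfq' must be a numeric matrix")
  }
  if (is.null(rownames(lfq))) {
    if (nrow(lfq) > 0) stop("'lfq' must have protein-group row names")
    rownames(lfq) <- character(0)
  }
  if (anyDuplicated(rownames(lfq))) {
    stop("duplicated protein group id(s): ",
         paste(unique(rownames(lfq)[duplicated(rownames(lfq))]),
               collapse = ", "))
  }
  if (is.null(colnames(lfq))) {
    stop("'lfq' must have sample column names")
  }
  if (is.null(precursors)) {
    precursors <- matrix(NA_real_, nrow(lfq), ncol(lfq),
                         dimnames = dimnames(lfq))
  }
  if (!identical(dim(precursors), dim(lfq))) {
    stop("'precursors' and 'lfq' must share dimensions")
  }
  dimnames(precursors) <- dimnames(lfq)
  # missing quantification implies no usable precursor evidence
  precursors[is.na(lfq)] <- 0
  if (any(precursors < 0, na.rm = TRUE)) {
    stop("precursor counts must be non-negative")
  }
  if (is.null(proteins)) {
    proteins <- data.frame(protein_id = rownames(lfq),
                           gene = rownames(lfq),
                           stringsAsFactors = FALSE)
  }
  if (!all(c("protein_id", "gene") %in% names(proteins)) ||
      nrow(proteins) != nrow(lfq)) {
    stop("'proteins' needs columns protein_id, gene and one row per protein")
  }
  if (nrow(lfq) > 0 &&
      !identical(as.character(proteins$protein_id), rownames(lfq))) {
    stop("'proteins$protein_id' must match rownames(lfq) in order")
  }
  structure(list(lfq = lfq, precursors = precursors,
                 proteins = proteins, scale = scale),
            class = "quant_table")
}

#' @export
dim.quant_table <- function(x) dim(x$lfq)

#' @export
print.quant_table <- function(x, ...) {
  cat(sprintf("quant_table: %d protein groups x %d samples (%s scale)\n",
              nrow(x$lfq), ncol(x$lfq), x$scale))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", sum(is.na(x$lfq)),
              100 * mean(is.na(x$lfq))))
  invisible(x)
}

#' Subset a quant_table
#'
#' @param x a [quant_table()].
#' @param i,j protein (row) and sample (column) indices.
#' @param ... ignored.
#' @return the subsetted `quant_table`.
#' @export
`[.quant_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$lfq))
  if (missing(j)) j <- seq_len(ncol(x$lfq))
  quant_table(x$lfq[i, j, drop = FALSE],
              x$precursors[i, j, drop = FALSE],
              x$proteins[i, , drop = FALSE],
              scale = x$scale)
}

#' Log2-transform a linear-scale quantification table
#'
#' Present intensities are replaced by their base-2 logarithm; missing cells
#' stay missing. Applying the transform twice is an error, caught via the
#' scale flag.
#'
#' @param table a linear-scale [quant_table()].
#' @return the table on the log2 scale.
#' @export
log2_transform <- function(table) {
  stopifnot(inherits(table, "quant_table"))
  if (table$scale == "log2") {
    stop("table is already log2 scale; refusing to transform twice")
  }
  if (any(table$lfq <= 0, na.rm = TRUE)) {
    stop("non-positive intensity present; cannot log2 transform")
  }
  table$lfq <- log2(table$lfq)
  table$scale <- "log2"
  table
}
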