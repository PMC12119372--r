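#' Read a sample sheet
#'
#' The sample sheet maps each MS run to a subject and design cell: columns
#' `sample_id`, `subject_id`, `cohort` (one of `infant`, `adult`, `qc`),
#' `group` (`SGA`, `AGA`, or empty for non-infants) and `day` (postnatal day
#' for infant samples; empty for adult and QC runs).
#'
#' @param path path to a CSV (or TSV) file with the header above.
#' @return a validated data.frame with one row per sample; `day` is numeric
#'   (`NA` for adult/QC runs) and `group` is `NA` where not applicable.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  sheet <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, na.strings = c("NA", ""))
  validate_sample_sheet(sheet)
}

#' Validate a sample sheet data.frame
#'
#' @param sheet data.frame with columns sample_id, subject_id, cohort, group,
#'   day.
#' @return the sheet, with `day` coerced to numeric, invisibly checked.
#' @export
validate_sample_sheet <- function(sheet) {
  required <- c("sample_id", "subject_id", "cohort", "group", "day")
  missing_cols <- setdiff(required, names(sheet))
  if (length(missing_cols)) {
    stop("sample sheet is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  sheet$sample_id <- as.character(sheet$sample_id)
  sheet$subject_id <- as.character(sheet$subject_id)
  sheet$day <- suppressWarnings(as.numeric(sheet$day))
  if (anyDuplicated(sheet$sample_id)) {
    stop("duplicated sample id(s): ",
         paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]),
               collapse = ", "))
  }
  bad_cohort <- setdiff(unique(sheet$cohort), c("infant", "adult", "qc"))
  if (length(bad_cohort)) {
    stop("unknown cohort label(s): ", paste(bad_cohort, collapse = ", "))
  }
  inf <- sheet$cohort == "infant"
  if (any(is.na(sheet$day[inf]))) {
    stop("infant sample(s) without a postnatal day: ",
         paste(sheet$sample_id[inf & is.na(sheet$day)], collapse = ", "))
  }
  if (any(!is.na(sheet$day[!inf]))) {
    stop("adult/qc sample(s) must not carry a day: ",
         paste(sheet$sample_id[!inf & !is.na(sheet$day)], collapse = ", "))
  }
  key <- paste(sheet$subject_id[inf], sheet$day[inf])
  if (anyDuplicated(key)) {
    stop("duplicated (subject, day) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  sheet
}

#' Read a protein-group quantification report
#'
#' Two report dialects are supported, both derived from DIA-NN style output:
#' \describe{
#'   \item{`wide_matrix`}{TSV with columns `Protein.Group`, `Genes`, then one
#'     intensity column per sample. Unique-precursor counts may be supplied
#'     as a second TSV of identical layout via `precursor_path`; without it
#'     counts are unknown (`NA`) and the precursor filter leaves those cells
#'     alone.}
#'   \item{`long_report`}{TSV with columns `Protein.Group`, `Genes`,
#'     `Sample`, `LFQ`, `Unique.Precursors`, one row per (protein, sample)
#'     quantification.}
#' }
#' Zero, empty or `NA` intensities are stored as missing cells, following the
#' usual LFQ convention that a zero is an absent quantification, not a
#' measured abundance.
#'
#' @param path path to the report TSV.
#' @param dialect `"wide_matrix"` or `"long_report"`.
#' @param sheet optional sample sheet (see [read_sample_sheet()]); when given,
#'   every sample column in the report must appear in the sheet.
#' @param precursor_path optional TSV of unique-precursor counts for the wide
#'   dialect.
#' @return a linear-scale [quant_table()].
#' @export
read_report <- function(path, dialect = c("wide_matrix", "long_report"),
                        sheet = NULL, precursor_path = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("report not found: ", path)
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  tab <- if (dialect == "wide_matrix") {
    parse_wide_report(raw, precursor_path)
  } else {
    parse_long_report(raw)
  }
  if (!is.null(sheet)) {
    unknown <- setdiff(colnames(tab$lfq), sheet$sample_id)
    if (length(unknown)) {
      stop("sample(s) in report absent from sample sheet: ",
           paste(unknown, collapse = ", "))
    }
  }
  tab
}

parse_wide_report <- function(raw, precursor_path) {
  need <- c("Protein.Group", "Genes")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("report is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  }
  if (anyDuplicated(raw$Protein.Group)) {
    stop("duplicated protein group(s) in report: ",
         paste(unique(raw$Protein.Group[duplicated(raw$Protein.Group)]),
               collapse = ", "))
  }
  sample_cols <- setdiff(names(raw), need)
  if (!length(sample_cols)) stop("report has no sample columns")
  lfq <- as.matrix(raw[, sample_cols, drop = FALSE])
  storage.mode(lfq) <- "double"
  rownames(lfq) <- raw$Protein.Group
  lfq[!is.na(lfq) & lfq == 0] <- NA  # zero-as-missing convention
  prec <- NULL
  if (!is.null(precursor_path)) {
    praw <- utils::read.delim(precursor_path, check.names = FALSE,
                              stringsAsFactors = FALSE)
    pm <- as.matrix(praw[, sample_cols, drop = FALSE])
    storage.mode(pm) <- "double"
    rownames(pm) <- praw$Protein.Group
    prec <- pm[rownames(lfq), colnames(lfq), drop = FALSE]
    prec[is.na(prec)] <- 0
  }
  quant_table(lfq, prec,
              data.frame(protein_id = raw$Protein.Group,
                         gene = as.character(raw$Genes),
                         stringsAsFactors = FALSE),
              scale = "linear")
}

parse_long_report <- function(raw) {
  need <- c("Protein.Group", "Genes", "Sample", "LFQ", "Unique.Precursors")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("report is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  }
  key <- paste(raw$Protein.Group, raw$Sample, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- raw[duplicated(key), c("Protein.Group", "Sample")][1, ]
    stop("duplicated (protein, sample) row(s) in long report, e.g. ",
         dup$Protein.Group, " / ", dup$Sample)
  }
  proteins <- unique(raw$Protein.Group)
  samples <- unique(raw$Sample)
  lfq <- matrix(NA_real_, length(proteins), length(samples),
                dimnames = list(proteins, samples))
  prec <- matrix(0, length(proteins), length(samples),
                 dimnames = list(proteins, samples))
  ri <- match(raw$Protein.Group, proteins)
  ci <- match(raw$Sample, samples)
  lfq[cbind(ri, ci)] <- raw$LFQ
  prec[cbind(ri, ci)] <- raw$Unique.Precursors
  lfq[!is.na(lfq) & lfq == 0] <- NA
  genes <- raw$Genes[match(proteins, raw$Protein.Group)]
  quant_table(lfq, prec,
              data.frame(protein_id = proteins, gene = as.character(genes),
                         stringsAsFactors = FALSE),
              scale = "linear")
}

#' Write a quant_table as a wide TSV
#'
#' @param table a [quant_table()].
#' @param path output path; missing cells are written as empty fields.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(table, path) {
  stopifnot(inherits(table, "quant_table"))
  out <- data.frame(Protein.Group = table$proteins$protein_id,
                    Genes = table$proteins$gene,
                    table$lfq, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
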