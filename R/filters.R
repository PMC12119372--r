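#' Filtering parameters
#'
#' Bundles the quantification filters: LFQ values are kept only when backed
#' by at least `min_unique_precursors` unique precursors, and a protein is
#' considered accurately quantified in the infant cohort when identified in
#' at least `min_frac_per_timepoint` of infant samples at every postnatal day
#' and in at least `min_frac_per_group` of all infant samples; for adults
#' (a single "timepoint") only the per-group fraction applies.
#'
#' All boundaries are inclusive (">= 2 precursors", ">= 50%", ">= 40%").
#'
#' @param min_unique_precursors minimum unique precursors per quantified cell.
#' @param min_frac_per_timepoint minimum identification fraction per infant
#'   timepoint.
#' @param min_frac_per_group minimum identification fraction per cohort.
#' @return a list of class `filter_config`.
#' @export
filter_config <- function(min_unique_precursors = 2L,
                          min_frac_per_timepoint = 0.5,
                          min_frac_per_group = 0.4) {
  stopifnot(min_unique_precursors >= 1,
            min_frac_per_timepoint >= 0, min_frac_per_timepoint <= 1,
            min_frac_per_group >= 0, min_frac_per_group <= 1)
  structure(list(min_unique_precursors = as.integer(min_unique_precursors),
                 min_frac_per_timepoint = min_frac_per_timepoint,
                 min_frac_per_group = min_frac_per_group),
            class = "filter_config")
}

#' Drop quantifications with too few unique precursors
#'
#' Cells whose unique-precursor count falls below the threshold are set to
#' missing; no protein rows are removed at this step. Cells with unknown
#' (`NA`) counts are left untouched. The operation is idempotent.
#'
#' @param table a [quant_table()].
#' @param config a [filter_config()].
#' @return the filtered `quant_table`.
#' @export
filter_min_precursors <- function(table, config = filter_config()) {
  stopifnot(inherits(table, "quant_table"))
  drop <- !is.na(table$precursors) &
    table$precursors < config$min_unique_precursors
  table$lfq[drop] <- NA
  table$precursors[drop] <- 0
  table
}

#' Completeness filter with retention report
#'
#' A protein is retained for the infant cohort iff it is identified (present
#' after the precursor filter) in at least the per-timepoint fraction of
#' infant samples at every postnatal day AND in at least the per-group
#' fraction of all infant samples; it is retained for the adult cohort iff
#' identified in at least the per-group fraction of adult samples. Proteins
#' retained in neither cohort are removed. QC samples are exempt: they do not
#' count towards identification and QC columns are preserved in the output.
#'
#' @param table a [quant_table()] with the precursor filter already applied.
#' @param sheet a sample sheet covering the table's samples.
#' @param config a [filter_config()].
#' @return a list with elements `table` (rows retained in either cohort) and
#'   `report` (per protein: per-day identification fractions, per-cohort
#'   fractions and decisions).
#' @export
filter_completeness <- function(table, sheet, config = filter_config()) {
  stopifnot(inherits(table, "quant_table"))
  sheet <- sheet[sheet$sample_id %in% colnames(table$lfq), , drop = FALSE]
  present <- !is.na(table$lfq)

  inf <- sheet[sheet$cohort == "infant", , drop = FALSE]
  days <- sort(unique(inf$day))
  day_frac <- matrix(NA_real_, nrow(table$lfq), length(days),
                     dimnames = list(rownames(table$lfq),
                                     paste0("frac_day_", days)))
  for (k in seq_along(days)) {
    ids <- inf$sample_id[inf$day == days[k]]
    if (!length(ids)) stop("timepoint with zero infant samples: day ", days[k])
    day_frac[, k] <- rowMeans(present[, ids, drop = FALSE])
  }
  infant_frac <- if (nrow(inf)) {
    rowMeans(present[, inf$sample_id, drop = FALSE])
  } else rep(NA_real_, nrow(table$lfq))
  retained_infant <- if (nrow(inf)) {
    apply(day_frac >= config$min_frac_per_timepoint, 1, all) &
      infant_frac >= config$min_frac_per_group
  } else rep(FALSE, nrow(table$lfq))

  adu_ids <- sheet$sample_id[sheet$cohort == "adult"]
  adult_frac <- if (length(adu_ids)) {
    rowMeans(present[, adu_ids, drop = FALSE])
  } else rep(NA_real_, nrow(table$lfq))
  retained_adult <- if (length(adu_ids)) {
    adult_frac >= config$min_frac_per_group
  } else rep(FALSE, nrow(table$lfq))

  report <- data.frame(protein_id = table$proteins$protein_id,
                       gene = table$proteins$gene,
                       day_frac,
                       frac_infant = infant_frac,
                       frac_adult = adult_frac,
                       retained_infant = retained_infant,
                       retained_adult = retained_adult,
                       retained = retained_infant | retained_adult,
                       stringsAsFactors = FALSE, check.names = FALSE)
  rownames(report) <- NULL
  list(table = table[report$retained, ], report = report)
}
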