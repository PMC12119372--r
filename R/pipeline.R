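#' Pipeline configuration
#'
#' Collects every stage's parameters plus paths and mode. In `"analyze"`
#' mode the report and sample sheet are read from `report_path` /
#' `sheet_path`; in `"simulate_analyze"` mode a synthetic cohort is
#' generated first from `generator`. A single global `seed` deterministically
#' derives every stage's random substream.
#'
#' @param mode `"analyze"` or `"simulate_analyze"`.
#' @param report_path,sheet_path input paths (analyze mode); `dialect` as in
#'   [read_report()], with `precursor_path` for the wide dialect.
#' @param generator a [generator_config()] (simulate mode); its seed is
#'   overridden by the global `seed`.
#' @param filter a [filter_config()].
#' @param imputation an [imputation_params()]; its seed is derived from the
#'   global `seed`.
#' @param qc_threshold QC CV pass threshold in percent.
#' @param qc_restrict gate downstream analyses on QC pass (default `FALSE`).
#' @param trajectory a [trajectory_config()].
#' @param alpha,lfc_min significance thresholds for the birth contrast.
#' @param contrast_day postnatal day of the differential contrast (default 0,
#'   the cord-blood samples).
#' @param deviation a [deviation_config()].
#' @param seed global integer seed.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate_analyze", "analyze"),
                            report_path = NULL, sheet_path = NULL,
                            dialect = "wide_matrix", precursor_path = NULL,
                            generator = generator_config(),
                            filter = filter_config(),
                            imputation = imputation_params(),
                            qc_threshold = 30, qc_restrict = FALSE,
                            trajectory = trajectory_config(),
                            alpha = 0.05, lfc_min = 1, contrast_day = 0,
                            deviation = deviation_config(), seed = 1L) {
  mode <- match.arg(mode)
  structure(list(mode = mode, report_path = report_path,
                 sheet_path = sheet_path, dialect = dialect,
                 precursor_path = precursor_path, generator = generator,
                 filter = filter, imputation = imputation,
                 qc_threshold = qc_threshold, qc_restrict = qc_restrict,
                 trajectory = trajectory, alpha = alpha, lfc_min = lfc_min,
                 contrast_day = contrast_day, deviation = deviation,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("[stage: ", stage, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Stage order: ingest (or simulate) -> precursor filter -> completeness
#' filter -> QC CV screen (linear scale) -> log2 transform -> downshifted
#' imputation of the infant-retained submatrix -> trajectory classification
#' -> moderated differential contrast at `contrast_day` -> SGA/AGA deviation
#' screen. Identical config and seed give identical results.
#'
#' @param config a [pipeline_config()].
#' @return a result bundle: list with `qc`, `retention`, `presence`,
#'   `trajectory`, `differential`, `deviation`, `manifest` (and `truth` in
#'   simulate mode).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  truth <- NULL
  if (config$mode == "simulate_analyze") {
    gen <- config$generator
    gen$seed <- seed
    sim <- with_stage("simulate", simulate_cohort(gen))
    table <- sim$table; sheet <- sim$sheet; truth <- sim$truth
  } else {
    if (is.null(config$sheet_path) || !file.exists(config$sheet_path)) {
      stop("[stage: ingest] sample sheet not found: ",
           if (is.null(config$sheet_path)) "<missing path>" else
             config$sheet_path, call. = FALSE)
    }
    sheet <- with_stage("ingest", read_sample_sheet(config$sheet_path))
    table <- with_stage("ingest",
                        read_report(config$report_path, config$dialect,
                                    sheet = sheet,
                                    precursor_path = config$precursor_path))
  }
  n0 <- nrow(table$lfq)

  table <- with_stage("precursor_filter",
                      filter_min_precursors(table, config$filter))
  comp <- with_stage("completeness_filter",
                     filter_completeness(table, sheet, config$filter))
  table <- comp$table

  qc <- NULL
  if (sum(sheet$cohort == "qc") >= 2) {
    qc <- with_stage("qc_cv", qc_cv(table, sheet, config$qc_threshold))
    if (config$qc_restrict) {
      table <- with_stage("qc_cv", restrict_to_pass(table, qc))
    }
  }

  table <- with_stage("log2", log2_transform(table))

  # infant-retained proteins, infant samples only, feed the infant analyses
  keep <- table$proteins$protein_id %in%
    comp$report$protein_id[comp$report$retained_infant]
  inf_ids <- sheet$sample_id[sheet$cohort == "infant"]
  infant <- table[keep, colnames(table$lfq) %in% inf_ids]
  imp_params <- config$imputation
  imp_params$seed <- substream_seed(seed, 3L)
  imp <- with_stage("impute", impute_downshift(infant, imp_params))

  traj <- with_stage("trajectory",
                     summarize_trajectories(imp$table, sheet,
                                            config$trajectory))

  d0_sheet <- sheet[sheet$cohort == "infant" & sheet$day == config$contrast_day, ]
  sga <- intersect(d0_sheet$sample_id[d0_sheet$group == "SGA"],
                   colnames(imp$table$lfq))
  aga <- intersect(d0_sheet$sample_id[d0_sheet$group == "AGA"],
                   colnames(imp$table$lfq))
  differential <- NULL
  if (length(sga) >= 2 && length(aga) >= 2) {
    differential <- with_stage("differential", {
      res <- moderated_ttest(imp$table$lfq[, sga, drop = FALSE],
                             imp$table$lfq[, aga, drop = FALSE])
      res$gene <- imp$table$proteins$gene[match(res$protein_id,
                                                imp$table$proteins$protein_id)]
      call_significant(res, config$alpha, config$lfc_min)
    })
  }

  deviation <- with_stage("deviation",
                          deviation_analysis(imp$table, sheet,
                                             config$deviation))

  manifest <- list(
    package = "preemietraj",
    version = as.character(utils::packageVersion("preemietraj")),
    mode = config$mode, seed = seed,
    parameters = list(filter = unclass(config$filter),
                      imputation = unclass(imp_params),
                      qc_threshold = config$qc_threshold,
                      qc_restrict = config$qc_restrict,
                      trajectory = unclass(config$trajectory)[c("r2_min",
                                                                "area_min",
                                                                "x_axis")],
                      alpha = config$alpha, lfc_min = config$lfc_min,
                      contrast_day = config$contrast_day,
                      deviation = unclass(config$deviation)),
    counts = list(
      proteins_in = n0,
      retained_any = sum(comp$report$retained),
      retained_infant = sum(comp$report$retained_infant),
      retained_adult = sum(comp$report$retained_adult),
      qc_pass = if (!is.null(qc)) sum(qc$pass) else NA,
      imputed_cells = sum(imp$mask),
      increasing = sum(traj$trajectory_class == "increasing"),
      decreasing = sum(traj$trajectory_class == "decreasing"),
      stable = sum(traj$trajectory_class == "stable"),
      significant_at_birth = if (!is.null(differential))
        sum(differential$significant) else NA,
      deviating = sum(deviation$category != "concordant"))
  )

  list(qc = qc, retention = comp$report,
       presence = presence_sets(comp$report),
       trajectory = traj, differential = differential,
       deviation = deviation, truth = truth, manifest = manifest)
}

#' Write a result bundle to disk
#'
#' One TSV per result table (stable column order, UTF-8, missing values as
#' empty fields) plus a JSON run manifest. No timestamps are written, so a
#' rerun with the same config and seed is byte-identical.
#'
#' @param bundle a [run_pipeline()] result.
#' @param outdir output directory (created if absent).
#' @return character vector of the files written, invisibly.
#' @export
write_outputs <- function(bundle, outdir) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", outdir)
  }
  write_tsv <- function(df, name) {
    path <- file.path(outdir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "", fileEncoding = "UTF-8")
    path
  }
  files <- character(0)
  if (!is.null(bundle$qc)) files <- c(files, write_tsv(bundle$qc, "qc_cv.tsv"))
  files <- c(files, write_tsv(bundle$retention, "retention.tsv"))
  files <- c(files, write_tsv(bundle$trajectory, "trajectory.tsv"))
  if (!is.null(bundle$differential)) {
    files <- c(files, write_tsv(bundle$differential, "differential.tsv"))
  }
  files <- c(files, write_tsv(bundle$deviation, "deviation.tsv"))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(bundle$manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  files <- c(files, manifest_path)
  invisible(files)
}
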