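#' Downshifted-normal imputation parameters
#'
#' Missing log2 intensities are assumed left-censored (low-abundance
#' proteins fall below the detection limit) and are imputed from a normal
#' distribution shifted below the observed one: within each scope unit with
#' observed mean mu and standard deviation sigma, missing cells are drawn
#' from Normal(mu - downshift * sigma, (width * sigma)^2). The defaults
#' (downshift 1.8, width 0.3) are the convention popularised by mainstream
#' proteomics software.
#'
#' @param downshift shift of the imputation distribution, in SD units.
#' @param width SD of the imputation distribution, in SD units.
#' @param scope `"per_sample"` (each sample column provides its own mu and
#'   sigma; the default) or `"global"` (all observed values pooled).
#' @param seed integer seed making the draw reproducible.
#' @return a list of class `imputation_params`.
#' @export
imputation_params <- function(downshift = 1.8, width = 0.3,
                              scope = c("per_sample", "global"), seed = 1L) {
  scope <- match.arg(scope)
  stopifnot(downshift >= 0, width > 0)
  structure(list(downshift = downshift, width = width, scope = scope,
                 seed = as.integer(seed)),
            class = "imputation_params")
}

#' Impute missing values from a downshifted normal
#'
#' @param table a log2-scale [quant_table()].
#' @param params an [imputation_params()].
#' @return a list with `table` (no missing cells) and `mask` (logical matrix,
#'   `TRUE` where a value was imputed). Observed cells are never overwritten.
#' @export
impute_downshift <- function(table, params = imputation_params()) {
  stopifnot(inherits(table, "quant_table"))
  if (table$scale != "log2") stop("imputation expects a log2-scale table")
  mask <- is.na(table$lfq)
  if (!any(mask)) return(list(table = table, mask = mask))

  set.seed(params$seed)
  if (params$scope == "global") {
    obs <- table$lfq[!mask]
    if (length(obs) < 2) stop("fewer than 2 observed values in table")
    mu <- mean(obs); sigma <- stats::sd(obs)
    table$lfq[mask] <- stats::rnorm(sum(mask),
                                    mu - params$downshift * sigma,
                                    params$width * sigma)
  } else {
    for (j in seq_len(ncol(table$lfq))) {
      mis <- mask[, j]
      if (!any(mis)) next
      obs <- table$lfq[!mis, j]
      if (length(obs) < 2) {
        stop("fewer than 2 observed values in sample ",
             colnames(table$lfq)[j])
      }
      mu <- mean(obs); sigma <- stats::sd(obs)
      table$lfq[mis, j] <- stats::rnorm(sum(mis),
                                        mu - params$downshift * sigma,
                                        params$width * sigma)
    }
  }
  list(table = table, mask = mask)
}

#' Coefficient-of-variation screen on repeated QC injections
#'
#' Technical reproducibility is measured per protein as the coefficient of
#' variation across repeated injections of a study-wide pooled sample,
#' CV% = 100 * SD / mean on linear-scale intensities (sample SD, n - 1
#' denominator). A protein passes when CV% is strictly below the threshold.
#' Proteins with any missing QC cell get an undefined CV and fail.
#'
#' @param table a linear-scale [quant_table()]; if `sheet` is supplied the
#'   table is first restricted to its QC samples.
#' @param sheet optional sample sheet used to pick out `cohort == "qc"`
#'   columns.
#' @param threshold CV threshold in percent (default 30, strict `<`).
#' @return a data.frame of class `qc_result` with columns `protein_id`,
#'   `mean`, `sd`, `cv_percent`, `pass`; the threshold is kept as an
#'   attribute.
#' @export
qc_cv <- function(table, sheet = NULL, threshold = 30) {
  stopifnot(inherits(table, "quant_table"))
  if (table$scale != "linear") {
    stop("QC CV is computed on linear-scale intensities")
  }
  m <- table$lfq
  if (!is.null(sheet)) {
    qc_ids <- sheet$sample_id[sheet$cohort == "qc"]
    m <- m[, colnames(m) %in% qc_ids, drop = FALSE]
  }
  if (ncol(m) < 2) stop("need at least 2 QC injections, got ", ncol(m))
  mu <- rowMeans(m)
  sdev <- apply(m, 1, stats::sd)
  cv <- 100 * sdev / mu
  cv[apply(is.na(m), 1, any)] <- NA
  res <- data.frame(protein_id = table$proteins$protein_id,
                    gene = table$proteins$gene,
                    mean = mu, sd = sdev, cv_percent = cv,
                    pass = !is.na(cv) & cv < threshold,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "threshold") <- threshold
  class(res) <- c("qc_result", class(res))
  res
}

#' Restrict a table to QC-passing proteins
#'
#' Optional gate: downstream analyses can be limited to proteins that passed
#' the QC CV screen. Off by default in the pipeline, where the screen serves
#' as workflow validation.
#'
#' @param table a [quant_table()] over the same protein set as `qcres`.
#' @param qcres a [qc_cv()] result.
#' @return the table restricted to passing proteins (with a warning when
#'   none pass).
#' @export
restrict_to_pass <- function(table, qcres) {
  stopifnot(inherits(table, "quant_table"), inherits(qcres, "qc_result"))
  keep <- qcres$protein_id[qcres$pass]
  idx <- table$proteins$protein_id %in% keep
  if (!any(idx)) warning("no protein passes the QC CV screen")
  table[idx, ]
}
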