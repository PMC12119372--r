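#' Deviation-screen parameters
#'
#' The SGA-vs-AGA deviation screen summarises each protein by (1) the
#' difference in longitudinal CV between the groups' per-day median profiles
#' (trend) and (2) the log2 fold change of the groups' overall medians
#' (level). A trend deviation is `|delta_cv| > cv_stable_max`; a level
#' deviation is a `group_lfc` outside the empirical
#' `[quantile_low, quantile_high]` window of the all-protein LFC
#' distribution.
#'
#' @param cv_stable_max CV-difference threshold in percent (default 30;
#'   trends are considered stable below it).
#' @param quantile_low,quantile_high empirical quantile window on the LFC
#'   distribution (defaults 0.05 and 0.95).
#' @param cv_scale `"linear"` (back-transform log2 medians before the CV;
#'   default) or `"log2"`.
#' @param window `"empirical"` (linear-interpolation quantiles, default) or
#'   `"normal"` (window from a fitted normal distribution).
#' @return a list of class `deviation_config`.
#' @export
deviation_config <- function(cv_stable_max = 30, quantile_low = 0.05,
                             quantile_high = 0.95,
                             cv_scale = c("linear", "log2"),
                             window = c("empirical", "normal")) {
  cv_scale <- match.arg(cv_scale)
  window <- match.arg(window)
  stopifnot(cv_stable_max > 0, quantile_low >= 0,
            quantile_low < quantile_high, quantile_high <= 1)
  structure(list(cv_stable_max = cv_stable_max, quantile_low = quantile_low,
                 quantile_high = quantile_high, cv_scale = cv_scale,
                 window = window),
            class = "deviation_config")
}

#' Per-group per-day median profiles
#'
#' @param table an imputed log2-scale infant [quant_table()].
#' @param sheet a sample sheet; the group must have samples at every day.
#' @param group `"SGA"` or `"AGA"`.
#' @return proteins x days matrix of medians (see [median_profile()]).
#' @export
group_median_profile <- function(table, sheet, group) {
  median_profile(table, sheet, group = group)
}

#' Longitudinal coefficient of variation of a median profile
#'
#' CV% = 100 * sample SD / mean of the per-day median values, a unitless
#' summary of how much a profile moves over the sampling days. Computed
#' directly on the values supplied; callers back-transform log2 medians to
#' the linear scale first when a scale-free CV is wanted.
#'
#' @param values per-day median values (>= 2 days).
#' @return the CV in percent.
#' @export
longitudinal_cv <- function(values) {
  if (length(values) < 2) stop("longitudinal CV needs at least 2 days")
  mu <- mean(values)
  if (mu <= 0) stop("longitudinal CV undefined for non-positive mean")
  100 * stats::sd(values) / mu
}

#' Between-group log2 fold change of overall medians
#'
#' `median(all SGA log2 values) - median(all AGA log2 values)`, pooling every
#' timepoint, per protein.
#'
#' @param table an imputed log2-scale infant [quant_table()].
#' @param sheet a sample sheet.
#' @return named numeric vector of per-protein LFCs (SGA minus AGA).
#' @export
group_lfc <- function(table, sheet) {
  stopifnot(inherits(table, "quant_table"))
  if (table$scale != "log2") stop("group LFC expects log2 intensities")
  inf <- sheet[sheet$cohort == "infant" &
                 sheet$sample_id %in% colnames(table$lfq), , drop = FALSE]
  sga <- inf$sample_id[!is.na(inf$group) & inf$group == "SGA"]
  aga <- inf$sample_id[!is.na(inf$group) & inf$group == "AGA"]
  if (!length(sga) || !length(aga)) stop("both SGA and AGA samples required")
  apply(table$lfq[, sga, drop = FALSE], 1, stats::median) -
    apply(table$lfq[, aga, drop = FALSE], 1, stats::median)
}

#' Categorise deviation from the trend and level flags
#'
#' @param delta_cv per-protein CV difference (SGA minus AGA), percent.
#' @param lfc per-protein between-group LFC.
#' @param lfc_distribution the LFC vector over all proteins, defining the
#'   empirical window.
#' @param config a [deviation_config()].
#' @return character vector with levels `concordant`, `different_trend`,
#'   `different_level_similar_trend`, `different_both`.
#' @export
flag_deviation <- function(delta_cv, lfc, lfc_distribution,
                           config = deviation_config()) {
  if (config$window == "normal") {
    mu <- mean(lfc_distribution); sdev <- stats::sd(lfc_distribution)
    qlo <- stats::qnorm(config$quantile_low, mu, sdev)
    qhi <- stats::qnorm(config$quantile_high, mu, sdev)
  } else {
    qlo <- stats::quantile(lfc_distribution, config$quantile_low,
                           names = FALSE)
    qhi <- stats::quantile(lfc_distribution, config$quantile_high,
                           names = FALSE)
  }
  if (qlo == qhi) {
    warning("degenerate LFC distribution: quantile window collapsed, ",
            "no level deviations flagged")
    level <- rep(FALSE, length(lfc))
  } else {
    level <- lfc < qlo | lfc > qhi
  }
  trend <- abs(delta_cv) > config$cv_stable_max
  out <- rep("concordant", length(lfc))
  out[trend & !level] <- "different_trend"
  out[!trend & level] <- "different_level_similar_trend"
  out[trend & level] <- "different_both"
  out
}

#' SGA-vs-AGA longitudinal deviation screen
#'
#' Runs the full procedure: per-group median profiles, longitudinal CVs and
#' their difference, pooled between-group LFCs, and category assignment
#' against the empirical LFC window.
#'
#' @param table an imputed log2-scale infant [quant_table()].
#' @param sheet a sample sheet.
#' @param config a [deviation_config()].
#' @return a data.frame with columns `protein_id`, `gene`, `cv_sga`,
#'   `cv_aga`, `delta_cv`, `group_lfc`, `category`.
#' @export
deviation_analysis <- function(table, sheet, config = deviation_config()) {
  prof_sga <- group_median_profile(table, sheet, "SGA")
  prof_aga <- group_median_profile(table, sheet, "AGA")
  to_scale <- function(m) if (config$cv_scale == "linear") 2^m else m
  cv_sga <- apply(to_scale(prof_sga), 1, longitudinal_cv)
  cv_aga <- apply(to_scale(prof_aga), 1, longitudinal_cv)
  lfc <- group_lfc(table, sheet)
  delta_cv <- cv_sga - cv_aga
  res <- data.frame(protein_id = table$proteins$protein_id,
                    gene = table$proteins$gene,
                    cv_sga = cv_sga, cv_aga = cv_aga, delta_cv = delta_cv,
                    group_lfc = lfc,
                    category = flag_deviation(delta_cv, lfc, lfc, config),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
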