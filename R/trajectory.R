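#' Trajectory classification parameters
#'
#' A protein's postnatal trajectory is summarised by (1) a similarity score,
#' the squared Pearson correlation between its per-day median profile and a
#' theoretical shape, and (2) an effect-size area, the signed trapezoidal
#' area of the baseline-normalised profile over postnatal days. A protein is
#' called increasing when similarity >= `r2_min` and area >= `area_min`,
#' decreasing when similarity >= `r2_min` and area <= -`area_min`, and stable
#' otherwise.
#'
#' The x-axis for the area is the actual postnatal day (0-28) rather than the
#' timepoint index: on a day axis the default threshold of 20 corresponds to
#' a sustained change of about 0.7 log2 units over the four weeks, which is
#' the scale of the effect sizes this procedure is designed to rank.
#'
#' @param r2_min minimum similarity score (default 0.5).
#' @param area_min minimum absolute effect-size area (default 20,
#'   log2-intensity x days).
#' @param x_axis `"day"` (integrate over postnatal days, default) or
#'   `"index"` (timepoint rank).
#' @param shapes named list of shape templates (one numeric value per day);
#'   `NULL` for the default single linear-in-day ramp. Because the score is a
#'   squared correlation, one ramp scores both directions.
#' @return a list of class `trajectory_config`.
#' @export
trajectory_config <- function(r2_min = 0.5, area_min = 20,
                              x_axis = c("day", "index"), shapes = NULL) {
  x_axis <- match.arg(x_axis)
  stopifnot(r2_min >= 0, r2_min <= 1, area_min >= 0)
  structure(list(r2_min = r2_min, area_min = area_min, x_axis = x_axis,
                 shapes = shapes),
            class = "trajectory_config")
}

#' Per-day median profiles over infant samples
#'
#' @param table an imputed, log2-scale [quant_table()] (infant columns are
#'   selected via the sheet).
#' @param sheet a sample sheet covering the table's samples.
#' @param group optional `"SGA"`/`"AGA"` restriction (used by the deviation
#'   screen); `NULL` uses all infants.
#' @return a numeric matrix, proteins x days; column names are the postnatal
#'   days, also attached as the numeric attribute `days`.
#' @export
median_profile <- function(table, sheet, group = NULL) {
  stopifnot(inherits(table, "quant_table"))
  if (table$scale != "log2") stop("median profiles expect log2 intensities")
  inf <- sheet[sheet$cohort == "infant" &
                 sheet$sample_id %in% colnames(table$lfq), , drop = FALSE]
  if (!is.null(group)) {
    inf <- inf[!is.na(inf$group) & inf$group == group, , drop = FALSE]
    if (!nrow(inf)) stop("no infant samples in group ", group)
  }
  days <- sort(unique(sheet$day[sheet$cohort == "infant"]))
  prof <- matrix(NA_real_, nrow(table$lfq), length(days),
                 dimnames = list(rownames(table$lfq), days))
  for (k in seq_along(days)) {
    ids <- inf$sample_id[inf$day == days[k]]
    if (!length(ids)) {
      stop("no ", if (is.null(group)) "infant" else group,
           " samples at day ", days[k])
    }
    prof[, k] <- apply(table$lfq[, ids, drop = FALSE], 1, stats::median)
  }
  attr(prof, "days") <- days
  prof
}

#' Similarity score against a theoretical shape
#'
#' The squared Pearson correlation between a per-day median profile and a
#' shape template evaluated on the same day grid. A zero-variance (constant)
#' profile scores 0 by convention, so flat proteins are always classified
#' stable. The score is invariant under positive affine transforms of either
#' argument and blind to direction (a profile and its negation score alike);
#' the sign of the change is carried by the effect-size area.
#'
#' @param profile numeric vector of per-day medians.
#' @param shape numeric vector of shape values, same length, non-constant.
#' @return the squared correlation, in `[0, 1]`.
#' @export
similarity_score <- function(profile, shape) {
  if (length(profile) != length(shape)) {
    stop("profile and shape differ in length (", length(profile), " vs ",
         length(shape), ")")
  }
  if (stats::var(shape) == 0) stop("shape template must be non-constant")
  if (stats::var(profile) == 0) return(0)
  stats::cor(profile, shape)^2
}

#' Baseline-normalised area effect size
#'
#' The first timepoint's median is subtracted from every median so the curve
#' starts at zero, and the resulting deltas are integrated over the x-axis by
#' the trapezoid rule. The result is signed: net increases are positive, net
#' decreases negative. Units are log2-intensity x days on the default day
#' axis.
#'
#' @param profile numeric vector of per-day medians (>= 2 days).
#' @param days numeric vector of postnatal days matching `profile`.
#' @param x_axis `"day"` or `"index"`.
#' @return the signed area.
#' @export
effect_area <- function(profile, days, x_axis = c("day", "index")) {
  x_axis <- match.arg(x_axis)
  if (length(profile) < 2) stop("effect area needs at least 2 timepoints")
  if (length(days) != length(profile)) stop("days and profile differ in length")
  x <- if (x_axis == "day") as.numeric(days) else seq_along(profile) - 1
  delta <- profile - profile[1]
  n <- length(delta)
  sum((delta[-1] + delta[-n]) / 2 * diff(x))
}

#' Classify a trajectory from similarity and area
#'
#' @param similarity similarity score(s) in `[0, 1]`.
#' @param area effect-size area(s).
#' @param config a [trajectory_config()].
#' @return character vector: `"increasing"`, `"decreasing"` or `"stable"`.
#' @export
classify_trajectory <- function(similarity, area, config = trajectory_config()) {
  stopifnot(all(similarity >= 0 & similarity <= 1))
  out <- rep("stable", length(similarity))
  out[similarity >= config$r2_min & area >= config$area_min] <- "increasing"
  out[similarity >= config$r2_min & area <= -config$area_min] <- "decreasing"
  out
}

#' Shape templates for a day grid
#'
#' @param days numeric day grid.
#' @return the default template list: a single linear-in-day ramp.
#' @export
default_shapes <- function(days) {
  list(linear = as.numeric(days))
}

#' Trajectory summary for every protein
#'
#' Computes per-day medians over infants, scores each protein against every
#' configured shape (the similarity is the maximum over shapes, `best_shape`
#' the argmax), computes the baseline-normalised area and classifies the
#' trajectory.
#'
#' @param table an imputed log2-scale infant [quant_table()].
#' @param sheet a sample sheet.
#' @param config a [trajectory_config()].
#' @return a data.frame with columns `protein_id`, `gene`, one `median_d<d>`
#'   column per day, `similarity`, `effect_area`, `best_shape`,
#'   `trajectory_class`.
#' @export
summarize_trajectories <- function(table, sheet, config = trajectory_config()) {
  prof <- median_profile(table, sheet)
  days <- attr(prof, "days")
  shapes <- config$shapes
  if (is.null(shapes)) shapes <- default_shapes(days)
  for (s in shapes) {
    if (length(s) != length(days)) stop("shape length does not match day grid")
    if (stats::var(s) == 0) stop("shape template must be non-constant")
  }
  r2 <- sapply(shapes, function(s) {
    v <- apply(prof, 1, stats::var)
    out <- rep(0, nrow(prof))
    ok <- v > 0
    if (any(ok)) {
      out[ok] <- as.vector(stats::cor(t(prof[ok, , drop = FALSE]), s))^2
    }
    out
  })
  r2 <- matrix(r2, nrow = nrow(prof),
               dimnames = list(rownames(prof), names(shapes)))
  best <- max.col(r2, ties.method = "first")
  similarity <- r2[cbind(seq_len(nrow(r2)), best)]
  area <- apply(prof, 1, effect_area, days = days, x_axis = config$x_axis)
  res <- data.frame(protein_id = table$proteins$protein_id,
                    gene = table$proteins$gene,
                    stringsAsFactors = FALSE)
  med <- as.data.frame(prof)
  names(med) <- paste0("median_d", days)
  res <- cbind(res, med)
  res$similarity <- similarity
  res$effect_area <- area
  res$best_shape <- names(shapes)[best]
  res$trajectory_class <- classify_trajectory(similarity, area, config)
  rownames(res) <- NULL
  res
}
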