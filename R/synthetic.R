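#' Synthetic cohort generator configuration
#'
#' Describes a synthetic longitudinal serum-proteomics study with the same
#' structure the analysis assumes: a preterm cohort of `n_aga + n_sga`
#' infants sampled on postnatal `days` with per-day `availability`, a small
#' adult reference group, repeated injections of a pooled QC sample, and a
#' protein panel with planted increasing / decreasing / stable trajectories,
#' a group-level abundance shift for a designated SGA-affected subset, and
#' intensity-dependent (MNAR) missingness.
#'
#' Defaults mirror the emulated study design: 67 infants (49 AGA, 18 SGA),
#' days 0/3/7/14/28 with availability 31/65/56/49/27, 6 adults, 7 QC
#' injections, 900 proteins of which 150 increase and 150 decrease. Where
#' the design leaves a knob open the default is a realistic serum DIA value:
#' log2 baselines ~ Normal(20, 2), within-subject residual SD 0.3 log2
#' units, planted plateau delta 3 log2 units (area 42 on the day axis, twice
#' the classification threshold), SGA shift 1.5 log2 units on 30 proteins,
#' logistic detection with midpoint 16 and slope 0.8 per log2 unit, and
#' unique-precursor counts 1 + Poisson(3) so about 5% of quantified cells
#' fall below the two-precursor filter.
#'
#' @param n_proteins number of protein groups.
#' @param n_aga,n_sga infants per group.
#' @param n_adults,n_qc adult samples and QC injections.
#' @param days strictly increasing postnatal days.
#' @param availability per-day infant sample counts (whole-sample dropout).
#' @param n_increasing,n_decreasing,n_stable planted class counts; must sum
#'   to `n_proteins` (`n_stable = NULL` takes the remainder).
#' @param effect_magnitude_log2 plateau delta of planted trajectories (log2).
#' @param group_shift_log2 planted SGA-vs-AGA offset (log2).
#' @param n_group_shifted number of proteins carrying the group shift.
#' @param noise_sd_log2 within-subject residual SD (log2).
#' @param baseline_mean_log2,baseline_sd_log2 log2 baseline distribution.
#' @param mnar_midpoint,mnar_slope logistic detection curve on log2
#'   intensity; `mnar_slope = 0` disables cell-level missingness.
#' @param min_precursor_lambda Poisson mean of `1 + Poisson(lambda)`
#'   unique-precursor counts.
#' @param qc_noise_sd_log2 technical SD of QC injections (log2).
#' @param adult_offset_sd_log2 SD of the per-protein adult baseline offset.
#' @param n_infant_only proteins absent from adult serum.
#' @param n_adult_only proteins absent from infant serum.
#' @param trajectory_shape `"linear"` ramp in day (default) or `"saturating"`
#'   exponential approach to the plateau.
#' @param seed integer master seed; all randomness derives from it.
#' @return a validated list of class `generator_config`.
#' @export
generator_config <- function(n_proteins = 900, n_aga = 49, n_sga = 18,
                             n_adults = 6, n_qc = 7,
                             days = c(0, 3, 7, 14, 28),
                             availability = c(31, 65, 56, 49, 27),
                             n_increasing = 150, n_decreasing = 150,
                             n_stable = NULL,
                             effect_magnitude_log2 = 3,
                             group_shift_log2 = 1.5, n_group_shifted = 30,
                             noise_sd_log2 = 0.3,
                             baseline_mean_log2 = 20, baseline_sd_log2 = 2,
                             mnar_midpoint = 16, mnar_slope = 0.8,
                             min_precursor_lambda = 3,
                             qc_noise_sd_log2 = 0.15,
                             adult_offset_sd_log2 = 0.5,
                             n_infant_only = 250, n_adult_only = 4,
                             trajectory_shape = c("linear", "saturating"),
                             seed = 1L) {
  trajectory_shape <- match.arg(trajectory_shape)
  if (is.null(n_stable)) n_stable <- n_proteins - n_increasing - n_decreasing
  cfg <- list(n_proteins = n_proteins, n_aga = n_aga, n_sga = n_sga,
              n_adults = n_adults, n_qc = n_qc, days = days,
              availability = availability, n_increasing = n_increasing,
              n_decreasing = n_decreasing, n_stable = n_stable,
              effect_magnitude_log2 = effect_magnitude_log2,
              group_shift_log2 = group_shift_log2,
              n_group_shifted = n_group_shifted,
              noise_sd_log2 = noise_sd_log2,
              baseline_mean_log2 = baseline_mean_log2,
              baseline_sd_log2 = baseline_sd_log2,
              mnar_midpoint = mnar_midpoint, mnar_slope = mnar_slope,
              min_precursor_lambda = min_precursor_lambda,
              qc_noise_sd_log2 = qc_noise_sd_log2,
              adult_offset_sd_log2 = adult_offset_sd_log2,
              n_infant_only = n_infant_only, n_adult_only = n_adult_only,
              trajectory_shape = trajectory_shape, seed = as.integer(seed))
  counts <- c(cfg$n_proteins, cfg$n_aga, cfg$n_sga, cfg$n_adults, cfg$n_qc,
              cfg$n_increasing, cfg$n_decreasing, cfg$n_stable,
              cfg$n_group_shifted, cfg$n_infant_only, cfg$n_adult_only)
  if (any(counts < 0)) stop("all counts must be non-negative")
  if (cfg$n_increasing + cfg$n_decreasing + cfg$n_stable != cfg$n_proteins) {
    stop("planted class counts must sum to n_proteins")
  }
  if (any(diff(cfg$days) <= 0)) stop("days must be strictly increasing")
  if (length(cfg$availability) != length(cfg$days)) {
    stop("availability needs one entry per day")
  }
  n_inf <- cfg$n_aga + cfg$n_sga
  if (any(cfg$availability > n_inf)) {
    stop("availability cannot exceed the infant cohort size (", n_inf, ")")
  }
  if (cfg$noise_sd_log2 < 0 || cfg$min_precursor_lambda <= 0 ||
      cfg$effect_magnitude_log2 < 0) {
    stop("noise_sd_log2 and effect_magnitude_log2 must be >= 0, ",
         "min_precursor_lambda > 0")
  }
  structure(cfg, class = "generator_config")
}

# per-stage RNG substreams derived from a single master seed, so adding a
# stage never perturbs an earlier stage's draws
substream_seed <- function(seed, k) {
  (abs(as.integer(seed)) %% 1000003L) * 1000L + as.integer(k)
}

#' Planted expected trajectory over the day grid
#'
#' @param class `"stable"`, `"increasing"` or `"decreasing"`.
#' @param baseline baseline log2 intensity (the day-0 value).
#' @param delta plateau change in log2 units (>= 0), reached at the last day.
#' @param days strictly increasing, non-empty day grid.
#' @param shape `"linear"` ramp (default) or `"saturating"` exponential
#'   approach `1 - exp(-3 t)` rescaled to hit the plateau at the last day.
#' @return expected log2 intensity per day.
#' @export
plant_profile <- function(class, baseline, delta, days,
                          shape = c("linear", "saturating")) {
  shape <- match.arg(shape)
  if (!length(days) || any(diff(days) <= 0)) {
    stop("days must be non-empty and strictly increasing")
  }
  if (delta < 0) stop("delta must be non-negative")
  if (!class %in% c("stable", "increasing", "decreasing")) {
    stop("unknown trajectory class: ", class)
  }
  if (class == "stable") return(rep(baseline, length(days)))
  t <- (days - days[1]) / (days[length(days)] - days[1])
  ramp <- if (shape == "linear") t else (1 - exp(-3 * t)) / (1 - exp(-3))
  sign <- if (class == "increasing") 1 else -1
  baseline + sign * delta * ramp
}

#' Simulate complete (pre-missingness) infant intensities
#'
#' Draws per-protein log2 baselines from Normal(`baseline_mean_log2`,
#' `baseline_sd_log2`), assigns planted trajectory classes and the
#' group-shift flag, and builds the complete protein x subject x day tensor
#' of true log2 intensities: planted profile + group shift (shift-flagged
#' proteins in SGA subjects only) + Gaussian residual noise.
#'
#' @param config a [generator_config()].
#' @return list with `truth` (data.frame: `protein_id`, `gene`, `class`,
#'   `delta`, `group_shifted`, `infant_only`, `adult_only`, `baseline`) and
#'   `tensor` (numeric array protein x subject x day, subjects named
#'   `P001...`, SGA subjects first).
#' @export
simulate_intensities <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(substream_seed(config$seed, 1L))
  np <- config$n_proteins
  ids <- sprintf("PG%04d", seq_len(np))
  classes <- rep(c("increasing", "decreasing", "stable"),
                 c(config$n_increasing, config$n_decreasing, config$n_stable))
  classes <- sample(classes)  # shuffle so class is independent of baseline
  baseline <- stats::rnorm(np, config$baseline_mean_log2,
                           config$baseline_sd_log2)
  shifted <- rep(FALSE, np)
  # a zero-magnitude shift is no shift: the flag stays false everywhere
  if (config$n_group_shifted > 0 && config$group_shift_log2 != 0) {
    shifted[sample.int(np, config$n_group_shifted)] <- TRUE
  }
  infant_only <- rep(FALSE, np)
  adult_only <- rep(FALSE, np)
  special <- sample.int(np, config$n_infant_only + config$n_adult_only)
  if (config$n_infant_only > 0) {
    infant_only[special[seq_len(config$n_infant_only)]] <- TRUE
  }
  if (config$n_adult_only > 0) {
    adult_only[special[config$n_infant_only + seq_len(config$n_adult_only)]] <- TRUE
  }
  truth <- data.frame(protein_id = ids, gene = sprintf("GENE%04d", seq_len(np)),
                      class = classes, delta = ifelse(classes == "stable", 0,
                                                      config$effect_magnitude_log2),
                      group_shifted = shifted, infant_only = infant_only,
                      adult_only = adult_only, baseline = baseline,
                      stringsAsFactors = FALSE)

  n_inf <- config$n_aga + config$n_sga
  subjects <- sprintf("P%03d", seq_len(n_inf))
  groups <- rep(c("SGA", "AGA"), c(config$n_sga, config$n_aga))
  nd <- length(config$days)
  expected <- t(vapply(seq_len(np), function(i) {
    plant_profile(classes[i], baseline[i], truth$delta[i], config$days,
                  shape = config$trajectory_shape)
  }, numeric(nd)))
  tensor <- array(NA_real_, c(np, n_inf, nd),
                  dimnames = list(ids, subjects, config$days))
  for (s in seq_len(n_inf)) {
    shift <- if (groups[s] == "SGA") config$group_shift_log2 * shifted else 0
    noise <- if (config$noise_sd_log2 > 0) {
      matrix(stats::rnorm(np * nd, 0, config$noise_sd_log2), np, nd)
    } else 0
    tensor[, s, ] <- expected + shift + noise
  }
  attr(tensor, "groups") <- stats::setNames(groups, subjects)
  list(truth = truth, tensor = tensor)
}

#' Apply the observation process to a complete tensor
#'
#' Turns the complete intensity tensor into an observed quantification table
#' and sample sheet: (1) whole-sample dropout — per day, only the configured
#' number of subjects is available (sampled without replacement); (2)
#' cell-level MNAR — each remaining cell is detected with probability
#' `plogis((intensity - mnar_midpoint) * mnar_slope)` (probability 1 when
#' `mnar_slope == 0`, which disables the mechanism); (3) detected cells get
#' unique-precursor counts `1 + Poisson(min_precursor_lambda)`. QC columns
#' are the per-protein infant cohort mean plus technical noise, replicated
#' `n_qc` times; adult columns come from a separate baseline set with the
#' infant-only protein subset absent (and adult-only proteins absent from
#' infant and QC columns).
#'
#' @param tensor complete log2 tensor from [simulate_intensities()].
#' @param truth the matching ground-truth data.frame.
#' @param config the [generator_config()] used to build the tensor.
#' @return list with `table` (linear-scale [quant_table()]) and `sheet`
#'   (sample sheet data.frame).
#' @export
apply_missingness <- function(tensor, truth, config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(substream_seed(config$seed, 2L))
  np <- dim(tensor)[1]; n_inf <- dim(tensor)[2]
  subjects <- dimnames(tensor)[[2]]
  groups <- attr(tensor, "groups")
  days <- config$days

  detect_prob <- function(x) {
    if (config$mnar_slope == 0) rep(1, length(x)) else
      stats::plogis((x - config$mnar_midpoint) * config$mnar_slope)
  }

  # 1) whole-sample dropout per day
  cols <- list(); meta <- list()
  for (k in seq_along(days)) {
    avail <- sample(subjects, config$availability[k])
    avail <- subjects[subjects %in% avail]  # keep subject order
    for (s in avail) {
      cols[[length(cols) + 1L]] <- tensor[, s, k]
      meta[[length(meta) + 1L]] <-
        data.frame(sample_id = sprintf("%s_d%02d", s, days[k]),
                   subject_id = s, cohort = "infant",
                   group = unname(groups[s]), day = days[k],
                   stringsAsFactors = FALSE)
    }
  }
  log2_mat <- do.call(cbind, cols)
  sheet <- do.call(rbind, meta)
  colnames(log2_mat) <- sheet$sample_id
  log2_mat[truth$adult_only, ] <- NA  # adult-only proteins absent in infants

  # QC pool: infant cohort mean per protein + technical noise
  if (config$n_qc > 0) {
    pool <- rowMeans(tensor, dims = 1)
    qc <- matrix(stats::rnorm(np * config$n_qc, 0, config$qc_noise_sd_log2),
                 np, config$n_qc) + pool
    qc[truth$adult_only, ] <- NA
    colnames(qc) <- sprintf("QC%d", seq_len(config$n_qc))
    log2_mat <- cbind(log2_mat, qc)
    sheet <- rbind(sheet,
                   data.frame(sample_id = colnames(qc), subject_id = colnames(qc),
                              cohort = "qc", group = NA_character_,
                              day = NA_real_, stringsAsFactors = FALSE))
  }

  # adults: separate baseline set
  if (config$n_adults > 0) {
    adult_base <- truth$baseline +
      stats::rnorm(np, 0, config$adult_offset_sd_log2)
    adu <- matrix(stats::rnorm(np * config$n_adults, 0, config$noise_sd_log2),
                  np, config$n_adults) + adult_base
    adu[truth$infant_only, ] <- NA
    colnames(adu) <- sprintf("A%d", seq_len(config$n_adults))
    log2_mat <- cbind(log2_mat, adu)
    sheet <- rbind(sheet,
                   data.frame(sample_id = colnames(adu), subject_id = colnames(adu),
                              cohort = "adult", group = NA_character_,
                              day = NA_real_, stringsAsFactors = FALSE))
  }

  # 2) cell-level MNAR detection (QC injections are always detected: the
  # pool is abundant by construction)
  is_qc <- sheet$cohort[match(colnames(log2_mat), sheet$sample_id)] == "qc"
  obs <- !is.na(log2_mat)
  det <- obs
  cand <- which(obs & !matrix(is_qc, np, ncol(log2_mat), byrow = TRUE))
  p <- detect_prob(log2_mat[cand])
  det[cand] <- stats::runif(length(cand)) < p
  log2_mat[!det] <- NA

  # 3) unique-precursor counts for detected cells
  prec <- matrix(0, np, ncol(log2_mat), dimnames = dimnames(log2_mat))
  prec[det] <- 1 + stats::rpois(sum(det), config$min_precursor_lambda)

  table <- quant_table(2^log2_mat, prec,
                       data.frame(protein_id = truth$protein_id,
                                  gene = truth$gene,
                                  stringsAsFactors = FALSE),
                       scale = "linear")
  rownames(sheet) <- NULL
  list(table = table, sheet = validate_sample_sheet(sheet))
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper running [simulate_intensities()] and
#' [apply_missingness()].
#'
#' @param config a [generator_config()].
#' @return list with `table`, `sheet`, `truth`, `tensor`.
#' @export
simulate_cohort <- function(config = generator_config()) {
  sim <- simulate_intensities(config)
  obs <- apply_missingness(sim$tensor, sim$truth, config)
  list(table = obs$table, sheet = obs$sheet, truth = sim$truth,
       tensor = sim$tensor)
}
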