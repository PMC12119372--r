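test_that("plant_profile reproduces the stated shapes", {
  days <- c(0, 3, 7, 14, 28)
  expect_equal(plant_profile("stable", 20, 5, days), rep(20, 5))
  # hand evaluation of 20 + 4 * day / 28
  expect_equal(plant_profile("increasing", 20, 4, days),
               c(20, 20.429, 21, 22, 24), tolerance = 1e-3)
  expect_equal(plant_profile("decreasing", 20, 4, c(0, 28)), c(20, 16))
  expect_error(plant_profile("wiggly", 20, 4, days), "unknown trajectory")
  expect_error(plant_profile("stable", 20, 4, c(3, 3, 7)),
               "strictly increasing")
  expect_error(plant_profile("increasing", 20, -1, days), "non-negative")
})

test_that("saturating profiles reach the plateau and stay monotone", {
  days <- c(0, 3, 7, 14, 28)
  p <- plant_profile("increasing", 10, 2, days, shape = "saturating")
  expect_equal(p[1], 10)
  expect_equal(p[5], 12)
  expect_true(all(diff(p) > 0))
  # saturating rises faster than linear at interior days
  lin <- plant_profile("increasing", 10, 2, days, shape = "linear")
  expect_true(all(p[2:4] > lin[2:4]))
})

test_that("simulate_intensities is seeded-deterministic and honours truth", {
  cfg <- small_config(seed = 5L)
  s1 <- simulate_intensities(cfg)
  s2 <- simulate_intensities(cfg)
  expect_identical(s1$tensor, s2$tensor)
  expect_identical(s1$truth, s2$truth)
  expect_equal(table(s1$truth$class)[["increasing"]], cfg$n_increasing)
  expect_equal(table(s1$truth$class)[["decreasing"]], cfg$n_decreasing)
  expect_equal(sum(s1$truth$group_shifted), cfg$n_group_shifted)
  # zero-magnitude shift means no protein is flagged shifted
  s0 <- simulate_intensities(small_config(group_shift_log2 = 0, seed = 5L))
  expect_false(any(s0$truth$group_shifted))
})

test_that("noiseless subjects match the planted profile exactly", {
  cfg <- small_config(noise_sd_log2 = 0, group_shift_log2 = 0, seed = 2L)
  sim <- simulate_intensities(cfg)
  for (i in c(1, 17, 60)) {
    planted <- plant_profile(sim$truth$class[i], sim$truth$baseline[i],
                             sim$truth$delta[i], cfg$days)
    for (s in c(1, 12)) {
      expect_equal(unname(sim$tensor[i, s, ]), planted)
    }
  }
})

test_that("residual noise has the configured SD (law of large numbers)", {
  cfg <- generator_config(n_proteins = 100, n_aga = 15, n_sga = 5,
                          availability = rep(20, 5), n_increasing = 20,
                          n_decreasing = 20, noise_sd_log2 = 0.5,
                          group_shift_log2 = 0, n_infant_only = 0,
                          n_adult_only = 0, seed = 8L)
  sim <- simulate_intensities(cfg)
  expected <- t(sapply(seq_len(100), function(i) {
    plant_profile(sim$truth$class[i], sim$truth$baseline[i],
                  sim$truth$delta[i], cfg$days)
  }))
  resid <- sweep(sim$tensor, c(1, 3), expected)  # 100 x 20 x 5 = 1e4 cells
  expect_equal(sd(resid), 0.5, tolerance = 0.02 / 0.5)
})

test_that("whole-sample dropout reproduces the per-day availability", {
  cfg <- generator_config(seed = 3L)  # 67 infants, availability 31/65/56/49/27
  sim <- simulate_cohort(cfg)
  inf <- sim$sheet[sim$sheet$cohort == "infant", ]
  counts <- as.vector(table(factor(inf$day, levels = cfg$days)))
  expect_equal(counts, c(31, 65, 56, 49, 27))
  # each (subject, day) occurs at most once and subjects are real cohort ids
  expect_false(anyDuplicated(paste(inf$subject_id, inf$day)) > 0)
  expect_true(all(table(inf$subject_id) <= length(cfg$days)))
})

test_that("mnar_slope = 0 disables cell-level missingness", {
  cfg <- small_config(mnar_slope = 0, n_adult_only = 0, n_infant_only = 0,
                      seed = 4L)
  sim <- simulate_cohort(cfg)
  inf_ids <- sim$sheet$sample_id[sim$sheet$cohort == "infant"]
  expect_false(anyNA(sim$table$lfq[, inf_ids]))
})

test_that("detection at the logistic midpoint is one half", {
  # all true intensities pinned exactly at the midpoint: 500 x 40 x 5 = 1e5
  cfg <- generator_config(n_proteins = 500, n_aga = 30, n_sga = 10,
                          availability = rep(40, 5), n_increasing = 0,
                          n_decreasing = 0, noise_sd_log2 = 0,
                          baseline_mean_log2 = 16, baseline_sd_log2 = 0,
                          mnar_midpoint = 16, mnar_slope = 0.8,
                          group_shift_log2 = 0, n_group_shifted = 0,
                          n_infant_only = 0, n_adult_only = 0,
                          n_adults = 0, n_qc = 0, seed = 9L)
  sim <- simulate_cohort(cfg)
  inf_ids <- sim$sheet$sample_id[sim$sheet$cohort == "infant"]
  frac <- mean(!is.na(sim$table$lfq[, inf_ids]))
  expect_equal(frac, 0.5, tolerance = 0.01 / 0.5)
})

test_that("missingness is monotone decreasing in planted intensity", {
  cfg <- generator_config(n_proteins = 400, n_aga = 30, n_sga = 10,
                          availability = rep(40, 5), n_increasing = 0,
                          n_decreasing = 0, noise_sd_log2 = 0,
                          baseline_mean_log2 = 17, baseline_sd_log2 = 2.5,
                          group_shift_log2 = 0, n_infant_only = 0,
                          n_adult_only = 0, n_adults = 0, n_qc = 0, seed = 10L)
  sim <- simulate_cohort(cfg)
  inf_ids <- sim$sheet$sample_id[sim$sheet$cohort == "infant"]
  miss <- rowMeans(is.na(sim$table$lfq[, inf_ids]))
  bins <- cut(sim$truth$baseline, quantile(sim$truth$baseline, 0:5 / 5),
              include.lowest = TRUE)
  rate <- tapply(miss, bins, mean)
  expect_true(all(diff(rate) < 0))
})

test_that("apply_missingness builds QC and adult columns as stated", {
  cfg <- small_config(noise_sd_log2 = 0, qc_noise_sd_log2 = 0,
                      group_shift_log2 = 0, mnar_slope = 0, seed = 6L)
  sim <- simulate_cohort(cfg)
  sheet <- sim$sheet
  expect_equal(sum(sheet$cohort == "qc"), cfg$n_qc)
  expect_equal(sum(sheet$cohort == "adult"), cfg$n_adults)
  # noiseless QC injections equal the per-protein infant cohort mean
  qc_ids <- sheet$sample_id[sheet$cohort == "qc"]
  pool <- rowMeans(sim$tensor, dims = 1)
  ord <- !sim$truth$adult_only
  expect_equal(unname(log2(sim$table$lfq[ord, qc_ids[1]])),
               unname(pool[ord]))
  # infant-only proteins are absent from every adult column
  adu_ids <- sheet$sample_id[sheet$cohort == "adult"]
  expect_true(all(is.na(sim$table$lfq[sim$truth$infant_only, adu_ids])))
  # adult-only proteins are absent from infant and QC columns
  inf_ids <- sheet$sample_id[sheet$cohort == "infant"]
  expect_true(all(is.na(sim$table$lfq[sim$truth$adult_only,
                                      c(inf_ids, qc_ids)])))
  # detected cells carry at least one unique precursor
  det <- !is.na(sim$table$lfq)
  expect_true(all(sim$table$precursors[det] >= 1))
  expect_true(all(sim$table$precursors[!det] == 0))
})

test_that("availability exceeding the cohort is rejected", {
  expect_error(generator_config(n_aga = 5, n_sga = 2,
                                availability = c(3, 8, 5, 5, 3)),
               "availability")
  expect_error(generator_config(n_increasing = 500, n_decreasing = 500,
                                n_stable = 100),
               "sum to n_proteins")
})
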