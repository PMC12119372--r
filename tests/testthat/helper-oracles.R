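# Independent brute-force oracles. These deliberately use naive loops and
# textbook formulas so they share no code path with the implementation.

# trapezoid rule by explicit segment summation
trapz_oracle <- function(y, x) {
  area <- 0
  for (i in seq_len(length(y) - 1)) {
    area <- area + (y[i] + y[i + 1]) / 2 * (x[i + 1] - x[i])
  }
  area
}

# squared Pearson correlation from raw sums
pearson_r2_oracle <- function(a, b) {
  n <- length(a)
  sxy <- sum(a * b) - n * mean(a) * mean(b)
  sxx <- sum(a^2) - n * mean(a)^2
  syy <- sum(b^2) - n * mean(b)^2
  (sxy / sqrt(sxx * syy))^2
}

# BH step-up straight from the definition: adj for the i-th smallest p is
# min over j >= i of p_(j) * m / j, capped at 1
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, sorted[j] * m / j)
    adj_sorted[i] <- min(1, best)
  }
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# CV in percent with an explicit n-1 sample SD
cv_oracle <- function(x) {
  mu <- sum(x) / length(x)
  100 * sqrt(sum((x - mu)^2) / (length(x) - 1)) / mu
}

# small hand-buildable quant tables
toy_table <- function(lfq, precursors = NULL, scale = "linear") {
  if (is.null(rownames(lfq))) {
    rownames(lfq) <- sprintf("PG%02d", seq_len(nrow(lfq)))
  }
  if (is.null(colnames(lfq))) {
    colnames(lfq) <- sprintf("S%02d", seq_len(ncol(lfq)))
  }
  quant_table(lfq, precursors, scale = scale)
}

# sheet for a pure infant design: one subject per sample column, day given
# per column
toy_infant_sheet <- function(sample_ids, days, groups = NULL) {
  data.frame(sample_id = sample_ids,
             subject_id = paste0("subj_", sample_ids),
             cohort = "infant",
             group = if (is.null(groups)) "AGA" else groups,
             day = days, stringsAsFactors = FALSE)
}

# a small fast generator config for tests that only need structure
small_config <- function(...) {
  defaults <- list(n_proteins = 60, n_aga = 8, n_sga = 4, n_adults = 3,
                   n_qc = 3, availability = c(6, 12, 10, 9, 5),
                   n_increasing = 10, n_decreasing = 10,
                   n_infant_only = 10, n_adult_only = 2, n_group_shifted = 5)
  do.call(generator_config, utils::modifyList(defaults, list(...)))
}
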