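write_wide_fixture <- function(path, lines) {
  writeLines(lines, path)
  path
}

test_that("wide reports round-trip with zero-as-missing", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Protein.Group\tGenes\tS1\tS2\tS3\tS4",
               "PG1\tALB\t1e6\t2e6\t0\t4e6",
               "PG2\tHPX\t5e5\t\t7e5\t8e5",
               "PG3\tIGHG2;IGHG4\t1\t2\t3\t4"), tmp)
  tab <- read_report(tmp, "wide_matrix")
  expect_equal(dim(tab), c(3L, 4L))
  expect_equal(tab$scale, "linear")
  expect_true(is.na(tab$lfq["PG1", "S3"]))  # zero becomes missing
  expect_true(is.na(tab$lfq["PG2", "S2"]))  # empty field stays missing
  expect_equal(tab$proteins$gene[3], "IGHG2;IGHG4")
  # missing cells carry precursor count 0, others unknown
  expect_equal(tab$precursors["PG1", "S3"], 0)
  expect_true(is.na(tab$precursors["PG1", "S1"]))
})

test_that("wide reports validate structure and sheet consistency", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Protein.Group\tGenes\tS1", "PG1\tA\t1", "PG1\tB\t2"), tmp)
  expect_error(read_report(tmp, "wide_matrix"), "duplicated protein group")

  writeLines(c("Protein.Group\tS1", "PG1\t1"), tmp)
  expect_error(read_report(tmp, "wide_matrix"), "Genes")

  writeLines(c("Protein.Group\tGenes\tS1\tSX", "PG1\tA\t1\t2"), tmp)
  sheet <- toy_infant_sheet("S1", 0)
  expect_error(read_report(tmp, "wide_matrix", sheet = sheet), "SX")
})

test_that("long reports pivot correctly and reject duplicates", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Protein.Group\tGenes\tSample\tLFQ\tUnique.Precursors",
               "PG1\tA\tS1\t100\t3",
               "PG1\tA\tS2\t200\t1",
               "PG2\tB\tS1\t300\t5"), tmp)
  tab <- read_report(tmp, "long_report")
  expect_equal(dim(tab), c(2L, 2L))
  expect_equal(tab$lfq["PG1", "S2"], 200)
  expect_equal(tab$precursors["PG1", "S2"], 1)
  expect_true(is.na(tab$lfq["PG2", "S2"]))  # unreported pair is missing
  expect_equal(tab$precursors["PG2", "S2"], 0)

  writeLines(c("Protein.Group\tGenes\tSample\tLFQ\tUnique.Precursors",
               "PG1\tA\tS1\t100\t3",
               "PG1\tA\tS1\t150\t2"), tmp)
  expect_error(read_report(tmp, "long_report"), "duplicated \\(protein, sample\\)")
})

test_that("sample sheets are validated", {
  sheet <- data.frame(sample_id = c("a", "b"), subject_id = c("p1", "p2"),
                      cohort = c("infant", "qc"), group = c("AGA", NA),
                      day = c(3, NA), stringsAsFactors = FALSE)
  expect_silent(validate_sample_sheet(sheet))
  bad <- sheet; bad$day[2] <- 7
  expect_error(validate_sample_sheet(bad), "must not carry a day")
  bad <- sheet; bad$day[1] <- NA
  expect_error(validate_sample_sheet(bad), "without a postnatal day")
  bad <- sheet; bad$cohort[2] <- "mouse"
  expect_error(validate_sample_sheet(bad), "unknown cohort")
  bad <- rbind(sheet, sheet[1, ])
  expect_error(validate_sample_sheet(bad), "duplicated sample id")
})

test_that("precursor filter censors low-evidence cells and is idempotent", {
  lfq <- matrix(1e6, 2, 3)
  prec <- matrix(c(1, 2, 3, 0, 2, 1), 2, 3)
  tab <- toy_table(lfq, prec)
  f <- filter_min_precursors(tab)
  # boundary: 1 precursor is censored, 2 retained unchanged
  expect_true(is.na(f$lfq[1, 1]))
  expect_equal(f$lfq[2, 1], 1e6)
  expect_true(is.na(f$lfq[2, 3]))
  expect_identical(filter_min_precursors(f), f)
  # all counts >= 2: no-op
  tab2 <- toy_table(matrix(10, 2, 2), matrix(2, 2, 2))
  expect_identical(filter_min_precursors(tab2), tab2)
  # never increases the number of present cells (random property)
  set.seed(1)
  for (k in 1:20) {
    lfq <- matrix(runif(30, 1, 10), 5, 6)
    lfq[sample(30, 8)] <- NA
    prec <- matrix(rpois(30, 2), 5, 6)
    t0 <- toy_table(lfq, prec)
    t1 <- filter_min_precursors(t0)
    expect_lte(sum(!is.na(t1$lfq)), sum(!is.na(t0$lfq)))
    expect_identical(filter_min_precursors(t1), t1)
  }
})

test_that("completeness filter applies the 50%/40% conjunction", {
  # 6 infant samples at each of two days, 5 adults
  days <- rep(c(0, 3), each = 6)
  inf_ids <- sprintf("I%02d", 1:12)
  sheet <- rbind(toy_infant_sheet(inf_ids, days),
                 data.frame(sample_id = sprintf("A%d", 1:5),
                            subject_id = sprintf("A%d", 1:5),
                            cohort = "adult", group = NA, day = NA))
  present <- function(pattern) ifelse(pattern == 1, 100, NA)
  lfq <- rbind(
    both_days_half = present(c(1,1,1,0,0,0, 1,1,1,0,0,0)),  # 3/6 = 50% each day
    one_day_third  = present(c(1,1,0,0,0,0, 1,1,1,1,1,1)),  # 33% at day 0
    infant_strong  = present(rep(1, 12)),
    never          = present(rep(0, 12)))
  adult <- rbind(both_days_half = present(c(1,1,0,0,0)),  # 2/5 = 40%
                 one_day_third  = present(c(1,0,0,0,0)),  # 20%
                 infant_strong  = present(rep(0, 5)),
                 never          = present(rep(1, 5)))
  m <- cbind(lfq, adult)
  colnames(m) <- c(inf_ids, sprintf("A%d", 1:5))
  tab <- quant_table(m, scale = "linear")
  res <- filter_completeness(tab, sheet)
  rep_ <- res$report
  # 50% at every day passes (inclusive boundary), and 6/12 >= 40% overall
  expect_true(rep_$retained_infant[rep_$protein_id == "both_days_half"])
  # 33% at one day fails the per-timepoint rule despite 58% overall
  expect_false(rep_$retained_infant[rep_$protein_id == "one_day_third"])
  # adults: inclusive 40% boundary
  expect_true(rep_$retained_adult[rep_$protein_id == "both_days_half"])
  expect_false(rep_$retained_adult[rep_$protein_id == "one_day_third"])
  # infant-only protein ends up in the infant-only presence set
  sets <- presence_sets(rep_)
  expect_true("infant_strong" %in% sets$infant_only)
  expect_true("never" %in% sets$adult_only)
  expect_true("both_days_half" %in% sets$shared)
  # "one_day_third" fails both cohorts (33% day rule, 20% adults): dropped
  expect_equal(sort(rownames(res$table$lfq)),
               sort(c("both_days_half", "infant_strong", "never")))
  expect_false("one_day_third" %in%
                 rep_$protein_id[rep_$retained_infant])
})

test_that("completeness filter is idempotent and reports brute-force fractions", {
  sim <- simulate_cohort(small_config(seed = 12L))
  tab <- filter_min_precursors(sim$table)
  res <- filter_completeness(tab, sim$sheet)
  res2 <- filter_completeness(res$table, sim$sheet)
  expect_identical(res2$table$lfq, res$table$lfq)
  expect_lte(nrow(res$table$lfq), nrow(tab$lfq))
  # fractions equal brute-force counting for a handful of proteins/days
  inf <- sim$sheet[sim$sheet$cohort == "infant", ]
  for (pid in sample(res$report$protein_id, 5)) {
    for (d in unique(inf$day)) {
      ids <- inf$sample_id[inf$day == d]
      frac <- sum(!is.na(tab$lfq[pid, ids])) / length(ids)
      expect_equal(res$report[res$report$protein_id == pid,
                              paste0("frac_day_", d)], frac)
    }
  }
})

test_that("log2 transform maps the examples and guards its domain", {
  tab <- toy_table(matrix(c(8, 1, NA, 2), 2, 2))
  lt <- log2_transform(tab)
  expect_equal(lt$lfq[1, 1], 3)
  expect_equal(lt$lfq[2, 1], 0)
  expect_true(is.na(lt$lfq[1, 2]))
  expect_equal(lt$scale, "log2")
  expect_error(log2_transform(lt), "already log2")
  expect_error(log2_transform(toy_table(matrix(c(-1, 1, 1, 1), 2, 2))),
               "non-positive")
})

test_that("quant tables are written and re-read faithfully", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  lfq <- matrix(c(100.5, NA, 3, 4e6), 2, 2)
  tab <- toy_table(lfq)
  write_quant_table(tab, tmp)
  back <- read_report(tmp, "wide_matrix")
  expect_equal(back$lfq, tab$lfq)
  expect_equal(back$proteins, tab$proteins)
})
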