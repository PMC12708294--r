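# cohort model: LANG definition, CSV round trip, validation, QC filtering,
# simulator contracts

test_that("LANG definition and improvement classes", {
  expect_equal(compute_lang(2, 1), list(lang = -1L, improved = 1L))
  expect_equal(compute_lang(0, 0), list(lang = 0L, improved = 0L))
  expect_equal(compute_lang(1, 3), list(lang = 2L, improved = 0L))
  expect_error(compute_lang(4, 1), "0-3")
  expect_error(compute_lang(1, -1), "0-3")
  expect_error(compute_lang(1.5, 1), "0-3")
})

test_that("CSV round trip preserves a synthetic cohort", {
  tb <- simulate_cohort(simulation_params(n_male = 30, n_female = 20,
                                          seed = 11))
  path <- file.path(tempdir(), "cohort.csv")
  write_cohort(tb, path)
  back <- load_cohort(path)
  expect_equal(nrow(back), 50)
  for (v in c("gcs", "vol", "lang", "crp"))
    expect_equal(back[[v]], tb[[v]], tolerance = 1e-8)
})

test_that("validation catches range and consistency violations", {
  tb <- as.data.frame(simulate_cohort(simulation_params(n_male = 5,
                                                        n_female = 5,
                                                        seed = 2)))
  path <- file.path(tempdir(), "bad.csv")
  bad <- tb; bad$gcs[1] <- 20
  write.csv(bad, path, row.names = FALSE)
  expect_error(load_cohort(path), "3, 15")
  bad2 <- tb; bad2$lang[2] <- bad2$lang[2] + 1
  write.csv(bad2, path, row.names = FALSE)
  expect_error(load_cohort(path), "inconsistent")
  bad3 <- tb; names(bad3)[names(bad3) == "gcs"] <- "gcs_score"
  write.csv(bad3, path, row.names = FALSE)
  expect_error(load_cohort(path), "column")
})

test_that("drop_incomplete: variables first, then complete cases", {
  tb <- simulate_cohort(simulation_params(n_male = 3, n_female = 3, seed = 3))
  df <- as.data.frame(tb)
  df$crp[2] <- NA
  t1 <- drop_incomplete(asymstroke:::as_cohort_table(df))
  expect_equal(nrow(t1), 5)
  # missingness confined to an excluded variable: nothing dropped
  df2 <- as.data.frame(tb)
  df2$mrs_3mo <- c(NA, NA, 1, 2, 3, NA)
  t2 <- drop_incomplete(asymstroke:::as_cohort_table(df2), "mrs_3mo")
  expect_equal(nrow(t2), 6)
  expect_error(drop_incomplete(tb, "nonexistent_var"), "not in table")
})

test_that("enrolment emulation: 204 rows reduce to exactly 164", {
  enr <- simulate_enrollment(seed = 7)
  expect_equal(nrow(enr), 204)
  flt <- drop_incomplete(enr, followup_vars())
  expect_equal(nrow(flt), 164)
  rpt <- attr(flt, "qc_report")
  expect_equal(rpt$n_before, 204)
  expect_gt(rpt$missing_per_var[["homocysteine"]], 0)
})

test_that("simulator is deterministic per seed and respects invariants", {
  p <- simulation_params(seed = 5)
  a <- simulate_cohort(p); b <- simulate_cohort(p)
  expect_identical(as.data.frame(a), as.data.frame(b))
  cb <- cohort_codebook()
  for (i in seq_len(nrow(cb))) {
    v <- a[[cb$name[i]]]
    expect_true(all(v >= cb$lo[i] & v <= cb$hi[i]), label = cb$name[i])
  }
  expect_true(all(a$lang == a$nihss9_post - a$nihss9_pre))
  expect_true(all(a$lang >= -3 & a$lang <= 3))
  expect_true(all(a$lang_improved == (a$lang < 0)))
})

test_that("parameter recovery at n = 10000 within 3 standard errors", {
  big <- simulate_cohort(simulation_params(n_male = 10000, n_female = 10000,
                                           seed = 6))
  cb <- cohort_codebook()
  for (v in c("age", "vol", "cl", "gcs")) {
    row <- cb[cb$name == v, ]
    x <- big[[v]][big$gender == "male"]
    se <- row$sd_male / sqrt(length(x))
    tol <- 3 * se + (row$integer) * 0.3   # rounding/truncation slack
    expect_lt(abs(mean(x) - row$mean_male), tol + 0.2)
  }
  for (v in c("hemisphere_left", "cerebellar")) {
    row <- cb[cb$name == v, ]
    x <- big[[v]][big$gender == "female"]
    se <- sqrt(row$prev_female * (1 - row$prev_female) / length(x))
    expect_lt(abs(mean(x) - row$prev_female), 3 * se + 1e-9)
  }
})

test_that("null outcome model decouples LANG from GCS", {
  hits <- 0
  for (s in 1:20) {
    tb <- simulate_cohort(simulation_params(
      outcome_coefs = c(gcs = 0, adl = 0, mrs_discharge = 0, vol = 0),
      seed = s))
    if (abs(cor(tb$gcs, tb$lang)) < 0.2) hits <- hits + 1
  }
  expect_gte(hits, 19)
})
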