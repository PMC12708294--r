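# group statistics: hand-derived values, enumeration oracles, invariants
# (published-value recomputation lives in test-acceptance.R)

test_that("Welch t: hand-evaluated example, identity case, antisymmetry", {
  # A = {1,2,3}, B = {2,3,4}: t = +1.2247, SE = sqrt(2/3)
  w <- welch_t(2, 1, 3, 3, 1, 3)
  expect_equal(w$t, 1 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(welch_t(5, 2, 10, 5, 2, 10)$t, 0)
  for (k in 1:10) {
    set.seed(k)
    s <- list(mA = rnorm(1), sA = runif(1, 0.5, 3), nA = sample(3:50, 1),
              mB = rnorm(1), sB = runif(1, 0.5, 3), nB = sample(3:50, 1))
    a <- welch_t(s$mA, s$sA, s$nA, s$mB, s$sB, s$nB)
    b <- welch_t(s$mB, s$sB, s$nB, s$mA, s$sA, s$nA)
    expect_equal(a$t, -b$t)
    expect_equal(a$p, b$p)
    da <- cohens_d_pooled(s$mA, s$sA, s$nA, s$mB, s$sB, s$nB)
    db <- cohens_d_pooled(s$mB, s$sB, s$nB, s$mA, s$sA, s$nA)
    expect_equal(da, -db)
  }
  expect_error(welch_t(1, 0, 5, 2, 0, 5), "zero variance")
})

test_that("Cohen's d: toy example with unit pooled SD", {
  expect_equal(cohens_d_pooled(2, 1, 3, 3, 1, 3), 1.0)
  expect_equal(cohens_d_pooled(4, 2, 9, 4, 3, 9), 0)
})

test_that("Yates chi-square: clamping and zero-margin routing", {
  expect_equal(yates_chi_square(10, 10, 20, 20)$chi2, 0)
  expect_error(yates_chi_square(0, 0, 5, 5), "margin")
  expect_error(yates_chi_square(1.5, 2, 3, 4), "integer")
})

test_that("Fisher exact: enumeration oracle and degenerate margins", {
  expect_equal(fisher_exact_two_sided(2, 0, 0, 2), 1 / 3)
  expect_equal(fisher_exact_two_sided(0, 0, 3, 4), 1)   # zero row margin
  # oracle: stats::fisher.test over random small tables (n <= 40)
  set.seed(42)
  for (k in 1:25) {
    tab <- as.vector(stats::rmultinom(1, sample(5:40, 1), runif(4, 0.05, 1)))
    ours <- fisher_exact_two_sided(tab[1], tab[2], tab[3], tab[4])
    ref <- stats::fisher.test(matrix(tab, 2, byrow = TRUE))$p.value
    expect_equal(ours, ref, tolerance = 1e-9,
                 label = paste(tab, collapse = ","))
  }
})

test_that("bias-corrected Cramer's V: perfect association and invariance", {
  expect_equal(cramers_v_bias_corrected(5, 0, 0, 5), 1.0)
  expect_error(cramers_v_bias_corrected(1, 0, 0, 0), "n >= 2")
  # swapping rows or columns leaves V unchanged
  expect_equal(cramers_v_bias_corrected(32, 13, 69, 50),
               cramers_v_bias_corrected(69, 50, 32, 13))
  expect_equal(cramers_v_bias_corrected(32, 13, 69, 50),
               cramers_v_bias_corrected(13, 32, 50, 69))
})

test_that("Benjamini-Hochberg: hand-evaluated cases, monotonicity, p.adjust oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.001, 0.5)), c(0.002, 0.5))
  set.seed(7)
  for (k in 1:10) {
    p <- runif(sample(2:30, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, p.adjust(p, "BH"))
    expect_true(all(adj >= p - 1e-12))
    # monotone with respect to the sorted raw p values
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    expect_true(all(adj <= 1))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("compare_groups routes by the expected-frequency rule", {
  # build a cohort whose Broca counts give min expected < 5 -> Fisher
  tb <- simulate_cohort(simulation_params(seed = 9))
  cmp <- compare_groups(tb, "gender")
  df <- as.data.frame(cmp)
  broca <- df[df$variable == "broca", ]
  n_broca <- sum(tb$broca)
  min_exp <- min(outer(c(n_broca, 164 - n_broca), c(101, 63)) / 164)
  if (min_exp < 5) expect_equal(broca$stat_kind, "fisher")
  hemi <- df[df$variable == "hemisphere_left", ]
  expect_equal(hemi$stat_kind, "yates_chi2")
  # adjusted p >= raw p, all p in [0,1]
  expect_true(all(df$p_adjusted >= df$p - 1e-12))
  expect_true(all(df$p >= 0 & df$p <= 1))
  # continuous variables use welch + cohens d
  expect_equal(df$stat_kind[df$variable == "age"], "welch_t")
  expect_equal(df$effect_kind[df$variable == "age"], "cohens_d")
  expect_error(compare_groups(tb, "vol"), "arg")
})

test_that("compare_groups by improvement includes gender, excludes lang", {
  tb <- simulate_cohort(simulation_params(seed = 10))
  cmp <- compare_groups(tb, "lang_improved")
  df <- as.data.frame(cmp)
  expect_true("gender" %in% df$variable)
  expect_false("lang" %in% df$variable)
  grp <- attr(cmp, "groups")
  expect_equal(sum(grp), 164)
  expect_equal(names(grp), c("1", "0"))   # improvement group first
})

test_that("type-I error calibration under a null grouping", {
  # identical distributions in both groups: raw p < 0.05 in ~5% of tests
  set.seed(123)
  hits <- 0; total <- 0
  for (s in 1:12) {
    tb <- simulate_cohort(simulation_params(
      n_male = 82, n_female = 82, seed = 400 + s,
      codebook = local({
        cb <- cohort_codebook()
        cb$mean_female <- cb$mean_male; cb$sd_female <- cb$sd_male
        cb$prev_female <- cb$prev_male
        cb
      })))
    cmp <- compare_groups(tb, "gender")
    hits <- hits + sum(cmp$p < 0.05)
    total <- total + nrow(cmp)
  }
  expect_lt(abs(hits / total - 0.05), 0.02)
})
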