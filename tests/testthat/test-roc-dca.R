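# ROC rank estimator + DeLong interval, threshold rule, decision curves

test_that("AUC matches rank-statistic enumeration on small cases", {
  expect_equal(roc_analysis(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_analysis(c(1, 1, 2, 2), c(0, 1, 0, 1))$auc, 0.5)
  r <- roc_analysis(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$ci[2], 1)
})

test_that("AUC equals the exhaustive pairwise oracle (n <= 200)", {
  set.seed(11)
  for (k in 1:20) {
    n <- sample(10:200, 1)
    labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- round(rnorm(n, labels, 1.2), sample(0:2, 1))  # induce ties
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    oracle <- 0
    for (a in pos) for (b in neg)
      oracle <- oracle + (a > b) + 0.5 * (a == b)
    oracle <- oracle / (length(pos) * length(neg))
    r <- roc_analysis(scores, labels)
    expect_equal(r$auc, oracle, tolerance = 1e-12)
    expect_true(r$ci[1] <= r$auc && r$auc <= r$ci[2])
  }
})

test_that("confusion metrics at the threshold are self-consistent", {
  # counts mirroring the published confusion structure:
  # TP 35, FN 10, TN 82, FP 37 -> sens .778, spec .689
  scores <- c(rep(0.9, 35), rep(0.1, 10), rep(0.05, 82), rep(0.8, 37))
  labels <- c(rep(1, 45), rep(0, 119))
  r <- roc_analysis(scores, labels, threshold = 0.5)
  expect_equal(unname(r$confusion), c(35, 37, 82, 10))
  expect_equal(r$sensitivity, 35 / 45, tolerance = 1e-12)
  expect_equal(r$specificity, 82 / 119, tolerance = 1e-12)
  expect_equal(r$accuracy, 117 / 164, tolerance = 1e-12)
  expect_equal(r$ppv, 35 / 72, tolerance = 1e-12)
  expect_equal(r$npv, 82 / 92, tolerance = 1e-12)
  expect_equal(round(r$sensitivity, 3), 0.778)
  expect_equal(round(r$specificity, 3), 0.689)
})

test_that("Youden ties resolve to the lower threshold; errors on one class", {
  scores <- c(1, 2, 3, 4)
  labels <- c(0, 0, 1, 1)
  r <- roc_analysis(scores, labels)
  expect_equal(r$threshold, 3)   # J max first reached at the lowest threshold
  expect_error(roc_analysis(scores, c(1, 1, 1, 1)), "both classes")
})

test_that("DeLong interval covers a true AUC of 0.8 in ~95% of samples", {
  # binormal scores at n = 164 (45/119), true AUC = 0.8
  mu <- sqrt(2) * qnorm(0.8)
  hits <- 0
  set.seed(99)
  for (k in 1:500) {
    neg <- rnorm(119); pos <- rnorm(45, mu)
    r <- roc_analysis(c(pos, neg), c(rep(1, 45), rep(0, 119)))
    if (r$ci[1] <= 0.8 && 0.8 <= r$ci[2]) hits <- hits + 1
  }
  expect_lt(abs(hits / 500 - 0.95), 0.03)
})

test_that("decision curve identities hold for arbitrary inputs", {
  set.seed(12)
  for (k in 1:5) {
    n <- sample(30:150, 1)
    labels <- rbinom(n, 1, runif(1, 0.2, 0.7))
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- runif(n)
    d <- decision_curve(scores, labels, n_boot = 30, seed = k)
    expect_equal(d$curve$nb_none, rep(0, nrow(d$curve)))
    expect_equal(d$curve$nb_model[1], d$prevalence)
    expect_equal(d$curve$nb_all[1], d$prevalence)
    # treat-all crosses zero at the prevalence
    pi_ <- d$prevalence
    f <- function(pt) pi_ - (1 - pi_) * pt / (1 - pt)
    expect_lt(abs(f(pi_)), 1e-12)
  }
})

test_that("hand-evaluated net benefit and input validation", {
  # n = 10, 4 positives; at pt = 0.5 classifier with TP = 3, FP = 1
  labels <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  scores <- c(0.9, 0.8, 0.7, 0.2, 0.6, 0.3, 0.2, 0.1, 0.1, 0.1)
  d <- decision_curve(scores, labels, thresholds = 0.5, n_boot = 10, seed = 1)
  expect_equal(d$curve$nb_model, (3 - 1 * 1) / 10)
  expect_error(decision_curve(scores, labels, thresholds = c(0.5, 1)),
               "1)")
  expect_error(decision_curve(scores * 2, labels), "probabilities")
})

test_that("bootstrap band is deterministic per seed and brackets the curve", {
  set.seed(13)
  labels <- rbinom(80, 1, 0.4); labels[1:2] <- c(0, 1)
  scores <- pmin(pmax(labels * 0.3 + runif(80, 0, 0.7), 0), 1)
  d1 <- decision_curve(scores, labels, n_boot = 100, seed = 5)
  d2 <- decision_curve(scores, labels, n_boot = 100, seed = 5)
  expect_identical(d1$curve, d2$curve)
  mid <- d1$curve$threshold > 0.05 & d1$curve$threshold < 0.6
  expect_true(all(d1$curve$nb_lo[mid] <= d1$curve$nb_hi[mid]))
})
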