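# GLASSO network, centralities, NOA, Bayesian structure learning, bootstrap

test_that("two correlated columns give one edge with the right weight", {
  set.seed(2)
  n <- 2000
  a <- rnorm(n); b <- 0.6 * a + sqrt(1 - 0.36) * rnorm(n); c <- rnorm(n)
  g <- glasso_network(data.frame(a, b, c), cor_method = "pearson")
  expect_equal(sum(g$weights[upper.tri(g$weights)] != 0), 1)
  expect_lt(abs(g$weights[1, 2] - 0.6), 0.05)
  expect_true(isSymmetric(g$weights))
  expect_equal(diag(g$weights), rep(0, 3))
})

test_that("precision-inversion oracle at vanishing penalty (p <= 6)", {
  set.seed(3)
  n <- 5000; p <- 6
  A <- matrix(0.25, p, p); diag(A) <- 1
  L <- chol(A)
  X <- matrix(rnorm(n * p), n, p) %*% L
  S <- cor(X)
  Theta <- asymstroke:::glasso_precision(S, 1e-6)
  pc_glasso <- asymstroke:::precision_to_pcor(Theta)
  pc_direct <- asymstroke:::precision_to_pcor(solve(S))
  expect_lt(max(abs(pc_glasso - pc_direct)), 0.02)
})

test_that("chain A-B-C: no direct A-C edge at the EBIC penalty", {
  absent <- 0
  for (s in 1:20) {
    set.seed(s)
    n <- 1000
    A <- rnorm(n); B <- 0.7 * A + rnorm(n, 0, 0.7)
    C <- 0.7 * B + rnorm(n, 0, 0.7)
    g <- glasso_network(data.frame(A, B, C), cor_method = "pearson")
    if (g$weights[1, 3] == 0) absent <- absent + 1
  }
  expect_gte(absent / 20, 0.9)
})

test_that("independent columns give an empty graph", {
  empty <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    X <- matrix(rnorm(500 * 5), 500, 5); colnames(X) <- letters[1:5]
    if (all(glasso_network(X, cor_method = "pearson")$weights == 0))
      empty <- empty + 1
  }
  expect_gte(empty / 20, 0.95)
})

test_that("selected edge count is non-increasing in the EBIC gamma", {
  set.seed(5)
  X <- matrix(rnorm(300 * 6), 300, 6)
  X[, 2] <- X[, 1] * 0.5 + rnorm(300, 0, 0.8)
  X[, 3] <- X[, 2] * 0.5 + rnorm(300, 0, 0.8)
  colnames(X) <- letters[1:6]
  ec <- vapply(c(0, 0.25, 0.5), function(g)
    sum(glasso_network(X, gamma = g,
                       cor_method = "pearson")$weights[upper.tri(diag(6))] != 0),
    0L)
  expect_true(all(diff(ec) <= 0))
})

test_that("centrality on hand-evaluated toy graphs", {
  W <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  W[1, 2] <- W[2, 1] <- 0.5; W[2, 3] <- W[3, 2] <- 0.3
  ct <- centrality(W)
  expect_equal(ct$strength, c(0.5, 0.8, 0.3))
  expect_equal(ct$expected_influence, c(0.5, 0.8, 0.3))
  expect_equal(ct$betweenness, c(0, 1, 0))
  expect_equal(ct$closeness[2], 1 / (1 / 0.5 + 1 / 0.3))
  # signed weights: strength uses absolute values, EI keeps the sign
  W[1, 2] <- W[2, 1] <- -0.5
  ct2 <- centrality(W)
  expect_equal(ct2$strength[2], 0.8)
  expect_equal(ct2$expected_influence[2], -0.2)
  expect_true(all(ct2$strength >= abs(ct2$expected_influence) - 1e-12))
  # empty graph
  ct0 <- centrality(matrix(0, 3, 3))
  expect_true(all(ct0$strength == 0 & ct0$closeness == 0 &
                    ct0$betweenness == 0))
})

test_that("NOA: errors, consistency with glasso, null outcome isolation", {
  set.seed(6)
  d <- data.frame(a = rnorm(400), b = rnorm(400), c = rnorm(400),
                  y = rnorm(400))
  expect_error(noa(d, c("a", "b", "y"), "y"), "must not be among")
  expect_error(noa(d, c("a", "zz"), "y"), "not in data")
  r <- noa(d, c("a", "b", "c"), "y", cor_method = "pearson")
  g <- glasso_network(d[, c("a", "b", "c", "y")], cor_method = "pearson")
  expect_equal(r$graph$weights, g$weights)
  # independent outcome: no outcome edges in most seeds
  iso <- 0
  for (s in 1:10) {
    set.seed(600 + s)
    d2 <- data.frame(a = rnorm(500), b = rnorm(500), c = rnorm(500))
    d2$a2 <- 0.5 * d2$a + rnorm(500, 0, 0.8)
    d2$y <- rnorm(500)
    if (length(noa(d2, c("a", "b", "c", "a2"), "y",
                   cor_method = "pearson")$outcome_edges) == 0) iso <- iso + 1
  }
  expect_gte(iso, 9)
})

test_that("hill climbing: null data give the empty graph", {
  # the BIC arc-addition rate under independence is ~0.9% per pair, so the
  # analytic empty-graph probability at p = 4, n = 1000 is (1-.009)^6 ~ .95;
  # with 40 finite seeds assert the property at 0.9
  empty <- 0
  for (s in 1:40) {
    set.seed(700 + s)
    X <- matrix(rnorm(1000 * 4), 1000, 4); colnames(X) <- letters[1:4]
    g <- hill_climb_bn(X, seed = s)
    if (nrow(g$arcs) == 0) empty <- empty + 1
  }
  expect_gte(empty / 40, 0.9)
})

test_that("collider orientation is identifiable and recovered", {
  # random restarts escape the score-equivalent fork/chain local optimum
  # that greedy search falls into when the first tie-coin orients C -> A
  hits <- 0
  for (s in 1:20) {
    set.seed(800 + s)
    A <- rnorm(2000); B <- rnorm(2000); C <- A + B + rnorm(2000)
    g <- hill_climb_bn(data.frame(A = A, B = B, C = C), seed = s,
                       restarts = 3)
    ok <- g$amat[1, 3] == 1 && g$amat[2, 3] == 1 &&
      g$amat[3, 1] == 0 && g$amat[3, 2] == 0 && nrow(g$arcs) == 2
    if (ok) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.9)
})

test_that("returned score equals independent BIC re-evaluation; DAG is acyclic", {
  set.seed(9)
  for (k in 1:5) {
    n <- 500; p <- sample(3:6, 1)
    X <- matrix(rnorm(n * p), n, p)
    for (j in 2:p) X[, j] <- X[, j] + 0.4 * X[, j - 1]
    colnames(X) <- paste0("v", 1:p)
    g <- hill_climb_bn(X, seed = k)
    C <- cov(X) * (n - 1) / n
    expect_equal(g$score, asymstroke:::bn_total_score(C, n, g$amat))
    # acyclicity via topological sort
    am <- g$amat
    order_ok <- TRUE
    remaining <- seq_len(p)
    while (length(remaining)) {
      roots <- remaining[colSums(am[remaining, remaining, drop = FALSE]) == 0]
      if (!length(roots)) { order_ok <- FALSE; break }
      remaining <- setdiff(remaining, roots)
    }
    expect_true(order_ok)
  }
})

test_that("bootstrap arcs: determinism, B = 1 strengths, thresholds", {
  set.seed(10)
  A <- rnorm(300); B <- 0.8 * A + rnorm(300, 0, 0.6); Z <- rnorm(300)
  d <- data.frame(A = A, B = B, Z = Z)
  b1 <- bootstrap_arcs(d, B = 50, seed = 3)
  b2 <- bootstrap_arcs(d, B = 50, seed = 3)
  expect_identical(b1$arcs, b2$arcs)
  single <- suppressWarnings(bootstrap_arcs(d, B = 1, seed = 3))
  expect_true(all(single$arcs$strength %in% c(0, 1)))
  expect_error(bootstrap_arcs(d, B = 0), "B must be")
  expect_error(bootstrap_arcs(d, B = 10, direction_threshold = 0.4),
               "0.5, 1")
  expect_warning(bootstrap_arcs(d, B = 5, direction_threshold = 0.99),
                 "small")
})

test_that("bootstrap consensus recovers the collider with directed arcs", {
  set.seed(11)
  A <- rnorm(2000); B <- rnorm(2000); C <- A + B + rnorm(2000)
  bb <- bootstrap_arcs(data.frame(A = A, B = B, C = C), B = 200, seed = 4)
  arcs <- bb$arcs[bb$arcs$directed, ]
  expect_setequal(paste(arcs$from, arcs$to), c("A C", "B C"))
  expect_true(all(arcs$direction_prob >= 0.51))
  expect_true(all(arcs$strength >= 0.5))
})

test_that("two-node Markov equivalence: the 51% rule abstains", {
  set.seed(1)
  A <- rnorm(300); D <- 0.7 * A + rnorm(300, 0, 0.7); Z <- rnorm(300)
  bb <- bootstrap_arcs(data.frame(A = A, D = D, Z = Z), B = 1000, seed = 4)
  ad <- bb$arcs[paste(bb$arcs$from, bb$arcs$to) %in% c("A D", "D A"), ]
  expect_equal(nrow(ad), 1)
  expect_gt(ad$strength, 0.9)
  # direction probability concentrates on 1/2 (score equivalence)
  expect_lt(abs(ad$direction_prob - 0.5), 0.05)
})
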