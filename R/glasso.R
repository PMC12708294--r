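# Regularized partial-correlation network: graphical lasso by block
# coordinate descent, EBIC penalty selection over a 100-point grid,
# centrality indices, and network outcome analysis (NOA).

# correlation matrix used as GLASSO input: Spearman rank correlations mapped
# to the Pearson scale through the sine transform (robust for ordinal scale
# scores), or plain Pearson.
input_correlation <- function(data, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (method == "pearson") return(cor(data))
  2 * sin(pi / 6 * cor(data, method = "spearman"))
}

# Graphical lasso for a fixed penalty: block coordinate descent
# (lasso regression of each variable on the rest against the current
# covariance estimate), returning the precision matrix Theta. `rho` may be
# a scalar or a p x p matrix of elementwise penalties (diagonal entries are
# added to the working covariance diagonal).
glasso_precision <- function(S, rho, tol = 1e-5, max_iter = 200) {
  p <- ncol(S)
  if (!is.matrix(rho)) rho <- matrix(rho, p, p)
  W <- S + diag(diag(rho))
  Bmat <- matrix(0, p - 1, p)      # warm-started regression coefficients
  for (it in seq_len(max_iter)) {
    W_old <- W
    for (j in seq_len(p)) {
      idx <- setdiff(seq_len(p), j)
      W11 <- W[idx, idx]
      s12 <- S[idx, j]
      rho_j <- rho[idx, j]
      # lasso subproblem: minimize 1/2 b' W11 b - s12' b + sum rho_j |b|
      b <- Bmat[, j]
      for (inner in seq_len(500)) {
        bmax <- 0
        for (k in seq_len(p - 1)) {
          bk <- b[k]
          zk <- s12[k] - sum(W11[k, ] * b) + W11[k, k] * bk
          bn <- soft_threshold(zk, rho_j[k]) / W11[k, k]
          if (bn != bk) {
            bmax <- max(bmax, abs(bn - bk))
            b[k] <- bn
          }
        }
        if (bmax < tol * 0.1) break
      }
      Bmat[, j] <- b
      W[idx, j] <- W11 %*% b
      W[j, idx] <- W[idx, j]
    }
    if (mean(abs(W - W_old)) < tol * mean(abs(S - diag(diag(S))) + 1e-12))
      break
  }
  Theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    b <- Bmat[, j]
    theta_jj <- 1 / (W[j, j] - sum(W[idx, j] * b))
    Theta[j, j] <- theta_jj
    Theta[idx, j] <- -b * theta_jj
  }
  (Theta + t(Theta)) / 2
}

# Restricted Gaussian MLE for a fixed support: graphical lasso with zero
# penalty on the support and an effectively infinite penalty elsewhere.
restricted_mle <- function(S, support) {
  p <- ncol(S)
  rho <- matrix(1e8, p, p)
  rho[support] <- 0
  diag(rho) <- 0
  glasso_precision(S, rho)
}

# Gaussian log-likelihood (up to constants) and EBIC of a precision matrix
ebic_score <- function(Theta, S, n, gamma) {
  p <- ncol(S)
  ld <- determinant(Theta, logarithm = TRUE)
  if (ld$sign <= 0) return(Inf)
  ll <- n / 2 * (as.numeric(ld$modulus) - sum(S * Theta))
  E <- sum(Theta[upper.tri(Theta)] != 0)
  -2 * ll + E * log(n) + 4 * gamma * E * log(p)
}

precision_to_pcor <- function(Theta) {
  D <- 1 / sqrt(diag(Theta))
  pc <- -Theta * outer(D, D)
  diag(pc) <- 0
  pc
}

#' Gaussian graphical model by graphical lasso with EBIC selection
#'
#' Estimates an L1-penalized precision matrix over a 100-point log-spaced
#' penalty grid (from the largest absolute off-diagonal input correlation
#' down to 1% of it) and picks the penalty minimizing the extended BIC with
#' parameter `gamma`. Edge weights are the partial correlations
#' `-theta_ij / sqrt(theta_ii theta_jj)`; every nonzero edge is retained
#' (no post-hoc threshold).
#'
#' @param data numeric matrix or data.frame (>= 3 columns); binary columns
#'   are used as 0/1 numerics.
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param n_lambda penalty-grid size (default 100).
#' @param lambda_min_ratio grid ratio (default 0.01).
#' @param cor_method `"spearman"` (sine-transformed, default) or
#'   `"pearson"`.
#' @return A `gaussian_graph`: `nodes`, `weights` (symmetric partial
#'   correlation matrix, zero diagonal), `lambda`, `gamma`, `n`,
#'   `lambda_grid`, `ebic`.
#' @export
glasso_network <- function(data, gamma = 0.5, n_lambda = 100,
                           lambda_min_ratio = 0.01,
                           cor_method = c("spearman", "pearson")) {
  data <- as.data.frame(data)
  num <- vapply(data, is.numeric, TRUE)
  data <- as.matrix(data[, num, drop = FALSE])
  if (ncol(data) < 3) stop_asym("glasso", "need at least 3 numeric columns")
  n <- nrow(data)
  if (n <= ncol(data))
    warning("fewer observations than variables; estimates are fragile")
  S <- input_correlation(data, match.arg(cor_method))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    # sine-transformed rank correlations can be slightly indefinite
    S <- S + diag(abs(min(ev)) + 1e-6, ncol(S))
    S <- stats::cov2cor(S)
  }
  lam_max <- max(abs(S[upper.tri(S)]))
  if (lam_max == 0) lam_max <- 0.1
  grid <- exp(seq(log(lam_max), log(lam_max * lambda_min_ratio),
                  length.out = n_lambda))
  # EBIC in its original form: each candidate support along the penalty
  # path is scored at the restricted maximum likelihood (refit), not at the
  # shrunken penalized estimate -- shrinkage of strong edges would otherwise
  # make the penalized likelihood decrease monotonically in lambda and the
  # selection degenerate to the smallest penalty.
  best <- NULL; best_ebic <- Inf
  ebics <- numeric(n_lambda)
  cache <- new.env(parent = emptyenv())
  for (k in seq_along(grid)) {
    Theta <- glasso_precision(S, grid[k])
    supp <- abs(Theta) > 1e-10
    key <- paste(which(supp[upper.tri(supp)]), collapse = ",")
    if (is.null(cache[[paste0("s", key)]])) {
      refit <- restricted_mle(S, supp)
      cache[[paste0("s", key)]] <- ebic_score(refit, S, n, gamma)
    }
    ebics[k] <- cache[[paste0("s", key)]]
    if (ebics[k] < best_ebic) {
      best_ebic <- ebics[k]; best <- list(support = supp, lambda = grid[k])
    }
  }
  if (is.null(best))
    stop_asym("glasso", "no penalty produced a positive-definite precision")
  # edge weights from the restricted MLE of the selected support (relaxed
  # refit): unshrunken partial correlations on the EBIC-selected pattern
  W <- precision_to_pcor(restricted_mle(S, best$support))
  W[!best$support] <- 0
  W[abs(W) < 1e-10] <- 0
  structure(list(nodes = colnames(data), weights = W, lambda = best$lambda,
                 gamma = gamma, n = n, lambda_grid = grid, ebic = ebics),
            class = "gaussian_graph")
}

#' @export
print.gaussian_graph <- function(x, ...) {
  E <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat(sprintf("<gaussian_graph> %d nodes, %d edges (lambda %.4g, gamma %.2g, n %d)\n",
              length(x$nodes), E, x$lambda, x$gamma, x$n))
  invisible(x)
}

#' Centrality indices of a partial-correlation network
#'
#' Strength (sum of absolute edge weights), expected influence (sum of
#' signed weights), closeness (inverse of the summed shortest-path lengths
#' to reachable nodes, edge length `1/|w|`) and betweenness (number of
#' shortest paths through the node). Isolated nodes get closeness and
#' betweenness 0.
#'
#' @param graph a `gaussian_graph` (or symmetric weight matrix).
#' @return Data.frame: node, strength, expected_influence, closeness,
#'   betweenness.
#' @export
centrality <- function(graph) {
  W <- if (inherits(graph, "gaussian_graph")) graph$weights else as.matrix(graph)
  nodes <- if (inherits(graph, "gaussian_graph")) graph$nodes
           else colnames(W) %||% paste0("V", seq_len(ncol(W)))
  p <- ncol(W)
  strength <- rowSums(abs(W))
  ei <- rowSums(W)
  closeness <- numeric(p); betweenness <- numeric(p)
  nz <- which(abs(W) > 0, arr.ind = TRUE)
  nz <- nz[nz[, 1] < nz[, 2], , drop = FALSE]
  if (nrow(nz) > 0) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = nodes[nz[, 1]], to = nodes[nz[, 2]]),
      directed = FALSE, vertices = data.frame(name = nodes))
    len <- 1 / abs(W[nz])
    d <- igraph::distances(g, weights = len)
    for (i in seq_len(p)) {
      di <- d[i, -i]
      fin <- di[is.finite(di)]
      closeness[i] <- if (length(fin)) 1 / sum(fin) else 0
    }
    betweenness <- igraph::betweenness(g, weights = len, directed = FALSE)
  }
  data.frame(node = nodes, strength = strength, expected_influence = ei,
             closeness = closeness, betweenness = as.numeric(betweenness),
             stringsAsFactors = FALSE)
}

#' Network outcome analysis (NOA)
#'
#' A GLASSO network restricted to the baseline predictors plus a single
#' outcome node, reporting the joint graph, its centralities, and the
#' outcome node's direct neighbours with edge weights.
#'
#' @param data data.frame with all variables.
#' @param baseline_vars character vector of predictor columns.
#' @param outcome_var single outcome column, not among `baseline_vars`.
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param ... passed to [glasso_network()].
#' @return List: `graph` (a `gaussian_graph`), `centrality`,
#'   `outcome_edges` (named weights of the outcome's direct neighbours).
#' @export
noa <- function(data, baseline_vars, outcome_var, gamma = 0.5, ...) {
  if (outcome_var %in% baseline_vars)
    stop_asym("noa", "outcome_var must not be among baseline_vars")
  missing_v <- setdiff(c(baseline_vars, outcome_var), names(data))
  if (length(missing_v))
    stop_asym("noa", paste("variables not in data:",
                           paste(missing_v, collapse = ", ")))
  g <- glasso_network(data[, c(baseline_vars, outcome_var), drop = FALSE],
                      gamma = gamma, ...)
  w <- g$weights[, match(outcome_var, g$nodes)]
  names(w) <- g$nodes
  w <- w[w != 0]
  list(graph = g, centrality = centrality(g), outcome_edges = w)
}

#' Export a network as an edge-list data.frame
#'
#' @param graph a `gaussian_graph` or `directed_graph`.
#' @return Data.frame `node_a`, `node_b`, `weight` (plus `strength`,
#'   `direction_prob` for directed graphs).
#' @export
edge_list <- function(graph) {
  if (inherits(graph, "directed_graph")) {
    return(graph$arcs)
  }
  W <- graph$weights
  nz <- which(abs(W) > 0, arr.ind = TRUE)
  nz <- nz[nz[, 1] < nz[, 2], , drop = FALSE]
  data.frame(node_a = graph$nodes[nz[, 1]], node_b = graph$nodes[nz[, 2]],
             weight = W[nz], stringsAsFactors = FALSE)
}
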