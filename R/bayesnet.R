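# Linear-Gaussian Bayesian network structure learning: greedy hill climbing
# over single-arc additions/deletions/reversals scored by the Gaussian BIC,
# and nonparametric-bootstrap aggregation of arc strength and direction.

# decomposable node score: Gaussian log-likelihood of node i given parents,
# minus (k/2) log n with k = |parents| + 2 (coefficients, intercept,
# variance). Computed from the MLE covariance.
node_score <- function(C, n, i, parents) {
  sigma2 <- if (length(parents) == 0) C[i, i] else {
    C[i, i] - C[i, parents, drop = FALSE] %*%
      solve(C[parents, parents, drop = FALSE],
            C[parents, i, drop = FALSE])
  }
  sigma2 <- max(as.numeric(sigma2), 1e-12)
  ll <- -n / 2 * (log(2 * pi * sigma2) + 1)
  ll - (length(parents) + 2) / 2 * log(n)
}

bn_total_score <- function(C, n, amat) {
  sum(vapply(seq_len(ncol(amat)),
             function(i) node_score(C, n, i, which(amat[, i] == 1)), 0.0))
}

# would adding arc from -> to create a cycle? (is `from` reachable from `to`)
creates_cycle <- function(amat, from, to) {
  stack <- to
  seen <- logical(ncol(amat))
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (v == from) return(TRUE)
    if (seen[v]) next
    seen[v] <- TRUE
    stack <- c(stack, which(amat[v, ] == 1))
  }
  FALSE
}

#' Hill-climbing Bayesian network structure learning
#'
#' Greedy search over directed acyclic graphs from the empty graph,
#' considering single-arc additions, deletions and reversals, maximizing the
#' Gaussian BIC score, until no move improves. Optional random restarts
#' perturb the current optimum and keep the best-scoring result.
#'
#' @param data numeric matrix/data.frame (categorical variables 0/1-coded).
#' @param restarts number of random restarts (default 0).
#' @param seed integer seed controlling the tie-break among score-equivalent
#'   moves and the random restarts; the fit is deterministic per seed.
#' @param max_parents cap on the in-degree (default 8).
#' @return A `directed_graph`: `nodes`, `amat` (adjacency, `amat[i, j] = 1`
#'   for arc i -> j), `arcs` (edge list), `score` (Gaussian BIC).
#' @export
hill_climb_bn <- function(data, restarts = 0, seed = 1L, max_parents = 8) {
  data <- as.matrix(as.data.frame(lapply(as.data.frame(data), as.numeric)))
  nodes <- colnames(data) %||% paste0("V", seq_len(ncol(data)))
  n <- nrow(data); p <- ncol(data)
  C <- cov(data) * (n - 1) / n
  climb <- function(amat) {
    ns <- vapply(seq_len(p), function(i) node_score(C, n, i,
                                                    which(amat[, i] == 1)),
                 0.0)
    repeat {
      best_delta <- 1e-10
      cand <- list()     # all moves tied (to relative 1e-9) with the best
      consider <- function(d, move) {
        tol <- 1e-9 * (1 + abs(best_delta))
        if (d > best_delta + tol) {
          best_delta <<- d; cand <<- list(move)
        } else if (d > best_delta - tol && length(cand)) {
          cand[[length(cand) + 1]] <<- move
        }
      }
      for (i in seq_len(p)) for (j in seq_len(p)) {
        if (i == j) next
        if (amat[i, j] == 1) {
          # deletion
          d <- node_score(C, n, j, setdiff(which(amat[, j] == 1), i)) - ns[j]
          consider(d, c(1, i, j))
          # reversal
          if (amat[j, i] == 0) {
            am2 <- amat; am2[i, j] <- 0
            if (!creates_cycle(am2, j, i) &&
                sum(amat[, i]) + 1 <= max_parents) {
              d2 <- (node_score(C, n, j, setdiff(which(amat[, j] == 1), i)) -
                       ns[j]) +
                (node_score(C, n, i, c(which(amat[, i] == 1), j)) - ns[i])
              consider(d2, c(2, i, j))
            }
          }
        } else if (amat[j, i] == 0) {
          # addition i -> j
          if (sum(amat[, j]) + 1 > max_parents) next
          if (creates_cycle(amat, i, j)) next
          d <- node_score(C, n, j, c(which(amat[, j] == 1), i)) - ns[j]
          consider(d, c(0, i, j))
        }
      }
      if (!length(cand)) break
      # score-equivalent moves (e.g. the two orientations of a fresh arc in
      # a Markov-equivalence class) are exact ties: break them at random so
      # bootstrap direction probabilities are unbiased
      best_move <- if (length(cand) == 1) cand[[1]] else
        cand[[sample.int(length(cand), 1)]]
      i <- best_move[2]; j <- best_move[3]
      if (best_move[1] == 0) {
        amat[i, j] <- 1
      } else if (best_move[1] == 1) {
        amat[i, j] <- 0
      } else {
        amat[i, j] <- 0; amat[j, i] <- 1
        ns[i] <- node_score(C, n, i, which(amat[, i] == 1))
      }
      ns[j] <- node_score(C, n, j, which(amat[, j] == 1))
    }
    amat
  }
  res <- with_seed(seed, {
    amat <- climb(matrix(0L, p, p))
    best_amat <- amat
    best_score <- bn_total_score(C, n, amat)
    for (r in seq_len(max(restarts, 0))) {
      # restart from a fresh random DAG: a random topological order with
      # each order-respecting arc present with probability 1/2 (restarting
      # from a perturbation of the incumbent rarely leaves its
      # equivalence-class basin)
      ord <- sample.int(p)
      am <- matrix(0L, p, p)
      for (a in seq_len(p - 1)) for (b in (a + 1):p) {
        if (runif(1) < 0.5 && sum(am[, ord[b]]) < max_parents)
          am[ord[a], ord[b]] <- 1L
      }
      am <- climb(am)
      sc <- bn_total_score(C, n, am)
      if (sc > best_score) { best_score <- sc; best_amat <- am }
    }
    list(amat = best_amat, score = best_score)
  })
  best_amat <- res$amat
  best_score <- res$score
  arcs_idx <- which(best_amat == 1, arr.ind = TRUE)
  arcs <- data.frame(from = nodes[arcs_idx[, 1]], to = nodes[arcs_idx[, 2]],
                     stringsAsFactors = FALSE)
  structure(list(nodes = nodes, amat = best_amat, arcs = arcs,
                 score = best_score),
            class = "directed_graph")
}

#' @export
print.directed_graph <- function(x, ...) {
  cat(sprintf("<directed_graph> %d nodes, %d arc(s)%s\n", length(x$nodes),
              nrow(x$arcs),
              if (!is.null(x$score)) sprintf(", BIC %.2f", x$score) else ""))
  if (nrow(x$arcs) > 0) {
    hdr <- if (!is.null(x$arcs$strength)) " (strength, direction)" else ""
    for (k in seq_len(min(nrow(x$arcs), 20))) {
      extra <- if (!is.null(x$arcs$strength))
        sprintf("  [%.2f, %.2f]", x$arcs$strength[k],
                x$arcs$direction_prob[k]) else ""
      cat(sprintf("  %s -> %s%s\n", x$arcs$from[k], x$arcs$to[k], extra))
    }
    if (nzchar(hdr)) invisible(NULL)
  }
  invisible(x)
}

#' Bootstrap arc strength and direction
#'
#' Refits the hill-climbing network on `B` nonparametric bootstrap resamples.
#' For each node pair, `strength` is the fraction of resamples containing an
#' arc in either direction, and `direction_prob` the fraction of those
#' oriented as reported. The consensus graph keeps pairs with
#' `strength >= strength_threshold` (default 0.5) and draws an orientation
#' only when `direction_prob >= direction_threshold` (default 0.51);
#' otherwise the arc is reported undirected (`directed = FALSE`).
#'
#' @param data numeric matrix/data.frame.
#' @param B number of bootstrap resamples (>= 1).
#' @param direction_threshold orientation rule in (0.5, 1].
#' @param strength_threshold inclusion rule (default 0.5).
#' @param seed integer RNG seed; results are deterministic per seed.
#' @param ... passed to [hill_climb_bn()].
#' @return A `directed_graph` whose `arcs` carry `strength`,
#'   `direction_prob` and `directed`; `amat` holds the directed consensus
#'   arcs only; `score` is the Gaussian BIC of the directed consensus on the
#'   full data.
#' @export
bootstrap_arcs <- function(data, B = 1000, direction_threshold = 0.51,
                           strength_threshold = 0.5, seed = 1L, ...) {
  if (B < 1) stop_asym("bootstrap", "B must be >= 1")
  if (!(direction_threshold > 0.5 && direction_threshold <= 1))
    stop_asym("bootstrap", "direction_threshold must lie in (0.5, 1]")
  if (B < 1 / (1 - direction_threshold + 1e-12))
    warning("B is small for the requested direction threshold")
  data <- as.data.frame(data)
  n <- nrow(data)
  p <- ncol(data)
  counts <- matrix(0, p, p)     # directed counts
  with_seed(seed, {
    fit_seeds <- sample.int(.Machine$integer.max - 1, B)
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      g <- hill_climb_bn(data[idx, , drop = FALSE], seed = fit_seeds[b], ...)
      counts <- counts + g$amat
    }
  })
  nodes <- names(data)
  either <- counts + t(counts)
  out <- list()
  amat <- matrix(0L, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i >= j) next
    s <- either[i, j] / B
    if (s < strength_threshold) next
    fwd <- counts[i, j] / either[i, j]
    if (fwd >= direction_threshold) {
      from <- i; to <- j; dp <- fwd; directed <- TRUE
    } else if (1 - fwd >= direction_threshold) {
      from <- j; to <- i; dp <- 1 - fwd; directed <- TRUE
    } else {
      from <- i; to <- j; dp <- max(fwd, 1 - fwd); directed <- FALSE
    }
    if (directed) amat[from, to] <- 1L
    out[[length(out) + 1]] <- data.frame(
      from = nodes[from], to = nodes[to], strength = s,
      direction_prob = dp, directed = directed, stringsAsFactors = FALSE)
  }
  arcs <- if (length(out)) do.call(rbind, out) else
    data.frame(from = character(), to = character(), strength = numeric(),
               direction_prob = numeric(), directed = logical(),
               stringsAsFactors = FALSE)
  dm <- as.matrix(as.data.frame(lapply(data, as.numeric)))
  C <- cov(dm) * (n - 1) / n
  structure(list(nodes = nodes, amat = amat, arcs = arcs,
                 score = bn_total_score(C, n, amat), B = B,
                 direction_threshold = direction_threshold, seed = seed),
            class = "directed_graph")
}
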