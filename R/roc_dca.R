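# ROC analysis with the DeLong variance for the AUC, Youden-threshold
# confusion metrics, and decision-curve analysis with a percentile bootstrap
# band over the net-benefit curve.

#' ROC analysis with DeLong confidence interval
#'
#' AUC by the rank (Mann-Whitney) estimator with half credit for ties, the
#' DeLong variance and Wald 95% confidence interval, a decision threshold
#' (default: maximum Youden's J on the empirical curve, ties broken toward
#' the lower threshold), and the confusion-matrix metrics at that threshold
#' (a case is called positive when `score >= threshold`).
#'
#' @param scores numeric predictions (higher = more likely positive).
#' @param labels binary 0/1 outcome, both classes present.
#' @param conf_level confidence level (default 0.95).
#' @param threshold optional fixed threshold overriding the Youden rule.
#' @return A `roc_result`: `auc`, `ci` (lo, hi), `se`, `threshold`,
#'   `confusion` (tp, fp, tn, fn), `accuracy`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`, and the empirical `curve` (threshold, sens, spec).
#' @export
roc_analysis <- function(scores, labels, conf_level = 0.95,
                         threshold = NULL) {
  if (length(scores) != length(labels))
    stop_asym("roc", "scores and labels differ in length")
  if (!all(labels %in% c(0, 1)) || length(unique(labels)) < 2)
    stop_asym("roc", "labels must contain both classes (0/1)")
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  # DeLong structural components
  v10 <- vapply(pos, function(x) (sum(x > neg) + 0.5 * sum(x == neg)) / n,
                0.0)
  v01 <- vapply(neg, function(x) (sum(pos > x) + 0.5 * sum(pos == x)) / m,
                0.0)
  auc <- mean(v10)
  se <- sqrt(var(v10) / m + var(v01) / n)
  zq <- qnorm(1 - (1 - conf_level) / 2)
  ci <- c(max(0, auc - zq * se), min(1, auc + zq * se))
  # empirical curve over unique thresholds
  thr_grid <- sort(unique(scores))
  sens <- vapply(thr_grid, function(t) mean(pos >= t), 0.0)
  spec <- vapply(thr_grid, function(t) mean(neg < t), 0.0)
  if (is.null(threshold)) {
    j <- sens + spec - 1
    threshold <- thr_grid[which.max(j)]   # which.max takes the first (lowest)
  }
  tp <- sum(pos >= threshold); fn <- m - tp
  fp <- sum(neg >= threshold); tn <- n - fp
  structure(list(
    auc = auc, ci = ci, se = se, conf_level = conf_level,
    threshold = threshold,
    confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
    accuracy = (tp + tn) / (m + n),
    sensitivity = tp / m, specificity = tn / n,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    curve = data.frame(threshold = thr_grid, sensitivity = sens,
                       specificity = spec)), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (%d%% CI %.3f-%.3f), sens %.3f spec %.3f\n",
              x$auc, round(100 * x$conf_level), x$ci[1], x$ci[2],
              x$sensitivity, x$specificity))
  invisible(x)
}

net_benefit <- function(scores, labels, thresholds) {
  n <- length(labels)
  vapply(thresholds, function(pt) {
    tp <- sum(scores >= pt & labels == 1)
    fp <- sum(scores >= pt & labels == 0)
    tp / n - fp / n * pt / (1 - pt)
  }, 0.0)
}

#' Decision-curve analysis
#'
#' Net benefit `NB(pt) = TP/n - FP/n * pt/(1-pt)` of the model across a
#' threshold-probability grid, against the treat-all reference
#' `pi - (1-pi) pt/(1-pt)` (`pi` = prevalence) and the treat-none reference
#' (identically zero), with a percentile bootstrap band for the model curve
#' and the threshold ranges where the model strictly beats both references.
#'
#' @param scores predicted probabilities in `[0, 1]`.
#' @param labels binary 0/1 outcome.
#' @param thresholds threshold grid in `[0, 1)` (default 0 to 0.99 by 0.01).
#' @param n_boot bootstrap resamples for the band (default 2000).
#' @param seed integer RNG seed.
#' @param conf_level band level (default 0.95).
#' @return A `dca_curve`: data.frame `curve` (threshold, net benefit of
#'   model / treat-all / treat-none, bootstrap band), `prevalence`,
#'   `advantageous` (logical per threshold), `ranges` (list of threshold
#'   intervals where the model wins).
#' @export
decision_curve <- function(scores, labels, thresholds = seq(0, 0.99, 0.01),
                           n_boot = 2000, seed = 1L, conf_level = 0.95) {
  if (any(scores < 0 | scores > 1))
    stop_asym("dca", "scores must be probabilities in [0, 1]")
  if (any(thresholds >= 1) || any(thresholds < 0))
    stop_asym("dca", "thresholds must lie in [0, 1)")
  if (!all(labels %in% c(0, 1))) stop_asym("dca", "labels must be 0/1")
  n <- length(labels)
  prev <- mean(labels)
  nb_model <- net_benefit(scores, labels, thresholds)
  nb_all <- prev - (1 - prev) * thresholds / (1 - thresholds)
  nb_none <- rep(0, length(thresholds))
  boot <- with_seed(seed, {
    matrix(vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      net_benefit(scores[idx], labels[idx], thresholds)
    }, numeric(length(thresholds))), nrow = length(thresholds))
  })
  alpha <- (1 - conf_level) / 2
  lo <- apply(boot, 1, quantile, probs = alpha, names = FALSE)
  hi <- apply(boot, 1, quantile, probs = 1 - alpha, names = FALSE)
  adv <- nb_model > pmax(nb_all, 0)
  ranges <- list()
  if (any(adv)) {
    r <- rle(adv)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in which(r$values))
      ranges[[length(ranges) + 1]] <- c(thresholds[starts[k]],
                                        thresholds[ends[k]])
  }
  structure(list(
    curve = data.frame(threshold = thresholds, nb_model = nb_model,
                       nb_all = nb_all, nb_none = nb_none,
                       nb_lo = lo, nb_hi = hi),
    prevalence = prev, advantageous = adv, ranges = ranges,
    n_boot = n_boot, seed = seed), class = "dca_curve")
}

#' @export
print.dca_curve <- function(x, ...) {
  rng <- if (length(x$ranges))
    paste(vapply(x$ranges, function(r) sprintf("%.2f-%.2f", r[1], r[2]), ""),
          collapse = ", ") else "none"
  cat(sprintf("<dca_curve> prevalence %.3f, advantageous thresholds: %s\n",
              x$prevalence, rng))
  invisible(x)
}
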