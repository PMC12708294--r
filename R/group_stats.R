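# Group-comparison machinery: Welch t from summary statistics, pooled
# Cohen's d, Yates-corrected chi-square, two-sided Fisher exact test,
# bias-corrected Cramer's V, Benjamini-Hochberg adjustment, and the
# table-driving compare_groups() composition. Sign convention throughout:
# statistics are oriented as (group B - group A).

#' Welch two-sample t test from summary statistics
#'
#' `t = (meanB - meanA) / sqrt(sdA^2/nA + sdB^2/nB)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p value.
#'
#' @param meanA,sdA,nA,meanB,sdB,nB group summaries; `n >= 2`, `sd >= 0`.
#' @return List: `t`, `df`, `p`.
#' @export
welch_t <- function(meanA, sdA, nA, meanB, sdB, nB) {
  if (nA < 2 || nB < 2) stop_asym("welch", "each group needs n >= 2")
  if (sdA < 0 || sdB < 0) stop_asym("welch", "sd must be >= 0")
  vA <- sdA^2 / nA; vB <- sdB^2 / nB
  if (vA + vB == 0) {
    if (meanA == meanB) return(list(t = 0, df = nA + nB - 2, p = 1))
    stop_asym("welch", "zero variance in both groups with unequal means")
  }
  se <- sqrt(vA + vB)
  t <- (meanB - meanA) / se
  df <- (vA + vB)^2 / (vA^2 / (nA - 1) + vB^2 / (nB - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Pooled-SD Cohen's d from summary statistics
#'
#' `d = (meanB - meanA) / sp` with
#' `sp = sqrt(((nA-1) sdA^2 + (nB-1) sdB^2) / (nA+nB-2))`.
#'
#' @inheritParams welch_t
#' @return Cohen's d (numeric).
#' @export
cohens_d_pooled <- function(meanA, sdA, nA, meanB, sdB, nB) {
  sp <- sqrt(((nA - 1) * sdA^2 + (nB - 1) * sdB^2) / (nA + nB - 2))
  if (sp == 0) {
    if (meanA == meanB) return(0)
    stop_asym("cohens_d", "pooled SD is zero")
  }
  (meanB - meanA) / sp
}

#' Yates continuity-corrected chi-square for a 2x2 table
#'
#' `chi2 = n (max(0, |ad - bc| - n/2))^2 / ((a+b)(c+d)(a+c)(b+d))`, 1 df.
#' The correction is clamped at zero, so proportional tables give exactly 0.
#'
#' @param a,b,c,d nonnegative integer cell counts, rows = groups.
#' @return List: `chi2`, `p` (from the 1-df chi-square distribution).
#' @export
yates_chi_square <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop_asym("chi2", "cells must be nonnegative integers")
  n <- sum(cells)
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0))
    stop_asym("chi2", "zero margin; use fisher_exact_two_sided")
  num <- max(0, abs(a * d - b * c) - n / 2)
  chi2 <- n * num^2 / prod(margins)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Sum of hypergeometric point probabilities not exceeding the observed
#' table's probability, with fixed margins.
#'
#' @inheritParams yates_chi_square
#' @return Two-sided p value.
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop_asym("fisher", "cells must be nonnegative integers")
  m <- a + b          # row 1 margin
  k <- a + c          # column 1 margin
  n <- sum(cells)
  if (m == 0 || m == n || k == 0 || k == n) return(1)
  lo <- max(0, k - (n - m)); hi <- min(k, m)
  supp <- lo:hi
  pr <- dhyper(supp, m, n - m, k)
  p_obs <- dhyper(a, m, n - m, k)
  min(1, sum(pr[pr <= p_obs * (1 + 1e-07)]))
}

#' Bias-corrected Cramer's V for a 2x2 table
#'
#' Computed from the uncorrected Pearson chi-square:
#' `phi2 = chi2/n`, `phi2~ = max(0, phi2 - (r-1)(c-1)/(n-1))`,
#' `r~ = r - (r-1)^2/(n-1)` (likewise `c~`), and
#' `V = sqrt(phi2~ / min(r~-1, c~-1))`.
#'
#' @inheritParams yates_chi_square
#' @return Bias-corrected V in `[0, 1]`.
#' @export
cramers_v_bias_corrected <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  n <- sum(cells)
  if (n <= 1) stop_asym("cramers_v", "need n >= 2")
  rowm <- c(a + b, c + d); colm <- c(a + c, b + d)
  if (any(rowm == 0) || any(colm == 0)) return(0)
  expd <- outer(rowm, colm) / n
  obs <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  chi2 <- sum((obs - expd)^2 / expd)
  phi2 <- chi2 / n
  phi2t <- max(0, phi2 - 1 / (n - 1))
  rt <- 2 - 1 / (n - 1)
  sqrt(phi2t / (rt - 1))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Sorts ascending, multiplies `p(i)` by `m/i`, enforces monotonicity from
#' the largest p downward, caps at 1, and returns values in input order.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return Adjusted p values, same order and length.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop_asym("bh", "p values must be in [0, 1]")
  m <- length(pvalues)
  if (m <= 1) return(pvalues)
  o <- order(pvalues)
  adj <- pvalues[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# expected-frequency rule: route to Fisher when any expected cell < 5
# (ties at exactly 5 go to Fisher)
use_fisher <- function(a, b, c, d) {
  n <- a + b + c + d
  expd <- outer(c(a + b, c + d), c(a + c, b + d)) / n
  any(expd <= 5 + 1e-12) && any(expd < 5 + 1e-12)
}

#' Group comparison table
#'
#' For a binary grouping, compares every indicator between groups:
#' continuous indicators by Welch t and pooled Cohen's d; binary indicators
#' by the Yates-corrected chi-square (or Fisher's exact test when any
#' expected cell count is below 5) and bias-corrected Cramer's V. Raw p
#' values are Benjamini-Hochberg adjusted across the whole table (the
#' family is the comparison table itself). Statistics are oriented as
#' (second group - first group), groups ordered as `group_levels`.
#'
#' @param table a `cohort_table`.
#' @param grouping `"gender"` or `"lang_improved"`.
#' @param group_levels optional length-2 vector fixing group A and B.
#' @return A data.frame of class `group_comparison_table`: variable, group
#'   summaries, statistic kind/value, df, p, adjusted p, effect-size
#'   kind/value.
#' @export
compare_groups <- function(table, grouping = c("gender", "lang_improved"),
                           group_levels = NULL) {
  grouping <- match.arg(grouping)
  df <- as.data.frame(table)
  g <- df[[grouping]]
  levs <- group_levels %||% if (grouping == "gender")
    c("male", "female") else c(1, 0)
  if (length(unique(g[!is.na(g)])) != 2)
    stop_asym("compare", "grouping variable must be binary in the data")
  A <- df[g == levs[1], , drop = FALSE]
  B <- df[g == levs[2], , drop = FALSE]
  cb <- cohort_codebook()
  vars <- cb$name
  extra <- if (grouping == "lang_improved") "gender" else "lang"
  rows <- list()
  for (v in c(extra, vars)) {
    if (v == grouping) next
    if (v == "gender") {
      xa <- as.integer(A[[v]] == "male"); xb <- as.integer(B[[v]] == "male")
      type <- "binary"
    } else {
      xa <- A[[v]]; xb <- B[[v]]
      type <- if (v == "lang") "continuous" else cb$type[cb$name == v]
    }
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    if (type == "binary") {
      a_ <- sum(xa == 1); b_ <- sum(xa == 0)
      c_ <- sum(xb == 1); d_ <- sum(xb == 0)
      fis <- use_fisher(a_, b_, c_, d_)
      if (fis) {
        p <- fisher_exact_two_sided(a_, b_, c_, d_)
        stat <- NA_real_; kind <- "fisher"
      } else {
        y <- yates_chi_square(a_, b_, c_, d_)
        p <- y$p; stat <- y$chi2; kind <- "yates_chi2"
      }
      rows[[v]] <- data.frame(
        variable = v, summary_a = sprintf("%d/%d", a_, a_ + b_),
        summary_b = sprintf("%d/%d", c_, c_ + d_), stat_kind = kind,
        statistic = stat, df = NA_real_, p = p,
        effect_kind = "cramers_v_corrected",
        effect = cramers_v_bias_corrected(a_, b_, c_, d_),
        stringsAsFactors = FALSE)
    } else {
      wt <- welch_t(mean(xa), sd(xa), length(xa), mean(xb), sd(xb),
                    length(xb))
      rows[[v]] <- data.frame(
        variable = v,
        summary_a = sprintf("%.2f ± %.2f", mean(xa), sd(xa)),
        summary_b = sprintf("%.2f ± %.2f", mean(xb), sd(xb)),
        stat_kind = "welch_t", statistic = wt$t, df = wt$df, p = wt$p,
        effect_kind = "cohens_d",
        effect = cohens_d_pooled(mean(xa), sd(xa), length(xa), mean(xb),
                                 sd(xb), length(xb)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adjusted <- bh_adjust(out$p)
  attr(out, "groups") <- stats::setNames(c(nrow(A), nrow(B)),
                                         as.character(levs))
  class(out) <- c("group_comparison_table", "data.frame")
  out
}
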