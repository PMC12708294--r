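# L1-regularized regression by cyclic coordinate descent on standardized
# predictors, gaussian objective (1/2n) RSS + lambda ||beta||_1 and binomial
# objective -(1/n) loglik + lambda ||beta||_1 (outer IRLS quadratic
# approximation), path over a 100-point log-spaced lambda grid, lambda chosen
# by minimum K-fold cross-validated deviance.

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

# gaussian coordinate descent at one lambda; X standardized (1/n variance 1),
# y centred. Returns standardized-scale coefficients.
cd_gaussian <- function(X, y, lambda, beta, tol = 1e-10, max_iter = 10000) {
  n <- nrow(X); p <- ncol(X)
  r <- y - X %*% beta
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(p)) {
      bj <- beta[j]
      zj <- sum(X[, j] * r) / n + bj      # since (1/n) X_j' X_j = 1
      bn <- soft_threshold(zj, lambda)
      if (bn != bj) {
        r <- r - X[, j] * (bn - bj)
        delta <- max(delta, abs(bn - bj))
        beta[j] <- bn
      }
    }
    if (delta < tol) break
  }
  beta
}

# weighted coordinate descent for the IRLS inner problem:
# minimize (1/2n) sum w (z - b0 - X beta)^2 + lambda |beta|
cd_weighted <- function(X, z, w, lambda, beta, b0, tol = 1e-9,
                        max_iter = 5000) {
  n <- nrow(X); p <- ncol(X)
  r <- z - b0 - X %*% beta
  wn <- w / n
  xwx <- colSums(sweep(X^2, 1, wn, `*`))
  for (it in seq_len(max_iter)) {
    delta <- 0
    b0n <- b0 + sum(wn * r) / sum(wn)
    r <- r - (b0n - b0); delta <- max(delta, abs(b0n - b0)); b0 <- b0n
    for (j in seq_len(p)) {
      bj <- beta[j]
      zj <- sum(wn * X[, j] * r) + xwx[j] * bj
      bn <- soft_threshold(zj, lambda) / xwx[j]
      if (bn != bj) {
        r <- r - X[, j] * (bn - bj)
        delta <- max(delta, abs(bn - bj))
        beta[j] <- bn
      }
    }
    if (delta < tol) break
  }
  list(beta = beta, b0 = b0)
}

fit_binomial_path_point <- function(X, y, lambda, beta, b0, tol = 1e-8,
                                    max_outer = 50) {
  for (it in seq_len(max_outer)) {
    eta <- as.numeric(b0 + X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-5)
    z <- eta + (y - mu) / w
    old <- c(b0, beta)
    fit <- cd_weighted(X, z, w, lambda, beta, b0)
    beta <- fit$beta; b0 <- fit$b0
    if (max(abs(c(b0, beta) - old)) < tol) break
  }
  list(beta = beta, b0 = b0)
}

binomial_deviance <- function(y, mu) {
  mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
  -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
}

#' Fit an L1-regularized (LASSO) regression path
#'
#' Cyclic coordinate descent over a log-spaced grid of 100 penalties from
#' `lambda_max` (the smallest penalty with an all-zero solution) down to
#' `0.01 * lambda_max`, with warm starts. Predictors are standardized
#' internally (mean 0, variance 1 with the 1/n convention); the gaussian
#' objective is `(1/2n) RSS + lambda ||beta||_1`. The penalty is chosen by
#' minimum K-fold cross-validated deviance (mean squared error for gaussian,
#' binomial deviance for binomial, stratified folds). Deterministic per seed.
#'
#' @param X numeric predictor matrix (no missing values).
#' @param y numeric outcome; for binomial, 0/1.
#' @param family `"gaussian"` or `"binomial"`.
#' @param cv_folds number of cross-validation folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param nlambda grid size (default 100).
#' @param lambda_min_ratio smallest-to-largest penalty ratio (default 0.01).
#' @return A `lasso_fit`: `lambda` (grid), `beta` (standardized coefficient
#'   matrix, p x nlambda), `beta_raw` (original scale), `intercept`,
#'   `lambda_min`, `index_min`, `cvm` (CV deviance per lambda), `foldid`,
#'   `family`, `seed`, plus the centring/scaling used.
#' @export
lasso_fit <- function(X, y, family = c("gaussian", "binomial"), cv_folds = 10,
                      seed = 1L, nlambda = 100, lambda_min_ratio = 0.01) {
  family <- match.arg(family)
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y)) stop_asym("lasso", "missing values not allowed")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  if (n < cv_folds) stop_asym("lasso", "need n >= cv_folds")
  if (var(y) == 0) stop_asym("lasso", "constant outcome")
  sds <- apply(X, 2, function(col) sqrt(mean((col - mean(col))^2)))
  keep <- sds > 0
  if (any(!keep)) {
    warning("dropping constant column(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
    sds <- sds[keep]
  }
  mus <- colMeans(X)
  Xs <- sweep(sweep(X, 2, mus), 2, sds, `/`)
  p <- ncol(Xs)
  if (family == "gaussian") {
    ybar <- mean(y); yc <- y - ybar
    lambda_max <- max(abs(crossprod(Xs, yc))) / n
  } else {
    if (!all(y %in% c(0, 1))) stop_asym("lasso", "binomial y must be 0/1")
    pbar <- mean(y)
    lambda_max <- max(abs(crossprod(Xs, y - pbar))) / n
  }
  lambda <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                    length.out = nlambda))
  fit_path <- function(Xs, y) {
    # returns list(beta = p x nlambda, b0 = nlambda)
    B <- matrix(0, ncol(Xs), length(lambda))
    b0s <- numeric(length(lambda))
    beta <- rep(0, ncol(Xs))
    if (family == "gaussian") {
      ybar_l <- mean(y); yc_l <- y - ybar_l
      for (k in seq_along(lambda)) {
        beta <- cd_gaussian(Xs, yc_l, lambda[k], beta)
        B[, k] <- beta
        b0s[k] <- ybar_l
      }
    } else {
      b0 <- log(mean(y) / (1 - mean(y)))
      for (k in seq_along(lambda)) {
        f <- fit_binomial_path_point(Xs, y, lambda[k], beta, b0)
        beta <- f$beta; b0 <- f$b0
        B[, k] <- beta
        b0s[k] <- b0
      }
    }
    list(beta = B, b0 = b0s)
  }
  full <- fit_path(Xs, y)
  # cross-validation folds (stratified for binomial)
  foldid <- with_seed(seed, {
    if (family == "binomial") {
      f <- integer(n)
      for (cls in c(0, 1)) {
        idx <- which(y == cls)
        f[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
      }
      f
    } else sample(rep_len(seq_len(cv_folds), n))
  })
  cvdev <- matrix(NA_real_, cv_folds, length(lambda))
  for (fold in seq_len(cv_folds)) {
    tr <- foldid != fold; te <- !tr
    mus_f <- colMeans(X[tr, , drop = FALSE])
    sds_f <- apply(X[tr, , drop = FALSE], 2,
                   function(col) sqrt(mean((col - mean(col))^2)))
    sds_f[sds_f == 0] <- 1
    Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mus_f), 2, sds_f, `/`)
    Xte <- sweep(sweep(X[te, , drop = FALSE], 2, mus_f), 2, sds_f, `/`)
    pf <- fit_path(Xtr, y[tr])
    eta <- sweep(Xte %*% pf$beta, 2, pf$b0, `+`)
    if (family == "gaussian") {
      cvdev[fold, ] <- colMeans((y[te] - eta)^2)
    } else {
      mu <- 1 / (1 + exp(-eta))
      cvdev[fold, ] <- apply(mu, 2, function(m)
        binomial_deviance(y[te], m)) / sum(te)
    }
  }
  cvm <- colMeans(cvdev)
  imin <- which.min(cvm)
  beta_std <- full$beta[, imin]
  names(beta_std) <- colnames(X)
  structure(list(lambda = lambda, beta = full$beta,
                 intercept_path = full$b0,
                 beta_std = beta_std,
                 beta_raw = beta_std / sds,
                 intercept = full$b0[imin] - sum((beta_std / sds) * mus),
                 lambda_min = lambda[imin], index_min = imin, cvm = cvm,
                 foldid = foldid, family = family, seed = seed,
                 center = mus, scale = sds, var_names = colnames(X)),
            class = "lasso_fit")
}

#' @export
print.lasso_fit <- function(x, ...) {
  nz <- sum(x$beta_std != 0)
  cat(sprintf("<lasso_fit> %s family, lambda_min %.4g (%d nonzero of %d)\n",
              x$family, x$lambda_min, nz, length(x$beta_std)))
  invisible(x)
}

#' Predict from a lasso fit at the CV-chosen penalty
#'
#' @param object a [lasso_fit()].
#' @param newdata matrix with the fit's columns.
#' @param type `"link"` or `"response"`.
#' @param ... unused.
#' @return Numeric predictions.
#' @export
predict.lasso_fit <- function(object, newdata,
                              type = c("link", "response"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)[, object$var_names, drop = FALSE]
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, `/`)
  eta <- as.numeric(Xs %*% object$beta_std +
                      object$intercept_path[object$index_min])
  if (object$family == "binomial" && type == "response")
    1 / (1 + exp(-eta)) else eta
}

#' Variables selected by the LASSO
#'
#' Names of the nonzero-coefficient variables at the CV-chosen penalty,
#' ordered by decreasing absolute standardized coefficient.
#'
#' @param fit a [lasso_fit()].
#' @return Character vector (possibly empty).
#' @export
select_predictors <- function(fit) {
  stopifnot(inherits(fit, "lasso_fit"))
  b <- fit$beta_std
  nz <- b[b != 0]
  names(nz)[order(abs(nz), decreasing = TRUE)]
}
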