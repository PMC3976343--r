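# L1-penalised linear regression with leave-one-out model selection.
#
# The solver minimises (1/2n) * RSS + lambda * ||beta||_1 by cyclic
# coordinate descent with residual updates and active-set iteration on
# internally standardised features (mean 0, mean-square 1) and a centred,
# unit-variance-scaled response; convergence is a per-sweep maximum
# coefficient change or duality gap below 1e-7 (relative to the response
# scale), with a sweep cap guarding the ill-conditioned path tail.
# Reported weights are de-standardised back to the original feature scale.

LASSO_TOL <- 1e-7
LASSO_MAX_SWEEPS_FIT <- 2000L  # final fits: deep budget
LASSO_MAX_SWEEPS_CV <- 100L    # cross-validation paths: the selected
                               # penalty is insensitive to the capped tail

# Standardisation constants: population (1/n) scaling so that an
# orthonormal design (X'X/n = I) gives the exact soft-threshold solution.
std_constants <- function(X) {
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  scl <- sqrt(colMeans(Xc^2))
  ok <- scl > 1e-12
  list(center = ctr, scale = ifelse(ok, scl, 1), ok = ok)
}

std_apply <- function(X, st) {
  Xs <- sweep(sweep(X, 2, st$center), 2, st$scale, "/")
  Xs[, !st$ok] <- 0  # zero-variance features carry no signal
  Xs
}

# Coefficients over a decreasing lambda path, standardised scale. The
# response is scaled to unit variance internally (an exact reparameterisation
# of the objective) so the convergence tolerance is relative to the response
# scale.
lasso_path_std <- function(Xs, yc, lambdas,
                           max_sweeps = LASSO_MAX_SWEEPS_CV) {
  sy <- sqrt(mean(yc^2))
  if (sy < 1e-300) return(matrix(0, ncol(Xs), length(lambdas)))
  sy * .lasso_path_cd(Xs, yc / sy, lambdas / sy, LASSO_TOL, max_sweeps)
}

#' Smallest penalty that zeroes every coefficient
#'
#' `lambda_max = max_j |<x_j, y - mean(y)>| / n` on standardised features;
#' at or above it the fitted model is the intercept alone.
#'
#' @param X Samples x features matrix.
#' @param y Response vector.
#' @return Non-negative scalar.
#' @export
lasso_lambda_max <- function(X, y) {
  st <- std_constants(X)
  Xs <- std_apply(X, st)
  max(abs(as.numeric(crossprod(Xs, y - mean(y)))) / nrow(X), 0)
}

#' Default penalty grid
#'
#' 100 log-spaced values from `lambda_max` down to `lambda_max * 1e-4`
#' (the standard empty-to-dense path). A constant response collapses the
#' grid to the single value 0.
#'
#' @param X,y Design and response.
#' @param nlambda Grid length.
#' @param min_ratio Ratio of the smallest to the largest penalty.
#' @return Decreasing numeric vector.
#' @export
lasso_lambda_grid <- function(X, y, nlambda = 100, min_ratio = 1e-4) {
  lmax <- lasso_lambda_max(X, y)
  if (lmax < 1e-12) return(0)
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = nlambda))
}

check_grid <- function(lambda_grid) {
  if (length(lambda_grid) == 0 || any(!is.finite(lambda_grid)) ||
      any(lambda_grid < 0))
    stop("degenerate lambda grid: need finite non-negative penalties")
  sort(unique(lambda_grid), decreasing = TRUE)
}

#' Fit an L1-penalised linear regression at one penalty
#'
#' @param X Samples x features numeric matrix (standardised internally).
#' @param y Numeric response (centred internally).
#' @param lambda Penalty `>= 0` in the `(1/2n) RSS + lambda * l1` scaling.
#' @return A `lasso_fit` object: `beta` (named weights on the original
#'   feature scale), `intercept`, `lambda`, `beta_std`, the
#'   standardisation constants, `selected_features` (names with nonzero
#'   weight) and `fitted` values.
#' @export
lasso_fit <- function(X, y, lambda) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop("non-finite values in X or y")
  stopifnot(nrow(X) >= 2, nrow(X) == length(y), length(lambda) == 1,
            lambda >= 0)
  st <- std_constants(X)
  Xs <- std_apply(X, st)
  ybar <- mean(y)
  # warm-started descent along a short path into the target penalty for
  # stable convergence at small lambda
  lmax <- max(abs(as.numeric(crossprod(Xs, y - ybar))) / nrow(X), 0)
  path <- if (lambda >= lmax || lmax < 1e-12) lambda else
    unique(c(exp(seq(log(lmax), log(max(lambda, lmax * 1e-8)),
                     length.out = 20)), lambda))
  bmat <- lasso_path_std(Xs, y - ybar, path, LASSO_MAX_SWEEPS_FIT)
  b_std <- bmat[, length(path)]
  b_std[abs(b_std) < 1e-10 * max(1, sqrt(mean((y - ybar)^2)))] <- 0
  beta <- setNames(b_std / st$scale, colnames(X))
  beta[!st$ok] <- 0
  intercept <- ybar - sum(beta * st$center)
  fitted <- as.numeric(X %*% beta) + intercept
  structure(list(beta = beta, intercept = intercept, lambda = lambda,
                 beta_std = setNames(b_std, colnames(X)),
                 center = st$center, scale = st$scale, y_center = ybar,
                 selected_features = names(beta)[beta != 0],
                 fitted = setNames(fitted, rownames(X))),
            class = "lasso_fit")
}

#' @export
predict.lasso_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  as.numeric(newdata %*% object$beta) + object$intercept
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat(sprintf("L1-penalised linear model: lambda = %.4g, %d/%d nonzero weights\n",
              x$lambda, length(x$selected_features), length(x$beta)))
  invisible(x)
}

#' Select the penalty by leave-one-out cross-validation
#'
#' For every grid penalty, each sample is predicted by a model trained on
#' the remaining `n - 1` (standardisation recomputed within each fold);
#' the selected penalty is the largest one attaining the minimum mean
#' squared leave-one-out error (the sparsest model among ties).
#'
#' @param X,y Design and response (`n >= 3`).
#' @param lambda_grid Decreasing penalty grid; defaults to
#'   [lasso_lambda_grid()].
#' @return List with `lambda` (selected), `cv` (data frame: `lambda`,
#'   `mse`) and `predictions` (n x nlambda matrix of out-of-fold values).
#' @export
loocv_select_lambda <- function(X, y, lambda_grid = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 3, n == length(y))
  lambda_grid <- check_grid(lambda_grid %||% lasso_lambda_grid(X, y))
  preds <- matrix(NA_real_, n, length(lambda_grid))
  for (i in seq_len(n)) {
    Xt <- X[-i, , drop = FALSE]
    yt <- y[-i]
    st <- std_constants(Xt)
    Xs <- std_apply(Xt, st)
    ybar <- mean(yt)
    bmat <- lasso_path_std(Xs, yt - ybar, lambda_grid)
    xs_new <- (X[i, ] - st$center) / st$scale
    xs_new[!st$ok] <- 0
    preds[i, ] <- ybar + as.numeric(xs_new %*% bmat)
  }
  mse <- colMeans((preds - y)^2)
  best <- which.min(mse)  # first index = largest lambda among exact ties
  list(lambda = lambda_grid[best],
       cv = data.frame(lambda = lambda_grid, mse = mse),
       predictions = preds)
}

#' Out-of-fold predictions by nested leave-one-out cross-validation
#'
#' For each held-out sample, the penalty is selected by LOOCV on the
#' remaining `n - 1` samples alone, a model is fitted on those `n - 1`,
#' and the held-out sample is predicted -- so every reported prediction is
#' honestly out of fold. The non-nested variant (penalty selected once on
#' the full data, then per-fold refits) is available with
#' `nested = FALSE`.
#'
#' @param X,y Design and response (`n >= 4`).
#' @param lambda_grid Optional penalty grid; by default each outer fold
#'   derives its own grid from its training data.
#' @param nested Use fully nested selection (default `TRUE`).
#' @return List with `predictions` (named by sample), `lambda` (per-fold
#'   selected penalties) and `nested`.
#' @export
nested_loocv_predict <- function(X, y, lambda_grid = NULL, nested = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n >= 4, n == length(y))
  ids <- rownames(X) %||% as.character(seq_len(n))
  preds <- setNames(numeric(n), ids)
  lam <- setNames(numeric(n), ids)
  lam_fixed <- if (!nested)
    loocv_select_lambda(X, y, lambda_grid)$lambda else NULL
  for (i in seq_len(n)) {
    Xt <- X[-i, , drop = FALSE]
    yt <- y[-i]
    li <- if (nested) {
      grid_i <- lambda_grid %||% lasso_lambda_grid(Xt, yt)
      loocv_select_lambda(Xt, yt, grid_i)$lambda
    } else lam_fixed
    fit <- lasso_fit(Xt, yt, li)
    preds[i] <- predict(fit, X[i, , drop = FALSE])
    lam[i] <- li
  }
  list(predictions = preds, lambda = lam, nested = nested)
}

#' NULL baseline: predict the mean of all teacher values
#'
#' @param y Numeric vector of experimentally determined values.
#' @return Vector of predictions, all equal to `mean(y)`.
#' @export
null_model <- function(y) {
  stopifnot(length(y) >= 1)
  setNames(rep(mean(y), length(y)), names(y))
}
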