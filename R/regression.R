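#' Closed-form ridge regression
#'
#' Solves the L2-penalized least-squares problem with an unpenalized
#' intercept: slopes minimize `||y - b0 - X b||^2 + alpha ||b||^2`.
#' Features are expected pre-standardized (as produced by
#' [build_feature_table()]). The solve is exact, via the singular value
#' decomposition of the centered design.
#'
#' @param x Numeric feature matrix (n x p), standardized columns.
#' @param y Numeric response (binding distance, Angstrom).
#' @param alpha Regularization strength (>= 0); default 1.0.
#' @return A `ridge_model` with fields `coefficients`, `intercept`,
#'   `alpha`.
#' @export
fit_ridge <- function(x, y, alpha = 1.0) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 samples")
  if (alpha < 0) stop("alpha must be >= 0")
  xm <- colMeans(x); ym <- mean(y)
  Xc <- sweep(x, 2, xm)
  s <- svd(Xc)
  if (alpha == 0 && any(s$d < max(s$d) * 1e-10))
    stop("singular system: collinear features with alpha = 0")
  shrink <- s$d / (s$d^2 + alpha)
  beta <- drop(s$v %*% (shrink * crossprod(s$u, y - ym)))
  names(beta) <- colnames(x)
  structure(list(coefficients = beta,
                 intercept = ym - sum(xm * beta),
                 alpha = alpha),
            class = "ridge_model")
}

#' @export
predict.ridge_model <- function(object, newdata, ...) {
  drop(as.matrix(newdata) %*% object$coefficients + object$intercept)
}

#' Train the 2-5-1 ReLU network
#'
#' A fixed-architecture multilayer perceptron (2 input features, one
#' hidden layer of 5 ReLU units, 1 linear output) trained by full-batch
#' gradient descent on the mean squared error. The target is
#' standardized internally for conditioning and predictions are returned
#' on the original scale. Weights are initialized uniformly in
#' `[-0.5, 0.5]` from `seed`; identical seeds give identical weights.
#'
#' @param x Numeric matrix with exactly 2 (standardized) feature columns.
#' @param y Numeric response.
#' @param seed Integer seed for initialization.
#' @param epochs Number of full-batch gradient steps (>= 0).
#' @param learning_rate Step size (> 0).
#' @return An `mlp_model` with weight matrices `W1` (2x5), `b1`, `W2`
#'   (5x1), `b2`, target scaling `y_center`/`y_scale`, and the
#'   per-epoch training `loss` trace (standardized-scale MSE).
#' @export
fit_mlp <- function(x, y, seed = 42L, epochs = 5000L,
                    learning_rate = 0.05) {
  x <- as.matrix(x)
  if (ncol(x) != 2) stop("architecture is fixed at 2 input features")
  if (nrow(x) < 2) stop("need at least 2 samples")
  if (epochs < 0 || learning_rate <= 0)
    stop("epochs must be >= 0 and learning_rate > 0")
  n <- nrow(x); h <- 5L
  ym <- mean(y); ys <- stats::sd(y)
  if (!is.finite(ys) || ys == 0) ys <- 1
  yz <- (y - ym) / ys
  init <- with_seed(seed, function() stats::runif(2 * h + h + h + 1, -0.5, 0.5))
  W1 <- matrix(init[1:(2 * h)], 2, h)
  b1 <- init[(2 * h + 1):(3 * h)]
  W2 <- matrix(init[(3 * h + 1):(4 * h)], h, 1)
  b2 <- init[4 * h + 1]
  loss <- numeric(epochs)
  for (e in seq_len(epochs)) {
    Z1 <- sweep(x %*% W1, 2, b1, "+")
    A1 <- pmax(Z1, 0)
    yhat <- drop(A1 %*% W2 + b2)
    err <- yhat - yz
    loss[e] <- mean(err^2)
    if (!is.finite(loss[e]))
      stop("non-finite training loss at epoch ", e,
           "; reduce the learning rate")
    gy <- 2 * err / n
    gZ1 <- outer(gy, drop(W2)) * (Z1 > 0)
    W2 <- W2 - learning_rate * crossprod(A1, gy)
    b2 <- b2 - learning_rate * sum(gy)
    W1 <- W1 - learning_rate * crossprod(x, gZ1)
    b1 <- b1 - learning_rate * colSums(gZ1)
  }
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                 y_center = ym, y_scale = ys,
                 seed = as.integer(seed), epochs = as.integer(epochs),
                 learning_rate = learning_rate, loss = loss),
            class = "mlp_model")
}

#' @export
predict.mlp_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  A1 <- pmax(sweep(x %*% object$W1, 2, object$b1, "+"), 0)
  drop(A1 %*% object$W2 + object$b2) * object$y_scale + object$y_center
}

mse_ <- function(y, yhat) mean((y - yhat)^2)
r2_ <- function(y, yhat) 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)

#' Evaluate a distance regressor with the 80/20 + 5-fold protocol
#'
#' Shuffles rows with `split_seed`, fits on the first 80% and reports
#' held-out mean squared error and R^2 on the remaining 20%; then
#' refits across `folds` contiguous cross-validation blocks of the
#' shuffled order and reports the mean and standard deviation of the
#' per-fold held-out metrics. Residuals are `predicted - actual` on the
#' 80/20 test rows.
#'
#' @param x Feature matrix or [build_feature_table()] output.
#' @param y Targets; `NULL` takes `target_r` from a feature table.
#' @param method `"ridge"` (default predictor) or `"mlp"`.
#' @param alpha Ridge regularization strength.
#' @param split_seed Seed controlling the shuffle (fold assignment is
#'   reproducible from it).
#' @param folds Number of cross-validation folds.
#' @param mlp_seed,mlp_epochs,mlp_lr Network training hyperparameters.
#' @return An `eval_report` list: `holdout` (mse, r2), `cv` (per-fold
#'   and mean/sd metrics), `residuals`, `fold_assignments`,
#'   `coefficients` (ridge weights, or input-layer weight norms for the
#'   network), `n`, `method`.
#' @export
evaluate_model <- function(x, y = NULL, method = c("ridge", "mlp"),
                           alpha = 1.0, split_seed = 1L, folds = 5L,
                           mlp_seed = 42L, mlp_epochs = 8000L,
                           mlp_lr = 0.05) {
  method <- match.arg(method)
  if (inherits(x, "feature_table")) {
    if (is.null(y)) y <- x$target_r
    x <- as.matrix(x[, c("f_native", "f_complex")])
  }
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 5) stop("need at least 5 samples for cross-validation")
  if (n < folds) stop("fewer samples than folds")
  fit_fn <- switch(method,
                   ridge = function(xt, yt) fit_ridge(xt, yt, alpha = alpha),
                   mlp = function(xt, yt) fit_mlp(xt, yt, seed = mlp_seed,
                                                  epochs = mlp_epochs,
                                                  learning_rate = mlp_lr))
  ord <- with_seed(split_seed, function() sample.int(n))
  n_train <- max(1L, floor(0.8 * n))
  tr <- ord[seq_len(n_train)]
  te <- ord[(n_train + 1L):n]
  model <- fit_fn(x[tr, , drop = FALSE], y[tr])
  pred_te <- stats::predict(model, x[te, , drop = FALSE])
  holdout <- list(mse = mse_(y[te], pred_te), r2 = r2_(y[te], pred_te))

  # contiguous blocks of the shuffled order
  fold_of <- integer(n)
  sizes <- rep(n %/% folds, folds) + (seq_len(folds) <= n %% folds)
  fold_of[ord] <- rep(seq_len(folds), times = sizes)
  cv_mse <- cv_r2 <- numeric(folds)
  for (f in seq_len(folds)) {
    trf <- fold_of != f
    m <- fit_fn(x[trf, , drop = FALSE], y[trf])
    p <- stats::predict(m, x[!trf, , drop = FALSE])
    cv_mse[f] <- mse_(y[!trf], p)
    cv_r2[f] <- r2_(y[!trf], p)
  }
  coefs <- if (method == "ridge") model$coefficients else
    stats::setNames(sqrt(rowSums(model$W1^2)), colnames(x))
  structure(list(
    method = method, n = n,
    holdout = holdout,
    cv = list(mse = cv_mse, r2 = cv_r2,
              mse_mean = mean(cv_mse), mse_sd = stats::sd(cv_mse),
              r2_mean = mean(cv_r2), r2_sd = stats::sd(cv_r2)),
    residuals = pred_te - y[te],
    residual_mean = mean(pred_te - y[te]),
    test_rows = te,
    fold_assignments = fold_of,
    coefficients = coefs,
    model = model), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s, n = %d\n", x$method, x$n))
  cat(sprintf("  80/20 holdout: MSE = %.4g, R2 = %.4f\n",
              x$holdout$mse, x$holdout$r2))
  cat(sprintf("  %d-fold CV:    MSE = %.4g +/- %.3g, R2 = %.4f +/- %.3g\n",
              length(x$cv$mse), x$cv$mse_mean, x$cv$mse_sd,
              x$cv$r2_mean, x$cv$r2_sd))
  if (x$n < 10)
    cat("  note: n < 10; metrics are descriptive, not inferential\n")
  invisible(x)
}
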