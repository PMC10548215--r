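#' Fit a univariate PLS regression by the orthogonal-scores algorithm
#'
#' Classical orthogonal-scores (NIPALS) partial least squares for a single
#' response: predictors and response are mean-centred (not scaled); each
#' component takes the weight vector `w = X'y / ||X'y||`, score `t = Xw`,
#' predictor loading `p = X't / t't` and response loading `q = y't / t't`,
#' then deflates `X <- X - t p'` and `y <- y - q t`. Scores of different
#' components are mutually orthogonal. Regression coefficients on the raw
#' predictor scale are `B_a = W (P'W)^-1 q` truncated at `a` components.
#'
#' @param X Calibration predictor matrix (rows = samples).
#' @param y Calibration response vector.
#' @param n_components Number of latent components, `>= 1` and at most
#'   `min(nrow - 1, ncol)`.
#' @return A list of class `plsr_model`: `coefficients` (per-component-count
#'   matrix, `p x n_components`), `intercepts`, `weights`, `loadings`,
#'   `scores`, `y_loadings`, `x_center`, `y_center`, `n_components`.
#' @export
fit_plsr <- function(X, y, n_components) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  if (stats::var(y) == 0) stop("zero-variance response")
  if (n_components < 1 || n_components > min(n - 1, p))
    stop("n_components out of range")
  x_center <- colMeans(X)
  y_center <- mean(y)
  E <- sweep(X, 2, x_center)
  f <- y - y_center
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  q <- numeric(n_components)
  for (a in seq_len(n_components)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps^0.5) {
      # residual response orthogonal to residual predictors: truncate
      W <- W[, seq_len(a - 1), drop = FALSE]
      P <- P[, seq_len(a - 1), drop = FALSE]
      Tm <- Tm[, seq_len(a - 1), drop = FALSE]
      q <- q[seq_len(a - 1)]
      n_components <- a - 1L
      break
    }
    w <- w / nw
    tt <- drop(E %*% w)
    t2 <- sum(tt^2)
    pp <- drop(crossprod(E, tt)) / t2
    qq <- sum(f * tt) / t2
    E <- E - tcrossprod(tt, pp)
    f <- f - qq * tt
    W[, a] <- w; P[, a] <- pp; Tm[, a] <- tt; q[a] <- qq
  }
  if (n_components == 0) stop("no usable components (response orthogonal to predictors)")
  R <- W %*% solve(crossprod(P, W))      # p x A projection to raw-X scale
  coefs <- sapply(seq_len(n_components), function(a)
    R[, seq_len(a), drop = FALSE] %*% q[seq_len(a)])
  coefs <- matrix(coefs, p, n_components)
  intercepts <- y_center - drop(crossprod(coefs, x_center))
  rownames(coefs) <- colnames(X)
  structure(list(coefficients = coefs, intercepts = intercepts,
                 weights = W, loadings = P, scores = Tm, y_loadings = q,
                 x_center = x_center, y_center = y_center,
                 n_components = n_components),
            class = "plsr_model")
}

#' Predict from a fitted PLS regression
#'
#' @param object A `plsr_model`.
#' @param newdata Predictor matrix with the training columns.
#' @param n_components Component count to use (default: the model's full
#'   count); 0 predicts the calibration mean.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.plsr_model <- function(object, newdata,
                               n_components = object$n_components, ...) {
  if (n_components == 0) return(rep(object$y_center, nrow(as.matrix(newdata))))
  stopifnot(n_components <= object$n_components)
  drop(as.matrix(newdata) %*% object$coefficients[, n_components]) +
    object$intercepts[n_components]
}

#' Choose the PLS component count by leave-one-out RMSEP
#'
#' Evaluates component counts `0..max_components` by leave-one-out
#' cross-validated RMSEP on the calibration set (count 0 is the
#' calibration-mean predictor) and returns the argmin; ties go to the
#' smaller count. An optimum at 0 components means no model beats the mean
#' and is reported as a not-fittable outcome rather than a model.
#'
#' @param X,y Calibration data.
#' @param max_components Upper bound on the component count; capped at
#'   `min(20, nrow - 2, ncol)`.
#' @return List of class `loo_selection`: `n_components` (0 when not
#'   fittable), `fittable`, `loo_rmsep` (named vector over `0..A`),
#'   `loo_predictions` (n x (A+1) matrix).
#' @export
select_components_loo <- function(X, y, max_components = 20) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 calibration rows for LOO selection")
  A <- min(max_components, n - 2, ncol(X))
  pred <- matrix(NA_real_, n, A + 1)
  for (i in seq_len(n)) {
    fit <- fit_plsr(X[-i, , drop = FALSE], y[-i], A)
    pred[i, 1] <- fit$y_center
    for (a in seq_len(fit$n_components))
      pred[i, a + 1] <- predict(fit, X[i, , drop = FALSE], n_components = a)
    if (fit$n_components < A)
      pred[i, (fit$n_components + 2):(A + 1)] <- pred[i, fit$n_components + 1]
  }
  rmsep <- sqrt(colMeans((pred - y)^2))
  names(rmsep) <- 0:A
  best <- unname(which.min(rmsep)) - 1L  # ties: first = smallest count
  structure(list(n_components = best, fittable = best > 0,
                 loo_rmsep = rmsep, loo_predictions = pred),
            class = "loo_selection")
}

#' Jackknife prediction intervals for PLS predictions
#'
#' Refits the model with each calibration sample left out, giving `n_cal`
#' coefficient vectors and `n_cal` predictions per validation sample. The
#' point prediction comes from the full-calibration model; the interval is
#' `point +/- z(level) * SE_jack`, with the jackknife variance
#' `(n-1)/n * sum((pred_(i) - mean(pred_(.)))^2)`.
#'
#' @param X_cal,y_cal Calibration data.
#' @param n_components Component count (from [select_components_loo()]).
#' @param X_val Validation predictors.
#' @param level Confidence level, default 0.95.
#' @return Data frame with `prediction`, `lower`, `upper`, `se`; the full
#'   model is attached as attribute `"model"`.
#' @export
jackknife_predict <- function(X_cal, y_cal, n_components, X_val,
                              level = 0.95) {
  X_cal <- as.matrix(X_cal); X_val <- as.matrix(X_val)
  n <- nrow(X_cal)
  if (n < 3) stop("need at least 3 calibration rows")
  full <- fit_plsr(X_cal, y_cal, n_components)
  point <- predict(full, X_val)
  reps <- matrix(NA_real_, n, nrow(X_val))
  for (i in seq_len(n)) {
    fit <- fit_plsr(X_cal[-i, , drop = FALSE], y_cal[-i],
                    min(n_components, n - 2))
    reps[i, ] <- predict(fit, X_val,
                         n_components = min(n_components, fit$n_components))
  }
  se <- sqrt((n - 1) / n * colSums(sweep(reps, 2, colMeans(reps))^2))
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- data.frame(prediction = point, lower = point - z * se,
                    upper = point + z * se, se = se)
  attr(out, "model") <- full
  attr(out, "replicates") <- reps
  out
}

#' Prediction metrics: RMSEP, R-squared and range-normalised RMSEP
#'
#' `RMSEP = sqrt(mean((y - yhat)^2))`;
#' `R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`;
#' `%RMSEP = 100 * RMSEP / range(y)`. A constant response leaves R2 and
#' %RMSEP undefined (`NA` with a warning).
#'
#' @param y Measured values.
#' @param y_hat Predicted values (LOO predictions for calibration context,
#'   validation predictions otherwise).
#' @param context Label stored with the metrics, e.g. `"calibration_loo"` or
#'   `"validation"`.
#' @return A one-row data frame: `r2`, `rmsep`, `pct_rmsep`, `n`, `context`.
#' @export
evaluate <- function(y, y_hat, context = "validation") {
  stopifnot(length(y) == length(y_hat), length(y) > 0)
  rmsep <- sqrt(mean((y - y_hat)^2))
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    warning("constant response: R2 and %RMSEP undefined")
    r2 <- NA_real_; pct <- NA_real_
  } else {
    r2 <- 1 - sum((y - y_hat)^2) / ss_tot
    pct <- 100 * rmsep / diff(range(y))
  }
  data.frame(r2 = r2, rmsep = rmsep, pct_rmsep = pct, n = length(y),
             context = context, stringsAsFactors = FALSE)
}
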