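# HRF shape features, fit-quality metrics, age correlations, leave-one-out
# age prediction and paired model comparison.

#' Peak amplitude and latency of an HRF curve
#'
#' The signed value and time of the sample with maximal absolute value
#' within the search window (earliest sample on ties).
#'
#' @param curve HRF values on a regular grid starting at 0.
#' @param step_s Grid step in seconds.
#' @param window_s Search window in seconds (default 16).
#' @return List with `amplitude` (signed) and `latency` (s).
#' @export
peak_features <- function(curve, step_s, window_s = 16) {
  t <- (seq_along(curve) - 1) * step_s
  if (max(t) < window_s) stop("curve must cover the search window")
  w <- which(t <= window_s)
  if (all(curve[w] == 0)) stop("curve is identically zero in the window")
  i <- w[which.max(abs(curve[w]))]
  list(amplitude = curve[i], latency = t[i])
}

#' Root-mean-squared error between two series
#'
#' Used both for residuals across the original BOLD timeseries and for
#' model-vs-FIR differences across post-stimulus time.
#'
#' @param y,fit Equal-length numeric vectors.
#' @return `sqrt(mean((y - fit)^2))`.
#' @export
rmse <- function(y, fit) {
  if (length(y) != length(fit)) stop("length mismatch")
  sqrt(mean((y - fit)^2))
}

#' Spearman rank correlation with age
#'
#' @param values Per-participant feature values.
#' @param ages Ages in years.
#' @return List with `rho` and two-sided `p`.
#' @export
spearman_age <- function(values, ages) {
  if (length(values) != length(ages)) stop("length mismatch")
  if (length(values) < 4) stop("need at least 4 participants")
  if (sd(values) == 0 || sd(ages) == 0) {
    stop("rank correlation undefined for constant input")
  }
  ct <- suppressWarnings(cor.test(values, ages, method = "spearman",
                                  exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Leave-one-out cross-validated age prediction
#'
#' For each participant, a multiple linear regression of age on the feature
#' columns is trained on all other participants and used to predict the
#' held-out age.
#'
#' @param features `n x k` matrix of per-participant features.
#' @param ages Ages in years.
#' @param intercept Include an intercept (default `TRUE`).
#' @return List with `predictions`, Pearson `r` between actual and predicted
#'   age, its one-sided `p` (r > 0), `abs_errors` and `median_error`.
#' @export
loo_age_prediction <- function(features, ages, intercept = TRUE) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (length(ages) != n) stop("ages must match feature rows")
  if (n <= ncol(X) + 1) stop("need more participants than features + 1")
  M <- if (intercept) cbind(1, X) else X
  if (qr(M)$rank < ncol(M)) stop("feature design is ill-conditioned")
  pred <- numeric(n)
  for (i in seq_len(n)) {
    cf <- qr.coef(qr(M[-i, , drop = FALSE]), ages[-i])
    cf[is.na(cf)] <- 0
    pred[i] <- sum(M[i, ] * cf)
  }
  ct <- cor.test(ages, pred, alternative = "greater")
  err <- abs(ages - pred)
  list(predictions = pred, r = unname(ct$estimate), p = ct$p.value,
       abs_errors = err, median_error = median(err))
}

#' Two-sided sign test on paired errors
#'
#' Exact binomial test on the sign of `a - b`, discarding exact ties.
#'
#' @param errors_a,errors_b Paired error vectors.
#' @return List with `p`, `n_effective`, `n_positive`.
#' @export
sign_test <- function(errors_a, errors_b) {
  if (length(errors_a) != length(errors_b)) stop("length mismatch")
  d <- errors_a - errors_b
  nz <- d != 0
  if (!any(nz)) stop("all pairs tied; sign test degenerate")
  k <- sum(d[nz] > 0)
  bt <- binom.test(k, sum(nz), p = 0.5, alternative = "two.sided")
  list(p = bt$p.value, n_effective = sum(nz), n_positive = k)
}
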