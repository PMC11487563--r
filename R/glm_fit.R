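# First-level prewhitened GLM machinery: discrete cosine high-pass set,
# AR(1)+white-noise ReML covariance estimation, whitened OLS with
# extra-sum-of-squares F contrasts, per-participant voxel selection, the ROI
# eigenvariate, and the second-level age model for FIR estimates.

#' Discrete cosine high-pass regressor set
#'
#' Unit-norm cosine columns whose periods are at least `cutoff_s`, plus a
#' constant; including them in the design high-pass filters model and data
#' identically. The number of non-constant cosines is
#' `floor(2 * n_scans * tr_s / cutoff_s)`.
#'
#' @param n_scans Number of scans.
#' @param tr_s Repetition time (s).
#' @param cutoff_s High-pass cutoff period in seconds (default 128).
#' @return `n_scans x (K+1)` orthonormal matrix; first column constant.
#' @export
dct_highpass_set <- function(n_scans, tr_s, cutoff_s = 128) {
  if (n_scans < 2) stop("n_scans must be >= 2")
  K <- floor(2 * n_scans * tr_s / cutoff_s)
  t <- seq_len(n_scans) - 1
  X <- matrix(0, n_scans, K + 1)
  X[, 1] <- 1 / sqrt(n_scans)
  for (k in seq_len(K)) {
    X[, k + 1] <- sqrt(2 / n_scans) * cos(pi * (2 * t + 1) * k / (2 * n_scans))
  }
  colnames(X) <- c("constant", if (K) paste0("dct_", seq_len(K)))
  X
}

#' Estimate an AR(1)+white-noise covariance by restricted maximum likelihood
#'
#' Models the scan-noise covariance as a mixture `h1 * I + h2 * Q(rho)` with
#' `Q(rho)` an AR(1) correlation matrix, estimating the mixture weights by
#' ReML (Fisher scoring on the restricted likelihood, with the design
#' projected out). By default the AR coefficient itself is first estimated
#' from the lag-1 autocorrelation of the pooled OLS residuals; pass a fixed
#' `ar_coef` (e.g. 0.2, the convention of some analysis packages) to skip
#' that step. The whitening operator is the inverse symmetric square root of
#' the fitted covariance.
#'
#' @param Y `n x v` data matrix (voxels pooled for the covariance estimate).
#' @param X Full design matrix used to restrict the likelihood.
#' @param ar_coef Fixed AR(1) coefficient, or `NULL` to estimate it.
#' @param max_iter,tol ReML iteration cap and log-likelihood tolerance.
#' @return A `noise_model` list: mixture `weights`, `ar_coef`, covariance
#'   `V`, whitening matrix `W`, iteration `trace`.
#' @export
reml_ar1 <- function(Y, X, ar_coef = NULL, max_iter = 32, tol = 1e-6) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (nrow(X) != n) stop("Y and X must have the same number of rows")
  if (n <= ncol(X)) stop("need more scans than regressors")
  if (is.null(ar_coef)) {
    res <- Y - X %*% qr.coef(qr(X), Y)
    num <- sum(res[-1, ] * res[-n, ])
    den <- sum(res^2)
    ar_coef <- if (den > 0) num / den else 0
    if (abs(ar_coef) < 0.05) ar_coef <- 0.2  # near-white: keep a reference component
    ar_coef <- max(min(ar_coef, 0.95), -0.95)
  }
  if (abs(ar_coef) >= 1) stop("ar_coef must satisfy |ar_coef| < 1")
  Q <- list(diag(n), toeplitz(ar_coef^(0:(n - 1))))
  S <- tcrossprod(Y) / ncol(Y)
  scale0 <- mean(diag(S))
  h <- c(scale0, 0)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    V <- h[1] * Q[[1]] + h[2] * Q[[2]]
    ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= scale0 * 1e-10) {
      # pull the proposal back toward a valid covariance
      h <- 0.5 * h + 0.5 * c(scale0, 0)
      next
    }
    iV <- chol2inv(chol(V))
    iVX <- iV %*% X
    P <- iV - iVX %*% solve(crossprod(X, iVX), t(iVX))
    PS <- P %*% S
    g <- H <- NULL
    PQ <- lapply(Q, function(q) P %*% q)
    g <- vapply(seq_along(Q), function(i) {
      -0.5 * sum(diag(PQ[[i]])) + 0.5 * sum(PQ[[i]] * t(PS))
    }, numeric(1))
    H <- matrix(0, 2, 2)
    for (i in 1:2) for (j in i:2) {
      H[i, j] <- H[j, i] <- 0.5 * sum(PQ[[i]] * t(PQ[[j]]))
    }
    dh <- tryCatch(solve(H, g), error = function(e) solve(H + diag(1e-8, 2), g))
    h <- h + dh
    dl <- sum(g * dh)
    trace <- c(trace, dl)
    if (is.finite(dl) && abs(dl) < tol) break
  }
  V <- h[1] * Q[[1]] + h[2] * Q[[2]]
  ed <- eigen(V, symmetric = TRUE)
  if (min(ed$values) <= 0) stop("ReML covariance is not positive definite")
  W <- ed$vectors %*% (t(ed$vectors) / sqrt(ed$values))
  structure(list(weights = h, ar_coef = ar_coef, V = V, W = W, trace = trace),
            class = "noise_model")
}

#' Fit a prewhitened general linear model
#'
#' Scales the data to a grand mean of `grand_mean` over all voxels and scans,
#' whitens model and data identically with the noise model's operator, and
#' estimates coefficients by least squares. An F statistic for the regressors
#' of interest (the columns of `X`) is formed by extra sums of squares
#' against the nuisance-only model.
#'
#' @param Y `n x v` data (or a vector for one voxel/region).
#' @param X Regressors of interest (`n x k`).
#' @param confounds Nuisance regressors (motion, compartments, cosine set);
#'   include a constant here, e.g. via [dct_highpass_set()].
#' @param noise A `noise_model` from [reml_ar1()], or `NULL` for identity
#'   whitening.
#' @param grand_mean Target grand mean, or `NULL` to skip scaling.
#' @return A `glm_fit` list: `beta` (interest), `beta_nuisance`, `fitted`,
#'   `residuals` (whitened), `sigma2`, `df`, `F`, `p`, `scale`.
#' @export
fit_glm <- function(Y, X, confounds = NULL, noise = NULL, grand_mean = 100) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  X <- as.matrix(X)
  if (nrow(X) != n) stop("dimension mismatch between Y and X")
  Z <- if (is.null(confounds)) matrix(1, n, 1) else as.matrix(confounds)
  if (nrow(Z) != n) stop("dimension mismatch between Y and confounds")
  full <- cbind(X, Z)
  if (qr(full)$rank < ncol(full)) stop("design matrix is rank deficient")
  scale <- 1
  if (!is.null(grand_mean)) {
    gm <- mean(Y)
    if (gm <= 0) stop("grand-mean scaling requires positive-mean data")
    scale <- grand_mean / gm
    Y <- Y * scale
  }
  W <- if (is.null(noise)) NULL else noise$W
  WY <- if (is.null(W)) Y else W %*% Y
  WX <- if (is.null(W)) full else W %*% full
  WZ <- if (is.null(W)) Z else W %*% Z
  qf <- qr(WX)
  beta <- qr.coef(qf, WY)
  res <- WY - WX %*% beta
  df <- n - qf$rank
  rss_full <- colSums(res^2)
  sigma2 <- rss_full / df
  qz <- qr(WZ)
  res0 <- WY - WZ %*% qr.coef(qz, WY)
  rss_red <- colSums(res0^2)
  k <- ncol(X)
  Fstat <- ((rss_red - rss_full) / k) / pmax(sigma2, .Machine$double.eps)
  pval <- pf(Fstat, k, df, lower.tail = FALSE)
  structure(list(
    beta = beta[seq_len(k), , drop = FALSE],
    beta_nuisance = beta[-seq_len(k), , drop = FALSE],
    fitted = WX %*% beta, residuals = res, sigma2 = sigma2, df = df,
    df_num = k, F = Fstat, p = pval, scale = scale
  ), class = "glm_fit")
}

#' Select responsive voxels within a participant
#'
#' Keeps voxels whose F contrast across the basis regressors is significant
#' at `alpha` (uncorrected). An empty selection flags the participant for
#' exclusion via the `excluded` attribute.
#'
#' @param fit A `glm_fit` over voxels.
#' @param alpha Uncorrected significance threshold (default 0.05).
#' @return Integer indices of retained voxels, with attribute `excluded`.
#' @export
participant_voxel_selection <- function(fit, alpha = 0.05) {
  idx <- which(fit$p < alpha)
  attr(idx, "excluded") <- length(idx) == 0L
  idx
}

#' First temporal component of a region of interest
#'
#' Singular value decomposition across voxels; the summary timeseries is the
#' first left singular vector scaled to the region's typical amplitude
#' (`u1 * d1 / sqrt(v)`), with its sign chosen so the mean voxel weight is
#' positive.
#'
#' @param Y `n x v` voxel timeseries matrix.
#' @return A `roi_summary` list: `eigenvariate`, `weights`, `voxels`,
#'   `variance_explained`.
#' @export
roi_eigenvariate <- function(Y) {
  Y <- as.matrix(Y)
  if (ncol(Y) < 1) stop("need at least one voxel")
  sv <- svd(Y)
  flip <- if (mean(sv$v[, 1]) < 0) -1 else 1
  structure(list(
    eigenvariate = flip * sv$u[, 1] * sv$d[1] / sqrt(ncol(Y)),
    weights = flip * sv$v[, 1],
    voxels = seq_len(ncol(Y)),
    variance_explained = sv$d[1]^2 / sum(sv$d^2)
  ), class = "roi_summary")
}

#' Second-level age model for FIR estimates
#'
#' Regresses each participant's per-bin FIR estimate on a constant, z-scored
#' age and centred squared z-age, and forms omnibus F tests spanning bins
#' for the mean, linear and quadratic age effects (pooled extra sums of
#' squares across bins).
#'
#' @param fir `n_participants x n_bins` matrix of FIR estimates.
#' @param ages Participant ages in years.
#' @return List with `coefficients` (3 x bins), `se`, per-effect omnibus `F`
#'   and `p`, and the design used.
#' @export
second_level_age_glm <- function(fir, ages) {
  fir <- as.matrix(fir)
  n <- nrow(fir)
  if (n < 4) stop("need at least 4 participants")
  if (length(ages) != n) stop("ages must match rows of fir")
  z <- as.numeric(scale(ages))
  z2 <- z^2 - mean(z^2)
  X <- cbind(mean = 1, age_linear = z, age_quadratic = z2)
  qf <- qr(X)
  beta <- qr.coef(qf, fir)
  res <- fir - X %*% beta
  b <- ncol(fir)
  df <- n - ncol(X)
  rss <- colSums(res^2)
  xtxi <- chol2inv(qr.R(qf))
  se <- sqrt(outer(diag(xtxi), rss / df))
  Fp <- sapply(seq_len(ncol(X)), function(k) {
    Xr <- X[, -k, drop = FALSE]
    resr <- fir - Xr %*% qr.coef(qr(Xr), fir)
    extra <- sum(colSums(resr^2) - rss)
    Fk <- (extra / b) / (sum(rss) / (b * df))
    c(Fk, pf(Fk, b, b * df, lower.tail = FALSE))
  })
  dimnames(beta) <- list(colnames(X), colnames(fir))
  list(coefficients = beta, se = se,
       F = setNames(Fp[1, ], colnames(X)),
       p = setNames(Fp[2, ], colnames(X)),
       design = X, df = df)
}
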