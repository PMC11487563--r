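# Prewhitened GLM: cosine set, ReML noise estimation, OLS/F oracles,
# voxel selection, eigenvariate, second-level age model.

test_that("cosine high-pass set has the expected size and orthogonality", {
  X <- dct_highpass_set(261, 1.97, 128)
  expect_equal(ncol(X), 9)  # 8 cosines + constant
  expect_equal(sd(X[, 1]), 0)
  # every non-constant column completes its k/2 cycles over >= 128 s
  periods <- 2 * 261 * 1.97 / seq_len(8)
  expect_true(all(periods >= 128))
  expect_lt(2 * 261 * 1.97 / 9, 128)  # the next cosine would be too fast
  G <- crossprod(X)
  expect_lt(max(abs(G - diag(ncol(X)))), 1e-10)
})

test_that("ReML attributes white noise to the white component", {
  set.seed(41)
  n <- 200
  X <- cbind(1, rnorm(n))
  Y <- matrix(rnorm(n * 30), n)
  nm <- reml_ar1(Y, X)
  # AR mixture weight is a small fraction of the white weight
  expect_lt(abs(nm$weights[2]) / nm$weights[1], 0.15)
  lag1 <- function(e) sum(e[-1] * e[-length(e)]) / sum(e^2)
  We <- nm$W %*% Y
  expect_lt(abs(mean(apply(We, 2, lag1))), 0.05)
})

test_that("whitening removes AR(1) autocorrelation (rho = 0.5)", {
  set.seed(42)
  n <- 200
  X <- cbind(1, seq_len(n) / n)
  Y <- sapply(1:30, function(i) {
    as.numeric(filter(rnorm(n), 0.5, method = "recursive"))
  })
  nm <- reml_ar1(Y, X)
  lag1 <- function(e) sum(e[-1] * e[-length(e)]) / sum(e^2)
  We <- nm$W %*% Y
  expect_lt(abs(mean(apply(We, 2, lag1))), 0.1)
})

test_that("whitening efficacy holds on average over many AR(1) datasets", {
  set.seed(43)
  n <- 120
  X <- cbind(1, rnorm(n))
  lag1 <- function(e) sum(e[-1] * e[-length(e)]) / sum(e^2)
  vals <- replicate(60, {
    Y <- sapply(1:8, function(i) {
      as.numeric(filter(rnorm(n), 0.3, method = "recursive"))
    })
    nm <- reml_ar1(Y, X)
    mean(apply(nm$W %*% Y, 2, lag1))
  })
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("a single identity component yields scaled-identity whitening", {
  set.seed(44)
  n <- 80
  Y <- matrix(rnorm(n * 5, sd = 2), n)
  nm <- reml_ar1(Y, cbind(1, rnorm(n)), ar_coef = 0.2, max_iter = 32)
  # V is close to sigma^2 I, so W is close to I/sigma
  offdiag <- nm$V - diag(diag(nm$V))
  expect_lt(max(abs(offdiag)) / mean(diag(nm$V)), 0.1)
})

test_that("whitened OLS and F statistics match brute-force oracles", {
  set.seed(45)
  for (rep in 1:50) {
    n <- 30
    X <- matrix(rnorm(n * 3), n)
    Z <- cbind(1, rnorm(n))
    y <- rnorm(n)
    A <- matrix(rnorm(n * n, sd = 0.2), n)
    V <- crossprod(A) + diag(n)
    ed <- eigen(V, symmetric = TRUE)
    W <- ed$vectors %*% (t(ed$vectors) / sqrt(ed$values))
    noise <- structure(list(W = W), class = "noise_model")
    fit <- fit_glm(y, X, Z, noise, grand_mean = NULL)
    orc <- glm_oracle(y, X, Z, W)
    expect_lt(max(abs(as.numeric(fit$beta) - orc$beta[1:3])), 1e-10)
    expect_lt(abs(fit$F - orc$F), 1e-10)
  }
})

test_that("noise-free data are recovered exactly and errors are caught", {
  set.seed(46)
  n <- 60
  X <- matrix(rnorm(n * 2), n)
  Z <- matrix(1, n, 1)
  bstar <- c(1.5, -2)
  y <- X %*% bstar + 3
  fit <- fit_glm(y, X, Z, grand_mean = NULL)
  expect_equal(as.numeric(fit$beta), bstar, tolerance = 1e-12)
  expect_error(fit_glm(y, cbind(X, X[, 1]), Z, grand_mean = NULL),
               "rank deficient")
  expect_error(fit_glm(y[1:10], X, Z, grand_mean = NULL), "mismatch")
  # grand-mean scaling
  fit2 <- fit_glm(matrix(50, n, 2), matrix(rnorm(n)), Z)
  expect_equal(fit2$scale, 2)
})

test_that("voxel selection has calibrated type-I error and finds signal", {
  set.seed(47)
  n <- 120
  X <- matrix(rnorm(n * 4), n)
  Z <- matrix(1, n, 1)
  Y <- matrix(rnorm(n * 10000), n)
  fit <- fit_glm(Y, X, Z, grand_mean = NULL)
  sel <- participant_voxel_selection(fit, 0.05)
  prop <- length(sel) / 10000
  expect_true(prop > 0.05 - 3 * sqrt(0.05 * 0.95 / 10000) &&
                prop < 0.05 + 3 * sqrt(0.05 * 0.95 / 10000))
  # strong signal is selected
  ys <- X[, 1] * 10 + rnorm(n)
  fs <- fit_glm(cbind(ys, rnorm(n)), X, Z, grand_mean = NULL)
  expect_true(1 %in% participant_voxel_selection(fs))
  # all-null flags exclusion
  fnull <- fit_glm(matrix(rnorm(n * 2), n), X, Z, grand_mean = NULL)
  fnull$p[] <- 0.9
  expect_true(attr(participant_voxel_selection(fnull), "excluded"))
})

test_that("the eigenvariate summarises a region faithfully", {
  set.seed(48)
  ts <- rnorm(100)
  Y <- matrix(ts, 100, 6)
  eig <- roi_eigenvariate(Y)
  expect_equal(abs(cor(eig$eigenvariate, ts)), 1)
  expect_true(mean(eig$weights) > 0)
  # rank-1 + tiny noise
  Y2 <- outer(ts, runif(8, 0.5, 2)) + matrix(rnorm(800, sd = 0.01), 100)
  expect_gt(roi_eigenvariate(Y2)$variance_explained, 0.99)
  # sign convention flips with the data
  e1 <- roi_eigenvariate(Y2)$eigenvariate
  e2 <- roi_eigenvariate(-Y2)$eigenvariate
  expect_equal(e1, -e2)
})

test_that("second-level age model recovers injected bin effects", {
  set.seed(49)
  n <- 80
  ages <- runif(n, 18, 88)
  z <- as.numeric(scale(ages))
  fir <- matrix(rnorm(n * 32, sd = 0.5), n)
  fir[, 5] <- fir[, 5] + 1 + 0.8 * z
  out <- second_level_age_glm(fir, ages)
  est <- out$coefficients["age_linear", 5]
  expect_lt(abs(est - 0.8), 3 * out$se[2, 5])
  expect_lt(out$p[["age_linear"]], 0.01)
  # no quadratic generation: quadratic omnibus not strongly significant
  expect_gt(out$p[["age_quadratic"]], 0.01)
  # identical participants: age effects vanish
  same <- matrix(rep(rnorm(32), each = 8), 8)
  out2 <- second_level_age_glm(same, runif(8, 18, 88))
  expect_lt(max(abs(out2$coefficients[c("age_linear", "age_quadratic"), ])),
            1e-10)
})
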