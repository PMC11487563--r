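# Parametric Empirical Bayes and Bayesian Model Reduction.

fake_post <- function(mean, cov, prior_var = c(1, 1, 1)) {
  structure(list(mean = setNames(mean, c("beta", "kappa", "transit")),
                 cov = cov,
                 priors = list(mean = c(beta = 0, kappa = 0, transit = 0),
                               var = setNames(prior_var,
                                              c("beta", "kappa", "transit")))),
            class = "vl_posterior")
}

test_that("identical posteriors give their shared mean as the group mean", {
  S <- diag(0.01, 3)
  posts <- replicate(6, fake_post(c(0.5, 0.2, -0.1), S), simplify = FALSE)
  pr <- peb_fit(posts, between = 1e-6)
  expect_equal(unname(pr$Eb[, 1]), c(0.5, 0.2, -0.1), tolerance = 0.02)
})

test_that("zero between-subject variance gives the precision-weighted mean", {
  set.seed(81)
  posts <- lapply(1:8, function(i) {
    fake_post(rnorm(3, c(0.4, 0.1, -0.1), 0.2), diag(runif(3, 0.05, 0.3)))
  })
  pr <- peb_fit(posts, between = 1e-8)
  # closed-form oracle: with Gamma -> 0 and a mean-only design, the group
  # posterior is the precision-weighted combination of participants + prior
  P <- diag(1 / c(1, 1, 1))
  rhs <- rep(0, 3)
  for (p in posts) {
    iS <- solve(p$cov)
    P <- P + iS
    rhs <- rhs + iS %*% p$mean
  }
  expect_equal(unname(pr$Eb[, 1]), as.numeric(solve(P, rhs)),
               tolerance = 1e-6)
})

test_that("an injected group age effect is recovered within its interval", {
  set.seed(82)
  n <- 60
  ages <- runif(n, 18, 88)
  z <- as.numeric(scale(ages))
  posts <- lapply(seq_len(n), function(i) {
    truth <- c(0.4, 0.25 * z[i], -0.1)
    fake_post(truth + rnorm(3, 0, 0.05), diag(0.02, 3))
  })
  pr <- peb_fit(posts, ages = ages)
  est <- pr$Eb["kappa", 2]
  sd_est <- sqrt(diag(pr$Sb)[5])
  expect_lt(abs(est - 0.25), 3 * sd_est + 0.05)
})

test_that("an unchanged prior changes nothing and BMR matches explicit refits", {
  set.seed(83)
  # linear-Gaussian toy: y = A theta + e
  for (rep in 1:50) {
    k <- 3
    n <- 24
    A <- matrix(rnorm(n * k), n)
    noise_var <- 0.5
    prior <- list(mean = rnorm(k, 0, 0.5), cov = diag(runif(k, 0.3, 2)))
    theta <- as.numeric(prior$mean + chol(prior$cov) %*% rnorm(k))
    y <- as.numeric(A %*% theta + rnorm(n, 0, sqrt(noise_var)))
    # exact Gaussian posterior under the full prior
    P <- crossprod(A) / noise_var + solve(prior$cov)
    S <- solve(P)
    m <- as.numeric(S %*% (crossprod(A, y) / noise_var +
                             solve(prior$cov, prior$mean)))
    post <- list(mean = m, cov = S)
    # identity reduction
    same <- bmr_evidence(post, prior, prior)
    expect_equal(same$dF, 0, tolerance = 1e-10)
    expect_equal(same$mean, m, tolerance = 1e-8)
    # random reduced prior (shrunk variances, shifted means)
    red <- list(mean = prior$mean * c(1, 0, 1),
                cov = diag(diag(prior$cov) * runif(k, 0.05, 1)))
    got <- bmr_evidence(post, prior, red)
    dF_refit <- gaussian_evidence(y, A, noise_var, red$mean, red$cov) -
      gaussian_evidence(y, A, noise_var, prior$mean, prior$cov)
    expect_lt(abs(got$dF - dF_refit), 1e-3)
  }
})

test_that("pruning a prior-like parameter is evidence-neutral", {
  set.seed(84)
  k <- 2
  prior <- list(mean = rep(0, k), cov = diag(c(1, 1e-6)))
  # posterior nearly equals prior in parameter 2
  post <- list(mean = c(0.8, 1e-5), cov = diag(c(0.05, 0.9e-6)))
  red <- list(mean = rep(0, k), cov = diag(c(1, 1e-10)))
  got <- bmr_evidence(post, prior, red)
  expect_lt(abs(got$dF), 0.1)
})

test_that("BMR search prunes null effects and keeps real ones with signs", {
  set.seed(85)
  n <- 80
  ages <- runif(n, 18, 88)
  z <- as.numeric(scale(ages))
  posts <- lapply(seq_len(n), function(i) {
    truth <- c(0.4, 0.2 * z[i], -0.15 * z[i])
    fake_post(truth + rnorm(3, 0, 0.05), diag(0.02, 3))
  })
  pr <- peb_fit(posts, ages = ages)
  bm <- bmr_search(pr)
  expect_false(bm$retained["beta", 2])
  expect_true(bm$retained["kappa", 2])
  expect_true(bm$retained["transit", 2])
  expect_gt(bm$Eb["kappa", 2], 0)
  expect_lt(bm$Eb["transit", 2], 0)
  # all effects null: every age effect pruned
  posts0 <- lapply(seq_len(n), function(i) {
    fake_post(c(0.4, 0, 0) + rnorm(3, 0, 0.05), diag(0.02, 3))
  })
  bm0 <- bmr_search(peb_fit(posts0, ages = ages))
  expect_false(any(bm0$retained[, 2]))
  # all strong: nothing pruned
  posts1 <- lapply(seq_len(n), function(i) {
    fake_post(c(0.4 + 0.3 * z[i], 0.3 * z[i], -0.3 * z[i]) + rnorm(3, 0, 0.05),
              diag(0.02, 3))
  })
  bm1 <- bmr_search(peb_fit(posts1, ages = ages))
  expect_true(all(bm1$retained[, 2]))
})

test_that("pruning decisions are invariant to parameter ordering", {
  set.seed(86)
  n <- 50
  ages <- runif(n, 18, 88)
  z <- as.numeric(scale(ages))
  mk <- function(perm) {
    posts <- lapply(seq_len(n), function(i) {
      truth <- c(0.4, 0.2 * z[i], 0)[perm]
      structure(list(mean = setNames(truth + rnorm(3, 0, 0.05),
                                     c("beta", "kappa", "transit")[perm]),
                     cov = diag(0.02, 3),
                     priors = list(mean = setNames(rep(0, 3),
                                                   c("beta", "kappa",
                                                     "transit")[perm]),
                                   var = setNames(rep(1, 3),
                                                  c("beta", "kappa",
                                                    "transit")[perm]))),
                class = "vl_posterior")
    })
    bm <- bmr_search(peb_fit(posts, ages = ages))
    bm$retained[order(perm), 2]
  }
  set.seed(87); r1 <- mk(1:3)
  set.seed(87); r2 <- mk(c(3, 1, 2))
  expect_equal(unname(r1), unname(r2))
})

test_that("collinear effects are not both retained", {
  # the data inform only the sum kappa + transit (anticorrelated posteriors),
  # so a single parameter can accommodate the shared age effect
  set.seed(88)
  n <- 60
  ages <- runif(n, 18, 88)
  z <- as.numeric(scale(ages))
  vd <- 2; vs <- 0.01
  Skt <- 0.5 * matrix(c(vd + vs, vs - vd, vs - vd, vd + vs), 2)
  posts <- lapply(seq_len(n), function(i) {
    truth <- c(0.4, 0.15 * z[i], 0.15 * z[i])
    S <- rbind(c(0.02, 0, 0), cbind(0, Skt))
    mvn <- as.numeric(t(chol(S)) %*% rnorm(3))
    fake_post(truth + mvn, S)
  })
  bm <- bmr_search(peb_fit(posts, ages = ages))
  expect_lt(sum(bm$retained[c("kappa", "transit"), 2]), 2)
  # the retained parameter carries the (positive) shared effect
  expect_gt(max(bm$Eb[c("kappa", "transit"), 2]), 0)
})
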