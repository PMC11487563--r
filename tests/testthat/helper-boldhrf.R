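# Shared fixtures and independent oracles, built in code at test time.

# Short scan protocol used where full-length runs are not needed.
short_design <- function() {
  list(tr_s = 1.97, n_scans = 130, base_soa_s = 2,
       jitter_low_s = 0.1, jitter_high_s = 0.3, msequence_degree = 6)
}

# Jittered m-sequence event table for a given degree, seeded.
make_events <- function(degree = 8, seed = 1, base_soa = 2,
                        jlo = 0.1, jhi = 0.3) {
  set.seed(seed)
  build_event_timing(generate_msequence(degree), base_soa, jlo, jhi)
}

# Independent fine-step reference integrator for the hemodynamic system,
# on the natural state scale via deSolve::lsoda.
desolve_reference <- function(p, events, duration_s, dt_out = 0.05,
                              impulse_duration_s = 0.375) {
  rhs <- function(t, state, parms) {
    z <- 0
    if (nrow(events)) {
      z <- as.numeric(any(t >= events$onset &
                            t < events$onset + impulse_duration_s))
    }
    list(hdm_derivs(state, z, p))
  }
  times <- seq(0, duration_s + 1, by = dt_out)
  out <- deSolve::lsoda(c(s = 0, f_in = 1, v = 1, q = 1), times, rhs,
                        parms = NULL, rtol = 1e-9, atol = 1e-9,
                        hmax = dt_out)  # do not step over the brief input
  y <- apply(out[, -1, drop = FALSE], 1, bold_from_state, p = p)
  list(time = out[, 1], y = y, states = out[, -1])
}

# Exhaustive grid-search oracle for the NLF warp at 0.01 resolution.
nlf_grid_oracle <- function(template, fir, t0_bounds = c(-4, 4),
                            t1_bounds = c(0.5, 2), res = 0.01) {
  t <- (seq_along(template$curve) - 1) * template$step_s
  t0s <- seq(t0_bounds[1], t0_bounds[2], by = res)
  t1s <- seq(t1_bounds[1], t1_bounds[2], by = res)
  best <- list(cor = -2, t0 = NA, t1 = NA)
  fc <- fir - mean(fir)
  fn <- sqrt(sum(fc^2))
  for (t1 in t1s) {
    # warped values for all t0 at once: arg[i, j] = t1 * t[i] - t0[j]
    arg <- outer(t1 * t, t0s, "-")
    w <- matrix(approx(t, template$curve, xout = arg, rule = 1)$y,
                nrow = length(t))
    w[is.na(w)] <- 0
    wc <- sweep(w, 2, colMeans(w))
    denom <- sqrt(colSums(wc^2)) * fn
    r <- ifelse(denom > 0, colSums(wc * fc) / denom, -2)
    j <- which.max(r)
    if (r[j] > best$cor) best <- list(cor = r[j], t0 = t0s[j], t1 = t1)
  }
  best
}

# Brute-force GLM oracle: normal equations and extra-sum-of-squares F.
glm_oracle <- function(y, X, Z, W) {
  Wy <- W %*% y
  WX <- W %*% cbind(X, Z)
  WZ <- W %*% Z
  b <- solve(crossprod(WX), crossprod(WX, Wy))
  rss1 <- sum((Wy - WX %*% b)^2)
  b0 <- solve(crossprod(WZ), crossprod(WZ, Wy))
  rss0 <- sum((Wy - WZ %*% b0)^2)
  df <- nrow(WX) - ncol(WX)
  k <- ncol(X)
  list(beta = b, F = ((rss0 - rss1) / k) / (rss1 / df))
}

# Explicit-refit oracle for Bayesian model reduction on a linear-Gaussian
# model y = A theta + noise: log evidence under a given Gaussian prior.
gaussian_evidence <- function(y, A, noise_var, prior_mean, prior_cov) {
  n <- length(y)
  S <- A %*% prior_cov %*% t(A) + diag(noise_var, n)
  e <- y - A %*% prior_mean
  -0.5 * (n * log(2 * pi) + determinant(S)$modulus[1] +
            sum(e * solve(S, e)))
}
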