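# Hemodynamic forward model: derivatives, observation equations, integration
# against an independent stiff-solver reference, and Volterra kernels.

p_def <- hdm_params()
rest <- c(s = 0, f_in = 1, v = 1, q = 1)

test_that("the resting state is a fixed point and input drives only s-dot", {
  expect_equal(unname(hdm_derivs(rest, 0, p_def)), rep(0, 4))
  d1 <- hdm_derivs(rest, 1, p_def)
  expect_equal(unname(d1["s"]), p_def$beta)
  expect_equal(unname(d1[c("f_in", "v", "q")]), rep(0, 3))
  # outflow is 1 at v = 1 for any alpha, so v-dot stays 0 there
  for (a in c(0.1, 0.32, 0.9)) {
    pa <- hdm_params(alpha = a)
    expect_equal(unname(hdm_derivs(rest, 0, pa)["v"]), 0)
  }
  expect_error(hdm_derivs(c(NA, 1, 1, 1), 0, p_def), "finite")
})

test_that("BOLD observation equations match their closed form", {
  expect_equal(bold_from_state(rest, p_def), 0)
  expect_equal(unname(bold_coefficients(p_def)["k1"]), 2.07948)
  expect_equal(unname(bold_coefficients(hdm_params(eps_h = 1))["k3"]), 0)
  st <- c(0, 1.2, 1.1, 0.9)
  k <- bold_coefficients(p_def)
  expect_equal(bold_from_state(st, p_def),
               100 * p_def$v0 * (k[["k1"]] * 0.1 + k[["k2"]] * (1 - 0.9 / 1.1) +
                                   k[["k3"]] * (-0.1)))
})

test_that("integration is quiescent without input and returns to rest", {
  sim <- hdm_integrate(p_def, z = numeric(100), dt_s = 0.375)
  expect_true(all(sim$y == 0))
  ev <- event_sequence(0)
  sim2 <- hdm_integrate(p_def, events = ev, dt_s = 0.375, duration_s = 80)
  late <- sim2$time >= 60
  devn <- abs(sweep(sim2$states[late, , drop = FALSE], 2, c(0, 1, 1, 1)))
  expect_lt(max(devn), 1e-3)
  # positive peak then undershoot
  expect_gt(max(sim2$y), 0)
  expect_lt(min(sim2$y), 0)
  expect_lt(which.min(sim2$y), length(sim2$y))  # undershoot after the peak
  expect_gt(which.min(sim2$y), which.max(sim2$y))
})

test_that("integrated response matches an independent fine-step reference", {
  skip_if_not_installed("deSolve")
  ev <- event_sequence(0)
  ref <- desolve_reference(p_def, ev, 40)
  sim <- hdm_integrate(p_def, events = ev, dt_s = 0.375, duration_s = 40,
                       impulse_duration_s = 0.375)
  yr <- approx(ref$time, ref$y, xout = sim$time)$y
  expect_lt(sqrt(mean((sim$y - yr)^2)) / sd(yr), 0.01)
  # peak latency in a physiological window
  expect_true(sim$time[which.max(sim$y)] >= 3 &&
                sim$time[which.max(sim$y)] <= 7)
})

test_that("integration error shrinks at fourth order in the step size", {
  skip_if_not_installed("deSolve")
  ev <- event_sequence(0)
  rhs <- function(t, state, parms) {
    list(hdm_derivs(state, as.numeric(t >= 0 & t < 0.75), p_def))
  }
  errs <- sapply(c(0.75, 0.375), function(dt) {
    sim <- hdm_integrate(p_def, events = ev, dt_s = dt, duration_s = 40,
                         impulse_duration_s = 0.75)
    # reference evaluated at exactly the coarse output times
    out <- deSolve::lsoda(c(s = 0, f_in = 1, v = 1, q = 1), sim$time, rhs,
                          parms = NULL, rtol = 1e-11, atol = 1e-11,
                          hmax = 0.01)
    yr <- apply(out[, -1, drop = FALSE], 1, bold_from_state, p = p_def)
    sqrt(mean((sim$y - yr)^2))
  })
  expect_gt(errs[1] / errs[2], 8)  # ~2^4 for a fourth-order scheme
})

test_that("divergent parameter regimes raise a named error", {
  bad <- hdm_params(beta = 80, kappa = 0.01, gamma = 0.01)
  expect_error(
    hdm_integrate(bad, events = event_sequence(0), dt_s = 0.375,
                  duration_s = 200, impulse_duration_s = 100),
    "diverged"
  )
})

test_that("scan downsampling is exact interpolation", {
  expect_equal(downsample_to_scans(rep(3, 50), 0.5, 2, 10), rep(3, 10))
  tgrid <- seq(0, 24, by = 0.5)
  expect_equal(downsample_to_scans(tgrid, tgrid, 2, 5), c(0, 2, 4, 6, 8))
  set.seed(3)
  y <- rnorm(49)
  tm <- seq(0, 24, by = 0.5)
  got <- downsample_to_scans(y, tm, 1.97, 12, offset_s = 0.3)
  want <- approx(tm, y, xout = 0.3 + (0:11) * 1.97)$y
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(downsample_to_scans(y, tm, 3, 12), "outside")
})

test_that("small-efficacy responses superpose linearly via the first kernel", {
  ps <- hdm_params(beta = 0.01)
  ev <- make_events(6, seed = 21)
  dur <- max(ev$onset) + 34
  sim <- hdm_integrate(ps, events = ev, dt_s = 0.375, duration_s = dur)
  lags <- seq(0, 32, by = 0.375)
  k1 <- volterra_kernel1(ps, lags, dt_s = 0.375)
  conv <- numeric(length(sim$time))
  for (on in ev$onset) {
    i0 <- floor(on / 0.375)
    idx <- i0 + seq_along(lags)
    keep <- idx <= length(conv)
    conv[idx[keep]] <- conv[idx[keep]] + k1[keep]
  }
  expect_lt(sqrt(sum((sim$y - conv)^2) / sum(sim$y^2)), 0.05)
})

test_that("the second-order kernel is symmetric and vanishes in the linear limit", {
  lags <- seq(0, 20, by = 1.5)
  K2 <- volterra_kernel2(p_def, lags, dt_s = 0.375)
  expect_equal(K2, t(K2))
  k1 <- volterra_kernel1(p_def, lags, dt_s = 0.375)
  ps <- hdm_params(beta = p_def$beta * 0.01)
  K2s <- volterra_kernel2(ps, lags, dt_s = 0.375)
  k1s <- volterra_kernel1(ps, lags, dt_s = 0.375)
  expect_lt(max(abs(K2s)) / max(abs(k1s)), 0.05)
  # a close pair saturates relative to isolated responses
  pk_pair <- max(hdm_integrate(p_def, events = event_sequence(c(0, 2)),
                               dt_s = 0.375, duration_s = 40)$y)
  pk_one <- max(hdm_integrate(p_def, events = event_sequence(0),
                              dt_s = 0.375, duration_s = 40)$y)
  expect_lt(pk_pair, 2 * pk_one)
})

test_that("second-order variance fraction reflects design density", {
  ev1 <- event_sequence(0)
  expect_equal(second_order_variance_fraction(ev1, p_def), 0)
  dense <- event_sequence(seq(0, 60, by = 2))
  sparse <- event_sequence(seq(0, 600, by = 20))
  fd <- second_order_variance_fraction(dense, p_def)
  fs <- second_order_variance_fraction(sparse, p_def)
  expect_gt(fd, fs)
  expect_gte(fs, 0)
  expect_lte(fd, 1)
  ps <- hdm_params(beta = 0.004)
  expect_lt(second_order_variance_fraction(dense, ps), 1e-4)
})
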