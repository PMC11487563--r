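# Synthetic cohort generation: ages, parameters, ROI data, determinism.

test_that("ages are uniform over the requested range", {
  spec <- cohort_spec(n_participants = 636, seed = 101)
  ages <- sample_ages(spec)
  expect_length(ages, 636)
  expect_true(all(ages >= 18 & ages <= 88))
  expect_length(sample_ages(cohort_spec(n_participants = 0)), 0)
  big <- sample_ages(cohort_spec(n_participants = 10000, seed = 102))
  ks <- suppressWarnings(stats::ks.test(big, "punif", 18, 88))
  expect_gt(ks$p.value, 0.01)
  expect_error(cohort_spec(age_range = c(60, 30)), "range")
})

test_that("parameter sampling honours the age models", {
  spec0 <- cohort_spec(param_age_models = list(
    beta = list(intercept = 0.4, slope = 0, sd = 0, scale = "linear"),
    kappa = list(intercept = 0, slope = 0, sd = 0, scale = "log"),
    transit = list(intercept = 0, slope = 0, sd = 0, scale = "log")
  ))
  p <- sample_parameters(30, spec0)
  expect_equal(p$kappa, 0.64)
  expect_equal(p$transit_rate, 1.02)
  expect_equal(p$beta, 0.4)
  # midpoint age with zero SD gives exactly the intercept-scaled prior
  spec1 <- cohort_spec(param_age_models = list(
    beta = list(intercept = 0.4, slope = 0.3, sd = 0, scale = "linear"),
    kappa = list(intercept = 0.1, slope = 0.3, sd = 0, scale = "log"),
    transit = list(intercept = -0.2, slope = 0.3, sd = 0, scale = "log")
  ))
  pm <- sample_parameters(53, spec1)
  expect_equal(pm$kappa, 0.64 * exp(0.1))
  expect_equal(pm$transit_rate, 1.02 * exp(-0.2))
  expect_error(sample_parameters(95, spec1), "range")
  # positive decay slope induces a positive rank correlation with age
  set.seed(103)
  spec2 <- cohort_spec()
  ages <- runif(200, 18, 88)
  kap <- sapply(ages, function(a) sample_parameters(a, spec2)$kappa)
  sp <- spearman_age(kap, ages)
  expect_gt(sp$rho, 0)
  expect_lt(sp$p, 0.01)
})

test_that("ROI simulation reduces to the model prediction without noise", {
  spec <- cohort_spec()
  ev <- make_events(6, seed = 104)
  prof <- list(n_voxels = 5, shared_signal_fraction = 1, voxel_noise_sd = 0)
  nn <- list(ar1_coefficient = 0, innovation_sd = 0, drift_amplitude = 0,
             confound_leak_sd = 0)
  des <- list(tr_s = 1.97, n_scans = 130)
  p <- hdm_params()
  M <- simulate_roi_timeseries(p, ev, prof, nn, des)
  sim <- hdm_integrate(p, events = ev, dt_s = 0.375,
                       duration_s = 129 * 1.97 + 0.75)
  want <- downsample_to_scans(sim$y, sim$time, 1.97, 130) + 100
  expect_equal(M[, 1], want, tolerance = 1e-10)
  # all columns identical in the noise-free shared-signal case
  expect_true(all(M == M[, 1]))
  expect_error(simulate_roi_timeseries(p, ev, prof, nn,
                                       list(tr_s = -1, n_scans = 10)),
               "positive")
})

test_that("voxel noise follows the configured AR(1) process", {
  set.seed(105)
  prof <- list(n_voxels = 1, shared_signal_fraction = 0, voxel_noise_sd = 1)
  nn <- list(ar1_coefficient = 0.4, innovation_sd = 0, drift_amplitude = 0,
             confound_leak_sd = 0)
  des <- list(tr_s = 1, n_scans = 10000)
  M <- simulate_roi_timeseries(hdm_params(), event_sequence(numeric(0)),
                               prof, nn, des)
  e <- M[, 1] - mean(M[, 1])
  lag1 <- sum(e[-1] * e[-length(e)]) / sum(e^2)
  expect_lt(abs(lag1 - 0.4), 0.05)
})

test_that("cohort generation is deterministic and complete", {
  spec <- cohort_spec(n_participants = 5, seed = 106)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  expect_length(a$participants, 5)
  for (p in a$participants) {
    expect_s3_class(p$events, "event_sequence")
    expect_length(p$voxel_data, 4)
    expect_equal(dim(p$confounds), c(261, 8))
    expect_equal(nrow(p$voxel_data$lAC), 261)
    expect_equal(ncol(p$voxel_data$lAC), 16)
  }
  # different seeds differ
  c2 <- generate_cohort(cohort_spec(n_participants = 5, seed = 107))
  expect_false(identical(a$ages, c2$ages))
})

test_that("a noiseless cohort is recovered by model inversion", {
  spec <- cohort_spec(
    n_participants = 10, seed = 108,
    roi_profiles = list(roi = list(n_voxels = 1, shared_signal_fraction = 1,
                                   voxel_noise_sd = 0)),
    noise = list(ar1_coefficient = 0, innovation_sd = 0, drift_amplitude = 0,
                 confound_leak_sd = 0)
  )
  ch <- generate_cohort(spec)
  rel_err <- sapply(ch$participants, function(p) {
    y <- p$voxel_data$roi[, 1] - 100
    fit <- vl_fit(y, p$events, 1.97, 261, nuisance = matrix(1, 261, 1))
    tp <- p$true_params$roi
    est <- c(fit$mean[["beta"]],
             hdm_params()$kappa * exp(fit$mean[["kappa"]]),
             hdm_params()$transit_rate * exp(fit$mean[["transit"]]))
    max(abs(est - c(tp$beta, tp$kappa, tp$transit_rate)) /
          abs(c(tp$beta, tp$kappa, tp$transit_rate)))
  })
  expect_gte(mean(rel_err < 0.05), 0.95)
})

test_that("cohort tables round-trip through disk", {
  spec <- cohort_spec(
    n_participants = 2, seed = 109,
    roi_profiles = list(lAC = list(n_voxels = 3, shared_signal_fraction = 0.7,
                                   voxel_noise_sd = 1)),
    design = list(tr_s = 1.97, n_scans = 40, base_soa_s = 2,
                  jitter_low_s = 0.1, jitter_high_s = 0.3,
                  msequence_degree = 5)
  )
  ch <- generate_cohort(spec)
  dir <- withr::local_tempdir()
  write_cohort(ch, dir)
  ev <- read_events(file.path(dir, "sub-001_events.tsv"))
  expect_equal(ev$onset, ch$participants[[1]]$events$onset, tolerance = 1e-8)
  ts <- read.delim(file.path(dir, "sub-001_lAC_timeseries.tsv"))
  expect_equal(as.matrix(ts), ch$participants[[1]]$voxel_data$lAC,
               tolerance = 1e-8, ignore_attr = TRUE)
  truth <- readLines(file.path(dir, "sub-001_truth.txt"))
  expect_true(any(grepl("^age:", truth)))
})
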