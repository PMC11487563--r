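# Synthetic cohorts with known age-dependent neurovascular parameters:
# the ground-truth test surface for every downstream stage.

#' Specify a synthetic cohort
#'
#' Defines the study conditions the generator emulates: ages uniform over the
#' adult lifespan; an m-sequence event design with 2 s base SOA and uniform
#' 0.1-0.3 s jitter; per-participant hemodynamic parameters whose decay rate
#' rises and transit rate falls with age (on the log scale, matching the
#' estimation-scale parameterisation) while neural efficacy is age-invariant
#' by default; multi-voxel regions sharing a model-generated BOLD signal; and
#' AR(1) scanner noise, slow drift and confound leakage, at levels giving
#' single-participant fit R-squared in roughly 0.2-0.6.
#'
#' @param n_participants Number of participants (>= 0).
#' @param age_range Age bounds in years (default 18-88).
#' @param param_age_models Per free parameter, a list with `intercept`,
#'   `slope` (per z-scored age; log scale for the rates, linear for
#'   efficacy), `sd` (between-subject) and `scale` (`"log"` or `"linear"`).
#' @param roi_profiles Per region, `n_voxels`, `shared_signal_fraction` in
#'   `[0, 1]`, and `voxel_noise_sd` (AR(1) innovation SD, signal units).
#' @param noise Global noise settings: `ar1_coefficient` in (-1, 1),
#'   `innovation_sd` (confound series scale), `drift_amplitude`,
#'   `confound_leak_sd`.
#' @param design Scan/design timing: `tr_s`, `n_scans`, `base_soa_s`,
#'   `jitter_low_s`, `jitter_high_s`, `msequence_degree`.
#' @param seed Integer seed controlling the whole cohort.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_participants = 20,
                        age_range = c(18, 88),
                        param_age_models = list(
                          beta = list(intercept = 0.8, slope = 0, sd = 0.12,
                                      scale = "linear"),
                          kappa = list(intercept = 0, slope = 0.15, sd = 0.08,
                                       scale = "log"),
                          transit = list(intercept = 0, slope = -0.10,
                                         sd = 0.06, scale = "log")
                        ),
                        roi_profiles = list(
                          lAC = list(n_voxels = 16, shared_signal_fraction = 0.7,
                                     voxel_noise_sd = 1.5),
                          bVC = list(n_voxels = 12, shared_signal_fraction = 0.7,
                                     voxel_noise_sd = 1.5),
                          lMC = list(n_voxels = 10, shared_signal_fraction = 0.6,
                                     voxel_noise_sd = 1.6),
                          rMC = list(n_voxels = 8, shared_signal_fraction = 0.5,
                                     voxel_noise_sd = 1.7)
                        ),
                        noise = list(ar1_coefficient = 0.2,
                                     innovation_sd = 0.25,
                                     drift_amplitude = 0.3,
                                     confound_leak_sd = 0.03),
                        design = list(tr_s = 1.97, n_scans = 261,
                                      base_soa_s = 2, jitter_low_s = 0.1,
                                      jitter_high_s = 0.3,
                                      msequence_degree = 8),
                        seed = 1L) {
  if (n_participants < 0) stop("n_participants must be >= 0")
  if (age_range[1] > age_range[2]) {
    stop("invalid age range: low exceeds high")
  }
  for (nm in names(param_age_models)) {
    if (param_age_models[[nm]]$sd < 0) stop("parameter SDs must be >= 0")
  }
  for (nm in names(roi_profiles)) {
    rp <- roi_profiles[[nm]]
    if (rp$shared_signal_fraction < 0 || rp$shared_signal_fraction > 1) {
      stop("shared_signal_fraction must lie in [0, 1]")
    }
    if (rp$voxel_noise_sd < 0) stop("voxel_noise_sd must be >= 0")
  }
  if (abs(noise$ar1_coefficient) >= 1) stop("|ar1_coefficient| must be < 1")
  if (design$tr_s <= 0 || design$n_scans <= 0) {
    stop("tr_s and n_scans must be positive")
  }
  structure(list(n_participants = n_participants, age_range = age_range,
                 param_age_models = param_age_models,
                 roi_profiles = roi_profiles, noise = noise, design = design,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# z-score of age against the uniform population implied by the spec range
.z_age <- function(age, spec) {
  mu <- mean(spec$age_range)
  sdev <- diff(spec$age_range) / sqrt(12)
  if (sdev == 0) return(age * 0)
  (age - mu) / sdev
}

#' Sample participant ages
#'
#' Uniform over the spec's age range; reproducible from the spec seed.
#'
#' @param spec A [cohort_spec()].
#' @return Numeric vector of `n_participants` ages.
#' @export
sample_ages <- function(spec) {
  set.seed(spec$seed)
  .sample_ages(spec)
}

.sample_ages <- function(spec) {
  if (spec$n_participants == 0) return(numeric(0))
  runif(spec$n_participants, spec$age_range[1], spec$age_range[2])
}

#' Sample hemodynamic parameters for one participant
#'
#' Rate parameters follow `prior_default * exp(intercept + slope * z(age) +
#' noise)`; efficacy is linear: `intercept + slope * z(age) + noise`.
#' Draws from the current R random stream.
#'
#' @param age Age in years (within the spec range).
#' @param spec A [cohort_spec()].
#' @return An [hdm_params()] object.
#' @export
sample_parameters <- function(age, spec) {
  if (age < spec$age_range[1] || age > spec$age_range[2]) {
    stop("age outside the cohort range")
  }
  z <- .z_age(age, spec)
  base <- hdm_params()
  draw <- function(m) m$intercept + m$slope * z + rnorm(1, 0, m$sd)
  pm <- spec$param_age_models
  hdm_params(
    beta = draw(pm$beta),
    kappa = base$kappa * exp(draw(pm$kappa)),
    transit_rate = base$transit_rate * exp(draw(pm$transit))
  )
}

#' Simulate a multi-voxel ROI timeseries
#'
#' Every voxel shares the hemodynamic-model-generated BOLD signal (scaled by
#' the ROI's shared-signal fraction) plus voxel-specific AR(1) noise, slow
#' cosine drift, and small leakage of the participant's confound regressors;
#' the matrix is then placed on a grand mean of 100.
#'
#' @param params True [hdm_params()] for this ROI.
#' @param events An [event_sequence()].
#' @param roi_profile One entry of a spec's `roi_profiles`.
#' @param noise The spec's `noise` list.
#' @param design The spec's `design` list.
#' @param confounds Optional `n_scans x 8` confound matrix that leaks into
#'   the voxel data.
#' @param dt_s Integration step for the shared signal.
#' @return `n_scans x n_voxels` matrix.
#' @export
simulate_roi_timeseries <- function(params, events, roi_profile, noise,
                                    design, confounds = NULL, dt_s = 0.375) {
  if (design$tr_s <= 0 || design$n_scans <= 0) {
    stop("tr_s and n_scans must be positive")
  }
  n <- design$n_scans
  dur <- (n - 1) * design$tr_s + 2 * dt_s
  if (nrow(events) && max(events$onset) > dur) {
    stop("events extend beyond the scan window")
  }
  sim <- hdm_integrate(params, events = events, dt_s = dt_s,
                       duration_s = dur)
  signal <- downsample_to_scans(sim$y, sim$time, design$tr_s, n)
  nv <- roi_profile$n_voxels
  M <- matrix(roi_profile$shared_signal_fraction * signal, n, nv)
  t01 <- (seq_len(n) - 1) / (n - 1)
  for (v in seq_len(nv)) {
    if (roi_profile$voxel_noise_sd > 0) {
      innov <- rnorm(n, 0, roi_profile$voxel_noise_sd)
      M[, v] <- M[, v] +
        as.numeric(filter(innov, noise$ar1_coefficient, method = "recursive"))
    }
    if (noise$drift_amplitude > 0) {
      M[, v] <- M[, v] +
        noise$drift_amplitude * (rnorm(1) * t01 +
                                   rnorm(1) * cos(pi * t01) +
                                   rnorm(1) * cos(2 * pi * t01)) / sqrt(3)
    }
    if (!is.null(confounds) && noise$confound_leak_sd > 0) {
      leak <- rnorm(ncol(confounds), 0, noise$confound_leak_sd)
      M[, v] <- M[, v] + as.numeric(scale(confounds) %*% leak)
    }
  }
  M + 100
}

.simulate_confounds <- function(n, sd) {
  motion <- sapply(seq_len(6), function(i) cumsum(rnorm(n, 0, sd / sqrt(n))))
  compartment <- sapply(seq_len(2), function(i) {
    as.numeric(filter(rnorm(n, 0, sd), 0.9, method = "recursive"))
  })
  cbind(motion, compartment)
}

#' Generate a synthetic cohort
#'
#' Draws ages, per-participant/per-ROI true hemodynamic parameters, jittered
#' m-sequence event timings, confounds and multi-voxel ROI data, all from a
#' single seeded stream so repeat calls with the same spec are identical.
#'
#' @param spec A [cohort_spec()].
#' @return A `cohort_dataset`: the spec plus a list of participants, each
#'   with `age`, `events`, `true_params` (per ROI), `voxel_data` (per ROI),
#'   `confounds` and `seed` provenance.
#' @export
generate_cohort <- function(spec) {
  set.seed(spec$seed)
  ages <- .sample_ages(spec)
  mseq <- generate_msequence(spec$design$msequence_degree)
  participants <- vector("list", spec$n_participants)
  for (i in seq_len(spec$n_participants)) {
    ev <- build_event_timing(mseq, spec$design$base_soa_s,
                             spec$design$jitter_low_s,
                             spec$design$jitter_high_s)
    n_catch <- if (nrow(ev) >= 8) 4L else 0L
    ev <- assign_trial_types(ev, c(audiovisual = NA, visual_only = n_catch,
                                   auditory_only = n_catch))
    confounds <- .simulate_confounds(spec$design$n_scans,
                                     spec$noise$innovation_sd)
    true_params <- lapply(spec$roi_profiles, function(rp) {
      sample_parameters(ages[i], spec)
    })
    voxel_data <- lapply(names(spec$roi_profiles), function(nm) {
      simulate_roi_timeseries(true_params[[nm]], ev, spec$roi_profiles[[nm]],
                              spec$noise, spec$design, confounds)
    })
    names(voxel_data) <- names(spec$roi_profiles)
    participants[[i]] <- list(
      id = i, age = ages[i], events = ev, true_params = true_params,
      voxel_data = voxel_data, confounds = confounds,
      seed = spec$seed
    )
  }
  structure(list(spec = spec, ages = ages, participants = participants),
            class = "cohort_dataset")
}

#' Write a cohort's tables to disk
#'
#' Per participant: a BIDS-style events table, one tab-separated timeseries
#' table per ROI (one column per voxel), and a structured-text truth record
#' (age, true parameters, seed).
#'
#' @param cohort A `cohort_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in cohort$participants) {
    tag <- sprintf("sub-%03d", p$id)
    write_events(p$events, file.path(dir, paste0(tag, "_events.tsv")))
    for (nm in names(p$voxel_data)) {
      write.table(p$voxel_data[[nm]],
                  file.path(dir, paste0(tag, "_", nm, "_timeseries.tsv")),
                  sep = "\t", row.names = FALSE, col.names = TRUE,
                  quote = FALSE)
    }
    truth <- c(
      paste("id:", p$id),
      paste("age:", format(p$age, digits = 15)),
      paste("seed:", p$seed),
      unlist(lapply(names(p$true_params), function(nm) {
        tp <- p$true_params[[nm]]
        sprintf("%s.%s: %s", nm, c("beta", "kappa", "transit_rate"),
                format(c(tp$beta, tp$kappa, tp$transit_rate), digits = 15))
      }))
    )
    writeLines(truth, file.path(dir, paste0(tag, "_truth.txt")))
  }
  invisible(dir)
}
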