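# Orchestration: event-table I/O, run configuration, and the end-to-end
# pipeline from a synthetic cohort to model fits, features, group effects
# and cross-validated age prediction.

#' Read / write BIDS-style event tables
#'
#' Tab-separated with header columns `onset`, `duration`, `trial_type`
#' (and optionally `jitter`); onsets in seconds, strictly increasing.
#'
#' @param path File path.
#' @return [read_events()] returns an [event_sequence()].
#' @export
read_events <- function(path) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("event file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!is.numeric(tab$onset)) {
    bad <- which(is.na(suppressWarnings(as.numeric(tab$onset))))[1]
    stop("non-numeric onset in ", path, " at data row ", bad)
  }
  ev <- event_sequence(
    onset = tab$onset, duration = tab$duration, trial_type = tab$trial_type,
    jitter = if ("jitter" %in% names(tab)) tab$jitter else NA_real_
  )
  ev
}

#' @rdname read_events
#' @param events An [event_sequence()].
#' @export
write_events <- function(events, path) {
  .validate_events(events)
  write.table(as.data.frame(events), path, sep = "\t", row.names = FALSE,
              col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Run duration arithmetic
#'
#' Total acquisition time of `n_scans` volumes, and its whole-minute
#' decomposition (seconds truncated).
#'
#' @param n_scans Number of volumes.
#' @param tr_s Repetition time (s).
#' @return List with `seconds`, `minutes`, `rem_seconds`.
#' @export
run_duration <- function(n_scans, tr_s) {
  total <- n_scans * tr_s
  list(seconds = total, minutes = floor(total / 60),
       rem_seconds = floor(total) %% 60)
}

#' Configure a pipeline run
#'
#' @param spec A [cohort_spec()] describing the synthetic cohort (its seed
#'   governs all randomness).
#' @param models Models to fit: subset of `FIR32`, `Can3`, `NLF4`, `HDM3`.
#' @param alpha_voxel Uncorrected threshold for within-participant voxel
#'   selection.
#' @param fir_bins,fir_bin_width_s FIR basis size (defaults 32 x 1 s).
#' @param bins_per_tr Microtime bins per TR.
#' @param highpass_s High-pass cutoff in seconds.
#' @param hdm_dt_s Hemodynamic model integration step.
#' @param out_dir Optional directory: results tables are written there.
#' @return A `run_config` list.
#' @export
run_config <- function(spec = cohort_spec(),
                       models = c("FIR32", "Can3", "NLF4", "HDM3"),
                       alpha_voxel = 0.05, fir_bins = 32,
                       fir_bin_width_s = 1, bins_per_tr = 32,
                       highpass_s = 128, hdm_dt_s = 0.375, out_dir = NULL) {
  known <- c("FIR32", "Can3", "NLF4", "HDM3")
  bad <- setdiff(models, known)
  if (length(bad)) {
    stop("unknown model(s): ", paste(bad, collapse = ", "),
         " (choose from ", paste(known, collapse = ", "), ")")
  }
  if (!length(models)) stop("model list must be non-empty")
  structure(list(spec = spec, models = models, alpha_voxel = alpha_voxel,
                 fir_bins = fir_bins, fir_bin_width_s = fir_bin_width_s,
                 bins_per_tr = bins_per_tr, highpass_s = highpass_s,
                 hdm_dt_s = hdm_dt_s, out_dir = out_dir),
            class = "run_config")
}

# Whiten+filter one participant-ROI, select voxels, extract the eigenvariate
# and refit the FIR model on it. Returns NULL when no voxel survives.
.first_level_roi <- function(Y, events, confounds, cfg) {
  d <- cfg$spec$design
  fir <- fir_basis(cfg$fir_bins, cfg$fir_bin_width_s, d$tr_s / cfg$bins_per_tr)
  X <- build_design_matrix(events, fir, d$tr_s, d$n_scans, cfg$bins_per_tr)
  Z <- cbind(confounds, dct_highpass_set(d$n_scans, d$tr_s, cfg$highpass_s))
  noise <- reml_ar1(Y, cbind(X, Z))
  fit <- fit_glm(Y, X, Z, noise)
  sel <- participant_voxel_selection(fit, cfg$alpha_voxel)
  if (attr(sel, "excluded")) return(NULL)
  # adjusted voxel data: whitened, filtered, confounds removed
  WY <- noise$W %*% (fit$scale * Y[, sel, drop = FALSE])
  WZ <- noise$W %*% Z
  E <- WY - WZ %*% qr.coef(qr(WZ), WY)
  eig <- roi_eigenvariate(E)
  WX <- noise$W %*% X
  WXr <- WX - WZ %*% qr.coef(qr(WZ), WX)
  efit <- fit_glm(eig$eigenvariate, WXr, confounds = matrix(1, d$n_scans, 1),
                  noise = NULL, grand_mean = NULL)
  list(eigenvariate = eig$eigenvariate, eig = eig, noise = noise,
       fir_beta = as.numeric(efit$beta), X_white = WXr, n_selected = length(sel),
       fir_names = colnames(X))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Simulates the cohort, runs prewhitened first-level FIR GLMs per voxel,
#' selects responsive voxels, summarises each region by its SVD
#' eigenvariate, fits the requested HRF models (FIR32, Can3, NLF4, HDM3),
#' extracts peak features, estimates group-level age effects (second-level
#' FIR model; PEB with Bayesian model reduction for the hemodynamic
#' parameters) and performs leave-one-out age prediction per model.
#' Deterministic given the spec seed.
#'
#' @param config A [run_config()].
#' @return A `results_bundle` list of tables (`fits`, `features`,
#'   `group_fir`, `peb`, `predictions`, `comparison`) plus a run `log`.
#'   Tables are written to `config$out_dir` when set.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop("config must be a run_config")
  cfg <- config
  d <- cfg$spec$design
  cohort <- generate_cohort(cfg$spec)
  rois <- names(cfg$spec$roi_profiles)
  n <- cfg$spec$n_participants
  step_fir <- cfg$fir_bin_width_s

  first <- list()
  excluded <- integer(0)
  for (i in seq_len(n)) {
    p <- cohort$participants[[i]]
    rs <- lapply(rois, function(nm) {
      .first_level_roi(p$voxel_data[[nm]], p$events, p$confounds, cfg)
    })
    names(rs) <- rois
    if (any(vapply(rs, is.null, logical(1)))) {
      excluded <- c(excluded, i)
    }
    first[[i]] <- rs
  }
  keep <- setdiff(seq_len(n), excluded)
  if (length(keep) < 2) stop("fewer than 2 participants survived voxel selection")
  ages <- cohort$ages[keep]

  micro_step <- d$tr_s / cfg$bins_per_tr
  can_basis <- informed_basis(step_s = micro_step)
  fits <- list(); feats <- list(); hdm_posts <- list()
  fir_mats <- lapply(rois, function(nm) {
    t(vapply(keep, function(i) first[[i]][[nm]]$fir_beta,
             numeric(cfg$fir_bins)))
  })
  names(fir_mats) <- rois
  templates <- if ("NLF4" %in% cfg$models) {
    lapply(fir_mats, make_template, step_s = step_fir)
  }

  add_row <- function(lst, ...) c(lst, list(data.frame(..., stringsAsFactors = FALSE)))

  for (ki in seq_along(keep)) {
    i <- keep[ki]
    p <- cohort$participants[[i]]
    for (nm in rois) {
      fl <- first[[i]][[nm]]
      y <- fl$eigenvariate
      if ("FIR32" %in% cfg$models) {
        pk <- peak_features(fl$fir_beta, step_fir)
        for (b in seq_len(cfg$fir_bins)) {
          fits <- add_row(fits, participant = i, roi = nm, model = "FIR32",
                          parameter = fl$fir_names[b], value = fl$fir_beta[b])
        }
        feats <- add_row(feats, participant = i, roi = nm, model = "FIR32",
                         amplitude = pk$amplitude, latency = pk$latency,
                         rmse_pst = 0)
      }
      if ("Can3" %in% cfg$models) {
        Xc <- build_design_matrix(p$events, can_basis, d$tr_s, d$n_scans,
                                  cfg$bins_per_tr)
        WXc <- fl$noise$W %*% Xc
        Z <- cbind(p$confounds, dct_highpass_set(d$n_scans, d$tr_s,
                                                 cfg$highpass_s))
        WZ <- fl$noise$W %*% Z
        WXcr <- WXc - WZ %*% qr.coef(qr(WZ), WXc)
        cfit <- fit_glm(y, WXcr, confounds = matrix(1, d$n_scans, 1),
                        noise = NULL, grand_mean = NULL)
        w <- as.numeric(cfit$beta)
        curve <- as.numeric(can_basis$curves %*% w)
        pk <- peak_features(curve, micro_step)
        tcurve <- (seq_along(curve) - 1) * micro_step
        bin_of <- pmin(floor(tcurve / step_fir) + 1, cfg$fir_bins)
        curve_bins <- tapply(curve, bin_of, mean)
        for (b in seq_len(3)) {
          fits <- add_row(fits, participant = i, roi = nm, model = "Can3",
                          parameter = can_basis$names[b], value = w[b])
        }
        feats <- add_row(feats, participant = i, roi = nm, model = "Can3",
                         amplitude = pk$amplitude, latency = pk$latency,
                         rmse_pst = rmse(fl$fir_beta, as.numeric(curve_bins)))
      }
      if ("NLF4" %in% cfg$models) {
        nf <- fit_nlf(templates[[nm]], fl$fir_beta)
        for (pb in c("a0", "a1", "t0", "t1")) {
          fits <- add_row(fits, participant = i, roi = nm, model = "NLF4",
                          parameter = pb, value = nf[[pb]])
        }
        feats <- add_row(feats, participant = i, roi = nm, model = "NLF4",
                         amplitude = nf$a1, latency = abs(nf$t1),
                         rmse_pst = rmse(fl$fir_beta, nf$fitted))
      }
      if ("HDM3" %in% cfg$models) {
        post <- vl_fit(y, p$events, d$tr_s, d$n_scans,
                       nuisance = matrix(1, d$n_scans, 1),
                       dt_s = cfg$hdm_dt_s)
        hdm_posts[[nm]] <- c(hdm_posts[[nm]], list(post))
        rates <- posterior_rates_hz(post)
        vals <- c(beta = unname(post$mean[["beta"]]),
                  decay_hz = unname(rates[["decay"]]),
                  transit_hz = unname(rates[["transit"]]))
        for (pb in names(vals)) {
          fits <- add_row(fits, participant = i, roi = nm, model = "HDM3",
                          parameter = pb, value = vals[[pb]])
        }
        hk <- volterra_kernel1(theta_to_params(post$mean),
                               seq(0, 16, by = step_fir), dt_s = cfg$hdm_dt_s)
        pk <- tryCatch(peak_features(hk, step_fir),
                       error = function(e) list(amplitude = 0, latency = NA))
        feats <- add_row(feats, participant = i, roi = nm, model = "HDM3",
                         amplitude = pk$amplitude, latency = pk$latency,
                         rmse_pst = rmse(y, post$fitted))
      }
    }
  }
  fits <- do.call(rbind, fits)
  feats <- do.call(rbind, feats)

  group_fir <- if ("FIR32" %in% cfg$models && length(keep) >= 4) {
    lapply(fir_mats, second_level_age_glm, ages = ages)
  }
  peb_tabs <- NULL
  if ("HDM3" %in% cfg$models && length(keep) >= 2) {
    peb_tabs <- lapply(rois, function(nm) {
      pr <- peb_fit(hdm_posts[[nm]], ages = ages)
      bm <- bmr_search(pr)
      cbind(roi = nm, bm$table)
    })
    peb_tabs <- do.call(rbind, peb_tabs)
  }

  predictions <- list(); comparison <- NULL
  err_by_model <- list()
  for (m in cfg$models) {
    fm <- fits[fits$model == m, ]
    cols <- unique(paste(fm$roi, fm$parameter))
    wide <- matrix(NA_real_, length(keep), length(cols),
                   dimnames = list(keep, cols))
    wide[cbind(match(fm$participant, keep),
               match(paste(fm$roi, fm$parameter), cols))] <- fm$value
    if (length(keep) <= ncol(wide) + 1) {
      warning("skipping LOO age prediction for ", m,
              ": more features than participants allow")
      next
    }
    if (length(keep) < 3 * ncol(wide)) {
      warning("LOO age prediction for ", m, " with n < 3x features")
    }
    loo <- loo_age_prediction(wide, ages)
    err_by_model[[m]] <- loo$abs_errors
    predictions <- add_row(predictions, participant = keep, model = m,
                           age = ages, predicted = loo$predictions,
                           abs_error = loo$abs_errors)
  }
  predictions <- if (length(predictions)) do.call(rbind, predictions)
  if (length(err_by_model) >= 2) {
    ms <- names(err_by_model)
    comparison <- do.call(rbind, lapply(seq_along(ms)[-1], function(j) {
      st <- sign_test(err_by_model[[ms[j]]], err_by_model[[ms[1]]])
      data.frame(model_a = ms[j], model_b = ms[1], p_sign = st$p,
                 median_a = median(err_by_model[[ms[j]]]),
                 median_b = median(err_by_model[[ms[1]]]),
                 stringsAsFactors = FALSE)
    }))
  }

  bundle <- structure(list(
    fits = fits, features = feats, group_fir = group_fir, peb = peb_tabs,
    predictions = predictions, comparison = comparison,
    excluded = excluded,
    log = list(seed = cfg$spec$seed, models = cfg$models,
               n_participants = n, n_kept = length(keep),
               package_version = as.character(utils::packageVersion("boldhrf")),
               timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  ), class = "results_bundle")
  if (!is.null(cfg$out_dir)) write_results(bundle, cfg$out_dir)
  bundle
}

#' Write a results bundle to tab-separated tables
#'
#' @param bundle A `results_bundle` from [run_pipeline()].
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_results <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) {
    if (!is.null(x)) {
      write.table(x, file.path(dir, f), sep = "\t", row.names = FALSE,
                  quote = FALSE)
    }
  }
  wt(bundle$fits, "fits.tsv")
  wt(bundle$features, "features.tsv")
  wt(bundle$peb, "peb.tsv")
  wt(bundle$predictions, "predictions.tsv")
  wt(bundle$comparison, "comparison.tsv")
  log <- bundle$log
  writeLines(c(paste("seed:", log$seed),
               paste("models:", paste(log$models, collapse = ",")),
               paste("n_participants:", log$n_participants),
               paste("n_kept:", log$n_kept),
               paste("package_version:", log$package_version),
               paste("timestamp:", log$timestamp)),
             file.path(dir, "run_log.txt"))
  invisible(dir)
}
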