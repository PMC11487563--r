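# Bayesian inversion of the hemodynamic model for a single timeseries via
# Variational Laplace: Gauss-Newton ascent on a Laplace free-energy bound
# with Levenberg-Marquardt damping and an estimated noise log-precision.

.vl_free_names <- c("beta", "kappa", "transit", "gamma", "alpha", "eps_h")

#' Priors for hemodynamic model inversion
#'
#' Priors on the estimation scale: the efficacy `beta` is estimated on its
#' natural (linear) scale around 0; the rates `kappa`, `transit`, `gamma` and
#' the ratio `eps_h` as log deviations from the default parameters (so 0 maps
#' to 0.64 Hz decay and 1.02 Hz transit); `alpha` as a logit deviation. The
#' noise is a single log precision with a Gaussian hyperprior whose mean is
#' set from the data variance at fit time.
#'
#' @param mean,var Named numeric vectors overriding individual prior means /
#'   variances on the estimation scale.
#' @param hyper_var Variance of the noise log-precision hyperprior.
#' @return A `vl_priors` list.
#' @export
hdm_priors <- function(mean = NULL, var = NULL, hyper_var = 16) {
  m <- setNames(rep(0, length(.vl_free_names)), .vl_free_names)
  v <- c(beta = 1, kappa = 1 / 16, transit = 1 / 16, gamma = 1 / 16,
         alpha = 1 / 16, eps_h = 1 / 16)
  if (!is.null(mean)) m[names(mean)] <- mean
  if (!is.null(var)) {
    if (any(var < 0)) stop("prior variances must be >= 0")
    v[names(var)] <- var
  }
  structure(list(mean = m, var = v,
                 hyper = list(mean = NULL, var = hyper_var)),
            class = "vl_priors")
}

#' Map estimation-scale parameters to hemodynamic parameters
#'
#' @param theta Named vector on the estimation scale (subset of
#'   `beta, kappa, transit, gamma, alpha, eps_h`).
#' @param base An [hdm_params()] object supplying fixed values and the
#'   reference point of the log/logit deviations.
#' @return An [hdm_params()] object.
#' @export
theta_to_params <- function(theta, base = hdm_params()) {
  p <- base
  nm <- names(theta)
  if ("beta" %in% nm) p$beta <- unname(theta["beta"])
  if ("kappa" %in% nm) p$kappa <- base$kappa * exp(unname(theta["kappa"]))
  if ("transit" %in% nm) {
    p$transit_rate <- base$transit_rate * exp(unname(theta["transit"]))
  }
  if ("gamma" %in% nm) p$gamma <- base$gamma * exp(unname(theta["gamma"]))
  if ("alpha" %in% nm) {
    p$alpha <- plogis(qlogis(base$alpha) + unname(theta["alpha"]))
  }
  if ("eps_h" %in% nm) p$eps_h <- base$eps_h * exp(unname(theta["eps_h"]))
  p
}

#' Predicted scan-level BOLD timeseries for estimation-scale parameters
#'
#' Maps `theta` to hemodynamic parameters, integrates the model over the
#' scan window and samples at scan acquisition times.
#'
#' @inheritParams theta_to_params
#' @param events An [event_sequence()].
#' @param tr_s,n_scans Scan timing.
#' @param dt_s Integration step (default 0.375 s).
#' @param offset_s Scan sampling offset (middle-slice reference).
#' @return Numeric vector of length `n_scans`.
#' @export
hdm_predict <- function(theta, events, tr_s, n_scans, dt_s = 0.375,
                        offset_s = 0, base = hdm_params()) {
  p <- theta_to_params(theta, base)
  dur <- (n_scans - 1) * tr_s + offset_s + 2 * dt_s
  sim <- hdm_integrate(p, events = events, dt_s = dt_s, duration_s = dur)
  downsample_to_scans(sim$y, sim$time, tr_s, n_scans, offset_s)
}

# Laplace free energy for given theta (free part), lambda, and their
# curvatures; deterministic in (theta, lambda) so accepted steps are
# comparable across iterations.
.vl_free_energy <- function(e, J, lam, dtheta, P0, lam0, vlam) {
  n <- length(e)
  A <- exp(lam) * crossprod(J) + P0
  cA <- chol(A)
  logdet_A <- 2 * sum(log(diag(cA)))
  logdet_P0 <- sum(log(diag(as.matrix(P0))))
  slam <- 0.5 * exp(lam) * sum(e^2) + 1 / vlam  # lambda posterior precision
  -0.5 * exp(lam) * sum(e^2) + 0.5 * n * (lam - log(2 * pi)) -
    0.5 * sum(dtheta * (P0 %*% dtheta)) +
    0.5 * (logdet_P0 - logdet_A) -
    0.5 * (lam - lam0)^2 / vlam - 0.5 * log(vlam) - 0.5 * log(slam)
}

#' Invert the hemodynamic model from a BOLD timeseries
#'
#' Variational Laplace: a Gaussian posterior over the free hemodynamic
#' parameters (and any nuisance regression weights) is obtained by
#' Gauss-Newton ascent on the Laplace free energy, with Levenberg-Marquardt
#' damping and central finite-difference prediction gradients. The noise is
#' white with a single estimated log precision. Steps are accepted only when
#' they increase the free energy, so the free-energy trace is non-decreasing
#' by construction.
#'
#' @param y Observed timeseries (length `n_scans`); the model fits deviations
#'   of `y` around the nuisance space, so include a constant in `nuisance`
#'   unless `y` is already centred.
#' @param events An [event_sequence()].
#' @param tr_s,n_scans Scan timing.
#' @param priors A [hdm_priors()] object. Parameters with zero prior variance
#'   are held fixed at their prior mean.
#' @param mask Character vector of free parameters (default
#'   `c("beta", "kappa", "transit")`, the three-parameter model).
#' @param nuisance Optional `n_scans x q` matrix of flat-prior regressors
#'   (constant, cosine drift set, confounds).
#' @param dt_s,offset_s Integration step and scan sampling offset.
#' @param base Fixed-parameter values, see [hdm_params()].
#' @param max_iter Iteration cap (default 64).
#' @param tol Convergence: change in free energy below `tol` on 4 consecutive
#'   accepted iterations (default 0.01).
#' @return A `vl_posterior` list: `mean`/`cov` over the free hemodynamic
#'   parameters, `full_mean`/`full_cov` including nuisance weights, free
#'   energy `F` and `trace`, noise `lambda`, `fitted`, `residuals`,
#'   `converged`, plus the priors, mask and design metadata.
#' @export
vl_fit <- function(y, events, tr_s, n_scans, priors = hdm_priors(),
                   mask = c("beta", "kappa", "transit"), nuisance = NULL,
                   dt_s = 0.375, offset_s = 0, base = hdm_params(),
                   max_iter = 64, tol = 0.01) {
  y <- as.numeric(y)
  if (length(y) != n_scans) stop("length(y) must equal n_scans")
  if (any(!is.finite(y))) stop("y must be finite")
  mask <- match.arg(mask, .vl_free_names, several.ok = TRUE)
  q <- if (is.null(nuisance)) 0L else ncol(nuisance)
  if (q) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != n_scans) stop("nuisance rows must equal n_scans")
  }

  m0 <- c(priors$mean[mask], rep(0, q))
  v0 <- c(priors$var[mask], rep(1e4 * max(var(y), 1e-6), q))
  names(m0) <- names(v0) <- c(mask, if (q) paste0("nuis_", seq_len(q)))
  free <- which(v0 > 0)
  fixed <- which(v0 == 0)
  p_h <- length(mask)

  predict_full <- function(th) {
    g <- hdm_predict(th[seq_len(p_h)], events, tr_s, n_scans, dt_s, offset_s,
                     base)
    if (q) g <- g + nuisance %*% th[p_h + seq_len(q)]
    as.numeric(g)
  }
  jac <- function(th) {
    J <- matrix(0, n_scans, length(th))
    step <- 1e-4
    hdm_free <- intersect(free, seq_len(p_h))
    for (j in hdm_free) {
      tp <- tm <- th[seq_len(p_h)]
      tp[j] <- tp[j] + step
      tm[j] <- tm[j] - step
      J[, j] <- (hdm_predict(tp, events, tr_s, n_scans, dt_s, offset_s, base) -
                   hdm_predict(tm, events, tr_s, n_scans, dt_s, offset_s,
                               base)) / (2 * step)
    }
    if (q) J[, p_h + seq_len(q)] <- nuisance
    J
  }

  vy <- max(var(y), 1e-12)
  lam0 <- -log(vy)
  vlam <- priors$hyper$var
  lam <- lam0

  theta <- m0
  if (!length(free)) {
    e <- y - predict_full(theta)
    Fval <- -0.5 * exp(lam) * sum(e^2) + 0.5 * n_scans * (lam - log(2 * pi))
    return(structure(list(
      mean = theta[seq_len(p_h)], cov = diag(0, p_h),
      full_mean = theta, full_cov = diag(0, length(theta)),
      F = Fval, trace = Fval, lambda = lam, fitted = predict_full(theta),
      residuals = e, converged = TRUE, priors = priors, mask = mask,
      n = n_scans, base = base,
      meta = list(tr_s = tr_s, dt_s = dt_s, offset_s = offset_s)
    ), class = "vl_posterior"))
  }

  P0 <- diag(1 / v0[free], length(free))
  clamp <- function(l) max(min(l, 40), -40)

  eval_state <- function(th, lam) {
    g <- predict_full(th)
    e <- y - g
    J <- jac(th)[, free, drop = FALSE]
    Fv <- .vl_free_energy(e, J, lam, th[free] - m0[free], P0, lam0, vlam)
    list(theta = th, e = e, J = J, F = Fv, g = g, lam = lam)
  }

  update_lambda <- function(st) {
    lam <- st$lam
    ee <- sum(st$e^2)
    JJ <- crossprod(st$J)
    for (i in 1:8) {
      A <- exp(lam) * JJ + P0
      trS <- sum(diag(solve(A, JJ)))  # tr(Sigma_theta J'J)
      g1 <- -0.5 * exp(lam) * ee + 0.5 * length(st$e) -
        0.5 * exp(lam) * trS - (lam - lam0) / vlam
      h1 <- -0.5 * exp(lam) * ee - 0.5 * exp(lam) * trS - 1 / vlam
      step <- -g1 / h1
      step <- max(min(step, 4), -4)
      lam <- clamp(lam + step)
      if (abs(step) < 1e-4) break
    }
    lam
  }

  cur <- eval_state(theta, lam)
  trace <- cur$F
  nu <- 1e-4
  stall <- 0L
  converged <- FALSE

  for (it in seq_len(max_iter)) {
    # noise precision update (accept only if it helps)
    lam_new <- update_lambda(cur)
    if (abs(lam_new - cur$lam) > 1e-10) {
      cand <- cur
      cand$lam <- lam_new
      cand$F <- .vl_free_energy(cand$e, cand$J, lam_new,
                                cand$theta[free] - m0[free], P0, lam0, vlam)
      if (cand$F >= cur$F) cur <- cand
    }
    # Gauss-Newton parameter step with Levenberg-Marquardt damping
    A <- exp(cur$lam) * crossprod(cur$J) + P0
    grad <- exp(cur$lam) * crossprod(cur$J, cur$e) -
      P0 %*% (cur$theta[free] - m0[free])
    accepted <- FALSE
    for (tries in 1:8) {
      Ad <- A + nu * diag(diag(A), nrow(A))
      dstep <- tryCatch(solve(Ad, grad), error = function(e) NULL)
      if (!is.null(dstep)) {
        th_new <- cur$theta
        th_new[free] <- th_new[free] + as.numeric(dstep)
        new <- tryCatch(eval_state(th_new, cur$lam), error = function(e) NULL)
        if (!is.null(new) && is.finite(new$F) && new$F > cur$F) {
          cur <- new
          nu <- max(nu / 4, 1e-8)
          accepted <- TRUE
          break
        }
      }
      nu <- nu * 8
    }
    trace <- c(trace, cur$F)
    dF <- trace[length(trace)] - trace[length(trace) - 1]
    stall <- if (dF < tol) stall + 1L else 0L
    if (stall >= 4L || (!accepted && dF < tol)) {
      converged <- TRUE
      break
    }
  }

  A <- exp(cur$lam) * crossprod(cur$J) + P0
  Sfree <- solve(A)
  full_cov <- matrix(0, length(theta), length(theta))
  full_cov[free, free] <- Sfree
  dimnames(full_cov) <- list(names(m0), names(m0))
  idx <- seq_len(p_h)
  structure(list(
    mean = cur$theta[idx], cov = full_cov[idx, idx, drop = FALSE],
    full_mean = cur$theta, full_cov = full_cov,
    F = cur$F, trace = trace, lambda = cur$lam,
    fitted = cur$g, residuals = cur$e, converged = converged,
    priors = priors, mask = mask, n = n_scans, base = base,
    meta = list(tr_s = tr_s, dt_s = dt_s, offset_s = offset_s)
  ), class = "vl_posterior")
}

#' Posterior decay and transit rates in Hz
#'
#' Transforms posterior expected log deviations back to rates in Hz:
#' `rate = default_rate * exp(posterior mean)`.
#'
#' @param post A `vl_posterior`.
#' @return Named vector with entries `decay` and/or `transit` (Hz), for
#'   whichever rates were estimated.
#' @export
posterior_rates_hz <- function(post) {
  out <- c()
  if ("kappa" %in% names(post$mean)) {
    out <- c(out, decay = unname(post$base$kappa * exp(post$mean[["kappa"]])))
  }
  if ("transit" %in% names(post$mean)) {
    out <- c(out,
             transit = unname(post$base$transit_rate *
                                exp(post$mean[["transit"]])))
  }
  out
}
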