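# Biophysical hemodynamic model: parameters, ODE right-hand side, BOLD
# observation equations, RK4 integration (compiled), Volterra kernels and a
# second-order variance summary of haemodynamic nonlinearity.

#' Hemodynamic model parameters
#'
#' Parameters of the balloon-type hemodynamic model. Neural activity drives a
#' vasoactive signal with efficacy `beta`; the signal decays at rate `kappa`
#' (Hz) and receives autoregulatory feedback at rate `gamma` (Hz). Blood
#' transits the venous compartment at rate `transit_rate` = 1/tau_h (Hz), with
#' outflow `v^(1/alpha)` (Grubb's exponent `alpha`) and resting oxygen
#' extraction fraction `e0`. The BOLD observation model uses resting blood
#' volume fraction `v0`, field-dependent frequency offset `theta0` (Hz),
#' intravascular relaxation slope `r0` (Hz), intra/extra-vascular signal ratio
#' `eps_h`, and echo time `te` (s).
#'
#' Defaults are the conventional 3T values: decay 0.64 Hz and transit 1.02 Hz
#' are the prior rates the fitting routines treat as their reference point.
#'
#' @param beta Neural efficacy (dimensionless; may be negative).
#' @param kappa Vasoactive signal decay rate in Hz.
#' @param gamma Autoregulatory feedback rate in Hz.
#' @param transit_rate Blood transit rate 1/tau_h in Hz.
#' @param alpha Grubb's exponent, in (0, 1).
#' @param e0 Resting oxygen extraction fraction, in (0, 1).
#' @param v0 Resting venous blood volume fraction.
#' @param theta0 Frequency offset at the outer vessel surface, Hz.
#' @param r0 Intravascular relaxation slope, Hz.
#' @param eps_h Intra/extra-vascular signal ratio.
#' @param te Echo time in seconds.
#' @return A list of class `hdm_params`.
#' @export
hdm_params <- function(beta = 0.4, kappa = 0.64, gamma = 0.41,
                       transit_rate = 1.02, alpha = 0.32, e0 = 0.4,
                       v0 = 0.04, theta0 = 40.3, r0 = 25, eps_h = 1,
                       te = 0.03) {
  p <- list(beta = beta, kappa = kappa, gamma = gamma,
            transit_rate = transit_rate, alpha = alpha, e0 = e0, v0 = v0,
            theta0 = theta0, r0 = r0, eps_h = eps_h, te = te)
  if (p$transit_rate <= 0) stop("transit_rate must be positive")
  if (p$e0 <= 0 || p$e0 >= 1) stop("e0 must lie in (0, 1)")
  if (p$alpha <= 0 || p$alpha >= 1) stop("alpha must lie in (0, 1)")
  if (p$v0 <= 0) stop("v0 must be positive")
  if (p$te <= 0) stop("te must be positive")
  class(p) <- "hdm_params"
  p
}

.hdm_par_vector <- function(p) {
  c(p$beta, p$kappa, p$gamma, p$transit_rate, p$alpha, p$e0,
    p$v0, p$theta0, p$r0, p$eps_h, p$te)
}

#' Hemodynamic state derivatives
#'
#' Right-hand side of the hemodynamic ODE system on the natural scale, for a
#' state `(s, f_in, v, q)` and binary neural input `z`.
#'
#' @param state Named or positional numeric vector `(s, f_in, v, q)`.
#' @param z Neural input at this instant (0 or 1; any scalar accepted).
#' @param p An [hdm_params()] object.
#' @return Named vector of derivatives `(s, f_in, v, q)`.
#' @export
hdm_derivs <- function(state, z, p) {
  state <- as.numeric(state)
  if (any(!is.finite(state))) stop("non-finite hemodynamic state")
  s <- state[1]; f <- state[2]; v <- state[3]; q <- state[4]
  if (f <= 0 || v <= 0 || q <= 0) stop("f_in, v and q must stay positive")
  fout <- v^(1 / p$alpha)
  extraction <- (1 - (1 - p$e0)^(1 / f)) / p$e0
  c(s = p$beta * z - p$kappa * s - p$gamma * (f - 1),
    f_in = s,
    v = p$transit_rate * (f - fout),
    q = p$transit_rate * (f * extraction - fout * q / v))
}

#' BOLD signal from a hemodynamic state
#'
#' `y = 100 * v0 * (k1 (1-q) + k2 (1 - q/v) + k3 (1-v))` with
#' `k1 = 4.3 theta0 e0 te`, `k2 = eps_h r0 e0 te`, `k3 = 1 - eps_h`.
#'
#' @param state Numeric vector `(s, f_in, v, q)` (only `v`, `q` are used).
#' @inheritParams hdm_derivs
#' @return BOLD signal in percent.
#' @export
bold_from_state <- function(state, p) {
  k <- bold_coefficients(p)
  v <- state[[3]]; q <- state[[4]]
  100 * p$v0 * (k[["k1"]] * (1 - q) + k[["k2"]] * (1 - q / v) +
                  k[["k3"]] * (1 - v))
}

#' @rdname bold_from_state
#' @export
bold_coefficients <- function(p) {
  c(k1 = 4.3 * p$theta0 * p$e0 * p$te,
    k2 = p$eps_h * p$r0 * p$e0 * p$te,
    k3 = 1 - p$eps_h)
}

#' Neural input train from events
#'
#' Builds the boxcar neural input `z(t)` on the integration grid. Each event
#' contributes a boxcar of `impulse_duration_s` starting at its onset;
#' the default of one integration bin treats trials as brief bursts.
#'
#' @param events An [event_sequence()].
#' @param dt_s Integration step in seconds.
#' @param duration_s Total duration covered by the grid.
#' @param impulse_duration_s Neural burst duration per event (seconds).
#' @return Numeric vector `z` with one value per integration bin; bin `i`
#'   covers `[(i-1) dt, i dt)`.
#' @export
neural_input <- function(events, dt_s, duration_s, impulse_duration_s = dt_s) {
  n <- ceiling(duration_s / dt_s)
  z <- numeric(n)
  if (!nrow(events)) return(z)
  nb <- max(1L, round(impulse_duration_s / dt_s))
  for (on in events$onset) {
    # snap to the grid: every event drives the same number of whole bins
    i0 <- floor(on / dt_s) + 1L
    idx <- i0:(i0 + nb - 1L)
    idx <- idx[idx >= 1L & idx <= n]
    z[idx] <- 1
  }
  z
}

#' Integrate the hemodynamic model
#'
#' Fixed-step fourth-order Runge-Kutta integration starting from the resting
#' state `(0, 1, 1, 1)`. Flow, volume and deoxyhemoglobin are propagated in
#' log space so they remain positive. Divergent parameter regimes raise an
#' error naming the offending parameters.
#'
#' @inheritParams hdm_derivs
#' @param z Neural input per bin (e.g. from [neural_input()]); alternatively
#'   pass `events` plus `duration_s`.
#' @param events Optional [event_sequence()] used to build `z`.
#' @param dt_s Integration step in seconds (default 0.375).
#' @param duration_s Required when `events` is given.
#' @param impulse_duration_s Neural burst length per event, default one bin.
#' @return List with `time` (length `n+1`, starting at 0), `y` (percent BOLD)
#'   and `states` (matrix with columns `s`, `f_in`, `v`, `q`).
#' @export
hdm_integrate <- function(p, z = NULL, events = NULL, dt_s = 0.375,
                          duration_s = NULL, impulse_duration_s = dt_s) {
  if (dt_s <= 0) stop("dt_s must be positive")
  if (is.null(z)) {
    if (is.null(events) || is.null(duration_s)) {
      stop("provide either z, or events plus duration_s")
    }
    if (duration_s < dt_s) stop("duration_s must be at least dt_s")
    z <- neural_input(events, dt_s, duration_s, impulse_duration_s)
  }
  out <- hdm_integrate_cpp(.hdm_par_vector(p), as.numeric(z), dt_s)
  list(
    time = seq(0, by = dt_s, length.out = nrow(out)),
    y = out[, 1],
    states = `colnames<-`(out[, 2:5, drop = FALSE], c("s", "f_in", "v", "q"))
  )
}

#' Sample a dense timeseries at scan acquisition times
#'
#' Linear interpolation of a dt-grid series at
#' `offset_s + (0:(n_scans-1)) * tr_s` (the offset encodes the middle-slice
#' reference of slice-timing correction).
#'
#' @param y Values on the dense grid.
#' @param time Times of `y`, or a scalar grid step (grid then starts at 0).
#' @param tr_s Repetition time in seconds.
#' @param n_scans Number of scans.
#' @param offset_s Acquisition-time offset in seconds.
#' @return Numeric vector of length `n_scans`.
#' @export
downsample_to_scans <- function(y, time, tr_s, n_scans, offset_s = 0) {
  if (length(time) == 1L) time <- seq(0, by = time, length.out = length(y))
  scan_t <- offset_s + (seq_len(n_scans) - 1) * tr_s
  if (min(scan_t) < min(time) - 1e-9 || max(scan_t) > max(time) + 1e-9) {
    stop("scan times fall outside the integration grid")
  }
  approx(time, y, xout = scan_t, rule = 2)$y
}

#' First-order Volterra kernel
#'
#' The modelled BOLD response to a single brief neural burst, evaluated at
#' the requested lags by integrating the full nonlinear system.
#'
#' @inheritParams hdm_derivs
#' @param lags Non-negative lags in seconds.
#' @param dt_s Integration step.
#' @param impulse_duration_s Neural burst duration.
#' @return Numeric vector `K1(lags)`.
#' @export
volterra_kernel1 <- function(p, lags, dt_s = 0.375,
                             impulse_duration_s = dt_s) {
  if (any(lags < 0)) stop("lags must be >= 0")
  dur <- max(lags) + 2 * dt_s
  z <- numeric(ceiling(dur / dt_s))
  z[seq_len(max(1L, round(impulse_duration_s / dt_s)))] <- 1
  sim <- hdm_integrate(p, z = z, dt_s = dt_s)
  approx(sim$time, sim$y, xout = lags, rule = 2)$y
}

#' Second-order Volterra kernel
#'
#' `K2(s1, s2)` is the response at lag `s1` after one burst and `s2` after a
#' second, minus the two isolated first-order responses: the nonlinear
#' interaction (saturation or facilitation) between stimulus pairs. Computed
#' by direct integration of the nonlinear system; symmetric by construction.
#'
#' @inheritParams volterra_kernel1
#' @return Matrix `K2` over `lags x lags`.
#' @export
volterra_kernel2 <- function(p, lags, dt_s = 0.375,
                             impulse_duration_s = dt_s) {
  if (any(lags < 0)) stop("lags must be >= 0")
  lags <- sort(unique(lags))
  nb <- max(1L, round(impulse_duration_s / dt_s))
  k1 <- volterra_kernel1(p, lags, dt_s, impulse_duration_s)
  n <- length(lags)
  K2 <- matrix(0, n, n)
  # onset separations (lower triangle incl. diagonal), snapped to the grid
  D <- round(outer(lags, lags, "-") / dt_s)
  dur <- 2 * max(lags) + 2 * dt_s
  for (sb in sort(unique(D[D >= 0]))) {
    z <- numeric(ceiling(dur / dt_s))
    z[seq_len(nb)] <- z[seq_len(nb)] + 1
    z[sb + seq_len(nb)] <- z[sb + seq_len(nb)] + 1
    sim <- hdm_integrate(p, z = z, dt_s = dt_s)
    hit <- which(D == sb & lower.tri(D, diag = TRUE), arr.ind = TRUE)
    ypair <- approx(sim$time, sim$y, xout = lags[hit[, 1]], rule = 2)$y
    val <- ypair - k1[hit[, 1]] - k1[hit[, 2]]
    K2[hit] <- val
    K2[hit[, 2:1, drop = FALSE]] <- val
  }
  K2
}

#' Fraction of explained variance carried by the second-order kernel
#'
#' Reconstructs the design's predicted timeseries from the first-order kernel
#' (linear superposition over events) and from the pairwise second-order
#' corrections, and returns `var(y2) / var(y1 + y2)`: the share of the total
#' kernel-explained variance attributable to nonlinear SOA effects.
#'
#' @param events An [event_sequence()].
#' @inheritParams hdm_derivs
#' @param dt_s Grid step for the reconstruction.
#' @param memory_s Kernel memory in seconds.
#' @return A fraction in `[0, 1]`.
#' @export
second_order_variance_fraction <- function(events, p, dt_s = 0.375,
                                           memory_s = 32) {
  .validate_events(events)
  if (!nrow(events)) stop("no events: total explained variance is zero")
  lag_grid <- seq(0, memory_s, by = dt_s)
  k1 <- volterra_kernel1(p, lag_grid, dt_s)
  K2 <- volterra_kernel2(p, lag_grid, dt_s)
  nlag <- length(lag_grid)
  dur <- max(events$onset) + memory_s + dt_s
  nt <- ceiling(dur / dt_s)
  bins <- round(events$onset / dt_s)  # 0-based onset bins
  y1 <- numeric(nt)
  for (b in bins) {
    idx <- b + seq_len(nlag)
    keep <- idx <= nt
    y1[idx[keep]] <- y1[idx[keep]] + k1[keep]
  }
  y2 <- numeric(nt)
  ne <- length(bins)
  if (ne >= 2) {
    for (i in seq_len(ne - 1)) {
      for (j in (i + 1):ne) {
        sep <- bins[j] - bins[i]
        if (sep >= nlag) break
        # both lags within memory: t runs from the later onset
        m <- nlag - sep
        idx <- bins[j] + seq_len(m)
        keep <- idx <= nt
        contrib <- K2[cbind(sep + seq_len(m), seq_len(m))]
        y2[idx[keep]] <- y2[idx[keep]] + contrib[keep]
      }
    }
  }
  tot <- var(y1 + y2)
  if (!is.finite(tot) || tot <= 0) stop("total explained variance is zero")
  var(y2) / tot
}
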