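# HRF basis sets: FIR top-hat bins, the canonical two-gamma HRF with its
# temporal and dispersion partial derivatives, two-gamma refitting, and
# microtime convolution design matrices.

.basis_set <- function(curves, names, step_s, window_s) {
  colnames(curves) <- names
  structure(list(curves = curves, names = names, step_s = step_s,
                 window_s = window_s),
            class = "basis_set")
}

#' Finite impulse response basis set
#'
#' Contiguous top-hat functions of `bin_width_s` duration spanning
#' `[0, n_bins * bin_width_s)` post-stimulus time, on a microtime grid.
#' Columns are mutually orthogonal and sum pointwise to one over the window.
#'
#' @param n_bins Number of time bins (default 32).
#' @param bin_width_s Bin width in seconds (default 1).
#' @param microtime_step_s Microtime grid step; defaults to `1.97/32`, the
#'   step obtained with a 1.97 s TR split into 32 bins.
#' @return A `basis_set`.
#' @export
fir_basis <- function(n_bins = 32, bin_width_s = 1,
                      microtime_step_s = 1.97 / 32) {
  if (n_bins < 1) stop("n_bins must be >= 1")
  window <- n_bins * bin_width_s
  t <- seq(0, window - microtime_step_s / 2, by = microtime_step_s)
  bin <- pmin(floor(t / bin_width_s), n_bins - 1)
  curves <- matrix(0, length(t), n_bins)
  curves[cbind(seq_along(t), bin + 1L)] <- 1
  .basis_set(curves, paste0("fir_", seq_len(n_bins)), microtime_step_s, window)
}

#' Two-gamma HRF parameters
#'
#' @param peak_delay Delay of the positive peak response (s).
#' @param undershoot_delay Delay of the undershoot (s).
#' @param peak_dispersion,undershoot_dispersion Gamma dispersions.
#' @param ratio Peak:undershoot amplitude ratio.
#' @param onset Onset shift (s).
#' @param length_s Kernel length (s).
#' @return List of class `two_gamma_params`.
#' @export
two_gamma_params <- function(peak_delay = 6, undershoot_delay = 16,
                             peak_dispersion = 1, undershoot_dispersion = 1,
                             ratio = 6, onset = 0, length_s = 32) {
  if (peak_delay <= 0 || undershoot_delay <= 0) stop("delays must be positive")
  if (peak_dispersion <= 0 || undershoot_dispersion <= 0) {
    stop("dispersions must be positive")
  }
  if (ratio <= 0) stop("ratio must be positive")
  structure(list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
                 peak_dispersion = peak_dispersion,
                 undershoot_dispersion = undershoot_dispersion,
                 ratio = ratio, onset = onset, length_s = length_s),
            class = "two_gamma_params")
}

.two_gamma_raw <- function(t, pd, ud, pdisp, udisp, ratio) {
  dgamma(t, shape = pd / pdisp, scale = pdisp) -
    dgamma(t, shape = ud / udisp, scale = udisp) / ratio
}

#' Canonical two-gamma HRF curve
#'
#' Difference of two gamma densities — a positive peak (around 5 s with the
#' defaults) minus a later undershoot — normalised to a maximum of one.
#'
#' @param p A [two_gamma_params()] object.
#' @param step_s Sampling step in seconds.
#' @return Numeric vector over `seq(0, length_s, by = step_s)`, with the time
#'   grid attached as attribute `time`.
#' @export
two_gamma_hrf <- function(p = two_gamma_params(), step_s = 1.97 / 32) {
  t <- seq(0, p$length_s, by = step_s)
  h <- .two_gamma_raw(t - p$onset, p$peak_delay, p$undershoot_delay,
                      p$peak_dispersion, p$undershoot_dispersion, p$ratio)
  h[t < p$onset] <- 0
  h <- h / max(h)
  attr(h, "time") <- t
  h
}

.orthogonalise <- function(M) {
  for (j in seq_len(ncol(M))[-1]) {
    prev <- M[, seq_len(j - 1), drop = FALSE]
    M[, j] <- M[, j] - prev %*% solve(crossprod(prev), crossprod(prev, M[, j]))
  }
  M
}

#' Informed basis set: canonical HRF plus partial derivatives
#'
#' Three columns: the canonical two-gamma HRF; its temporal derivative (the
#' finite difference obtained by shifting the onset by 1 s); and its
#' dispersion derivative (the finite difference obtained by increasing the
#' peak dispersion by 1 percent). The derivative columns capture small
#' latency shifts and width changes of the response within a linear model.
#'
#' @inheritParams two_gamma_hrf
#' @param orthogonalise Orthogonalise the derivative columns with respect to
#'   preceding columns (default `TRUE`).
#' @return A `basis_set` with columns `canonical`, `temporal_derivative`,
#'   `dispersion_derivative`.
#' @export
informed_basis <- function(p = two_gamma_params(), step_s = 1.97 / 32,
                           orthogonalise = TRUE) {
  h <- as.numeric(two_gamma_hrf(p, step_s))
  p_shift <- p; p_shift$onset <- p$onset + 1
  h_shift <- as.numeric(two_gamma_hrf(p_shift, step_s))
  td <- (h - h_shift) / 1
  p_disp <- p; p_disp$peak_dispersion <- p$peak_dispersion * 1.01
  h_disp <- as.numeric(two_gamma_hrf(p_disp, step_s))
  dd <- (h - h_disp) / 0.01
  M <- cbind(h, td, dd)
  if (orthogonalise) M <- .orthogonalise(M)
  .basis_set(M, c("canonical", "temporal_derivative", "dispersion_derivative"),
             step_s, p$length_s)
}

#' Fit a two-gamma model to an empirical HRF curve
#'
#' Least-squares refit of the two-gamma form (peak delay/dispersion,
#' undershoot delay/dispersion, peak:undershoot ratio, overall amplitude) to
#' a mean FIR curve, e.g. to derive a revised canonical HRF matched to a
#' study sample. Levenberg-Marquardt with multiple starts around the
#' canonical defaults.
#'
#' @param curve Empirical HRF values.
#' @param step_s Sampling step of `curve` in seconds.
#' @param start Starting [two_gamma_params()].
#' @return A `two_gamma_params` with attributes `amplitude` (fitted scale)
#'   and `r.squared`.
#' @export
fit_two_gamma <- function(curve, step_s = 1, start = two_gamma_params()) {
  t <- (seq_along(curve) - 1) * step_s
  if (max(t) < 24) stop("curve must cover at least 24 s of post-stimulus time")
  dat <- data.frame(t = t, y = as.numeric(curve))
  best <- NULL
  for (fac in c(1, 0.8, 1.25)) {
    st <- list(a = max(abs(curve)) * sign(curve[which.max(abs(curve))]),
               pd = start$peak_delay * fac, ud = start$undershoot_delay,
               pdisp = start$peak_dispersion, udisp = start$undershoot_dispersion,
               ratio = start$ratio)
    fit <- try(minpack.lm::nlsLM(
      y ~ a * (dgamma(t, shape = pd / pdisp, scale = pdisp) -
                 dgamma(t, shape = ud / udisp, scale = udisp) / ratio),
      data = dat, start = st,
      lower = c(a = -Inf, pd = 1, ud = 4, pdisp = 0.05, udisp = 0.05,
                ratio = 0.5),
      upper = c(a = Inf, pd = 16, ud = 32, pdisp = 8, udisp = 8, ratio = 1e4),
      control = nls.control(maxiter = 200)
    ), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      if (is.null(best) || sum(resid(fit)^2) < sum(resid(best)^2)) best <- fit
    }
  }
  if (is.null(best)) stop("two-gamma refit did not converge from any start")
  cf <- coef(best)
  out <- two_gamma_params(peak_delay = cf[["pd"]],
                          undershoot_delay = cf[["ud"]],
                          peak_dispersion = cf[["pdisp"]],
                          undershoot_dispersion = cf[["udisp"]],
                          ratio = cf[["ratio"]],
                          length_s = max(t))
  attr(out, "amplitude") <- cf[["a"]]
  attr(out, "r.squared") <- 1 - sum(resid(best)^2) / sum((dat$y - mean(dat$y))^2)
  out
}

#' Build a convolution design matrix on a microtime grid
#'
#' Convolves a delta train at the event onsets with each basis column in a
#' high-resolution space of `bins_per_tr` time points per TR, then samples
#' the result at the middle microtime bin of each scan (matching a
#' middle-slice slice-timing reference).
#'
#' @param events An [event_sequence()].
#' @param basis A `basis_set` whose `step_s` equals `tr_s / bins_per_tr`.
#' @param tr_s Repetition time (s).
#' @param n_scans Number of scans.
#' @param bins_per_tr Microtime bins per TR (default 32).
#' @return `n_scans x k` matrix with attributes `microtime_step_s` and
#'   `basis_names`; events after the last scan are dropped with a warning.
#' @export
build_design_matrix <- function(events, basis, tr_s, n_scans,
                                bins_per_tr = 32) {
  .validate_events(events)
  dt <- tr_s / bins_per_tr
  if (abs(basis$step_s - dt) > 1e-8) {
    stop("basis microtime step (", basis$step_s,
         ") must equal tr_s / bins_per_tr (", dt, ")")
  }
  n_micro <- n_scans * bins_per_tr
  k <- ncol(basis$curves)
  len <- nrow(basis$curves)
  X <- matrix(0, n_micro, k)
  late <- events$onset >= n_scans * tr_s
  if (any(late)) {
    warning(sum(late), " event(s) after the last scan were dropped")
  }
  for (on in events$onset[!late]) {
    i0 <- floor(on / dt) + 1L
    m <- min(len, n_micro - i0 + 1L)
    if (m > 0) {
      X[i0:(i0 + m - 1L), ] <- X[i0:(i0 + m - 1L), ] +
        basis$curves[seq_len(m), , drop = FALSE]
    }
  }
  mid <- max(1L, round(bins_per_tr / 2))
  rows <- (seq_len(n_scans) - 1L) * bins_per_tr + mid
  out <- X[rows, , drop = FALSE]
  colnames(out) <- basis$names
  attr(out, "microtime_step_s") <- dt
  attr(out, "basis_names") <- basis$names
  out
}
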