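# m-sequence experimental design: maximal-length shift-register sequences,
# jittered event timings, and trial-type assignment.

# One primitive feedback polynomial per register length (Fibonacci LFSR tap
# positions). Any user-supplied primitive polynomial is accepted instead.
.default_taps <- list(
  `2` = c(2L, 1L),  `3` = c(3L, 2L),   `4` = c(4L, 3L),
  `5` = c(5L, 3L),  `6` = c(6L, 5L),   `7` = c(7L, 6L),
  `8` = c(8L, 6L, 5L, 4L), `9` = c(9L, 5L), `10` = c(10L, 7L),
  `11` = c(11L, 9L), `12` = c(12L, 6L, 4L, 1L), `13` = c(13L, 4L, 3L, 1L),
  `14` = c(14L, 5L, 3L, 1L), `15` = c(15L, 14L), `16` = c(16L, 15L, 13L, 4L)
)

#' Generate a maximal-length binary m-sequence
#'
#' Runs a Fibonacci linear-feedback shift register of the given degree for one
#' full period of `2^degree - 1` steps. A maximal sequence contains exactly
#' `2^(degree-1)` ones, and its +/-1 coding has periodic autocorrelation -1 at
#' every nonzero lag, which is what makes these sequences efficient designs
#' for sampling the haemodynamic impulse response.
#'
#' @param degree Register length, an integer in 2..16.
#' @param taps Feedback tap positions (a primitive polynomial). Defaults to a
#'   built-in primitive polynomial for the degree. Non-primitive taps are
#'   detected by a period check and raise an error.
#' @return Integer vector of 0/1 of length `2^degree - 1`.
#' @export
#' @examples
#' s <- generate_msequence(8)
#' length(s)  # 255
#' sum(s)     # 128
generate_msequence <- function(degree, taps = NULL) {
  if (!is.numeric(degree) || length(degree) != 1L || degree != round(degree) ||
      degree < 2 || degree > 16) {
    stop("degree must be a single integer in 2..16")
  }
  degree <- as.integer(degree)
  if (is.null(taps)) taps <- .default_taps[[as.character(degree)]]
  taps <- as.integer(taps)
  if (any(taps < 1L | taps > degree) || anyDuplicated(taps) ||
      !(degree %in% taps)) {
    stop("taps must be distinct positions in 1..degree and include degree")
  }
  n <- 2L^degree - 1L
  reg <- rep(1L, degree)
  pack <- function(r) sum(r * 2^(seq_len(degree) - 1))
  start <- pack(reg)
  out <- integer(n)
  for (k in seq_len(n)) {
    out[k] <- reg[degree]
    fb <- 0L
    for (t in taps) fb <- bitwXor(fb, reg[t])
    reg <- c(fb, reg[-degree])
    if (k < n && pack(reg) == start) {
      stop(sprintf(
        "taps {%s} do not form a primitive polynomial: register period %d < %d",
        paste(taps, collapse = ","), k, n
      ))
    }
  }
  if (pack(reg) != start) {
    stop("register did not return to its initial state; taps are not primitive")
  }
  out
}

.validate_events <- function(events) {
  stopifnot(is.data.frame(events))
  need <- c("onset", "duration", "trial_type")
  missing <- setdiff(need, names(events))
  if (length(missing)) {
    stop("event table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!is.numeric(events$onset)) stop("onsets must be numeric")
  if (nrow(events)) {
    if (any(events$onset < 0)) stop("onsets must be >= 0")
    bad <- which(diff(events$onset) <= 0)
    if (length(bad)) {
      stop("onsets must be strictly increasing; first violation at row ", bad[1] + 1L)
    }
  }
  invisible(events)
}

#' Construct an event sequence from onsets
#'
#' @param onset Event onsets in seconds from the first scan.
#' @param duration Stimulus durations in seconds (recycled).
#' @param trial_type Trial labels (recycled).
#' @param jitter Optional per-trial jitter values already contained in `onset`.
#' @return A `data.frame` of class `event_sequence`.
#' @export
event_sequence <- function(onset, duration = 0.3,
                           trial_type = "audiovisual", jitter = NA_real_) {
  ev <- data.frame(
    onset = as.numeric(onset),
    duration = rep_len(as.numeric(duration), length(onset)),
    trial_type = rep_len(as.character(trial_type), length(onset)),
    jitter = rep_len(as.numeric(jitter), length(onset)),
    stringsAsFactors = FALSE
  )
  .validate_events(ev)
  class(ev) <- c("event_sequence", "data.frame")
  ev
}

#' Build jittered event timings from a binary sequence
#'
#' Element `k` of the sequence (1-based) owns the slot starting at
#' `(k-1) * base_soa_s`; elements equal to one yield an event at the slot time
#' plus a uniform jitter, null elements yield no event. Jitter is additive per
#' trial, not cumulative, so the effective post-stimulus sampling grid is
#' finer than the base SOA.
#'
#' @param seq Binary 0/1 vector (e.g. from [generate_msequence()]).
#' @param base_soa_s Minimal stimulus onset asynchrony in seconds.
#' @param jitter_low_s,jitter_high_s Uniform jitter bounds in seconds.
#' @param duration Stimulus duration recorded in the event table (seconds).
#' @return An [event_sequence()] with one row per non-null element. Uses the
#'   current R random stream; call `set.seed()` for reproducibility.
#' @export
build_event_timing <- function(seq, base_soa_s = 2,
                               jitter_low_s = 0.1, jitter_high_s = 0.3,
                               duration = 0.3) {
  if (base_soa_s <= 0) stop("base_soa_s must be positive")
  if (jitter_low_s < 0 || jitter_low_s > jitter_high_s) {
    stop("jitter bounds must satisfy 0 <= low <= high")
  }
  seq <- as.integer(seq)
  idx <- which(seq == 1L)
  jit <- if (jitter_high_s > jitter_low_s) {
    runif(length(idx), jitter_low_s, jitter_high_s)
  } else {
    rep(jitter_low_s, length(idx))
  }
  event_sequence(
    onset = (idx - 1) * base_soa_s + jit,
    duration = duration,
    trial_type = "audiovisual",
    jitter = jit
  )
}

#' Assign trial types to an event sequence
#'
#' By default all but eight trials are bimodal; the eight "catch" trials
#' (four visual-only, four auditory-only) are placed at uniformly random
#' positions, mirroring the sensorimotor paradigm.
#'
#' @param events An [event_sequence()].
#' @param counts Named counts for `audiovisual`, `visual_only`,
#'   `auditory_only`. An `NA` audiovisual count is filled with the remainder.
#'   Counts must sum to the number of events.
#' @return The event sequence with `trial_type` filled in.
#' @export
assign_trial_types <- function(events,
                               counts = c(audiovisual = NA, visual_only = 4,
                                          auditory_only = 4)) {
  .validate_events(events)
  n <- nrow(events)
  need <- c("audiovisual", "visual_only", "auditory_only")
  if (!all(need %in% names(counts))) {
    stop("counts must be named audiovisual, visual_only, auditory_only")
  }
  counts <- counts[need]
  if (is.na(counts["audiovisual"])) {
    counts["audiovisual"] <- n - sum(counts[-1])
  }
  if (any(counts < 0) || sum(counts) != n) {
    stop("trial-type counts must be non-negative and sum to the number of events (",
         n, ")")
  }
  types <- rep(names(counts), times = counts)
  events$trial_type <- sample(types, n)
  events
}
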