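#' Rapid eye movement detector configuration
#'
#' Defaults follow the standard amplitude-based EOG detector settings:
#' 0.3-10 Hz prefilter, minimum peak amplitude 50 uV, event duration
#' 0.3-1.2 s, dominant frequency 0.5-5 Hz.
#'
#' @param band prefilter band `c(lo, hi)` in Hz.
#' @param min_amplitude minimum absolute peak amplitude in uV.
#' @param duration_bounds admissible event duration `c(lo, hi)` in s.
#' @param freq_bounds admissible dominant frequency `c(lo, hi)` in Hz.
#' @return object of class `em_detect_config`.
#' @export
em_detect_config <- function(band = c(0.3, 10), min_amplitude = 50,
                             duration_bounds = c(0.3, 1.2),
                             freq_bounds = c(0.5, 5)) {
  stopifnot(band[1] < band[2], duration_bounds[1] < duration_bounds[2],
            freq_bounds[1] < freq_bounds[2], min_amplitude > 0)
  out <- list(band = band, min_amplitude = min_amplitude,
              duration_bounds = duration_bounds, freq_bounds = freq_bounds)
  class(out) <- "em_detect_config"
  out
}

#' Detect rapid eye movement events on a bilateral EOG pair
#'
#' Both channels are zero-phase band-pass filtered to the configured band.
#' Candidate events are contiguous stretches where a rolling-maximum
#' envelope of the larger channel excursion exceeds `min_amplitude`; a
#' candidate is retained only if the two channels deflect in anti-phase at
#' the extremum (negative product of the filtered signals, the conjugacy
#' signature of a genuine eye movement). The event extent is taken as
#' twice the half-period of the deflection lobe containing the extremum
#' (the span between the flanking zero crossings), the dominant frequency
#' as the reciprocal of twice that half-period, and events whose duration
#' or frequency fall outside the configured bounds are discarded. The
#' reported peak amplitude is the maximum absolute excursion across both
#' filtered channels within the event; it is never below `min_amplitude`.
#'
#' @param loc,roc left/right EOG in uV, equal length.
#' @param sample_rate sampling rate in Hz, at least 20 Hz.
#' @param cfg an [em_detect_config()].
#' @return data.frame with columns `onset_s`, `duration_s`, `peak_amp_uV`,
#'   `extremum_s`, ordered by onset.
#' @export
detect_rem_events <- function(loc, roc, sample_rate, cfg = em_detect_config()) {
  if (length(loc) != length(roc)) stop("EOG channels must have equal length")
  if (sample_rate < 20) {
    stop("sample_rate must be >= 20 Hz to resolve the 0.5-5 Hz criterion")
  }
  lf <- bandpass_filter(loc, sample_rate, cfg$band[1], cfg$band[2])
  rf <- bandpass_filter(roc, sample_rate, cfg$band[1], cfg$band[2])
  env <- pmax(abs(lf), abs(rf))
  env_sm <- rolling_max(env, round(0.25 * sample_rate))
  runs <- logical_runs(env_sm > cfg$min_amplitude)
  empty <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                      peak_amp_uV = numeric(0), extremum_s = numeric(0))
  if (nrow(runs) == 0) return(empty)

  n <- length(env)
  out <- vector("list", nrow(runs))
  for (i in seq_len(nrow(runs))) {
    a <- runs[i, 1]; b <- runs[i, 2]
    ipk <- a + which.max(env[a:b]) - 1L
    if (lf[ipk] * rf[ipk] >= 0) next  # not conjugate
    ch <- if (abs(lf[ipk]) >= abs(rf[ipk])) lf else rf
    sgn <- sign(ch[ipk])
    il <- ipk
    while (il > 1 && sign(ch[il - 1]) == sgn) il <- il - 1L
    ir <- ipk
    while (ir < n && sign(ch[ir + 1]) == sgn) ir <- ir + 1L
    half_period <- (ir - il + 1) / sample_rate
    duration <- 2 * half_period
    freq <- 1 / (2 * half_period)
    if (duration < cfg$duration_bounds[1] || duration > cfg$duration_bounds[2]) next
    if (freq < cfg$freq_bounds[1] || freq > cfg$freq_bounds[2]) next
    e0 <- max(1L, ipk - as.integer(round(duration / 2 * sample_rate)))
    e1 <- min(n, ipk + as.integer(round(duration / 2 * sample_rate)))
    out[[i]] <- data.frame(
      onset_s = (e0 - 1) / sample_rate,
      duration_s = duration,
      peak_amp_uV = max(env[e0:e1]),
      extremum_s = (ipk - 1) / sample_rate
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res[order(res$onset_s), , drop = FALSE]
}

#' Per-epoch EM peak amplitude series
#'
#' Maps detected events onto a 4-s epoch grid: each epoch carries the
#' maximum `peak_amp_uV` of the events whose extremum falls inside it,
#' and 0 if no event does. Keeping event-free epochs (at amplitude 0) in
#' the series preserves the grid for cross-correlation; the subsequent
#' rank transform absorbs the resulting ties as mid-ranks.
#'
#' @param events data.frame from [detect_rem_events()].
#' @param n_epochs number of epochs on the grid.
#' @param epoch_length epoch length in seconds.
#' @return numeric vector of length `n_epochs` (uV).
#' @export
epoch_amplitude_series <- function(events, n_epochs, epoch_length = 4) {
  amp <- numeric(n_epochs)
  if (nrow(events) == 0) return(amp)
  ep <- floor(events$extremum_s / epoch_length) + 1L
  ok <- ep >= 1 & ep <= n_epochs
  if (any(ok)) {
    agg <- tapply(events$peak_amp_uV[ok], ep[ok], max)
    amp[as.integer(names(agg))] <- agg
  }
  amp
}
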