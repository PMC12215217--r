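#' Specification of a synthetic REM sleep episode
#'
#' Collects the generative parameters for [synth_rem_episode()]: the
#' state-dependent spectral exponents of the EEG, superimposed narrowband
#' oscillations, the infra-slow clustering of rapid eye movement (EM)
#' bursts on the EOG, and the EM amplitude law. Defaults follow values
#' typical of adult REM sleep: low-band (2-30 Hz) exponents near -2.1 with
#' the phasic state steeper by 0.15, high-band (30-48 Hz) exponents near
#' -3.9 with the phasic state flatter by 0.4, EM bursts recurring on a
#' ~2-min infra-slow timescale, and EM peak amplitudes drawn from a
#' log-normal law (median 180 uV, sigma_log 0.3) truncated at 150 uV so
#' that every scripted event satisfies the phasic scoring criterion.
#'
#' @param sample_rate sampling rate in Hz. Must be at least twice the
#'   highest analysis frequency times the largest IRASA resampling factor
#'   (48 Hz x 1.9 => >= 182.4 Hz).
#' @param duration episode length in seconds; use > 600 s for episodes
#'   meant for within-episode analysis.
#' @param low_exponent_tonic,low_exponent_phasic generative exponents of
#'   the 2-30 Hz band in the tonic and phasic state (dimensionless,
#'   negative: log-power falls with log-frequency).
#' @param high_exponent_tonic,high_exponent_phasic generative exponents of
#'   the 30-48 Hz band.
#' @param exponent_shift scalar added to all four exponents; used to model
#'   between-participant baseline differences.
#' @param oscillations list of `c(freq, amplitude)` pairs: narrowband
#'   sinusoids added to every EEG channel (frequency in Hz, RMS amplitude
#'   in uV).
#' @param em_burst_period recurrence interval of EM bursts in seconds.
#' @param em_burst_length burst length in seconds (snapped to whole 4-s
#'   epochs).
#' @param em_rate_in_burst event rate within a burst (events/s).
#' @param em_amplitude_median,em_amplitude_sdlog parameters of the
#'   log-normal EM peak-amplitude law (uV; truncated at
#'   `em_amplitude_min`).
#' @param em_amplitude_min lower truncation of the amplitude law in uV.
#' @param em_duration_range range of event durations in seconds.
#' @param eog_noise_sd standard deviation of the Gaussian EOG background in
#'   uV; must stay well below the 25-uV tonic quiescence bound.
#' @param eeg_sd broadband standard deviation of each synthetic EEG channel
#'   in uV.
#' @param coupling_lag_epochs shift (in 4-s epochs) of the spectral state
#'   relative to the EM schedule; negative values make the aperiodic slope
#'   lead the eye movements.
#' @param epoch_length analysis epoch length in seconds.
#' @param seed default integer seed used by the generator functions.
#'
#' @return An object of class `synthetic_spec` (a list of the above).
#' @export
synthetic_spec <- function(sample_rate = 250,
                           duration = 720,
                           low_exponent_tonic = -2.10,
                           low_exponent_phasic = -2.25,
                           high_exponent_tonic = -3.90,
                           high_exponent_phasic = -3.50,
                           exponent_shift = 0,
                           oscillations = list(c(7.5, 3)),
                           em_burst_period = 120,
                           em_burst_length = 20,
                           em_rate_in_burst = 1,
                           em_amplitude_median = 180,
                           em_amplitude_sdlog = 0.3,
                           em_amplitude_min = 150,
                           em_duration_range = c(0.3, 0.5),
                           eog_noise_sd = 5,
                           eeg_sd = 20,
                           coupling_lag_epochs = 0,
                           epoch_length = 4,
                           seed = 1L) {
  stopifnot(sample_rate > 0, duration > 0, epoch_length > 0)
  exps <- c(low_exponent_tonic, low_exponent_phasic,
            high_exponent_tonic, high_exponent_phasic)
  if (any(!is.finite(exps)) || any(exps + exponent_shift > 0)) {
    stop("generative exponents must be finite and non-positive")
  }
  if (sample_rate < 2 * 48 * 1.9) {
    stop("sample_rate must be >= 182.4 Hz so that 48 Hz x 1.9 stays below Nyquist")
  }
  spec <- list(
    sample_rate = sample_rate, duration = duration,
    low_exponent_tonic = low_exponent_tonic,
    low_exponent_phasic = low_exponent_phasic,
    high_exponent_tonic = high_exponent_tonic,
    high_exponent_phasic = high_exponent_phasic,
    exponent_shift = exponent_shift,
    oscillations = oscillations,
    em_burst_period = em_burst_period,
    em_burst_length = em_burst_length,
    em_rate_in_burst = em_rate_in_burst,
    em_amplitude_median = em_amplitude_median,
    em_amplitude_sdlog = em_amplitude_sdlog,
    em_amplitude_min = em_amplitude_min,
    em_duration_range = em_duration_range,
    eog_noise_sd = eog_noise_sd,
    eeg_sd = eeg_sd,
    coupling_lag_epochs = coupling_lag_epochs,
    epoch_length = epoch_length,
    seed = seed
  )
  class(spec) <- "synthetic_spec"
  spec
}

# Gaussian noise whose amplitude spectrum is shaped by `shape(f)`;
# the expected power spectral density is proportional to shape(f)^2 at
# every DFT bin. Output is zero-mean and rescaled to standard deviation
# `sd`.
shaped_noise <- function(n, sample_rate, shape, seed = NULL, sd = 1) {
  stopifnot(n >= 2)
  with_seed(seed, {
    half <- n %/% 2
    freqs <- (1:half) * sample_rate / n
    amp <- shape(freqs)
    if (any(!is.finite(amp)) || any(amp < 0)) {
      stop("spectral shape must be finite and non-negative")
    }
    Z <- rep(0 + 0i, n)
    npos <- if (n %% 2 == 0) half - 1 else half
    re <- stats::rnorm(npos)
    im <- stats::rnorm(npos)
    Z[2:(npos + 1)] <- complex(real = re, imaginary = im) * amp[1:npos] / sqrt(2)
    Z[n:(n - npos + 1)] <- Conj(Z[2:(npos + 1)])
    if (n %% 2 == 0) Z[half + 1] <- stats::rnorm(1) * amp[half]
    x <- Re(stats::fft(Z, inverse = TRUE)) / n
    x <- x - mean(x)
    s <- stats::sd(x)
    if (s == 0) stop("degenerate realization with zero variance")
    x * (sd / s)
  })
}

# Amplitude shape of a broken power law continuous at the knee: PSD
# proportional to f^a_low below the knee and f^a_high above it.
broken_law_shape <- function(a_low, a_high, knee = 30) {
  force(a_low); force(a_high); force(knee)
  function(f) {
    ifelse(f <= knee,
           f^(a_low / 2),
           knee^((a_low - a_high) / 2) * f^(a_high / 2))
  }
}

#' Synthesize a power-law ("1/f-like") signal
#'
#' Generates Gaussian noise whose expected power spectral density is
#' proportional to `f^exponent`, by shaping the amplitude spectrum of
#' white noise as `f^(exponent/2)` with random phases and inverse
#' transforming. The expected log-log spectral slope equals `exponent`
#' exactly at every frequency bin, which makes slope recovery an analytic
#' property of the generator.
#'
#' @param exponent spectral exponent (<= 0; 0 gives white noise).
#' @param sample_rate sampling rate in Hz.
#' @param duration length in seconds (`duration * sample_rate >= 2`).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param sd standard deviation of the output in uV.
#' @return Numeric vector of `duration * sample_rate` samples, zero mean.
#' @examples
#' x <- synth_aperiodic_signal(-2, 250, 4, seed = 1)
#' @export
synth_aperiodic_signal <- function(exponent, sample_rate, duration,
                                   seed = NULL, sd = 20) {
  if (!is.finite(exponent)) stop("exponent must be finite")
  if (exponent > 0) stop("exponent must be <= 0")
  if (duration <= 0) stop("duration must be positive")
  n <- round(duration * sample_rate)
  if (n < 2) stop("duration * sample_rate must be >= 2 samples")
  shape <- if (exponent == 0) function(f) rep(1, length(f)) else function(f) f^(exponent / 2)
  shaped_noise(n, sample_rate, shape, seed = seed, sd = sd)
}

# Truncated log-normal EM peak amplitudes.
draw_em_amplitudes <- function(k, median, sdlog, minimum) {
  if (k == 0) return(numeric(0))
  out <- numeric(0)
  while (length(out) < k) {
    cand <- stats::rlnorm(2 * k, meanlog = log(median), sdlog = sdlog)
    out <- c(out, cand[cand >= minimum])
  }
  out[seq_len(k)]
}

#' Schedule rapid eye movement bursts
#'
#' Draws EM event onsets from a clustered point process: burst centers
#' recur every `em_burst_period` seconds (with jitter), each burst spans a
#' whole number of 4-s epochs, and within a burst every 2-s subwindow
#' receives `round(2 * em_rate_in_burst)` (at least one) non-overlapping
#' events. Amplitudes follow the configured truncated log-normal law;
#' durations are uniform over `em_duration_range`. Placing at least one
#' event in every burst subwindow guarantees that burst epochs satisfy the
#' phasic scoring rule (two EMs in adjacent 2-s windows) by construction.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed (defaults to `spec$seed`).
#' @return data.frame with columns `onset_s`, `duration_s`, `peak_amp_uV`,
#'   `epoch_index` (1-based 4-s epoch) and `subwindow` (1-based 2-s
#'   window), ordered by onset.
#' @export
schedule_em_bursts <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$em_burst_period <= 0) stop("em_burst_period must be positive")
  empty <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                      peak_amp_uV = numeric(0), epoch_index = integer(0),
                      subwindow = integer(0))
  if (spec$em_rate_in_burst <= 0) return(empty)
  ev_per_sub <- max(1L, as.integer(round(2 * spec$em_rate_in_burst)))
  dmax <- max(spec$em_duration_range)
  min_gap <- 0.4
  if (ev_per_sub * (dmax + min_gap) > 2 - 0.1) {
    stop("em_rate_in_burst too high: non-overlapping placement infeasible in a 2-s window")
  }
  ep_len <- spec$epoch_length
  n_epochs <- floor(spec$duration / ep_len)
  n_bursts <- floor(spec$duration / spec$em_burst_period)
  burst_epochs_n <- max(1L, as.integer(round(spec$em_burst_length / ep_len)))

  with_seed(seed, {
    centers <- (seq_len(n_bursts) - 0.5) * spec$em_burst_period +
      stats::runif(n_bursts, -0.2, 0.2) * spec$em_burst_period
    first_ep <- pmax(1L, pmin(n_epochs - burst_epochs_n + 1L,
                              as.integer(round(centers / ep_len)) - burst_epochs_n %/% 2L + 1L))
    if (length(first_ep) == 0) return(empty)
    # drop bursts that would touch the previous one
    keep <- c(TRUE, diff(first_ep) >= burst_epochs_n + 2L)
    first_ep <- first_ep[keep]
    rows <- list()
    for (fe in first_ep) {
      for (ep in fe:(fe + burst_epochs_n - 1L)) {
        for (sw in 1:2) {
          t0 <- (ep - 1) * ep_len + (sw - 1) * 2
          durs <- stats::runif(ev_per_sub, spec$em_duration_range[1], dmax)
          amps <- draw_em_amplitudes(ev_per_sub, spec$em_amplitude_median,
                                     spec$em_amplitude_sdlog, spec$em_amplitude_min)
          onsets <- numeric(ev_per_sub)
          cursor <- t0 + 0.05
          for (j in seq_len(ev_per_sub)) {
            slack <- (t0 + 2 - 0.05) - cursor -
              sum(durs[j:ev_per_sub]) - (ev_per_sub - j) * min_gap
            onsets[j] <- cursor + stats::runif(1, 0, max(0, slack) / 2)
            cursor <- onsets[j] + durs[j] + min_gap
          }
          rows[[length(rows) + 1L]] <- data.frame(
            onset_s = onsets, duration_s = durs, peak_amp_uV = amps,
            epoch_index = ep, subwindow = (ep - 1L) * 2L + sw
          )
        }
      }
    }
    if (length(rows) == 0) return(empty)
    out <- do.call(rbind, rows)
    out[order(out$onset_s), , drop = FALSE]
  })
}

#' Render scripted EM events onto a bilateral EOG pair
#'
#' Each event becomes one biphasic cycle (a full sine period over its
#' duration) reaching its scripted peak amplitude, rendered in anti-phase
#' on the two channels as expected for conjugate eye movements, on top of
#' Gaussian background noise.
#'
#' @param em_events data.frame as returned by [schedule_em_bursts()]
#'   (columns `onset_s`, `duration_s`, `peak_amp_uV`).
#' @param sample_rate sampling rate in Hz.
#' @param duration signal length in seconds; all events must fit inside.
#' @param noise_sd background noise standard deviation in uV. Values at or
#'   above 25 uV contaminate the tonic quiescence criterion and trigger a
#'   warning.
#' @param seed integer seed.
#' @return list with numeric components `left` and `right` (uV).
#' @export
synth_eog <- function(em_events, sample_rate, duration, noise_sd = 5,
                      seed = NULL) {
  n <- round(duration * sample_rate)
  if (nrow(em_events) > 0 &&
      any(em_events$onset_s < 0 | em_events$onset_s + em_events$duration_s > duration)) {
    stop("all EM events must fit inside the signal duration")
  }
  if (noise_sd >= 25) {
    warning("noise_sd >= 25 uV: tonic windows will violate the quiescence rule")
  }
  with_seed(seed, {
    base <- numeric(n)
    if (nrow(em_events) > 0) {
      for (i in seq_len(nrow(em_events))) {
        on <- em_events$onset_s[i]
        D <- em_events$duration_s[i]
        A <- em_events$peak_amp_uV[i]
        i0 <- floor(on * sample_rate) + 1L
        i1 <- min(n, ceiling((on + D) * sample_rate))
        tt <- ((i0:i1) - 1) / sample_rate
        base[i0:i1] <- base[i0:i1] + A * sin(2 * pi * (tt - on) / D)
      }
    }
    list(left = base + stats::rnorm(n, 0, noise_sd),
         right = -base + stats::rnorm(n, 0, noise_sd))
  })
}

# Per-sample crossfade weight (0 = tonic stream, 1 = phasic stream) from a
# per-epoch phasic mask, with 0.5-s raised-cosine transitions so state
# switches do not inject broadband edges.
crossfade_weight <- function(phasic_epoch, sample_rate, epoch_length, n) {
  w <- rep(as.numeric(phasic_epoch), each = round(epoch_length * sample_rate))
  w <- w[seq_len(min(n, length(w)))]
  if (length(w) < n) w <- c(w, rep(w[length(w)], n - length(w)))
  k <- round(0.5 * sample_rate)
  if (k %% 2 == 0) k <- k + 1
  kern <- hann_window(k + 2)[2:(k + 1)]
  kern <- kern / sum(kern)
  wp <- c(rep(w[1], k), w, rep(w[length(w)], k))
  sm <- stats::filter(wp, kern, sides = 2)
  as.numeric(sm[(k + 1):(k + n)])
}

# Epoch labels implied by a scripted event schedule, mirroring the scoring
# rules: phasic iff both 2-s subwindows of the epoch contain an event;
# tonic iff the epoch and its flanking 2-s windows contain none.
schedule_labels <- function(em_events, n_epochs) {
  n_win <- 2L * n_epochs
  has_ev <- rep(FALSE, n_win)
  if (nrow(em_events) > 0) {
    sw <- em_events$subwindow
    has_ev[sw[sw >= 1 & sw <= n_win]] <- TRUE
  }
  labels <- character(n_epochs)
  for (i in seq_len(n_epochs)) {
    w1 <- 2L * i - 1L; w2 <- 2L * i
    neigh <- c(w1 - 1L, w1, w2, w2 + 1L)
    neigh <- neigh[neigh >= 1 & neigh <= n_win]
    if (has_ev[w1] && has_ev[w2]) {
      labels[i] <- "phasic"
    } else if (!any(has_ev[neigh])) {
      labels[i] <- "tonic"
    } else {
      labels[i] <- "unclassified"
    }
  }
  labels
}

#' Generate a synthetic REM sleep episode with ground truth
#'
#' Composes the EM burst schedule, the bilateral EOG rendering and
#' state-switched power-law EEG into a full multichannel recording. Each
#' topographical area receives an independent broken-power-law noise pair
#' (one stream with the tonic low/high-band exponents, one with the phasic
#' exponents, spectra matched at the 30-Hz knee) crossfaded over 0.5 s
#' according to the phasic/tonic schedule, plus the configured narrowband
#' oscillations. A non-zero `coupling_lag_epochs` shifts the
#' spectral state relative to the EM schedule, creating a known lag between
#' aperiodic slopes and eye movement amplitudes.
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed (defaults to `spec$seed`).
#' @return list with components `recording` (a [new_recording()] with
#'   channels Fz, Cz, Pz, O1, LOC, ROC and an all-REM hypnogram) and
#'   `ground_truth` (class `rem_ground_truth`: `$epochs` with per-epoch
#'   label, scripted peak amplitude and true band exponents; `$events`;
#'   `$spec`).
#' @export
synth_rem_episode <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  fs <- spec$sample_rate
  ep_len <- spec$epoch_length
  n_epochs <- floor(spec$duration / ep_len)
  n <- round(spec$duration * fs)

  events <- schedule_em_bursts(spec, seed = child_seed(seed, 1))
  labels <- schedule_labels(events, n_epochs)

  # spectral state, possibly lagged relative to the EM schedule
  lag <- spec$coupling_lag_epochs
  phasic <- labels == "phasic"
  state <- if (lag == 0) phasic else {
    if (lag > 0) c(rep(FALSE, lag), phasic)[seq_len(n_epochs)]
    else c(phasic[(-lag + 1):n_epochs], rep(FALSE, -lag))
  }
  w <- crossfade_weight(state, fs, ep_len, n)

  sh <- spec$exponent_shift
  shape_t <- broken_law_shape(spec$low_exponent_tonic + sh,
                              spec$high_exponent_tonic + sh)
  shape_p <- broken_law_shape(spec$low_exponent_phasic + sh,
                              spec$high_exponent_phasic + sh)
  areas <- c(frontal = "Fz", central = "Cz", parietal = "Pz", occipital = "O1")
  channels <- list()
  for (a in seq_along(areas)) {
    xt <- shaped_noise(n, fs, shape_t, seed = child_seed(seed, 10 + a), sd = spec$eeg_sd)
    xp <- shaped_noise(n, fs, shape_p, seed = child_seed(seed, 20 + a), sd = spec$eeg_sd)
    x <- (1 - w) * xt + w * xp
    if (length(spec$oscillations) > 0) {
      tt <- (seq_len(n) - 1) / fs
      ph <- with_seed(child_seed(seed, 30 + a),
                      stats::runif(length(spec$oscillations), 0, 2 * pi))
      for (o in seq_along(spec$oscillations)) {
        osc <- spec$oscillations[[o]]
        x <- x + osc[2] * sqrt(2) * sin(2 * pi * osc[1] * tt + ph[o])
      }
    }
    channels[[areas[a]]] <- x
  }
  eog <- synth_eog(events, fs, spec$duration, noise_sd = spec$eog_noise_sd,
                   seed = child_seed(seed, 40))
  channels$LOC <- eog$left
  channels$ROC <- eog$right

  rec <- new_recording(
    channels = channels, sample_rate = fs,
    hypnogram = rep("R", ceiling(spec$duration / 30)),
    area_map = list(frontal = "Fz", central = "Cz",
                    parietal = "Pz", occipital = "O1"),
    participant = "synthetic"
  )

  peak_amp <- numeric(n_epochs)
  if (nrow(events) > 0) {
    agg <- tapply(events$peak_amp_uV, events$epoch_index, max)
    idx <- as.integer(names(agg))
    ok <- idx >= 1 & idx <= n_epochs
    peak_amp[idx[ok]] <- agg[ok]
  }
  low_true <- ifelse(state, spec$low_exponent_phasic, spec$low_exponent_tonic) + sh
  high_true <- ifelse(state, spec$high_exponent_phasic, spec$high_exponent_tonic) + sh
  gt <- list(
    epochs = data.frame(
      epoch_index = seq_len(n_epochs),
      start_s = (seq_len(n_epochs) - 1) * ep_len,
      label = labels,
      peak_amp_uV = peak_amp,
      low_exponent = low_true,
      high_exponent = high_true
    ),
    events = events,
    spec = spec
  )
  class(gt) <- "rem_ground_truth"
  list(recording = rec, ground_truth = gt)
}

#' Generate a synthetic cohort of REM recordings
#'
#' Replicates [synth_rem_episode()] across participants, drawing a
#' participant-specific baseline shift of the spectral exponents from a
#' normal law to emulate stable individual differences.
#'
#' @param n_participants number of participants.
#' @param spec template [synthetic_spec()].
#' @param participant_sd standard deviation of the per-participant
#'   exponent baseline shift (dimensionless).
#' @param seed integer seed.
#' @return list of per-participant lists (`recording`, `ground_truth`);
#'   recordings carry participant ids `S01`, `S02`, ...
#' @export
synth_cohort <- function(n_participants, spec = synthetic_spec(),
                         participant_sd = 0.1, seed = spec$seed) {
  stopifnot(n_participants >= 1)
  shifts <- with_seed(child_seed(seed, 999),
                      stats::rnorm(n_participants, 0, participant_sd))
  lapply(seq_len(n_participants), function(i) {
    sp <- spec
    sp$exponent_shift <- spec$exponent_shift + shifts[i]
    out <- synth_rem_episode(sp, seed = child_seed(seed, i))
    out$recording$participant <- sprintf("S%02d", i)
    out
  })
}

#' Generate coupled slope and EM-amplitude epoch series
#'
#' A lightweight series-level generator for the within-episode analysis:
#' the EM amplitude series is a bursty non-negative sequence (log-normal
#' amplitudes inside bursts recurring every 30 epochs, zeros elsewhere) and
#' the slope series responds linearly to the EM series shifted by
#' `lag_epochs`, with Gaussian noise mixed in so the expected rank
#' correlation at the generative lag is about `coupling`. Negative lags
#' make the slope series lead the eye movements.
#'
#' @param n_epochs series length (4-s epochs).
#' @param lag_epochs generative lag in epochs.
#' @param coupling target correlation at the generative lag (0..1); 0 gives
#'   independent series.
#' @param seed integer seed.
#' @return list with numeric `slope` and `em` vectors of length `n_epochs`.
#' @export
synth_coupled_series <- function(n_epochs, lag_epochs = 0, coupling = 0.6,
                                 seed = NULL) {
  stopifnot(n_epochs > 10, abs(coupling) <= 1)
  with_seed(seed, {
    em <- numeric(n_epochs)
    starts <- seq(4, n_epochs - 4, by = 30) +
      sample(-3:3, size = length(seq(4, n_epochs - 4, by = 30)), replace = TRUE)
    for (s in starts) {
      idx <- s:min(n_epochs, s + 3)
      em[idx] <- stats::rlnorm(length(idx), log(180), 0.4)
    }
    drive <- as.numeric(scale(em))
    shifted <- if (lag_epochs == 0) drive else if (lag_epochs > 0) {
      c(rep(0, lag_epochs), drive)[seq_len(n_epochs)]
    } else {
      c(drive[(-lag_epochs + 1):n_epochs], rep(0, -lag_epochs))
    }
    noise <- stats::rnorm(n_epochs)
    slope <- -2.2 + 0.15 * (coupling * shifted + sqrt(1 - coupling^2) * noise)
    list(slope = slope, em = em)
  })
}

#' Write ground-truth epoch labels to CSV with a JSON sidecar
#'
#' @param gt a `rem_ground_truth` from [synth_rem_episode()].
#' @param csv_path output CSV (`epoch_index,start_s,label,peak_amp_uV`).
#' @param json_path optional JSON sidecar holding the generating
#'   [synthetic_spec()].
#' @return invisibly, `csv_path`.
#' @export
write_ground_truth <- function(gt, csv_path, json_path = NULL) {
  stopifnot(inherits(gt, "rem_ground_truth"))
  utils::write.csv(
    gt$epochs[, c("epoch_index", "start_s", "label", "peak_amp_uV")],
    csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    sp <- unclass(gt$spec)
    jsonlite::write_json(sp, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
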