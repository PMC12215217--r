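#' IRASA configuration
#'
#' Holds the resampling factors and analysis bands for the irregularly
#' resampled auto-spectral analysis. The default factor set (1.1 to 1.9 in
#' steps of 0.05) follows the method's canonical description; the bands
#' are the standard low (2-30 Hz), low-control (5-30 Hz) and high
#' (30-48 Hz) fitting ranges used for sleep EEG.
#'
#' @param hset resampling factors, all > 1.
#' @param band_low,band_low_control,band_high fitting bands as
#'   `c(f_lo, f_hi)` in Hz.
#' @param window taper; only `"hann"` is implemented.
#' @return object of class `irasa_config`.
#' @export
irasa_config <- function(hset = seq(1.1, 1.9, by = 0.05),
                         band_low = c(2, 30),
                         band_low_control = c(5, 30),
                         band_high = c(30, 48),
                         window = "hann") {
  stopifnot(all(hset > 1), band_low[1] < band_low[2],
            band_high[1] < band_high[2], window == "hann")
  out <- list(hset = hset, band_low = band_low,
              band_low_control = band_low_control,
              band_high = band_high, window = window)
  class(out) <- "irasa_config"
  out
}

#' Average channels into topographical area signals
#'
#' Sample-wise arithmetic mean of the channels belonging to each
#' topographical area (the conventional groupings are frontal Fz/F3/F4,
#' central Cz/C3/C4, parietal Pz/P3/P4 and occipital O1/O2; any mapping
#' can be supplied).
#'
#' @param channels named list of equal-length numeric vectors (uV).
#' @param area_map named list mapping area name to a character vector of
#'   channel labels.
#' @return named list of numeric vectors, one per area.
#' @export
average_area_signal <- function(channels, area_map) {
  lens <- lengths(channels)
  if (length(unique(lens)) > 1) stop("channels must have equal lengths")
  out <- list()
  for (area in names(area_map)) {
    labs <- area_map[[area]]
    if (anyDuplicated(labs)) {
      stop(sprintf("area '%s' lists channel '%s' more than once",
                   area, labs[duplicated(labs)][1]))
    }
    missing <- setdiff(labs, names(channels))
    if (length(missing) > 0) {
      stop(sprintf("channel '%s' (area '%s') not found in recording",
                   missing[1], area))
    }
    m <- do.call(cbind, channels[labs])
    out[[area]] <- rowMeans(m)
  }
  out
}

#' One-sided Hann-tapered periodogram
#'
#' Single-taper power spectral density of one analysis segment (density
#' scaling, uV^2/Hz): the segment is demeaned, multiplied by a periodic
#' Hann window and Fourier transformed; one-sided power is normalized by
#' `sample_rate * sum(w^2)` so that `sum(power) * df` matches the signal
#' variance (Parseval, after taper correction). A 4-s segment yields the
#' 0.25-Hz grid used throughout.
#'
#' @param signal numeric vector (uV), at least one second of samples.
#' @param sample_rate sampling rate in Hz.
#' @return list with `freqs` (Hz, from 0 to Nyquist) and `power`
#'   (uV^2/Hz).
#' @export
compute_psd <- function(signal, sample_rate) {
  n <- length(signal)
  if (n < sample_rate) stop("need at least one second of samples")
  if (any(!is.finite(signal))) stop("signal contains non-finite samples")
  x <- signal - mean(signal)
  w <- hann_window(n)
  X <- stats::fft(x * w)
  half <- n %/% 2
  idx <- 1:(half + 1)
  p <- (Mod(X[idx])^2) / (sample_rate * sum(w^2))
  scale2 <- rep(2, length(idx))
  scale2[1] <- 1
  if (n %% 2 == 0) scale2[length(idx)] <- 1
  list(freqs = (idx - 1) * sample_rate / n, power = p * scale2)
}

# Periodogram of a resampled series expressed on a caller-supplied grid.
# The resampled series is treated as if it still had the nominal sampling
# rate, which maps physical frequency f onto h*f of the original process;
# interpolation is linear in log-log coordinates, where a power law is
# exactly linear.
resampled_psd_on_grid <- function(x, sample_rate, target_freqs) {
  ps <- compute_psd(x, sample_rate)
  pos <- ps$freqs > 0 & ps$power > 0
  lf <- log(ps$freqs[pos]); lp <- log(ps$power[pos])
  out <- rep(NA_real_, length(target_freqs))
  tpos <- target_freqs > 0
  ap <- stats::approx(lf, lp, xout = log(target_freqs[tpos]), rule = 2)
  out[tpos] <- exp(ap$y)
  out[!tpos] <- ps$power[1]
  out
}

#' IRASA decomposition of one analysis segment
#'
#' Separates the power spectrum of an EEG segment into its fractal
#' (aperiodic) and oscillatory components. For every factor `h` in the
#' configured set the segment is resampled by `h` and by `1/h`
#' (Fourier-domain resampling with ideal anti-aliasing); both spectra are
#' evaluated on the segment's original frequency grid and their geometric
#' mean taken. A power law is a fixed point of this operation, whereas
#' narrowband peaks are displaced to `f/h` and `f*h` and suppressed by the
#' median across the factor set. The fractal component is that median; the
#' oscillatory component is the bin-wise remainder `total - fractal`.
#'
#' @param signal numeric vector (uV), one analysis segment.
#' @param sample_rate sampling rate in Hz.
#' @param cfg an [irasa_config()]. The highest analysed frequency times
#'   `max(hset)` must stay below the Nyquist frequency.
#' @return object of class `spectral_decomposition`: list with `freqs`,
#'   `total`, `fractal`, `oscillatory` (all per-bin, uV^2/Hz;
#'   `total == fractal + oscillatory` exactly).
#' @export
irasa_decompose <- function(signal, sample_rate, cfg = irasa_config()) {
  f_top <- max(cfg$band_low[2], cfg$band_high[2])
  if (f_top * max(cfg$hset) >= sample_rate / 2) {
    stop(sprintf(
      "Nyquist constraint violated: %.1f Hz x h=%.2f = %.1f Hz exceeds %.1f Hz",
      f_top, max(cfg$hset), f_top * max(cfg$hset), sample_rate / 2))
  }
  total <- compute_psd(signal, sample_rate)
  n <- length(signal)
  gm <- matrix(NA_real_, nrow = length(cfg$hset), ncol = length(total$freqs))
  for (i in seq_along(cfg$hset)) {
    h <- cfg$hset[i]
    up <- fft_resample(signal, round(n * h))
    dn <- fft_resample(signal, round(n / h))
    p_up <- resampled_psd_on_grid(up, sample_rate, total$freqs)
    p_dn <- resampled_psd_on_grid(dn, sample_rate, total$freqs)
    gm[i, ] <- sqrt(p_up * p_dn)
  }
  fractal <- apply(gm, 2, stats::median)
  out <- list(freqs = total$freqs, total = total$power,
              fractal = fractal, oscillatory = total$power - fractal)
  class(out) <- "spectral_decomposition"
  out
}

#' Fit the aperiodic (power-law) slope of a spectrum
#'
#' Ordinary least squares of `log10(power)` on `log10(frequency)` over the
#' bins inside `band` (edges inclusive). Applied to the fractal component
#' of a [irasa_decompose()] result this estimates the spectral exponent of
#' the aperiodic activity; the slope is negative in sleep EEG.
#'
#' @param dec a `spectral_decomposition`, or any list with `freqs` and the
#'   component named by `component`.
#' @param band `c(f_lo, f_hi)` in Hz, `f_lo < f_hi`; at least 3 bins must
#'   fall inside.
#' @param component which spectrum to fit: `"fractal"` (default) or
#'   `"total"`.
#' @return object of class `aperiodic_fit`: list with `band`, `slope`
#'   (dimensionless, dlog10 power / dlog10 frequency), `intercept`
#'   (log10 uV^2/Hz at 1 Hz), `r_squared` and `n_bins`.
#' @export
fit_aperiodic_slope <- function(dec, band, component = c("fractal", "total")) {
  component <- match.arg(component)
  stopifnot(band[1] < band[2])
  pw <- dec[[component]]
  sel <- dec$freqs >= band[1] - 1e-9 & dec$freqs <= band[2] + 1e-9
  f <- dec$freqs[sel]
  p <- pw[sel]
  if (length(f) < 3) stop("fewer than 3 frequency bins inside the band")
  if (any(!is.finite(p)) || any(p <= 0)) {
    stop("non-positive power in band: spectral decomposition failed numerically")
  }
  lx <- log10(f); ly <- log10(p)
  mx <- mean(lx); my <- mean(ly)
  sxx <- sum((lx - mx)^2)
  slope <- sum((lx - mx) * (ly - my)) / sxx
  intercept <- my - slope * mx
  res <- ly - (intercept + slope * lx)
  r2 <- if (sum((ly - my)^2) == 0) 1 else 1 - sum(res^2) / sum((ly - my)^2)
  out <- list(band = band, slope = slope, intercept = intercept,
              r_squared = max(0, min(1, r2)), n_bins = length(f))
  class(out) <- "aperiodic_fit"
  out
}

#' Per-epoch aperiodic slopes for every area and band
#'
#' Splits each area-averaged signal of a recording into consecutive 4-s
#' epochs, IRASA-decomposes every epoch and fits the aperiodic slope in
#' the configured low and high bands. Epochs containing non-finite samples
#' or failing the fit preconditions yield `NA` slopes (never a silent
#' zero).
#'
#' @param recording a [new_recording()].
#' @param cfg an [irasa_config()].
#' @param epoch_length epoch length in seconds.
#' @param epochs optional integer vector of 1-based epoch indices to
#'   compute (default: all whole epochs in the recording).
#' @param bands named list of bands to fit; defaults to the config's low
#'   and high bands.
#' @return data.frame with columns `epoch_index`, `start_s`, `area`,
#'   `band`, `slope`, `intercept`, `r2`.
#' @export
epoch_slopes <- function(recording, cfg = irasa_config(), epoch_length = 4,
                         epochs = NULL,
                         bands = list(low = cfg$band_low, high = cfg$band_high)) {
  stopifnot(inherits(recording, "recording"))
  fs <- recording$sample_rate
  spe <- round(epoch_length * fs)
  eeg <- recording$channels[setdiff(names(recording$channels),
                                    unlist(recording$eog))]
  areas <- average_area_signal(eeg, recording$area_map)
  n_total <- length(areas[[1]]) %/% spe
  if (is.null(epochs)) epochs <- seq_len(n_total)
  if (length(epochs) > 0 && (min(epochs) < 1 || max(epochs) > n_total)) {
    stop("requested epochs extend beyond the recording")
  }
  rows <- vector("list", length(epochs) * length(areas) * length(bands))
  k <- 0L
  for (area in names(areas)) {
    x <- areas[[area]]
    for (ep in epochs) {
      seg <- x[((ep - 1L) * spe + 1L):(ep * spe)]
      fits <- NULL
      if (all(is.finite(seg)) && stats::sd(seg) > 0) {
        dec <- irasa_decompose(seg, fs, cfg)
        fits <- lapply(bands, function(b) {
          tryCatch(fit_aperiodic_slope(dec, b), error = function(e) NULL)
        })
      }
      for (bn in names(bands)) {
        k <- k + 1L
        ft <- fits[[bn]]
        rows[[k]] <- data.frame(
          epoch_index = ep, start_s = (ep - 1) * epoch_length,
          area = area, band = bn,
          slope = if (is.null(ft)) NA_real_ else ft$slope,
          intercept = if (is.null(ft)) NA_real_ else ft$intercept,
          r2 = if (is.null(ft)) NA_real_ else ft$r_squared
        )
      }
    }
  }
  do.call(rbind, rows[seq_len(k)])
}

#' @export
print.spectral_decomposition <- function(x, ...) {
  cat(sprintf(
    "<spectral_decomposition> %d bins, %.2f-%.2f Hz (df = %.3g Hz)\n",
    length(x$freqs), min(x$freqs), max(x$freqs), x$freqs[2] - x$freqs[1]))
  invisible(x)
}

#' @export
print.aperiodic_fit <- function(x, ...) {
  cat(sprintf("<aperiodic_fit> band %g-%g Hz: slope %.3f (r^2 %.3f, %d bins)\n",
              x$band[1], x$band[2], x$slope, x$r_squared, x$n_bins))
  invisible(x)
}
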