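# Internal numerical helpers shared across modules.

# Periodic Hann taper (DFT-consistent).
hann_window <- function(n) {
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)
}

# Fourier-domain resampling of a real series to n_out samples spanning the
# same physical duration. Band limitation is exact: frequencies at or above
# the smaller of the two Nyquists are dropped, so downsampling is ideally
# anti-aliased. Amplitudes of retained components are preserved.
fft_resample <- function(x, n_out) {
  n <- length(x)
  n_out <- as.integer(round(n_out))
  if (n_out == n) return(x)
  X <- stats::fft(x)
  m <- min(n, n_out)
  # number of strictly-positive frequencies below the smaller Nyquist
  npos <- if (m %% 2 == 0) m %/% 2 - 1 else (m - 1) %/% 2
  Y <- rep(0 + 0i, n_out)
  Y[1] <- X[1]
  if (npos > 0) {
    Y[2:(npos + 1)] <- X[2:(npos + 1)]
    Y[(n_out - npos + 1):n_out] <- X[(n - npos + 1):n]
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

# Centered rolling maximum with an odd window of k samples, computed as a
# pmax over shifted copies (edges fall back to the available samples).
rolling_max <- function(x, k) {
  k <- max(1L, as.integer(k))
  half <- (k - 1L) %/% 2L
  if (half == 0L) return(x)
  n <- length(x)
  out <- x
  for (s in seq_len(half)) {
    lead <- c(x[-seq_len(s)], rep(-Inf, s))
    lag <- c(rep(-Inf, s), x[seq_len(n - s)])
    out <- pmax(out, lead, lag)
  }
  out
}

# Zero-phase Butterworth band-pass.
bandpass_filter <- function(x, sample_rate, lo, hi, order = 3) {
  ny <- sample_rate / 2
  stopifnot(lo > 0, hi > lo, hi < ny)
  bf <- signal::butter(order, c(lo, hi) / ny, type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# Contiguous runs of TRUE as a two-column matrix of start/end indices.
logical_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched. `seed = NULL` uses the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.finite(seed)) stop("seed must be a finite integer")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible child seed bounded below 2^31.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 7919 + k * 104729) %% 2147483629)
}
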