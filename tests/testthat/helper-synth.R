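# Shared synthetic fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

synth_fixture <- function(duration = 720, seed = 42, ...) {
  key <- paste0("ep_", duration, "_", seed, "_",
                paste(unlist(list(...)), collapse = "_"))
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <-
      synth_rem_episode(synthetic_spec(duration = duration, seed = seed, ...))
  }
  .fixture_cache[[key]]
}

# Match detected events to scripted ones by extremum proximity (the
# scripted extremum sits mid-event); returns the scripted row index per
# detected event, NA when nothing lies within `tol` seconds.
match_events <- function(detected, scripted, tol = 0.3) {
  if (nrow(detected) == 0) return(integer(0))
  mid <- scripted$onset_s + scripted$duration_s / 2
  vapply(detected$extremum_s, function(t) {
    i <- which.min(abs(mid - t))
    if (length(i) == 1 && abs(mid[i] - t) < tol) i else NA_integer_
  }, integer(1))
}

# One biphasic anti-phase EOG deflection (a full sine cycle) on a quiet
# background, for detector unit tests.
make_deflection_pair <- function(peak, duration, fs = 250, total = 20,
                                 onset = 10, noise_sd = 0, seed = 1) {
  ev <- data.frame(onset_s = onset, duration_s = duration,
                   peak_amp_uV = peak, epoch_index = NA, subwindow = NA)
  synth_eog(ev, fs, total, noise_sd = noise_sd, seed = seed)
}
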