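test_that("power-law synthesis is deterministic under seed and decorrelated across seeds", {
  a <- synth_aperiodic_signal(-2, 250, 8, seed = 7)
  b <- synth_aperiodic_signal(-2, 250, 8, seed = 7)
  expect_identical(a, b)
  expect_equal(mean(a), 0, tolerance = 1e-10)
  # independence across seeds, checked where the effective sample size is
  # large (a steep power law concentrates variance in a handful of
  # low-frequency components, so its empirical correlations are broad)
  w1 <- synth_aperiodic_signal(0, 250, 8, seed = 7)
  w2 <- synth_aperiodic_signal(0, 250, 8, seed = 8)
  expect_lt(abs(cor(w1, w2)), 0.1)
})

test_that("white-noise limit yields a near-zero fitted slope", {
  x <- synth_aperiodic_signal(0, 250, 120, seed = 2)
  sl <- vapply(1:30, function(ep) {
    seg <- x[((ep - 1) * 1000 + 1):(ep * 1000)]
    fit_aperiodic_slope(irasa_decompose(seg, 250), c(2, 30))$slope
  }, numeric(1))
  expect_lt(abs(median(sl)), 0.1)
})

test_that("a -2.5 exponent is recovered by the per-epoch spectral fit", {
  x <- synth_aperiodic_signal(-2.5, 250, 200, seed = 3)
  sl <- vapply(1:50, function(ep) {
    seg <- x[((ep - 1) * 1000 + 1):(ep * 1000)]
    fit_aperiodic_slope(irasa_decompose(seg, 250), c(2, 30))$slope
  }, numeric(1))
  expect_lt(abs(median(sl) - (-2.5)), 0.1)
})

test_that("signal synthesis rejects invalid arguments", {
  expect_error(synth_aperiodic_signal(NaN, 250, 10), "finite")
  expect_error(synth_aperiodic_signal(1, 250, 10), "<= 0")
  expect_error(synth_aperiodic_signal(-2, 250, 0), "positive")
})

test_that("EM burst scheduling follows the infra-slow period", {
  sp <- synthetic_spec(duration = 720, seed = 5)
  ev <- schedule_em_bursts(sp)
  # bursts every ~120 s over 720 s: 6 +- 1 burst groups
  gaps <- which(diff(sort(unique(ev$epoch_index))) > 2)
  n_bursts <- length(gaps) + 1
  expect_gte(n_bursts, 5)
  expect_lte(n_bursts, 7)
  # determinism and the zero-rate edge case
  expect_identical(ev, schedule_em_bursts(sp))
  sp0 <- synthetic_spec(duration = 720, em_rate_in_burst = 0)
  expect_identical(nrow(schedule_em_bursts(sp0)), 0L)
  expect_error(schedule_em_bursts(synthetic_spec(em_rate_in_burst = 3)),
               "infeasible")
  # no overlap, amplitudes above the phasic threshold
  o <- order(ev$onset_s)
  expect_true(all(diff(ev$onset_s[o]) >= ev$duration_s[o][-nrow(ev)]))
  expect_true(all(ev$peak_amp_uV >= 150))
  expect_true(all(ev$duration_s >= 0.3 & ev$duration_s <= 0.5))
})

test_that("EOG rendering reaches the scripted peak in anti-phase", {
  eog <- make_deflection_pair(peak = 200, duration = 0.3)
  il <- which.max(abs(eog$left))
  expect_lt(abs(max(abs(eog$left)) - 200) / 200, 0.1)
  expect_lt(abs(max(abs(eog$right)) - 200) / 200, 0.1)
  expect_lt(eog$left[il] * eog$right[il], 0)
})

test_that("event-free EOG stays below the tonic quiescence bound", {
  eog <- synth_eog(data.frame(onset_s = numeric(0), duration_s = numeric(0),
                              peak_amp_uV = numeric(0)),
                   250, 120, noise_sd = 5, seed = 9)
  expect_lt(max(abs(eog$left)), 25)
  expect_lt(max(abs(eog$right)), 25)
  expect_warning(synth_eog(data.frame(onset_s = 1, duration_s = 0.3,
                                      peak_amp_uV = 200),
                           250, 10, noise_sd = 30, seed = 1),
                 "quiescence")
  expect_error(synth_eog(data.frame(onset_s = 9.9, duration_s = 0.4,
                                    peak_amp_uV = 200),
                         250, 10, seed = 1), "fit inside")
})

test_that("two EMs in adjacent 2-s windows make the epoch phasic downstream", {
  ev <- data.frame(onset_s = c(8.6, 10.4), duration_s = c(0.4, 0.4),
                   peak_amp_uV = c(200, 220))
  eog <- synth_eog(ev, 250, 16, noise_sd = 5, seed = 4)
  seg <- segment_rem(eog$left, eog$right, 250)
  expect_identical(seg$label[3], "phasic")
})

test_that("ground-truth labels satisfy their construction invariants", {
  fx <- synth_fixture()
  gt <- fx$ground_truth
  ev <- gt$events
  for (i in which(gt$epochs$label == "phasic")) {
    sw <- ev$subwindow[ev$epoch_index == i]
    expect_true(all(c(2 * i - 1, 2 * i) %in% sw))
  }
  tonic_idx <- gt$epochs$epoch_index[gt$epochs$label == "tonic"]
  expect_false(any(ev$epoch_index %in% tonic_idx))
  expect_true(all(table(gt$epochs$label)[c("phasic", "tonic")] > 0))
})

test_that("an all-tonic spec yields zero phasic epochs and pure exponents", {
  fx <- synth_fixture(duration = 240, seed = 12, em_rate_in_burst = 0)
  expect_identical(sum(fx$ground_truth$epochs$label == "phasic"), 0L)
  expect_true(all(fx$ground_truth$epochs$low_exponent ==
                    fx$ground_truth$spec$low_exponent_tonic))
})

test_that("whole-episode synthesis is reproducible and writable", {
  a <- synth_rem_episode(synthetic_spec(duration = 60, seed = 21))
  b <- synth_rem_episode(synthetic_spec(duration = 60, seed = 21))
  expect_identical(a$recording$channels, b$recording$channels)
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_ground_truth(a$ground_truth, csv, js)
  back <- read.csv(csv)
  expect_identical(nrow(back), nrow(a$ground_truth$epochs))
  expect_identical(jsonlite::fromJSON(js)$seed, 21L)
})
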