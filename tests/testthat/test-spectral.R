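test_that("area averaging is the sample-wise mean over the mapped channels", {
  ch <- list(Fz = c(1, 2, 3), F3 = c(3, 2, 1), F4 = c(2, 2, 2), O1 = c(0, 0, 0))
  out <- average_area_signal(ch, list(frontal = c("Fz", "F3", "F4"),
                                      occipital = "O1"))
  expect_equal(out$frontal, c(2, 2, 2))
  expect_equal(out$occipital, ch$O1)  # single channel: identity
  expect_error(average_area_signal(ch, list(frontal = c("Fz", "Fz"))),
               "more than once")
  expect_error(average_area_signal(ch, list(occipital = c("O1", "O2"))), "O2")
})

test_that("the periodogram concentrates a sinusoid and satisfies Parseval", {
  fs <- 256
  tt <- (0:(4 * fs - 1)) / fs
  ps <- compute_psd(sin(2 * pi * 10 * tt), fs)
  inband <- abs(ps$freqs - 10) <= 0.25
  expect_gt(sum(ps$power[inband]) / sum(ps$power), 0.99)
  expect_equal(compute_psd(rep(0, 4 * fs), fs)$power,
               rep(0, 2 * fs + 1))
  set.seed(11)
  x <- rnorm(600 * 250, sd = 2)
  ps <- compute_psd(x, 250)
  df <- ps$freqs[2] - ps$freqs[1]
  expect_lt(abs(sum(ps$power) * df - 4) / 4, 0.01)
  expect_error(compute_psd(c(rep(0, 300), NA), 250), "non-finite")
})

test_that("IRASA leaves a pure power law in the fractal component", {
  x <- synth_aperiodic_signal(-2, 250, 80, seed = 13)
  dec <- irasa_decompose(x[1:1000], 250)
  expect_equal(dec$total, dec$fractal + dec$oscillatory)  # bin-exact
  # the power law is a fixed point of the h/1-h geometric mean up to a
  # frequency-independent small-sample factor (geometric means of
  # single-taper chi-square bins shrink the level, never the slope): the
  # fractal and total fits agree, and no structured residual appears
  decs <- lapply(1:20, function(ep)
    irasa_decompose(x[((ep - 1) * 1000 + 1):(ep * 1000)], 250))
  sl_frac <- vapply(decs, function(d)
    fit_aperiodic_slope(d, c(2, 48), "fractal")$slope, numeric(1))
  sl_tot <- vapply(decs, function(d)
    fit_aperiodic_slope(d, c(2, 48), "total")$slope, numeric(1))
  expect_lt(abs(median(sl_frac) - median(sl_tot)), 0.05)
  mean_osc <- rowMeans(vapply(decs, `[[`, numeric(501), "oscillatory"))
  mean_tot <- rowMeans(vapply(decs, `[[`, numeric(501), "total"))
  band <- decs[[1]]$freqs >= 2 & decs[[1]]$freqs <= 48
  ratio <- mean_osc[band] / mean_tot[band]
  expect_lt(median(abs(ratio)), 0.5)
})

test_that("IRASA rejects an added oscillation from the fractal fit", {
  x <- synth_aperiodic_signal(-2, 250, 120, seed = 14)
  tt <- (seq_along(x) - 1) / 250
  x_osc <- x + 4 * sqrt(2) * sin(2 * pi * 10 * tt)
  fit_med <- function(sig, comp) {
    median(vapply(1:30, function(ep) {
      seg <- sig[((ep - 1) * 1000 + 1):(ep * 1000)]
      fit_aperiodic_slope(irasa_decompose(seg, 250), c(2, 30),
                          component = comp)$slope
    }, numeric(1)))
  }
  dec <- irasa_decompose(x_osc[1:1000], 250)
  i10 <- which(dec$freqs == 10)
  expect_gt(dec$oscillatory[i10] / dec$fractal[i10], 3)
  # oscillatory residual peaks at the 10-Hz bin
  inband <- dec$freqs >= 2 & dec$freqs <= 48
  expect_equal(dec$freqs[inband][which.max(dec$oscillatory[inband])], 10)
  shift_fractal <- abs(fit_med(x_osc, "fractal") - fit_med(x, "fractal"))
  shift_total <- abs(fit_med(x_osc, "total") - fit_med(x, "total"))
  expect_lt(shift_fractal, 0.1)
  expect_gt(shift_total, 2 * shift_fractal)
})

test_that("the Nyquist precondition is enforced with a helpful message", {
  x <- synth_aperiodic_signal(-2, 150, 4, seed = 1)
  expect_error(irasa_decompose(x, 150), "91.2")
})

test_that("log-log OLS recovers exact power laws", {
  f <- seq(0, 125, by = 0.25)
  dec <- list(freqs = f, fractal = c(NA, 3 * f[-1]^-2))
  fit <- fit_aperiodic_slope(dec, c(2, 30))
  expect_equal(fit$slope, -2, tolerance = 1e-6)
  expect_gt(fit$r_squared, 1 - 1e-9)
  flat <- list(freqs = f, fractal = c(NA, rep(5, length(f) - 1)))
  expect_equal(fit_aperiodic_slope(flat, c(2, 30))$slope, 0)
  expect_error(fit_aperiodic_slope(dec, c(2, 2.2)), "fewer than 3")
  bad <- list(freqs = f, fractal = rep(-1, length(f)))
  expect_error(fit_aperiodic_slope(bad, c(2, 30)), "non-positive")
})

test_that("epoch_slopes produces one row per epoch, area and band", {
  fx <- synth_fixture(duration = 120, seed = 33)
  rec <- fx$recording
  sl <- epoch_slopes(rec)
  expect_identical(nrow(sl), 30L * 4L * 2L)
  expect_true(all(c("frontal", "central", "parietal", "occipital") %in% sl$area))
  expect_true(all(is.finite(sl$slope)))
  # an epoch with non-finite samples yields a missing marker, never a zero
  rec$channels$Fz[1001:1005] <- NaN
  sl2 <- epoch_slopes(rec)
  expect_true(all(is.na(sl2$slope[sl2$epoch_index == 2 & sl2$area == "frontal"])))
  expect_true(all(is.finite(sl2$slope[sl2$area == "central"])))
  expect_error(epoch_slopes(rec, epochs = 31L), "beyond")
})

test_that("the fitted slope decreases monotonically with the generative exponent", {
  med <- vapply(c(-1, -2, -3), function(a) {
    x <- synth_aperiodic_signal(a, 250, 80, seed = 17)
    median(vapply(1:20, function(ep) {
      seg <- x[((ep - 1) * 1000 + 1):(ep * 1000)]
      fit_aperiodic_slope(irasa_decompose(seg, 250), c(2, 30))$slope
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med) < 0))
})
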