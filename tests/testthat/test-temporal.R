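test_that("episode selection keeps only REM runs longer than 10 minutes", {
  hyp <- c(rep("N2", 4), rep("R", 24), rep("N2", 2), rep("R", 18),
           rep("W", 1), rep("R", 25))
  eps <- select_episodes(hyp)
  # 12-min run kept, 9-min run dropped, runs split by the interruptions
  expect_identical(nrow(eps), 2L)
  expect_equal(eps$duration_s, c(720, 750))
  expect_equal(eps$start_s[1], 120)
  expect_error(select_episodes(character(0)), "empty")
  expect_identical(nrow(select_episodes(rep("R", 20))), 0L)  # exactly 10 min
})

test_that("mid-ranks are assigned to ties", {
  expect_equal(rank_with_ties(c(10, 20, 30)), c(1, 2, 3))
  expect_equal(rank_with_ties(c(5, 5, 9)), c(1.5, 1.5, 3))
  expect_equal(rank_with_ties(rep(7, 4)), rep(2.5, 4))
  expect_error(rank_with_ties(c(1, NA)), "finite")
})

test_that("cross-correlation peaks where the construction places it", {
  set.seed(5)
  s <- rnorm(200)
  em <- c(rnorm(2), s[1:198])  # em is the slope series delayed by 2 epochs
  cc <- cross_correlate(s, em, max_lag_s = 60)
  expect_identical(cc$lag_s[which.max(abs(cc$r))], -8)  # slope leads
  cc0 <- cross_correlate(s, s, max_lag_s = 20)
  expect_equal(cc0$r[cc0$lag_s == 0], 1)
  expect_true(cc0$significant[cc0$lag_s == 0])
})

test_that("cross-correlation is antisymmetric under argument exchange", {
  set.seed(6)
  x <- rnorm(80); y <- rnorm(80)
  a <- cross_correlate(x, y, max_lag_s = 40)
  b <- cross_correlate(y, x, max_lag_s = 40)
  expect_equal(a$r, rev(b$r))
  expect_equal(a$z, atanh(a$r))
})

test_that("overlaps of four or fewer epochs are marked missing", {
  set.seed(7)
  cc <- cross_correlate(rnorm(12), rnorm(12), max_lag_s = 44)
  expect_true(all(is.na(cc$r[cc$n <= 4])))
  expect_true(all(!is.na(cc$r[cc$n > 4])))
  expect_error(cross_correlate(rnorm(5), rnorm(5)), "more than 10")
  expect_error(cross_correlate(rnorm(20), rnorm(21)), "equal length")
})

test_that("per-lag significance is calibrated near alpha on independent series", {
  rates <- vapply(1:40, function(i) {
    set.seed(i)
    cc <- cross_correlate(rnorm(250), rnorm(250))
    mean(cc$significant, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.05), 0.03)
})

test_that("pooling averages Fisher z across episodes", {
  set.seed(8)
  cs <- synth_coupled_series(160, 0, 0.6, seed = 1)
  one <- cross_correlate(cs$slope, cs$em, max_lag_s = 40)
  pooled1 <- pool_episode_correlations(list(one))
  expect_equal(pooled1$mean_z, one$z)
  flipped <- one; flipped$z <- -one$z
  pooled2 <- pool_episode_correlations(list(one, flipped))
  expect_equal(pooled2$mean_z, rep(0, nrow(one)), tolerance = 1e-12)
  expect_error(pool_episode_correlations(list()), "at least one")
})

test_that("pooled lag recovery matches the generative coupling lag", {
  for (L in c(-2, 0, 2)) {
    res <- lapply(1:8, function(i) {
      cs <- synth_coupled_series(160, L, 0.6, seed = 100 * L + i)
      cross_correlate(cs$slope, cs$em, max_lag_s = 60)
    })
    pc <- pool_episode_correlations(res)
    expect_identical(pc$lag_s[which.max(abs(pc$mean_z))], 4L * L)
  }
})

test_that("episode-centred effect sizes count significant episodes", {
  coupled <- lapply(1:6, function(i) {
    cs <- synth_coupled_series(160, 0, 0.7, seed = i)
    cross_correlate(cs$slope, cs$em, max_lag_s = 20)
  })
  es <- episode_effect_size(coupled)
  expect_equal(es$proportion, es$k / es$n)
  expect_identical(es$n, 6L)
  expect_gt(es$proportion, 0.5)
  null <- lapply(1:6, function(i) {
    set.seed(i)
    cross_correlate(rnorm(160), rnorm(160), max_lag_s = 20)
  })
  es0 <- episode_effect_size(null, sign = "negative")
  expect_lte(es0$k, es0$n)
  expect_error(episode_effect_size(coupled, lag_window = c(900, 900)),
               "outside")
})

test_that("the prevalence MAP matches its closed form and the HPDI covers it", {
  for (kn in list(c(0, 10), c(2, 40), c(12, 40), c(40, 40), c(7, 19))) {
    pv <- bayesian_prevalence(kn[1], kn[2])
    cf <- max(0, (kn[1] / kn[2] - 0.05) / 0.95)
    expect_lt(abs(pv$map_estimate - cf), 0.001)
    expect_gte(pv$map_estimate, pv$hpdi[1])
    expect_lte(pv$map_estimate, pv$hpdi[2])
  }
  expect_equal(bayesian_prevalence(12, 40)$map_estimate, 0.263, tolerance = 0.001)
  expect_error(bayesian_prevalence(5, 4), "k <= n")
  expect_error(bayesian_prevalence(2, 4, alpha = 1), "alpha")
})
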