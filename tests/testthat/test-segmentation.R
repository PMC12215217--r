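make_eog_with <- function(deflections, total = 20, fs = 250) {
  # deflections: data.frame(onset, duration, peak); rendered as one
  # rectangular-ish excursion so the above-threshold extent is controlled
  x <- numeric(total * fs)
  for (i in seq_len(nrow(deflections))) {
    i0 <- round(deflections$onset[i] * fs) + 1
    i1 <- round((deflections$onset[i] + deflections$duration[i]) * fs)
    x[i0:i1] <- deflections$peak[i]
  }
  x
}

test_that("2-s windows are flagged by the amplitude and duration rules", {
  fs <- 250
  em <- make_eog_with(data.frame(onset = 0.8, duration = 0.3, peak = 200),
                      total = 2)
  expect_identical(find_deflections(em, fs)[1], "EM")
  sustained <- make_eog_with(data.frame(onset = 0.6, duration = 0.8, peak = 200),
                             total = 2)
  expect_identical(find_deflections(sustained, fs)[1], "intermediate")
  quiet <- rep(20, 2 * fs) * sin(seq_len(2 * fs) / 40)
  expect_identical(find_deflections(quiet, fs)[1], "quiescent")
  mid <- rep(60, 2 * fs)
  expect_identical(find_deflections(mid, fs)[1], "intermediate")
})

test_that("epochs classify by the adjacent-subwindow rules", {
  lab <- function(flags) classify_epochs(flags)$label
  expect_identical(lab(c("EM", "EM")), "phasic")
  expect_identical(lab(c("quiescent", "quiescent")), "tonic")
  expect_identical(lab(c("EM", "quiescent")), "unclassified")
  # a neighbouring EM window breaks the tonic rule for the middle epoch
  fl <- c("EM", "EM", "quiescent", "quiescent", "quiescent", "quiescent")
  expect_identical(lab(fl), c("phasic", "unclassified", "tonic"))
  expect_error(classify_epochs(c("EM", "EM", "EM")), "whole epochs")
})

test_that("the 8-s separation rule keeps the earliest candidate of a run", {
  labs <- data.frame(epoch_index = 1:2, start_s = c(0, 4),
                     label = c("phasic", "tonic"))
  out <- enforce_separation(labs)
  expect_identical(out$kept, c(TRUE, FALSE))       # 0-s gap: second excluded
  labs2 <- data.frame(epoch_index = 1:4, start_s = c(0, 4, 8, 12),
                      label = c("phasic", "unclassified", "unclassified", "tonic"))
  out2 <- enforce_separation(labs2)
  expect_identical(out2$kept, c(TRUE, FALSE, FALSE, TRUE))  # exactly 8 s apart
  expect_identical(nrow(enforce_separation(labs2[0, ])), 0L)
  expect_identical(out2$label, labs2$label)        # labels never change class
})

test_that("kept segments of a synthetic episode are pairwise >= 8 s apart", {
  fx <- synth_fixture()
  rec <- fx$recording
  seg <- segment_rem(rec$channels$LOC, rec$channels$ROC, rec$sample_rate)
  kept <- seg[seg$kept, ]
  if (nrow(kept) > 1) {
    gaps <- diff(sort(kept$start_s)) - 4
    expect_true(all(gaps >= 8))
  }
  expect_gt(nrow(kept), 0)
})

test_that("segmentation reproduces the scripted ground truth", {
  fx <- synth_fixture()
  rec <- fx$recording
  truth <- fx$ground_truth$epochs$label
  seg <- segment_rem(rec$channels$LOC, rec$channels$ROC, rec$sample_rate)
  est <- seg$label[seq_along(truth)]
  phasic_recall <- mean(est[truth == "phasic"] == "phasic")
  expect_gte(phasic_recall, 0.95)
  expect_identical(sum(truth == "tonic" & est == "phasic"), 0L)
})

test_that("raising the quiescence bound never decreases the tonic count", {
  fx <- synth_fixture(duration = 240, seed = 77, eog_noise_sd = 12)
  rec <- fx$recording
  counts <- vapply(c(15, 25, 60), function(th) {
    cfg <- segmentation_config(tonic_max_amplitude = th)
    seg <- segment_rem(rec$channels$LOC, rec$channels$ROC, rec$sample_rate, cfg)
    sum(seg$label == "tonic")
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})
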