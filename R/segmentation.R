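#' Phasic/tonic segmentation configuration
#'
#' The scoring thresholds for the binary REM microstate classification:
#' a 2-s window counts as containing an eye movement (EM) when an EOG
#' deflection exceeds 150 uV with an above-threshold extent shorter than
#' 500 ms; it counts as quiescent when all EOG excursions stay below
#' 25 uV; selected segments must lie at least 8 s apart.
#'
#' @param window epoch length in s (4).
#' @param subwindow scoring subwindow in s (2; must divide `window`).
#' @param phasic_min_amplitude EM amplitude threshold in uV.
#' @param phasic_max_duration maximum above-threshold extent in s.
#' @param tonic_max_amplitude quiescence bound in uV.
#' @param min_separation minimum edge-to-edge separation of selected
#'   segments in s.
#' @return object of class `segmentation_config`.
#' @export
segmentation_config <- function(window = 4, subwindow = 2,
                                phasic_min_amplitude = 150,
                                phasic_max_duration = 0.5,
                                tonic_max_amplitude = 25,
                                min_separation = 8) {
  stopifnot(window > 0, subwindow > 0, window %% subwindow == 0,
            phasic_min_amplitude > 0, tonic_max_amplitude > 0,
            phasic_max_duration > 0, min_separation >= 0)
  out <- list(window = window, subwindow = subwindow,
              phasic_min_amplitude = phasic_min_amplitude,
              phasic_max_duration = phasic_max_duration,
              tonic_max_amplitude = tonic_max_amplitude,
              min_separation = min_separation)
  class(out) <- "segmentation_config"
  out
}

#' Flag 2-s EOG windows as EM, quiescent or intermediate
#'
#' A window is `EM` if it contains a deflection whose absolute excursion
#' exceeds the phasic amplitude threshold and whose contiguous
#' above-threshold extent is shorter than the maximum duration
#' (deflections straddling a window edge are assigned to the window
#' holding their largest sample); `quiescent` if every excursion stays
#' below the tonic bound; otherwise `intermediate`.
#'
#' @param eog numeric EOG series in uV.
#' @param sample_rate sampling rate in Hz.
#' @param cfg a [segmentation_config()].
#' @return character vector, one flag per complete subwindow.
#' @export
find_deflections <- function(eog, sample_rate, cfg = segmentation_config()) {
  spw <- round(cfg$subwindow * sample_rate)
  n_win <- length(eog) %/% spw
  if (n_win == 0) stop("signal shorter than one scoring subwindow")
  flags <- character(n_win)

  # above-threshold runs, each assigned to the window of its peak sample
  runs <- logical_runs(abs(eog) > cfg$phasic_min_amplitude)
  em_win <- rep(FALSE, n_win)
  if (nrow(runs) > 0) {
    for (i in seq_len(nrow(runs))) {
      a <- runs[i, 1]; b <- runs[i, 2]
      extent <- (b - a + 1) / sample_rate
      if (extent >= cfg$phasic_max_duration) next
      ipk <- a + which.max(abs(eog[a:b])) - 1L
      w <- (ipk - 1L) %/% spw + 1L
      if (w >= 1 && w <= n_win) em_win[w] <- TRUE
    }
  }
  for (w in seq_len(n_win)) {
    seg <- eog[((w - 1L) * spw + 1L):(w * spw)]
    flags[w] <- if (em_win[w]) {
      "EM"
    } else if (max(abs(seg)) < cfg$tonic_max_amplitude) {
      "quiescent"
    } else {
      "intermediate"
    }
  }
  flags
}

#' Classify 4-s epochs as phasic, tonic or unclassified
#'
#' An epoch is `phasic` when both of its 2-s subwindows are flagged EM
#' (two consecutive eye movements in adjacent windows); `tonic` when both
#' subwindows and the immediately adjacent 2-s windows on each side are
#' quiescent (windows beyond the recording edge count as quiescent);
#' otherwise `unclassified`.
#'
#' @param window_flags character vector from [find_deflections()]; its
#'   length must be even (two subwindows per epoch).
#' @param cfg a [segmentation_config()].
#' @return data.frame with `epoch_index`, `start_s`, `label`.
#' @export
classify_epochs <- function(window_flags, cfg = segmentation_config()) {
  n_win <- length(window_flags)
  if (n_win %% 2 != 0) stop("window flags must cover whole epochs")
  n_ep <- n_win %/% 2L
  quiet <- function(w) w < 1 | w > n_win | window_flags[pmax(1, pmin(n_win, w))] == "quiescent"
  labels <- character(n_ep)
  for (i in seq_len(n_ep)) {
    w1 <- 2L * i - 1L; w2 <- 2L * i
    if (window_flags[w1] == "EM" && window_flags[w2] == "EM") {
      labels[i] <- "phasic"
    } else if (all(quiet(c(w1 - 1L, w1, w2, w2 + 1L)))) {
      labels[i] <- "tonic"
    } else {
      labels[i] <- "unclassified"
    }
  }
  data.frame(epoch_index = seq_len(n_ep),
             start_s = (seq_len(n_ep) - 1) * cfg$window,
             label = labels)
}

#' Enforce the minimum separation between selected segments
#'
#' Greedy earliest-first scan over the time-ordered epochs: a phasic or
#' tonic epoch is kept only if its start lies at least `min_separation`
#' seconds after the end of the last kept epoch. Dropped epochs keep their
#' class but are marked unselected (`kept = FALSE`); labels never change.
#'
#' @param labels data.frame from [classify_epochs()].
#' @param cfg a [segmentation_config()].
#' @return the input data.frame with a logical `kept` column (always
#'   `FALSE` for unclassified epochs).
#' @export
enforce_separation <- function(labels, cfg = segmentation_config()) {
  kept <- rep(FALSE, nrow(labels))
  last_end <- -Inf
  if (nrow(labels) > 0) {
    ord <- order(labels$start_s)
    for (i in ord) {
      if (!(labels$label[i] %in% c("phasic", "tonic"))) next
      if (labels$start_s[i] - last_end >= cfg$min_separation) {
        kept[i] <- TRUE
        last_end <- labels$start_s[i] + cfg$window
      }
    }
  }
  labels$kept <- kept
  labels
}

#' Segment a bilateral EOG pair into phasic/tonic epochs
#'
#' Convenience wrapper running [find_deflections()] on each channel,
#' combining the flags (a window is EM if either channel shows a
#' qualifying deflection, quiescent only if both channels are quiescent),
#' then [classify_epochs()] and [enforce_separation()].
#'
#' @param loc,roc EOG channels in uV.
#' @param sample_rate sampling rate in Hz.
#' @param cfg a [segmentation_config()].
#' @return data.frame with `epoch_index`, `start_s`, `label`, `kept`.
#' @export
segment_rem <- function(loc, roc, sample_rate, cfg = segmentation_config()) {
  fl <- find_deflections(loc, sample_rate, cfg)
  fr <- find_deflections(roc, sample_rate, cfg)
  comb <- ifelse(fl == "EM" | fr == "EM", "EM",
                 ifelse(fl == "quiescent" & fr == "quiescent",
                        "quiescent", "intermediate"))
  n_win <- 2L * (length(comb) %/% 2L)
  enforce_separation(classify_epochs(comb[seq_len(n_win)], cfg), cfg)
}
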