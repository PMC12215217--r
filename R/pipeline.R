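#' Construct a polysomnography recording object
#'
#' A lightweight container for a multichannel EEG/EOG signal block: named
#' channels in uV, one sampling rate, a stage-per-epoch hypnogram, and
#' the mapping from topographical areas to EEG channel labels.
#'
#' @param channels named list of equal-length numeric vectors (uV).
#' @param sample_rate sampling rate in Hz.
#' @param hypnogram character vector of sleep stages, one per
#'   `hyp_epoch_s`-second scoring epoch; its span must match the signal
#'   within one scoring epoch.
#' @param area_map named list mapping area names to channel labels.
#' @param participant participant identifier.
#' @param eog list with elements `left` and `right` naming the EOG
#'   channels.
#' @param hyp_epoch_s scoring epoch length in seconds.
#' @return object of class `recording`.
#' @export
new_recording <- function(channels, sample_rate, hypnogram, area_map,
                          participant = "P01",
                          eog = list(left = "LOC", right = "ROC"),
                          hyp_epoch_s = 30) {
  lens <- lengths(channels)
  if (length(unique(lens)) != 1) stop("all channels must have equal length")
  mapped <- unlist(area_map, use.names = FALSE)
  missing <- setdiff(c(mapped, unlist(eog)), names(channels))
  if (length(missing) > 0) {
    stop(sprintf("channel '%s' required by the area map or EOG assignment is absent",
                 missing[1]))
  }
  sig_span <- lens[1] / sample_rate
  hyp_span <- length(hypnogram) * hyp_epoch_s
  if (abs(sig_span - hyp_span) > hyp_epoch_s) {
    stop(sprintf("hypnogram spans %.0f s but the signal spans %.0f s (> one scoring epoch apart)",
                 hyp_span, sig_span))
  }
  out <- list(channels = channels, sample_rate = sample_rate,
              hypnogram = hypnogram, area_map = area_map,
              participant = participant, eog = eog,
              hyp_epoch_s = hyp_epoch_s)
  class(out) <- "recording"
  out
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s: %d channels @ %g Hz, %.1f min, %d scored epochs\n",
              x$participant, length(x$channels), x$sample_rate,
              length(x$channels[[1]]) / x$sample_rate / 60,
              length(x$hypnogram)))
  invisible(x)
}

#' Read a recording from EDF plus a hypnogram CSV
#'
#' @param edf_path EDF file (physical units uV).
#' @param area_map named list mapping areas to channel labels; all listed
#'   channels must exist in the file.
#' @param hypnogram_path CSV with columns `epoch_index,stage`.
#' @param ... further arguments passed to [new_recording()] (e.g. `eog`).
#' @return a [new_recording()].
#' @export
read_recording <- function(edf_path, area_map, hypnogram_path, ...) {
  if (!file.exists(edf_path)) stop(sprintf("no such EDF file: %s", edf_path))
  edf <- read_edf(edf_path)
  hyp <- read_hypnogram(hypnogram_path)
  new_recording(channels = edf$channels, sample_rate = edf$sample_rate,
                hypnogram = hyp, area_map = area_map,
                participant = edf$patient, ...)
}

#' Analysis configuration
#'
#' Bundles the per-stage configurations and the pipeline-level switches.
#' The object serializes losslessly to JSON via [config_to_json()].
#'
#' @param irasa an [irasa_config()].
#' @param segmentation a [segmentation_config()].
#' @param em_detect an [em_detect_config()].
#' @param use_zscore run the group contrasts and ROC on within-participant
#'   z-scored summaries (the device-robust scale) rather than raw slopes.
#' @param fdr_q false discovery rate for the Benjamini-Hochberg step.
#' @param min_episode_s minimum REM episode duration for the
#'   within-episode analysis (s).
#' @param max_lag_s,step_s cross-correlation lag range and step (s).
#' @param effect_lag_window lag window for the episode-centred effect
#'   size (s).
#' @param effect_sign required sign for counting a significant episode.
#' @param alpha per-episode test level for the prevalence model.
#' @param ci_mode per-lag or pooled confidence threshold, see
#'   [cross_correlate()].
#' @return object of class `run_config`.
#' @export
run_config <- function(irasa = irasa_config(),
                       segmentation = segmentation_config(),
                       em_detect = em_detect_config(),
                       use_zscore = TRUE,
                       fdr_q = 0.05,
                       min_episode_s = 600,
                       max_lag_s = 300,
                       step_s = 4,
                       effect_lag_window = c(0, 0),
                       effect_sign = "any",
                       alpha = 0.05,
                       ci_mode = "per_lag") {
  out <- list(irasa = irasa, segmentation = segmentation,
              em_detect = em_detect, use_zscore = use_zscore,
              fdr_q = fdr_q, min_episode_s = min_episode_s,
              max_lag_s = max_lag_s, step_s = step_s,
              effect_lag_window = effect_lag_window,
              effect_sign = effect_sign, alpha = alpha, ci_mode = ci_mode)
  class(out) <- "run_config"
  out
}

#' Serialize / restore a run configuration
#'
#' @param cfg a [run_config()].
#' @param path optional file; if omitted the JSON string is returned.
#' @return `config_to_json`: JSON string or (invisibly) `path`;
#'   `config_from_json`: a [run_config()] identical to the serialized one.
#' @export
config_to_json <- function(cfg, path = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  strip <- function(x) {
    if (is.list(x)) x <- lapply(x, strip)
    attr(x, "class") <- NULL
    x
  }
  js <- jsonlite::toJSON(strip(cfg), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname config_to_json
#' @param json JSON string (alternative to `path`).
#' @export
config_from_json <- function(path = NULL, json = NULL) {
  txt <- if (is.null(json)) paste(readLines(path), collapse = "\n") else json
  pl <- jsonlite::fromJSON(txt, simplifyVector = TRUE)
  cfg <- run_config(
    irasa = do.call(irasa_config, pl$irasa[setdiff(names(pl$irasa), character(0))]),
    segmentation = do.call(segmentation_config, pl$segmentation),
    em_detect = do.call(em_detect_config, pl$em_detect),
    use_zscore = pl$use_zscore, fdr_q = pl$fdr_q,
    min_episode_s = pl$min_episode_s, max_lag_s = pl$max_lag_s,
    step_s = pl$step_s, effect_lag_window = pl$effect_lag_window,
    effect_sign = pl$effect_sign, alpha = pl$alpha, ci_mode = pl$ci_mode)
  cfg
}

# 4-s epochs whose containing scoring epoch is REM.
rem_epoch_mask <- function(recording, n_epochs, epoch_length = 4) {
  starts <- (seq_len(n_epochs) - 1) * epoch_length
  hyp_idx <- floor(starts / recording$hyp_epoch_s) + 1
  hyp_idx <- pmin(hyp_idx, length(recording$hypnogram))
  recording$hypnogram[hyp_idx] == "R"
}

#' Binary (epoched) phasic-versus-tonic analysis
#'
#' The end-to-end epoched pipeline: EOG-based segmentation of each
#' recording into phasic and tonic 4-s epochs (with the 8-s separation
#' rule), IRASA aperiodic slopes for the kept REM epochs in the low and
#' high bands over the four areas, per-participant state means (raw and
#' within-participant z-scored), paired contrasts (phasic minus tonic)
#' with Cohen's d, Benjamini-Hochberg adjustment across the area-by-band
#' contrasts, and ROC/AUC per area and band. Participants lacking kept
#' epochs of either state are dropped with a logged exclusion.
#'
#' @param recordings list of [new_recording()] objects (>= 3 usable
#'   participants required for the group statistics).
#' @param cfg a [run_config()].
#' @return list with `participants` (per-cell summaries), `contrasts`
#'   (t, p, adjusted p, d per area and band), `roc`, `exclusions`, and
#'   `n_participants`.
#' @export
run_binary_analysis <- function(recordings, cfg = run_config()) {
  ep_len <- cfg$segmentation$window
  summaries <- list()
  exclusions <- data.frame(participant = character(0), reason = character(0))
  for (rec in recordings) {
    fs <- rec$sample_rate
    loc <- rec$channels[[rec$eog$left]]
    roc <- rec$channels[[rec$eog$right]]
    seg <- segment_rem(loc, roc, fs, cfg$segmentation)
    rem <- rem_epoch_mask(rec, nrow(seg), ep_len)
    seg$kept <- seg$kept & rem
    kept <- seg[seg$kept & seg$label %in% c("phasic", "tonic"), ]
    if (!all(c("phasic", "tonic") %in% kept$label)) {
      exclusions <- rbind(exclusions, data.frame(
        participant = rec$participant, reason = "missing_state"))
      warning(sprintf("participant %s dropped: no kept epochs of one state",
                      rec$participant))
      next
    }
    sl <- epoch_slopes(rec, cfg$irasa, epoch_length = ep_len,
                       epochs = kept$epoch_index)
    sl$state <- kept$label[match(sl$epoch_index, kept$epoch_index)]
    sl <- sl[is.finite(sl$slope), ]
    # within-participant z over the pooled epoch-level vector, per band
    sl$slope_z <- NA_real_
    for (bn in unique(sl$band)) {
      i <- sl$band == bn
      sl$slope_z[i] <- zscore_within_participant(sl$slope[i])
    }
    agg <- stats::aggregate(cbind(slope, slope_z) ~ area + band + state,
                            data = sl, FUN = mean)
    nctr <- stats::aggregate(slope ~ area + band + state, data = sl, FUN = length)
    agg$n_epochs <- nctr$slope
    agg$participant <- rec$participant
    summaries[[length(summaries) + 1L]] <- agg
  }
  if (length(summaries) < 3) {
    stop("fewer than 3 usable participants for group statistics")
  }
  smry <- do.call(rbind, summaries)
  value_col <- if (cfg$use_zscore) "slope_z" else "slope"

  cells <- unique(smry[, c("area", "band")])
  ctr <- list(); rocs <- list()
  for (i in seq_len(nrow(cells))) {
    a <- cells$area[i]; b <- cells$band[i]
    ph <- smry[smry$area == a & smry$band == b & smry$state == "phasic", ]
    to <- smry[smry$area == a & smry$band == b & smry$state == "tonic", ]
    common <- intersect(ph$participant, to$participant)
    pv <- ph[[value_col]][match(common, ph$participant)]
    tv <- to[[value_col]][match(common, to$participant)]
    cres <- paired_contrast(pv, tv)
    cres$area <- a; cres$band <- b
    ctr[[i]] <- cres
    rres <- auc_mann_whitney(pv, tv)
    rres$area <- a; rres$band <- b
    rocs[[i]] <- rres
  }
  contrasts <- do.call(rbind, ctr)
  adj <- bh_adjust(contrasts$p, q = cfg$fdr_q)
  contrasts$p_adj <- adj$p_adj
  contrasts$significant <- adj$rejected
  list(participants = smry, contrasts = contrasts,
       roc = do.call(rbind, rocs), exclusions = exclusions,
       n_participants = length(unique(smry$participant)))
}

#' Within-episode cross-correlation analysis
#'
#' The end-to-end continuous pipeline: REM episodes longer than
#' `min_episode_s` are selected from each hypnogram; within every episode
#' the per-4-s-epoch aperiodic slope series (per area and band) and the
#' EM peak-amplitude series (events detected on the episode's EOG) are
#' cross-correlated at lags up to +-5 min; Fisher-z curves are pooled
#' across episodes, the episode-centred effect size counted, and the
#' Bayesian population prevalence estimated per area and band.
#'
#' @param recordings list of [new_recording()] objects.
#' @param cfg a [run_config()].
#' @return list with `status` (`"ok"` or `"no episodes > 10 min"`),
#'   `episodes`, `crosscorr` (long per-lag table), `pooled`,
#'   `effect_sizes` and `prevalence` tables.
#' @export
run_within_episode_analysis <- function(recordings, cfg = run_config()) {
  ep_len <- cfg$step_s
  episodes <- list(); results <- list(); keys <- list()
  for (rec in recordings) {
    eps <- select_episodes(rec$hypnogram, epoch_s = rec$hyp_epoch_s,
                           min_duration = cfg$min_episode_s)
    if (nrow(eps) == 0) next
    fs <- rec$sample_rate
    for (e in seq_len(nrow(eps))) {
      n_ep <- floor(eps$duration_s[e] / ep_len)
      first_ep <- floor(eps$start_s[e] / ep_len) + 1L
      ep_idx <- first_ep:(first_ep + n_ep - 1L)
      sl <- epoch_slopes(rec, cfg$irasa, epoch_length = ep_len, epochs = ep_idx)
      i0 <- round(eps$start_s[e] * fs) + 1L
      i1 <- min(length(rec$channels[[1]]), round(eps$end_s[e] * fs))
      ev <- detect_rem_events(rec$channels[[rec$eog$left]][i0:i1],
                              rec$channels[[rec$eog$right]][i0:i1],
                              fs, cfg$em_detect)
      amp <- epoch_amplitude_series(ev, n_ep, ep_len)
      eid <- sprintf("%s_ep%02d", rec$participant, e)
      episodes[[length(episodes) + 1L]] <- data.frame(
        episode = eid, participant = rec$participant,
        start_s = eps$start_s[e], end_s = eps$end_s[e],
        duration_s = eps$duration_s[e], n_epochs = as.integer(n_ep),
        n_em_events = nrow(ev))
      for (a in unique(sl$area)) {
        for (b in unique(sl$band)) {
          s <- sl$slope[sl$area == a & sl$band == b][order(sl$epoch_index[sl$area == a & sl$band == b])]
          if (any(!is.finite(s))) {
            if (mean(is.finite(s)) < 0.9) next
            s <- stats::approx(seq_along(s)[is.finite(s)], s[is.finite(s)],
                               xout = seq_along(s), rule = 2)$y
          }
          cc <- cross_correlate(s, amp, max_lag_s = cfg$max_lag_s,
                                step_s = cfg$step_s, ci_mode = cfg$ci_mode)
          results[[length(results) + 1L]] <- cc
          keys[[length(keys) + 1L]] <- data.frame(episode = eid, area = a, band = b)
        }
      }
    }
  }
  if (length(episodes) == 0) {
    return(list(status = "no episodes > 10 min",
                episodes = data.frame(), crosscorr = data.frame(),
                pooled = data.frame(), effect_sizes = data.frame(),
                prevalence = data.frame()))
  }
  keydf <- do.call(rbind, keys)
  long <- do.call(rbind, lapply(seq_along(results), function(i) {
    cbind(keydf[rep(i, nrow(results[[i]])), , drop = FALSE],
          as.data.frame(results[[i]]))
  }))
  rownames(long) <- NULL
  pooled <- list(); effs <- list(); prevs <- list()
  for (a in unique(keydf$area)) {
    for (b in unique(keydf$band)) {
      sel <- which(keydf$area == a & keydf$band == b)
      if (length(sel) == 0) next
      pc <- pool_episode_correlations(results[sel])
      pc$area <- a; pc$band <- b
      pooled[[length(pooled) + 1L]] <- pc
      es <- episode_effect_size(results[sel],
                                lag_window = cfg$effect_lag_window,
                                sign = cfg$effect_sign)
      effs[[length(effs) + 1L]] <- data.frame(
        area = a, band = b, proportion = es$proportion, k = es$k, n = es$n)
      pv <- bayesian_prevalence(es$k, es$n, alpha = cfg$alpha)
      prevs[[length(prevs) + 1L]] <- data.frame(
        area = a, band = b, k = pv$k, n = pv$n, alpha = pv$alpha,
        map = pv$map_estimate, hpdi_lo = pv$hpdi[1], hpdi_hi = pv$hpdi[2])
    }
  }
  list(status = "ok",
       episodes = do.call(rbind, episodes),
       crosscorr = long,
       pooled = do.call(rbind, pooled),
       effect_sizes = do.call(rbind, effs),
       prevalence = do.call(rbind, prevs))
}
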