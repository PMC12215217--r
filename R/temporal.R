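#' Select REM episodes from a hypnogram
#'
#' Maximal contiguous runs of the REM stage; runs not longer than
#' `min_duration` (default 10 min) are discarded, because shorter episodes
#' cannot contain several periods of the ~2-min infra-slow eye-movement
#' bursting and carry too little statistical power for within-episode
#' cross-correlation.
#'
#' @param hypnogram character vector of stage labels, one per scoring
#'   epoch.
#' @param epoch_s scoring epoch length in seconds (30 by convention).
#' @param stage label of the REM stage.
#' @param min_duration minimum episode duration in seconds (strictly
#'   greater than).
#' @return data.frame with `start_s`, `end_s`, `duration_s` per episode.
#' @export
select_episodes <- function(hypnogram, epoch_s = 30, stage = "R",
                            min_duration = 600) {
  if (length(hypnogram) == 0) stop("empty hypnogram")
  runs <- logical_runs(hypnogram == stage)
  out <- data.frame(start_s = numeric(0), end_s = numeric(0),
                    duration_s = numeric(0))
  if (nrow(runs) == 0) return(out)
  start_s <- (runs[, 1] - 1) * epoch_s
  end_s <- runs[, 2] * epoch_s
  dur <- end_s - start_s
  keep <- dur > min_duration
  data.frame(start_s = start_s[keep], end_s = end_s[keep],
             duration_s = dur[keep])
}

#' Rank a series with mid-ranks for ties
#'
#' Ascending ranks 1..n; tied values receive the mean of the ranks they
#' occupy. Applied to both series before cross-correlation, making every
#' per-lag correlation a Spearman coefficient.
#'
#' @param x numeric vector of finite values.
#' @return numeric vector of ranks.
#' @export
rank_with_ties <- function(x) {
  if (any(!is.finite(x))) stop("rank_with_ties requires finite values")
  rank(x, ties.method = "average")
}

#' Lagged rank cross-correlation between slope and EM series
#'
#' Both series are rank-transformed once (mid-ranks for ties); for each
#' lag the Pearson correlation of the overlapping portions is computed
#' (truncation, no wraparound; overlap length `n - |lag|`). Correlations
#' are Fisher z-transformed and a 95% confidence half-width
#' `tanh(1.96 / sqrt(n_lag - 3))` determines per-lag significance
#' (`|r|` above the half-width). Sign convention: a peak at a negative
#' lag means the slope series leads the eye movements; a delayed copy of
#' the slope series in `em` therefore peaks at a negative lag.
#'
#' @param slope_series,em_series equal-length numeric vectors on the
#'   shared 4-s epoch grid (`n > 10`).
#' @param max_lag_s,step_s lag range and step in seconds (defaults
#'   +-300 s in steps of 4 s, i.e. 151 lags).
#' @param conf_level confidence level of the per-lag interval.
#' @param rerank if `TRUE`, re-rank the overlapping sub-series at every
#'   lag instead of ranking the full series once.
#' @param ci_mode `"per_lag"` uses the overlap length at each lag for the
#'   confidence half-width; `"pooled"` uses the full series length for
#'   every lag (one flat threshold).
#' @return object of class `crosscorr_result`: data.frame with `lag_s`,
#'   `n`, `r`, `z`, `ci`, `significant`. Lags whose overlap is 4 or fewer
#'   points carry `NA`.
#' @export
cross_correlate <- function(slope_series, em_series, max_lag_s = 300,
                            step_s = 4, conf_level = 0.95, rerank = FALSE,
                            ci_mode = c("per_lag", "pooled")) {
  ci_mode <- match.arg(ci_mode)
  n <- length(slope_series)
  if (length(em_series) != n) stop("series must have equal length")
  if (n <= 10) stop("need more than 10 epochs")
  rx <- rank_with_ties(slope_series)
  ry <- rank_with_ties(em_series)
  L <- as.integer(round(max_lag_s / step_s))
  lags <- (-L):L
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  res <- data.frame(lag_s = lags * step_s, n = n - abs(lags),
                    r = NA_real_, z = NA_real_, ci = NA_real_,
                    significant = NA)
  for (k in seq_along(lags)) {
    l <- lags[k]
    nl <- n - abs(l)
    if (nl <= 4) next
    # r(l) = cor(slope[t + l], em[t]); slope leading shows at l < 0
    if (l >= 0) {
      xs <- rx[(1 + l):n]; ys <- ry[1:nl]
    } else {
      xs <- rx[1:nl]; ys <- ry[(1 - l):n]
    }
    if (rerank) {
      xs <- rank(xs, ties.method = "average")
      ys <- rank(ys, ties.method = "average")
    }
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) next
    r <- stats::cor(xs, ys)
    n_ci <- if (ci_mode == "per_lag") nl else n
    ci <- tanh(zq / sqrt(n_ci - 3))
    res$r[k] <- r
    res$z[k] <- atanh(max(-1 + 1e-15, min(1 - 1e-15, r)))
    res$ci[k] <- ci
    res$significant[k] <- abs(r) > ci
  }
  class(res) <- c("crosscorr_result", "data.frame")
  res
}

#' Pool cross-correlation curves across episodes
#'
#' Fisher z-scores are averaged per lag across episodes (the
#' variance-stabilized scale on which averaging is justified) and mapped
#' back through `tanh`; dispersion is the per-lag standard deviation of
#' the z-scores.
#'
#' @param results list of `crosscorr_result` objects sharing a lag grid.
#' @return data.frame with `lag_s`, `n_episodes`, `mean_z`, `sd_z`, `r`.
#' @export
pool_episode_correlations <- function(results) {
  if (length(results) == 0) stop("need at least one episode")
  lag0 <- results[[1]]$lag_s
  for (r in results) {
    if (!isTRUE(all.equal(r$lag_s, lag0))) stop("episodes must share the lag grid")
  }
  zmat <- vapply(results, function(r) r$z, numeric(length(lag0)))
  zmat <- matrix(zmat, nrow = length(lag0))
  mean_z <- rowMeans(zmat, na.rm = TRUE)
  sd_z <- apply(zmat, 1, stats::sd, na.rm = TRUE)
  n_ep <- rowSums(!is.na(zmat))
  data.frame(lag_s = lag0, n_episodes = n_ep, mean_z = mean_z,
             sd_z = sd_z, r = tanh(mean_z))
}

#' Episode-centred effect size
#'
#' Fraction of episodes showing a significant correlation of the required
#' sign within a lag window (default: lag 0 only) — the number of
#' significant correlations divided by the number of all performed
#' correlations.
#'
#' @param results list of `crosscorr_result` objects.
#' @param lag_window `c(lo, hi)` in seconds.
#' @param sign `"any"`, `"negative"` or `"positive"` — required sign of
#'   the significant correlation.
#' @return list with `proportion`, `k` (significant episodes) and `n`.
#' @export
episode_effect_size <- function(results, lag_window = c(0, 0),
                                sign = c("any", "negative", "positive")) {
  sign <- match.arg(sign)
  if (length(results) == 0) stop("need at least one episode")
  hit <- vapply(results, function(res) {
    sel <- res$lag_s >= lag_window[1] & res$lag_s <= lag_window[2]
    if (!any(sel)) stop("lag_window outside the computed lags")
    sig <- res$significant[sel] & !is.na(res$significant[sel])
    if (sign == "negative") sig <- sig & res$r[sel] < 0
    if (sign == "positive") sig <- sig & res$r[sel] > 0
    any(sig, na.rm = TRUE)
  }, logical(1))
  list(proportion = mean(hit), k = sum(hit), n = length(hit))
}

#' Bayesian population prevalence of a within-episode effect
#'
#' Given `k` significant tests out of `n` episodes at per-test level
#' `alpha`, each episode is modelled as significant with probability
#' `theta = gamma + (1 - gamma) * alpha`, where `gamma` is the population
#' prevalence of true effects (within-episode sensitivity taken as 1).
#' With a uniform prior the posterior of `theta` is Beta(k+1, n-k+1);
#' it is transformed through `gamma = (theta - alpha)/(1 - alpha)` and
#' truncated to `[0, 1]`, the posterior mass below `theta = alpha`
#' becoming a point mass at `gamma = 0`. The maximum a posteriori
#' estimate and the highest posterior density interval are computed on a
#' gamma grid; the MAP equals `max(0, (k/n - alpha)/(1 - alpha))` up to
#' grid resolution.
#'
#' @param k number of significant episodes (`0 <= k <= n`).
#' @param n number of episodes tested.
#' @param alpha per-episode test level in (0, 1).
#' @param hpdi_level probability mass of the highest posterior density
#'   interval (0.96 by convention for this analysis).
#' @param grid_step gamma grid step (<= 0.001).
#' @return object of class `prevalence_estimate`: list with `k`, `n`,
#'   `alpha`, `map_estimate`, `hpdi` (`c(lo, hi)`), `hpdi_level`.
#' @export
bayesian_prevalence <- function(k, n, alpha = 0.05, hpdi_level = 0.96,
                                grid_step = 5e-4) {
  if (k < 0 || k > n) stop("require 0 <= k <= n")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  stopifnot(grid_step <= 0.001, n >= 1)
  g <- seq(0, 1, by = grid_step)
  theta <- alpha + (1 - alpha) * g
  dens <- stats::dbeta(theta, k + 1, n - k + 1) * (1 - alpha)
  # posterior mass with theta < alpha collapses onto gamma = 0
  p0 <- stats::pbeta(alpha, k + 1, n - k + 1)
  cell <- dens * grid_step
  cell[1] <- cell[1] + p0
  cell <- cell / sum(cell)
  # MAP is the mode of the truncated continuous density (the atom at 0
  # carries mass, not density); the atom enters the HPDI mass accounting.
  map <- g[which.max(dens)]
  ord <- order(dens, decreasing = TRUE)
  csum <- cumsum(cell[ord])
  inhpd <- ord[seq_len(which(csum >= hpdi_level)[1])]
  out <- list(k = k, n = n, alpha = alpha, map_estimate = map,
              hpdi = c(min(g[inhpd]), max(g[inhpd])),
              hpdi_level = hpdi_level)
  class(out) <- "prevalence_estimate"
  out
}

#' @export
print.prevalence_estimate <- function(x, ...) {
  cat(sprintf(
    "<prevalence_estimate> k = %d of n = %d at alpha = %.3g: MAP %.3f, %g%% HPDI [%.3f, %.3f]\n",
    x$k, x$n, x$alpha, x$map_estimate, 100 * x$hpdi_level,
    x$hpdi[1], x$hpdi[2]))
  invisible(x)
}
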