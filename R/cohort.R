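#' Within-participant z-transform
#'
#' Standardizes a pooled vector of values (e.g. all epoch-level slopes of
#' one participant across the four areas and both states, merged into one
#' vector) to mean 0 and unit standard deviation (n-1 denominator).
#' Pooling before standardizing preserves the relative differences
#' between areas and states while removing the participant's overall
#' offset and scale, which differ across recording devices.
#'
#' @param values numeric vector with at least two distinct finite values.
#' @return numeric vector of z-scores.
#' @export
zscore_within_participant <- function(values) {
  v <- values[is.finite(values)]
  if (length(unique(v)) < 2) stop("need at least 2 distinct values")
  s <- stats::sd(values, na.rm = TRUE)
  if (s == 0) stop("zero variance")
  (values - mean(values, na.rm = TRUE)) / s
}

#' Paired contrast between two states
#'
#' Two-tailed paired Student t-test and paired Cohen's d computed on
#' difference scores (`mean(diff) / sd(diff)`), for per-participant means
#' of e.g. phasic versus tonic aperiodic slopes.
#'
#' @param x,y paired numeric vectors (e.g. phasic and tonic means), at
#'   least 3 pairs. The contrast is `x - y`.
#' @return data.frame with `t`, `p`, `d`, `n`, `mean_diff`.
#' @export
paired_contrast <- function(x, y) {
  if (length(x) != length(y)) stop("inputs must be paired")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  d <- x - y
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(data.frame(t = 0, p = 1, d = 0, n = length(x), mean_diff = 0))
    }
    stop("zero-variance differences")
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  data.frame(t = unname(tt$statistic), p = tt$p.value,
             d = mean(d) / stats::sd(d), n = length(x),
             mean_diff = mean(d))
}

#' ROC AUC via the Mann-Whitney rank identity
#'
#' The area under the ROC curve equals the probability that a value from
#' the positive class ranks above one from the negative class, with half
#' credit for ties (Mann-Whitney U identity). The class with the larger
#' mean is taken as positive. Sensitivity and specificity are evaluated
#' at a single cutoff: the median of all pooled values. The standard
#' error follows Hanley & McNeil and is reported for description only.
#'
#' @param phasic,tonic numeric vectors of the two classes (non-empty).
#' @return data.frame with `auc`, `auc_se`, `sensitivity`, `specificity`,
#'   `cutoff`, `positive_class` (`"phasic"` or `"tonic"`), `n_phasic`,
#'   `n_tonic`.
#' @export
auc_mann_whitney <- function(phasic, tonic) {
  phasic <- phasic[is.finite(phasic)]
  tonic <- tonic[is.finite(tonic)]
  if (length(phasic) == 0 || length(tonic) == 0) stop("both groups must be non-empty")
  pos_is_phasic <- mean(phasic) >= mean(tonic)
  pos <- if (pos_is_phasic) phasic else tonic
  neg <- if (pos_is_phasic) tonic else phasic
  n1 <- length(pos); n2 <- length(neg)
  r <- rank(c(pos, neg), ties.method = "average")
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n2 - 1) * (q2 - auc^2)) / (n1 * n2))
  cutoff <- stats::median(c(phasic, tonic))
  data.frame(auc = auc, auc_se = se,
             sensitivity = mean(pos > cutoff),
             specificity = mean(neg <= cutoff),
             cutoff = cutoff,
             positive_class = if (pos_is_phasic) "phasic" else "tonic",
             n_phasic = length(phasic), n_tonic = length(tonic))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false discovery rate control: returns monotone
#' adjusted p-values and the rejection flags at rate `q`.
#'
#' @param pvals p-values in (0, 1].
#' @param q false discovery rate.
#' @return data.frame with `p`, `p_adj`, `rejected`.
#' @export
bh_adjust <- function(pvals, q = 0.05) {
  if (any(pvals <= 0 | pvals > 1)) stop("p-values must lie in (0, 1]")
  adj <- stats::p.adjust(pvals, method = "BH")
  data.frame(p = pvals, p_adj = adj, rejected = adj <= q)
}

#' Epoch-level Spearman correlation between EM amplitude and slope
#'
#' Pooled-epoch association for the continuous analysis: epochs carrying
#' an eye movement (amplitude above `min_amplitude`) contribute their EM
#' peak amplitude and matched aperiodic slope; the association is
#' summarized with Spearman's rank correlation.
#'
#' @param em_amplitudes per-epoch EM peak amplitudes in uV.
#' @param slopes matched per-epoch aperiodic slopes.
#' @param min_amplitude inclusion threshold in uV (epochs at or below it
#'   are excluded).
#' @param min_epochs minimum number of qualifying epochs (refuses below).
#' @return data.frame with `rho`, `p`, `n`.
#' @export
epoch_amplitude_correlation <- function(em_amplitudes, slopes,
                                        min_amplitude = 50, min_epochs = 10) {
  if (length(em_amplitudes) != length(slopes)) stop("series must be matched")
  sel <- em_amplitudes > min_amplitude & is.finite(slopes)
  if (sum(sel) < min_epochs) {
    stop(sprintf("only %d epochs with EM events (need >= %d)",
                 sum(sel), min_epochs))
  }
  ct <- suppressWarnings(
    stats::cor.test(em_amplitudes[sel], slopes[sel], method = "spearman"))
  data.frame(rho = unname(ct$estimate), p = ct$p.value, n = sum(sel))
}
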