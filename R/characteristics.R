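#' Binomial proportion confidence interval
#'
#' Interval for a binomial proportion `k / n`. The default is the
#' Clopper–Pearson exact interval (beta-quantile form, the same interval
#' inverted from the binomial tail probabilities), with Wilson score and
#' Wald intervals available. Boundaries are handled exactly: the lower
#' limit is 0 when `k = 0` and the upper limit is 1 when `k = n`.
#'
#' @param k Successes (vectorised).
#' @param n Trials (vectorised, all > 0).
#' @param level Confidence level, default 0.95.
#' @param method One of `"clopper_pearson"`, `"wilson"`, `"wald"`.
#' @return Tibble with columns `estimate`, `conf_low`, `conf_high`.
#' @examples
#' proportion_ci(258, 2705)
#' @export
proportion_ci <- function(k, n, level = 0.95,
                          method = c("clopper_pearson", "wilson", "wald")) {
  method <- match.arg(method)
  if (any(n <= 0)) abort("`n` must be positive")
  if (any(k < 0 | k > n)) abort("need 0 <= k <= n")
  alpha <- 1 - level
  p <- k / n
  if (method == "clopper_pearson") {
    low <- ifelse(k == 0, 0, qbeta(alpha / 2, k, n - k + 1))
    high <- ifelse(k == n, 1, qbeta(1 - alpha / 2, k + 1, n - k))
  } else if (method == "wilson") {
    z <- qnorm(1 - alpha / 2)
    centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    # the score interval hits 0 / 1 exactly at empty / full counts
    low <- ifelse(k == 0, 0, pmax(0, centre - half))
    high <- ifelse(k == n, 1, pmin(1, centre + half))
  } else {
    z <- qnorm(1 - alpha / 2)
    half <- z * sqrt(p * (1 - p) / n)
    low <- pmax(0, p - half)
    high <- pmin(1, p + half)
  }
  tibble::tibble(estimate = p, conf_low = low, conf_high = high)
}

#' Likelihood-ratio confidence intervals (log method)
#'
#' Positive and negative likelihood ratios with delta-method intervals on
#' the log scale (Simel's method for ratios of proportions):
#' `exp(log(LR) +/- z * SE)` with
#' `SE(log LR+) = sqrt(1/tp - 1/(tp+fn) + 1/fp - 1/(fp+tn))` and
#' `SE(log LR-) = sqrt(1/fn - 1/(tp+fn) + 1/tn - 1/(fp+tn))`.
#' Point estimates are exact ratios. A zero false-positive count makes
#' LR+ infinite; this is signalled explicitly (point `Inf`, lower bound
#' `NA`) rather than surfacing as overflow, and symmetrically a zero
#' false-negative count gives LR- = 0 with an `NA` upper bound.
#'
#' @param tp,fp,fn,tn Confusion-matrix counts (scalars, >= 0).
#' @param level Confidence level.
#' @return Tibble with rows `lr_positive`, `lr_negative` and columns
#'   `measure`, `estimate`, `conf_low`, `conf_high`.
#' @examples
#' lr_ci(tp = 258, fp = 2447, fn = 903, tn = 159102)
#' @export
lr_ci <- function(tp, fp, fn, tn, level = 0.95) {
  if (any(c(tp, fp, fn, tn) < 0)) abort("counts must be non-negative")
  P <- tp + fn; Np <- fp + tn
  if (P == 0 || Np == 0) abort("both outcome classes must be represented")
  z <- qnorm(1 - (1 - level) / 2)
  sens <- tp / P; spec <- tn / Np

  if (fp == 0) {
    warn("positive likelihood ratio is infinite (no false positives)")
    lrp <- c(Inf, NA_real_, Inf)
  } else {
    est <- sens / (1 - spec)
    if (tp == 0) {
      lrp <- c(0, 0, NA_real_)
    } else {
      se <- sqrt(1 / tp - 1 / P + 1 / fp - 1 / Np)
      lrp <- c(est, exp(log(est) - z * se), exp(log(est) + z * se))
    }
  }
  if (tn == 0) {
    warn("negative likelihood ratio is infinite (no true negatives)")
    lrn <- c(Inf, NA_real_, Inf)
  } else {
    est <- (1 - sens) / spec
    if (fn == 0) {
      lrn <- c(0, 0, NA_real_)
    } else {
      se <- sqrt(1 / fn - 1 / P + 1 / tn - 1 / Np)
      lrn <- c(est, exp(log(est) - z * se), exp(log(est) + z * se))
    }
  }
  tibble::tibble(
    measure = c("lr_positive", "lr_negative"),
    estimate = c(lrp[1], lrn[1]),
    conf_low = c(lrp[2], lrn[2]),
    conf_high = c(lrp[3], lrn[3])
  )
}

#' Test characteristics of the score at a threshold
#'
#' Treats "ABC score >= t" as the positive prediction for a favourable
#' outcome (CPC 1--2) and computes sensitivity, specificity, and the
#' positive and negative likelihood ratios with confidence intervals.
#' Sensitivity and specificity intervals use [proportion_ci()] (method
#' pluggable); likelihood-ratio intervals use [lr_ci()].
#'
#' @param table A [stratum_table()].
#' @param threshold Integer threshold in 1..3.
#' @param level Confidence level.
#' @param ci_method Proportion CI method, see [proportion_ci()].
#' @return A one-row tibble with the counts (`tp`, `fp`, `fn`, `tn`) and
#'   each measure with its interval, on the proportion scale for
#'   sensitivity/specificity.
#' @examples
#' tab <- stratum_table(n = c(87474, 58603, 13928, 2705),
#'                      pos = c(157, 338, 408, 258), group = "G2005")
#' characteristics_at_threshold(tab, 2)
#' @export
characteristics_at_threshold <- function(table, threshold, level = 0.95,
                                         ci_method = "clopper_pearson") {
  stopifnot(inherits(table, "stratum_table"))
  if (!threshold %in% 1:3) abort("`threshold` must be 1, 2 or 3")
  P <- table$P; Np <- table$N - table$P
  if (P == 0 || Np == 0) {
    abort("undefined test characteristics: a class (favourable or unfavourable) is empty")
  }
  st <- table$strata
  hi <- st$score >= threshold
  tp <- sum(st$pos[hi]); fn <- P - tp
  fp <- sum(st$n[hi] - st$pos[hi]); tn <- Np - fp
  sens <- proportion_ci(tp, P, level, ci_method)
  spec <- proportion_ci(tn, Np, level, ci_method)
  lrs <- lr_ci(tp, fp, fn, tn, level)
  tibble::tibble(
    group = table$group, threshold = as.integer(threshold),
    tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = sens$estimate,
    sensitivity_low = sens$conf_low, sensitivity_high = sens$conf_high,
    specificity = spec$estimate,
    specificity_low = spec$conf_low, specificity_high = spec$conf_high,
    lr_positive = lrs$estimate[1],
    lr_positive_low = lrs$conf_low[1], lr_positive_high = lrs$conf_high[1],
    lr_negative = lrs$estimate[2],
    lr_negative_low = lrs$conf_low[2], lr_negative_high = lrs$conf_high[2]
  )
}

#' @rdname characteristics_at_threshold
#' @param thresholds Integer thresholds to evaluate, default all of 1..3.
#' @export
test_characteristics <- function(table, thresholds = 1:3, level = 0.95,
                                 ci_method = "clopper_pearson") {
  purrr::map_dfr(thresholds, characteristics_at_threshold,
                 table = table, level = level, ci_method = ci_method)
}

#' Observed favourable-outcome proportion per score
#'
#' The per-score proportion of patients with CPC 1--2, with confidence
#' intervals, as plotted on the outcome-gradient and calibration figures.
#' Empty strata are kept in the output but flagged, with an undefined
#' proportion.
#'
#' @inheritParams characteristics_at_threshold
#' @return Tibble with columns `group`, `score`, `n`, `pos`,
#'   `proportion`, `conf_low`, `conf_high`, `undefined`.
#' @export
observed_proportions_by_score <- function(table, level = 0.95,
                                          ci_method = "clopper_pearson") {
  stopifnot(inherits(table, "stratum_table"))
  st <- table$strata
  out <- tibble::tibble(
    group = table$group, score = st$score, n = st$n, pos = st$pos,
    proportion = NA_real_, conf_low = NA_real_, conf_high = NA_real_,
    undefined = st$n == 0
  )
  ok <- !out$undefined
  if (any(ok)) {
    ci <- proportion_ci(st$pos[ok], st$n[ok], level, ci_method)
    out$proportion[ok] <- ci$estimate
    out$conf_low[ok] <- ci$conf_low
    out$conf_high[ok] <- ci$conf_high
  }
  out
}
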