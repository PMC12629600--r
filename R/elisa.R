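# Robust replicate screen: the multiplier k is calibrated by simulation so
# that on clean Gaussian quadruplicates the per-well false-flag rate is
# ~= q = 0.01 (empirical 99th percentile of max|x - median|/MAD over 4e5
# simulated wells of n = 4). MAD at n = 4 is extremely variable, so the
# calibrated k is much larger than large-sample intuition suggests.
.mad_k_n4_q01 <- 16.1

#' Remove gross replicate outliers from a well
#'
#' Median/MAD screen standing in for robust-regression outlier tests in
#' plate software: the replicate with the largest absolute deviation from
#' the well median is flagged when that deviation exceeds `k * MAD`, with
#' `k` calibrated by simulation so the false-flag rate on clean Gaussian
#' replicates is about `q`. At most one replicate is removed per well, and
#' wells with fewer than 3 replicates are left untouched.
#'
#' @param x numeric vector of replicate ODs for one well.
#' @param q nominal false-flag rate (default 0.01; the calibrated
#'   multiplier is stored for n = 4 and reused for other n >= 3).
#' @return list with `values` (kept replicates) and `flagged` (logical
#'   mask on the input).
#' @export
remove_outliers <- function(x, q = 0.01) {
  n <- length(x)
  flagged <- rep(FALSE, n)
  if (n >= 3) {
    k <- .mad_k_n4_q01 * sqrt(0.01 / q)  # heavier tail guard for smaller q
    med <- stats::median(x)
    dev <- abs(x - med)
    madv <- stats::mad(x)
    i <- which.max(dev)
    if (dev[i] > k * madv && dev[i] > 0) flagged[i] <- TRUE
  }
  list(values = x[!flagged], flagged = flagged)
}

#' Area under a dilution-series OD curve
#'
#' Trapezoidal area of mean OD against log2(concentration), so 1:2
#' dilution steps are equally spaced with unit width. With
#' `truncate = TRUE`, points at concentrations above the truncation point
#' are dropped before integration: the truncation point is the lowest
#' concentration achieving the series maximum mean OD (or the first mean
#' OD at or above `od_max`, whichever concentration is lower), which
#' excludes the saturated shoulder of curves that plateau.
#'
#' @param series data.frame with columns `concentration` and `od`
#'   (replicate rows allowed; they are averaged per concentration after
#'   optional outlier removal by the caller).
#' @param truncate drop the saturated shoulder (default `FALSE`).
#' @param od_max instrument ceiling (default 3.0).
#' @param truncate_at optional explicit truncation concentration (used to
#'   apply one series' truncation point to a paired series).
#' @return list with `auc`, `concentrations` (those integrated) and
#'   `truncate_at` (the truncation concentration, or `NA`).
#' @export
auc_dilution <- function(series, truncate = FALSE, od_max = 3.0,
                         truncate_at = NA) {
  mean_od <- tapply(series$od, series$concentration, mean)
  conc <- as.numeric(names(mean_od))
  o <- order(conc)
  conc <- conc[o]; mean_od <- as.numeric(mean_od[o])
  if (truncate && is.na(truncate_at)) {
    hit <- which(mean_od >= od_max)
    peak <- which(mean_od >= max(mean_od) - 1e-12)
    truncate_at <- conc[min(c(hit, peak))]
  }
  if (!is.na(truncate_at)) {
    keep <- conc <= truncate_at + 1e-12
    conc <- conc[keep]; mean_od <- mean_od[keep]
  }
  if (length(conc) < 2L) cs_input_error("fewer than 2 points to integrate")
  x <- log2(conc)
  auc <- sum(diff(x) * (utils::head(mean_od, -1) + utils::tail(mean_od, -1)) / 2)
  list(auc = auc, concentrations = conc, truncate_at = truncate_at)
}

# internal: outlier-clean a long-format series (one row per replicate)
clean_series <- function(series, q = 0.01) {
  parts <- split(series, series$concentration)
  cleaned <- lapply(parts, function(w) {
    keep <- !remove_outliers(w$od, q = q)$flagged
    w[keep, , drop = FALSE]
  })
  do.call(rbind, cleaned)
}

#' Classify insulin binding from AUC ratios
#'
#' The binding score of a test mAb is the ratio of its dilution-series AUC
#' to the isotype-negative control's AUC on the same dilution grid. The
#' positivity cutoff is half the positive control's AUC ratio; a test mAb
#' is called positive when its ratio meets the cutoff (inclusive). Both
#' the exact cutoff and its rounded value are reported; the call uses the
#' exact one.
#'
#' @param test,negative,positive data.frames with `concentration`, `od`
#'   (replicate rows), measured on the same dilution grid.
#' @param q outlier-removal rate passed to [remove_outliers()].
#' @param truncate integrate truncated curves (default `FALSE`: full
#'   curves for the binding screen).
#' @return list: `auc`, `auc_negative`, `auc_positive`, `auc_ratio`,
#'   `positive_control_ratio`, `cutoff` (exact), `cutoff_rounded`,
#'   `positive` (logical call).
#' @export
classify_binding <- function(test, negative, positive, q = 0.01,
                             truncate = FALSE) {
  a_t <- auc_dilution(clean_series(test, q), truncate = truncate)$auc
  a_n <- auc_dilution(clean_series(negative, q), truncate = truncate)$auc
  a_p <- auc_dilution(clean_series(positive, q), truncate = truncate)$auc
  if (a_n <= 0) cs_input_error("degenerate negative control (AUC <= 0)")
  ratio <- a_t / a_n
  pos_ratio <- a_p / a_n
  cutoff <- pos_ratio / 2
  list(auc = a_t, auc_negative = a_n, auc_positive = a_p,
       auc_ratio = ratio, positive_control_ratio = pos_ratio,
       cutoff = cutoff, cutoff_rounded = round_half_up(cutoff),
       positive = ratio >= cutoff)
}

#' Percent inhibition of binding by soluble competitor
#'
#' 100 x (1 - AUC(inhibited) / AUC(un-inhibited)), with both curves
#' truncated at the un-inhibited series' truncation point (lowest
#' concentration reaching its maximum or the instrument ceiling), so the
#' saturated shoulder does not dilute the inhibition estimate.
#'
#' @param plain,inhibited data.frames with `concentration` and `od`
#'   (replicate rows) for the buffer and competitor conditions.
#' @param q outlier-removal rate.
#' @param od_max instrument ceiling (default 3.0).
#' @return percent inhibition (<= 100; negative values possible when the
#'   inhibited curve exceeds the plain one).
#' @export
percent_inhibition <- function(plain, inhibited, q = 0.01, od_max = 3.0) {
  ap <- auc_dilution(clean_series(plain, q), truncate = TRUE, od_max = od_max)
  if (ap$auc <= 0) cs_input_error("un-inhibited AUC is not positive")
  ai <- auc_dilution(clean_series(inhibited, q), truncate = TRUE,
                     od_max = od_max, truncate_at = ap$truncate_at)
  100 * (1 - ai$auc / ap$auc)
}
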