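#' Default serial-dilution concentration grid
#'
#' 1:2 dilutions from 10 ug/ml, `n` points (default 8: 10 down to
#' ~0.078 ug/ml).
#'
#' @param n number of dilution points.
#' @return numeric vector of concentrations, descending.
#' @export
dilution_grid <- function(n = 8) 10 / 2^(0:(n - 1))

# internal: saturating binding curve (4PL with bottom = baseline)
binding_curve <- function(conc, baseline, amplitude, ec50, hill = 1) {
  baseline + amplitude / (1 + (ec50 / conc)^hill)
}

#' Build a binder panel specification
#'
#' Describes each simulated mAb by its TRUE target AUC ratio relative to
#' the isotype-negative control (the unit the classifier measures), its
#' EC50, and (for binders tested with competitor) the true inhibition
#' fraction. The curve amplitude is solved from the noise-free trapezoid
#' integral so that a mAb with `true_auc_ratio = r` has exactly r times
#' the negative control's noise-free AUC. Includes the isotype-negative
#' and anti-insulin-positive control rows.
#'
#' @param test data.frame with columns `mab_id`, `true_auc_ratio`,
#'   optionally `ec50` (default 0.3) and `inhibition_fraction` (`NA` when
#'   no competitor series is run).
#' @param positive_ratio true AUC ratio of the positive control
#'   (default 14).
#' @param positive_inhibition inhibition fraction of the positive control
#'   (default 0.88).
#' @param baseline negative-control OD level (default 0.08).
#' @param concentrations dilution grid (default [dilution_grid()]).
#' @return data.frame binder spec with one row per (mAb, role).
#' @export
binder_spec <- function(test, positive_ratio = 14,
                        positive_inhibition = 0.88, baseline = 0.08,
                        concentrations = dilution_grid()) {
  if (!"ec50" %in% names(test)) test$ec50 <- 0.3
  if (!"inhibition_fraction" %in% names(test))
    test$inhibition_fraction <- NA_real_
  if (any(test$ec50 <= 0)) cs_config_error("EC50 must be positive")
  controls <- data.frame(
    mab_id = c("isotype_negative", "anti_insulin_positive"),
    true_auc_ratio = c(1, positive_ratio),
    ec50 = c(0.3, 0.3),
    inhibition_fraction = c(NA_real_, positive_inhibition),
    stringsAsFactors = FALSE)
  spec <- rbind(test[, names(controls)], controls)
  spec$role <- c(rep("test", nrow(test)), "isotype_negative",
                 "anti_insulin_positive")
  spec$baseline <- baseline
  # amplitude A s.t. trapezoid(baseline + A*g) = ratio * trapezoid(baseline)
  x <- log2(sort(concentrations))
  trap <- function(y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  span <- trap(rep(1, length(x)))
  spec$amplitude <- vapply(seq_len(nrow(spec)), function(i) {
    g <- binding_curve(sort(concentrations), 0, 1, spec$ec50[i])
    (spec$true_auc_ratio[i] - 1) * baseline * span / trap(g)
  }, numeric(1))
  attr(spec, "concentrations") <- concentrations
  spec
}

#' Simulate ELISA plates for a binder panel
#'
#' Samples replicate ODs from each mAb's binding curve on the 1:2
#' dilution grid with Gaussian noise, injects gross outliers (a replicate
#' replaced by a uniform draw on \[0, od_max\]) at `outlier_rate`, and
#' clips at the instrument maximum. mAbs with a true inhibition fraction
#' get a paired competitor ("inhibited") series whose specific signal is
#' scaled by (1 - fraction).
#'
#' @param spec binder panel from [binder_spec()].
#' @param n_replicates replicates per well (default 4).
#' @param noise_sd replicate OD noise (default 0.05).
#' @param outlier_rate per-well-replicate gross error rate (default 0.02).
#' @param od_max instrument ceiling (default 3.0).
#' @param seed integer seed.
#' @return long data.frame `plates`: `mab_id`, `role`, `condition`
#'   (`plain`/`inhibited`), `concentration`, `replicate`, `od`, plus
#'   logical `is_outlier` (the injected truth). Attribute `"truth"`
#'   carries the spec.
#' @export
simulate_plates <- function(spec, n_replicates = 4, noise_sd = 0.05,
                            outlier_rate = 0.02, od_max = 3.0, seed = 1L) {
  set.seed(seed)
  conc <- sort(attr(spec, "concentrations"), decreasing = TRUE)
  rows <- list()
  for (i in seq_len(nrow(spec))) {
    conds <- if (!is.na(spec$inhibition_fraction[i]))
      c("plain", "inhibited") else "plain"
    for (cond in conds) {
      mu <- binding_curve(conc, spec$baseline[i], spec$amplitude[i],
                          spec$ec50[i])
      # competitor scales the whole measured curve, so the planted
      # inhibition fraction is exact in AUC terms over any truncation grid
      if (cond == "inhibited") mu <- mu * (1 - spec$inhibition_fraction[i])
      od <- rep(mu, each = n_replicates) +
        stats::rnorm(length(conc) * n_replicates, 0, noise_sd)
      # at most one gross error per replicate group, matching the
      # one-removal design of the outlier screen (same marginal rate)
      hit_well <- stats::runif(length(conc)) < n_replicates * outlier_rate
      outl <- rep(FALSE, length(od))
      for (w in which(hit_well)) {
        j <- (w - 1) * n_replicates + sample.int(n_replicates, 1)
        outl[j] <- TRUE
        od[j] <- stats::runif(1, 0, od_max)
      }
      od <- pmin(pmax(od, 0), od_max)
      rows[[length(rows) + 1L]] <- data.frame(
        mab_id = spec$mab_id[i], role = spec$role[i], condition = cond,
        concentration = rep(conc, each = n_replicates),
        replicate = rep(seq_len(n_replicates), length(conc)),
        od = od, is_outlier = outl, stringsAsFactors = FALSE)
    }
  }
  plates <- do.call(rbind, rows)
  attr(plates, "truth") <- spec
  plates
}
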