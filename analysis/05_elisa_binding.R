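#!/usr/bin/env Rscript
# ELISA screen of a mAb panel drawn from expanded memory clonotypes:
# simulate dilution-series plates (with replicate noise and gross
# outliers), remove outliers, compute AUC ratios against the isotype
# negative control, classify binding at half the positive-control ratio,
# and measure percent inhibition for the binders.

suppressPackageStartupMessages(library(clonoscan))

cells_bcr <- read.csv("results/cells_bcr.csv", stringsAsFactors = FALSE)
qcc <- read.csv("results/cohort/cells_qc.csv", stringsAsFactors = FALSE,
                colClasses = "character")
ct_tab <- read.csv("results/clonotypes.csv", stringsAsFactors = FALSE)

# rebuild the clonotype object surface the panel selector expects
ct <- list(clonotypes = ct_tab, cells = cells_bcr)
ct$clonotypes$members <- lapply(ct$clonotypes$clonotype_id, function(id)
  cells_bcr$cell_id[cells_bcr$clonotype_id == id])

panel <- select_mab_panel(ct, qcc, cells_bcr)
if (is.null(panel)) stop("no expanded memory clonotypes to screen")
message(sprintf("screening %d mAbs (%d planted binders)", nrow(panel),
                sum(panel$true_binder)))

spec <- binder_spec(panel[, c("mab_id", "true_auc_ratio",
                              "inhibition_fraction")])
plates <- simulate_plates(spec, seed = 20260920L)
write.csv(plates, "results/plates.csv", row.names = FALSE)

neg <- plates[plates$role == "isotype_negative" &
                plates$condition == "plain", ]
pos <- plates[plates$role == "anti_insulin_positive" &
                plates$condition == "plain", ]
calls <- do.call(rbind, lapply(panel$mab_id, function(id) {
  tst <- plates[plates$mab_id == id & plates$condition == "plain", ]
  cb <- classify_binding(tst, neg, pos)
  data.frame(mab_id = id, auc_ratio = cb$auc_ratio, cutoff = cb$cutoff,
             cutoff_rounded = cb$cutoff_rounded, positive = cb$positive)
}))
calls <- merge(calls, panel[, c("mab_id", "true_binder", "clonotype_id")])
write.csv(calls, "results/binding_calls.csv", row.names = FALSE)
message(sprintf("positive calls: %d | agreement with truth: %d/%d",
                sum(calls$positive),
                sum(calls$positive == calls$true_binder), nrow(calls)))

inh_ids <- panel$mab_id[!is.na(panel$inhibition_fraction)]
if (length(inh_ids)) {
  inh <- data.frame(
    mab_id = inh_ids,
    truth = 100 * panel$inhibition_fraction[match(inh_ids, panel$mab_id)],
    percent_inhibition = vapply(inh_ids, function(id) {
      percent_inhibition(
        plates[plates$mab_id == id & plates$condition == "plain", ],
        plates[plates$mab_id == id & plates$condition == "inhibited", ])
    }, numeric(1)))
  write.csv(inh, "results/inhibition.csv", row.names = FALSE)
  message("percent inhibition (planted vs measured):")
  print(inh, row.names = FALSE)
}
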