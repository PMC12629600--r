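#!/usr/bin/env Rscript
# BCR repertoire analysis from the AIRR fixture: parse chains, resolve one
# heavy + one light per cell, group into clonotypes (matching V genes +
# >= 85% CDR3 identity, single linkage), flag clonal expansion, quantify
# somatic hypermutation against germline V genes, isotype proportions,
# and the chi-squared test of expanded-cell distribution across clusters.

suppressPackageStartupMessages(library(clonoscan))

out <- "results/cohort"
chains <- read_airr(file.path(out, "repertoire.airr.tsv"))
germ <- read_germline_fasta(file.path(out, "germline.fasta"))
qcc <- read.csv(file.path(out, "cells_qc.csv"), stringsAsFactors = FALSE,
                colClasses = "character")

resolved <- resolve_cell_chains(chains)
resolved <- resolved[resolved$cell_id %in% qcc$cell_id, ]
message(sprintf("resolved %d paired cells (%d putative doublets excluded)",
                nrow(resolved), length(attr(resolved, "doublets"))))
resolved <- annotate_shm(resolved, germ)

ct <- flag_expanded(build_clonotypes(resolved))
message(sprintf("%d clonotypes; %d expanded (max size %d)",
                nrow(ct$clonotypes), sum(ct$clonotypes$expanded),
                max(ct$clonotypes$size)))
write.csv(ct$clonotypes[, setdiff(names(ct$clonotypes), "members")],
          "results/clonotypes.csv", row.names = FALSE)
write.csv(ct$cells, "results/cells_bcr.csv", row.names = FALSE)

shm_sub <- shm_group_test(resolved, qcc, stratum_col = "subset")
shm_cl <- shm_group_test(resolved, qcc, stratum_col = "cluster")
write.csv(shm_sub, "results/shm_subset.csv", row.names = FALSE)
write.csv(shm_cl, "results/shm_cluster.csv", row.names = FALSE)
message("VH SHM by subset (group means, Wilcoxon p):")
print(shm_sub)

iso <- isotype_proportions(resolved, qcc)
write.csv(iso, "results/isotype_proportions.csv", row.names = FALSE)

chi2 <- expansion_distribution_test(ct$cells, qcc)
if (!is.null(chi2)) {
  message(sprintf("expanded-cell distribution: chi2 = %.3f (df %d), p = %.4g%s",
                  chi2$statistic, chi2$df, chi2$p.value,
                  if (chi2$low_expected) " [expected counts < 5]" else ""))
  jsonlite::write_json(list(statistic = chi2$statistic, df = chi2$df,
                            p = chi2$p.value,
                            low_expected = chi2$low_expected),
                       "results/expansion_chi2.json", auto_unbox = TRUE,
                       pretty = TRUE)
}
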