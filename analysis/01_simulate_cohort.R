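#!/usr/bin/env Rscript
# Simulate a desk-scale synthetic cohort (9 stage1 + 8 healthy donors,
# 300-400 cells kept per donor so the whole workflow runs in minutes) and
# write the fixture files every later step consumes. Ground truth (planted
# DE genes, lineage ids, SHM counts, QC failures) goes to
# results/ground_truth.json so each stage's recovery can be checked.

suppressPackageStartupMessages({
  library(clonoscan)
  library(Matrix)
})

out <- "results/cohort"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 20260919L,
                  cells_per_donor = c(300L, 400L),
                  n_genes = 1200L)
sim <- simulate_cohort(cfg)
message(sprintf("simulated %d cells x %d genes across %d donors",
                ncol(sim$rna), nrow(sim$rna),
                length(unique(sim$cells$donor_id))))

invisible(Matrix::writeMM(sim$rna, file.path(out, "matrix.mtx")))
writeLines(rownames(sim$rna), file.path(out, "genes.csv"))
writeLines(colnames(sim$rna), file.path(out, "barcodes.csv"))
write.csv(sim$cells, file.path(out, "cells.csv"), row.names = FALSE)
write.csv(as.data.frame(as.matrix(sim$adt)),
          file.path(out, "adt.csv"))

rep_sim <- simulate_repertoire(sim$cells, cfg)
write_airr(rep_sim$chains_with_alleles, file.path(out, "repertoire.airr.tsv"))
write_germline_fasta(rep_sim$germlines, file.path(out, "germline.fasta"))
write.csv(rep_sim$truth$cells, file.path(out, "repertoire_truth.csv"),
          row.names = FALSE)

truth <- list(
  de_genes = sim$truth$de_genes,
  n_qc_fail_low = length(sim$truth$qc_fail_low),
  n_qc_fail_mito = length(sim$truth$qc_fail_mito),
  n_lineages = length(rep_sim$truth$lineage_sizes),
  lineage_size_table = as.list(table(rep_sim$truth$lineage_sizes)))
jsonlite::write_json(truth, "results/ground_truth.json", auto_unbox = TRUE,
                     pretty = TRUE)
message("wrote ", out, " and results/ground_truth.json")
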