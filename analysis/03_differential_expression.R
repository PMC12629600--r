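#!/usr/bin/env Rscript
# Per-subset differential expression between disease groups with the full
# filter stack (fold change > 1.2, Bonferroni-adjusted p < 0.05, expressed
# in > 30% of cells in either group, Ig/Y genes blocklisted), plus the
# cross-subset shared-gene partition. Reports how many planted genes were
# recovered.

suppressPackageStartupMessages(library(clonoscan))

out <- "results/cohort"
qcc <- read.csv(file.path(out, "cells_qc.csv"), stringsAsFactors = FALSE,
                colClasses = "character")
qcc$qc_pass <- TRUE
norm <- readRDS("scratch/norm.rds")
truth <- jsonlite::read_json("results/ground_truth.json",
                             simplifyVector = TRUE)

bl <- build_blocklist(rownames(norm), y_genes = c("RPS4Y1", "DDX3Y"))
deg <- list()
for (s in unique(qcc$subset)) {
  r <- tryCatch(deg_test(norm, qcc, stratum = s, blocklist = bl,
                         groups = c("stage1", "healthy")),
                warning = function(w) { message(conditionMessage(w)); NULL })
  if (is.null(r)) next
  deg[[s]] <- r
  write.csv(r, sprintf("results/deg_%s.csv", s), row.names = FALSE)
}

counts <- vapply(deg, function(r) sum(r$passes_filters), integer(1))
message("significant genes per subset:")
print(counts)
planted <- truth$de_genes
for (s in names(deg)) {
  pg <- planted$gene[planted$stratum == s]
  if (!length(pg)) next
  hit <- sum(pg %in% deg[[s]]$gene[deg[[s]]$passes_filters])
  message(sprintf("  %s: recovered %d of %d planted genes", s, hit,
                  length(pg)))
}

sets <- lapply(deg, function(r) r$gene[r$passes_filters])
sets <- sets[vapply(sets, length, integer(1)) > 0]
if (length(sets) >= 2) {
  venn <- shared_gene_partition(sets)
  jsonlite::write_json(venn$counts, "results/venn.json", auto_unbox = TRUE,
                       pretty = TRUE)
  message("shared-gene partition:")
  print(venn$counts)
}
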