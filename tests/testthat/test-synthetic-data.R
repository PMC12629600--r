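test_that("identical seed and config reproduce the cohort exactly", {
  cfg <- sim_config(seed = 5, n_donors_per_group = c(stage1 = 2L,
                                                     healthy = 2L),
                    cells_per_donor = c(200L, 220L), n_genes = 400L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$cells, b$cells)
  expect_identical(a$rna, b$rna)
  expect_identical(a$adt, b$adt)
  ra <- simulate_repertoire(a$cells, cfg)
  rb <- simulate_repertoire(b$cells, cfg)
  expect_identical(ra$chains, rb$chains)
  expect_identical(ra$germlines, rb$germlines)
})

test_that("donor design and cluster layout match the cohort blueprint", {
  cfg <- sim_config(seed = 6, cells_per_donor = c(200L, 200L),
                    n_genes = 300L)
  sim <- simulate_cohort(cfg)
  tab <- table(unique(sim$cells[, c("donor_id", "group")])$group)
  expect_equal(unname(tab[c("stage1", "healthy")]), c(9L, 8L),
               ignore_attr = TRUE)
  expect_equal(length(unique(sim$cells$cluster)), 12)
  expect_setequal(unique(sim$cells$subset),
                  c("naive", "memory", "transitional", "activated",
                    "plasmablast"))
})

test_that("invalid probability vectors raise configuration errors", {
  expect_error(sim_config(clonal_size_distribution = c("1" = 0.7,
                                                       "2" = 0.6)),
               class = "clonoscan_config_error")
  expect_error(sim_config(cells_per_donor = c(50L, 100L)),
               class = "clonoscan_config_error")
  expect_error(sim_config(shm_rate_per_cluster = modifyList(
    default_shm_rates(), list("3" = 0.5))),
    class = "clonoscan_config_error")
  # a cluster without an SHM rate is caught at repertoire time too
  cfg <- small_config()
  cells <- data.frame(cell_id = "c1", donor_id = "d", group = "stage1",
                      cluster = "99", stringsAsFactors = FALSE)
  expect_error(simulate_repertoire(cells, cfg),
               class = "clonoscan_config_error")
})

test_that("planted QC failures are recovered by the QC stage", {
  cfg <- sim_config(seed = 7, n_donors_per_group = c(stage1 = 2L,
                                                     healthy = 2L),
                    cells_per_donor = c(300L, 300L), n_genes = 800L,
                    qc_fail_low_rate = 0.05, qc_fail_mito_rate = 0.05)
  sim <- simulate_cohort(cfg)
  ct <- qc_filter(sim$rna, sim$cells)
  planted <- c(sim$truth$qc_fail_low, sim$truth$qc_fail_mito)
  flagged <- ct$cell_id[!ct$qc_pass]
  # every planted failure is flagged
  expect_true(all(planted %in% flagged))
  # chance failures come from the Beta(2,46) mito tail above 0.10
  # (P ~ 0.044); allow binomial noise around it
  expect_lt(length(setdiff(flagged, planted)) / nrow(ct), 0.07)
})

test_that("a zero SHM rate yields germline-identical V regions", {
  cfg <- small_config(shm_rate_per_cluster = modifyList(
    default_shm_rates(), list("0" = 0)))
  cells <- data.frame(cell_id = sprintf("c%03d", 1:40), donor_id = "S01",
                      group = "stage1", cluster = "0",
                      stringsAsFactors = FALSE)
  rs <- simulate_repertoire(cells, cfg)
  res <- annotate_shm(resolve_cell_chains(rs$chains), rs$germlines)
  expect_equal(res$shm_vh_pct, rep(0, nrow(res)))
  expect_equal(res$shm_vl_pct, rep(0, nrow(res)))
})

test_that("lineages stay within CDR3 divergence bounds and cluster as one", {
  cfg <- small_config(seed = 9)
  cells <- data.frame(cell_id = sprintf("c%03d", 1:200), donor_id = "S01",
                      group = "stage1", cluster = "3",
                      stringsAsFactors = FALSE)
  rs <- simulate_repertoire(cells, cfg)
  res <- resolve_cell_chains(rs$chains)
  ct <- build_clonotypes(res)
  truth <- rs$truth$cells
  m <- merge(ct$cells[, c("cell_id", "clonotype_id")],
             truth[, c("cell_id", "lineage_id")], by = "cell_id")
  expect_true(same_partition(m$clonotype_id, m$lineage_id))
  # members are within 15% divergence of their founder's CDR3
  for (lid in names(which(table(truth$lineage_id) >= 3))) {
    ids <- truth$cell_id[truth$lineage_id == lid]
    h <- res$heavy_cdr3_aa[match(ids, res$cell_id)]
    founder <- h[1]
    for (x in h[-1]) expect_gte(cdr3_identity(founder, x), 0.85)
  }
})

test_that("lineage size histogram follows the configured distribution", {
  p <- c("1" = 0.8, "2" = 0.1, "12" = 0.1)
  cfg <- sim_config(seed = 10, clonal_size_distribution = p,
                    cells_per_donor = c(9000L, 9000L), n_genes = 300L)
  cells <- data.frame(cell_id = sprintf("c%05d", 1:9000), donor_id = "S01",
                      group = "stage1", cluster = "1",
                      stringsAsFactors = FALSE)
  rs <- simulate_repertoire(cells, cfg)
  sizes <- rs$truth$lineage_sizes
  # drop the final (possibly truncated) lineage
  sizes <- sizes[-length(sizes)]
  n <- length(sizes)
  for (s in c(1, 2, 12)) {
    phat <- mean(sizes == s)
    se <- sqrt(p[[as.character(s)]] * (1 - p[[as.character(s)]]) / n)
    expect_lt(abs(phat - p[[as.character(s)]]), 4 * se + 1e-3)
  }
})

test_that("hand-built size-4 lineage with one edit per descendant links up", {
  founder <- "CARDGYSSGWYFW"  # 13-mer
  edit_at <- function(s, p, to) { v <- strsplit(s, "")[[1]]; v[p] <- to
    paste0(v, collapse = "") }
  d1 <- edit_at(founder, 5, "A")
  d2 <- edit_at(founder, 8, "T")
  d3 <- edit_at(founder, 11, "K")
  cdr3s <- c(founder, d1, d2, d3)
  ids <- outer(cdr3s, cdr3s, Vectorize(cdr3_identity))
  expect_true(all(ids >= 11 / 13 - 1e-12))   # all pairwise >= 0.846
  cells <- make_cells_bcr(c("f", "d1", "d2", "d3"), "d1", "IGHV1", "IGKV1",
                          cdr3s, "CQQYNSYSW")
  ct <- build_clonotypes(cells)
  expect_equal(nrow(ct$clonotypes), 1)
  expect_equal(ct$clonotypes$size, 4)
})

test_that("simulated plates carry exact AUC-ratio and inhibition truth", {
  test <- data.frame(mab_id = c("flat", "pos14"),
                     true_auc_ratio = c(1, 14),
                     inhibition_fraction = c(NA, 0.88))
  spec <- binder_spec(test)
  pl <- simulate_plates(spec, noise_sd = 0, outlier_rate = 0, seed = 2)
  neg <- pl[pl$role == "isotype_negative" & pl$condition == "plain", ]
  pos <- pl[pl$role == "anti_insulin_positive" & pl$condition == "plain", ]
  # noise-free: a flat non-binder has AUC ratio exactly 1
  cb <- classify_binding(pl[pl$mab_id == "flat" & pl$condition == "plain", ],
                         neg, pos)
  expect_equal(cb$auc_ratio, 1, tolerance = 1e-9)
  expect_false(cb$positive)
  cb2 <- classify_binding(pl[pl$mab_id == "pos14" &
                               pl$condition == "plain", ], neg, pos)
  expect_equal(cb2$auc_ratio, 14, tolerance = 1e-9)
  expect_true(cb2$positive)
  # planted inhibition is exact in AUC terms
  pi <- percent_inhibition(
    pl[pl$mab_id == "pos14" & pl$condition == "plain", ],
    pl[pl$mab_id == "pos14" & pl$condition == "inhibited", ])
  expect_equal(pi, 88, tolerance = 1e-9)
  expect_error(binder_spec(data.frame(mab_id = "x", true_auc_ratio = 2,
                                      ec50 = -1)),
               class = "clonoscan_config_error")
})

test_that("doublet planting produces excluded putative doublets", {
  cfg <- small_config(seed = 12, doublet_rate = 0.2)
  cells <- data.frame(cell_id = sprintf("c%03d", 1:100), donor_id = "S01",
                      group = "stage1", cluster = "1",
                      stringsAsFactors = FALSE)
  rs <- simulate_repertoire(cells, cfg)
  res <- resolve_cell_chains(rs$chains)
  # extra heavies alone do not make a doublet under the 2H+2L rule; the
  # best-UMI heavy (the original, higher UMI) is kept
  expect_equal(nrow(res), 100)
  tr <- rs$truth$cells
  expect_equal(res$vh_gene, tr$vh_gene[match(res$cell_id, tr$cell_id)])
})
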