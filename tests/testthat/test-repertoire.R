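airr_path <- function(df) {
  p <- tempfile(fileext = ".tsv")
  utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}

test_that("AIRR parsing strips alleles and drops CDR3-less rows", {
  df <- data.frame(
    cell_id = c("c1", "c1", "c2"), locus = c("IGH", "IGK", "IGH"),
    v_call = c("IGHV3-15*01", "IGKV1-5*02", "IGHV1-2*01"),
    j_call = c("IGHJ4*02", "IGKJ2*01", "IGHJ6*01"),
    productive = c("T", "T", "T"),
    cdr3_aa = c("CARDYW", "CQQYNSW", ""),
    cdr3 = c("TGT", "TGT", ""),
    sequence = c("ACGT", "ACGT", "ACGT"), stringsAsFactors = FALSE)
  ch <- suppressMessages(read_airr(airr_path(df)))
  expect_equal(nrow(ch), 2)            # row without CDR3 dropped
  expect_equal(ch$v_call, c("IGHV3-15", "IGKV1-5"))
  expect_equal(ch$j_call, c("IGHJ4", "IGKJ2"))
})

test_that("AIRR parsing errors name the missing column; empty file warns", {
  df <- data.frame(cell_id = "c1", locus = "IGH", v_call = "IGHV1-2",
                   productive = "T", cdr3_aa = "CARW", sequence = "ACGT",
                   stringsAsFactors = FALSE)
  expect_error(read_airr(airr_path(df)), "j_call",
               class = "clonoscan_input_error")
  empty <- df[0, c("cell_id", "locus", "v_call", "productive", "cdr3_aa",
                   "sequence")]
  expect_warning(out <- read_airr(airr_path(empty)), "empty")
  expect_equal(nrow(out), 0)
})

test_that("AIRR round-trip through the writer preserves chain records", {
  cfg <- small_config(seed = 21, n_donors_per_group = c(stage1 = 1L,
                                                        healthy = 1L))
  cells <- data.frame(cell_id = sprintf("c%03d", 1:60), donor_id = "S01",
                      group = "stage1", cluster = "1",
                      stringsAsFactors = FALSE)
  rs <- simulate_repertoire(cells, cfg)
  p <- tempfile(fileext = ".tsv")
  write_airr(rs$chains_with_alleles, p)
  back <- read_airr(p)
  expect_equal(nrow(back), nrow(rs$chains))
  expect_equal(sort(unique(back$v_call)), sort(unique(rs$chains$v_call)))
  expect_true(all(back$productive))
  # productive junctions translate without internal stops
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(back$cdr3_nt)))
  expect_false(any(grepl("\\*", aa)))
  expect_equal(aa, back$cdr3_aa)
})

test_that("chain resolution applies the UMI/length/lexicographic tie-break", {
  ch <- data.frame(
    cell_id = c("c1", "c1", "c1", "c2", "c3", "c3", "c3", "c3"),
    locus = c("IGH", "IGH", "IGK", "IGK", "IGH", "IGH", "IGK", "IGK"),
    v_call = c("IGHV1", "IGHV2", "IGKV1", "IGKV1",
               "IGHV1", "IGHV2", "IGKV1", "IGKV2"),
    j_call = "J", c_call = c("IGHM", "IGHM", "IGKC", "IGKC",
                             "IGHG1", "IGHM", "IGKC", "IGKC"),
    cdr3_nt = c("AAA", "CCC", "GGG", "TTT", "AAA", "CCC", "GGG", "TTT"),
    cdr3_aa = c("CAW", "CSW", "CQW", "CLW", "CAW", "CSW", "CQW", "CLW"),
    productive = TRUE, in_frame = TRUE,
    umi_count = c(10L, 3L, 5L, 5L, 8L, 8L, 4L, 4L),
    v_sequence = c("ACGTACGT", "ACGT", "ACGT", "ACGT",
                   "ACGTACGT", "ACGT", "ACGT", "ACGT"),
    donor_id = "d1", stringsAsFactors = FALSE)
  res <- resolve_cell_chains(ch)
  # c1: heavy umi 10 beats 3; c2 has only a light chain -> excluded;
  # c3: two heavies AND two lights -> putative doublet, excluded
  expect_equal(res$cell_id, "c1")
  expect_equal(res$vh_gene, "IGHV1")
  expect_equal(attr(res, "doublets"), "c3")
  expect_equal(res$isotype, "IGHM")
})

test_that("CDR3 identity follows hamming/Levenshtein rules and is symmetric", {
  expect_equal(cdr3_identity("CARDGYSSGWYFDYW", "CARDGYSSGWYFDYW"), 1)
  # 13-mers differing at 2 positions: 11/13, just under the 0.85 threshold
  expect_equal(cdr3_identity("CARDGYSSGWYFW", "CARDGYSSGAYFF"), 11 / 13)
  expect_lt(cdr3_identity("CARDGYSSGWYFW", "CARDGYSSGAYFF"), 0.85)
  # unequal length: Levenshtein 1 over max length 5
  expect_equal(cdr3_identity("CARDY", "CARD"), 0.8)
  set.seed(31)
  strs <- random_cdr3_block(20, seed = 31)
  for (i in 1:19) {
    expect_equal(cdr3_identity(strs[i], strs[i + 1]),
                 cdr3_identity(strs[i + 1], strs[i]))
    expect_equal(cdr3_identity(strs[i], strs[i]) == 1, TRUE)
  }
  expect_error(cdr3_identity("", "CAR"), class = "clonoscan_input_error")
})

test_that("single linkage merges identity chains and V genes partition", {
  # A-B and B-C linked (12/13 = 0.923), A-C only 11/13 = 0.846 < 0.85:
  # one clonotype by transitivity
  A <- "CARDGYSSGWYFW"
  B <- sub("GYS", "GYT", A)             # 1 edit from A
  C <- sub("WYF", "AYF", B)             # 1 edit from B, 2 from A
  cells <- make_cells_bcr(c("a", "b", "c"), "d1", "IGHV1", "IGKV1",
                          c(A, B, C), "CQQYNSYSW")
  ct <- build_clonotypes(cells)
  expect_equal(nrow(ct$clonotypes), 1)
  expect_equal(ct$clonotypes$size, 3)
  # same CDR3s, different light V gene -> separate clonotypes
  cells2 <- make_cells_bcr(c("a", "b"), "d1", "IGHV1", c("IGKV1", "IGKV3"),
                           A, "CQQYNSYSW")
  expect_equal(nrow(build_clonotypes(cells2)$clonotypes), 2)
  # both-chain rule: heavy identical but light CDR3s unrelated -> split
  cells3 <- make_cells_bcr(c("a", "b"), "d1", "IGHV1", "IGKV1", A,
                           c("CQQYNSYSW", "CLLTWDAFW"))
  expect_equal(nrow(build_clonotypes(cells3)$clonotypes), 2)
  expect_equal(nrow(build_clonotypes(cells3,
                                     chain_mode = "heavy")$clonotypes), 1)
})

test_that("clonotype partition is input-order invariant and conserves cells", {
  set.seed(41)
  n <- 120
  cells <- make_cells_bcr(sprintf("c%03d", 1:n),
                          sample(c("d1", "d2"), n, TRUE),
                          sample(c("IGHV1", "IGHV2"), n, TRUE),
                          sample(c("IGKV1", "IGKV2"), n, TRUE),
                          random_cdr3_block(n, seed = 42),
                          random_cdr3_block(n, seed = 43))
  ct1 <- build_clonotypes(cells)
  perm <- sample(n)
  ct2 <- build_clonotypes(cells[perm, ])
  m1 <- ct1$cells[order(ct1$cells$cell_id), c("cell_id", "clonotype_id")]
  m2 <- ct2$cells[order(ct2$cells$cell_id), c("cell_id", "clonotype_id")]
  expect_equal(m1, m2, ignore_attr = TRUE)
  expect_equal(sum(ct1$clonotypes$size), n)
})

test_that("union-find equals brute-force transitive closure on random blocks", {
  for (r in 1:25) {
    n <- sample(5:60, 1)
    hs <- random_cdr3_block(n, seed = 500 + r)
    ls <- random_cdr3_block(n, seed = 900 + r)
    cells <- make_cells_bcr(sprintf("c%03d", 1:n), "d1", "IGHV1", "IGKV1",
                            hs, ls)
    ct <- build_clonotypes(cells)
    got <- ct$cells$clonotype_id[match(sprintf("c%03d", 1:n),
                                       ct$cells$cell_id)]
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      adj[i, j] <- cdr3_identity(hs[i], hs[j]) >= 0.85 &&
        cdr3_identity(ls[i], ls[j]) >= 0.85
    }
    expect_true(same_partition(got, brute_components(adj)))
  }
})

test_that("expansion flags follow the n >= 2 rule", {
  sizes <- c(1L, 2L, 12L)
  cells <- make_cells_bcr(sprintf("c%02d", 1:15), "d1",
                          rep(c("IGHV1", "IGHV2", "IGHV3"), sizes),
                          "IGKV1",
                          rep(c("CARAAAAAW", "CARCCCCCW", "CARDDDDDW"),
                              sizes),
                          "CQQYNSYSW")
  ct <- flag_expanded(build_clonotypes(cells))
  expect_equal(sort(ct$clonotypes$size), sizes)
  expect_equal(ct$clonotypes$expanded[order(ct$clonotypes$size)],
               c(FALSE, TRUE, TRUE))
})

test_that("SHM percent is mismatches over aligned columns, junction-free", {
  set.seed(51)
  germ <- paste0(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  expect_equal(compute_shm(germ, germ), 0)
  mut <- function(s, pos) {
    v <- strsplit(s, "")[[1]]
    for (p in pos) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
    paste0(v, collapse = "")
  }
  expect_equal(compute_shm(mut(germ, c(50, 150, 250)), germ), 1.0)
  germ286 <- substr(germ, 1, 286)
  expect_equal(compute_shm(mut(germ286, 100), germ286), 100 / 286,
               tolerance = 1e-9)
  expect_equal(round(compute_shm(mut(germ286, 100), germ286), 2), 0.35)
  # a junction + J tail appended to the V region does not change SHM
  tail <- paste0(sample(c("A", "C", "G", "T"), 45, TRUE), collapse = "")
  obs <- paste0(mut(germ, c(50, 150, 250)), tail)
  expect_equal(compute_shm(obs, germ), 1.0, tolerance = 0.2)
})

test_that("SHM estimator recovers per-site mutation rates within 3 SE", {
  set.seed(52)
  germ <- paste0(sample(c("A", "C", "G", "T"), 294, TRUE), collapse = "")
  for (mu in c(0.005, 0.01, 0.04)) {
    n <- 150
    est <- vapply(seq_len(n), function(i) {
      k <- rbinom(1, 294, mu)
      v <- strsplit(germ, "")[[1]]
      pos <- sample(294, k)
      for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
      compute_shm(paste0(v, collapse = ""), germ)
    }, numeric(1)) / 100
    se <- sd(est) / sqrt(n)
    expect_lt(abs(mean(est) - mu), 3 * se + 1e-4)
  }
})

test_that("per-stratum SHM comparison reports means and exact p", {
  cells <- data.frame(cell_id = sprintf("c%d", 1:8),
                      shm_vh_pct = c(0.1, 0.2, 0.3, 0.4, 1, 1, 1, 1),
                      stringsAsFactors = FALSE)
  meta <- data.frame(cell_id = sprintf("c%d", 1:8),
                     group = rep(c("stage1", "healthy"), 4),
                     subset = rep(c("memory", "naive"), each = 4),
                     stringsAsFactors = FALSE)
  res <- shm_group_test(cells, meta)
  mem <- res[res$stratum == "memory", ]
  # memory: stage1 {0.1, 0.3} vs healthy {0.2, 0.4} -> enumeration over
  # C(4,2): 6 of 6 splits as extreme as observed? ranks 1,3 vs 2,4:
  # |sum-5|=1; splits with deviation >= 1: {1,2},{1,3},{2,4},{3,4} -> 4/6
  expect_equal(mem$p, 4 / 6)
  naive <- res[res$stratum == "naive", ]
  expect_equal(naive$p, 1)  # all tied
  expect_equal(naive$mean_shm_stage1, 1)
})

test_that("group SHM contrast at study effect size rejects reliably", {
  # planted 2.42% vs 3.52% per-site rates, 200 cells per group
  set.seed(53)
  germ <- paste0(sample(c("A", "C", "G", "T"), 294, TRUE), collapse = "")
  rej <- 0L; n_rep <- 20
  for (r in seq_len(n_rep)) {
    shm1 <- 100 * rbinom(200, 294, 0.0242) / 294
    shm2 <- 100 * rbinom(200, 294, 0.0352) / 294
    p <- wilcox_rank_sum(shm1, shm2)$p.value
    if (p < 0.05) rej <- rej + 1L
  }
  expect_gte(rej / n_rep, 0.95)
})

test_that("isotype proportions sum to one and bin missing calls", {
  cells <- data.frame(cell_id = sprintf("c%d", 1:5),
                      isotype = c("IGHM", "IGHM", "IGHM", "IGHD", NA),
                      stringsAsFactors = FALSE)
  meta <- data.frame(cell_id = sprintf("c%d", 1:5), cluster = "3",
                     group = "stage1", stringsAsFactors = FALSE)
  res <- isotype_proportions(cells, meta)
  expect_equal(sum(res$proportion), 1)
  expect_equal(res$proportion[res$isotype == "IGHM"], 0.6)
  expect_equal(res$proportion[res$isotype == "unknown"], 0.2)
  # single-isotype cluster -> proportion 1
  res2 <- isotype_proportions(cells[1:3, ], meta[1:3, ])
  expect_equal(res2$proportion[res2$count > 0], 1)
})

test_that("expansion chi-squared matches the hand formula", {
  mkcells <- function(counts) {
    # counts: matrix clusters x groups of expanded cells
    rows <- list()
    k <- 0
    for (i in seq_len(nrow(counts))) for (j in seq_len(ncol(counts))) {
      if (counts[i, j] == 0) next
      ids <- sprintf("e%04d", k + seq_len(counts[i, j])); k <- k + length(ids)
      rows[[length(rows) + 1]] <- data.frame(
        cell_id = ids, cluster = rownames(counts)[i],
        group = colnames(counts)[j], stringsAsFactors = FALSE)
    }
    meta <- do.call(rbind, rows)
    cells <- data.frame(cell_id = meta$cell_id, expanded = TRUE,
                        stringsAsFactors = FALSE)
    list(cells = cells, meta = meta)
  }
  tab <- matrix(c(10, 20, 20, 10), 2, dimnames = list(c("1", "3"),
                                                      c("healthy", "stage1")))
  fx <- mkcells(tab)
  res <- expansion_distribution_test(fx$cells, fx$meta)
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-6)  # 6.6667 by hand
  expect_equal(res$df, 1)
  # identical distributions -> statistic 0, p = 1
  tab2 <- matrix(c(15, 15, 15, 15), 2, dimnames = dimnames(tab))
  fx2 <- mkcells(tab2)
  res2 <- expansion_distribution_test(fx2$cells, fx2$meta)
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p.value, 1)
  # a group without expanded cells -> NULL with warning
  tab3 <- matrix(c(10, 10, 0, 0), 2, dimnames = dimnames(tab))
  fx3 <- mkcells(tab3)
  fx3$meta <- rbind(fx3$meta,
                    data.frame(cell_id = "x1", cluster = "1",
                               group = "stage1", stringsAsFactors = FALSE))
  fx3$cells <- rbind(fx3$cells,
                     data.frame(cell_id = "x1", expanded = FALSE,
                                stringsAsFactors = FALSE))
  expect_warning(res3 <- expansion_distribution_test(fx3$cells, fx3$meta))
  expect_null(res3)
})
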