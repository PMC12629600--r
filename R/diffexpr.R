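#' Build the differential-expression gene blocklist
#'
#' Immunoglobulin variable and joining segments of all three loci, kappa
#' and lambda constant genes, and Y-chromosome genes are excluded from
#' differential expression: V(D)J usage tracks clonal composition rather
#' than transcriptional state, and Y genes track donor sex. Membership is
#' decided by symbol pattern (IGHV/IGKV/IGLV, IGHJ/IGKJ/IGLJ, IGKC/IGLC)
#' plus a supplied list of Y-chromosome symbols. Heavy-chain constant
#' genes (IGHM, IGHG1, ...) are deliberately not blocked.
#'
#' @param genes character vector of gene symbols present in the data.
#' @param y_genes character vector of Y-chromosome gene symbols.
#' @return character vector: the blocked subset of `genes`.
#' @export
build_blocklist <- function(genes, y_genes = character()) {
  pat <- "^IG(HV|KV|LV|HJ|KJ|LJ|KC|LC)"
  sort(unique(c(grep(pat, genes, value = TRUE), intersect(genes, y_genes))))
}

# internal: per-gene Wilcoxon + summary statistics between two cell sets
deg_gene_stats <- function(norm, cells1, cells2, eps = 1e-9) {
  m1 <- norm[, cells1, drop = FALSE]
  m2 <- norm[, cells2, drop = FALSE]
  mean1 <- Matrix::rowMeans(expm1(m1))
  mean2 <- Matrix::rowMeans(expm1(m2))
  fc <- (mean1 + eps) / (mean2 + eps)
  pct1 <- Matrix::rowMeans(m1 > 0)
  pct2 <- Matrix::rowMeans(m2 > 0)
  d1 <- as.matrix(m1); d2 <- as.matrix(m2)
  p <- vapply(seq_len(nrow(norm)), function(i) {
    wilcox_rank_sum(d1[i, ], d2[i, ])$p.value
  }, numeric(1))
  data.frame(gene = rownames(norm), fold_change = as.numeric(fc),
             log2fc = log2(as.numeric(fc)),
             pct_group1 = as.numeric(pct1), pct_group2 = as.numeric(pct2),
             p_raw = p, stringsAsFactors = FALSE)
}

#' Per-stratum Wilcoxon differential expression with filter stack
#'
#' For one stratum (a cluster or collapsed subset), tests every gene
#' between the two disease groups with a two-sided Wilcoxon rank-sum test
#' on normalized expression. Fold change is the ratio of group means on
#' the de-logged (`expm1`) scale with a small epsilon; percent expressed
#' is the fraction of cells with any counts. Adjusted p values are
#' Bonferroni over `p_adjust_n` genes. A gene passes the filter stack iff
#' `fold_change > fc` AND `p_adj < alpha` AND expressed in more than
#' `min_pct` of cells in either group AND not on the blocklist.
#'
#' @param norm normalized genes x cells matrix (see [normalize_rna()]).
#' @param cells per-cell metadata with `cell_id`, the group column, and the
#'   stratum column; only `qc_pass` cells are used when that column exists.
#' @param stratum stratum value to test (or `NULL` to use all cells).
#' @param stratum_col metadata column holding the stratum (default "subset").
#' @param group_col metadata column with the two group labels.
#' @param groups optional character(2): which level is the "up" group
#'   (group 1) and the reference; defaults to sorted unique levels.
#' @param blocklist genes excluded from passing (see [build_blocklist()]).
#' @param fc fold-change threshold (default 1.2, strict).
#' @param alpha adjusted-p threshold (default 0.05, strict).
#' @param min_pct percent-expressed threshold (default 0.30, strict,
#'   in either group).
#' @param min_cells minimum cells per group to run the stratum (default 3).
#' @param p_adjust_n Bonferroni factor; default `nrow(norm)` (all genes in
#'   the object, the reference single-cell convention).
#' @return data.frame of per-gene records sorted by `p_adj` then
#'   decreasing fold change, with `passes_filters`; `NULL` (with a
#'   warning) if the stratum has too few cells in either group.
#' @export
deg_test <- function(norm, cells, stratum = NULL, stratum_col = "subset",
                     group_col = "group", groups = NULL,
                     blocklist = character(), fc = 1.2, alpha = 0.05,
                     min_pct = 0.30, min_cells = 3,
                     p_adjust_n = nrow(norm)) {
  if ("qc_pass" %in% names(cells)) cells <- cells[cells$qc_pass, , drop = FALSE]
  if (!is.null(stratum))
    cells <- cells[as.character(cells[[stratum_col]]) == as.character(stratum),
                   , drop = FALSE]
  if (is.null(groups))
    groups <- sort(unique(as.character(cells[[group_col]])))
  c1 <- cells$cell_id[as.character(cells[[group_col]]) == groups[1]]
  c2 <- cells$cell_id[as.character(cells[[group_col]]) == groups[2]]
  if (length(c1) < min_cells || length(c2) < min_cells) {
    warning(sprintf("stratum '%s' skipped: fewer than %d cells in a group",
                    as.character(stratum %||% "all"), min_cells))
    return(NULL)
  }
  res <- deg_gene_stats(norm, c1, c2)
  res$p_adj <- pmin(1, res$p_raw * p_adjust_n)
  res$passes_filters <- res$fold_change > fc & res$p_adj < alpha &
    pmax(res$pct_group1, res$pct_group2) > min_pct &
    !(res$gene %in% blocklist)
  res$stratum <- as.character(stratum %||% "all")
  res[order(res$p_adj, -res$fold_change), ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Partition significant genes by membership pattern across strata
#'
#' Exact Venn-style partition: every gene appearing in at least one
#' stratum's significant set is assigned to the region named by the
#' strata that contain it.
#'
#' @param sets named list of character vectors (per-stratum gene sets).
#' @return list with `regions` (named list, region label "a+b" -> genes)
#'   and `counts` (named integer vector of region sizes).
#' @export
shared_gene_partition <- function(sets) {
  if (length(sets) < 2L) cs_input_error("need >= 2 strata")
  universe <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1,
                                               dimnames = list(NULL, names(sets)))
  label <- apply(member, 1, function(m) paste(names(sets)[m], collapse = "+"))
  regions <- split(universe, label)
  list(regions = regions,
       counts = vapply(regions, length, integer(1)))
}

#' Insulin-binding vs non-binding cell contrast
#'
#' Ranks genes by fold change between a small set of antigen-binding cells
#' (IBCs) and non-binding cells from the same clonally-expanded pool.
#' Genes must be expressed in at least `min_pct_ibc` of the IBC group
#' (inclusive) and show at least `fc` fold change (inclusive); the top
#' `top_n` by fold change are reported. Adjusted p values are reported for
#' reference but are NOT a filter: at these cell numbers significance is
#' not expected. A background cluster can be down-sampled (seeded) for
#' display alongside the contrast.
#'
#' @param norm normalized genes x cells matrix.
#' @param ibc_cells,non_ibc_cells disjoint character vectors of cell ids.
#' @param background_cells optional cell ids of the background cluster.
#' @param seed integer seed for the background down-sample.
#' @param min_pct_ibc minimum fraction of IBCs expressing the gene
#'   (default 0.50, inclusive).
#' @param fc minimum fold change (default 1.2, inclusive).
#' @param top_n maximum genes reported (default 40; fewer if fewer pass).
#' @param downsample_n background down-sample size (default 100).
#' @param p_adjust_n Bonferroni factor (default all genes).
#' @return data.frame of passing genes ranked by decreasing fold change
#'   (at most `top_n` rows), with attribute `"display_cells"` holding the
#'   down-sampled background cell ids.
#' @export
ibc_contrast <- function(norm, ibc_cells, non_ibc_cells,
                         background_cells = NULL, seed = 1L,
                         min_pct_ibc = 0.50, fc = 1.2, top_n = 40,
                         downsample_n = 100, p_adjust_n = nrow(norm)) {
  if (length(intersect(ibc_cells, non_ibc_cells)))
    cs_input_error("IBC and non-IBC sets must be disjoint")
  if (length(ibc_cells) < 2L || length(non_ibc_cells) < 2L)
    cs_input_error("need >= 2 cells per group")
  res <- deg_gene_stats(norm, ibc_cells, non_ibc_cells)
  names(res)[names(res) == "pct_group1"] <- "pct_ibc"
  names(res)[names(res) == "pct_group2"] <- "pct_non_ibc"
  res$p_adj <- pmin(1, res$p_raw * p_adjust_n)
  keep <- res$pct_ibc >= min_pct_ibc & res$fold_change >= fc
  res <- res[keep, , drop = FALSE]
  res <- res[order(-res$fold_change), , drop = FALSE]
  res <- utils::head(res, top_n)
  display <- NULL
  if (!is.null(background_cells)) {
    set.seed(seed)
    display <- sample(background_cells,
                      min(downsample_n, length(background_cells)))
  }
  attr(res, "display_cells") <- display
  res
}
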