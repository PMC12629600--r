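#' Cell quality control
#'
#' Flags cells for removal using the standard droplet-QC rules: a cell is
#' removed iff it has fewer than `min_features` detected RNA features or
#' more than `max_mito` of its counts in mitochondrial genes (strict
#' inequalities on both sides, so a cell at exactly 200 features and
#' exactly 10% mitochondrial content is retained). Mitochondrial genes are
#' identified by name prefix.
#'
#' @param counts genes x cells count matrix (dense or `dgCMatrix`) with
#'   gene rownames and cell-id colnames.
#' @param cells data.frame of per-cell metadata with a `cell_id` column
#'   (plus typically `donor_id`, `group`, `cluster`).
#' @param min_features minimum detected features to keep a cell (default 200).
#' @param max_mito maximum tolerated mitochondrial fraction (default 0.10).
#' @param mito_prefix gene-name prefix identifying mitochondrial genes
#'   (default `"MT-"`).
#' @return `cells` augmented with `n_rna_features`, `mito_fraction` and
#'   `qc_pass`, with an attribute `"removed_per_donor"` giving the number
#'   of removed cells per donor.
#' @export
qc_filter <- function(counts, cells, min_features = 200, max_mito = 0.10,
                      mito_prefix = "MT-") {
  if (nrow(counts) == 0L || ncol(counts) == 0L)
    cs_input_error("empty count matrix")
  if (!all(cells$cell_id %in% colnames(counts)))
    cs_input_error("cells missing from count matrix")
  counts <- counts[, cells$cell_id, drop = FALSE]
  nfeat <- Matrix::colSums(counts > 0)
  lib <- Matrix::colSums(counts)
  mito_genes <- grep(paste0("^", mito_prefix), rownames(counts), value = TRUE)
  mito <- if (length(mito_genes))
    Matrix::colSums(counts[mito_genes, , drop = FALSE]) / pmax(lib, 1)
  else rep(0, ncol(counts))
  cells$n_rna_features <- as.integer(nfeat)
  cells$mito_fraction <- as.numeric(mito)
  cells$qc_pass <- cells$n_rna_features >= min_features &
    cells$mito_fraction <= max_mito
  removed <- cells[!cells$qc_pass, , drop = FALSE]
  attr(cells, "removed_per_donor") <-
    if (nrow(removed)) table(removed$donor_id) else table(character(0))
  cells
}

#' Library-size normalization of RNA counts
#'
#' Scales each cell to `scale_factor` total counts and applies `log1p`
#' ("log1p-CP10K"). Used in place of variance-stabilizing transforms for
#' all downstream expression statistics; scale-invariant per cell.
#'
#' @param counts genes x cells count matrix (QC-passed cells).
#' @param scale_factor target library size (default 1e4).
#' @return normalized matrix of the same shape, with attribute
#'   `normalization = "log1p-CP10K"`.
#' @export
normalize_rna <- function(counts, scale_factor = 1e4) {
  lib <- Matrix::colSums(counts)
  if (any(lib == 0)) cs_input_error("cell with all-zero counts")
  out <- counts %*% Matrix::Diagonal(x = scale_factor / lib)
  out <- log1p(out)
  dimnames(out) <- dimnames(counts)
  attr(out, "normalization") <- "log1p-CP10K"
  out
}

#' Centered log-ratio normalization of ADT counts
#'
#' Per cell, x_i -> ln((x_i + 1) / geometric mean(x + 1)) across all
#' surface markers, the standard CITE-seq ADT transform. Each cell's
#' transformed values sum to zero.
#'
#' @param adt markers x cells count matrix (non-negative).
#' @return dense matrix of CLR values with attribute `normalization = "CLR"`.
#' @export
clr_normalize_adt <- function(adt) {
  adt <- as.matrix(adt)
  if (any(adt < 0)) cs_input_error("ADT counts must be non-negative")
  lg <- log(adt + 1)
  out <- sweep(lg, 2, colMeans(lg), "-")
  attr(out, "normalization") <- "CLR"
  out
}

#' Collapse fine clusters into major B cell subsets
#'
#' @param cells per-cell metadata with a `cluster` column.
#' @param mapping named character vector, cluster id -> subset name; every
#'   observed cluster must be mapped.
#' @return `cells` with a `subset` column; attributes
#'   `"donor_cluster_counts"` and `"donor_subset_counts"` hold the
#'   per-donor tabulations.
#' @export
collapse_subsets <- function(cells, mapping) {
  cl <- as.character(cells$cluster)
  missing <- setdiff(unique(cl), names(mapping))
  if (length(missing))
    cs_config_error(paste0("clusters without subset mapping: ",
                           paste(missing, collapse = ", ")))
  cells$subset <- unname(mapping[cl])
  attr(cells, "donor_cluster_counts") <- table(cells$donor_id, cells$cluster)
  attr(cells, "donor_subset_counts") <- table(cells$donor_id, cells$subset)
  cells
}

#' Per-donor cluster-frequency group comparison
#'
#' For each donor, the frequency of each cluster (or subset) among that
#' donor's QC-passed cells; each cluster is then compared between the two
#' disease groups with a two-sided Wilcoxon rank-sum test on the per-donor
#' frequencies (exact whenever enumeration is feasible, see
#' [wilcox_rank_sum()]).
#'
#' @param cells per-cell metadata with `donor_id`, `group`, the stratum
#'   column, and optionally `qc_pass` (if present, only passing cells count).
#' @param by stratum column to tabulate, `"cluster"` or `"subset"`.
#' @param group_col grouping column (two levels required).
#' @return data.frame with one row per stratum: group mean frequencies and
#'   the Wilcoxon p value. Attribute `"frequencies"` carries the donor x
#'   stratum frequency matrix.
#' @export
cluster_frequency_test <- function(cells, by = "cluster", group_col = "group") {
  if ("qc_pass" %in% names(cells)) cells <- cells[cells$qc_pass, , drop = FALSE]
  grp_of <- tapply(as.character(cells[[group_col]]), cells$donor_id,
                   function(g) g[1])
  groups <- sort(unique(as.character(cells[[group_col]])))
  if (length(groups) != 2L) cs_input_error("exactly two groups required")
  n_per_donor <- table(cells$donor_id)
  empty <- names(n_per_donor)[n_per_donor == 0]
  if (length(empty)) warning("donors with zero cells excluded: ",
                             paste(empty, collapse = ", "))
  tab <- table(cells$donor_id, as.character(cells[[by]]))
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  freq <- sweep(unclass(tab), 1, rowSums(tab), "/")
  if (any(table(grp_of) < 2)) cs_input_error("need >= 2 donors per group")
  res <- lapply(colnames(freq), function(s) {
    f1 <- freq[names(grp_of)[grp_of == groups[1]], s]
    f2 <- freq[names(grp_of)[grp_of == groups[2]], s]
    wt <- wilcox_rank_sum(f1, f2)
    data.frame(stratum = s, mean_freq_1 = mean(f1), mean_freq_2 = mean(f2),
               p = wt$p.value, exact = wt$exact, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  names(out)[2:3] <- paste0("mean_freq_", groups)
  attr(out, "frequencies") <- freq
  attr(out, "groups") <- groups
  out
}
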