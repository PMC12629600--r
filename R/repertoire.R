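#' Resolve one heavy and one light chain per cell
#'
#' Keeps cells with at least one productive heavy (IGH) and one productive
#' light (IGK/IGL) chain. When a cell carries several productive chains of
#' the same type, the chain with the highest UMI count wins; ties break to
#' the longest sequence, then lexicographically smallest CDR3 nucleotide
#' sequence. Cells that still carry two or more heavy AND two or more
#' light chains are flagged as putative doublets and excluded.
#'
#' @param chains data.frame of chain records (see [read_airr()]).
#' @return data.frame with one row per resolved cell: `cell_id`,
#'   `donor_id`, `vh_gene`, `vl_gene`, `heavy_cdr3_aa`, `heavy_cdr3_nt`,
#'   `light_cdr3_aa`, `light_cdr3_nt`, `heavy_v_sequence`,
#'   `light_v_sequence`, `heavy_c_call`, `isotype`, `heavy_umi`,
#'   `light_umi`. Attribute `"doublets"`: excluded cell ids.
#' @export
resolve_cell_chains <- function(chains) {
  chains <- chains[chains$productive & !is.na(chains$cdr3_aa) &
                     chains$cdr3_aa != "", , drop = FALSE]
  chains$chain_type <- ifelse(chains$locus == "IGH", "heavy",
                              ifelse(chains$locus %in% c("IGK", "IGL"),
                                     "light", NA))
  chains <- chains[!is.na(chains$chain_type), , drop = FALSE]
  if (!nrow(chains)) return(empty_cells_bcr())

  n_by <- table(chains$cell_id, chains$chain_type)
  have_both <- rownames(n_by)[n_by[, "heavy"] >= 1 & n_by[, "light"] >= 1]
  doublets <- rownames(n_by)[n_by[, "heavy"] >= 2 & n_by[, "light"] >= 2]
  keep_cells <- setdiff(have_both, doublets)
  chains <- chains[chains$cell_id %in% keep_cells, , drop = FALSE]

  # best chain per (cell, type): highest UMI, then longest sequence, then
  # lexicographically smallest CDR3 nt
  o <- order(chains$cell_id, chains$chain_type,
             -ifelse(is.na(chains$umi_count), 0L, chains$umi_count),
             -nchar(chains$v_sequence), chains$cdr3_nt)
  chains <- chains[o, , drop = FALSE]
  best <- chains[!duplicated(paste(chains$cell_id, chains$chain_type)), ,
                 drop = FALSE]
  h <- best[best$chain_type == "heavy", , drop = FALSE]
  l <- best[best$chain_type == "light", , drop = FALSE]
  stopifnot(identical(h$cell_id, l$cell_id))
  res <- data.frame(cell_id = h$cell_id, donor_id = h$donor_id,
                    vh_gene = h$v_call, vl_gene = l$v_call,
                    heavy_cdr3_aa = h$cdr3_aa, heavy_cdr3_nt = h$cdr3_nt,
                    light_cdr3_aa = l$cdr3_aa, light_cdr3_nt = l$cdr3_nt,
                    heavy_v_sequence = h$v_sequence,
                    light_v_sequence = l$v_sequence,
                    heavy_v_call = h$v_call, light_v_call = l$v_call,
                    heavy_c_call = h$c_call,
                    isotype = isotype_from_c_call(h$c_call),
                    heavy_umi = h$umi_count, light_umi = l$umi_count,
                    stringsAsFactors = FALSE)
  res <- res[order(res$cell_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "doublets") <- doublets
  res
}

empty_cells_bcr <- function() {
  data.frame(cell_id = character(), donor_id = character(),
             vh_gene = character(), vl_gene = character(),
             heavy_cdr3_aa = character(), heavy_cdr3_nt = character(),
             light_cdr3_aa = character(), light_cdr3_nt = character(),
             heavy_v_sequence = character(), light_v_sequence = character(),
             heavy_v_call = character(), light_v_call = character(),
             heavy_c_call = character(), isotype = character(),
             heavy_umi = integer(), light_umi = integer(),
             stringsAsFactors = FALSE)
}

# internal: isotype from heavy-chain constant gene call
isotype_from_c_call <- function(c_call) {
  iso <- c("IGHM", "IGHD", "IGHG1", "IGHG2", "IGHG3", "IGHG4",
           "IGHA1", "IGHA2", "IGHE")
  out <- rep("unknown", length(c_call))
  for (i in iso) out[!is.na(c_call) & startsWith(c_call, i)] <- i
  out
}

#' CDR3 sequence identity
#'
#' Fraction of identical positions between two CDR3 sequences. Equal
#' lengths: positionwise matches / length. Unequal lengths:
#' `1 - Levenshtein(a, b) / max(nchar)`. Symmetric, in \[0, 1\], and 1 iff
#' the strings are equal.
#'
#' @param a,b non-empty CDR3 strings (amino acid by convention;
#'   nucleotide works identically).
#' @return identity fraction.
#' @examples
#' cdr3_identity("CARDYW", "CARDYW")  # 1
#' cdr3_identity("CARDY", "CARD")     # 0.8
#' @export
cdr3_identity <- function(a, b) {
  if (is.na(a) || is.na(b) || nchar(a) == 0L || nchar(b) == 0L)
    cs_input_error("CDR3 strings must be non-empty")
  la <- nchar(a); lb <- nchar(b)
  if (la == lb) {
    va <- utf8ToInt(a); vb <- utf8ToInt(b)
    sum(va == vb) / la
  } else {
    1 - utils::adist(a, b)[1, 1] / max(la, lb)
  }
}

#' Group cells into clonotypes
#'
#' Within each donor, cells are partitioned by exact (vh_gene, vl_gene)
#' match; within a partition, two cells are linked when BOTH the heavy and
#' the light CDR3 identities reach `threshold` (inclusive), and clonotypes
#' are the connected components (single linkage via union-find). Identity
#' is computed on amino acids by default.
#'
#' @param cells resolved cells (see [resolve_cell_chains()]).
#' @param threshold minimum CDR3 identity (default 0.85).
#' @param chain_mode `"both"` (default) requires the threshold on heavy
#'   and light CDR3s; `"heavy"` on the heavy CDR3 only.
#' @param use_nt compare nucleotide CDR3s instead of amino acid.
#' @return list with `clonotypes` (one row per clonotype: `clonotype_id`,
#'   `donor_id`, `vh_gene`, `vl_gene`, `founder_cdr3_heavy`,
#'   `founder_cdr3_light`, `size`, `expanded` (all `FALSE` until
#'   [flag_expanded()]), plus list-column `members`) and `cells` (input
#'   augmented with `clonotype_id` and `clone_size`). Clonotype ids are
#'   stable under input reordering (cells are canonically sorted first).
#' @export
build_clonotypes <- function(cells, threshold = 0.85,
                             chain_mode = c("both", "heavy"),
                             use_nt = FALSE) {
  chain_mode <- match.arg(chain_mode)
  cells <- cells[order(cells$donor_id, cells$cell_id), , drop = FALSE]
  hcol <- if (use_nt) "heavy_cdr3_nt" else "heavy_cdr3_aa"
  lcol <- if (use_nt) "light_cdr3_nt" else "light_cdr3_aa"
  key <- paste(cells$donor_id, cells$vh_gene, cells$vl_gene, sep = "\r")
  blocks <- split(seq_len(nrow(cells)), key)
  blocks <- blocks[order(vapply(blocks, min, integer(1)))]

  cells$clonotype_id <- NA_character_
  clist <- list()
  for (b in blocks) {
    n <- length(b)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    if (n > 1) {
      hs <- cells[[hcol]][b]; ls <- cells[[lcol]][b]
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        ok <- cdr3_identity(hs[i], hs[j]) >= threshold - 1e-12
        if (ok && chain_mode == "both")
          ok <- cdr3_identity(ls[i], ls[j]) >= threshold - 1e-12
        if (ok) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
    comp <- vapply(seq_len(n), find, integer(1))
    for (root in sort(unique(comp))) {
      idx <- b[comp == root]
      clist[[length(clist) + 1L]] <- idx
    }
  }
  # canonical ids: order components by donor then first member cell id
  first_cell <- vapply(clist, function(idx) cells$cell_id[idx[1]], character(1))
  donor_of <- vapply(clist, function(idx) cells$donor_id[idx[1]], character(1))
  o <- order(donor_of, first_cell)
  clist <- clist[o]
  per_donor_counter <- list()
  rows <- vector("list", length(clist))
  for (k in seq_along(clist)) {
    idx <- clist[[k]]
    d <- cells$donor_id[idx[1]]
    per_donor_counter[[d]] <- (per_donor_counter[[d]] %||% 0L) + 1L
    cid <- sprintf("%s_ct%04d", d, per_donor_counter[[d]])
    cells$clonotype_id[idx] <- cid
    rows[[k]] <- data.frame(
      clonotype_id = cid, donor_id = d,
      vh_gene = cells$vh_gene[idx[1]], vl_gene = cells$vl_gene[idx[1]],
      founder_cdr3_heavy = cells[[hcol]][idx[1]],
      founder_cdr3_light = cells[[lcol]][idx[1]],
      size = length(idx), expanded = FALSE, stringsAsFactors = FALSE)
  }
  clonotypes <- do.call(rbind, rows)
  clonotypes$members <- lapply(clist, function(idx) cells$cell_id[idx])
  size_of <- stats::setNames(clonotypes$size, clonotypes$clonotype_id)
  cells$clone_size <- unname(size_of[cells$clonotype_id])
  list(clonotypes = clonotypes, cells = cells)
}

#' Flag clonally expanded clonotypes
#'
#' A clonotype is expanded when it contains at least `min_size` cells
#' within one donor.
#'
#' @param ct result of [build_clonotypes()].
#' @param min_size expansion threshold (default 2).
#' @return `ct` with `expanded` set on both tables and an attribute
#'   `"expanded_fraction_per_donor"` (fraction of cells in expanded
#'   clonotypes, per donor).
#' @export
flag_expanded <- function(ct, min_size = 2) {
  ct$clonotypes$expanded <- ct$clonotypes$size >= min_size
  ct$cells$expanded <- ct$cells$clone_size >= min_size
  frac <- tapply(ct$cells$expanded, ct$cells$donor_id, mean)
  attr(ct, "expanded_fraction_per_donor") <- frac
  ct
}

#' Percent somatic hypermutation of a V region against germline
#'
#' Aligns the observed sequence to its germline V gene with a global
#' end-free (overlap) alignment (match +1, mismatch -1, gap -2, terminal
#' gaps free), so junction-derived or J-segment tails that extend past the
#' V region hang off as free end gaps. SHM% = 100 x mismatches / aligned
#' non-gap columns; internal gap columns are excluded from numerator and
#' denominator.
#'
#' @param sequence observed nucleotide sequence containing the V region.
#' @param germline germline V-region nucleotide sequence.
#' @return SHM percentage in \[0, 100\].
#' @export
compute_shm <- function(sequence, germline) {
  if (is.na(sequence) || is.na(germline) || nchar(sequence) == 0L ||
      nchar(germline) == 0L)
    cs_input_error("sequence and germline must be non-empty")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(sequence), Biostrings::DNAString(germline),
    type = "overlap", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2)
  nm <- Biostrings::nmismatch(al)
  denom <- Biostrings::nmatch(al) + nm
  if (denom == 0) return(NA_real_)
  100 * nm / denom
}

#' Annotate resolved cells with heavy/light SHM percentages
#'
#' @param cells resolved cells (see [resolve_cell_chains()]).
#' @param germlines named character vector (or `DNAStringSet`) mapping V
#'   gene name to germline V-region sequence. Cells whose V call is not
#'   resolvable get `NA` SHM with a message.
#' @return `cells` with `shm_vh_pct` and `shm_vl_pct` columns.
#' @export
annotate_shm <- function(cells, germlines) {
  germlines <- stats::setNames(as.character(germlines), names(germlines))
  cells$shm_vh_pct <- shm_batch(cells$heavy_v_sequence, cells$vh_gene,
                                germlines)
  cells$shm_vl_pct <- shm_batch(cells$light_v_sequence, cells$vl_gene,
                                germlines)
  n_missing <- sum(is.na(cells$shm_vh_pct)) + sum(is.na(cells$shm_vl_pct))
  if (n_missing) message(n_missing,
                         " chain(s) without resolvable germline excluded from SHM")
  cells
}

# internal: vectorized SHM over many chains sharing germlines — one
# vectorized overlap alignment per V gene (same scoring as compute_shm)
shm_batch <- function(seqs, calls, germlines) {
  out <- rep(NA_real_, length(seqs))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  for (g in unique(calls)) {
    germ <- germlines[g]
    idx <- which(calls == g)
    if (is.na(germ)) next
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(seqs[idx]), Biostrings::DNAString(germ),
      type = "overlap", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = 2)
    nm <- Biostrings::nmismatch(al)
    denom <- Biostrings::nmatch(al) + nm
    out[idx] <- ifelse(denom == 0, NA_real_, 100 * nm / denom)
  }
  out
}

#' Per-stratum group comparison of somatic hypermutation
#'
#' For each stratum (cluster or subset), the mean per-cell SHM per disease
#' group and a two-sided Wilcoxon rank-sum p value on the per-cell values.
#'
#' @param cells SHM-annotated cells (see [annotate_shm()]).
#' @param cell_table per-cell metadata with `cell_id`, group and stratum.
#' @param stratum_col stratum column (default "subset").
#' @param group_col group column.
#' @param value which SHM column to compare (default `"shm_vh_pct"`).
#' @return data.frame: stratum, per-group n and mean SHM, p value (`NA`
#'   with a warning when a group is empty in a stratum).
#' @export
shm_group_test <- function(cells, cell_table, stratum_col = "subset",
                           group_col = "group", value = "shm_vh_pct") {
  m <- merge(cells[, c("cell_id", value)], cell_table, by = "cell_id")
  m <- m[!is.na(m[[value]]), , drop = FALSE]
  groups <- sort(unique(as.character(m[[group_col]])))
  res <- lapply(split(m, as.character(m[[stratum_col]])), function(d) {
    x1 <- d[[value]][as.character(d[[group_col]]) == groups[1]]
    x2 <- d[[value]][as.character(d[[group_col]]) == groups[2]]
    p <- if (!length(x1) || !length(x2)) {
      warning("empty group in stratum ", d[[stratum_col]][1])
      NA_real_
    } else wilcox_rank_sum(x1, x2)$p.value
    data.frame(stratum = as.character(d[[stratum_col]][1]),
               n_1 = length(x1), n_2 = length(x2),
               mean_shm_1 = mean(x1), mean_shm_2 = mean(x2),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  names(out) <- c("stratum", paste0("n_", groups), paste0("mean_shm_", groups), "p")
  out
}

#' Isotype proportions per cluster and disease group
#'
#' @param cells resolved cells with an `isotype` column.
#' @param cell_table per-cell metadata with `cell_id`, `cluster`, group.
#' @param group_col group column.
#' @return data.frame with cluster, group, isotype, count and proportion;
#'   proportions sum to 1 within each (cluster, group). Missing isotypes
#'   are in the `"unknown"` bin.
#' @export
isotype_proportions <- function(cells, cell_table, group_col = "group") {
  m <- merge(cells[, c("cell_id", "isotype")], cell_table, by = "cell_id")
  m$isotype[is.na(m$isotype) | m$isotype == ""] <- "unknown"
  tab <- as.data.frame(table(cluster = as.character(m$cluster),
                             group = as.character(m[[group_col]]),
                             isotype = m$isotype),
                       stringsAsFactors = FALSE)
  names(tab)[4] <- "count"
  tot <- stats::ave(tab$count, tab$cluster, tab$group, FUN = sum)
  tab <- tab[tot > 0, , drop = FALSE]
  tab$proportion <- tab$count / stats::ave(tab$count, tab$cluster, tab$group,
                                           FUN = sum)
  tab
}

#' Pearson chi-squared test of expanded-cell distribution across clusters
#'
#' Builds the clusters x group contingency table of clonally expanded
#' cells and tests homogeneity with Pearson's chi-squared (no continuity
#' correction). Clusters with zero expanded cells overall are dropped; a
#' caveat flag reports whether any expected count is below 5.
#'
#' @param cells expanded-flagged cells (see [flag_expanded()]; rows with
#'   `expanded == TRUE` are used).
#' @param cell_table per-cell metadata with `cell_id`, `cluster`, group.
#' @param group_col group column.
#' @return list with `statistic`, `df`, `p.value`, `table` and
#'   `low_expected` (logical caveat flag); `NULL` with a warning when a
#'   group has no expanded cells.
#' @export
expansion_distribution_test <- function(cells, cell_table,
                                        group_col = "group") {
  m <- merge(cells[cells$expanded, c("cell_id", "expanded")], cell_table,
             by = "cell_id")
  groups <- sort(unique(as.character(cell_table[[group_col]])))
  tab <- table(factor(as.character(m$cluster)),
               factor(as.character(m[[group_col]]), levels = groups))
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (any(colSums(tab) == 0) || nrow(tab) < 2) {
    warning("expansion test skipped: a group has no expanded cells ",
            "or fewer than 2 clusters are represented")
    return(NULL)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p.value = ct$p.value, table = tab,
       low_expected = any(ct$expected < 5))
}
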