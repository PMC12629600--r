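# One canonical codon per amino acid (first codon in the standard code),
# so amino-acid CDR3 edits can be mirrored exactly at the nucleotide level.
aa_codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  aas <- unique(gc)
  stats::setNames(vapply(aas, function(a) names(gc)[gc == a][1], character(1)),
                  aas)
}

random_cdr3 <- function(len) {
  # junction-style amino acid loop: starts with C, ends with W/F
  alphabet <- setdiff(names(aa_codon_table()), "*")
  mid <- sample(alphabet, len - 2, replace = TRUE)
  paste0(c("C", mid, sample(c("W", "F"), 1)), collapse = "")
}

aa_to_nt <- function(aa) {
  tab <- aa_codon_table()
  paste0(tab[strsplit(aa, "")[[1]]], collapse = "")
}

mutate_cdr3 <- function(aa, n_edits) {
  if (n_edits == 0) return(aa)
  alphabet <- setdiff(names(aa_codon_table()), "*")
  v <- strsplit(aa, "")[[1]]
  pos <- sample(2:(length(v) - 1), n_edits)  # keep the C...W/F frame
  for (p in pos) v[p] <- sample(setdiff(alphabet, v[p]), 1)
  paste0(v, collapse = "")
}

mutate_sequence <- function(seq, n_mut) {
  if (n_mut == 0) return(seq)
  v <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(v), n_mut)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  paste0(v, collapse = "")
}

#' Simulate the BCR repertoire for a cohort
#'
#' Each cell receives one productive heavy and one productive light chain.
#' Cells are grouped into clonal lineages within (donor, cluster): lineage
#' sizes are drawn from the configured size distribution, lineage founders
#' land in clusters tilted by per-group expansion weights, all lineage
#' members share the founder's V genes, and member CDR3s diverge from the
#' founder by amino-acid edits (mirrored in the nucleotide CDR3) capped at
#' 15% of CDR3 length, so members stay within the clonotype identity
#' threshold of the founder. V-region point mutations are placed uniformly
#' at the cluster's (optionally group-specific) SHM rate; isotypes are
#' drawn from the cluster's mix. A doublet rate > 0 gives some cells an
#' extra lower-UMI heavy chain to exercise chain resolution.
#'
#' @param cells per-cell metadata from [simulate_cohort()].
#' @param config the same [sim_config()].
#' @return list with `chains` (AIRR-style chain table, two rows per cell
#'   plus any doublet extras), `germlines` (named character vector of
#'   germline V-region sequences) and `truth` (per-cell lineage id, true
#'   SHM counts, germline V gene per chain, lineage size table).
#' @export
simulate_repertoire <- function(cells, config) {
  missing_shm <- setdiff(unique(cells$cluster),
                         names(config$shm_rate_per_cluster))
  if (length(missing_shm))
    cs_config_error(paste0("clusters without SHM rate: ",
                           paste(missing_shm, collapse = ", ")))
  set.seed(config$seed + 1L)
  vh_genes <- c("IGHV3-15", "IGHV3-33", "IGHV6-1", "IGHV1-2", "IGHV1-69",
                "IGHV3-23", "IGHV4-34", "IGHV4-59", "IGHV5-51", "IGHV3-7")
  vl_genes <- c("IGKV3-11", "IGKV1-5", "IGKV1D-39", "IGKV3-20", "IGKV4-1",
                "IGLV2-14", "IGLV1-40", "IGLV3-1")
  jh_genes <- paste0("IGHJ", 1:6)
  jl_genes <- c("IGKJ1", "IGKJ2", "IGKJ4", "IGLJ2", "IGLJ3")
  v_len <- 294
  germ <- c(vh_genes, vl_genes)
  germlines <- stats::setNames(
    vapply(germ, function(g)
      paste0(sample(c("A", "C", "G", "T"), v_len, replace = TRUE),
             collapse = ""), character(1)),
    germ)
  j_stub <- stats::setNames(
    vapply(c(jh_genes, jl_genes), function(g)
      paste0(sample(c("A", "C", "G", "T"), 21, replace = TRUE),
             collapse = ""), character(1)),
    c(jh_genes, jl_genes))

  sizes <- as.integer(names(config$clonal_size_distribution))
  size_p <- as.numeric(config$clonal_size_distribution)

  chain_rows <- list(); truth_rows <- list(); lineage_sizes <- integer()
  lineage_counter <- 0L
  for (d in unique(cells$donor_id)) {
    dc <- cells[cells$donor_id == d, , drop = FALSE]
    grp <- dc$group[1]
    w <- config$expansion_weights[[grp]]
    if (is.null(w)) w <- stats::setNames(rep(1, 12), as.character(0:11))
    unassigned <- split(dc$cell_id, dc$cluster)
    while (sum(lengths(unassigned)) > 0) {
      avail <- lengths(unassigned)
      pw <- avail * w[names(unassigned)]
      cl <- sample(names(unassigned), 1, prob = pw)
      s <- sample(sizes, 1, prob = size_p)
      s <- min(s, avail[[cl]])
      members <- unassigned[[cl]][seq_len(s)]
      unassigned[[cl]] <- unassigned[[cl]][-seq_len(s)]
      lineage_counter <- lineage_counter + 1L
      lid <- sprintf("L%05d", lineage_counter)
      lineage_sizes[lid] <- s

      vh <- sample(vh_genes, 1); vl <- sample(vl_genes, 1)
      jh <- sample(jh_genes, 1)
      jl <- if (startsWith(vl, "IGKV")) sample(jl_genes[1:3], 1)
            else sample(jl_genes[4:5], 1)
      h_len <- sample(11:19, 1); l_len <- sample(9:13, 1)
      h_founder <- random_cdr3(h_len); l_founder <- random_cdr3(l_len)
      rate <- config$shm_rate_per_cluster[[cl]]
      if (length(rate) > 1) rate <- rate[[grp]]
      iso_mix <- config$isotype_mix_per_cluster[[cl]]

      h_edits <- c(0L, pmin(stats::rbinom(s - 1, h_len, 0.03),
                            floor(0.15 * h_len)))
      l_edits <- c(0L, pmin(stats::rbinom(s - 1, l_len, 0.015),
                            floor(0.15 * l_len)))
      h_aa <- vapply(h_edits, function(e) mutate_cdr3(h_founder, e),
                     character(1))
      l_aa <- vapply(l_edits, function(e) mutate_cdr3(l_founder, e),
                     character(1))
      n_mut_h <- stats::rbinom(s, v_len, rate)
      n_mut_l <- stats::rbinom(s, v_len, rate)
      h_seq <- vapply(seq_len(s), function(i)
        paste0(mutate_sequence(germlines[[vh]], n_mut_h[i]),
               aa_to_nt(h_aa[i]), j_stub[[jh]]), character(1))
      l_seq <- vapply(seq_len(s), function(i)
        paste0(mutate_sequence(germlines[[vl]], n_mut_l[i]),
               aa_to_nt(l_aa[i]), j_stub[[jl]]), character(1))
      iso <- sample(names(iso_mix), s, replace = TRUE, prob = iso_mix)
      lc <- if (startsWith(vl, "IGKV")) "IGKC" else "IGLC2"
      locus_l <- if (startsWith(vl, "IGKV")) "IGK" else "IGL"
      chain_rows[[length(chain_rows) + 1L]] <- list(
        cell_id = rep(members, 2),
        locus = rep(c("IGH", locus_l), each = s),
        v_call = rep(paste0(c(vh, vl), "*01"), each = s),
        j_call = rep(paste0(c(jh, jl), "*01"), each = s),
        c_call = c(iso, rep(lc, s)),
        cdr3_nt = c(vapply(h_aa, aa_to_nt, character(1)),
                    vapply(l_aa, aa_to_nt, character(1))),
        cdr3_aa = c(h_aa, l_aa),
        umi_count = sample(5:60, 2 * s, replace = TRUE),
        v_sequence = c(h_seq, l_seq),
        donor_id = rep(d, 2 * s))
      truth_rows[[length(truth_rows) + 1L]] <- list(
        cell_id = members, lineage_id = rep(lid, s), cluster = rep(cl, s),
        vh_gene = rep(vh, s), vl_gene = rep(vl, s),
        shm_count_vh = n_mut_h, shm_count_vl = n_mut_l,
        v_len = rep(v_len, s))
    }
  }
  bind_cols <- function(lst) {
    cols <- names(lst[[1]])
    out <- lapply(cols, function(cn) unlist(lapply(lst, `[[`, cn),
                                            use.names = FALSE))
    names(out) <- cols
    as.data.frame(out, stringsAsFactors = FALSE)
  }
  chains <- bind_cols(chain_rows)
  chains$productive <- TRUE
  chains$in_frame <- TRUE
  truth <- bind_cols(truth_rows)

  if (config$doublet_rate > 0) {
    dbl <- unique(chains$cell_id)[stats::runif(length(unique(chains$cell_id))) <
                                    config$doublet_rate]
    extra <- chains[chains$locus == "IGH" & chains$cell_id %in% dbl, ,
                    drop = FALSE]
    if (nrow(extra)) {
      extra$umi_count <- pmax(1L, extra$umi_count %/% 4L)
      extra$cdr3_aa <- vapply(nchar(extra$cdr3_aa), random_cdr3, character(1))
      extra$cdr3_nt <- vapply(extra$cdr3_aa, aa_to_nt, character(1))
      chains <- rbind(chains, extra)
    }
  }
  # strip allele suffixes for the in-memory representation (the writer
  # emits them; read_airr strips them again)
  chains_mem <- chains
  chains_mem$v_call <- sub("\\*.*$", "", chains_mem$v_call)
  chains_mem$j_call <- sub("\\*.*$", "", chains_mem$j_call)
  list(chains = chains_mem,
       chains_with_alleles = chains,
       germlines = germlines,
       truth = list(cells = truth, lineage_sizes = lineage_sizes))
}

#' Write germline V sequences to FASTA
#'
#' @param germlines named character vector of V-region sequences.
#' @param path output path.
#' @export
write_germline_fasta <- function(germlines, path) {
  ss <- Biostrings::DNAStringSet(germlines)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read germline V sequences from FASTA
#'
#' @param path FASTA path.
#' @return named uppercase character vector of sequences.
#' @export
read_germline_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(ss)), names(ss))
}
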