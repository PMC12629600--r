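#' Cohort summary statistics
#'
#' Per-group participant counts, percent female (rounded half-up, the
#' convention of demographic tables), and age range. When the metadata
#' carries a logical `contributed_binder` column, the percentage of
#' participants contributing validated binding antibodies is also
#' reported.
#'
#' @param meta participant metadata with columns `group`, `sex`
#'   (`"F"`/`"M"`), `age`, optionally `contributed_binder`.
#' @return data.frame, one row per group: `group`, `n`, `n_female`,
#'   `pct_female`, `age_min`, `age_max`, and (if available)
#'   `pct_binder_contributors`.
#' @export
summarize_cohort <- function(meta) {
  need <- c("group", "sex", "age")
  miss <- setdiff(need, names(meta))
  if (length(miss)) cs_input_error(paste0("metadata missing: ",
                                          paste(miss, collapse = ", ")))
  if (any(is.na(meta$sex) | meta$sex == ""))
    warning("missing sex values counted as reported")
  out <- lapply(split(meta, meta$group), function(g) {
    r <- data.frame(group = g$group[1], n = nrow(g),
                    n_female = sum(g$sex == "F", na.rm = TRUE),
                    stringsAsFactors = FALSE)
    r$pct_female <- round_half_up(100 * r$n_female / r$n)
    r$age_min <- min(g$age); r$age_max <- max(g$age)
    if ("contributed_binder" %in% names(g))
      r$pct_binder_contributors <-
        round_half_up(100 * sum(g$contributed_binder) / r$n)
    r
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Load the packaged participant demographics table
#'
#' A plain-text transcription of the cohort demographics table (9 stage1
#' vs 8 healthy first-degree-relative controls) shipped with the package
#' for cohort-summary computations.
#'
#' @return data.frame of participant metadata.
#' @export
cohort_demographics <- function() {
  path <- system.file("extdata", "table1_cohort.csv", package = "clonoscan")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Link ELISA-validated mAbs back to cells
#'
#' The insulin-binding cell (IBC) set contains every cell whose clonotype
#' id matches a positive mAb AND whose heavy and light CDR3 amino-acid
#' sequences equal the tested sequences; the non-IBC set is built
#' identically from the negative mAbs.
#'
#' @param calls data.frame with `mab_id` and logical `positive`.
#' @param mab_info data.frame with `mab_id`, `clonotype_id`,
#'   `heavy_cdr3_aa`, `light_cdr3_aa` (the tested sequences).
#' @param cells resolved, clonotyped cells (from [build_clonotypes()]).
#' @return list with `ibc_cells` and `non_ibc_cells` (character vectors
#'   of cell ids). mAbs without a clonotype mapping are excluded with a
#'   warning.
#' @export
link_binders_to_cells <- function(calls, mab_info, cells) {
  m <- merge(calls, mab_info, by = "mab_id")
  unmapped <- is.na(m$clonotype_id) |
    !(m$clonotype_id %in% cells$clonotype_id)
  if (any(unmapped)) {
    warning("mAb(s) without clonotype mapping excluded: ",
            paste(m$mab_id[unmapped], collapse = ", "))
    m <- m[!unmapped, , drop = FALSE]
  }
  match_cells <- function(rows) {
    unique(unlist(lapply(seq_len(nrow(rows)), function(i) {
      cells$cell_id[cells$clonotype_id == rows$clonotype_id[i] &
                      cells$heavy_cdr3_aa == rows$heavy_cdr3_aa[i] &
                      cells$light_cdr3_aa == rows$light_cdr3_aa[i]]
    })))
  }
  list(ibc_cells = match_cells(m[m$positive, , drop = FALSE]),
       non_ibc_cells = match_cells(m[!m$positive, , drop = FALSE]))
}

#' Choose a mAb screening panel from expanded clonotypes
#'
#' Selects expanded clonotypes for recombinant expression and ELISA
#' screening (up to 24 stage1 and 9 healthy, preferring memory-compartment
#' and atypical-like clonotypes), and assigns ground-truth binding: the
#' first `n_binders` stage1 panel members become true binders with the
#' given AUC ratios and inhibition fractions. The tested BCR sequence for
#' each clonotype is the member with the highest VH SHM.
#'
#' @param ct expanded-flagged clonotype result (see [flag_expanded()]).
#' @param cell_table per-cell metadata with `cluster`, `subset`, `group`.
#' @param cells_shm SHM-annotated resolved cells (see [annotate_shm()]).
#' @param n_stage1,n_healthy panel sizes per group.
#' @param n_binders number of true binders planted among stage1 members.
#' @param binder_ratios,binder_inhibition truth for the planted binders.
#' @return data.frame panel (one row per mAb) or `NULL` when no expanded
#'   clonotypes qualify.
#' @export
select_mab_panel <- function(ct, cell_table, cells_shm,
                             n_stage1 = 24, n_healthy = 9, n_binders = 4,
                             binder_ratios = c(11.54, 13.83, 10.29, 10.00),
                             binder_inhibition = c(0.23, 0.34, 0.45, 0.55)) {
  cl_of <- stats::setNames(as.character(cell_table$cluster),
                           cell_table$cell_id)
  grp_of <- stats::setNames(as.character(cell_table$group),
                            cell_table$cell_id)
  sub_of <- stats::setNames(as.character(cell_table$subset),
                            cell_table$cell_id)
  ctab <- ct$clonotypes[ct$clonotypes$expanded, , drop = FALSE]
  if (!nrow(ctab)) return(NULL)
  info <- lapply(seq_len(nrow(ctab)), function(i) {
    mem <- ctab$members[[i]]
    subs <- sub_of[mem]
    data.frame(clonotype_id = ctab$clonotype_id[i],
               donor_id = ctab$donor_id[i],
               group = grp_of[mem[1]], size = ctab$size[i],
               memory_like = mean(subs %in% c("memory", "plasmablast"),
                                  na.rm = TRUE),
               atypical = mean(cl_of[mem] == "3", na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  info <- do.call(rbind, info)
  pick_group <- function(g, n) {
    cand <- info[info$group == g & info$memory_like > 0.5, , drop = FALSE]
    cand <- cand[order(-cand$atypical, -cand$size), , drop = FALSE]
    utils::head(cand, n)
  }
  s1 <- pick_group("stage1", n_stage1)
  hc <- pick_group("healthy", n_healthy)
  panel <- rbind(s1, hc)
  if (!nrow(panel)) return(NULL)
  panel$mab_id <- sprintf("mab%02d", seq_len(nrow(panel)))
  n_b <- min(n_binders, nrow(s1))
  panel$true_binder <- FALSE
  if (n_b > 0) panel$true_binder[seq_len(n_b)] <- TRUE
  panel$true_auc_ratio <- stats::runif(nrow(panel), 0.8, 2.0)
  panel$true_auc_ratio[panel$true_binder] <- binder_ratios[seq_len(n_b)]
  panel$inhibition_fraction <- NA_real_
  panel$inhibition_fraction[panel$true_binder] <- binder_inhibition[seq_len(n_b)]
  # the tested BCR is the member with the highest VH SHM
  shm_of <- stats::setNames(cells_shm$shm_vh_pct, cells_shm$cell_id)
  seqs <- lapply(panel$clonotype_id, function(cid) {
    mem <- ct$cells[ct$cells$clonotype_id == cid, , drop = FALSE]
    mem[order(-shm_of[mem$cell_id]), ][1, c("heavy_cdr3_aa", "light_cdr3_aa")]
  })
  seqs <- do.call(rbind, seqs)
  panel$heavy_cdr3_aa <- seqs$heavy_cdr3_aa
  panel$light_cdr3_aa <- seqs$light_cdr3_aa
  panel
}

#' Run the full pipeline on a synthetic cohort
#'
#' Orchestrates every stage: cohort simulation, QC, RNA/ADT
#' normalization, cluster-frequency comparison, per-subset differential
#' expression with the filter stack and shared-gene partition, repertoire
#' simulation and analysis (chain resolution, clonotypes, expansion,
#' SHM, isotypes, expansion chi-squared), ELISA simulation and AUC-ratio
#' classification of a mAb panel drawn from expanded clonotypes, linkage
#' of positive mAbs back to cells, and the IBC contrast. Fully
#' deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, the JSON report is
#'   written to `file.path(out_dir, "report.json")`.
#' @param deg_alpha adjusted-p threshold for the DE stage (default 0.05).
#' @return the report (a nested list); when written, the file path is in
#'   `attr(report, "path")`.
#' @export
run_all <- function(config, out_dir = NULL, deg_alpha = 0.05) {
  sim <- simulate_cohort(config)
  cells <- qc_filter(sim$rna, sim$cells)
  qc_cells <- cells[cells$qc_pass, , drop = FALSE]
  norm <- normalize_rna(sim$rna[, qc_cells$cell_id, drop = FALSE])
  adt <- clr_normalize_adt(sim$adt[, qc_cells$cell_id, drop = FALSE])

  freq_cluster <- cluster_frequency_test(qc_cells, by = "cluster")
  freq_subset <- cluster_frequency_test(qc_cells, by = "subset")

  blocklist <- build_blocklist(rownames(norm), y_genes = c("RPS4Y1", "DDX3Y"))
  subsets <- unique(qc_cells$subset)
  deg <- list()
  for (s in subsets) {
    r <- withCallingHandlers(
      deg_test(norm, qc_cells, stratum = s, blocklist = blocklist,
               groups = c("stage1", "healthy"), alpha = deg_alpha),
      warning = function(w) invokeRestart("muffleWarning"))
    if (!is.null(r)) deg[[s]] <- r
  }
  sig_sets <- lapply(deg, function(r) r$gene[r$passes_filters])
  sig_sets <- sig_sets[vapply(sig_sets, length, integer(1)) > 0]
  venn <- if (length(sig_sets) >= 2) shared_gene_partition(sig_sets) else NULL

  rep_sim <- simulate_repertoire(qc_cells, config)
  resolved <- resolve_cell_chains(rep_sim$chains)
  resolved <- annotate_shm(resolved, rep_sim$germlines)
  ct <- flag_expanded(build_clonotypes(resolved))
  muffle <- function(expr) withCallingHandlers(
    expr, warning = function(w) invokeRestart("muffleWarning"))
  shm_subset <- muffle(shm_group_test(resolved, qc_cells,
                                      stratum_col = "subset"))
  shm_cluster <- muffle(shm_group_test(resolved, qc_cells,
                                       stratum_col = "cluster"))
  iso <- isotype_proportions(resolved, qc_cells)
  chi2 <- withCallingHandlers(
    expansion_distribution_test(ct$cells, qc_cells),
    warning = function(w) invokeRestart("muffleWarning"))

  panel <- select_mab_panel(ct, qc_cells, resolved)
  binding <- NULL; inhibition <- NULL; ibc <- NULL; ibc_table <- NULL
  if (!is.null(panel) && nrow(panel) > 0) {
    spec <- binder_spec(panel[, c("mab_id", "true_auc_ratio",
                                  "inhibition_fraction")])
    plates <- simulate_plates(spec, noise_sd = config$plate_noise_sd,
                              outlier_rate = config$outlier_rate,
                              seed = config$seed + 2L)
    neg <- plates[plates$role == "isotype_negative" &
                    plates$condition == "plain", ]
    pos <- plates[plates$role == "anti_insulin_positive" &
                    plates$condition == "plain", ]
    calls <- lapply(panel$mab_id, function(id) {
      tst <- plates[plates$mab_id == id & plates$condition == "plain", ]
      cb <- classify_binding(tst, neg, pos)
      data.frame(mab_id = id, auc_ratio = cb$auc_ratio, cutoff = cb$cutoff,
                 cutoff_rounded = cb$cutoff_rounded, positive = cb$positive,
                 stringsAsFactors = FALSE)
    })
    binding <- do.call(rbind, calls)
    inh_ids <- panel$mab_id[!is.na(panel$inhibition_fraction)]
    if (length(inh_ids)) {
      inhibition <- data.frame(mab_id = inh_ids, percent_inhibition =
        vapply(inh_ids, function(id) {
          pl <- plates[plates$mab_id == id & plates$condition == "plain", ]
          inh <- plates[plates$mab_id == id & plates$condition == "inhibited", ]
          percent_inhibition(pl, inh)
        }, numeric(1)), stringsAsFactors = FALSE)
    }
    link <- withCallingHandlers(
      link_binders_to_cells(binding, panel, ct$cells),
      warning = function(w) invokeRestart("muffleWarning"))
    ibc <- link
    if (length(link$ibc_cells) >= 2 && length(link$non_ibc_cells) >= 2) {
      bg <- qc_cells$cell_id[qc_cells$cluster == "3" &
                               qc_cells$group == "stage1"]
      bg <- setdiff(bg, c(link$ibc_cells, link$non_ibc_cells))
      ibc_table <- ibc_contrast(norm, link$ibc_cells, link$non_ibc_cells,
                                background_cells = bg, seed = config$seed)
    }
  }

  report <- list(
    config = list(seed = config$seed,
                  n_donors_per_group = as.list(config$n_donors_per_group),
                  n_genes = config$n_genes),
    qc = list(n_cells = nrow(cells), n_pass = sum(cells$qc_pass),
              removed_per_donor =
                as.list(attr(cells, "removed_per_donor"))),
    cluster_frequencies = freq_cluster[, c("stratum", "p")],
    subset_frequencies = freq_subset[, c("stratum", "p")],
    deg_counts = lapply(deg, function(r) sum(r$passes_filters)),
    venn_counts = if (!is.null(venn)) as.list(venn$counts) else NULL,
    shm_subset = shm_subset, shm_cluster = shm_cluster,
    isotype = iso,
    expansion_chi2 = if (!is.null(chi2))
      list(statistic = chi2$statistic, df = chi2$df, p = chi2$p.value,
           low_expected = chi2$low_expected) else NULL,
    binding = binding, inhibition = inhibition,
    ibc = if (!is.null(ibc)) list(n_ibc = length(ibc$ibc_cells),
                                  n_non_ibc = length(ibc$non_ibc_cells))
          else NULL,
    ibc_top_genes = if (!is.null(ibc_table)) ibc_table$gene else NULL,
    thresholds = list(min_features = 200, max_mito = 0.10, fc = 1.2,
                      alpha = deg_alpha, min_pct = 0.30, identity = 0.85,
                      min_clone_size = 2, elisa_q = 0.01,
                      ibc_min_pct = 0.50, downsample_n = 100))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(out_dir, "report.json")
    write_report(report, path)
    attr(report, "path") <- path
  }
  report
}

#' Write a pipeline report as canonical JSON
#'
#' @param report list from [run_all()].
#' @param path output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, null = "null")
  invisible(path)
}
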