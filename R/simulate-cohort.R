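# Default 12-cluster -> 5-subset layout. Memory clusters 1, 3, 7 (3 is the
# "atypical-like" one), naive includes cluster 6, plasmablast is cluster 11;
# this mirrors the B cell subset structure the pipeline is built to analyze.
#' Default 12-cluster to 5-subset mapping
#'
#' @return named character vector, cluster id -> subset name.
#' @export
default_cluster_map <- function() {
  c("0" = "naive", "1" = "memory", "2" = "naive", "3" = "memory",
    "4" = "transitional", "5" = "activated", "6" = "naive", "7" = "memory",
    "8" = "transitional", "9" = "activated", "10" = "naive",
    "11" = "plasmablast")
}

# Per-cluster mean SHM rate (fraction of V-region nucleotides), optionally
# per disease group. Memory and plasmablast carry substantial mutation,
# atypical-like cluster 3 shows the largest group contrast (reduced in
# stage1), activated a small one, naive/transitional near-germline.
#' Default per-cluster SHM rates
#'
#' @return list, cluster id -> mean mutated V-region fraction (scalar or
#'   per-group named vector).
#' @export
default_shm_rates <- function() {
  list("0" = 0.005, "1" = c(stage1 = 0.0389, healthy = 0.0431),
       "2" = 0.005, "3" = c(stage1 = 0.0242, healthy = 0.0352),
       "4" = 0.004, "5" = c(stage1 = 0.00622, healthy = 0.0111),
       "6" = 0.005, "7" = 0.040, "8" = 0.004,
       "9" = c(stage1 = 0.00622, healthy = 0.0111),
       "10" = 0.005, "11" = 0.045)
}

default_isotype_mix <- function() {
  naive <- c(IGHM = 0.85, IGHD = 0.15)
  trans <- c(IGHM = 0.9, IGHD = 0.1)
  act <- c(IGHM = 0.7, IGHD = 0.1, IGHG1 = 0.15, IGHA1 = 0.05)
  mem <- c(IGHM = 0.4, IGHD = 0.05, IGHG1 = 0.3, IGHG2 = 0.1, IGHA1 = 0.15)
  atyp <- c(IGHM = 0.8, IGHD = 0.1, IGHG1 = 0.1)
  pb <- c(IGHM = 0.2, IGHG1 = 0.5, IGHA1 = 0.3)
  list("0" = naive, "1" = mem, "2" = naive, "3" = atyp, "4" = trans,
       "5" = act, "6" = naive, "7" = mem, "8" = trans, "9" = act,
       "10" = naive, "11" = pb)
}

# Lineage sizes 1..12; mostly singletons with a geometric tail, matching
# the observed range of 2..12 cells per expanded clonotype.
default_clone_sizes <- function() {
  p <- c(0.82, 0.09, 0.04, 0.02, 0.01, 0.008, 0.005, 0.003, 0.002,
         0.001, 0.0006, 0.0004)
  stats::setNames(p / sum(p), as.character(1:12))
}

# Which clusters attract multi-cell lineages, per group: expansion
# concentrates in atypical-like memory cluster 3 for stage1 donors and in
# memory cluster 1 for healthy donors.
default_expansion_weights <- function() {
  w1 <- rep(1, 12); names(w1) <- as.character(0:11)
  w2 <- w1
  w1["3"] <- 3; w1["1"] <- 1.5   # stage1
  w2["1"] <- 3                   # healthy
  list(stage1 = w1, healthy = w2)
}

# Planted disease-group differential expression (upregulated in stage1
# within a subset), concentrated in memory as in the study design.
#' Default planted differential-expression table
#'
#' @return data.frame with columns `gene`, `stratum`, `log2fc`.
#' @export
default_de_genes <- function() {
  data.frame(
    gene = sprintf("GENE%04d", c(1:20, 101:108, 201:205, 301:303)),
    stratum = c(rep("memory", 20), rep("naive", 8), rep("transitional", 5),
                rep("activated", 3)),
    log2fc = c(rep(1.2, 20), rep(1.0, 8), rep(1.0, 5), rep(1.0, 3)),
    stringsAsFactors = FALSE)
}

#' Build a synthetic-cohort configuration
#'
#' Bundles every knob of the synthetic cohort: donor design (9 stage1 vs
#' 8 healthy), per-donor cell recovery, the 12-cluster/5-subset layout,
#' planted differential expression, per-cluster SHM rates and isotype
#' mixes, the clonal-size distribution, QC-failure planting and the
#' donor-level cluster-frequency model. All defaults emulate the cohort
#' structure the pipeline targets; tests typically override
#' `cells_per_donor` and `n_genes` downward.
#'
#' @param seed integer seed; the whole cohort is a deterministic function
#'   of (seed, config).
#' @param n_donors_per_group named integer vector, donors per group.
#' @param cells_per_donor length-2 range of cells recovered per donor.
#' @param n_genes number of RNA features (includes mitochondrial,
#'   immunoglobulin and Y genes).
#' @param cluster_map named cluster -> subset mapping (12 -> 5 default).
#' @param cluster_base_freq baseline cluster probabilities (default mildly
#'   uneven across the 12 clusters).
#' @param cluster_freq_shift named per-cluster log-odds shifts applied to
#'   stage1 donors (default: naive cluster 6 up, memory cluster 3 and
#'   plasmablast cluster 11 down).
#' @param donor_concentration Dirichlet concentration for per-donor
#'   cluster-frequency variability (larger = less variable).
#' @param de_genes data.frame (gene, stratum, log2fc) of planted
#'   stage1-upregulated genes; stratum names refer to subsets or clusters.
#' @param shm_rate_per_cluster list, cluster -> mean mutated fraction of
#'   V-region nucleotides (scalar, or named per-group vector).
#' @param clonal_size_distribution named probability vector over lineage
#'   sizes 1..12.
#' @param isotype_mix_per_cluster list, cluster -> named isotype
#'   probability vector.
#' @param expansion_weights list per group of per-cluster weights tilting
#'   where multi-cell lineages land.
#' @param mito_fraction_params Beta(shape1, shape2) for healthy cells'
#'   mitochondrial fraction.
#' @param qc_fail_low_rate fraction of cells planted to fail the
#'   feature-count rule.
#' @param qc_fail_mito_rate fraction planted to fail the mito rule.
#' @param doublet_rate fraction of cells given an extra heavy chain in the
#'   repertoire (exercises chain resolution; default 0).
#' @param plate_noise_sd replicate OD noise (OD units).
#' @param outlier_rate fraction of replicate wells replaced by gross
#'   errors (uniform on \[0, od_max\]).
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_donors_per_group = c(stage1 = 9L, healthy = 8L),
                       cells_per_donor = c(2000L, 5000L),
                       n_genes = 2000L,
                       cluster_map = default_cluster_map(),
                       cluster_base_freq = NULL,
                       cluster_freq_shift = c("6" = 0.4, "3" = -0.35,
                                              "11" = -0.6),
                       donor_concentration = 150,
                       de_genes = default_de_genes(),
                       shm_rate_per_cluster = default_shm_rates(),
                       clonal_size_distribution = default_clone_sizes(),
                       isotype_mix_per_cluster = default_isotype_mix(),
                       expansion_weights = default_expansion_weights(),
                       mito_fraction_params = c(shape1 = 2, shape2 = 46),
                       qc_fail_low_rate = 0.03,
                       qc_fail_mito_rate = 0.03,
                       doublet_rate = 0,
                       plate_noise_sd = 0.05,
                       outlier_rate = 0.02) {
  clusters <- names(cluster_map)
  if (is.null(cluster_base_freq)) {
    w <- c(18, 14, 12, 10, 8, 8, 8, 7, 5, 4, 4, 2)[seq_along(clusters)]
    cluster_base_freq <- stats::setNames(w / sum(w), clusters)
  }
  cfg <- list(seed = as.integer(seed),
              n_donors_per_group = n_donors_per_group,
              cells_per_donor = cells_per_donor, n_genes = as.integer(n_genes),
              cluster_map = cluster_map, cluster_base_freq = cluster_base_freq,
              cluster_freq_shift = cluster_freq_shift,
              donor_concentration = donor_concentration, de_genes = de_genes,
              shm_rate_per_cluster = shm_rate_per_cluster,
              clonal_size_distribution = clonal_size_distribution,
              isotype_mix_per_cluster = isotype_mix_per_cluster,
              expansion_weights = expansion_weights,
              mito_fraction_params = mito_fraction_params,
              qc_fail_low_rate = qc_fail_low_rate,
              qc_fail_mito_rate = qc_fail_mito_rate,
              doublet_rate = doublet_rate,
              plate_noise_sd = plate_noise_sd, outlier_rate = outlier_rate)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  check_prob(cfg$cluster_base_freq, "cluster_base_freq")
  check_prob(cfg$clonal_size_distribution, "clonal_size_distribution")
  for (cl in names(cfg$isotype_mix_per_cluster))
    check_prob(cfg$isotype_mix_per_cluster[[cl]],
               paste0("isotype_mix_per_cluster[", cl, "]"))
  if (cfg$cells_per_donor[1] < 200 || cfg$cells_per_donor[2] > 1e5)
    cs_config_error("cells_per_donor must lie within [200, 1e5]")
  rates <- unlist(cfg$shm_rate_per_cluster)
  if (any(rates < 0 | rates > 0.2))
    cs_config_error("shm rates must lie in [0, 0.2]")
  missing_shm <- setdiff(names(cfg$cluster_map),
                         names(cfg$shm_rate_per_cluster))
  if (length(missing_shm))
    cs_config_error(paste0("clusters without SHM rate: ",
                           paste(missing_shm, collapse = ", ")))
  invisible(cfg)
}

# Gene universe: mitochondrial genes (MT- prefix), immunoglobulin segments
# and Y-chromosome genes at fixed positions, generic symbols elsewhere.
sim_gene_names <- function(n_genes) {
  mt <- paste0("MT-", c("ND1", "ND2", "CO1", "CO2", "ATP8", "ATP6", "CO3",
                        "ND3", "ND4L", "ND4", "ND5", "ND6", "CYB"))
  ig <- c("IGHV3-15", "IGHV3-33", "IGHV6-1", "IGKV3-11", "IGKV1-5",
          "IGLV2-14", "IGHJ4", "IGKJ2", "IGLJ3", "IGKC", "IGLC2")
  y <- c("RPS4Y1", "DDX3Y")
  base <- sprintf("GENE%04d", seq_len(n_genes))
  n_special <- length(mt) + length(ig) + length(y)
  if (n_genes <= n_special)
    cs_config_error("n_genes too small for the fixed gene panel")
  c(mt, ig, y, base[seq_len(n_genes - n_special)])
}

#' Simulate the cohort: cells, RNA and ADT counts, ground truth
#'
#' Draws a full synthetic cohort: donors in two disease groups, per-donor
#' cell recovery, per-cell cluster assignment (Dirichlet-perturbed donor
#' frequencies with group-level shifts), negative-binomial RNA counts with
#' cluster marker profiles and planted disease-group DE effects, planted
#' QC failures (low-feature and high-mito cells), and negative-binomial
#' ADT counts for a small surface panel (CD21 low in the atypical-like
#' memory cluster, CD27 high in memory). Deterministic given
#' (seed, config).
#'
#' @param config a [sim_config()].
#' @return list with `cells` (per-cell metadata: `cell_id`, `donor_id`,
#'   `group`, `cluster`, `subset`), `rna` (genes x cells `dgCMatrix`),
#'   `adt` (markers x cells matrix) and `truth` (list: planted DE table,
#'   QC-failure flags, true mito fractions, cluster labels).
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  groups <- names(config$n_donors_per_group)
  donors <- unlist(lapply(seq_along(groups), function(g) {
    sprintf("%s%02d", toupper(substr(groups[g], 1, 1)),
            seq_len(config$n_donors_per_group[g]))
  }))
  donor_group <- rep(groups, config$n_donors_per_group)
  clusters <- names(config$cluster_map)

  genes <- sim_gene_names(config$n_genes)
  mt_genes <- grep("^MT-", genes)
  non_mt <- setdiff(seq_along(genes), mt_genes)

  # gene-level baseline means and dispersions (non-mito genes)
  base_mu <- stats::setNames(exp(stats::rnorm(length(genes), log(0.5), 1.0)),
                             genes)
  base_mu <- pmin(base_mu, 8)
  theta <- stats::setNames(stats::runif(length(genes), 1.5, 4), genes)
  # cluster marker blocks: 25 genes per cluster at 2.5x, placed away from
  # the low-numbered gene symbols used for planted DE
  marker_sets <- lapply(seq_along(clusters), function(i) {
    pos <- (((i - 1) * 25 + 400):((i - 1) * 25 + 424) - 1) %% length(non_mt) + 1
    genes[non_mt[pos]]
  })
  names(marker_sets) <- clusters

  de <- config$de_genes
  de <- de[de$gene %in% genes, , drop = FALSE]
  # planted DE genes sit on moderately expressed genes: a planted effect
  # on a gene below the percent-expressed floor of the DE filter stack
  # would be unrecoverable by construction
  if (nrow(de)) base_mu[de$gene] <- pmax(base_mu[de$gene], 0.8)
  shift <- rep(0, length(clusters)); names(shift) <- clusters
  if (length(config$cluster_freq_shift))
    shift[names(config$cluster_freq_shift)] <- config$cluster_freq_shift

  cell_rows <- list(); mats <- list(); adt_list <- list()
  truth_fail_low <- character(); truth_fail_mito <- character()
  truth_mito <- numeric()
  for (d in seq_along(donors)) {
    n_cells <- if (config$cells_per_donor[1] == config$cells_per_donor[2])
      config$cells_per_donor[1]
    else sample(config$cells_per_donor[1]:config$cells_per_donor[2], 1)
    grp <- donor_group[d]
    # donor cluster frequencies: group-shifted base, Dirichlet-perturbed
    logit <- log(config$cluster_base_freq) +
      if (grp == "stage1") shift else 0
    pr <- exp(logit); pr <- pr / sum(pr)
    alpha <- pr * config$donor_concentration
    g <- stats::rgamma(length(alpha), shape = alpha)
    pr_donor <- g / sum(g)
    cl <- sample(clusters, n_cells, replace = TRUE, prob = pr_donor)
    cell_id <- sprintf("%s_c%05d", donors[d], seq_len(n_cells))

    # per-cluster mean matrix for this donor's group
    mu_by_cluster <- lapply(clusters, function(cc) {
      mu <- base_mu
      mu[marker_sets[[cc]]] <- mu[marker_sets[[cc]]] * 2.5
      if (nrow(de)) {
        subset_of <- config$cluster_map[[cc]]
        hit <- de$stratum == cc | de$stratum == subset_of
        if (grp == "stage1" && any(hit))
          mu[de$gene[hit]] <- mu[de$gene[hit]] * 2^de$log2fc[hit]
      }
      mu
    })
    names(mu_by_cluster) <- clusters

    libf <- exp(stats::rnorm(n_cells, 0, 0.3))
    counts <- matrix(0L, nrow = length(genes), ncol = n_cells,
                     dimnames = list(genes, cell_id))
    for (cc in clusters) {
      idx <- which(cl == cc)
      if (!length(idx)) next
      mu <- mu_by_cluster[[cc]][non_mt]
      th <- theta[non_mt]
      m <- outer(mu, libf[idx])
      counts[non_mt, idx] <- stats::rnbinom(length(m), mu = m,
                                            size = rep(th, length(idx)))
    }
    # planted QC failures and mitochondrial counts
    fail_low <- stats::runif(n_cells) < config$qc_fail_low_rate
    fail_mito <- !fail_low & stats::runif(n_cells) < config$qc_fail_mito_rate
    for (i in which(fail_low)) {
      keep <- sample(non_mt, 120)
      z <- rep(0L, length(genes)); z[keep] <- counts[keep, i]
      counts[, i] <- z
    }
    mito_frac <- stats::rbeta(n_cells, config$mito_fraction_params[1],
                              config$mito_fraction_params[2])
    mito_frac[fail_mito] <- stats::runif(sum(fail_mito), 0.12, 0.30)
    nonmito_lib <- pmax(colSums(counts), 1)
    mito_tot <- round(mito_frac / (1 - mito_frac) * nonmito_lib)
    mito_share <- c(4, 3, 3, 2, 1, 2, 2, 1, 1, 2, 2, 1, 2)
    mito_share <- mito_share / sum(mito_share)
    for (i in seq_len(n_cells)) {
      if (mito_tot[i] > 0)
        counts[mt_genes, i] <-
          as.integer(stats::rmultinom(1, mito_tot[i], mito_share))
    }

    # ADT: small surface panel with cluster-informative means
    adt_mu <- sim_adt_means(cl, config$cluster_map)
    adt <- matrix(stats::rnbinom(length(adt_mu), mu = adt_mu, size = 8),
                  nrow = nrow(adt_mu), dimnames = dimnames(adt_mu))
    colnames(adt) <- cell_id

    cell_rows[[d]] <- data.frame(
      cell_id = cell_id, donor_id = donors[d], group = grp, cluster = cl,
      subset = unname(config$cluster_map[cl]), stringsAsFactors = FALSE)
    mats[[d]] <- Matrix::Matrix(counts, sparse = TRUE)
    adt_list[[d]] <- adt
    truth_fail_low <- c(truth_fail_low, cell_id[fail_low])
    truth_fail_mito <- c(truth_fail_mito, cell_id[fail_mito])
    truth_mito <- c(truth_mito, stats::setNames(mito_frac, cell_id))
  }
  cells <- do.call(rbind, cell_rows)
  rna <- do.call(cbind, mats)
  adt <- do.call(cbind, adt_list)
  truth <- list(de_genes = de,
                qc_fail_low = truth_fail_low,
                qc_fail_mito = truth_fail_mito,
                mito_fraction = truth_mito,
                cluster = stats::setNames(cells$cluster, cells$cell_id),
                marker_sets = marker_sets)
  list(cells = cells, rna = rna, adt = adt, truth = truth)
}

sim_adt_means <- function(cl, cluster_map) {
  markers <- c("CD19", "CD20", "CD21", "CD27", "CD38", "CD11c",
               "IgD", "IgM", "CD24", "HLA-DR")
  subset <- unname(cluster_map[cl])
  mu <- matrix(30, nrow = length(markers), ncol = length(cl),
               dimnames = list(markers, NULL))
  mu["CD27", subset %in% c("memory", "plasmablast")] <- 120
  mu["CD21", ] <- 80
  mu["CD21", cl == "3"] <- 15          # atypical-like: CD21-low
  mu["CD11c", cl == "3"] <- 90
  mu["CD38", subset == "plasmablast"] <- 200
  mu["IgD", subset %in% c("naive", "transitional")] <- 100
  mu["CD24", subset == "transitional"] <- 150
  mu
}
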