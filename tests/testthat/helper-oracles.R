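# Independent oracles used across tests. These deliberately use different
# algorithms from the package code paths they check.

# Brute-force two-sided rank-sum p value: enumerate every subset of size n1
# via bitmasks (no combn, unlike the implementation).
brute_wilcox_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  mu <- n1 * (n + 1) / 2
  obs <- abs(sum(r[seq_len(n1)]) - mu)
  hits <- 0L; total <- 0L
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[1:n]
    if (sum(bits) != n1) next
    total <- total + 1L
    if (abs(sum(r[bits == 1L]) - mu) >= obs - 1e-9) hits <- hits + 1L
  }
  hits / total
}

# Transitive closure over an explicit adjacency matrix by boolean matrix
# powering; returns component label per node.
brute_components <- function(adj) {
  n <- nrow(adj)
  reach <- adj | diag(TRUE, n)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  labels <- integer(n)
  lab <- 0L
  for (i in seq_len(n)) {
    if (labels[i] == 0L) {
      lab <- lab + 1L
      labels[reach[i, ]] <- lab
    }
  }
  labels
}

# Partition equality up to label renaming
same_partition <- function(a, b) {
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

# Random amino-acid CDR3 families: founders plus mutated descendants, with
# edit counts straddling the 15% divergence boundary so linkage decisions
# are exercised.
random_cdr3_block <- function(n, seed) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  n_fam <- max(1L, rpois(1, n / 6))
  founders <- replicate(n_fam, paste0(sample(aa, sample(11:16, 1),
                                             replace = TRUE), collapse = ""))
  vapply(seq_len(n), function(i) {
    f <- founders[sample.int(n_fam, 1)]
    v <- strsplit(f, "")[[1]]
    k <- sample(0:4, 1)
    if (k > 0) {
      pos <- sample(seq_along(v), k)
      for (p in pos) v[p] <- sample(aa, 1)
    }
    paste0(v, collapse = "")
  }, character(1))
}

# A tiny resolved-cells table for clonotype tests
make_cells_bcr <- function(cell_id, donor_id, vh, vl, hcdr3, lcdr3) {
  data.frame(cell_id = cell_id, donor_id = donor_id,
             vh_gene = vh, vl_gene = vl,
             heavy_cdr3_aa = hcdr3, heavy_cdr3_nt = hcdr3,
             light_cdr3_aa = lcdr3, light_cdr3_nt = lcdr3,
             heavy_v_sequence = "ACGT", light_v_sequence = "ACGT",
             heavy_v_call = vh, light_v_call = vl,
             heavy_c_call = "IGHM", isotype = "IGHM",
             heavy_umi = 1L, light_umi = 1L, stringsAsFactors = FALSE)
}

# Small cohort config shared by several suites
small_config <- function(seed = 1,
                         n_donors_per_group = c(stage1 = 3L, healthy = 3L),
                         cells_per_donor = c(250L, 300L),
                         n_genes = 800L, ...) {
  sim_config(seed = seed, n_donors_per_group = n_donors_per_group,
             cells_per_donor = cells_per_donor, n_genes = n_genes, ...)
}
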