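#' Two-sided Wilcoxon rank-sum test with exact mid-rank enumeration
#'
#' Rank-sum (Mann-Whitney) test used throughout the pipeline for group
#' comparisons of per-donor cluster frequencies, per-cell normalized
#' expression and per-cell somatic hypermutation. Ties are handled with
#' mid-ranks in both modes.
#'
#' For small samples the two-sided p value is computed by exhaustive
#' enumeration of all `choose(n1+n2, n1)` assignments of the pooled
#' mid-ranks to group 1: p = proportion of assignments whose rank-sum
#' deviates from its null mean by at least as much as the observed one.
#' This coincides with the classical exact test when there are no ties and
#' remains exact under ties (where `stats::wilcox.test` falls back to an
#' approximation). When enumeration is infeasible the tie-corrected normal
#' approximation with continuity correction is used.
#'
#' @param x,y numeric vectors of observations for the two groups.
#' @param exact force (`TRUE`)/suppress (`FALSE`) enumeration; default
#'   `NULL` enumerates whenever `choose(n1+n2, n1) <= max_combinations`.
#' @param max_combinations enumeration budget (default 1e5; covers all
#'   group sizes up to 8 vs 8 and the 9-vs-8 donor design).
#' @return list with `statistic` (Mann-Whitney U of group 1), `p.value`,
#'   and `exact` (logical, which mode was used).
#' @examples
#' wilcox_rank_sum(c(1, 2, 3), c(4, 5, 6))$p.value  # 2/20 = 0.1
#' @export
wilcox_rank_sum <- function(x, y, exact = NULL, max_combinations = 1e5) {
  x <- as.numeric(x[!is.na(x)])
  y <- as.numeric(y[!is.na(y)])
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) cs_input_error("both groups must be non-empty")
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  mu <- n1 * (n1 + n2 + 1) / 2
  if (is.null(exact)) exact <- choose(n1 + n2, n1) <= max_combinations
  if (exact) {
    combs <- utils::combn(n1 + n2, n1)
    ws <- colSums(matrix(r[combs], nrow = n1))
    p <- mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
  } else {
    u <- w_obs - n1 * (n1 + 1) / 2
    mu_u <- n1 * n2 / 2
    tab <- table(r)
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tab^3 - tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1  # all observations tied
    } else {
      z <- u - mu_u
      z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  list(statistic = unname(w_obs - n1 * (n1 + 1) / 2), p.value = p, exact = exact)
}
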