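# Target-set overrepresentation: three one-sided tests (binomial,
# Fisher, hypergeometric) on the cluster x target 2x2 table, Hochberg
# adjustment across miRNAs per test, and the all-three consensus call.

#' Triple overrepresentation test for a target set in a gene cluster
#'
#' Computes one-sided (overrepresentation) p-values for the overlap
#' between a cluster of genes and a miRNA target set within a universe,
#' with three tests on the same 2x2 table: binomial (k successes in n
#' cluster draws at rate K/N), Fisher's exact, and the hypergeometric
#' upper tail. The Fisher and hypergeometric p-values are identical by
#' construction and serve as a cross-check.
#'
#' @param cluster Character vector of cluster gene ids.
#' @param targets Character vector of target gene ids.
#' @param universe Character vector of all gene ids; `cluster` and
#'   `targets` must be subsets.
#' @return A list: `p_binomial`, `p_fisher`, `p_hypergeometric`, and
#'   `counts` (k = overlap, n = cluster size, K = target-set size,
#'   N = universe size).
#' @export
enrichment_tests <- function(cluster, targets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  cluster <- unique(cluster)
  targets <- unique(targets)
  if (!all(cluster %in% universe) || !all(targets %in% universe)) {
    stop("cluster and targets must be subsets of the universe",
         call. = FALSE)
  }
  N <- length(universe)
  n <- length(cluster)
  K <- length(targets)
  k <- length(intersect(cluster, targets))
  p_hyper <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  p_binom <- if (n == 0L) 1 else {
    stats::binom.test(k, n, p = K / N, alternative = "greater")$p.value
  }
  p_fisher <- if (n == 0L || K == 0L) 1 else {
    tab <- matrix(c(k, n - k, K - k, N - n - K + k), nrow = 2L)
    stats::fisher.test(tab, alternative = "greater")$p.value
  }
  list(p_binomial = p_binom, p_fisher = p_fisher,
       p_hypergeometric = p_hyper,
       counts = c(k = k, n = n, K = K, N = N))
}

#' Hochberg step-up adjustment
#'
#' @param p Numeric vector of raw p-values in [0, 1].
#' @return Adjusted p-values (>= raw, capped at 1), in input order.
#' @export
hochberg <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "hochberg")
}

#' Consensus target-overrepresentation calls across miRNAs
#'
#' Applies the Hochberg correction across miRNAs separately for each of
#' the three tests and flags a miRNA's target set as overrepresented in
#' the cluster only when all three adjusted p-values fall below `alpha`.
#'
#' @param records data.frame with one row per miRNA and columns
#'   `mirna_id`, `p_binomial`, `p_fisher`, `p_hypergeometric` (as
#'   produced by [enrichment_tests()]); all rows must refer to the same
#'   cluster and universe.
#' @param alpha Significance level (default 0.05).
#' @return The input with columns `adj_binomial`, `adj_fisher`,
#'   `adj_hypergeometric` and logical `consensus` appended.
#' @export
consensus_enrichment <- function(records, alpha = 0.05) {
  need <- c("mirna_id", "p_binomial", "p_fisher", "p_hypergeometric")
  if (!all(need %in% names(records))) {
    stop("records must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  records$adj_binomial <- hochberg(records$p_binomial)
  records$adj_fisher <- hochberg(records$p_fisher)
  records$adj_hypergeometric <- hochberg(records$p_hypergeometric)
  records$consensus <- records$adj_binomial < alpha &
    records$adj_fisher < alpha & records$adj_hypergeometric < alpha
  records
}
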