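# DEG-intersection concordance analysis: which genes respond to miRNA
# antagonism the same way they respond to aging? Genes differentially
# expressed in both an aging contrast and a sponge (miRNA loss-of-
# function) contrast are typed by their direction pattern and the
# concordant fraction is tested against independence.

#' Intersect two DEG tables
#'
#' @param aging,sponge DEG data.frames with columns `gene_id`, `log2FC`,
#'   and (optionally, when `fdr` is given) `FDR`.
#' @param fdr Optional FDR threshold applied to both tables before
#'   intersecting; `NULL` assumes the tables are pre-filtered.
#' @return Character vector of gene ids present in both tables.
#' @export
intersect_degs <- function(aging, sponge, fdr = NULL) {
  if (!is.null(fdr)) {
    aging <- aging[aging$FDR < fdr, , drop = FALSE]
    sponge <- sponge[sponge$FDR < fdr, , drop = FALSE]
  }
  intersect(aging$gene_id, sponge$gene_id)
}

#' Classify intersected genes by direction pattern
#'
#' Type 1: up in both contrasts; type 2: up in aging, down in sponge;
#' type 3: down in both; type 4: down in aging, up in sponge. Genes with
#' a zero log2 fold change in either contrast cannot be assigned a
#' direction and are excluded with a warning.
#'
#' @inheritParams intersect_degs
#' @param genes Optional gene set to restrict to (defaults to the
#'   intersection of the two tables).
#' @return data.frame with columns `gene_id`, `type` (integer 1-4),
#'   `log2FC_aging`, `log2FC_sponge`.
#' @export
classify_types <- function(aging, sponge, genes = NULL) {
  if (is.null(genes)) genes <- intersect_degs(aging, sponge)
  a <- aging$log2FC[match(genes, aging$gene_id)]
  s <- sponge$log2FC[match(genes, sponge$gene_id)]
  zero <- a == 0 | s == 0
  if (any(zero)) {
    warning(sprintf("%d gene(s) with zero log2FC excluded: %s",
                    sum(zero), paste(genes[zero], collapse = ", ")))
    genes <- genes[!zero]
    a <- a[!zero]
    s <- s[!zero]
  }
  type <- ifelse(a > 0, ifelse(s > 0, 1L, 2L), ifelse(s > 0, 4L, 3L))
  data.frame(gene_id = genes, type = type, log2FC_aging = a,
             log2FC_sponge = s, stringsAsFactors = FALSE)
}

#' Concordance summary of a typed DEG intersection
#'
#' Concordant genes (types 1 and 3) change in the same direction in both
#' contrasts. The percent concordant/discordant is rounded to the
#' nearest integer. Independence of the two direction labels is tested
#' with a 2x2 chi-square test without continuity correction; when any
#' expected count falls below 5 a Fisher exact test is substituted (and
#' noted in `test_used`).
#'
#' @param typed Output of [classify_types()] (or any data.frame with a
#'   `type` column).
#' @param total_override Optional externally stated intersection total
#'   used as the percentage denominator (the internally computed total
#'   is always reported alongside).
#' @return A list of class `concordance_summary`: `counts` (n1-n4),
#'   `n_classified`, `total` (denominator used), `concordant`,
#'   `concordant_percent`, `discordant_percent`, `chisq` statistic, `p`,
#'   and `test_used`.
#' @export
concordance <- function(typed, total_override = NULL) {
  if (!nrow(typed)) stop("no typed genes", call. = FALSE)
  counts <- vapply(1:4, function(t) sum(typed$type == t), integer(1))
  names(counts) <- paste0("type", 1:4)
  n_classified <- sum(counts)
  total <- if (is.null(total_override)) n_classified else total_override
  concordant <- counts[["type1"]] + counts[["type3"]]
  # 2x2: aging direction (up = types 1,2; down = types 3,4) x sponge
  # direction (up = types 1,4; down = types 2,3)
  tab <- matrix(c(counts[["type1"]], counts[["type2"]],
                  counts[["type4"]], counts[["type3"]]),
                nrow = 2L, byrow = TRUE,
                dimnames = list(aging = c("up", "down"),
                                sponge = c("up", "down")))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    p <- stats::fisher.test(tab)$p.value
    stat <- NA_real_
    test_used <- "fisher"
  } else {
    ct <- stats::chisq.test(tab, correct = FALSE)
    p <- ct$p.value
    stat <- unname(ct$statistic)
    test_used <- "chisq"
  }
  structure(list(counts = counts, n_classified = n_classified,
                 total = total, concordant = unname(concordant),
                 concordant_percent = round(100 * concordant / total),
                 discordant_percent = round(100 * (total - concordant) /
                                              total),
                 chisq = stat, p = p, test_used = test_used),
            class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf(paste0("DEG intersection concordance: %d/%d concordant ",
                     "(~%d%%), %d discordant (~%d%%)\n"),
              x$concordant, x$total, x$concordant_percent,
              x$total - x$concordant, x$discordant_percent))
  cat(sprintf("  types 1-4: %s; %s p = %.3g\n",
              paste(x$counts, collapse = ", "), x$test_used, x$p))
  invisible(x)
}

#' Correlation of fold changes across the intersection
#'
#' @inheritParams classify_types
#' @return Pearson correlation of (log2FC aging, log2FC sponge) pairs.
#' @export
foldchange_correlation <- function(aging, sponge, genes = NULL) {
  if (is.null(genes)) genes <- intersect_degs(aging, sponge)
  if (!length(genes)) stop("empty intersection", call. = FALSE)
  pearson(aging$log2FC[match(genes, aging$gene_id)],
          sponge$log2FC[match(genes, sponge$gene_id)])
}

#' Fisher overlap test between a DEG set and a trait-associated set
#'
#' Two-sided Fisher exact test on the 2x2 membership table within a
#' universe, e.g. DEGs versus genes whose expression correlates with
#' lifespan. The sample odds ratio (ad/bc) is reported.
#'
#' @param deg_set,trait_set Character vectors, subsets of `universe`.
#' @param universe Character vector of all considered genes.
#' @return List with `odds_ratio`, `p`, and the 2x2 `table`.
#' @export
overlap_fisher <- function(deg_set, trait_set, universe) {
  universe <- unique(universe)
  deg_set <- unique(deg_set)
  trait_set <- unique(trait_set)
  if (!all(deg_set %in% universe) || !all(trait_set %in% universe)) {
    stop("both sets must be subsets of the universe", call. = FALSE)
  }
  a <- length(intersect(deg_set, trait_set))
  b <- length(deg_set) - a
  c_ <- length(trait_set) - a
  d <- length(universe) - a - b - c_
  tab <- matrix(c(a, b, c_, d), nrow = 2L,
                dimnames = list(deg = c("in", "out"),
                                trait = c("in", "out")))
  p <- if (length(trait_set) == 0L || length(deg_set) == 0L) 1 else {
    stats::fisher.test(tab, alternative = "two.sided")$p.value
  }
  list(odds_ratio = (a * d) / (b * c_), p = p, table = tab)
}
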