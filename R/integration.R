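#' Hypergeometric overlap of two gene sets
#'
#' Upper-tail (enrichment) p-value for drawing an overlap of size k
#' between sets of sizes nA and nB from a universe of N genes:
#' P(X >= k) with X ~ hypergeometric(N, nA, nB). The universe should be
#' the genes represented on the array/annotation, not the genome; every
#' report carries N so this choice is explicit.
#'
#' @param n_a,n_b Set sizes.
#' @param k Observed overlap.
#' @param n_universe Universe size N.
#' @param alternative `"enrichment"` (upper tail, default) or
#'   `"depletion"` (lower tail).
#' @return A list of class `gene_set_comparison`: `n_universe`, `n_a`,
#'   `n_b`, `k`, `expected`, `fold_enrichment`, `p`.
#' @export
hypergeometric_overlap <- function(n_a, n_b, k, n_universe,
                                   alternative = c("enrichment", "depletion")) {
  alternative <- match.arg(alternative)
  n_a <- check_count(n_a, "n_a"); n_b <- check_count(n_b, "n_b")
  k <- check_count(k, "k"); N <- check_count(n_universe, "n_universe", 1L)
  if (n_a > N || n_b > N) stopf("set sizes cannot exceed the universe")
  if (k > min(n_a, n_b)) stopf("overlap k = %d exceeds min(nA, nB) = %d", k, min(n_a, n_b))
  p <- if (alternative == "enrichment")
    stats::phyper(k - 1L, n_a, N - n_a, n_b, lower.tail = FALSE)
  else
    stats::phyper(k, n_a, N - n_a, n_b, lower.tail = TRUE)
  expected <- n_a * n_b / N
  structure(list(n_universe = N, n_a = n_a, n_b = n_b, k = k,
                 expected = expected,
                 fold_enrichment = if (expected > 0) k / expected else NA_real_,
                 p = p, alternative = alternative),
            class = "gene_set_comparison")
}

#' @export
print.gene_set_comparison <- function(x, ...) {
  cat(sprintf(
    "<gene_set_comparison> k = %d of nA = %d x nB = %d in N = %d (universe: annotated genes)\n  expected %.2f, fold %.2f, %s p = %.3g\n",
    x$k, x$n_a, x$n_b, x$n_universe, x$expected, x$fold_enrichment,
    x$alternative, x$p))
  invisible(x)
}

#' Direction-of-regulation fractions among bound, regulated genes
#'
#' Among genes that are both bound and pass the DE filter, the fraction
#' whose expression falls upon knockdown (factor-activated targets) and
#' the fraction that rises (factor-repressed). The two fractions sum to
#' one; an empty bound-and-regulated set is flagged undefined.
#'
#' @param deg_table A `deg_table`.
#' @param bound_flags Data frame (`gene_id`, `bound`) or character
#'   vector of bound gene ids.
#' @return A list: `n`, `frac_activated`, `frac_repressed`, `defined`.
#' @export
direction_fractions <- function(deg_table, bound_flags) {
  stopifnot(inherits(deg_table, "deg_table"))
  bound_ids <- if (is.character(bound_flags)) bound_flags else
    bound_flags$gene_id[bound_flags$bound]
  sel <- deg_table$passes_filter & deg_table$gene_id %in% bound_ids
  n <- sum(sel)
  if (n == 0L)
    return(list(n = 0L, frac_activated = NA_real_, frac_repressed = NA_real_,
                defined = FALSE))
  down <- sum(deg_table$direction[sel] == "down")
  list(n = n, frac_activated = down / n, frac_repressed = 1 - down / n,
       defined = TRUE)
}

#' Putative direct targets: bound fraction of regulated genes
#'
#' Intersects a differentially-expressed gene list with the bound gene
#' set and reports the bound fraction with exact arithmetic (count,
#' fraction and percentage).
#'
#' @param deg_list Character vector of regulated gene ids (no
#'   duplicates).
#' @param bound_genes Character vector of bound gene ids (no
#'   duplicates).
#' @return A list: `targets`, `n_deg`, `n_bound`, `n_overlap`,
#'   `fraction`, `percent`.
#' @export
putative_direct_targets <- function(deg_list, bound_genes) {
  if (anyDuplicated(deg_list)) stopf("duplicate gene ids in `deg_list`")
  if (anyDuplicated(bound_genes)) stopf("duplicate gene ids in `bound_genes`")
  targets <- intersect(deg_list, bound_genes)
  frac <- if (length(deg_list)) length(targets) / length(deg_list) else NA_real_
  list(targets = targets, n_deg = length(deg_list),
       n_bound = length(bound_genes), n_overlap = length(targets),
       fraction = frac, percent = 100 * frac)
}
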