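#' Overlap-matching parameters
#'
#' The domain-set comparison rule: two domains match if at least one of
#' them has at least `min_fraction` of its length covered by the other
#' (`mode = "either"`, the default) or if both do
#' (`mode = "reciprocal"`).
#'
#' @param min_fraction Minimum overlap fraction (default 0.80).
#' @param mode `"either"` or `"reciprocal"`.
#' @return A list of class `overlap_params`.
#' @export
overlap_params <- function(min_fraction = 0.80, mode = c("either", "reciprocal")) {
  if (!is_number(min_fraction) || min_fraction <= 0 || min_fraction > 1)
    stopf("`min_fraction` must be in (0, 1]")
  structure(list(min_fraction = min_fraction, mode = match.arg(mode)),
            class = "overlap_params")
}

#' Gene-assignment parameters
#'
#' A gene is called bound if any domain overlaps (by at least 1 bp) the
#' union of its body and a strand-aware upstream promoter window.
#'
#' @param upstream_window bp upstream of the transcription start
#'   (default 2000).
#' @param downstream_window bp downstream of the transcription end
#'   (default 0).
#' @param use_gene_body Include the gene body (default `TRUE`).
#' @return A list of class `gene_assignment_params`.
#' @export
gene_assignment_params <- function(upstream_window = 2000,
                                   downstream_window = 0,
                                   use_gene_body = TRUE) {
  structure(list(upstream_window = check_number(upstream_window, "upstream_window", 0),
                 downstream_window = check_number(downstream_window, "downstream_window", 0),
                 use_gene_body = isTRUE(use_gene_body)),
            class = "gene_assignment_params")
}

#' Length of the intersection of two half-open intervals
#'
#' @param a,b Intervals as `list`/`data.frame` rows or vectors with
#'   `chrom`, `start`, `end`.
#' @return Overlap length in bp (0 for different chromosomes, by
#'   contract).
#' @export
overlap_length <- function(a, b) {
  if (as.character(a$chrom) != as.character(b$chrom)) return(0)
  max(0, min(a$end, b$end) - max(a$start, b$start))
}

# Vectorized pairwise overlap for same-chromosome frames.
overlap_bp <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

#' Match two domain sets by fractional overlap
#'
#' Pairs (a, b) are candidates iff `overlap/len(a) >= min_fraction` OR
#' `overlap/len(b) >= min_fraction` (mode "either"; AND for
#' "reciprocal"). Each domain is matched to at most one partner,
#' greedily by largest overlap, ties broken toward the leftmost
#' interval.
#'
#' @param set_a,set_b Interval data frames (`chrom`, `start`, `end`,
#'   `name`), each sorted and non-overlapping within itself.
#' @param params An [overlap_params()].
#' @return A list: `pairs` (id_a, id_b, overlap_bp, frac_a, frac_b),
#'   `a_only`, `b_only` (unmatched ids).
#' @export
match_domain_sets <- function(set_a, set_b, params = overlap_params()) {
  for (nm in c("set_a", "set_b")) {
    s <- get(nm)
    msg <- first_interval_violation(s)
    if (!is.null(msg)) stopf("%s: %s", nm, msg)
  }
  cand <- list()
  for (chr in intersect(unique(set_a$chrom), unique(set_b$chrom))) {
    a <- set_a[set_a$chrom == chr, , drop = FALSE]
    b <- set_b[set_b$chrom == chr, , drop = FALSE]
    for (i in seq_len(nrow(a))) {
      ov <- overlap_bp(a$start[i], a$end[i], b$start, b$end)
      hit <- which(ov > 0)
      if (!length(hit)) next
      cand[[length(cand) + 1L]] <- data.frame(
        id_a = a$name[i], id_b = b$name[hit], overlap_bp = ov[hit],
        frac_a = ov[hit] / (a$end[i] - a$start[i]),
        frac_b = ov[hit] / (b$end[hit] - b$start[hit]),
        a_start = a$start[i], b_start = b$start[hit],
        stringsAsFactors = FALSE)
    }
  }
  pairs0 <- if (length(cand)) do.call(rbind, cand) else NULL
  if (!is.null(pairs0)) {
    ok <- if (params$mode == "either")
      pairs0$frac_a >= params$min_fraction | pairs0$frac_b >= params$min_fraction
    else
      pairs0$frac_a >= params$min_fraction & pairs0$frac_b >= params$min_fraction
    pairs0 <- pairs0[ok, , drop = FALSE]
  }
  pairs <- data.frame(id_a = character(), id_b = character(),
                      overlap_bp = numeric(), frac_a = numeric(),
                      frac_b = numeric(), stringsAsFactors = FALSE)
  if (!is.null(pairs0) && nrow(pairs0)) {
    pairs0 <- pairs0[order(-pairs0$overlap_bp, pairs0$a_start, pairs0$b_start), ,
                     drop = FALSE]
    used_a <- used_b <- character(0)
    keep <- logical(nrow(pairs0))
    for (i in seq_len(nrow(pairs0))) {
      if (pairs0$id_a[i] %in% used_a || pairs0$id_b[i] %in% used_b) next
      keep[i] <- TRUE
      used_a <- c(used_a, pairs0$id_a[i])
      used_b <- c(used_b, pairs0$id_b[i])
    }
    pairs <- pairs0[keep, c("id_a", "id_b", "overlap_bp", "frac_a", "frac_b"),
                    drop = FALSE]
    rownames(pairs) <- NULL
  }
  list(pairs = pairs,
       a_only = setdiff(set_a$name, pairs$id_a),
       b_only = setdiff(set_b$name, pairs$id_b))
}

# Strand-aware regulatory intervals of one gene (list of [start,end) pairs).
gene_regions <- function(start, end, strand, params) {
  regs <- list()
  if (params$use_gene_body) regs[[length(regs) + 1L]] <- c(start, end)
  if (params$upstream_window > 0) {
    regs[[length(regs) + 1L]] <- if (strand == "+")
      c(max(0, start - params$upstream_window), start)
    else c(end, end + params$upstream_window)
  }
  if (params$downstream_window > 0) {
    regs[[length(regs) + 1L]] <- if (strand == "+")
      c(end, end + params$downstream_window)
    else c(max(0, start - params$downstream_window), start)
  }
  regs
}

#' Assign domains to genes
#'
#' A gene is flagged bound iff any domain overlaps (by at least 1 bp)
#' the union of its body (if `use_gene_body`) and the strand-aware
#' upstream window before its transcription start (for a minus-strand
#' gene "upstream" extends to higher coordinates).
#'
#' @param domains Interval data frame.
#' @param genes Stranded BED6-style data frame (`chrom`, `start`,
#'   `end`, `name`, `score`, `strand`), sorted.
#' @param params A [gene_assignment_params()].
#' @return A list: `gene_flags` (gene_id, bound, domain ids), and
#'   `domain_genes` (domain_id, gene ids).
#' @export
assign_domains_to_genes <- function(domains, genes,
                                    params = gene_assignment_params()) {
  if (!all(genes$strand %in% c("+", "-")))
    stopf("unknown strand symbol: %s",
          paste(setdiff(unique(genes$strand), c("+", "-")), collapse = ","))
  bound <- logical(nrow(genes))
  gene_doms <- character(nrow(genes))
  dom_genes <- stats::setNames(vector("list", nrow(domains)), domains$name)
  for (gi in seq_len(nrow(genes))) {
    regs <- gene_regions(genes$start[gi], genes$end[gi], genes$strand[gi], params)
    d <- domains[domains$chrom == genes$chrom[gi], , drop = FALSE]
    if (!nrow(d) || !length(regs)) next
    hit <- rep(FALSE, nrow(d))
    for (rg in regs) hit <- hit | (d$start < rg[2] & d$end > rg[1])
    if (any(hit)) {
      bound[gi] <- TRUE
      gene_doms[gi] <- paste(d$name[hit], collapse = ",")
      for (dn in d$name[hit])
        dom_genes[[dn]] <- c(dom_genes[[dn]], genes$name[gi])
    }
  }
  list(
    gene_flags = data.frame(gene_id = genes$name, bound = bound,
                            domains = gene_doms, stringsAsFactors = FALSE),
    domain_genes = data.frame(
      domain_id = domains$name,
      genes = vapply(dom_genes, function(g) paste(g, collapse = ","), character(1)),
      stringsAsFactors = FALSE)
  )
}
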