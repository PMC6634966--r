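#' Configuration for the synthetic DamID study generator
#'
#' Bundles every knob of the simulated study: a NimbleGen-style probe
#' grid (~300 bp spacing), two biological replicates plus a dye-swap
#' technical replicate of a two-channel Dam-fusion vs. Dam-only
#' hybridization, planted enriched domains on the log2-ratio track, a
#' smooth intensity-dependent distortion for LOESS to remove, a stranded
#' gene annotation linked to a subset of domains, and a two-group
#' expression matrix with 2-fold-or-greater planted effects.
#'
#' @param seed Integer seed; the same seed reproduces every output
#'   byte-identically.
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_length Chromosome length in bp.
#' @param probe_spacing Probe start-to-start spacing in bp (default 300).
#' @param probe_length Probe length in bp.
#' @param n_domains Number of planted enriched domains.
#' @param domain_length_range Length range (bp) of planted domains;
#'   must be at least twice the probe spacing.
#' @param domain_effect Mean log2 ratio inside planted domains.
#' @param noise_sd Per-probe Gaussian noise on the log2 ratio.
#' @param intensity_bias_amplitude Amplitude (log2 units) of a smooth
#'   intensity-dependent distortion added to the raw ratio; this is the
#'   component LOESS normalization is expected to remove.
#' @param n_biological_replicates Biological replicates (default 2).
#' @param include_dye_swap Add one dye-swap technical replicate
#'   (channels exchanged; default `TRUE`).
#' @param baseline_log2_mean,baseline_log2_sd Distribution of the
#'   per-probe mean log2 intensity A. Setting `baseline_log2_sd = 0`
#'   gives a constant-A array (normalization then falls back to median
#'   subtraction, which is exact), useful for noise-free checks.
#' @param n_genes Number of annotated genes.
#' @param frac_genes_linked Fraction of planted domains linked to a gene
#'   (the gene body overlaps the domain).
#' @param frac_de_bound Fraction of planted differentially expressed
#'   genes that are domain-linked ("bound"); the remainder are planted
#'   on unbound genes.
#' @param frac_activated Among bound DE genes, fraction planted as
#'   factor-activated (down upon knockdown).
#' @param de_fold_change Linear fold change of planted effects
#'   (default 2).
#' @param n_expr_replicates Expression replicates per group (default 3).
#' @param expr_noise_sd Per-measurement log2 noise in the expression
#'   matrix.
#' @param margin_probes Probes left free of domains at each chromosome
#'   end (keeps edge statistics defined across every planted boundary).
#' @param min_gap_probes Minimum inter-domain gap in probes (keeps
#'   flanking windows of neighbouring domains from interfering).
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_chromosomes = 2L,
                             chromosome_length = 3e6,
                             probe_spacing = 300L,
                             probe_length = 50L,
                             n_domains = 50L,
                             domain_length_range = c(15000, 30000),
                             domain_effect = 1.0,
                             noise_sd = 0.25,
                             intensity_bias_amplitude = 0.5,
                             n_biological_replicates = 2L,
                             include_dye_swap = TRUE,
                             baseline_log2_mean = 11,
                             baseline_log2_sd = 1,
                             n_genes = 2000L,
                             frac_genes_linked = 0.7,
                             frac_de_bound = 0.35,
                             frac_activated = 0.7,
                             de_fold_change = 2,
                             n_expr_replicates = 3L,
                             expr_noise_sd = 0.25,
                             margin_probes = 100L,
                             min_gap_probes = 100L) {
  cfg <- list(
    seed = check_count(seed, "seed"),
    n_chromosomes = check_count(n_chromosomes, "n_chromosomes", 1L),
    chromosome_length = check_number(chromosome_length, "chromosome_length", 1),
    probe_spacing = check_count(probe_spacing, "probe_spacing", 1L),
    probe_length = check_count(probe_length, "probe_length", 1L),
    n_domains = check_count(n_domains, "n_domains"),
    domain_length_range = as.numeric(domain_length_range),
    domain_effect = check_number(domain_effect, "domain_effect"),
    noise_sd = check_number(noise_sd, "noise_sd", 0),
    intensity_bias_amplitude =
      check_number(intensity_bias_amplitude, "intensity_bias_amplitude", 0),
    n_biological_replicates =
      check_count(n_biological_replicates, "n_biological_replicates", 1L),
    include_dye_swap = isTRUE(include_dye_swap),
    baseline_log2_mean = check_number(baseline_log2_mean, "baseline_log2_mean"),
    baseline_log2_sd = check_number(baseline_log2_sd, "baseline_log2_sd", 0),
    n_genes = check_count(n_genes, "n_genes"),
    frac_genes_linked = check_number(frac_genes_linked, "frac_genes_linked", 0, 1),
    frac_de_bound = check_number(frac_de_bound, "frac_de_bound", 0, 1),
    frac_activated = check_number(frac_activated, "frac_activated", 0, 1),
    de_fold_change = check_number(de_fold_change, "de_fold_change", 1),
    n_expr_replicates = check_count(n_expr_replicates, "n_expr_replicates", 2L),
    expr_noise_sd = check_number(expr_noise_sd, "expr_noise_sd", 0),
    margin_probes = check_count(margin_probes, "margin_probes"),
    min_gap_probes = check_count(min_gap_probes, "min_gap_probes")
  )
  if (length(cfg$domain_length_range) != 2L ||
      any(!is.finite(cfg$domain_length_range)) ||
      cfg$domain_length_range[1] > cfg$domain_length_range[2])
    stopf("`domain_length_range` must be an increasing pair of lengths")
  if (cfg$n_domains > 0 &&
      cfg$domain_length_range[1] < 2 * cfg$probe_spacing)
    stopf("domain lengths must be at least twice the probe spacing")
  if (cfg$probe_length > cfg$probe_spacing)
    stopf("`probe_length` must not exceed `probe_spacing`")
  class(cfg) <- "synthetic_config"
  cfg
}

#' Lay out the probe grid of a synthetic tiling array
#'
#' Probes tile each chromosome at a fixed spacing, sorted and
#' non-overlapping, in 0-based half-open coordinates. A chromosome
#' shorter than one spacing gets no probes (with a warning).
#'
#' @param config A [synthetic_config()].
#' @return A data frame (`chrom`, `start`, `end`, `probe_id`).
#' @export
make_probe_grid <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  out <- vector("list", config$n_chromosomes)
  for (c_i in seq_len(config$n_chromosomes)) {
    chr <- sprintf("chr%d", c_i)
    n <- floor(config$chromosome_length / config$probe_spacing)
    if (n < 1) {
      warnf("chromosome %s shorter than one probe spacing: no probes", chr)
      next
    }
    start <- (seq_len(n) - 1L) * config$probe_spacing
    out[[c_i]] <- data.frame(
      chrom = chr,
      start = start,
      end = start + config$probe_length,
      probe_id = sprintf("%s_p%06d", chr, seq_len(n)),
      stringsAsFactors = FALSE
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      probe_id = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plant non-overlapping enriched domains on the probe grid
#'
#' Domain lengths are drawn uniformly from `domain_length_range`, then
#' snapped to probe boundaries: a domain runs from the start of its
#' first probe to the end of its last. Domains are pairwise
#' non-overlapping, separated by at least `min_gap_probes`, and kept
#' `margin_probes` away from chromosome ends.
#'
#' @param config A [synthetic_config()].
#' @param grid Probe grid from [make_probe_grid()].
#' @return A `truth_set` list: `domains` (chrom, start, end, name,
#'   effect), empty `de_genes` and `links` (filled by
#'   [simulate_gene_annotation()]).
#' @export
plant_domains <- function(config, grid) {
  stopifnot(inherits(config, "synthetic_config"))
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), effect = numeric(),
                      stringsAsFactors = FALSE)
  truth <- structure(
    list(domains = empty,
         de_genes = data.frame(gene_id = character(), log2fc = numeric(),
                               stringsAsFactors = FALSE),
         links = data.frame(domain_id = character(), gene_id = character(),
                            stringsAsFactors = FALSE)),
    class = "truth_set")
  if (config$n_domains == 0L) return(truth)
  if (nrow(grid) == 0L) stopf("cannot plant domains on an empty grid")

  set.seed(stage_seed(config$seed, "plant_domains"))
  chroms <- unique(grid$chrom)
  n_per <- vapply(chroms, function(ch) sum(grid$chrom == ch), integer(1))
  # occupied probe index windows per chromosome (inclusive, with gap padding)
  occupied <- lapply(chroms, function(ch) matrix(numeric(0), ncol = 2))
  names(occupied) <- chroms
  placed <- 0L
  rows <- vector("list", config$n_domains)
  max_tries <- 200L * config$n_domains
  tries <- 0L
  while (placed < config$n_domains && tries < max_tries) {
    tries <- tries + 1L
    len <- stats::runif(1, config$domain_length_range[1], config$domain_length_range[2])
    k <- max(2L, as.integer(round(len / config$probe_spacing)))
    ch <- sample(chroms, 1L, prob = n_per)
    n <- n_per[[ch]]
    lo <- config$margin_probes + 1L
    hi <- n - config$margin_probes - k + 1L
    if (hi < lo) next
    i <- sample(lo:hi, 1L)
    j <- i + k - 1L
    occ <- occupied[[ch]]
    pad <- config$min_gap_probes
    if (nrow(occ) && any(i - pad <= occ[, 2] & j + pad >= occ[, 1])) next
    occupied[[ch]] <- rbind(occ, c(i, j))
    g <- grid[grid$chrom == ch, , drop = FALSE]
    placed <- placed + 1L
    rows[[placed]] <- data.frame(
      chrom = ch, start = g$start[i], end = g$end[j],
      name = sprintf("true_dom_%03d", placed),
      effect = config$domain_effect, stringsAsFactors = FALSE)
  }
  if (placed < config$n_domains)
    stopf("could only place %d of %d non-overlapping domains", placed, config$n_domains)
  dom <- do.call(rbind, rows[seq_len(placed)])
  dom <- dom[order(dom$chrom, dom$start), , drop = FALSE]
  rownames(dom) <- NULL
  # stable ids in coordinate order
  dom$name <- sprintf("true_dom_%03d", seq_len(nrow(dom)))
  truth$domains <- dom
  truth
}

probe_in_domains <- function(grid, domains) {
  inside <- rep(FALSE, nrow(grid))
  if (nrow(domains) == 0L) return(inside)
  for (r in seq_len(nrow(domains))) {
    inside <- inside | (grid$chrom == domains$chrom[r] &
                          grid$start >= domains$start[r] &
                          grid$end <= domains$end[r])
  }
  inside
}

#' Simulate two-channel DamID array replicates
#'
#' Each replicate carries per-probe fusion and control intensities such
#' that the expected log2(fusion/control) equals the planted effect
#' inside true domains and 0 outside, plus Gaussian noise and a smooth
#' intensity-dependent distortion (a half-sine in the mean log
#' intensity A, amplitude `intensity_bias_amplitude`) that LOESS
#' normalization is expected to remove. The Dam-fusion channel is
#' compared against methylase alone, so the control channel represents
#' non-specific accessibility. The dye-swap replicate has its channels
#' exchanged exactly.
#'
#' @param config A [synthetic_config()].
#' @param grid Probe grid.
#' @param truth A `truth_set` from [plant_domains()].
#' @return A list of `array_sample` objects (see [array_sample()]),
#'   biological replicates first, then the dye swap if enabled.
#' @export
simulate_damid_arrays <- function(config, grid, truth) {
  stopifnot(inherits(config, "synthetic_config"), inherits(truth, "truth_set"))
  if (config$noise_sd < 0) stopf("`noise_sd` must be non-negative")
  set.seed(stage_seed(config$seed, "simulate_damid_arrays"))
  inside <- probe_in_domains(grid, truth$domains)
  m_true <- ifelse(inside, config$domain_effect, 0)
  n <- nrow(grid)
  n_rep <- config$n_biological_replicates + as.integer(config$include_dye_swap)
  samples <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    swapped <- config$include_dye_swap && r == n_rep
    a0 <- stats::rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)
    noise <- if (config$noise_sd > 0) stats::rnorm(n, 0, config$noise_sd) else 0
    if (config$intensity_bias_amplitude > 0 && diff(range(a0)) > 0) {
      z <- (a0 - min(a0)) / diff(range(a0))
      bias <- config$intensity_bias_amplitude * sin(pi * z)
    } else bias <- 0
    m_obs <- m_true + noise + bias
    fusion <- 2^(a0 + m_obs / 2)
    control <- 2^(a0 - m_obs / 2)
    if (swapped) { tmp <- fusion; fusion <- control; control <- tmp }
    probes <- grid
    probes$intensity_fusion <- fusion
    probes$intensity_control <- control
    samples[[r]] <- array_sample(
      probes,
      sample_id = if (swapped) "rep_dyeswap" else sprintf("rep%d", r),
      dye_swapped = swapped)
  }
  samples
}

#' Simulate a stranded gene annotation linked to planted domains
#'
#' A fraction of planted domains (`frac_genes_linked`) each get a gene
#' whose body overlaps the domain; the remaining genes are placed away
#' from all domains. A set of differentially expressed genes is chosen
#' so that `frac_de_bound` of them are domain-linked, and
#' `frac_activated` of the bound DE genes are planted as
#' factor-activated (log2 fold change negative upon knockdown, i.e. the
#' factor is required for their expression).
#'
#' @param config A [synthetic_config()].
#' @param grid Probe grid (defines chromosome extents).
#' @param truth A `truth_set` from [plant_domains()]; returned updated.
#' @return A list with `genes` (BED6-style data frame: chrom, start,
#'   end, name, score, strand) and the updated `truth` whose `de_genes`
#'   and `links` are filled.
#' @export
simulate_gene_annotation <- function(config, grid, truth) {
  stopifnot(inherits(config, "synthetic_config"), inherits(truth, "truth_set"))
  set.seed(stage_seed(config$seed, "simulate_gene_annotation"))
  chroms <- unique(grid$chrom)
  chrom_len <- vapply(chroms, function(ch) max(grid$end[grid$chrom == ch]), numeric(1))
  doms <- truth$domains
  n_linked <- round(config$frac_genes_linked * nrow(doms))
  linked_dom <- if (n_linked > 0) sort(sample(seq_len(nrow(doms)), n_linked)) else integer(0)

  gene_rows <- vector("list", config$n_genes)
  links <- vector("list", length(linked_dom))
  gi <- 0L
  for (idx in seq_along(linked_dom)) {
    d <- doms[linked_dom[idx], ]
    gi <- gi + 1L
    glen <- round(stats::runif(1, 2000, 8000))
    gstart <- max(0, round(stats::runif(1, d$start - glen / 2, d$end - glen / 2)))
    gene_rows[[gi]] <- data.frame(
      chrom = d$chrom, start = gstart, end = gstart + glen,
      name = sprintf("gene_%05d", gi), score = 0,
      strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE)
    links[[idx]] <- data.frame(domain_id = d$name,
                               gene_id = sprintf("gene_%05d", gi),
                               stringsAsFactors = FALSE)
  }
  # Unlinked genes are rejection-sampled with a 2 kb clearance from every
  # domain so they stay unbound under the default promoter-window
  # assignment rule, keeping the planted linkage fraction recoverable.
  clearance <- 2000
  while (gi < config$n_genes) {
    gi <- gi + 1L
    repeat {
      ch <- sample(chroms, 1L)
      glen <- round(stats::runif(1, 2000, 8000))
      gstart <- round(stats::runif(1, 0, chrom_len[[ch]] - glen))
      dch <- doms[doms$chrom == ch, , drop = FALSE]
      if (!nrow(dch) || all(gstart + glen + clearance <= dch$start |
                              gstart - clearance >= dch$end)) break
    }
    gene_rows[[gi]] <- data.frame(
      chrom = ch, start = gstart, end = gstart + glen,
      name = sprintf("gene_%05d", gi), score = 0,
      strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, gene_rows)
  truth$links <- if (length(links)) do.call(rbind, links) else truth$links

  bound_ids <- truth$links$gene_id
  n_de_bound <- length(bound_ids)
  n_de_total <- if (config$frac_de_bound > 0)
    round(n_de_bound / config$frac_de_bound) else n_de_bound
  unbound_pool <- setdiff(genes$name, bound_ids)
  n_unbound_de <- min(max(0L, n_de_total - n_de_bound), length(unbound_pool))
  unbound_de <- if (n_unbound_de > 0) sample(unbound_pool, n_unbound_de) else character(0)
  de_ids <- c(bound_ids, unbound_de)
  lfc <- log2(config$de_fold_change)
  sign_bound <- ifelse(stats::runif(n_de_bound) < config$frac_activated, -1, 1)
  sign_unbound <- sample(c(-1, 1), n_unbound_de, replace = TRUE)
  truth$de_genes <- data.frame(
    gene_id = de_ids,
    log2fc = c(sign_bound, sign_unbound) * lfc,
    stringsAsFactors = FALSE)
  list(genes = genes, truth = truth)
}

#' Simulate a two-group log-scale expression matrix
#'
#' Control and knockdown groups with `n_expr_replicates` columns each.
#' Genes in `truth$de_genes` are shifted in the knockdown group by
#' their signed planted log2 fold change; all measurements get i.i.d.
#' Gaussian noise of sd `expr_noise_sd`.
#'
#' @param config A [synthetic_config()].
#' @param truth A `truth_set` with planted DE genes.
#' @param genes Gene annotation (row per gene; `name` column), or a
#'   character vector of gene ids.
#' @return A list: `matrix` (genes x samples, log2 scale), `groups`
#'   (character vector aligned to columns, "control"/"knockdown").
#' @export
simulate_expression <- function(config, truth, genes) {
  stopifnot(inherits(config, "synthetic_config"), inherits(truth, "truth_set"))
  ids <- if (is.character(genes)) genes else genes$name
  if (!length(ids)) stopf("`genes` must be non-empty")
  if (config$n_expr_replicates < 2L)
    stopf("`n_expr_replicates` must be at least 2 (variance undefined otherwise)")
  set.seed(stage_seed(config$seed, "simulate_expression"))
  n <- length(ids)
  k <- config$n_expr_replicates
  base <- stats::rnorm(n, 8, 1.5)
  shift <- stats::setNames(rep(0, n), ids)
  shift[truth$de_genes$gene_id] <- truth$de_genes$log2fc
  mat <- matrix(0, nrow = n, ncol = 2 * k,
                dimnames = list(ids, c(sprintf("control_%d", seq_len(k)),
                                       sprintf("knockdown_%d", seq_len(k)))))
  mat[, seq_len(k)] <- base
  mat[, k + seq_len(k)] <- base + shift
  if (config$expr_noise_sd > 0)
    mat <- mat + matrix(stats::rnorm(length(mat), 0, config$expr_noise_sd), nrow = n)
  list(matrix = mat,
       groups = rep(c("control", "knockdown"), each = k))
}

#' Generate random background DNA sequences
#'
#' i.i.d. sequences with lengths uniform on a range and base
#' composition set by a GC fraction; the classic background set is six
#' thousand sequences of 2-5 kb.
#'
#' @param n Number of sequences (may be 0).
#' @param length_range Length range in bp (pair, each >= 2).
#' @param gc GC fraction in `[0, 1]` (default 0.5; C and G
#'   equiprobable, likewise A and T).
#' @param seed Integer seed.
#' @return A [Biostrings::DNAStringSet] named `bg_000001`, ...
#' @export
simulate_background_sequences <- function(n, length_range = c(2000, 5000),
                                          gc = 0.5, seed = 1L) {
  n <- check_count(n, "n")
  if (!is_fraction(gc)) stopf("`gc` must be in [0, 1]")
  if (length(length_range) != 2L || any(length_range < 2) ||
      length_range[1] > length_range[2])
    stopf("`length_range` must be an increasing pair of lengths >= 2")
  set.seed(check_count(seed, "seed"))
  if (n == 0L) return(Biostrings::DNAStringSet())
  lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
  prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(lens, function(L) {
    paste(sample(names(prob), L, replace = TRUE, prob = prob), collapse = "")
  }, character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- sprintf("bg_%06d", seq_len(n))
  out
}

#' Simulate grouped binary phenotype counts
#'
#' Binomial event counts per group, e.g. gut-integrity failures among
#' scored flies.
#'
#' @param spec Data frame with columns `group`, `n`, `p` (event
#'   probability per individual).
#' @param seed Integer seed.
#' @return Data frame `group`, `events`, `total`.
#' @export
simulate_phenotype_counts <- function(spec, seed = 1L) {
  stopifnot(is.data.frame(spec), all(c("group", "n", "p") %in% names(spec)))
  if (any(spec$n < 0)) stopf("group sizes must be non-negative")
  if (any(spec$p < 0 | spec$p > 1)) stopf("probabilities must be in [0, 1]")
  set.seed(check_count(seed, "seed"))
  data.frame(group = spec$group,
             events = stats::rbinom(nrow(spec), spec$n, spec$p),
             total = spec$n, stringsAsFactors = FALSE)
}

#' Simulate per-individual survival times
#'
#' Death days drawn from a Weibull distribution per group (rounded up
#' to whole days), optionally right-censored at a fixed day.
#'
#' @param spec Data frame with columns `group`, `n`, `shape`, `scale`
#'   (Weibull parameters, days).
#' @param censor_day Individuals alive past this day are censored there
#'   (`Inf` for none).
#' @param seed Integer seed.
#' @return Data frame `group`, `day`, `censored` (one row per
#'   individual).
#' @export
simulate_survival <- function(spec, censor_day = Inf, seed = 1L) {
  stopifnot(is.data.frame(spec), all(c("group", "n", "shape", "scale") %in% names(spec)))
  if (any(spec$n < 0)) stopf("group sizes must be non-negative")
  set.seed(check_count(seed, "seed"))
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    day <- pmax(1, ceiling(stats::rweibull(spec$n[i], spec$shape[i], spec$scale[i])))
    cens <- day > censor_day
    day[cens] <- censor_day
    data.frame(group = spec$group[i], day = day, censored = cens,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
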