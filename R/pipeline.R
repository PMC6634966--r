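#' Default pipeline configuration
#'
#' Nested sections mirror the per-stage parameter objects; defaults are
#' the established analysis values (window 199 probes, edge threshold
#' 0.3, 70% positive probes, 80% overlap, 2-fold change at p < 0.05,
#' 6000 background sequences of 2-5 kb, ~300 bp probe spacing).
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    simulate = list(
      n_chromosomes = 2L, chromosome_length = 3e6, probe_spacing = 300L,
      probe_length = 50L, n_domains = 50L,
      domain_length_range = c(15000, 30000), domain_effect = 1.0,
      noise_sd = 0.25, intensity_bias_amplitude = 0.5,
      n_biological_replicates = 2L, include_dye_swap = TRUE,
      baseline_log2_mean = 11, baseline_log2_sd = 1,
      n_genes = 2000L, frac_genes_linked = 0.7, frac_de_bound = 0.35,
      frac_activated = 0.7, de_fold_change = 2, n_expr_replicates = 3L,
      expr_noise_sd = 0.25, margin_probes = 100L, min_gap_probes = 100L),
    normalize = list(loess_span = 0.3, pseudocount = 1.0),
    domains = list(window_probes = 199L, edge_threshold = 0.3,
                   min_positive_fraction = 0.70, min_probes_per_domain = 3L,
                   peak_min_run = 2L, peak_threshold_quantile = 0.95),
    overlap = list(min_fraction = 0.80, mode = "either"),
    genes = list(upstream_window = 2000, downstream_window = 0,
                 use_gene_body = TRUE),
    de = list(alpha = 0.05, min_fold_change = 2.0, filter_on = "p"),
    profile = list(align = "center", flank = 30000, bin = 300,
                   weight = "probe"),
    motif = list(pattern = "CANNTG", n_background = 6000,
                 background_length_range = c(2000, 5000),
                 n_permutations = 1000, count_mode = "forward_only",
                 n_foreground = 200, fg_planted_per_kb = 1, gc = 0.5,
                 enabled = TRUE),
    phenotype = list(
      accessibility_5mc = list(percent = c(9, 22), n = c(206, 406)),
      gut_integrity = list(percent = c(0, 22), n = c(94, 94)))
  )
}

merge_config <- function(defaults, user, path = "", errors = new.env()) {
  if (!is.list(user)) {
    assign("msgs", c(get0("msgs", errors, ifnotfound = character(0)),
                     sprintf("%s: expected a section, got a value", path)), errors)
    return(defaults)
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    assign("msgs", c(get0("msgs", errors, ifnotfound = character(0)),
                     sprintf("unknown key: %s%s", ifelse(nzchar(path), paste0(path, "."), ""), unknown)),
           errors)
  for (nm in intersect(names(user), names(defaults))) {
    sub_path <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]], sub_path, errors)
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Validate and normalize a pipeline configuration
#'
#' Fills every default, rejects unknown keys, and checks each section's
#' invariants via its parameter constructor; all problems are reported
#' together with their field paths.
#'
#' @param config A nested list, a YAML file path, or `NULL`/empty for
#'   the full defaults.
#' @return The normalized configuration (class `pipeline_config`).
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (is.null(config)) config <- list()
  errors <- new.env()
  cfg <- merge_config(default_config(), config, errors = errors)
  msgs <- get0("msgs", errors, ifnotfound = character(0))

  check_section <- function(section, fn, args) {
    tryCatch({ do.call(fn, args); NULL },
             error = function(e) sprintf("%s: %s", section, conditionMessage(e)))
  }
  msgs <- c(msgs, unlist(list(
    check_section("simulate", synthetic_config,
                  c(list(seed = cfg$seed), cfg$simulate)),
    check_section("normalize", normalization_params, cfg$normalize),
    check_section("domains", domain_call_params, cfg$domains),
    check_section("overlap", overlap_params, cfg$overlap),
    check_section("genes", gene_assignment_params, cfg$genes),
    check_section("de", de_params, cfg$de),
    check_section("profile", profile_params, cfg$profile),
    check_section("motif", motif_params,
                  cfg$motif[setdiff(names(cfg$motif),
                                    c("n_foreground", "fg_planted_per_kb",
                                      "gc", "enabled"))])
  )))
  if (length(msgs)) stopf("invalid configuration:\n  %s", paste(msgs, collapse = "\n  "))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Recovery statistics of a called domain set against planted truth
#'
#' Matching requires at least 50% reciprocal overlap; matches are
#' one-to-one, greedily by largest overlap. The boundary error is the
#' mean absolute start/end offset of matched pairs, in probes.
#'
#' @param called,truth_domains Interval data frames.
#' @param probe_spacing Probe spacing in bp (converts boundary offsets
#'   to probes).
#' @return A list: `n_called`, `n_true`, `tp`, `precision`, `recall`,
#'   `f1`, `boundary_error_probes`.
#' @export
recovery_stats <- function(called, truth_domains, probe_spacing = 300) {
  m <- match_domain_sets(called, truth_domains,
                         overlap_params(min_fraction = 0.5, mode = "reciprocal"))
  tp <- nrow(m$pairs)
  n_called <- nrow(called)
  n_true <- nrow(truth_domains)
  precision <- if (n_called) tp / n_called else NA_real_
  recall <- if (n_true) tp / n_true else NA_real_
  f1 <- if (tp) 2 * precision * recall / (precision + recall) else 0
  be <- NA_real_
  if (tp) {
    ia <- match(m$pairs$id_a, called$name)
    ib <- match(m$pairs$id_b, truth_domains$name)
    be <- mean((abs(called$start[ia] - truth_domains$start[ib]) +
                  abs(called$end[ia] - truth_domains$end[ib])) / 2) / probe_spacing
  }
  list(n_called = n_called, n_true = n_true, tp = tp,
       precision = precision, recall = recall, f1 = f1,
       boundary_error_probes = be)
}

normalize_arrays <- function(samples, nparams) {
  lapply(samples, function(s) loess_normalize(compute_log_ratio(s, nparams), nparams))
}

#' Run the full analysis pipeline on synthetic data
#'
#' simulate -> normalize -> call -> integrate -> report, deterministic
#' under the configured seed. Writes every stage's files under
#' `outdir` plus a single `report.json`; a stage failure aborts with
#' the stage named, leaving earlier outputs in place.
#'
#' @param config A `pipeline_config` (see [validate_config()]), a
#'   nested list, or a YAML path.
#' @param outdir Output directory (created if needed).
#' @param simulate_only Stop after writing the synthetic inputs.
#' @return The report, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config = NULL, outdir, simulate_only = FALSE) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(force(expr),
             error = function(e) stopf("pipeline stage '%s' failed: %s",
                                       name, conditionMessage(e)))
  }

  # --- simulate ---------------------------------------------------------
  sim <- stage("simulate", {
    scfg <- do.call(synthetic_config, c(list(seed = config$seed), config$simulate))
    grid <- make_probe_grid(scfg)
    truth <- plant_domains(scfg, grid)
    ann <- simulate_gene_annotation(scfg, grid, truth)
    samples <- simulate_damid_arrays(scfg, grid, ann$truth)
    expr <- simulate_expression(scfg, ann$truth, ann$genes)
    for (s in samples)
      write_probe_table(s, file.path(outdir, sprintf("probes_%s.tsv", s$sample_id)))
    td <- ann$truth$domains
    td$score <- td$effect
    write_bed(td, file.path(outdir, "truth_domains.bed"))
    write_bed(ann$genes, file.path(outdir, "genes.bed"))
    write_expression(expr$matrix, expr$groups, file.path(outdir, "expression.csv"))
    list(scfg = scfg, grid = grid, truth = ann$truth, genes = ann$genes,
         samples = samples, expr = expr)
  })
  if (simulate_only) return(invisible(list(simulate = "done", outdir = outdir)))

  # --- normalize --------------------------------------------------------
  nparams <- do.call(normalization_params, config$normalize)
  combined <- stage("normalize", {
    tracks <- normalize_arrays(sim$samples, nparams)
    for (t in tracks)
      write_bedgraph(t, file.path(outdir, sprintf("norm_%s.bedgraph",
                                                  attr(t, "sample_id"))))
    comb <- combine_replicates(tracks)
    write_bedgraph(comb, file.path(outdir, "norm_combined.bedgraph"))
    utils::write.table(comb, file.path(outdir, "norm_combined.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    comb
  })

  # --- call domains -----------------------------------------------------
  dparams <- do.call(domain_call_params, config$domains)
  called <- stage("call_domains", call_domains(combined, dparams))
  peaks <- stage("call_peaks", call_peaks(combined, dparams, called))
  write_bed(called, file.path(outdir, "domains.bed"),
            sidecar = file.path(outdir, "domains_scores.tsv"))
  write_bed(peaks, file.path(outdir, "peaks.bed"))
  jsonlite::write_json(attr(called, "diagnostics"),
                       file.path(outdir, "domain_diagnostics.json"),
                       auto_unbox = TRUE)
  rec <- recovery_stats(called, sim$truth$domains, sim$scfg$probe_spacing)

  # --- differential expression -----------------------------------------
  deparams <- do.call(de_params, config$de)
  deg <- stage("diffexpr",
               moderated_t_test(sim$expr$matrix, sim$expr$groups, deparams))
  degs <- filter_degs(deg, deparams)
  utils::write.table(deg, file.path(outdir, "deg_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # --- integration ------------------------------------------------------
  gparams <- do.call(gene_assignment_params, config$genes)
  integ <- stage("integrate", {
    asn <- assign_domains_to_genes(called, sim$genes, gparams)
    bound_ids <- asn$gene_flags$gene_id[asn$gene_flags$bound]
    tg <- putative_direct_targets(degs$all$gene_id, bound_ids)
    hg <- hypergeometric_overlap(length(degs$all$gene_id), length(bound_ids),
                                 tg$n_overlap, nrow(sim$genes))
    dirs <- direction_fractions(deg, bound_ids)
    utils::write.table(asn$gene_flags, file.path(outdir, "bound_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(n_bound_genes = length(bound_ids), targets = tg, hyper = hg,
         directions = dirs)
  })

  # --- meta-profile -----------------------------------------------------
  pparams <- do.call(profile_params, config$profile)
  prof <- stage("profile", end_profile(combined, called, pparams))
  utils::write.table(prof, file.path(outdir, "profile.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # --- motif ------------------------------------------------------------
  motif_report <- NULL
  if (isTRUE(config$motif$enabled)) {
    motif_report <- stage("motif", {
      mp <- do.call(motif_params,
                    config$motif[setdiff(names(config$motif),
                                         c("n_foreground", "fg_planted_per_kb",
                                           "gc", "enabled"))])
      bg <- simulate_background_sequences(
        mp$n_background, mp$background_length_range, config$motif$gc,
        seed = stage_seed(config$seed, "motif_background"))
      fg <- simulate_background_sequences(
        config$motif$n_foreground, mp$background_length_range, config$motif$gc,
        seed = stage_seed(config$seed, "motif_foreground"))
      fg <- plant_motifs(fg, mp$pattern, config$motif$fg_planted_per_kb,
                         seed = stage_seed(config$seed, "motif_plant"))
      write_fasta(bg, file.path(outdir, "background.fa"))
      write_fasta(fg, file.path(outdir, "foreground.fa"))
      set.seed(stage_seed(config$seed, "motif_permutation"))
      res <- motif_enrichment_seqs(fg, bg, mp)
      list(pattern = res$pattern, enrichment = res$enrichment,
           p_empirical = res$p_empirical,
           fg_density_per_kb = res$fg_density,
           bg_density_per_kb = res$bg_density)
    })
  }

  # --- phenotype statistics --------------------------------------------
  pheno <- stage("phenotype", {
    lapply(config$phenotype, function(tab) {
      cnt <- mapply(function(p, n) counts_from_percent(p, n, "nearest"),
                    tab$percent, tab$n)
      ft <- fisher_exact(rbind(c(cnt[1], tab$n[1] - cnt[1]),
                               c(cnt[2], tab$n[2] - cnt[2])))
      list(counts = as.integer(cnt), n = as.integer(tab$n), p = ft$p,
           odds_ratio = ft$odds_ratio)
    })
  })

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  report <- list(
    schema_version = "1.0",
    provenance = list(package = "damidseg",
                      version = as.character(utils::packageVersion("damidseg")),
                      seed = config$seed,
                      config_md5 = unname(tools::md5sum(tmp))),
    domains = list(n_called = nrow(called), n_planted = nrow(sim$truth$domains),
                   n_peaks = nrow(peaks), recovery = rec,
                   diagnostics = attr(called, "diagnostics")),
    diffexpr = list(n_up = nrow(degs$up), n_down = nrow(degs$down),
                    alpha = deparams$alpha,
                    min_fold_change = deparams$min_fold_change,
                    prior_df = attr(deg, "prior_df"),
                    prior_var = attr(deg, "prior_var")),
    integration = list(
      n_bound_genes = integ$n_bound_genes,
      n_deg = integ$targets$n_deg,
      n_bound_deg = integ$targets$n_overlap,
      bound_deg_fraction = integ$targets$fraction,
      universe = "annotated genes (not the genome)",
      n_universe = integ$hyper$n_universe,
      hypergeometric_p = integ$hyper$p,
      fold_enrichment = integ$hyper$fold_enrichment,
      frac_activated = integ$directions$frac_activated,
      frac_repressed = integ$directions$frac_repressed),
    profile = list(file = "profile.tsv",
                   center_mean = prof$mean[which.min(abs(prof$bin_center))]),
    motif = motif_report,
    phenotype = pheno)
  unlink(tmp)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Plant motif instances into sequences
#'
#' Inserts (overwrites in place) approximately `per_kb` concrete
#' instances of the IUPAC pattern per kilobase at random positions of
#' each sequence; used to construct positive controls for enrichment.
#'
#' @param seqs A [Biostrings::DNAStringSet] or character vector.
#' @param pattern IUPAC pattern; ambiguity codes are concretized
#'   uniformly at each planted site.
#' @param per_kb Planted instances per kb (Poisson-rounded mean).
#' @param seed Integer seed.
#' @return Sequences of the same class and lengths.
#' @export
plant_motifs <- function(seqs, pattern = "CANNTG", per_kb = 1, seed = 1L) {
  was_dss <- inherits(seqs, "DNAStringSet")
  s <- as.character(seqs)
  set.seed(check_count(seed, "seed"))
  pat <- strsplit(toupper(pattern), "")[[1]]
  k <- length(pat)
  for (i in seq_along(s)) {
    L <- nchar(s[[i]])
    n_ins <- stats::rpois(1, per_kb * L / 1000)
    if (n_ins == 0 || L < k) next
    pos <- sample.int(L - k + 1L, min(n_ins, L - k + 1L))
    for (p in pos) {
      inst <- vapply(pat, function(ch) sample(iupac_sets[[ch]], 1L), character(1))
      substr(s[[i]], p, p + k - 1L) <- paste(inst, collapse = "")
    }
  }
  out <- if (was_dss) Biostrings::DNAStringSet(s) else s
  names(out) <- names(seqs)
  out
}
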