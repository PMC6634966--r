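# Shared in-code fixtures.

# A probe_track straight from a normalized-ratio vector.
toy_track <- function(m, chrom = "chr1", spacing = 300, probe_len = 50) {
  n <- length(m)
  start <- (seq_len(n) - 1) * spacing
  df <- data.frame(chrom = chrom, start = start, end = start + probe_len,
                   probe_id = sprintf("%s_p%04d", chrom, seq_len(n)),
                   A = NA_real_, M = m, M_norm = m,
                   stringsAsFactors = FALSE)
  class(df) <- c("probe_track", "data.frame")
  df
}

# A minimal valid two-channel sample from explicit intensities.
toy_sample <- function(fusion, control, dye_swapped = FALSE, spacing = 300) {
  n <- length(fusion)
  start <- (seq_len(n) - 1) * spacing
  array_sample(data.frame(chrom = "chr1", start = start, end = start + 50,
                          probe_id = sprintf("p%03d", seq_len(n)),
                          intensity_fusion = fusion,
                          intensity_control = control,
                          stringsAsFactors = FALSE),
               sample_id = "toy", dye_swapped = dye_swapped)
}

# Full simulate -> normalize -> combine chain for one configuration.
sim_combined <- function(cfg) {
  grid <- make_probe_grid(cfg)
  truth <- plant_domains(cfg, grid)
  samples <- simulate_damid_arrays(cfg, grid, truth)
  tracks <- suppressWarnings(
    lapply(samples, function(s) loess_normalize(compute_log_ratio(s))))
  list(grid = grid, truth = truth, samples = samples,
       combined = combine_replicates(tracks))
}

# An empty truth set (no planted domains or effects).
empty_truth <- function() {
  plant_domains(synthetic_config(n_domains = 0L),
                make_probe_grid(synthetic_config(n_domains = 0L,
                                                 n_chromosomes = 1L,
                                                 chromosome_length = 3000)))
}

# Build a deg_table by hand for filter tests.
manual_deg_table <- function(log2fc, p) {
  q <- stats::p.adjust(p, "BH")
  df <- data.frame(gene_id = sprintf("g%03d", seq_along(p)),
                   log2fc = log2fc, s2 = 1, s2_post = 1,
                   t = log2fc, p = p, q = q,
                   direction = ifelse(log2fc > 0, "up", "down"),
                   passes_filter = NA, stringsAsFactors = FALSE)
  class(df) <- c("deg_table", "data.frame")
  df
}
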