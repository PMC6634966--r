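test_that("probe grid tiles chromosomes at fixed spacing", {
  cfg <- synthetic_config(n_chromosomes = 1, chromosome_length = 3000,
                          probe_spacing = 300, probe_length = 50,
                          n_domains = 0)
  g <- make_probe_grid(cfg)
  expect_equal(nrow(g), 10L)
  expect_equal(g$start, seq(0, 2700, by = 300))
  expect_equal(g$end, g$start + 50)
  expect_true(all(diff(g$start) > 0))
})

test_that("a chromosome shorter than one spacing gets no probes, with a warning", {
  cfg <- synthetic_config(n_chromosomes = 1, chromosome_length = 299,
                          probe_spacing = 300, n_domains = 0)
  expect_warning(g <- make_probe_grid(cfg), "no probes")
  expect_equal(nrow(g), 0L)
})

test_that("the grid is deterministic under a fixed configuration", {
  cfg <- synthetic_config(seed = 11)
  expect_identical(make_probe_grid(cfg), make_probe_grid(cfg))
})

test_that("planted domains are disjoint, snapped to probes, and reproducible", {
  cfg <- synthetic_config(seed = 5)
  grid <- make_probe_grid(cfg)
  truth <- plant_domains(cfg, grid)
  d <- truth$domains
  expect_equal(nrow(d), 50L)
  # brute-force pairwise disjointness
  for (i in seq_len(nrow(d) - 1)) {
    for (j in (i + 1):nrow(d)) {
      if (d$chrom[i] != d$chrom[j]) next
      expect_lte(min(d$end[i], d$end[j]) - max(d$start[i], d$start[j]), 0)
    }
  }
  expect_true(all(d$start %% cfg$probe_spacing == 0))
  expect_true(all((d$end - cfg$probe_length) %% cfg$probe_spacing == 0))
  expect_true(all(d$end - d$start >= cfg$domain_length_range[1] - cfg$probe_spacing))
  expect_identical(plant_domains(cfg, grid), truth)
})

test_that("zero domains gives an empty truth set", {
  cfg <- synthetic_config(n_domains = 0)
  truth <- plant_domains(cfg, make_probe_grid(cfg))
  expect_s3_class(truth, "truth_set")
  expect_equal(nrow(truth$domains), 0L)
})

test_that("noise-free arrays carry the exact planted log2 ratio", {
  cfg <- synthetic_config(seed = 2, noise_sd = 0, intensity_bias_amplitude = 0,
                          n_domains = 5, n_chromosomes = 1)
  grid <- make_probe_grid(cfg)
  truth <- plant_domains(cfg, grid)
  ss <- simulate_damid_arrays(cfg, grid, truth)
  expect_length(ss, 3L)  # 2 biological + 1 dye swap
  raw <- log2(ss[[1]]$probes$intensity_fusion / ss[[1]]$probes$intensity_control)
  inside <- rep(FALSE, nrow(grid))
  for (r in seq_len(nrow(truth$domains)))
    inside <- inside | (grid$start >= truth$domains$start[r] &
                          grid$end <= truth$domains$end[r])
  expect_equal(raw[inside], rep(1, sum(inside)), tolerance = 1e-12)
  expect_equal(raw[!inside], rep(0, sum(!inside)), tolerance = 1e-12)
})

test_that("the dye-swap replicate is the exact channel exchange of the signal", {
  cfg <- synthetic_config(seed = 2, noise_sd = 0, intensity_bias_amplitude = 0,
                          n_domains = 5, n_chromosomes = 1)
  grid <- make_probe_grid(cfg)
  truth <- plant_domains(cfg, grid)
  ss <- simulate_damid_arrays(cfg, grid, truth)
  swap <- ss[[length(ss)]]
  expect_true(swap$dye_swapped)
  raw_swap <- log2(swap$probes$intensity_fusion / swap$probes$intensity_control)
  raw_first <- log2(ss[[1]]$probes$intensity_fusion / ss[[1]]$probes$intensity_control)
  # noise-free: per-probe expected ratios are deterministic, so the raw
  # swapped ratio is exactly the negation of the un-swapped one
  expect_equal(raw_swap, -raw_first, tolerance = 1e-12)
})

test_that("null array ratios average to zero within the CLT bound", {
  cfg <- synthetic_config(seed = 3, noise_sd = 0.2, intensity_bias_amplitude = 0,
                          n_domains = 0, n_chromosomes = 1,
                          chromosome_length = 3e6)
  grid <- make_probe_grid(cfg)
  truth <- plant_domains(cfg, grid)
  s <- simulate_damid_arrays(cfg, grid, truth)[[1]]
  raw <- log2(s$probes$intensity_fusion / s$probes$intensity_control)
  expect_lt(abs(mean(raw)), 3 * 0.2 / sqrt(nrow(grid)))
})

test_that("negative noise is rejected", {
  expect_error(synthetic_config(noise_sd = -0.1), "noise_sd")
})

test_that("noise-free expression shifts DE genes by exactly log2 fold change", {
  cfg <- synthetic_config(seed = 4, expr_noise_sd = 0, de_fold_change = 2)
  grid <- make_probe_grid(cfg)
  ann <- simulate_gene_annotation(cfg, grid, plant_domains(cfg, grid))
  ex <- simulate_expression(cfg, ann$truth, ann$genes)
  k <- cfg$n_expr_replicates
  diff <- rowMeans(ex$matrix[, ex$groups == "knockdown"]) -
    rowMeans(ex$matrix[, ex$groups == "control"])
  planted <- setNames(rep(0, nrow(ex$matrix)), rownames(ex$matrix))
  planted[ann$truth$de_genes$gene_id] <- ann$truth$de_genes$log2fc
  expect_equal(unname(diff), unname(planted), tolerance = 1e-12)
  expect_true(all(abs(ann$truth$de_genes$log2fc) == 1))
})

test_that("expression simulation is reproducible and rejects single replicates", {
  cfg <- synthetic_config(seed = 6)
  grid <- make_probe_grid(cfg)
  ann <- simulate_gene_annotation(cfg, grid, plant_domains(cfg, grid))
  e1 <- simulate_expression(cfg, ann$truth, ann$genes)
  e2 <- simulate_expression(cfg, ann$truth, ann$genes)
  expect_identical(e1, e2)
  cfg1 <- synthetic_config(seed = 6, n_expr_replicates = 2)
  expect_error(synthetic_config(n_expr_replicates = 1), "n_expr_replicates")
  expect_silent(simulate_expression(cfg1, ann$truth, ann$genes))
  expect_error(simulate_expression(cfg, ann$truth, character(0)), "non-empty")
})

test_that("background sequences honour count, length range, and composition", {
  seqs <- simulate_background_sequences(200, c(2000, 5000), seed = 7)
  expect_length(seqs, 200L)
  w <- Biostrings::width(seqs)
  expect_true(all(w >= 2000 & w <= 5000))
  at_only <- simulate_background_sequences(5, c(100, 200), gc = 0, seed = 1)
  expect_true(all(strsplit(paste(as.character(at_only), collapse = ""), "")[[1]]
                  %in% c("A", "T")))
  empty <- simulate_background_sequences(0, c(100, 200), seed = 1)
  expect_length(empty, 0L)
  expect_error(simulate_background_sequences(5, c(100, 200), gc = 1.2), "gc")
})

test_that("generated files round-trip through the package readers bit-exactly", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(seed = 8, n_domains = 5, n_chromosomes = 1,
                          n_genes = 50)
  grid <- make_probe_grid(cfg)
  truth <- plant_domains(cfg, grid)
  s <- simulate_damid_arrays(cfg, grid, truth)[[1]]
  p <- file.path(dir, "probes.tsv")
  write_probe_table(s, p)
  s2 <- read_probe_table(p, sample_id = s$sample_id)
  expect_equal(s2$probes, s$probes, tolerance = 1e-12)
  fa <- file.path(dir, "bg.fa")
  seqs <- simulate_background_sequences(10, c(100, 300), seed = 2)
  write_fasta(seqs, fa)
  expect_identical(as.character(read_fasta(fa)), as.character(seqs))
  ann <- simulate_gene_annotation(cfg, grid, truth)
  ex <- simulate_expression(cfg, ann$truth, ann$genes)
  ep <- file.path(dir, "expr.csv")
  write_expression(ex$matrix, ex$groups, ep)
  back <- read_expression(ep)
  expect_equal(back$matrix, ex$matrix, tolerance = 1e-12)
  expect_identical(back$groups, ex$groups)
})

test_that("phenotype count simulation respects degenerate probabilities", {
  spec <- data.frame(group = c("a", "b"), n = c(50, 50), p = c(0, 1))
  cnt <- simulate_phenotype_counts(spec, seed = 1)
  expect_equal(cnt$events, c(0L, 50L))
  big <- simulate_phenotype_counts(
    data.frame(group = "g", n = 10000, p = 0.5), seed = 2)
  expect_lt(abs(big$events - 5000), 3 * sqrt(10000 * 0.25))
  expect_error(simulate_phenotype_counts(
    data.frame(group = "g", n = -1, p = 0.5), seed = 1), "non-negative")
  expect_error(simulate_phenotype_counts(
    data.frame(group = "g", n = 5, p = 1.5), seed = 1), "probabilities")
})

test_that("survival simulation produces positive, reproducible death days", {
  spec <- data.frame(group = c("ctl", "kd"), n = c(30, 30),
                     shape = c(5, 5), scale = c(40, 20))
  s1 <- simulate_survival(spec, censor_day = 45, seed = 3)
  expect_identical(s1, simulate_survival(spec, censor_day = 45, seed = 3))
  expect_true(all(s1$day > 0))
  expect_true(all(s1$day[s1$censored] == 45))
})
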