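test_that("probe tables are validated on read", {
  dir <- withr::local_tempdir()
  # handcrafted 10-probe fixture
  df <- data.frame(chrom = "chr1", start = seq(0, 2700, 300),
                   end = seq(0, 2700, 300) + 50,
                   probe_id = sprintf("p%02d", 1:10),
                   intensity_fusion = 100 + 1:10,
                   intensity_control = 200 - 1:10)
  p <- file.path(dir, "probes.tsv")
  write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  s <- read_probe_table(p, sample_id = "fix")
  expect_equal(nrow(s$probes), 10L)
  expect_equal(s$probes$start, df$start)
  expect_equal(s$probes$end, df$end)

  bad <- df[c(2, 1, 3:10), ]
  write.table(bad, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_probe_table(p), "out of order")

  df$intensity_fusion[3] <- -1
  write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_probe_table(p), "negative intensity")
})

test_that("M and A follow the two-channel definitions", {
  s <- toy_sample(fusion = c(4, 8, 2), control = c(1, 8, 2))
  tr <- compute_log_ratio(s, normalization_params(pseudocount = 0))
  expect_equal(tr$M[1], 2)
  expect_equal(tr$A[1], 1)
  expect_equal(tr$M[2:3], c(0, 0))  # fusion == control -> M = 0
})

test_that("dye-swap correction restores the common orientation", {
  f <- c(40, 10, 25, 80); c0 <- c(10, 40, 25, 20)
  straight <- compute_log_ratio(toy_sample(f, c0),
                                normalization_params(pseudocount = 0))
  swapped <- compute_log_ratio(toy_sample(c0, f, dye_swapped = TRUE),
                               normalization_params(pseudocount = 0))
  expect_equal(swapped$M, straight$M, tolerance = 1e-12)
})

test_that("a probe with both intensities zero is flagged missing", {
  s <- toy_sample(fusion = c(0, 4, 5), control = c(0, 2, 5))
  tr <- compute_log_ratio(s)
  expect_true(is.na(tr$M[1]))
  expect_false(anyNA(tr$M[-1]))
})

test_that("a perfectly linear M-A trend is removed at interior probes", {
  set.seed(1)
  A <- sort(runif(300, 6, 14))
  M <- 0.5 * A
  s <- toy_sample(fusion = 2^(A + M / 2), control = 2^(A - M / 2))
  tr <- loess_normalize(compute_log_ratio(s, normalization_params(pseudocount = 0)),
                        normalization_params(pseudocount = 0))
  interior <- A > quantile(A, 0.05) & A < quantile(A, 0.95)
  expect_lt(max(abs(tr$M_norm[interior])), 1e-6)
})

test_that("a constant M is normalized to exactly zero", {
  set.seed(2)
  A <- runif(100, 6, 14)
  s <- toy_sample(fusion = 2^(A + 0.35), control = 2^(A - 0.35))
  tr <- loess_normalize(compute_log_ratio(s, normalization_params(pseudocount = 0)),
                        normalization_params(pseudocount = 0))
  expect_lt(max(abs(tr$M_norm)), 1e-8)
})

test_that("identical A values trigger the median-subtraction fallback", {
  m <- c(rep(0, 30), rep(1, 5), rep(0, 30))
  s <- toy_sample(fusion = 1000 * 2^(m / 2), control = 1000 * 2^(-m / 2))
  expect_warning(
    tr <- loess_normalize(compute_log_ratio(s, normalization_params(pseudocount = 0))),
    "median")
  expect_equal(tr$M_norm, m - median(m), tolerance = 1e-9)
})

test_that("normalization needs a minimum number of informative probes", {
  s <- toy_sample(fusion = rep(2, 5), control = rep(1, 5))
  expect_error(loess_normalize(compute_log_ratio(s)), "at least 10")
})

test_that("replicate combination averages with the stated SE conventions", {
  t1 <- toy_track(c(1, 0.5))
  t2 <- toy_track(c(-1, 0.5))
  comb <- combine_replicates(list(t1, t2))
  expect_equal(comb$M_norm, c(0, 0.5))
  expect_equal(comb$se, c(1, 0))
  single <- combine_replicates(list(t1))
  expect_equal(single$M_norm, t1$M_norm)
  expect_equal(single$se, c(0, 0))
  triple <- combine_replicates(list(t1, t1, t1))
  expect_equal(triple$M_norm, t1$M_norm)
  expect_equal(triple$se, c(0, 0))
})

test_that("probes missing in one replicate are averaged over the rest", {
  t1 <- toy_track(c(1, 2, 3))
  t2 <- toy_track(c(1, NA, 5))
  comb <- combine_replicates(list(t1, t2))
  expect_equal(comb$M_norm, c(1, 2, 4))
  expect_equal(comb$n_rep, c(2L, 1L, 2L))
  expect_equal(comb$se[2], 0)
})

test_that("mismatched replicate grids are rejected naming the probe", {
  t1 <- toy_track(c(1, 2, 3))
  t2 <- toy_track(c(1, 2, 3))
  t2$probe_id[2] <- "other"
  expect_error(combine_replicates(list(t1, t2)), "different probe grid")
})

test_that("combining a replicate with its exact dye swap preserves the signal", {
  cfg <- synthetic_config(seed = 2, noise_sd = 0, intensity_bias_amplitude = 0,
                          baseline_log2_sd = 0, n_domains = 5, n_chromosomes = 1)
  grid <- make_probe_grid(cfg)
  truth <- plant_domains(cfg, grid)
  ss <- simulate_damid_arrays(cfg, grid, truth)
  tracks <- suppressWarnings(lapply(ss[c(1, 3)], function(s)
    loess_normalize(compute_log_ratio(s))))
  comb <- combine_replicates(tracks)
  # signal survives (mean ~= each replicate), it does not cancel to ~0
  expect_equal(comb$M_norm, tracks[[1]]$M_norm, tolerance = 1e-6)
  expect_gt(max(comb$M_norm), 0.9)
})

test_that("no stage reorders, adds, or drops probes", {
  cfg <- synthetic_config(seed = 9, n_domains = 5, n_chromosomes = 1)
  res <- sim_combined(cfg)
  expect_identical(res$combined$probe_id, res$grid$probe_id)
  expect_equal(nrow(res$combined), nrow(res$grid))
})

test_that("re-normalizing a normalized track changes it only marginally", {
  cfg <- synthetic_config(seed = 42, n_chromosomes = 1,
                          chromosome_length = 6e6)
  grid <- make_probe_grid(cfg)
  truth <- plant_domains(cfg, grid)
  s <- simulate_damid_arrays(cfg, grid, truth)[[1]]
  t1 <- loess_normalize(compute_log_ratio(s))
  t2 <- t1
  t2$M <- t1$M_norm
  t2 <- loess_normalize(t2)
  delta <- abs(t2$M_norm - t1$M_norm)
  expect_lt(max(delta, na.rm = TRUE), 0.05)
  expect_lt(quantile(delta, 0.99, na.rm = TRUE), 0.01)
})
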