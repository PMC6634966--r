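params3 <- function(...) domain_call_params(window_probes = 3,
                                            min_probes_per_domain = 2, ...)

test_that("edge scores follow the flanking half-window difference", {
  tr <- edge_score(toy_track(c(0, 0, 0, 1, 1, 1)), params3())
  expect_equal(tr$edge, c(NA, 0, 1, 1, 0, NA))
})

test_that("a constant track has all defined edge scores zero", {
  tr <- edge_score(toy_track(rep(0.7, 20)), params3())
  expect_lt(max(abs(tr$edge[2:19])), 1e-12)
  expect_true(is.na(tr$edge[1]) && is.na(tr$edge[20]))
})

test_that("a short chromosome gets all-undefined scores with a warning", {
  expect_warning(tr <- edge_score(toy_track(c(0, 1)), params3()), "undefined")
  expect_true(all(is.na(tr$edge)))
})

test_that("a clean step's maximum edge equals the step height", {
  # brute-force oracle over a 500-probe synthetic step
  m <- c(rep(0, 250), rep(0.7, 250))
  p <- domain_call_params(window_probes = 21)
  tr <- edge_score(toy_track(m), p)
  h <- 10
  oracle <- rep(NA_real_, 500)
  for (i in (h + 1):(500 - h))
    oracle[i] <- mean(m[(i + 1):(i + h)]) - mean(m[(i - h):(i - 1)])
  expect_equal(tr$edge, oracle)
  expect_equal(max(abs(tr$edge), na.rm = TRUE), 0.7)
})

test_that("transition calling thresholds and localizes the step", {
  m <- c(rep(0, 250), rep(1, 250))
  p <- domain_call_params(window_probes = 21)
  tr <- call_transitions(edge_score(toy_track(m), p), p)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$sign, "up")
  expect_equal(tr$row, 250L)  # probe adjacent to the first enriched probe

  flat <- call_transitions(edge_score(toy_track(rep(0.2, 100)), p), p)
  expect_equal(nrow(flat), 0L)

  small <- c(rep(0, 250), rep(0.2, 250))  # sub-threshold step
  expect_equal(nrow(call_transitions(edge_score(toy_track(small), p), p)), 0L)
})

test_that("the worked step example yields one all-positive domain", {
  p <- params3()
  tr <- edge_score(toy_track(c(0, 0, 0, 1, 1, 1)), p)
  trans <- call_transitions(tr, p)
  dom <- assemble_domains(trans, tr, p)
  expect_equal(nrow(dom), 1L)
  # probes 4-6: starts 900..1500, probe length 50
  expect_equal(dom$start, 900)
  expect_equal(dom$end, 1550)
  expect_equal(dom$score, 1)
  expect_equal(attr(dom, "diagnostics")$n_open_ended, 1L)
})

test_that("the positive-probe rule rejects candidates at its boundary", {
  run <- function(vals) {
    m <- c(rep(0, 30), vals, rep(0, 30))
    tr <- toy_track(m)
    tr$edge <- NA_real_
    trans <- data.frame(chrom = "chr1", row = c(30L, 41L),
                        pos = tr$start[c(30, 41)], edge = c(1, -1),
                        sign = c("up", "down"), stringsAsFactors = FALSE)
    assemble_domains(trans, tr, domain_call_params(min_probes_per_domain = 2))
  }
  seven_of_ten <- run(c(1, 1, 1, 1, 1, 1, 1, -0.1, -0.1, -0.1))
  expect_equal(nrow(seven_of_ten), 1L)  # 70% positive passes
  six_of_ten <- run(c(1, 1, 1, 1, 1, 1, -0.1, -0.1, -0.1, -0.1))
  expect_equal(nrow(six_of_ten), 0L)    # 60% positive fails
  expect_equal(attr(six_of_ten, "diagnostics")$n_rejected_positive, 1L)
})

test_that("candidates below the probe-count floor are dropped", {
  m <- c(rep(0, 30), rep(1, 2), rep(0, 30))
  tr <- toy_track(m)
  trans <- data.frame(chrom = "chr1", row = c(30L, 33L),
                      pos = tr$start[c(30, 33)], edge = c(1, -1),
                      sign = c("up", "down"), stringsAsFactors = FALSE)
  dom <- assemble_domains(trans, tr, domain_call_params(min_probes_per_domain = 3))
  expect_equal(nrow(dom), 0L)
  expect_equal(attr(dom, "diagnostics")$n_rejected_size, 1L)
})

test_that("noise-free planted domains are recovered exactly, boundaries included", {
  cfg <- synthetic_config(seed = 3, noise_sd = 0, intensity_bias_amplitude = 0,
                          baseline_log2_sd = 0, n_domains = 10,
                          n_chromosomes = 1)
  res <- sim_combined(cfg)
  called <- call_domains(res$combined)
  expect_equal(nrow(called), 10L)
  expect_equal(called$start, res$truth$domains$start)
  expect_equal(called$end, res$truth$domains$end)
})

test_that("called domains never overlap one another", {
  cfg <- synthetic_config(seed = 7)
  called <- call_domains(sim_combined(cfg)$combined)
  for (chr in unique(called$chrom)) {
    d <- called[called$chrom == chr, ]
    if (nrow(d) > 1) expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }
})

test_that("mirroring the track flips transitions and yields zero domains", {
  cfg <- synthetic_config(seed = 12, n_chromosomes = 1,
                          chromosome_length = 6e6)
  comb <- sim_combined(cfg)$combined
  p <- domain_call_params()
  tr_pos <- call_transitions(edge_score(comb, p), p)
  neg <- comb
  neg$M_norm <- -neg$M_norm
  tr_neg <- call_transitions(edge_score(neg, p), p)
  expect_equal(sum(tr_neg$sign == "down"), sum(tr_pos$sign == "up"))
  expect_equal(sum(tr_neg$sign == "up"), sum(tr_pos$sign == "down"))
  expect_equal(tr_neg$row[tr_neg$sign == "down"], tr_pos$row[tr_pos$sign == "up"])
  expect_equal(nrow(call_domains(neg, p)), 0L)
})

test_that("caller output is invariant under a constant offset plus re-normalization", {
  # constant-A track: normalization falls back to median subtraction,
  # which removes any added offset exactly
  m <- c(rep(0, 150), rep(1, 60), rep(0, 150))
  mk <- function(off) {
    s <- toy_sample(fusion = 1000 * 2^((m + off) / 2),
                    control = 1000 * 2^(-(m + off) / 2))
    suppressWarnings(loess_normalize(
      compute_log_ratio(s, normalization_params(pseudocount = 0)),
      normalization_params(pseudocount = 0)))
  }
  p <- domain_call_params(window_probes = 21)
  d0 <- call_domains(mk(0), p)
  d5 <- call_domains(mk(5), p)
  expect_equal(d5$start, d0$start)
  expect_equal(d5$end, d0$end)
  expect_equal(d5$score, d0$score, tolerance = 1e-9)
})

test_that("single peaks are maximal supra-quantile runs outside domains", {
  m <- rep(0, 1000)
  m[501:503] <- 2
  p <- domain_call_params(peak_min_run = 2)
  peaks <- call_peaks(toy_track(m), p)
  expect_equal(nrow(peaks), 1L)
  expect_equal(peaks$start, (501 - 1) * 300)
  expect_equal(peaks$end, (503 - 1) * 300 + 50)

  # constant track: quantile equals every value, strict inequality -> none
  expect_equal(nrow(call_peaks(toy_track(rep(1, 100)), p)), 0L)

  # single-probe spike below the run floor
  m1 <- rep(0, 1000); m1[500] <- 2
  expect_equal(nrow(call_peaks(toy_track(m1), p)), 0L)

  # runs inside called domains are excluded
  dom <- data.frame(chrom = "chr1", start = 149700, end = 151000,
                    name = "d1", score = 2, kind = "domain")
  expect_equal(nrow(call_peaks(toy_track(m), p, domains = dom)), 0L)
})

test_that("parameter invariants are enforced", {
  expect_error(domain_call_params(window_probes = 200), "odd")
  expect_error(domain_call_params(edge_threshold = 0), "edge_threshold")
  expect_error(domain_call_params(min_positive_fraction = 1.5),
               "min_positive_fraction")
})
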