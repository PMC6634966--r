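#' Two-channel array sample
#'
#' One hybridization of a Dam-fusion sample against the unfused
#' methylase control, as an ordered per-chromosome probe table.
#'
#' @param probes Data frame with columns `chrom`, `start`, `end`,
#'   `probe_id`, `intensity_fusion`, `intensity_control`; probes must be
#'   sorted and non-overlapping within each chromosome and intensities
#'   finite and non-negative.
#' @param sample_id Sample label.
#' @param dye_swapped Was this hybridization dye-swapped (channels
#'   exchanged)?
#' @return An object of class `array_sample`.
#' @export
array_sample <- function(probes, sample_id, dye_swapped = FALSE) {
  need <- c("chrom", "start", "end", "probe_id",
            "intensity_fusion", "intensity_control")
  if (!is.data.frame(probes) || !all(need %in% names(probes)))
    stopf("`probes` must have columns %s", paste(need, collapse = ", "))
  if (!is_flag(dye_swapped)) stopf("`dye_swapped` must be TRUE or FALSE")
  if (any(!is.finite(probes$intensity_fusion)) ||
      any(!is.finite(probes$intensity_control)))
    stopf("intensities must be finite")
  if (any(probes$intensity_fusion < 0) || any(probes$intensity_control < 0))
    stopf("negative intensity in sample '%s'", sample_id)
  msg <- first_interval_violation(probes)
  if (!is.null(msg)) stopf("sample '%s': %s", sample_id, msg)
  structure(list(sample_id = as.character(sample_id),
                 dye_swapped = dye_swapped,
                 probes = probes[, need]),
            class = "array_sample")
}

#' @export
print.array_sample <- function(x, ...) {
  cat(sprintf("<array_sample> %s: %d probes on %d chromosome(s)%s\n",
              x$sample_id, nrow(x$probes), length(unique(x$probes$chrom)),
              if (x$dye_swapped) " [dye swap]" else ""))
  invisible(x)
}

#' Normalization parameters
#'
#' @param loess_span LOESS span (fraction of probes in each local fit;
#'   default 0.3, local linear with tricube weights and robustifying
#'   iterations).
#' @param pseudocount Intensity pseudocount guarding zero intensities
#'   (default 1.0).
#' @return A list of class `normalization_params`.
#' @export
normalization_params <- function(loess_span = 0.3, pseudocount = 1.0) {
  if (!is_number(loess_span) || loess_span <= 0 || loess_span > 1)
    stopf("`loess_span` must be in (0, 1]")
  structure(list(loess_span = loess_span,
                 pseudocount = check_number(pseudocount, "pseudocount", 0)),
            class = "normalization_params")
}

#' Read a probe table
#'
#' Reads the TSV written by [write_probe_table()] (columns `chrom`,
#' `start`, `end`, `probe_id`, `intensity_fusion`, `intensity_control`),
#' validating sort order, non-overlap and non-negative intensities.
#'
#' @param path File path.
#' @param sample_id Sample label (default: file name without extension).
#' @param dye_swapped Dye-swap flag for this sample.
#' @return An [array_sample()].
#' @export
read_probe_table <- function(path, sample_id = NULL, dye_swapped = FALSE) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "probe_id",
            "intensity_fusion", "intensity_control")
  if (!identical(names(df), need))
    stopf("unexpected header in %s: got (%s)", path, paste(names(df), collapse = ", "))
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  array_sample(df, sample_id, dye_swapped)
}

#' Write a probe table
#'
#' @param sample An [array_sample()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_probe_table <- function(sample, path) {
  stopifnot(inherits(sample, "array_sample"))
  utils::write.table(sample$probes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Compute per-probe log ratios (M) and mean log intensities (A)
#'
#' M = log2(fusion/control) and A = 0.5 log2(fusion * control), with a
#' pseudocount on both channels. For a dye-swapped sample M is negated
#' so all replicates share the same orientation. A probe with both
#' intensities zero has no usable ratio: M is flagged missing (NA) and
#' excluded downstream.
#'
#' @param sample An [array_sample()].
#' @param params A [normalization_params()].
#' @return A `probe_track` data frame: `chrom`, `start`, `end`,
#'   `probe_id`, `A`, `M`, `M_norm` (NA until normalized).
#' @export
compute_log_ratio <- function(sample, params = normalization_params()) {
  stopifnot(inherits(sample, "array_sample"),
            inherits(params, "normalization_params"))
  p <- sample$probes
  eps <- params$pseudocount
  f <- p$intensity_fusion + eps
  ctl <- p$intensity_control + eps
  M <- log2(f) - log2(ctl)
  A <- 0.5 * (log2(f) + log2(ctl))
  both_zero <- p$intensity_fusion == 0 & p$intensity_control == 0
  M[both_zero] <- NA_real_
  A[both_zero] <- NA_real_
  if (sample$dye_swapped) M <- -M
  track <- data.frame(chrom = p$chrom, start = p$start, end = p$end,
                      probe_id = p$probe_id, A = A, M = M,
                      M_norm = NA_real_, stringsAsFactors = FALSE)
  class(track) <- c("probe_track", "data.frame")
  attr(track, "sample_id") <- sample$sample_id
  track
}

#' LOESS-normalize a probe track
#'
#' Removes intensity-dependent bias by subtracting a locally weighted
#' regression of M on A (robust local linear fit, tricube weights,
#' span `loess_span`): `M_norm = M - fhat(A)`. Enriched probes are
#' one-sided outliers that a single robust fit downweights but does not
#' exclude, so the trend is re-estimated on the probes lying within 2.5
#' MADs of the first fit and interpolated back to all probes
#' (invariant-probe refinement). Probe order is unchanged. If all A
#' values are identical the fit is degenerate and the global median of
#' M is subtracted instead (with a warning).
#'
#' @param track A `probe_track` from [compute_log_ratio()].
#' @param params A [normalization_params()].
#' @return The track with `M_norm` filled in.
#' @export
loess_normalize <- function(track, params = normalization_params()) {
  stopifnot(inherits(track, "probe_track"))
  ok <- !is.na(track$M) & !is.na(track$A)
  if (sum(ok) < 10L)
    stopf("need at least 10 probes with defined ratios to normalize (have %d)", sum(ok))
  A <- track$A[ok]
  M <- track$M[ok]
  # An A axis with (essentially) no spread cannot support a local fit of
  # M on A; treat it as constant and subtract the global median instead.
  if (diff(range(A)) < 0.01) {
    warnf("A values (essentially) identical; falling back to median subtraction")
    fitted <- rep(stats::median(M), length(M))
  } else {
    fitted <- limma::loessFit(y = M, x = A, span = params$loess_span)$fitted
    res <- M - fitted
    s <- stats::mad(res)
    if (is.finite(s) && s > 1e-8) {
      keep <- abs(res - stats::median(res)) <= 2.5 * s
      if (sum(keep) >= 10L && sum(keep) < length(M)) {
        fit2 <- limma::loessFit(y = M[keep], x = A[keep],
                                span = params$loess_span)
        o <- order(A[keep])
        fitted <- stats::approx(A[keep][o], fit2$fitted[o], xout = A,
                                rule = 2, ties = mean)$y
      }
    }
  }
  track$M_norm <- NA_real_
  track$M_norm[ok] <- M - fitted
  track
}

#' Combine replicate tracks
#'
#' Per-probe mean of normalized ratios across replicates, with the
#' standard error of the mean. Probes missing in some replicates are
#' averaged over the available ones; a single available value has
#' SE = 0 by convention.
#'
#' @param tracks List of normalized `probe_track`s on identical grids.
#' @return A `probe_track` with `M_norm` = replicate mean, plus `se`
#'   and `n_rep` columns.
#' @export
combine_replicates <- function(tracks) {
  stopifnot(is.list(tracks), length(tracks) >= 1L,
            all(vapply(tracks, inherits, logical(1), "probe_track")))
  ref <- tracks[[1L]]
  for (t_i in seq_along(tracks)[-1L]) {
    tr <- tracks[[t_i]]
    same <- nrow(tr) == nrow(ref) &&
      all(tr$chrom == ref$chrom & tr$start == ref$start &
            tr$end == ref$end & tr$probe_id == ref$probe_id)
    if (!same) {
      bad <- which(!(tracks[[t_i]]$probe_id[seq_len(min(nrow(tr), nrow(ref)))] ==
                       ref$probe_id[seq_len(min(nrow(tr), nrow(ref)))]))
      first <- if (length(bad)) ref$probe_id[bad[1L]] else "(length mismatch)"
      stopf("replicate %d is on a different probe grid (first mismatch at %s)",
            t_i, first)
    }
  }
  vals <- vapply(tracks, function(t) t$M_norm, numeric(nrow(ref)))
  vals <- matrix(vals, nrow = nrow(ref))
  n_avail <- rowSums(!is.na(vals))
  mean_m <- rowMeans(vals, na.rm = TRUE)
  mean_m[n_avail == 0L] <- NA_real_
  sds <- apply(vals, 1L, stats::sd, na.rm = TRUE)
  se <- ifelse(n_avail >= 2L, sds / sqrt(n_avail), ifelse(n_avail == 1L, 0, NA_real_))
  out <- ref
  out$M <- NA_real_
  out$A <- NA_real_
  out$M_norm <- mean_m
  out$se <- se
  out$n_rep <- n_avail
  attr(out, "sample_id") <- "combined"
  out
}
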