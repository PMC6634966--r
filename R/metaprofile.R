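#' Meta-profile parameters
#'
#' @param align Anchor: `"center"` (default), `"start"` or `"end"`;
#'   start/end are strand-aware for gene regions (the biological start
#'   of a minus-strand gene is its higher coordinate), and distances
#'   are strand-flipped so "downstream" is always positive.
#' @param flank Half-width of the profile in bp (default 5000), a
#'   multiple of `bin`.
#' @param bin Bin width in bp (default 300).
#' @param weight `"probe"` (default): mean and SE across all
#'   probe-region incidences per bin; `"region"`: average per-region
#'   bin means, SE across regions.
#' @return A list of class `profile_params`.
#' @export
profile_params <- function(align = c("center", "start", "end"),
                           flank = 5000, bin = 300,
                           weight = c("probe", "region")) {
  align <- match.arg(align)
  weight <- match.arg(weight)
  flank <- check_number(flank, "flank", 1)
  bin <- check_number(bin, "bin", 1)
  if (flank %% bin != 0) stopf("`flank` must be a multiple of `bin`")
  structure(list(align = align, flank = flank, bin = bin, weight = weight),
            class = "profile_params")
}

region_anchor <- function(regions, align) {
  strand <- if ("strand" %in% names(regions)) regions$strand else
    rep("+", nrow(regions))
  minus <- strand == "-"
  switch(align,
         center = (regions$start + regions$end) / 2,
         start = ifelse(minus, regions$end, regions$start),
         end = ifelse(minus, regions$start, regions$end))
}

#' End analysis: average signal around aligned regions
#'
#' Aligns all regions at the chosen anchor and averages the normalized
#' probe signal as a function of distance. Each probe contributes to
#' the bin of its center's distance from the anchor (strand-flipped for
#' minus-strand regions when `align` is "start" or "end"); a probe near
#' several regions contributes once per region.
#'
#' @param track A normalized `probe_track`.
#' @param regions Interval data frame (optionally stranded).
#' @param params A [profile_params()].
#' @return Data frame `bin_center`, `mean`, `se`, `n` (contributing
#'   incidences per bin).
#' @export
end_profile <- function(track, regions, params = profile_params()) {
  stopifnot(inherits(track, "probe_track"))
  if (!nrow(regions)) stopf("`regions` must be non-empty")
  anchors <- region_anchor(regions, params$align)
  strand <- if ("strand" %in% names(regions)) regions$strand else
    rep("+", nrow(regions))
  nbin <- as.integer(2 * params$flank / params$bin)
  centers <- -params$flank + (seq_len(nbin) - 0.5) * params$bin
  vals <- vector("list", nrow(regions))
  bins <- vector("list", nrow(regions))
  probe_center <- (track$start + track$end) / 2
  ord <- order(track$chrom, probe_center)
  for (ri in seq_len(nrow(regions))) {
    sel <- which(track$chrom == regions$chrom[ri] & !is.na(track$M_norm))
    if (!length(sel)) next
    d <- probe_center[sel] - anchors[ri]
    if (params$align != "center" && strand[ri] == "-") d <- -d
    inwin <- d >= -params$flank & d < params$flank
    if (!any(inwin)) next
    vals[[ri]] <- track$M_norm[sel][inwin]
    bins[[ri]] <- as.integer(floor((d[inwin] + params$flank) / params$bin)) + 1L
  }
  used <- !vapply(vals, is.null, logical(1))
  if (!any(used)) {
    warnf("no probes within the flank of any region: empty profile")
    return(data.frame(bin_center = centers, mean = NA_real_, se = NA_real_,
                      n = 0L))
  }
  if (params$weight == "probe") {
    v <- unlist(vals[used]); b <- unlist(bins[used])
    n <- tabulate(b, nbins = nbin)
    s <- vapply(seq_len(nbin), function(k) sum(v[b == k]), numeric(1))
    mu <- ifelse(n > 0, s / n, NA_real_)
    sdv <- vapply(seq_len(nbin), function(k)
      if (n[k] >= 2) stats::sd(v[b == k]) else 0, numeric(1))
    se <- ifelse(n > 0, sdv / sqrt(pmax(n, 1L)), NA_real_)
    data.frame(bin_center = centers, mean = mu, se = se, n = n)
  } else {
    per_region <- lapply(which(used), function(ri) {
      m <- rep(NA_real_, nbin)
      agg <- tapply(vals[[ri]], bins[[ri]], mean)
      m[as.integer(names(agg))] <- agg
      m
    })
    mat <- do.call(rbind, per_region)
    n <- colSums(!is.na(mat))
    mu <- ifelse(n > 0, colMeans(mat, na.rm = TRUE), NA_real_)
    sdv <- apply(mat, 2L, stats::sd, na.rm = TRUE)
    se <- ifelse(n >= 2, sdv / sqrt(n), ifelse(n == 1, 0, NA_real_))
    data.frame(bin_center = centers, mean = mu, se = se, n = n)
  }
}

#' Per-state distribution of region-mean signal
#'
#' For each labeled region the mean normalized signal of enclosed
#' probes (probe centers within the region); regions without probes are
#' excluded and counted. Region means are then grouped by state label
#' with summary quantiles, the numbers behind a per-state boxplot.
#'
#' @param track A normalized `probe_track`.
#' @param states Labeled interval data frame (`chrom`, `start`, `end`,
#'   `state`), non-overlapping.
#' @return A list: `regions` (per-region means), `summary` (per-state
#'   n, mean, quartiles), `n_empty`.
#' @export
state_signal_summary <- function(track, states) {
  stopifnot(inherits(track, "probe_track"))
  if (!"state" %in% names(states)) stopf("`states` must carry a `state` column")
  probe_center <- (track$start + track$end) / 2
  means <- rep(NA_real_, nrow(states))
  nprobe <- integer(nrow(states))
  for (ri in seq_len(nrow(states))) {
    sel <- track$chrom == states$chrom[ri] &
      probe_center >= states$start[ri] & probe_center < states$end[ri] &
      !is.na(track$M_norm)
    nprobe[ri] <- sum(sel)
    if (nprobe[ri] > 0) means[ri] <- mean(track$M_norm[sel])
  }
  keep <- nprobe > 0
  regions <- data.frame(states[keep, c("chrom", "start", "end", "state")],
                        mean_signal = means[keep], n_probes = nprobe[keep],
                        stringsAsFactors = FALSE)
  rownames(regions) <- NULL
  summ <- do.call(rbind, lapply(split(regions$mean_signal, regions$state),
                                function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(n = length(v), mean = mean(v), q25 = q[1], median = q[2],
               q75 = q[3])
  }))
  summ <- data.frame(state = rownames(summ), summ, stringsAsFactors = FALSE)
  rownames(summ) <- NULL
  list(regions = regions, summary = summ, n_empty = sum(!keep))
}
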