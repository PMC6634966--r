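#' Domain-caller parameters
#'
#' Defaults follow standard DamID tiling-array practice: a sliding edge
#' filter of 199 probes, a transition threshold of 0.3 log2 units, and
#' domains required to have at least 70% of enclosed probes with a
#' positive log2 ratio. The single-peak caller is an extension with its
#' own conservative parameters.
#'
#' @param window_probes Odd edge-filter window size in probes
#'   (default 199).
#' @param edge_threshold Transition threshold in log2 units
#'   (default 0.3).
#' @param min_positive_fraction Minimum fraction of enclosed probes
#'   with positive normalized ratio (default 0.70).
#' @param min_probes_per_domain Minimum probes per domain (default 3).
#' @param peak_min_run Minimum consecutive probes for a single peak
#'   (default 2).
#' @param peak_threshold_quantile Per-chromosome quantile of the
#'   normalized ratio above which probes are peak candidates
#'   (default 0.95, strict inequality).
#' @param boundary_refine_probes Half-window (probes) of the local
#'   edge statistic used to re-localize each detected transition
#'   (default 10; capped at the detection half-window). Detection at
#'   the full window is stable but its maximum forms a wide plateau
#'   when a domain is shorter than the half-window; re-scoring within
#'   one window of the detected position at this small scale collapses
#'   the plateau to the probe adjacent to the true boundary.
#' @return A list of class `domain_call_params`.
#' @export
domain_call_params <- function(window_probes = 199L,
                               edge_threshold = 0.3,
                               min_positive_fraction = 0.70,
                               min_probes_per_domain = 3L,
                               peak_min_run = 2L,
                               peak_threshold_quantile = 0.95,
                               boundary_refine_probes = 10L) {
  window_probes <- check_count(window_probes, "window_probes", 3L)
  if (window_probes %% 2L == 0L) stopf("`window_probes` must be odd")
  if (!is_number(edge_threshold) || edge_threshold <= 0)
    stopf("`edge_threshold` must be > 0")
  if (!is_number(min_positive_fraction) || min_positive_fraction <= 0 ||
      min_positive_fraction > 1)
    stopf("`min_positive_fraction` must be in (0, 1]")
  if (!is_number(peak_threshold_quantile) || peak_threshold_quantile <= 0 ||
      peak_threshold_quantile > 1)
    stopf("`peak_threshold_quantile` must be in (0, 1]")
  structure(list(
    window_probes = window_probes,
    edge_threshold = edge_threshold,
    min_positive_fraction = min_positive_fraction,
    min_probes_per_domain = check_count(min_probes_per_domain, "min_probes_per_domain", 1L),
    peak_min_run = check_count(peak_min_run, "peak_min_run", 1L),
    peak_threshold_quantile = peak_threshold_quantile,
    boundary_refine_probes = check_count(boundary_refine_probes,
                                         "boundary_refine_probes", 1L)
  ), class = "domain_call_params")
}

# Moving half-window means via cumulative sums, NA-aware.
half_window_means <- function(x, h) {
  n <- length(x)
  x0 <- ifelse(is.na(x), 0, x)
  ind <- as.numeric(!is.na(x))
  S <- c(0, cumsum(x0))
  C <- c(0, cumsum(ind))
  right_mean <- left_mean <- rep(NA_real_, n)
  i <- seq_len(n)
  valid <- i > h & i <= n - h
  iv <- i[valid]
  rs <- S[iv + h + 1L] - S[iv + 1L]
  rc <- C[iv + h + 1L] - C[iv + 1L]
  ls <- S[iv] - S[iv - h]
  lc <- C[iv] - C[iv - h]
  right_mean[iv] <- ifelse(rc > 0, rs / rc, NA_real_)
  left_mean[iv] <- ifelse(lc > 0, ls / lc, NA_real_)
  list(right = right_mean, left = left_mean)
}

#' Sliding edge filter
#'
#' For probe i with half-window h = (window_probes - 1) / 2, the edge
#' statistic is the mean normalized ratio of the h probes to the right
#' minus the mean of the h probes to the left (center probe excluded).
#' Scores are undefined (NA) within h probes of a chromosome end rather
#' than computed on truncated windows. A chromosome with fewer than
#' `window_probes` probes gets all-NA scores with a warning.
#'
#' @param track A replicate-combined, normalized `probe_track`.
#' @param params A [domain_call_params()].
#' @return The track with an `edge` column.
#' @export
edge_score <- function(track, params = domain_call_params()) {
  stopifnot(inherits(track, "probe_track"))
  h <- (params$window_probes - 1L) %/% 2L
  track$edge <- NA_real_
  for (chr in unique(track$chrom)) {
    sel <- which(track$chrom == chr)
    if (length(sel) < params$window_probes) {
      warnf("chromosome %s has %d probes (< window of %d): edge scores undefined",
            chr, length(sel), params$window_probes)
      next
    }
    hw <- half_window_means(track$M_norm[sel], h)
    track$edge[sel] <- hw$right - hw$left
  }
  track
}

#' Call signed transitions from edge scores
#'
#' Positions where the absolute edge score exceeds `edge_threshold` and
#' is the maximum among same-signed scores within one window
#' (non-maximum suppression). Ties on a plateau are broken toward the
#' leftmost maximum for up-transitions and the rightmost for
#' down-transitions, so a noise-free step yields transitions
#' symmetrically flanking the enclosed probes. Each surviving
#' transition is then re-localized within one detection window using
#' the same statistic at the small `boundary_refine_probes` half-window
#' (same tie-break), which pins the transition to the probe adjacent to
#' the step for enriched runs shorter than the detection half-window.
#'
#' @param track A `probe_track` with an `edge` column (see
#'   [edge_score()]).
#' @param params A [domain_call_params()].
#' @return Data frame `chrom`, `row` (row index into `track`), `pos`
#'   (probe start), `edge`, `sign` ("up"/"down"), ordered by
#'   coordinate.
#' @export
call_transitions <- function(track, params = domain_call_params()) {
  stopifnot(inherits(track, "probe_track"), "edge" %in% names(track))
  h <- (params$window_probes - 1L) %/% 2L
  out <- list()
  for (chr in unique(track$chrom)) {
    sel <- which(track$chrom == chr)
    e <- track$edge[sel]
    cand <- which(!is.na(e) & abs(e) > params$edge_threshold)
    keep <- logical(length(cand))
    for (ci in seq_along(cand)) {
      i <- cand[ci]
      up <- e[i] > 0
      win <- max(1L, i - h):min(length(e), i + h)
      same <- win[!is.na(e[win]) & (e[win] > 0) == up & abs(e[win]) > params$edge_threshold]
      mx <- max(abs(e[same]))
      tol <- 1e-9 * max(1, mx)  # plateau ties must not be broken by cumsum rounding
      if (abs(e[i]) < mx - tol) next
      at_max <- same[abs(e[same]) >= mx - tol]
      keep[ci] <- if (up) i == min(at_max) else i == max(at_max)
    }
    kept <- cand[keep]
    if (!length(kept)) next
    ups <- e[kept] > 0
    edges <- e[kept]
    # boundary re-localization at the small half-window
    hr <- min(params$boundary_refine_probes, h)
    if (hr < h) {
      hw <- half_window_means(track$M_norm[sel], hr)
      er <- hw$right - hw$left
      kept <- vapply(seq_along(kept), function(ki) {
        i <- kept[ki]
        win <- max(1L, i - h):min(length(er), i + h)
        score <- if (ups[ki]) er[win] else -er[win]
        if (all(is.na(score))) return(i)
        mx <- max(score, na.rm = TRUE)
        tol <- 1e-9 * max(1, abs(mx))
        at_max <- win[!is.na(score) & score >= mx - tol]
        if (ups[ki]) min(at_max) else max(at_max)
      }, integer(1))
      dup <- duplicated(data.frame(kept, ups))
      kept <- kept[!dup]; ups <- ups[!dup]; edges <- edges[!dup]
      o <- order(kept)
      kept <- kept[o]; ups <- ups[o]; edges <- edges[o]
    }
    out[[chr]] <- data.frame(chrom = chr, row = sel[kept],
                             pos = track$start[sel[kept]],
                             edge = edges,
                             sign = ifelse(ups, "up", "down"),
                             stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(), row = integer(), pos = numeric(),
                      edge = numeric(), sign = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assemble domains from paired transitions
#'
#' Each maximal (up, next down) transition pair encloses the candidate
#' probes strictly between the two transition positions. An up
#' transition with no subsequent down closes at the chromosome's last
#' probe, and a leading down opens at the first probe; both are counted
#' in the diagnostics as open-ended candidates. A candidate is retained
#' as a domain iff it encloses at least `min_probes_per_domain` probes
#' and the fraction with positive normalized ratio is at least
#' `min_positive_fraction`. Domain start is the start of the first
#' enclosed probe and end the end of the last; the score is the mean
#' normalized ratio of enclosed probes.
#'
#' @param transitions Output of [call_transitions()].
#' @param track The `probe_track` the transitions refer to.
#' @param params A [domain_call_params()].
#' @return An interval data frame (`chrom`, `start`, `end`, `name`,
#'   `score`, `kind` = "domain") with a `diagnostics` attribute
#'   (transition counts, open-ended and rejected candidates).
#' @export
assemble_domains <- function(transitions, track, params = domain_call_params()) {
  stopifnot(inherits(track, "probe_track"))
  diag <- list(n_up = sum(transitions$sign == "up"),
               n_down = sum(transitions$sign == "down"),
               n_open_ended = 0L, n_rejected_positive = 0L,
               n_rejected_size = 0L)
  rows <- list()
  k <- 0L
  for (chr in unique(track$chrom)) {
    sel <- which(track$chrom == chr)
    tr <- transitions[transitions$chrom == chr, , drop = FALSE]
    # local probe indices of transitions within this chromosome
    loc <- match(tr$row, sel)
    candidates <- list()
    open_up <- NA_integer_
    for (ti in seq_len(nrow(tr))) {
      if (tr$sign[ti] == "up") {
        if (is.na(open_up)) open_up <- loc[ti]  # maximal pair: keep first up
      } else {
        if (!is.na(open_up)) {
          candidates[[length(candidates) + 1L]] <-
            list(from = open_up + 1L, to = loc[ti] - 1L, open = FALSE)
          open_up <- NA_integer_
        } else {
          candidates[[length(candidates) + 1L]] <-
            list(from = 1L, to = loc[ti] - 1L, open = TRUE)
        }
      }
    }
    if (!is.na(open_up))
      candidates[[length(candidates) + 1L]] <-
        list(from = open_up + 1L, to = length(sel), open = TRUE)
    for (cnd in candidates) {
      if (cnd$open) diag$n_open_ended <- diag$n_open_ended + 1L
      if (cnd$to < cnd$from) next
      idx <- sel[cnd$from:cnd$to]
      m <- track$M_norm[idx]
      m <- m[!is.na(m)]
      if (length(m) < params$min_probes_per_domain) {
        diag$n_rejected_size <- diag$n_rejected_size + 1L
        next
      }
      if (mean(m > 0) < params$min_positive_fraction) {
        diag$n_rejected_positive <- diag$n_rejected_positive + 1L
        next
      }
      k <- k + 1L
      rows[[k]] <- data.frame(chrom = chr,
                              start = track$start[idx[1L]],
                              end = track$end[idx[length(idx)]],
                              name = "", score = mean(m), kind = "domain",
                              stringsAsFactors = FALSE)
    }
  }
  out <- if (k) do.call(rbind, rows) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               name = character(), score = numeric(), kind = character(),
               stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out)) out$name <- sprintf("dom_%04d", seq_len(nrow(out)))
  attr(out, "diagnostics") <- diag
  out
}

#' Call enriched domains from a normalized track
#'
#' Convenience wrapper: [edge_score()], [call_transitions()],
#' [assemble_domains()].
#'
#' @param track A replicate-combined, normalized `probe_track`.
#' @param params A [domain_call_params()].
#' @return See [assemble_domains()].
#' @export
call_domains <- function(track, params = domain_call_params()) {
  scored <- edge_score(track, params)
  assemble_domains(call_transitions(scored, params), scored, params)
}

#' Call single peaks
#'
#' Maximal runs of at least `peak_min_run` consecutive probes with
#' normalized ratio strictly above the per-chromosome
#' `peak_threshold_quantile` of the ratio. On a constant track the
#' quantile equals every value, so strict inequality yields no peaks.
#' Runs overlapping called domains are excluded.
#'
#' @param track A normalized `probe_track`.
#' @param params A [domain_call_params()].
#' @param domains Optional domain set whose runs are excluded.
#' @return An interval data frame (`kind` = "peak").
#' @export
call_peaks <- function(track, params = domain_call_params(), domains = NULL) {
  stopifnot(inherits(track, "probe_track"))
  rows <- list()
  k <- 0L
  for (chr in unique(track$chrom)) {
    sel <- which(track$chrom == chr)
    m <- track$M_norm[sel]
    q <- stats::quantile(m, params$peak_threshold_quantile, na.rm = TRUE, names = FALSE)
    above <- !is.na(m) & m > q
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (ri in which(r$values & r$lengths >= params$peak_min_run)) {
      idx <- sel[starts[ri]:ends[ri]]
      s <- track$start[idx[1L]]
      e <- track$end[idx[length(idx)]]
      if (!is.null(domains) && nrow(domains)) {
        d <- domains[domains$chrom == chr, , drop = FALSE]
        if (nrow(d) && any(d$start < e & d$end > s)) next
      }
      k <- k + 1L
      rows[[k]] <- data.frame(chrom = chr, start = s, end = e, name = "",
                              score = mean(track$M_norm[idx], na.rm = TRUE),
                              kind = "peak", stringsAsFactors = FALSE)
    }
  }
  out <- if (k) do.call(rbind, rows) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               name = character(), score = numeric(), kind = character(),
               stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out)) out$name <- sprintf("peak_%04d", seq_len(nrow(out)))
  out
}
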