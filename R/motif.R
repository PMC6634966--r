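#' Motif-scan and enrichment parameters
#'
#' @param pattern IUPAC motif (default the degenerate E-box "CANNTG",
#'   the HES/Hey-related binding site; it is reverse-complement
#'   symmetric, so forward-only counting is complete).
#' @param n_background Background sequences to generate (default 6000).
#' @param background_length_range Background length range in bp
#'   (default 2000-5000).
#' @param n_permutations Label permutations for the empirical p
#'   (default 1000).
#' @param count_mode `"forward_only"` (default) or
#'   `"both_strands_dedup"` (a position counts once if it matches on
#'   either strand).
#' @return A list of class `motif_params`.
#' @export
motif_params <- function(pattern = "CANNTG", n_background = 6000,
                         background_length_range = c(2000, 5000),
                         n_permutations = 1000,
                         count_mode = c("forward_only", "both_strands_dedup")) {
  pattern <- toupper(pattern)
  if (!nzchar(pattern)) stopf("`pattern` must be non-empty")
  bad <- setdiff(strsplit(pattern, "")[[1]], names(iupac_sets))
  if (length(bad)) stopf("non-IUPAC character in pattern: %s", bad[1])
  structure(list(pattern = pattern,
                 n_background = check_count(n_background, "n_background", 1L),
                 background_length_range = as.numeric(background_length_range),
                 n_permutations = check_count(n_permutations, "n_permutations", 1L),
                 count_mode = match.arg(count_mode)),
            class = "motif_params")
}

iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

revcomp_pattern <- function(pattern) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(pattern, "")[[1]]]), collapse = "")
}

# codes: integer vector over 1..5 for A/C/G/T/N
match_positions <- function(codes, pattern) {
  k <- nchar(pattern)
  L <- length(codes)
  if (L < k) return(logical(0))
  pat <- strsplit(pattern, "")[[1]]
  ok <- rep(TRUE, L - k + 1L)
  bases <- c("A", "C", "G", "T", "N")
  for (j in seq_len(k)) {
    lut <- bases %in% iupac_sets[[pat[j]]]  # input N never listed: matches nothing
    ok <- ok & lut[codes[j:(L - k + j)]]
  }
  ok
}

#' Count degenerate-motif occurrences per sequence
#'
#' Counts positions matching the IUPAC pattern; pattern N matches any
#' base, an ambiguous input base (N) matches nothing, overlapping
#' occurrences all count, and matching is case-insensitive.
#'
#' @param sequences A [Biostrings::DNAStringSet] or character vector
#'   over A/C/G/T/N.
#' @param params A [motif_params()] (or a bare IUPAC string).
#' @return Named integer vector of per-sequence counts.
#' @export
scan_motif <- function(sequences, params = motif_params()) {
  if (is.character(params)) params <- motif_params(pattern = params)
  seqs <- if (inherits(sequences, "DNAStringSet")) as.character(sequences)
  else as.character(sequences)
  nm <- names(seqs) %||% sprintf("seq_%d", seq_along(seqs))
  pat_r <- revcomp_pattern(params$pattern)
  counts <- vapply(seq_along(seqs), function(i) {
    chars <- strsplit(toupper(seqs[[i]]), "")[[1]]
    codes <- match(chars, c("A", "C", "G", "T", "N"))
    bad <- which(is.na(codes))
    if (length(bad))
      stopf("non-IUPAC character '%s' in sequence %s at position %d",
            chars[bad[1]], nm[i], bad[1])
    hit <- match_positions(codes, params$pattern)
    if (params$count_mode == "both_strands_dedup")
      hit <- hit | match_positions(codes, pat_r)
    sum(hit)
  }, integer(1))
  stats::setNames(counts, nm)
}

#' Motif enrichment of foreground vs. background sequences
#'
#' Enrichment is the ratio of mean per-kilobase motif density
#' (foreground over background, sequences weighted equally), with an
#' empirical p-value from permuting sequence labels:
#' `p = (1 + #{permutations with ratio >= observed}) / (n_permutations + 1)`.
#'
#' @param fg_counts,bg_counts Per-sequence motif counts (see
#'   [scan_motif()]).
#' @param fg_lengths,bg_lengths Matching sequence lengths in bp.
#' @param params A [motif_params()].
#' @return A list of class `motif_result`: densities, `enrichment`,
#'   `p_empirical`, `n_permutations`.
#' @export
motif_enrichment <- function(fg_counts, fg_lengths, bg_counts, bg_lengths,
                             params = motif_params()) {
  if (!length(fg_counts) || !length(bg_counts))
    stopf("both sequence sets must be non-empty")
  stopifnot(length(fg_counts) == length(fg_lengths),
            length(bg_counts) == length(bg_lengths))
  dens_fg <- fg_counts / (fg_lengths / 1000)
  dens_bg <- bg_counts / (bg_lengths / 1000)
  if (mean(dens_bg) == 0) stopf("zero background motif density")
  ratio <- mean(dens_fg) / mean(dens_bg)
  pool <- c(dens_fg, dens_bg)
  n_fg <- length(dens_fg)
  n <- length(pool)
  B <- params$n_permutations
  hits <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n_fg)
    mb <- mean(pool[-idx])
    rb <- if (mb > 0) mean(pool[idx]) / mb else Inf
    if (rb >= ratio) hits <- hits + 1L
  }
  structure(list(fg_density = mean(dens_fg), bg_density = mean(dens_bg),
                 fg_densities = dens_fg, bg_densities = dens_bg,
                 enrichment = ratio,
                 p_empirical = (1 + hits) / (B + 1),
                 n_permutations = B, pattern = params$pattern),
            class = "motif_result")
}

#' @export
print.motif_result <- function(x, ...) {
  cat(sprintf(
    "<motif_result> %s: fg %.3f/kb vs bg %.3f/kb, enrichment %.3f, empirical p = %.4g (%d permutations)\n",
    x$pattern, x$fg_density, x$bg_density, x$enrichment, x$p_empirical,
    x$n_permutations))
  invisible(x)
}

#' Scan-and-test convenience wrapper
#'
#' @param fg_seqs,bg_seqs Foreground and background sequences
#'   ([Biostrings::DNAStringSet] or character).
#' @param params A [motif_params()].
#' @return See [motif_enrichment()].
#' @export
motif_enrichment_seqs <- function(fg_seqs, bg_seqs, params = motif_params()) {
  fg <- scan_motif(fg_seqs, params)
  bg <- scan_motif(bg_seqs, params)
  motif_enrichment(fg, nchar(as.character(fg_seqs)),
                   bg, nchar(as.character(bg_seqs)), params)
}
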