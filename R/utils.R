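# Internal helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 0L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= min && x == as.integer(x)
}

is_number <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)

is_fraction <- function(x) is_number(x) && x >= 0 && x <= 1

is_flag <- function(x) length(x) == 1L && is.logical(x) && !is.na(x)

check_count <- function(x, name, min = 0L) {
  if (!is_count(x, min)) stopf("`%s` must be a single integer >= %d", name, min)
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is_number(x) || x < min || x > max)
    stopf("`%s` must be a single finite number in [%s, %s]", name, min, max)
  as.numeric(x)
}

#' Derive a reproducible per-stage seed from a global seed
#'
#' Stages of the pipeline draw from independent streams keyed by stage
#' name, so any stage can be re-run in isolation with the same result.
#' The derived seed stays below 2^31 - 1.
#'
#' @param seed Global integer seed.
#' @param stage Character stage name.
#' @return A single integer seed.
#' @export
stage_seed <- function(seed, stage) {
  seed <- check_count(seed, "seed")
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((seed + h * 10007) %% 2147483629)
}

# Sorted, non-overlapping check for a BED-like frame; returns NULL or an
# informative message naming the first offending pair.
first_interval_violation <- function(df) {
  for (chr in unique(df$chrom)) {
    d <- df[df$chrom == chr, , drop = FALSE]
    if (nrow(d) < 2L) next
    bad_order <- which(diff(d$start) < 0)
    if (length(bad_order)) {
      i <- bad_order[1L]
      return(sprintf("intervals out of order on %s: [%d,%d) before [%d,%d)",
                     chr, d$start[i], d$end[i], d$start[i + 1L], d$end[i + 1L]))
    }
    bad_ovl <- which(d$end[-nrow(d)] > d$start[-1L])
    if (length(bad_ovl)) {
      i <- bad_ovl[1L]
      return(sprintf("overlapping intervals on %s: [%d,%d) and [%d,%d)",
                     chr, d$start[i], d$end[i], d$start[i + 1L], d$end[i + 1L]))
    }
  }
  NULL
}
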