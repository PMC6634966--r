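#' Reconstruct integer counts from a printed percentage
#'
#' Papers often report "x% of n"; the underlying count is recovered
#' either as the nearest integer (`round(percent * n / 100)`, halves
#' up) or as the full set of integers consistent with the printed
#' percentage (`all_consistent`: every c with
#' `round(100 * c / n) == percent`). An empty consistent set is
#' returned as a zero-length vector with a warning.
#'
#' @param percent Printed percentage in `[0, 100]`.
#' @param n Sample size.
#' @param rounding `"nearest"` or `"all_consistent"`.
#' @return Integer count (nearest) or integer vector (all_consistent).
#' @export
counts_from_percent <- function(percent, n,
                                rounding = c("nearest", "all_consistent")) {
  rounding <- match.arg(rounding)
  percent <- check_number(percent, "percent", 0, 100)
  n <- check_count(n, "n", 1L)
  round_half_up <- function(x) floor(x + 0.5)
  if (rounding == "nearest") return(as.integer(round_half_up(percent * n / 100)))
  cand <- 0:n
  hit <- cand[round_half_up(100 * cand / n) == round_half_up(percent)]
  if (!length(hit)) warnf("no integer count of %d is consistent with %g%%", n, percent)
  as.integer(hit)
}

#' Fisher's exact test for a 2x2 contingency table
#'
#' Exact conditional test: the two-sided p-value sums the
#' probabilities of all margin-fixed tables whose point probability is
#' at most the observed table's (the classic rule, delegated to
#' `stats::fisher.test`). The sample odds ratio (a*d)/(b*c) is
#' reported alongside the conditional MLE; 0/0 is flagged as NaN.
#'
#' @param table 2x2 integer matrix or data frame (rows = groups,
#'   columns = outcomes).
#' @return A list: `p`, `odds_ratio` (sample), `odds_ratio_mle`
#'   (conditional MLE), `table`.
#' @export
fisher_exact <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L))) stopf("`table` must be 2x2")
  if (any(m < 0) || any(m != round(m))) stopf("counts must be non-negative integers")
  if (sum(m) == 0) stopf("all-zero table")
  ft <- stats::fisher.test(m)
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  list(p = ft$p.value, odds_ratio = unname(or),
       odds_ratio_mle = unname(ft$estimate), table = m)
}

#' Classify polyploid cells by lineage-tracing markers
#'
#' Dual-marker lineage tracing scores each cell for a permanent
#' recombination-activated history marker (GFP) and a current-identity
#' marker (RFP). Polyploid cells fall into four classes: EC
#' (GFP+ RFP+, differentiated identity intact), PPC** (GFP+ RFP-,
#' former ECs that lost current identity), PPC* (GFP- RFP-, cells that
#' never activated the system), and PPC^R (GFP- RFP+, current marker
#' without recombination). Non-polyploid cells are excluded.
#'
#' @param cells Data frame with logical columns `gfp`, `rfp`,
#'   `polyploid`.
#' @return Named fractions (`EC`, `PPCss`, `PPCs`, `PPCr`) summing to 1
#'   over polyploid cells, with attribute `n` (polyploid cell count).
#' @export
classify_gtrace <- function(cells) {
  stopifnot(is.data.frame(cells),
            all(c("gfp", "rfp", "polyploid") %in% names(cells)))
  pp <- cells[cells$polyploid, , drop = FALSE]
  if (!nrow(pp)) stopf("no polyploid cells to classify")
  n <- nrow(pp)
  fr <- c(EC = sum(pp$gfp & pp$rfp),
          PPCss = sum(pp$gfp & !pp$rfp),
          PPCs = sum(!pp$gfp & !pp$rfp),
          PPCr = sum(!pp$gfp & pp$rfp)) / n
  attr(fr, "n") <- n
  fr
}

#' Simple life-table survival summary
#'
#' Per group: the fraction surviving past a horizon day (individuals
#' censored at or before the horizon are counted alive through their
#' censor day, then excluded from the denominator) and the median
#' survival day DT50, the first day by which cumulative deaths reach
#' 50% of the starting cohort. A horizon before the first recorded day
#' gives fraction 1 by convention.
#'
#' @param table Data frame with columns `group`, `day` (> 0) and
#'   optionally `censored` (logical).
#' @param horizon_day Horizon in days.
#' @return Data frame `group`, `n`, `n_at_risk`, `frac_surviving`,
#'   `dt50`.
#' @export
survival_summary <- function(table, horizon_day) {
  stopifnot(is.data.frame(table), all(c("group", "day") %in% names(table)))
  if (any(table$day <= 0)) stopf("days must be positive")
  if (!"censored" %in% names(table)) table$censored <- FALSE
  horizon_day <- check_number(horizon_day, "horizon_day")
  rows <- lapply(split(table, table$group), function(g) {
    n0 <- nrow(g)
    cens_before <- g$censored & g$day <= horizon_day
    at_risk <- sum(!cens_before)
    frac <- if (at_risk > 0)
      sum(g$day[!cens_before] > horizon_day |
            (g$censored[!cens_before] & g$day[!cens_before] > horizon_day)) / at_risk
    else NA_real_
    deaths <- sort(g$day[!g$censored])
    cum <- seq_along(deaths)
    dt50 <- if (length(deaths) && max(cum) >= n0 / 2)
      deaths[which(cum >= n0 / 2)[1]] else NA_real_
    data.frame(group = g$group[1], n = n0, n_at_risk = at_risk,
               frac_surviving = frac, dt50 = dt50, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
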