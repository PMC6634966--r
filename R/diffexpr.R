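#' Differential-expression parameters
#'
#' @param alpha Significance level for the filter (default 0.05).
#' @param min_fold_change Minimum linear fold change (default 2).
#' @param filter_on Filter on raw p (`"p"`, default) or BH-adjusted q
#'   (`"q"`); both statistics are always reported.
#' @param prior_df,prior_var Optional overrides of the empirical-Bayes
#'   prior degrees of freedom d0 and prior variance s0^2; `NULL` means
#'   estimate both by method of moments on the log residual variances.
#'   `prior_df = 0` gives the ordinary pooled-variance t-test.
#' @return A list of class `de_params`.
#' @export
de_params <- function(alpha = 0.05, min_fold_change = 2.0,
                      filter_on = c("p", "q"),
                      prior_df = NULL, prior_var = NULL) {
  if (!is_number(alpha) || alpha <= 0 || alpha >= 1)
    stopf("`alpha` must be in (0, 1)")
  if (!is_number(min_fold_change) || min_fold_change < 1)
    stopf("`min_fold_change` must be >= 1")
  if (!is.null(prior_df) && !(is.numeric(prior_df) && length(prior_df) == 1 && prior_df >= 0))
    stopf("`prior_df` must be a single number >= 0 (or NULL)")
  if (!is.null(prior_var) && !(is_number(prior_var) && prior_var > 0))
    stopf("`prior_var` must be a single positive number (or NULL)")
  structure(list(alpha = alpha, min_fold_change = min_fold_change,
                 filter_on = match.arg(filter_on),
                 prior_df = prior_df, prior_var = prior_var),
            class = "de_params")
}

# Inverse of trigamma by Newton iteration on 1/trigamma (monotone).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

# Method-of-moments fit of the scaled inverse chi-square variance prior
# on observed residual variances s2 with df residual degrees of freedom.
fit_variance_prior <- function(s2, df) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (length(s2) < 2L)
    stopf("too few positive residual variances to estimate a prior")
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_2 <- exp(mean(e))
  }
  list(prior_df = d0, prior_var = s0_2)
}

#' Empirical-Bayes moderated t-test for a two-group expression matrix
#'
#' Per-gene pooled residual variance s^2 (d residual df) is shrunk
#' toward a prior s0^2 with d0 prior df:
#' `s2_post = (d0 * s0^2 + d * s^2) / (d0 + d)`; the moderated t uses
#' `s2_post` and is referred to a t distribution on d0 + d df. The
#' prior is estimated by method of moments on the log residual
#' variances (overridable via [de_params()]); with `prior_df = 0` the
#' statistic reduces to the ordinary pooled-variance two-sample t.
#'
#' @param mat Numeric matrix, genes x samples, log2 scale, with row
#'   names as gene ids.
#' @param groups Character/factor vector (length `ncol(mat)`) with
#'   exactly two levels.
#' @param params A [de_params()].
#' @param ref Reference (control) group label; the log2 fold change is
#'   the other group minus `ref`.
#' @return A `deg_table` data frame: `gene_id`, `log2fc`, `s2`,
#'   `s2_post`, `t`, `p`, `q`, `direction`, `passes_filter`, with the
#'   fitted prior in attributes `prior_df`, `prior_var`.
#' @export
moderated_t_test <- function(mat, groups, params = de_params(),
                             ref = "control") {
  stopifnot(is.matrix(mat), is.numeric(mat))
  groups <- as.character(groups)
  if (length(groups) != ncol(mat)) stopf("`groups` must match columns of `mat`")
  lev <- unique(groups)
  if (length(lev) != 2L) stopf("exactly two groups required")
  if (!ref %in% lev) stopf("reference group '%s' not present", ref)
  other <- setdiff(lev, ref)
  i1 <- groups == ref
  i2 <- groups == other
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2L || n2 < 2L) stopf("each group needs at least 2 replicates")
  m1 <- rowMeans(mat[, i1, drop = FALSE])
  m2 <- rowMeans(mat[, i2, drop = FALSE])
  v1 <- apply(mat[, i1, drop = FALSE], 1L, stats::var)
  v2 <- apply(mat[, i2, drop = FALSE], 1L, stats::var)
  d <- n1 + n2 - 2L
  s2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / d
  lfc <- m2 - m1

  if (all(s2 == 0)) {
    if (all(lfc == 0)) {
      warnf("all residual variances and group differences are zero; flagging all genes non-significant")
      out <- data.frame(gene_id = rownames(mat), log2fc = lfc, s2 = s2,
                        s2_post = 0, t = 0, p = 1, q = 1,
                        direction = NA_character_, passes_filter = FALSE,
                        stringsAsFactors = FALSE)
      class(out) <- c("deg_table", "data.frame")
      return(out)
    }
    stopf("zero residual variance across all genes: degenerate input")
  }

  d0 <- params$prior_df
  s0_2 <- params$prior_var
  if (is.null(d0) || is.null(s0_2)) {
    fit <- fit_variance_prior(s2, d)
    if (is.null(d0)) d0 <- fit$prior_df
    if (is.null(s0_2)) s0_2 <- fit$prior_var
  }
  s2_post <- if (is.infinite(d0)) rep(s0_2, length(s2)) else
    (d0 * s0_2 + d * s2) / (d0 + d)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, sign(lfc) * Inf))
  df_total <- d0 + d
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  p[is.infinite(tstat)] <- 0
  q <- bh_fdr(p)
  crit <- if (params$filter_on == "p") p else q
  passes <- crit < params$alpha & abs(lfc) >= log2(params$min_fold_change)
  out <- data.frame(
    gene_id = rownames(mat) %||% sprintf("gene_%05d", seq_along(lfc)),
    log2fc = lfc, s2 = s2, s2_post = s2_post, t = tstat, p = p, q = q,
    direction = ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", NA_character_)),
    passes_filter = passes, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("deg_table", "data.frame")
  attr(out, "prior_df") <- d0
  attr(out, "prior_var") <- s0_2
  attr(out, "residual_df") <- d
  out
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' q_i = min over j with rank(j) >= rank(i) of m * p_(j) / j, in input
#' order (the classic step-up rule, delegated to
#' `stats::p.adjust(method = "BH")`).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p)) stopf("`p` must be numeric")
  if (any(is.na(p)) || any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Apply the significance and fold-change filter
#'
#' Keeps genes with p (or q, per `filter_on`) below `alpha` and
#' absolute log2 fold change of at least `log2(min_fold_change)`, split
#' by direction.
#'
#' @param table A `deg_table` from [moderated_t_test()].
#' @param params A [de_params()].
#' @return A list: `up`, `down` (data frames), and `all` (both).
#' @export
filter_degs <- function(table, params = de_params()) {
  stopifnot(inherits(table, "deg_table"))
  crit <- if (params$filter_on == "p") table$p else table$q
  keep <- !is.na(crit) & crit < params$alpha &
    abs(table$log2fc) >= log2(params$min_fold_change)
  sel <- table[keep, , drop = FALSE]
  list(up = sel[sel$log2fc > 0, , drop = FALSE],
       down = sel[sel$log2fc < 0, , drop = FALSE],
       all = sel)
}
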