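#' Normality-gated two-group comparison
#'
#' Mirrors the conventional decision rule of the field: both samples are
#' assessed for normality with the Shapiro-Wilk test; when both pass at
#' `alpha_normality`, a two-sided Student's t-test is used, otherwise
#' the (exact) Mann-Whitney U test. The gate outcome is recorded in the
#' report.
#'
#' @param x,y numeric samples (each n >= 3).
#' @param alpha_normality significance level of the normality gate.
#' @param var_equal use the classical equal-variance t-test (default
#'   TRUE, Student's t).
#' @return list with `test` ("t" or "mann-whitney"), `statistic`, `p`
#'   (two-sided), `shapiro_p` (both samples), `normal` (gate outcome).
#' @export
compare_groups <- function(x, y, alpha_normality = 0.05, var_equal = TRUE) {
  if (length(x) < 3 || length(y) < 3)
    stop("each sample needs n >= 3")
  sw <- function(v) {
    if (stats::sd(v) == 0) return(0)  # constant sample: clearly non-normal
    stats::shapiro.test(v)$p.value
  }
  shapiro_p <- c(x = sw(x), y = sw(y))
  normal <- all(shapiro_p >= alpha_normality)
  if (normal) {
    tt <- stats::t.test(x, y, var.equal = var_equal)
    list(test = "t", statistic = unname(tt$statistic), p = tt$p.value,
         shapiro_p = shapiro_p, normal = TRUE)
  } else {
    mw <- mann_whitney_exact(x, y)
    list(test = "mann-whitney", statistic = mw$U, p = mw$p,
         shapiro_p = shapiro_p, normal = FALSE)
  }
}

# U statistic of x vs y from midranks (ties counted 1/2)
u_statistic <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Exact Mann-Whitney U test
#'
#' Computes the U statistic from midranks and a two-sided p-value: by
#' full enumeration of all group-label assignments when the combined
#' sample size is at most `exact_limit` (default 14, where enumeration
#' is instant), and by the normal approximation with tie correction
#' above it. Enumeration handles ties exactly; the two-sided p is the
#' probability, over all C(n, n_x) labelings, of a U at least as far
#' from its null mean as observed.
#'
#' @param x,y numeric samples (non-empty).
#' @param exact_limit maximum combined n for full enumeration.
#' @return list with `U` (for `x`), `p` (two-sided), `method`.
#' @export
mann_whitney_exact <- function(x, y, exact_limit = 14) {
  if (!length(x) || !length(y)) stop("empty sample")
  nx <- length(x); ny <- length(y); n <- nx + ny
  U <- u_statistic(x, y)
  mu <- nx * ny / 2
  if (n <= exact_limit) {
    pool <- c(x, y)
    idx <- utils::combn(n, nx)
    obs_dev <- abs(U - mu)
    us <- apply(idx, 2, function(i) u_statistic(pool[i], pool[-i]))
    p <- mean(abs(us - mu) >= obs_dev - 1e-9)
    list(U = U, p = p, method = "exact enumeration")
  } else {
    r <- rank(c(x, y))
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * (n + 1 - tie_term)
    if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal approximation"))
    z <- (U - mu) / sqrt(sigma2)
    list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))),
         method = "normal approximation")
  }
}

#' Holm step-down adjustment
#'
#' Order-preserving Holm correction of a p-value vector (monotonicity
#' enforced), as provided by [stats::p.adjust()].
#'
#' @param p numeric p-values in [0, 1].
#' @return adjusted p-values in the input order.
#' @export
holm_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact test of association: the p-value sums the
#' hypergeometric probabilities (margins fixed) of all tables no more
#' probable than the observed one, and the conditional maximum-likelihood
#' odds ratio is reported, as in [stats::fisher.test()].
#'
#' @param table 2x2 matrix of non-negative integer counts (rows =
#'   groups, columns = outcome).
#' @return list with `odds_ratio`, `p` (two-sided).
#' @export
fisher_exact <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == 2) || any(m < 0) || any(m != round(m)))
    stop("'table' must be a 2x2 matrix of non-negative integers")
  if (sum(m) == 0) stop("table total must be > 0")
  ft <- stats::fisher.test(m, alternative = "two.sided")
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Relative expression by the 2^-ddCt method
#'
#' ddCt = (Ct_goi,treated - Ct_hk,treated) - (Ct_goi,control -
#' Ct_hk,control); the relative expression of the gene of interest,
#' normalized to the housekeeping gene and the control condition, is
#' 2^-ddCt (valid when both genes amplify with similar efficiency).
#'
#' @param ct_goi_treated,ct_hk_treated,ct_goi_control,ct_hk_control
#'   threshold-cycle values (finite; vectors are averaged).
#' @return relative expression fold change.
#' @export
fold_change_ddct <- function(ct_goi_treated, ct_hk_treated,
                             ct_goi_control, ct_hk_control) {
  vals <- c(ct_goi_treated, ct_hk_treated, ct_goi_control, ct_hk_control)
  if (any(!is.finite(vals))) stop("Ct values must be finite")
  ddct <- (mean(ct_goi_treated) - mean(ct_hk_treated)) -
    (mean(ct_goi_control) - mean(ct_hk_control))
  2^(-ddct)
}

#' Group-comparison report for a metrics table
#'
#' Runs [compare_groups()] on one metric column split by a two-level
#' group column and returns a one-row report (test used, statistic,
#' two-sided p, group sizes). Convenience wrapper used by the pipeline
#' and command-line interface.
#'
#' @param df data frame.
#' @param value_col metric column name.
#' @param group_col grouping column name (2 levels).
#' @param ... passed to [compare_groups()].
#' @return one-row data frame.
#' @export
stats_report <- function(df, value_col, group_col = "group", ...) {
  g <- as.factor(df[[group_col]])
  if (nlevels(g) != 2) stop("exactly two groups required")
  v <- df[[value_col]]
  ok <- is.finite(v)
  x <- v[ok & g == levels(g)[1]]; y <- v[ok & g == levels(g)[2]]
  res <- compare_groups(x, y, ...)
  data.frame(metric = value_col, group1 = levels(g)[1],
             group2 = levels(g)[2], n1 = length(x), n2 = length(y),
             test = res$test, statistic = res$statistic, p = res$p)
}
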