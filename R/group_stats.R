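#' Two-sample comparisons with FDR correction
#'
#' Per-variable two-tailed two-sample t-tests (Welch by default) between two
#' groups of subjects, with Benjamini-Hochberg correction applied within the
#' family of variables tested in this call (all ROIs of one parameter, or
#' one set of clinical variables — families are per analysis, never pooled
#' across analyses). Missing values are dropped pairwise per variable and
#' the retained counts reported; a variable with fewer than two non-missing
#' values in either group is marked untestable and excluded from the FDR
#' family.
#'
#' @param x Numeric matrix or data frame, subjects in rows (row names are
#'   subject IDs), variables in columns.
#' @param ids_a,ids_b Subject IDs of the two groups.
#' @param variables Columns to test (default: all).
#' @param alpha Significance level on the FDR-adjusted q-values.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return Data frame with one row per variable: group sizes used,
#'   `statistic`, `p`, `q`, and `significant` (q < `alpha`). Untestable
#'   variables carry `NA` statistics.
#' @export
two_sample_tests <- function(x, ids_a, ids_b, variables = NULL, alpha = 0.05,
                             var_equal = FALSE) {
  x <- as.matrix(as.data.frame(x, check.names = FALSE))
  if (is.null(rownames(x))) stop("x must have subject IDs as row names")
  miss <- setdiff(c(ids_a, ids_b), rownames(x))
  if (length(miss)) stop("unknown subject IDs: ", paste(miss, collapse = ", "))
  if (length(ids_a) < 2 || length(ids_b) < 2)
    stop("both groups need at least two subjects")
  variables <- variables %||% colnames(x)

  one <- function(v) {
    va <- x[ids_a, v]; vb <- x[ids_b, v]
    va <- va[is.finite(va)]; vb <- vb[is.finite(vb)]
    if (length(va) < 2 || length(vb) < 2)
      return(data.frame(variable = v, n_a = length(va), n_b = length(vb),
                        statistic = NA_real_, p = NA_real_))
    if (stats::var(va) == 0 && stats::var(vb) == 0) {
      # degenerate but well-defined: identical constants agree perfectly
      tt <- if (mean(va) == mean(vb)) c(0, 1) else c(sign(mean(va) - mean(vb)) * Inf, 0)
      return(data.frame(variable = v, n_a = length(va), n_b = length(vb),
                        statistic = tt[1], p = tt[2]))
    }
    ht <- t.test(va, vb, var.equal = var_equal)
    data.frame(variable = v, n_a = length(va), n_b = length(vb),
               statistic = unname(ht$statistic), p = ht$p.value)
  }
  out <- do.call(rbind, lapply(variables, one))
  out$q <- NA_real_
  testable <- !is.na(out$p)
  out$q[testable] <- fdr_bh(out$p[testable])
  out$significant <- !is.na(out$q) & out$q < alpha
  rownames(out) <- NULL
  out
}

#' Chi-square test of a diagnosis-by-subtype table
#'
#' Pearson chi-square test of independence on a contingency table of counts
#' (e.g. primary diagnosis by subtype), without continuity correction by
#' default. Used to ask whether the likelihood of each diagnosis differs
#' from chance across subtypes.
#'
#' @param tab Matrix of non-negative integer counts with positive margins.
#' @param correct Apply the Yates continuity correction (2x2 only).
#' @return List with `statistic`, `df`, `p`, and the `expected` counts.
#' @examples
#' chi_square_diagnosis(matrix(c(49, 50, 25, 24), 2)) # balanced: p near 1
#' @export
chi_square_diagnosis <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("every row and column margin must be positive")
  ht <- suppressWarnings(chisq.test(tab, correct = correct))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, expected = ht$expected)
}

#' One-way ANOVA with Tukey post-hoc comparisons
#'
#' Fixed-effects one-way ANOVA across three or more groups; when the
#' omnibus F-test is significant at `alpha`, Tukey HSD pairwise
#' comparisons are run, otherwise no post-hoc is performed.
#'
#' @param values Numeric response vector.
#' @param group_labels Group label per value (3+ groups, each with at least
#'   2 observations).
#' @param alpha Omnibus significance gate for the post-hoc step.
#' @return List with `F`, `df`, `p`, and `tukey` (a data frame of pairwise
#'   differences with adjusted p-values, or `NULL` when the omnibus test is
#'   not significant).
#' @export
anova_posthoc <- function(values, group_labels, alpha = 0.05) {
  g <- factor(group_labels)
  if (nlevels(g) < 3)
    stop("anova_posthoc requires at least 3 groups; use two_sample_tests")
  if (any(table(g) < 2)) stop("every group needs at least 2 observations")
  if (length(values) != length(g)) stop("values and group_labels differ in length")
  fit <- aov(values ~ g)
  sm <- summary(fit)[[1]]
  Fval <- sm[["F value"]][1]
  p <- sm[["Pr(>F)"]][1]
  tk <- NULL
  if (is.finite(p) && p < alpha) {
    th <- TukeyHSD(fit)$g
    tk <- data.frame(pair = rownames(th), diff = th[, "diff"],
                     lwr = th[, "lwr"], upr = th[, "upr"],
                     p_adj = th[, "p adj"], row.names = NULL)
  }
  list(F = Fval, df = unname(sm[["Df"]]), p = p, tukey = tk)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR-adjusted q-values (clipped to 1, monotone after sorting).
#' Declaring the variables with `q < alpha` significant controls the
#' expected false-discovery proportion at `alpha`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (may be empty).
#' @return Adjusted q-values, same length and order as the input.
#' @export
fdr_bh <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must be in [0, 1] with no missing values")
  p.adjust(p_values, method = "BH")
}
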