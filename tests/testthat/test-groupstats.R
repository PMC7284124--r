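test_that("two-sample tests return null results for identical groups", {
  x <- matrix(rnorm(40), 10, 4,
              dimnames = list(paste0("s", 1:10), paste0("v", 1:4)))
  x <- rbind(x, x)
  rownames(x) <- paste0("s", 1:20)
  res <- two_sample_tests(x, paste0("s", 1:10), paste0("s", 11:20))
  expect_equal(res$statistic, rep(0, 4))
  expect_equal(res$p, rep(1, 4))
  expect_false(any(res$significant))
})

test_that("planted shifts are detected after FDR and q matches a step-up oracle", {
  set.seed(50)
  n <- 60; p_aff <- 20; p_null <- 40
  x <- matrix(rnorm(2 * n * (p_aff + p_null)), 2 * n)
  colnames(x) <- paste0("v", seq_len(p_aff + p_null))
  rownames(x) <- paste0("s", seq_len(2 * n))
  x[seq_len(n), seq_len(p_aff)] <- x[seq_len(n), seq_len(p_aff)] + 2.0
  res <- two_sample_tests(x, paste0("s", 1:n), paste0("s", (n + 1):(2 * n)))
  expect_gte(mean(res$significant[seq_len(p_aff)]), 0.9)

  # independent Benjamini-Hochberg step-up recomputation
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(m / (m:1) * p[o]))[ro]
  }
  expect_equal(res$q, bh_oracle(res$p), tolerance = 1e-12)
})

test_that("two-sample p-values are invariant to affine rescaling", {
  set.seed(51)
  x <- matrix(rnorm(60), 20, 3,
              dimnames = list(paste0("s", 1:20), paste0("v", 1:3)))
  res1 <- two_sample_tests(x, paste0("s", 1:10), paste0("s", 11:20))
  x2 <- sweep(sweep(x, 2, c(3, 0.5, 100), "*"), 2, c(-2, 7, 0.1), "+")
  res2 <- two_sample_tests(x2, paste0("s", 1:10), paste0("s", 11:20))
  expect_equal(res1$p, res2$p, tolerance = 1e-12)
})

test_that("untestable variables are excluded from the FDR family", {
  x <- matrix(rnorm(40), 10, 4,
              dimnames = list(paste0("s", 1:10), paste0("v", 1:4)))
  x[1:4, 2] <- NA # group A has < 2 non-missing values for v2
  res <- two_sample_tests(x, paste0("s", 1:5), paste0("s", 6:10))
  expect_true(is.na(res$statistic[2]) && is.na(res$q[2]))
  expect_false(res$significant[2])
  expect_equal(res$q[-2], fdr_bh(res$p[-2]))
})

test_that("chi-square matches the hand formula and the study's printed tables", {
  expect_equal(chi_square_diagnosis(matrix(c(10, 10, 10, 10), 2))$statistic, 0)
  expect_equal(chi_square_diagnosis(matrix(c(10, 10, 10, 10), 2))$p, 1)

  tab <- matrix(c(49, 50, 25, 24), 2) # diagnosis x subtype counts
  res <- chi_square_diagnosis(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - expected)^2 / expected),
               tolerance = 1e-12)
  expect_equal(res$df, 1)
  expect_gt(res$p, 0.05)

  # invariance to swapping rows and to swapping columns
  expect_equal(chi_square_diagnosis(tab[2:1, ])$statistic, res$statistic)
  expect_equal(chi_square_diagnosis(tab[, 2:1])$statistic, res$statistic)

  expect_error(chi_square_diagnosis(matrix(c(0, 0, 5, 5), 2)), "margin")
  expect_error(chi_square_diagnosis(matrix(c(1.5, 2, 3, 4), 2)), "integers")
})

test_that("ANOVA reduces to t-squared with two groups and gates the post-hoc", {
  set.seed(52)
  v <- rnorm(30); g <- rep(c("a", "b", "c"), each = 10)
  # identical groups: F = 0, p = 1, no post-hoc
  v3 <- rep(rnorm(10), 3)
  res0 <- anova_posthoc(v3, g)
  expect_equal(res0$F, 0)
  expect_equal(res0$p, 1)
  expect_null(res0$tukey)

  # separated third group: omnibus significant, Tukey flags the two pairs
  v_sep <- c(rnorm(10), rnorm(10), rnorm(10) + 5)
  res1 <- anova_posthoc(v_sep, g)
  expect_lt(res1$p, 0.05)
  sig_pairs <- res1$tukey$pair[res1$tukey$p_adj < 0.05]
  expect_setequal(sig_pairs, c("c-a", "c-b"))

  # two-group identity F = t^2 (via an internal 2-group aov)
  y <- rnorm(20); g2 <- rep(c("a", "b"), each = 10)
  Fv <- summary(aov(y ~ factor(g2)))[[1]][["F value"]][1]
  tv <- t.test(y[g2 == "a"], y[g2 == "b"], var.equal = TRUE)$statistic
  expect_equal(Fv, unname(tv)^2, tolerance = 1e-10)
  expect_error(anova_posthoc(y, g2), "at least 3 groups")
})

test_that("fdr_bh handles the hand-computed and degenerate cases", {
  expect_equal(fdr_bh(numeric(0)), numeric(0))
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(fdr_bh(rep(0.2, 10)), rep(0.2, 10))
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(fdr_bh(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("FDR keeps the realized false-discovery proportion near its level", {
  set.seed(53)
  fdp <- replicate(60, {
    n <- 30; p_tot <- 40; p_true <- 10
    x <- matrix(rnorm(2 * n * p_tot), 2 * n)
    colnames(x) <- paste0("v", seq_len(p_tot))
    rownames(x) <- paste0("s", seq_len(2 * n))
    x[seq_len(n), seq_len(p_true)] <- x[seq_len(n), seq_len(p_true)] + 2
    res <- two_sample_tests(x, paste0("s", 1:n), paste0("s", (n + 1):(2 * n)))
    rej <- which(res$significant)
    if (!length(rej)) return(NA_real_)
    mean(rej > p_true) # fraction of rejections that are nulls
  })
  expect_lte(mean(fdp, na.rm = TRUE), 0.05 + 2 * 0.05)
})
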