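#' Choose the number of subtypes by cross-validated stability
#'
#' Sweeps `k` over `k_range`, fitting [hydra()] on `n_folds` overlapping
#' training sets (all controls plus the clinical subjects outside one fold)
#' and scoring, for every pair of folds, the agreement of the two solutions
#' on the clinical subjects common to both training sets: adjusted Rand
#' index (the selection criterion), plain Rand index, and aligned Hamming
#' distance. The selected `k` maximizes mean ARI; ties go to the smaller
#' `k` (parsimony). With `n_folds = 2` there is a single fold pair, and the
#' standard deviations are reported as 0.
#'
#' @param x Feature matrix or [feature_table()] (covariate-adjusted).
#' @param group Clinical/control indicator per row (see [hydra()]).
#' @param k_range Candidate numbers of subtypes.
#' @param n_folds Cross-validation folds over the clinical subjects.
#' @param n_restarts,max_iterations,cost,svm_epochs,svm_tol Passed to
#'   [hydra()] for each fold fit.
#' @param seed Master seed for fold assignment and all fold fits.
#' @return Object of class `hydra_stability`: a per-`k` table of mean/sd
#'   ARI, Rand, and Hamming, plus `selected_k`.
#' @export
cv_stability_sweep <- function(x, group, k_range = 2:10, n_folds = 10,
                               n_restarts = 5, max_iterations = 50,
                               cost = 0.25, seed = 1L,
                               svm_epochs = 200, svm_tol = 1e-4) {
  x <- as_feature_matrix(x)
  is_clin <- normalize_group(group, nrow(x))
  if (n_folds < 2) stop("n_folds must be >= 2")
  n_clin <- sum(is_clin)
  folds <- with_seed(seed, sample(rep_len(seq_len(n_folds), n_clin)))
  min_train <- n_clin - max(tabulate(folds, n_folds))
  if (min_train < max(k_range))
    stop("a fold leaves fewer clinical training subjects than max(k_range)")

  fit_seeds <- derive_seeds(seed + 1L, length(k_range) * n_folds)
  rows <- lapply(seq_along(k_range), function(ki) {
    k <- k_range[ki]
    per_fold <- cv_fold_labels(x, is_clin, k, folds, n_folds,
                               fit_seeds[(ki - 1L) * n_folds + seq_len(n_folds)],
                               n_restarts, max_iterations, cost,
                               svm_epochs, svm_tol)
    agg <- pairwise_fold_indices(per_fold)
    data.frame(k = k,
               ari_mean = mean(agg$ari), ari_sd = sd0(agg$ari),
               rand_mean = mean(agg$rand), rand_sd = sd0(agg$rand),
               hamming_mean = mean(agg$hamming), hamming_sd = sd0(agg$hamming),
               n_pairs = length(agg$ari))
  })
  tab <- do.call(rbind, rows)
  sel <- tab$k[which.max(tab$ari_mean)] # which.max takes the first = smallest k
  structure(list(table = tab, selected_k = sel, k_range = k_range,
                 n_folds = n_folds, n_restarts = n_restarts, seed = seed),
            class = "hydra_stability")
}

# Fit one hydra per fold (training = controls + out-of-fold clinical).
# Each fold solution carries consensus labels for its training clinical
# subjects plus polytope-predicted labels for the held-out fold, so any
# pair of folds can be compared.
cv_fold_labels <- function(x, is_clin, k, folds, n_folds, seeds,
                           n_restarts, max_iterations, cost,
                           svm_epochs, svm_tol) {
  clin_idx <- which(is_clin)
  rn <- rownames(x) %||% paste0("row_", seq_len(nrow(x)))
  lapply(seq_len(n_folds), function(f) {
    drop_rows <- clin_idx[folds == f]
    keep <- setdiff(seq_len(nrow(x)), drop_rows)
    xf <- x[keep, , drop = FALSE]
    rownames(xf) <- rn[keep]
    fit <- hydra(xf, is_clin[keep], k = k,
                 n_restarts = n_restarts, max_iterations = max_iterations,
                 cost = cost, seed = seeds[f],
                 svm_epochs = svm_epochs, svm_tol = svm_tol)
    held <- stats::setNames(
      predict(fit, x[drop_rows, , drop = FALSE]), rn[drop_rows])
    list(train = fit$labels, full = c(fit$labels, held))
  })
}

# Pairwise fold-solution agreement on the clinical subjects common to both
# training sets; when that set is empty (only possible with 2 folds), the
# solutions are compared on all clinical subjects using the predicted
# labels of each fold's held-out subjects.
pairwise_fold_indices <- function(per_fold) {
  nf <- length(per_fold)
  ari <- rand <- hamming <- numeric(0)
  for (f in seq_len(nf - 1L)) for (g in (f + 1L):nf) {
    shared <- intersect(names(per_fold[[f]]$train), names(per_fold[[g]]$train))
    if (length(shared) >= 2L) {
      a <- per_fold[[f]]$train[shared]; b <- per_fold[[g]]$train[shared]
    } else {
      ids <- names(per_fold[[f]]$full)
      a <- per_fold[[f]]$full[ids]; b <- per_fold[[g]]$full[ids]
    }
    ari <- c(ari, adjusted_rand_index(a, b))
    rand <- c(rand, rand_index(a, b))
    hamming <- c(hamming, hamming_distance(a, b))
  }
  list(ari = ari, rand = rand, hamming = hamming)
}

sd0 <- function(v) if (length(v) < 2L) 0 else stats::sd(v)

#' @export
print.hydra_stability <- function(x, ...) {
  cat(sprintf("Cross-validated stability sweep (%d folds, %d restarts/fit)\n",
              x$n_folds, x$n_restarts))
  print(x$table, row.names = FALSE, digits = 3)
  cat(sprintf("Selected k = %d (highest mean ARI, ties to smaller k)\n",
              x$selected_k))
  invisible(x)
}

#' @export
plot.hydra_stability <- function(x, ...) {
  tab <- x$table
  plot(tab$k, tab$ari_mean, type = "b", pch = 19,
       ylim = range(c(tab$ari_mean - tab$ari_sd, tab$ari_mean + tab$ari_sd)),
       xlab = "number of subtypes k", ylab = "cross-validated ARI",
       main = "Cluster-number stability", ...)
  segments(tab$k, tab$ari_mean - tab$ari_sd, tab$k, tab$ari_mean + tab$ari_sd)
  abline(v = x$selected_k, lty = 2)
  invisible(x)
}

#' Permutation significance of a clustering solution
#'
#' Tests whether the cross-validated stability of the `k`-subtype solution
#' exceeds what arises when the supervised signal is destroyed: at each
#' iteration the clinical/control group labels are shuffled across all
#' subjects (group sizes preserved), the cross-validated mean ARI at `k` is
#' recomputed on the shuffled data, and these form the null distribution.
#' The p-value uses add-one smoothing, `p = (1 + #\{null >= observed\}) /
#' (1 + n_permutations)`, so it is never exactly 0 and ties count against
#' the observed value.
#'
#' @inheritParams cv_stability_sweep
#' @param k Number of subtypes under test (typically the selected one).
#' @param n_permutations Null iterations (desk-scale default 199; increase
#'   to 5000 for publication-grade p-values).
#' @return Object of class `hydra_permutation`: `p_value`,
#'   `observed_ari`, the `null` distribution, and settings.
#' @export
permutation_test <- function(x, group, k, n_permutations = 199, n_folds = 10,
                             n_restarts = 1, max_iterations = 50, cost = 0.25,
                             seed = 1L, svm_epochs = 200, svm_tol = 1e-4) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  x <- as_feature_matrix(x)
  is_clin <- normalize_group(group, nrow(x))
  mean_cv_ari <- function(ic, s) {
    n_cl <- sum(ic)
    folds <- with_seed(s, sample(rep_len(seq_len(n_folds), n_cl)))
    seeds <- derive_seeds(s + 1L, n_folds)
    per_fold <- cv_fold_labels(x, ic, k, folds, n_folds, seeds,
                               n_restarts, max_iterations, cost,
                               svm_epochs, svm_tol)
    mean(pairwise_fold_indices(per_fold)$ari)
  }
  observed <- mean_cv_ari(is_clin, seed)
  perm_seeds <- derive_seeds(seed + 2L, n_permutations)
  null <- vapply(seq_len(n_permutations), function(b) {
    ic_b <- with_seed(perm_seeds[b], sample(is_clin))
    mean_cv_ari(ic_b, perm_seeds[b])
  }, numeric(1))
  structure(list(p_value = perm_pvalue(observed, null),
                 observed_ari = observed, null = null,
                 n_permutations = n_permutations, k = k,
                 n_folds = n_folds, seed = seed),
            class = "hydra_permutation")
}

# Add-one smoothed permutation p-value; ties count as >=.
perm_pvalue <- function(observed, null) {
  (1 + sum(null >= observed)) / (1 + length(null))
}

#' @export
print.hydra_permutation <- function(x, ...) {
  cat(sprintf("Permutation test of clustering significance (k = %d)\n", x$k))
  cat(sprintf("Observed mean CV ARI: %.3f; null mean %.3f (n = %d)\n",
              x$observed_ari, mean(x$null), x$n_permutations))
  cat(sprintf("p = %.4g\n", x$p_value))
  invisible(x)
}
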