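# Shared fixture factories; everything is generated in code at test time.

small_cohort <- function(seed = 1, effect_size = 1.5, n_control = 40,
                         n_clinical = 60, n_rois = 40, n_subtypes = 2, ...) {
  generate_cohort(cohort_spec(
    n_control = n_control, n_clinical = n_clinical, n_rois = n_rois,
    n_subtypes = n_subtypes, affected_fraction = 0.3,
    effect_size = effect_size, seed = seed, ...))
}

adjusted_small_cohort <- function(...) {
  ch <- small_cohort(...)
  list(adj = adjust_covariates(ch$features, ch$records),
       records = ch$records, truth = ch$truth)
}

# Independent brute-force pair-counting oracles for the partition indices.
oracle_pair_counts <- function(a, b) {
  n <- length(a)
  s_both <- s_apart <- s_total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same_a <- a[i] == a[j]; same_b <- b[i] == b[j]
    s_total <- s_total + 1
    if (same_a && same_b) s_both <- s_both + 1
    if (!same_a && !same_b) s_apart <- s_apart + 1
  }
  list(agree = s_both + s_apart, together_both = s_both, total = s_total)
}

oracle_rand <- function(a, b) {
  pc <- oracle_pair_counts(a, b)
  pc$agree / pc$total
}

oracle_ari <- function(a, b) {
  # pair-counting ARI from the contingency table, assembled independently
  # of the package implementation (explicit double loop over cells)
  la <- unique(a); lb <- unique(b)
  nij2 <- ai2 <- bj2 <- 0
  for (u in la) for (v in lb) nij2 <- nij2 + choose(sum(a == u & b == v), 2)
  for (u in la) ai2 <- ai2 + choose(sum(a == u), 2)
  for (v in lb) bj2 <- bj2 + choose(sum(b == v), 2)
  tot <- choose(length(a), 2)
  exp_idx <- ai2 * bj2 / tot
  max_idx <- (ai2 + bj2) / 2
  if (max_idx == exp_idx) return(1)
  (nij2 - exp_idx) / (max_idx - exp_idx)
}

# Exhaustive bijection enumeration for the aligned Hamming distance.
oracle_hamming <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (length(unique(b)) > length(unique(a))) { tmp <- a; a <- b; b <- tmp }
  la <- unique(a); lb <- unique(b)
  perm_list <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perm_list(v[-i]), function(r) c(v[i], r)))
    out
  }
  best <- Inf
  for (pr in perm_list(la)) {
    map <- stats::setNames(pr[seq_along(lb)], lb)
    best <- min(best, mean(map[b] != a))
  }
  best
}

random_label_pair <- function(n, kmax = 4) {
  list(a = sample.int(sample(2:kmax, 1), n, replace = TRUE),
       b = sample.int(sample(2:kmax, 1), n, replace = TRUE))
}
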