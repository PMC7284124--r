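#' Partition agreement indices
#'
#' Pair-counting agreement measures between two labelings of the same
#' subjects, used as cross-validated stability criteria for choosing the
#' number of subtypes: the adjusted Rand index (chance-corrected, `<= 1`,
#' `1` iff identical partitions), the plain Rand index (fraction of subject
#' pairs on which the partitions agree), and the aligned Hamming distance
#' (minimum over label-name bijections of the fraction of mismatched
#' subjects, `0` iff identical partitions). All three are symmetric and
#' invariant to label renaming.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return A single number.
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)) # 1: renaming is free
#' rand_index(c(1, 2), c(1, 1))                      # 0: the one pair disagrees
#' hamming_distance(c(1, 1, 2, 2), c(1, 2, 2, 2))    # 0.25
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  check_pair(labels_a, labels_b)
  tab <- table(labels_a, labels_b)
  n <- length(labels_a)
  s_ij <- sum(choose(tab, 2))
  s_a <- sum(choose(rowSums(tab), 2))
  s_b <- sum(choose(colSums(tab), 2))
  tot <- choose(n, 2)
  expected <- s_a * s_b / tot
  max_idx <- (s_a + s_b) / 2
  if (max_idx == expected) return(1) # both partitions trivial and identical
  (s_ij - expected) / (max_idx - expected)
}

#' @rdname adjusted_rand_index
#' @export
rand_index <- function(labels_a, labels_b) {
  check_pair(labels_a, labels_b)
  n <- length(labels_a)
  if (n < 2) stop("need at least two subjects for pair counting")
  tab <- table(labels_a, labels_b)
  agree <- choose(n, 2) + 2 * sum(choose(tab, 2)) -
    sum(choose(rowSums(tab), 2)) - sum(choose(colSums(tab), 2))
  agree / choose(n, 2)
}

#' @rdname adjusted_rand_index
#' @export
hamming_distance <- function(labels_a, labels_b) {
  check_pair(labels_a, labels_b)
  a <- as.character(labels_a); b <- as.character(labels_b)
  # align the smaller label set onto the larger
  if (length(unique(b)) > length(unique(a))) { tmp <- a; a <- b; b <- tmp }
  bj <- best_bijection(a, b)
  1 - bj$overlap / length(a)
}

check_pair <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty labelings")
  if (length(a) != length(b)) stop("labelings differ in length")
  invisible(TRUE)
}

#' Dice membership consistency between two subtype solutions
#'
#' Measures how consistently two clustering solutions (for example, from
#' two parcellations, or with/without dual-diagnosis subjects) assign the
#' same subjects to the same subtype. Subtypes are first aligned by the
#' label bijection maximizing total overlap on the shared subjects
#' (exhaustive search; k is small in practice), then each aligned pair
#' contributes `dice = 2|A∩B| / (|A| + |B|)`.
#'
#' @param labels_ref Named reference labeling (names are subject IDs).
#' @param labels_other Named comparison labeling; must use the same number
#'   of subtypes.
#' @param shared_ids Optional subject IDs to restrict to; defaults to the
#'   intersection of the two name sets (so solutions computed on different
#'   inclusion criteria compare on their common subjects).
#' @return List with `per_subtype` dice (named by reference subtype),
#'   `overall` (size-weighted mean, equal to the fraction of shared
#'   subjects assigned consistently), the label `mapping` applied to
#'   `labels_other`, and `n_shared`.
#' @export
dice_membership <- function(labels_ref, labels_other, shared_ids = NULL) {
  if (is.null(names(labels_ref)) || is.null(names(labels_other)))
    stop("labelings must be named by subject ID")
  shared_ids <- shared_ids %||% intersect(names(labels_ref), names(labels_other))
  if (!length(shared_ids)) stop("no shared subjects between the labelings")
  a <- labels_ref[shared_ids]
  b <- labels_other[shared_ids]
  ka <- length(unique(a)); kb <- length(unique(b))
  if (ka != kb)
    stop(sprintf("solutions use different numbers of subtypes (%d vs %d)", ka, kb))
  bj <- best_bijection(as.character(a), as.character(b))
  b_aligned <- unname(bj$map[as.character(b)])
  subs <- sort(unique(as.character(a)))
  dice <- vapply(subs, function(s) {
    na <- sum(a == s); nb <- sum(b_aligned == s)
    2 * sum(a == s & b_aligned == s) / (na + nb)
  }, numeric(1))
  # weight by the mean aligned-pair size, so the overall value equals the
  # fraction of shared subjects kept together and is symmetric in its inputs
  sizes <- vapply(subs, function(s)
    (sum(a == s) + sum(b_aligned == s)) / 2, numeric(1))
  list(per_subtype = dice,
       overall = sum(dice * sizes) / sum(sizes),
       mapping = bj$map, n_shared = length(shared_ids))
}
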