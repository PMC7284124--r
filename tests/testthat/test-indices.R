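test_that("index values on hand-checked partitions", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  a <- c(1, 1, 1, 2, 2, 2); b <- c(1, 1, 2, 2, 3, 3)
  expect_equal(adjusted_rand_index(a, b), oracle_ari(a, b), tolerance = 1e-12)

  expect_equal(rand_index(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(rand_index(c(1, 2), c(1, 1)), 0)

  expect_equal(hamming_distance(1:4, 1:4), 0)
  expect_equal(hamming_distance(c(1, 1, 2, 2), c(2, 2, 1, 1)), 0)
  expect_equal(hamming_distance(c(1, 1, 2, 2), c(1, 2, 2, 2)), 0.25)

  expect_error(adjusted_rand_index(1:3, 1:4), "length")
  expect_error(rand_index(integer(0), integer(0)), "empty")
})

test_that("indices agree with brute-force oracles on random partitions", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(5:30, 1)
    pr <- random_label_pair(n)
    expect_equal(adjusted_rand_index(pr$a, pr$b), oracle_ari(pr$a, pr$b),
                 tolerance = 1e-12)
    expect_equal(rand_index(pr$a, pr$b), oracle_rand(pr$a, pr$b),
                 tolerance = 1e-12)
    expect_equal(hamming_distance(pr$a, pr$b), oracle_hamming(pr$a, pr$b),
                 tolerance = 1e-12)
  }
})

test_that("indices are symmetric, renaming-invariant, and consistent at identity", {
  skip_if_not_installed("mclust")
  set.seed(7)
  for (i in 1:50) {
    pr <- random_label_pair(sample(6:25, 1))
    a <- pr$a; b <- pr$b
    expect_equal(adjusted_rand_index(a, b), adjusted_rand_index(b, a))
    expect_equal(rand_index(a, b), rand_index(b, a))
    expect_equal(hamming_distance(a, b), hamming_distance(b, a))
    # renaming b leaves all indices unchanged
    perm <- sample(max(b))
    b2 <- perm[b]
    expect_equal(adjusted_rand_index(a, b2), adjusted_rand_index(a, b))
    expect_equal(hamming_distance(a, b2), hamming_distance(a, b))
    # independent cross-check of ARI
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
    # identity relations: ARI = 1 iff Rand = 1 iff Hamming = 0
    same <- hamming_distance(a, b) == 0
    expect_equal(rand_index(a, b) == 1, same)
    expect_equal(adjusted_rand_index(a, b) == 1, same)
  }
})

test_that("dice membership consistency aligns labels and counts overlap", {
  ids <- paste0("s", 1:8)
  a <- stats::setNames(rep(1:2, each = 4), ids)
  expect_equal(dice_membership(a, a)$per_subtype, c(`1` = 1, `2` = 1))
  # renamed labels align to dice 1
  b <- stats::setNames(rep(c(2, 1), each = 4), ids)
  expect_equal(unname(dice_membership(a, b)$per_subtype), c(1, 1))
  # hand-counted example: one swap in each direction
  b2 <- stats::setNames(c(1, 1, 1, 2, 1, 2, 2, 2), ids)
  d <- dice_membership(a, b2)
  expect_equal(unname(d$per_subtype), c(0.75, 0.75))
  expect_equal(d$overall, 0.75)
  # shared-subject restriction and k mismatch
  b3 <- stats::setNames(rep(1:2, each = 3), paste0("s", 3:8))
  expect_equal(dice_membership(a, b3)$n_shared, 6)
  expect_error(dice_membership(a, stats::setNames(rep(1, 8), ids)),
               "different numbers")
  expect_error(dice_membership(a, stats::setNames(1:2, c("x1", "x2"))),
               "no shared")
})

test_that("dice is symmetric on a common subject set and 1 only at identity", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(8:20, 1)
    ids <- paste0("s", seq_len(n))
    a <- stats::setNames(sample(1:3, n, replace = TRUE), ids)
    b <- stats::setNames(sample(1:3, n, replace = TRUE), ids)
    if (length(unique(a)) != length(unique(b))) next
    expect_equal(dice_membership(a, b)$overall, dice_membership(b, a)$overall,
                 tolerance = 1e-12)
    if (dice_membership(a, b)$overall == 1)
      expect_equal(hamming_distance(a, b), 0)
  }
})
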