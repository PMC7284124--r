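test_that("k = 1 degenerates to a single case-control max-margin classifier", {
  ch <- small_cohort(seed = 6, n_control = 30, n_clinical = 30, n_rois = 20)
  adj <- adjust_covariates(ch$features, ch$records)
  grp <- ch$records$group
  fit <- hydra(adj, grp, k = 1, n_restarts = 3, seed = 2)
  expect_true(all(fit$labels == 1))

  # the same classifier fit directly on the standardized features
  x <- unclass(adj)
  xs <- scale(x)
  y <- ifelse(grp == "clinical", 1, -1)
  m <- linear_svm(xs, y, cost = fit$cost, seed = 2,
                  max_epochs = 200, tol = 1e-4)
  d_direct <- predict(m, xs)
  d_hydra <- predict(fit, x, type = "decision")[, 1]
  expect_equal(unname(d_hydra), unname(d_direct), tolerance = 1e-8)
})

test_that("separable planted subtypes are recovered exactly", {
  ch <- small_cohort(seed = 8, effect_size = 2.0, n_control = 40,
                     n_clinical = 50, n_rois = 40)
  adj <- adjust_covariates(ch$features, ch$records)
  fit <- hydra(adj, ch$records$group, k = 2, n_restarts = 10, seed = 3)
  truth <- ch$truth$subtype[names(fit$labels)]
  expect_equal(adjusted_rand_index(fit$labels, truth), 1)
  # training subjects reassigned by the consensus polytope agree with the
  # stored consensus labels almost everywhere
  clin <- ch$records$group == "clinical"
  re <- predict(fit, unclass(adj)[clin, , drop = FALSE])
  expect_gte(mean(re == unname(fit$labels)), 0.95)
})

test_that("fitting is deterministic and the coassignment matrix is well-formed", {
  ch <- small_cohort(seed = 10, n_control = 25, n_clinical = 30, n_rois = 15)
  adj <- adjust_covariates(ch$features, ch$records)
  f1 <- hydra(adj, ch$records$group, k = 2, n_restarts = 5, seed = 11)
  f2 <- hydra(adj, ch$records$group, k = 2, n_restarts = 5, seed = 11)
  expect_identical(f1$labels, f2$labels)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$coassignment, f2$coassignment)

  co <- f1$coassignment
  expect_equal(unname(diag(co)), rep(1, nrow(co)))
  expect_equal(co, t(co))
  expect_true(all(co >= 0 & co <= 1))
  # single restart: consensus equals that restart's labels
  f3 <- hydra(adj, ch$records$group, k = 2, n_restarts = 1, seed = 4)
  single <- hydracluster:::fit_polytope_once(
    scale(unclass(adj)), ch$records$group == "clinical", 2, f3$cost, 50,
    hydracluster:::derive_seeds(4, 1)[1])
  expect_equal(unname(f3$labels), single$labels)
})

test_that("recovery degrades monotonically as the planted effect shrinks", {
  effect_sizes <- c(2.0, 1.0, 0.5, 0.0)
  med_ari <- vapply(effect_sizes, function(es) {
    aris <- vapply(1:5, function(s) {
      ch <- small_cohort(seed = 300 + s, effect_size = es, n_control = 30,
                         n_clinical = 40, n_rois = 30)
      adj <- adjust_covariates(ch$features, ch$records)
      fit <- hydra(adj, ch$records$group, k = 2, n_restarts = 5, seed = s)
      adjusted_rand_index(fit$labels, ch$truth$subtype[names(fit$labels)])
    }, numeric(1))
    median(aris)
  }, numeric(1))
  expect_true(all(diff(med_ari) <= 0.05)) # near-zero ARI jitters by a few %
})

test_that("alternating optimization approaches the enumerated optimum at tiny n", {
  # exhaustive oracle: all 2-subtype assignments of <= 8 clinical subjects
  enum_best <- function(xs, is_clin, cost) {
    n_clin <- sum(is_clin)
    best <- Inf
    for (code in 0:(2^n_clin - 1)) {
      lab <- as.integer(intToBits(code))[seq_len(n_clin)] + 1L
      if (length(unique(lab)) < 2L) next
      obj <- hydracluster:::fit_faces(xs, is_clin, lab, 2, cost, 1)$objective
      best <- min(best, obj)
    }
    best
  }
  set.seed(17)
  hits <- 0; n_inst <- 12
  for (i in seq_len(n_inst)) {
    n_ctrl <- 10; n_clin <- 7; p <- 4
    x <- matrix(rnorm((n_ctrl + n_clin) * p), n_ctrl + n_clin, p)
    shift <- sample(c(-1.5, 1.5), n_clin, replace = TRUE)
    x[n_ctrl + seq_len(n_clin), 1] <- x[n_ctrl + seq_len(n_clin), 1] + shift
    is_clin <- c(rep(FALSE, n_ctrl), rep(TRUE, n_clin))
    xs <- scale(x)
    opt <- enum_best(xs, is_clin, 0.25)
    reached <- min(vapply(1:5, function(s)
      hydracluster:::fit_polytope_once(xs, is_clin, 2, 0.25, 50, s)$objective,
      numeric(1)))
    if (reached <= opt * 1.05 + 1e-9) hits <- hits + 1
  }
  expect_gte(hits, ceiling(0.9 * n_inst))
})

test_that("prediction honours the tie rule and validates dimensions", {
  ch <- small_cohort(seed = 12, n_control = 20, n_clinical = 20, n_rois = 10)
  adj <- adjust_covariates(ch$features, ch$records)
  fit <- hydra(adj, ch$records$group, k = 2, n_restarts = 3, seed = 5)
  expect_error(predict(fit, matrix(0, 2, 3)), "dimension mismatch")

  # duplicate faces force exact ties on every subject: tie rule picks face 1
  tied <- fit
  tied$weights[2, ] <- tied$weights[1, ]
  tied$intercepts[2] <- tied$intercepts[1]
  expect_true(all(predict(tied, unclass(adj)) == 1L))

  k1 <- hydra(adj, ch$records$group, k = 1, n_restarts = 1, seed = 5)
  expect_true(all(predict(k1, unclass(adj)) == 1L))
})

test_that("degenerate inputs are rejected", {
  ch <- small_cohort(seed = 13, n_control = 10, n_clinical = 8, n_rois = 6)
  adj <- adjust_covariates(ch$features, ch$records)
  grp <- ch$records$group
  expect_error(hydra(adj, grp, k = 9), "fewer clinical")
  expect_error(hydra(adj, rep("clinical", nrow(adj)), k = 2), "no control")
  bad <- unclass(adj); bad[1, 1] <- NA
  expect_error(hydra(bad, grp, k = 2), "non-finite")
  expect_error(hydra(adj, grp[-1], k = 2), "length")
})
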