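#' Semi-supervised max-margin subtyping (HYDRA-style polytope clustering)
#'
#' Finds `k` subtypes within the clinical group while each subtype is
#' separated from the control group by its own regularized max-margin
#' hyperplane; together the `k` hyperplanes form a convex polytope enclosing
#' the controls. Clustering and classification are thus performed
#' simultaneously: subjects cluster according to their direction of
#' deviation from controls rather than by overall similarity, which keeps
#' non-pathophysiological variation from driving the partition.
#'
#' One restart alternates (a) fitting, for each subtype, a weighted linear
#' hinge-loss classifier of that subtype's members (positive) against all
#' controls (negative, each control down-weighted by `1/k` so the control
#' class does not dominate the polytope); and (b) reassigning every clinical
#' subject to the face with the largest decision value, until assignments
#' are stable or `max_iterations` is reached. A subtype emptied during
#' reassignment is reseeded with the clinical subject whose best decision
#' value is lowest (the subject the current polytope explains worst).
#' Restart label sets are aggregated into a co-assignment frequency matrix;
#' consensus labels cut an average-linkage tree of `1 - coassignment` into
#' `k` groups, and the polytope is refit once from the consensus labels.
#'
#' Features should be nuisance-adjusted first (see [adjust_covariates()]);
#' they are per-ROI z-scored internally by default, as margin methods are
#' scale-sensitive.
#'
#' @param x Feature matrix or [feature_table()] (all subjects).
#' @param group Group indicator per row of `x`: `"clinical"`/`"control"`, or
#'   logical (`TRUE` = clinical).
#' @param k Number of subtypes (`k = 1` degenerates to an ordinary
#'   case-control max-margin classifier).
#' @param n_restarts Random restarts aggregated by consensus.
#' @param max_iterations Cap on assign/refit alternations per restart.
#' @param cost Margin-violation penalty C of each face.
#' @param standardize Per-ROI z-scoring before fitting (recommended).
#' @param seed Master seed; restart seeds derive from it deterministically.
#' @param consensus_trim Relative objective slack defining which restarts
#'   vote in the consensus: only restarts whose objective is within this
#'   fraction of the best restart's. The reported co-assignment matrix
#'   always covers all restarts.
#' @param svm_epochs,svm_tol Inner solver controls (see [linear_svm()]).
#' @return Object of class `hydra`: consensus `labels` (named by clinical
#'   subject), `weights` (k x ROI matrix), `intercepts`, `objective`,
#'   `coassignment`, `converged` (fraction of converged restarts),
#'   standardization parameters, and the configuration.
#' @seealso [cv_stability_sweep()] to choose `k`, [permutation_test()] for
#'   its significance, [predict.hydra()] to label new subjects.
#' @export
hydra <- function(x, group, k = 2, n_restarts = 20, max_iterations = 50,
                  cost = 0.25, standardize = TRUE, seed = 1L,
                  consensus_trim = 0.10, svm_epochs = 200, svm_tol = 1e-4) {
  x <- as_feature_matrix(x)
  is_clin <- normalize_group(group, nrow(x))
  if (any(!is.finite(x))) stop("non-finite feature values")
  if (k < 1) stop("k must be >= 1")
  if (sum(is_clin) < k) stop("fewer clinical subjects than k")
  if (!any(!is_clin)) stop("no control subjects")
  if (n_restarts < 1) stop("n_restarts must be >= 1")

  ctr <- if (standardize) colMeans(x) else rep(0, ncol(x))
  scl <- if (standardize) apply(x, 2, stats::sd) else rep(1, ncol(x))
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")

  seeds <- derive_seeds(seed, n_restarts)
  n_clin <- sum(is_clin)
  co <- matrix(0, n_clin, n_clin)
  fits <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    fits[[r]] <- fit_polytope_once(xs, is_clin, k, cost, max_iterations,
                                   seeds[r], svm_epochs, svm_tol)
    co <- co + outer(fits[[r]]$labels, fits[[r]]$labels, "==")
  }
  co <- co / n_restarts

  objs <- vapply(fits, `[[`, numeric(1), "objective")
  best <- which.min(objs)
  if (k == 1L || n_clin == 1L) {
    labels <- rep(1L, n_clin)
  } else {
    # Consensus vote restricted to restarts near the best objective: deep
    # local optima carry the subtype signal, shallow ones only blur it. The
    # reported coassignment matrix still covers every restart.
    keep <- which(objs <= min(objs) * (1 + consensus_trim))
    co_vote <- matrix(0, n_clin, n_clin)
    for (r in keep)
      co_vote <- co_vote + outer(fits[[r]]$labels, fits[[r]]$labels, "==")
    hc <- hclust(as.dist(1 - co_vote / length(keep)), method = "average")
    labels <- unname(cutree(hc, k = k))
    if (k <= 8L) labels <- align_labels(fits[[best]]$labels, labels)
  }

  final <- fit_faces(xs, is_clin, labels, k, cost, seed, svm_epochs, svm_tol)
  clin_ids <- rownames(x)[is_clin] %||% paste0("clin_", seq_len(n_clin))
  dimnames(co) <- list(clin_ids, clin_ids)

  structure(list(
    labels = stats::setNames(as.integer(labels), clin_ids),
    k = as.integer(k),
    weights = final$W, intercepts = final$b,
    objective = final$objective,
    coassignment = co,
    converged = mean(vapply(fits, `[[`, logical(1), "converged")),
    restart_objectives = vapply(fits, `[[`, numeric(1), "objective"),
    center = ctr, scale = scl, standardize = standardize,
    cost = cost, n_restarts = n_restarts, max_iterations = max_iterations,
    seed = seed, n_control = sum(!is_clin), n_clinical = n_clin,
    call = match.call()), class = "hydra")
}

# Accept "clinical"/"control" labels or a logical vector.
normalize_group <- function(group, n) {
  if (is.logical(group)) {
    is_clin <- group
  } else {
    g <- as.character(group)
    if (!all(g %in% c("clinical", "control")))
      stop("group must be 'clinical'/'control' or logical")
    is_clin <- g == "clinical"
  }
  if (length(is_clin) != n) stop("group length != number of subjects")
  is_clin
}

# One alternating-optimization restart on standardized features.
# Each restart is seeded from k random clinical deviation directions:
# k distinct clinical subjects are drawn, their (unit-normalized) offsets
# from the control centroid act as provisional face normals, and every
# clinical subject starts on the face of largest projection. Purely random
# label initialization loses the directional structure the polytope is
# meant to find and stalls in shallow local optima.
fit_polytope_once <- function(xs, is_clin, k, cost, max_iterations, seed,
                              svm_epochs = 200, svm_tol = 1e-4) {
  n_clin <- sum(is_clin)
  Xc_dev <- sweep(xs[is_clin, , drop = FALSE], 2, colMeans(xs[!is_clin, , drop = FALSE]))
  labels <- with_seed(seed, {
    anchors <- sample.int(n_clin, k)
    Wr <- Xc_dev[anchors, , drop = FALSE]
    nrm <- sqrt(rowSums(Wr^2)); nrm[nrm == 0] <- 1
    lab <- max.col(Xc_dev %*% t(Wr / nrm), ties.method = "first")
    lab[anchors] <- seq_len(k) # anchors pin their own face: no empty start
    lab
  })
  converged <- FALSE
  iterations <- 0L
  fit <- fit_faces(xs, is_clin, labels, k, cost, seed, svm_epochs, svm_tol)
  for (it in seq_len(max_iterations)) {
    iterations <- it
    D <- decision_matrix(xs[is_clin, , drop = FALSE], fit$W, fit$b)
    new_labels <- max.col(D, ties.method = "first")
    empties <- which(tabulate(new_labels, k) == 0L)
    if (length(empties)) {
      worst <- order(apply(D, 1, max)) # least well explained first
      used <- integer(0)
      for (j in empties) {
        pick <- worst[!worst %in% used][1L]
        new_labels[pick] <- j
        used <- c(used, pick)
      }
    }
    if (identical(new_labels, labels)) { converged <- TRUE; break }
    labels <- new_labels
    fit <- fit_faces(xs, is_clin, labels, k, cost, seed, svm_epochs, svm_tol)
  }
  list(labels = labels, W = fit$W, b = fit$b, objective = fit$objective,
       converged = converged, iterations = iterations)
}

# Fit the k polytope faces for a fixed assignment; controls weighted 1/k.
fit_faces <- function(xs, is_clin, labels, k, cost, seed,
                      svm_epochs = 200, svm_tol = 1e-4) {
  Xn <- xs[!is_clin, , drop = FALSE]
  Xc <- xs[is_clin, , drop = FALSE]
  p <- ncol(xs)
  W <- matrix(0, k, p, dimnames = list(NULL, colnames(xs)))
  b <- numeric(k)
  obj <- 0
  wt_ctrl <- rep(1 / k, nrow(Xn))
  for (j in seq_len(k)) {
    members <- which(labels == j)
    if (!length(members))
      stop("internal error: empty subtype reached face fitting")
    Xj <- rbind(Xn, Xc[members, , drop = FALSE])
    yj <- c(rep(-1, nrow(Xn)), rep(1, length(members)))
    wj <- c(wt_ctrl, rep(1, length(members)))
    m <- linear_svm(Xj, yj, cost = cost, weights = wj,
                    max_epochs = svm_epochs, tol = svm_tol, seed = seed)
    W[j, ] <- m$w
    b[j] <- m$b
    obj <- obj + svm_objective(m$w, m$b, Xj, yj, cost * wj, m$bias_scale)
  }
  list(W = W, b = b, objective = obj)
}

decision_matrix <- function(x, W, b) {
  sweep(x %*% t(W), 2, b, "+")
}

#' Assign subjects to the subtypes of a fitted polytope
#'
#' Labels each row of `newdata` with the polytope face of largest decision
#' value \eqn{w_j^\top x + b_j}; ties go to the lowest subtype index.
#'
#' @param object A fitted [hydra()] model.
#' @param newdata Feature matrix on the model's ROIs (raw scale; the model's
#'   stored standardization is applied).
#' @param type `"class"` for subtype labels, `"decision"` for the
#'   subjects-by-k decision-value matrix.
#' @param ... Unused.
#' @return Integer subtype labels, or the decision matrix.
#' @export
predict.hydra <- function(object, newdata, type = c("class", "decision"), ...) {
  type <- match.arg(type)
  newdata <- as_feature_matrix(newdata)
  if (ncol(newdata) != ncol(object$weights))
    stop("feature dimension mismatch: model has ", ncol(object$weights), " ROIs")
  xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  D <- decision_matrix(xs, object$weights, object$intercepts)
  if (type == "decision") return(D)
  as.integer(max.col(D, ties.method = "first"))
}

#' @export
print.hydra <- function(x, ...) {
  cat(sprintf("HYDRA polytope model: k = %d subtypes, %d clinical vs %d controls\n",
              x$k, x$n_clinical, x$n_control))
  cat("Subtype sizes:", paste(tabulate(x$labels, x$k), collapse = " / "), "\n")
  cat(sprintf("Objective %.4f; %.0f%% of %d restarts converged\n",
              x$objective, 100 * x$converged, x$n_restarts))
  invisible(x)
}

#' @export
summary.hydra <- function(object, n_top = 5, ...) {
  sizes <- tabulate(object$labels, object$k)
  top <- lapply(seq_len(object$k), function(j) {
    w <- object$weights[j, ]
    names(sort(abs(w), decreasing = TRUE))[seq_len(min(n_top, length(w)))]
  })
  out <- list(k = object$k, sizes = sizes, objective = object$objective,
              converged = object$converged,
              mean_coassignment = mean(object$coassignment[
                upper.tri(object$coassignment)]),
              top_rois = top)
  class(out) <- "summary.hydra"
  out
}

#' @export
print.summary.hydra <- function(x, ...) {
  cat(sprintf("HYDRA solution with k = %d subtypes (sizes %s)\n",
              x$k, paste(x$sizes, collapse = ", ")))
  cat(sprintf("Final objective: %.4f; restart convergence: %.0f%%\n",
              x$objective, 100 * x$converged))
  cat(sprintf("Mean off-diagonal co-assignment: %.3f\n", x$mean_coassignment))
  for (j in seq_along(x$top_rois))
    cat(sprintf("  subtype %d top |weight| ROIs: %s\n", j,
                paste(x$top_rois[[j]], collapse = ", ")))
  invisible(x)
}

#' @export
coef.hydra <- function(object, ...) {
  cbind(`(Intercept)` = object$intercepts, object$weights)
}

#' Co-assignment heatmap of a HYDRA solution
#'
#' Displays the restart co-assignment frequency matrix with subjects ordered
#' by consensus subtype; block structure along the diagonal indicates a
#' stable partition.
#'
#' @param x A fitted [hydra()] model.
#' @param ... Passed to [graphics::image()].
#' @export
plot.hydra <- function(x, ...) {
  ord <- order(x$labels)
  m <- x$coassignment[ord, ord]
  image(seq_len(nrow(m)), seq_len(ncol(m)), m[, rev(seq_len(ncol(m)))],
        zlim = c(0, 1), xlab = "clinical subjects (by subtype)",
        ylab = "", axes = FALSE,
        main = sprintf("Co-assignment over %d restarts (k = %d)",
                       x$n_restarts, x$k), ...)
  invisible(x)
}
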