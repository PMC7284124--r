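#' Regularized linear max-margin classifier
#'
#' Fits the instance-weighted L1-loss (hinge) linear support-vector machine
#'
#' \deqn{\min_w \tfrac12 \lVert w\rVert^2 + \sum_i C_i \max(0,\, 1 - y_i w^\top x_i)}
#'
#' by dual coordinate descent with randomly permuted sweeps. The bias term is
#' carried as an augmented constant feature of value `bias_scale`, so it is
#' weakly regularized. This is the face primitive of the max-margin polytope
#' used by [hydra()]: each polytope face is one such classifier separating
#' all controls from one clinical subtype.
#'
#' @param x Numeric matrix, observations in rows.
#' @param y Class labels: `+1`/`-1` numeric, or logical (`TRUE` = positive).
#' @param cost Margin-violation penalty C (> 0).
#' @param weights Optional per-observation multipliers of `cost` (e.g. to
#'   down-weight an over-represented class).
#' @param bias_scale Value of the augmented bias feature.
#' @param max_epochs,tol Dual coordinate descent sweep cap and stopping
#'   tolerance on the largest projected gradient.
#' @param seed Seed of the coordinate-permutation stream (the optimum of the
#'   strictly convex primal does not depend on it; determinism of the exact
#'   floating-point result does).
#' @return An object of class `linear_svm` with elements `w` (named weight
#'   vector), `b`, `alpha` (dual variables), `cost`, `converged`, `epochs`.
#' @export
linear_svm <- function(x, y, cost = 0.25, weights = NULL, bias_scale = 1,
                       max_epochs = 2000, tol = 1e-8, seed = 1L) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (is.logical(y)) y <- ifelse(y, 1, -1)
  if (!all(y %in% c(-1, 1))) stop("y must be +1/-1 (or logical)")
  if (length(y) != nrow(x)) stop("length(y) != nrow(x)")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (cost <= 0) stop("cost must be positive")
  if (any(!is.finite(x))) stop("non-finite feature values")
  weights <- weights %||% rep(1, nrow(x))
  fit <- .dcd_svm(t(x), as.numeric(y), cost * weights, bias_scale,
                  as.integer(max_epochs), tol, as.integer(seed))
  structure(list(w = stats::setNames(fit$w, colnames(x)), b = fit$b,
                 alpha = fit$alpha, cost = cost, bias_scale = bias_scale,
                 converged = fit$converged, epochs = fit$epochs),
            class = "linear_svm")
}

#' @param object A `linear_svm` fit.
#' @param newdata Matrix of observations to score.
#' @param type `"decision"` for signed decision values `w'x + b`,
#'   `"class"` for their signs.
#' @param ... Unused.
#' @rdname linear_svm
#' @export
predict.linear_svm <- function(object, newdata, type = c("decision", "class"), ...) {
  type <- match.arg(type)
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != length(object$w)) stop("feature dimension mismatch")
  d <- drop(newdata %*% object$w + object$b)
  if (type == "decision") d else ifelse(d >= 0, 1, -1)
}

#' @export
print.linear_svm <- function(x, ...) {
  cat(sprintf("Linear max-margin classifier: %d features, C = %g, %s in %d epochs\n",
              length(x$w), x$cost,
              if (x$converged) "converged" else "epoch cap reached", x$epochs))
  invisible(x)
}

# Primal objective of the (augmented-bias) weighted hinge SVM.
svm_objective <- function(w, b, x, y, costvec, bias_scale = 1) {
  margins <- y * (drop(x %*% w) + b)
  0.5 * (sum(w^2) + (b / bias_scale)^2) + sum(costvec * pmax(0, 1 - margins))
}
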