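#' Remove nuisance-covariate effects from a feature table
#'
#' Regresses every ROI on the named covariates (age and handedness by
#' default) by ordinary least squares and returns the residuals. By default
#' the fit uses the pooled sample (controls + clinical); `method =
#' "control_only"` estimates the covariate slopes on controls alone and
#' subtracts them from everyone, a common alternative when clinical effects
#' might leak into the nuisance model. Residuals are centered; after pooled
#' adjustment each ROI is numerically orthogonal to every covariate.
#'
#' @param features A [feature_table()] or numeric matrix.
#' @param records Subject metadata with a `subject_id` column and one column
#'   per covariate, in the same subject order as `features`.
#' @param covariates Covariate column names; constant covariates are dropped
#'   with a warning, missing values are an error.
#' @param method Sample on which the slopes are estimated.
#' @return A `feature_table` of residuals, same dimensions and names.
#' @export
adjust_covariates <- function(features, records,
                              covariates = c("age", "handedness"),
                              method = c("pooled", "control_only")) {
  method <- match.arg(method)
  x <- as_feature_matrix(features)
  if (nrow(x) != nrow(records))
    stop("features and records have different numbers of subjects")
  missing_cov <- setdiff(covariates, names(records))
  if (length(missing_cov))
    stop("covariates not in records: ", paste(missing_cov, collapse = ", "))
  Z <- as.matrix(records[, covariates, drop = FALSE])
  if (!is.numeric(Z)) stop("covariates must be numeric")
  if (anyNA(Z)) stop("missing covariate values; complete the records first")
  keep <- apply(Z, 2, function(v) stats::sd(v) > 0)
  if (!all(keep)) {
    warning("dropping constant covariate(s): ",
            paste(covariates[!keep], collapse = ", "))
    Z <- Z[, keep, drop = FALSE]
  }

  if (method == "pooled" || ncol(Z) == 0L) {
    X <- cbind(1, Z)
    fit <- lm.fit(X, x)
    res <- fit$residuals
  } else {
    ctrl <- records$group == "control"
    if (!any(ctrl)) stop("control_only adjustment requires control subjects")
    Zc <- scale(Z, center = TRUE, scale = FALSE) # center on pooled means
    fit <- lm.fit(cbind(1, Zc[ctrl, , drop = FALSE]), x[ctrl, , drop = FALSE])
    beta <- fit$coefficients[-1, , drop = FALSE]
    beta[is.na(beta)] <- 0
    res <- scale(x - Zc %*% beta, center = TRUE, scale = FALSE)
  }
  dimnames(res) <- dimnames(x)
  feature_table(res, attr(features, "parameter") %||% "CT",
                attr(features, "atlas_id") %||% "atlas")
}
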