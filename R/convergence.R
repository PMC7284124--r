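#' Conjunction of significant-ROI masks
#'
#' Intersects two or more masks of significant ROIs (e.g. the subtype-vs-
#' control results of several analysis configurations) to find the regions
#' consistently altered across all of them. All masks must live on the same
#' atlas; project masks from other parcellations first with
#' [project_mask()].
#'
#' @param masks List (optionally named by configuration) of character
#'   vectors of ROI IDs.
#' @param atlas_ids Optional atlas label per mask; if given, they must all
#'   agree.
#' @return List with `configuration_ids` and the sorted `mask`
#'   intersection.
#' @export
conjunction_mask <- function(masks, atlas_ids = NULL) {
  if (!is.list(masks) || length(masks) < 2)
    stop("need at least two masks")
  if (!is.null(atlas_ids) && length(unique(atlas_ids)) > 1)
    stop("masks come from different atlases; project to a common atlas first")
  list(configuration_ids = names(masks) %||% seq_along(masks),
       mask = sort(Reduce(intersect, masks)))
}

#' Project an ROI mask onto another parcellation
#'
#' Carries a mask from the source atlas of a crosswalk to its target atlas:
#' a target ROI is kept iff the fraction of its area covered by masked
#' source ROIs reaches `threshold`. The normalization by the target's total
#' overlap makes the rule work in both the fine-to-coarse and the
#' coarse-to-fine direction (a raw row-stochastic sum can never reach 0.5
#' for a fine target sitting inside one coarse source ROI).
#'
#' @param mask Character vector of source-atlas ROI IDs.
#' @param crosswalk Row-stochastic overlap matrix from
#'   [generate_crosswalk()] (rows = source ROIs).
#' @param threshold Minimum covered fraction of a target ROI for inclusion.
#' @return Character vector of target-atlas ROI IDs.
#' @export
project_mask <- function(mask, crosswalk, threshold = 0.5) {
  if (length(mask) == 0L) return(character(0))
  unknown <- setdiff(mask, rownames(crosswalk))
  if (length(unknown))
    stop("mask ROIs missing from crosswalk: ", paste(unknown, collapse = ", "))
  w <- attr(crosswalk, "source_widths") %||%
    rep(1 / nrow(crosswalk), nrow(crosswalk))
  L <- crosswalk * w                      # absolute overlap areas
  covered <- colSums(L[mask, , drop = FALSE]) / colSums(L)
  colnames(crosswalk)[covered >= threshold]
}

#' Per-network percentages of altered regions
#'
#' Summarizes a mask of altered ROIs over the resting-state networks of an
#' atlas. The reported default percentage is the fraction of each network
#' that is altered (`100 * |mask ∩ network| / |network|`); the complementary
#' view — what fraction of the mask falls in each network — is returned
#' alongside.
#'
#' @param mask Character vector of ROI IDs.
#' @param mapping Atlas mapping from [generate_atlas_mapping()] (columns
#'   `roi_id`, `network`; every network non-empty).
#' @return Data frame with one row per network: `n_rois`, `n_altered`,
#'   `pct_of_network`, `pct_of_mask`.
#' @export
network_percentages <- function(mask, mapping) {
  if (!all(c("roi_id", "network") %in% names(mapping)))
    stop("mapping must have columns roi_id and network")
  if (any(table(mapping$network) == 0L) || anyDuplicated(mapping$roi_id))
    stop("invalid atlas mapping")
  unknown <- setdiff(mask, mapping$roi_id)
  if (length(unknown))
    stop("mask ROIs missing from mapping: ", paste(unknown, collapse = ", "))
  nets <- sort(unique(mapping$network))
  n_rois <- vapply(nets, function(nw) sum(mapping$network == nw), numeric(1))
  n_alt <- vapply(nets, function(nw)
    sum(mapping$roi_id[mapping$network == nw] %in% mask), numeric(1))
  data.frame(network = nets, n_rois = n_rois, n_altered = n_alt,
             pct_of_network = 100 * n_alt / n_rois,
             pct_of_mask = if (length(mask)) 100 * n_alt / length(mask) else 0,
             row.names = NULL)
}
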