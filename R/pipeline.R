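#' Configure a full subtyping pipeline run
#'
#' Collects every setting of the end-to-end analysis: cohort source
#' (synthetic [cohort_spec()] or TSV paths), nuisance covariates, the
#' cluster-number sweep, the permutation test, subtype characterization,
#' and the cross-atlas / inclusion-criteria consistency grid.
#'
#' @param cohort A [cohort_spec()] to simulate from, or a
#'   `list(feature_path=, metadata_path=)` to ingest.
#' @param covariates Nuisance covariates removed before fitting.
#' @param k_range Candidate numbers of subtypes.
#' @param n_folds Cross-validation folds for the stability sweep.
#' @param n_permutations Permutation iterations for the significance test.
#' @param n_restarts Consensus restarts for the final per-cell fits.
#' @param cv_restarts,perm_restarts Restarts inside sweep / permutation
#'   fits (smaller, for tractability).
#' @param max_iterations,cost [hydra()] controls.
#' @param alpha Significance level.
#' @param cross_atlas Also run on a second, coarser parcellation reached
#'   through an ROI-overlap crosswalk.
#' @param n_rois_b Size of the second parcellation (default: scaled to
#'   about 37% of the first, mimicking a 400-to-148 region pair).
#' @param n_networks Resting-state networks for the conjunction summary.
#' @param with_dual_criterion Also rerun excluding dual-diagnosis subjects.
#' @param seed Master seed; fixes the entire report bit-identically.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            covariates = c("age", "handedness"),
                            k_range = 2:10, n_folds = 10,
                            n_permutations = 199, n_restarts = 20,
                            cv_restarts = 5, perm_restarts = 1,
                            max_iterations = 50, cost = 0.25, alpha = 0.05,
                            cross_atlas = TRUE, n_rois_b = NULL,
                            n_networks = 7, with_dual_criterion = TRUE,
                            seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full transdiagnostic subtyping pipeline
#'
#' Executes, under one master seed: cohort simulation or ingestion;
#' nuisance-covariate adjustment; the cross-validated cluster-number sweep;
#' the permutation significance test at the selected k; a consensus HYDRA
#' fit, diagnosis-by-subtype chi-square, clinical-variable comparisons and
#' FDR-corrected ROI-wise subtype-vs-control comparisons for every
#' (atlas x inclusion-criterion) cell; dice membership consistency of every
#' cell against the reference cell; conjunction masks of the ROI results
#' across cells with per-network percentages; and a conventional ROI-wise
#' three-group diagnostic ANOVA. A fixed seed reproduces the report
#' bit-identically.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `run_report` (a nested list mirroring the stage
#'   outputs; see [write_report()]).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- derive_seeds(config$seed, 8L)

  # --- stage: cohort -------------------------------------------------------
  if (inherits(config$cohort, "cohort_spec")) {
    cohort <- generate_cohort(config$cohort)
  } else {
    cohort <- read_cohort(config$cohort$feature_path, config$cohort$metadata_path)
  }
  features_a <- cohort$features
  records <- cohort$records
  n_rois <- ncol(features_a)
  atlas_a <- attr(features_a, "atlas_id") %||% "atlasA"

  mapping_a <- generate_atlas_mapping(n_rois, config$n_networks,
                                      seed = seeds[1], atlas_id = atlas_a)
  atlases <- list()
  atlases[[atlas_a]] <- list(features = features_a, mapping = mapping_a,
                             to_ref = NULL)
  if (isTRUE(config$cross_atlas)) {
    nb <- config$n_rois_b %||% max(config$n_networks, round(0.37 * n_rois))
    mapping_b <- generate_atlas_mapping(nb, config$n_networks,
                                        seed = seeds[2], atlas_id = "atlasB")
    cw_ab <- generate_crosswalk(mapping_a, mapping_b, seed = seeds[3])
    cw_ba <- generate_crosswalk(mapping_b, mapping_a, seed = seeds[3])
    atlases[["atlasB"]] <- list(
      features = project_features(features_a, cw_ab, atlas_id = "atlasB"),
      mapping = mapping_b, to_ref = cw_ba)
  }

  inclusions <- c("all", if (isTRUE(config$with_dual_criterion)) "no_dual")
  cells <- expand.grid(atlas = names(atlases), inclusion = inclusions,
                       stringsAsFactors = FALSE)
  ref_cell <- paste(names(atlases)[1], "all", sep = "_")

  # --- stage: model selection on the reference cell ------------------------
  adj_ref <- adjust_covariates(features_a, records, config$covariates)
  group <- records$group
  sweep_res <- cv_stability_sweep(adj_ref, group, k_range = config$k_range,
                                  n_folds = config$n_folds,
                                  n_restarts = config$cv_restarts,
                                  max_iterations = config$max_iterations,
                                  cost = config$cost, seed = seeds[4])
  k_sel <- sweep_res$selected_k

  perm <- permutation_test(adj_ref, group, k = k_sel,
                           n_permutations = config$n_permutations,
                           n_folds = config$n_folds,
                           n_restarts = config$perm_restarts,
                           max_iterations = config$max_iterations,
                           cost = config$cost, seed = seeds[5])

  # --- stage: per-cell fits and characterization ---------------------------
  cell_out <- list()
  for (ci in seq_len(nrow(cells))) {
    at <- cells$atlas[ci]; inc <- cells$inclusion[ci]
    cell_id <- paste(at, inc, sep = "_")
    keep <- if (inc == "no_dual") !(records$group == "clinical" & records$dual_diagnosis)
            else rep(TRUE, nrow(records))
    rec_c <- records[keep, , drop = FALSE]
    feat_c <- atlases[[at]]$features[keep, , drop = FALSE]
    adj_c <- adjust_covariates(feat_c, rec_c, config$covariates)
    fit <- hydra(adj_c, rec_c$group, k = k_sel,
                 n_restarts = config$n_restarts,
                 max_iterations = config$max_iterations, cost = config$cost,
                 seed = seeds[6] + ci)
    cell_out[[cell_id]] <- characterize_cell(fit, adj_c, rec_c, config$alpha)
    cell_out[[cell_id]]$atlas <- at
    cell_out[[cell_id]]$inclusion <- inc
  }

  # --- stage: membership consistency (dice vs reference cell) --------------
  ref_labels <- cell_out[[ref_cell]]$labels
  dice_tab <- lapply(setdiff(names(cell_out), ref_cell), function(cid) {
    d <- dice_membership(ref_labels, cell_out[[cid]]$labels)
    data.frame(cell = cid, subtype = names(d$per_subtype),
               dice = unname(d$per_subtype), overall = d$overall,
               n_shared = d$n_shared, row.names = NULL)
  })
  dice_tab <- if (length(dice_tab)) do.call(rbind, dice_tab) else NULL

  # --- stage: conjunction across cells, on the reference atlas -------------
  conjunction <- lapply(seq_len(k_sel), function(j) {
    masks <- lapply(names(cell_out), function(cid) {
      # align this cell's subtype naming to the reference cell
      map <- if (cid == ref_cell) stats::setNames(seq_len(k_sel), seq_len(k_sel))
             else dice_membership(ref_labels, cell_out[[cid]]$labels)$mapping
      j_local <- as.integer(names(map)[map == j][1])
      m <- cell_out[[cid]]$roi_masks[[j_local]]
      cw <- atlases[[cell_out[[cid]]$atlas]]$to_ref
      if (is.null(cw)) m else project_mask(m, cw)
    })
    names(masks) <- names(cell_out)
    cj <- conjunction_mask(masks)
    list(subtype = j, mask = cj$mask,
         networks = network_percentages(cj$mask, mapping_a))
  })

  # --- stage: conventional three-group diagnostic ANOVA --------------------
  anova_tab <- diagnostic_anova(adj_ref, records, config$alpha)

  report <- list(
    software = list(package = "hydracluster",
                    version = as.character(packageVersion("hydracluster"))),
    seed = config$seed,
    config = config_echo(config),
    stability = list(table = sweep_res$table, selected_k = k_sel,
                     n_folds = config$n_folds),
    permutation = list(p_value = perm$p_value,
                       observed_ari = perm$observed_ari,
                       n_permutations = perm$n_permutations),
    cells = lapply(cell_out, cell_summary),
    dice = dice_tab,
    conjunction = conjunction,
    diagnostic_anova = anova_tab)
  class(report) <- "run_report"
  report
}

# Subtype characterization within one (atlas x inclusion) cell.
characterize_cell <- function(fit, adj, rec, alpha) {
  clin <- rec$subject_id[rec$group == "clinical"]
  ctrl <- rec$subject_id[rec$group == "control"]
  labels <- fit$labels

  # diagnosis-by-subtype table and chi-square (guard degenerate margins)
  dtab <- table(factor(rec$primary_diagnosis[match(clin, rec$subject_id)]),
                factor(labels[clin], levels = seq_len(fit$k)))
  chi <- if (all(rowSums(dtab) > 0) && all(colSums(dtab) > 0) && nrow(dtab) > 1)
    chi_square_diagnosis(unclass(dtab)) else NULL

  # clinical-variable comparisons between subtypes (first pair when k = 2)
  pheno <- c("age", "handedness", "iq", "aq_total", "caars_total")
  pheno <- intersect(pheno, names(rec))
  ph <- as.matrix(rec[, pheno, drop = FALSE])
  rownames(ph) <- rec$subject_id
  clin_cmp <- NULL
  if (fit$k >= 2) {
    g1 <- names(labels)[labels == 1]; g2 <- names(labels)[labels == 2]
    if (length(g1) >= 2 && length(g2) >= 2)
      clin_cmp <- two_sample_tests(ph, g1, g2, alpha = alpha)
  }

  # ROI-wise subtype-vs-control comparisons, FDR per call
  roi_tests <- lapply(seq_len(fit$k), function(j) {
    members <- names(labels)[labels == j]
    if (length(members) < 2) return(NULL) # singleton subtype: untestable
    two_sample_tests(unclass(adj), members, ctrl, alpha = alpha)
  })
  roi_masks <- lapply(roi_tests, function(tt)
    if (is.null(tt)) character(0) else tt$variable[tt$significant])

  list(labels = labels, k = fit$k, sizes = tabulate(labels, fit$k),
       objective = fit$objective, converged = fit$converged,
       diagnosis_table = as.data.frame.matrix(dtab), chi_square = chi,
       clinical_comparisons = clin_cmp,
       roi_tests = roi_tests, roi_masks = roi_masks)
}

cell_summary <- function(cell) {
  list(atlas = cell$atlas, inclusion = cell$inclusion, k = cell$k,
       sizes = cell$sizes, labels = as.list(cell$labels),
       objective = cell$objective, converged = cell$converged,
       diagnosis_table = cell$diagnosis_table,
       chi_square = if (!is.null(cell$chi_square))
         cell$chi_square[c("statistic", "df", "p")] else NULL,
       clinical_comparisons = cell$clinical_comparisons,
       n_significant_rois = vapply(cell$roi_masks, length, integer(1)),
       roi_masks = cell$roi_masks)
}

# ROI-wise one-way ANOVA across diagnostic groups (control/ASD/ADHD) with
# FDR over ROIs; Tukey HSD only on FDR-significant ROIs.
diagnostic_anova <- function(adj, records, alpha) {
  g <- ifelse(records$group == "control", "NTC", records$primary_diagnosis)
  if (length(unique(g)) < 3) return(NULL)
  x <- unclass(adj)
  res <- lapply(colnames(x), function(v) {
    a <- anova_posthoc(x[, v], g, alpha = 1) # gate post-hoc after FDR instead
    data.frame(roi = v, F = a$F, p = a$p)
  })
  tab <- do.call(rbind, res)
  tab$q <- fdr_bh(tab$p)
  tab$significant <- tab$q < alpha
  list(n_rois = nrow(tab), n_significant = sum(tab$significant),
       table = tab)
}

config_echo <- function(config) {
  ce <- unclass(config)
  ce$cohort <- if (inherits(ce$cohort, "cohort_spec")) unclass(ce$cohort)
               else ce$cohort
  ce
}

#' @export
print.run_report <- function(x, ...) {
  cat("Transdiagnostic subtyping run report\n")
  cat(sprintf("  selected k = %d; permutation p = %.4g (observed CV ARI %.3f)\n",
              x$stability$selected_k, x$permutation$p_value,
              x$permutation$observed_ari))
  for (cid in names(x$cells)) {
    cl <- x$cells[[cid]]
    cat(sprintf("  cell %s: sizes %s; chi-square p = %s; significant ROIs %s\n",
                cid, paste(cl$sizes, collapse = "/"),
                if (is.null(cl$chi_square)) "NA"
                else sprintf("%.3f", cl$chi_square$p),
                paste(cl$n_significant_rois, collapse = "/")))
  }
  if (!is.null(x$dice))
    cat(sprintf("  dice vs reference: %s\n",
                paste(sprintf("%.2f", unique(x$dice$overall)), collapse = ", ")))
  invisible(x)
}

#' Persist a pipeline report to disk
#'
#' Writes the master JSON report plus TSV tables (stability sweep, per-cell
#' clinical and ROI comparisons, dice) and a run log. Existing files are
#' never clobbered: a numeric version suffix is appended instead.
#'
#' @param report A [run_pipeline()] result.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(obj, file, tsv = FALSE) {
    path <- versioned_path(file.path(out_dir, file))
    if (tsv) write.table(obj, path, sep = "\t", quote = FALSE, row.names = FALSE)
    else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                              null = "null", na = "null", pretty = TRUE)
    paths <<- c(paths, path)
  }
  wr(unclass(report), "report.json")
  wr(report$stability$table, "stability.tsv", tsv = TRUE)
  if (!is.null(report$dice)) wr(report$dice, "dice.tsv", tsv = TRUE)
  for (cid in names(report$cells)) {
    cc <- report$cells[[cid]]
    if (!is.null(cc$clinical_comparisons))
      wr(cc$clinical_comparisons, sprintf("clinical_%s.tsv", cid), tsv = TRUE)
  }
  log_path <- versioned_path(file.path(out_dir, "run.log"))
  writeLines(c(sprintf("hydracluster %s", report$software$version),
               sprintf("written %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
               sprintf("seed %d", report$seed),
               sprintf("files: %s", paste(basename(paths), collapse = ", "))),
             log_path)
  invisible(c(paths, log_path))
}
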