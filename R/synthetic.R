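#' Specify a synthetic case-control morphometry cohort
#'
#' Bundles the design parameters of a simulated cohort of ROI-level cortical
#' features with planted subtype structure. The defaults emulate a single-site
#' adult male case-control study: 105 neurotypical controls and 148 clinical
#' subjects (ASD or ADHD primary diagnosis, a small dual-diagnosis fraction),
#' 400 cortical ROIs, and two clinical subtypes with opposite-signed shifts on
#' partially overlapping ROI sets.
#'
#' @param n_control,n_clinical Numbers of control and clinical subjects.
#' @param n_rois Number of ROIs in the parcellation.
#' @param n_subtypes True number of planted clinical subtypes (k).
#' @param affected_fraction Fraction of ROIs shifted in each subtype.
#' @param effect_size Standardized mean shift (Cohen's d units, i.e. in
#'   multiples of `noise_sd`) applied to a subtype's affected ROIs.
#' @param effect_pattern `"opposite"` alternates the sign of the shift across
#'   subtypes (subtype 1 up, subtype 2 down, ...) on partially overlapping
#'   ROI sets; `"same"` shifts all subtypes upward on disjoint draws.
#' @param age_range Uniform age range in years.
#' @param age_slope Linear feature change per year of age, applied to all
#'   ROIs (mm/year for cortical thickness; negative means age-related
#'   thinning).
#' @param handedness_right Proportion of right-handed subjects. Handedness is
#'   recorded as a laterality score in `[-100, 100]`.
#' @param handedness_slope Feature change per laterality unit, applied to a
#'   random 10% subset of ROIs.
#' @param noise_sd Residual (between-subject) standard deviation per ROI, in
#'   feature units.
#' @param diagnosis_mix Probability that a clinical subject's primary
#'   diagnosis is ASD (vs ADHD); either a scalar (diagnosis independent of
#'   subtype, the default) or a length-`n_subtypes` vector of per-subtype
#'   probabilities (plants a diagnosis-subtype association).
#' @param dual_fraction Proportion of clinical subjects flagged as meeting
#'   criteria for both diagnoses.
#' @param baseline_range Range the per-ROI baseline means are drawn from
#'   (a cortical-thickness-like scale by default; cosmetic, as fitting
#'   standardizes features).
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#'
#' @return An object of class `cohort_spec` (a validated list).
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_control = 105, n_clinical = 148, n_rois = 400,
                        n_subtypes = 2, affected_fraction = 0.3,
                        effect_size = 1.5,
                        effect_pattern = c("opposite", "same"),
                        age_range = c(20, 50), age_slope = -0.005,
                        handedness_right = 0.9, handedness_slope = 5e-4,
                        noise_sd = 0.15,
                        diagnosis_mix = 99 / 148, dual_fraction = 13 / 148,
                        baseline_range = c(1.5, 4.5), seed = 1L) {
  effect_pattern <- match.arg(effect_pattern)
  spec <- list(n_control = as.integer(n_control),
               n_clinical = as.integer(n_clinical),
               n_rois = as.integer(n_rois),
               n_subtypes = as.integer(n_subtypes),
               affected_fraction = affected_fraction,
               effect_size = effect_size, effect_pattern = effect_pattern,
               age_range = age_range, age_slope = age_slope,
               handedness_right = handedness_right,
               handedness_slope = handedness_slope,
               noise_sd = noise_sd, diagnosis_mix = diagnosis_mix,
               dual_fraction = dual_fraction,
               baseline_range = baseline_range, seed = as.integer(seed))
  with(spec, {
    if (n_control < 1 || n_clinical < 1 || n_rois < 1)
      stop("all counts must be positive")
    if (n_subtypes < 1) stop("n_subtypes must be >= 1")
    if (n_subtypes > n_clinical) stop("n_subtypes exceeds n_clinical")
    if (affected_fraction < 0 || affected_fraction > 1)
      stop("affected_fraction must be in [0, 1]")
    if (dual_fraction < 0 || dual_fraction > 1)
      stop("dual_fraction must be in [0, 1]")
    if (noise_sd <= 0) stop("noise_sd must be positive")
    if (effect_size > 0 && affected_fraction * n_rois < 1)
      stop("affected_fraction * n_rois < 1 ROI while effect_size > 0")
    if (!length(diagnosis_mix) %in% c(1L, n_subtypes))
      stop("diagnosis_mix must be scalar or one probability per subtype")
    if (any(diagnosis_mix < 0 | diagnosis_mix > 1))
      stop("diagnosis_mix entries must be probabilities")
  })
  structure(spec, class = "cohort_spec")
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws a subjects-by-ROI feature table plus subject metadata from a
#' [cohort_spec()]. Control features are a per-ROI baseline mean plus linear
#' covariate effects (age on all ROIs, handedness on a random 10% subset)
#' plus Gaussian noise; clinical subjects additionally receive their planted
#' subtype's mean shift of magnitude `effect_size * noise_sd` on that
#' subtype's affected ROIs. Primary diagnosis (ASD/ADHD) and the
#' dual-diagnosis flag are sampled per `diagnosis_mix` and `dual_fraction`,
#' independent of subtype unless a per-subtype `diagnosis_mix` is given.
#'
#' @param spec A [cohort_spec()].
#' @param parameter Cortical parameter label for the feature table.
#' @param atlas_id Parcellation label for the feature table.
#' @return A list with `features` (a [feature_table()]), `records` (subject
#'   metadata data frame), and `truth` (planted subtype labels, per-subtype
#'   affected ROI sets and shift signs, and covariate coefficients).
#' @export
generate_cohort <- function(spec, parameter = "CT", atlas_id = "synthA") {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_control + spec$n_clinical
    ids <- sprintf("sub_%04d", seq_len(n))
    group <- rep(c("control", "clinical"), c(spec$n_control, spec$n_clinical))
    rois <- paste0("roi_", seq_len(spec$n_rois))

    age <- runif(n, spec$age_range[1], spec$age_range[2])
    right <- rbinom(n, 1, spec$handedness_right) == 1
    handed <- ifelse(right, runif(n, 40, 100), runif(n, -100, 40))

    baseline <- runif(spec$n_rois, spec$baseline_range[1], spec$baseline_range[2])
    age_coef <- rep(spec$age_slope, spec$n_rois)
    hand_rois <- sample(spec$n_rois, max(1L, round(0.1 * spec$n_rois)))
    hand_coef <- numeric(spec$n_rois)
    hand_coef[hand_rois] <- spec$handedness_slope

    # planted subtype structure
    k <- spec$n_subtypes
    subtype <- sample(rep_len(seq_len(k), spec$n_clinical))
    m <- max(1L, round(spec$affected_fraction * spec$n_rois))
    affected <- vector("list", k)
    signs <- numeric(k)
    for (j in seq_len(k)) {
      if (j == 1L || spec$effect_pattern == "same") {
        affected[[j]] <- sort(sample(spec$n_rois, m))
      } else {
        # partial overlap: half carried over from the previous subtype
        carry <- sample(affected[[j - 1L]], min(m %/% 2L, length(affected[[j - 1L]])))
        fresh <- sample(setdiff(seq_len(spec$n_rois), carry), m - length(carry))
        affected[[j]] <- sort(c(carry, fresh))
      }
      signs[j] <- if (spec$effect_pattern == "opposite") (-1)^(j - 1) else 1
    }

    age_c <- age - mean(spec$age_range)
    vals <- matrix(rnorm(n * spec$n_rois, sd = spec$noise_sd), n, spec$n_rois)
    vals <- vals + rep(baseline, each = n) +
      outer(age_c, age_coef) + outer(handed, hand_coef)
    shift <- spec$effect_size * spec$noise_sd
    for (j in seq_len(k)) {
      rows <- spec$n_control + which(subtype == j)
      vals[rows, affected[[j]]] <- vals[rows, affected[[j]]] + signs[j] * shift
    }
    dimnames(vals) <- list(ids, rois)

    p_asd <- if (length(spec$diagnosis_mix) == 1L) rep(spec$diagnosis_mix, k)
             else spec$diagnosis_mix
    is_clin <- group == "clinical"
    diag <- rep("none", n)
    diag[is_clin] <- ifelse(rbinom(spec$n_clinical, 1, p_asd[subtype]) == 1,
                            "ASD", "ADHD")
    dual <- rep(FALSE, n)
    dual[is_clin] <- rbinom(spec$n_clinical, 1, spec$dual_fraction) == 1
    medic <- rep(FALSE, n)
    medic[is_clin] <- rbinom(spec$n_clinical, 1, 0.5) == 1

    records <- data.frame(
      subject_id = ids, group = group, primary_diagnosis = diag,
      dual_diagnosis = dual, age = age, handedness = handed,
      iq = round(rnorm(n, 105, 12)),
      aq_total = ifelse(is_clin, round(rnorm(n, 30, 7)), NA_real_),
      caars_total = ifelse(is_clin, round(rnorm(n, 60, 10)), NA_real_),
      medication = medic, stringsAsFactors = FALSE)

    truth <- list(
      subtype = stats::setNames(subtype, ids[is_clin]),
      affected_rois = lapply(affected, function(ix) rois[ix]),
      signs = signs,
      covariate_coefficients = list(age = stats::setNames(age_coef, rois),
                                    handedness = stats::setNames(hand_coef, rois)))

    list(features = feature_table(vals, parameter, atlas_id),
         records = records, truth = truth)
  })
}

#' Assign ROIs of a parcellation to resting-state networks
#'
#' Randomly maps every ROI of an atlas to one of `n_networks` networks
#' (seven canonical resting-state networks by default), guaranteeing each
#' network is non-empty.
#'
#' @param n_rois Number of ROIs.
#' @param n_networks Number of networks; must not exceed `n_rois`.
#' @param seed Integer seed.
#' @param atlas_id Parcellation label.
#' @return A data frame with columns `roi_id` and `network` and an
#'   `atlas_id` attribute.
#' @export
generate_atlas_mapping <- function(n_rois, n_networks = 7, seed = 1L,
                                   atlas_id = "synthA") {
  if (n_networks > n_rois) stop("n_networks exceeds n_rois")
  if (n_networks < 1) stop("n_networks must be >= 1")
  nets <- if (n_networks == 7) {
    c("Visual", "Somatomotor", "DorsalAttention", "VentralAttention",
      "Limbic", "Frontoparietal", "Default")
  } else paste0("network_", seq_len(n_networks))
  with_seed(seed, {
    lab <- c(seq_len(n_networks),
             sample.int(n_networks, n_rois - n_networks, replace = TRUE))
    lab <- sample(lab) # shuffle so the guaranteed ROIs are not the first ones
    out <- data.frame(roi_id = paste0("roi_", seq_len(n_rois)),
                      network = nets[lab], stringsAsFactors = FALSE)
    attr(out, "atlas_id") <- atlas_id
    out
  })
}

#' ROI-overlap crosswalk between two parcellations
#'
#' Builds a row-stochastic source-by-target overlap matrix between two
#' atlases by laying both parcellations out as interval partitions of a
#' common one-dimensional cortex coordinate: equal-width intervals by
#' default, optionally with jittered boundaries. Two atlases of the same
#' size therefore yield the identity, and a nested coarse/fine pair yields
#' 0/1 rows.
#'
#' @param mapping_a,mapping_b Atlas mappings from [generate_atlas_mapping()]
#'   (only their ROI sets are used; A is the source, B the target).
#' @param seed Integer seed (only consumed when `jitter > 0`).
#' @param jitter Relative boundary jitter in (0, 1); 0 keeps equal widths.
#' @return Matrix of overlap proportions, rows = atlas A ROIs (summing to
#'   1), columns = atlas B ROIs, with a `source_widths` attribute.
#' @export
generate_crosswalk <- function(mapping_a, mapping_b, seed = 1L, jitter = 0) {
  na <- nrow(mapping_a); nb <- nrow(mapping_b)
  if (na < 1 || nb < 1) stop("both mappings must be non-empty")
  brk <- function(n, s) {
    b <- seq(0, 1, length.out = n + 1L)
    if (jitter > 0) {
      b[-c(1, n + 1L)] <- b[-c(1, n + 1L)] +
        with_seed(s, runif(n - 1L, -jitter / (2 * n), jitter / (2 * n)))
      b <- sort(b)
    }
    b
  }
  ba <- brk(na, seed); bb <- brk(nb, seed + 1L)
  cw <- matrix(0, na, nb, dimnames = list(mapping_a$roi_id, mapping_b$roi_id))
  for (i in seq_len(na)) {
    lo <- pmax(ba[i], bb[-(nb + 1L)]); hi <- pmin(ba[i + 1L], bb[-1L])
    cw[i, ] <- pmax(0, hi - lo)
  }
  widths <- diff(ba)
  cw <- cw / rowSums(cw)
  attr(cw, "source_widths") <- widths
  cw
}

#' Project a feature table onto another parcellation
#'
#' Computes target-atlas ROI values as overlap-weighted averages of source
#' ROI values, the standard way ROI measures are carried between
#' parcellations when vertex data are unavailable.
#'
#' @param features A [feature_table()] on the crosswalk's source atlas.
#' @param crosswalk Output of [generate_crosswalk()].
#' @param atlas_id Label for the projected table.
#' @return A `feature_table` on the target atlas.
#' @export
project_features <- function(features, crosswalk, atlas_id = "synthB") {
  x <- as_feature_matrix(features)
  if (!all(colnames(x) == rownames(crosswalk)))
    stop("feature table ROIs do not match crosswalk source ROIs")
  w <- attr(crosswalk, "source_widths") %||% rep(1 / nrow(crosswalk), nrow(crosswalk))
  L <- crosswalk * w                    # absolute overlap lengths
  proj <- (x %*% L) / rep(colSums(L), each = nrow(x))
  feature_table(proj, attr(features, "parameter") %||% "CT", atlas_id)
}
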