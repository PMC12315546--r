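#' Canonical column name of the intracranial-volume ROI
#'
#' The per-scan tables follow the SynthSeg+ convention of reporting total
#' intracranial volume (ICV) as a regular ROI column named
#' `"total intracranial"`.
#'
#' @return The ICV column name, a string.
#' @export
icv_roi <- function() "total intracranial"

#' Demographic group labels
#'
#' The cohort is stratified by self-reported race (Asian, Black, White) and
#' sex (Female, Male): six closed race-by-sex cells.
#'
#' @return A tibble with columns `race` and `sex` listing the six cells.
#' @export
group_labels <- function() {
  tidyr::expand_grid(
    race = c("Asian", "Black", "White"),
    sex = c("Female", "Male")
  )
}

#' Default per-group demographic and ICV statistics
#'
#' The built-in calibration of the synthetic cohort: per race-by-sex cell,
#' the subject count, age mean and SD (years), and ICV mean and SD (litres).
#' These are the published group statistics of the reference cohort
#' (N = 5977 adults aged 18--90 drawn from a hospital imaging archive).
#'
#' @return A tibble with columns `race`, `sex`, `n`, `age_mean`, `age_sd`,
#'   `icv_mean`, `icv_sd` (ICV in litres).
#' @export
default_group_stats <- function() {
  tibble::tribble(
    ~race,   ~sex,     ~n,   ~age_mean, ~age_sd, ~icv_mean, ~icv_sd,
    "Asian", "Female", 1058, 48.9,      18.6,    1.4078,    0.10769,
    "Asian", "Male",   733,  52.3,      18.6,    1.5753,    0.12189,
    "Black", "Female", 1213, 52.0,      18.5,    1.3641,    0.10857,
    "Black", "Male",   833,  53.1,      18.1,    1.5296,    0.12255,
    "White", "Female", 1179, 55.1,      19.0,    1.4319,    0.11411,
    "White", "Male",   961,  55.4,      17.7,    1.6144,    0.1277
  )
}

#' Default ROI trajectory models for the synthetic cohort
#'
#' Each ROI's generative aging trajectory is specified as a fraction of ICV
#' (litres of ROI per litre of ICV) at the four anchor ages 27, 45, 63 and
#' 81 years, together with a Laplace residual scale expressed as a fraction
#' of the age-specific median. Ventricles are simulated with a
#' multiplicative (log-scale) Laplace residual to reproduce their strong
#' right skew; all other ROIs use additive residuals. The shapes are
#' plausible adult aging curves (gradual atrophy of grey structures,
#' late-life white-matter decline, accelerating ventricular expansion); the
#' ICV statistics, not the ROI curves, are the calibrated quantities.
#'
#' @return A tibble with columns `roi`, `anchors` (list of 4 fractions of
#'   ICV at the anchor ages), `scale_frac` (list, length 1 or 4) and
#'   `log_normal` (logical).
#' @export
default_roi_models <- function() {
  tibble::tibble(
    roi = c("whole brain", "white matter", "cortex", "thalamus",
            "hippocampus", "amygdala", "brainstem", "ventricles"),
    anchors = list(
      c(0.800, 0.785, 0.760, 0.720),
      c(0.305, 0.305, 0.298, 0.282),
      c(0.335, 0.322, 0.306, 0.288),
      c(0.0106, 0.0102, 0.0097, 0.0089),
      c(0.00560, 0.00548, 0.00525, 0.00470),
      c(0.00240, 0.00236, 0.00228, 0.00212),
      c(0.0152, 0.0152, 0.0151, 0.0148),
      c(0.0095, 0.0120, 0.0185, 0.0330)
    ),
    scale_frac = list(0.035, 0.045, 0.040, 0.055, 0.060, 0.065, 0.045, 0.30),
    log_normal = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
  )
}

#' Specify a synthetic cohort
#'
#' Bundles all generative parameters of the synthetic scan-level cohort:
#' per-group sizes, age and ICV laws, ROI trajectory models, visit/scan
#' structure, the QC-score law, and the seed. Defaults reproduce the
#' published group statistics (see [default_group_stats()]); sampling
#' details are documented under [simulate_cohort()].
#'
#' @param group_stats Per-group calibration tibble in the format of
#'   [default_group_stats()] (`icv_mean`/`icv_sd` in litres). Group sizes
#'   are the analysis sample sizes; planted QC failures are generated on
#'   top of them.
#' @param roi_models ROI trajectory tibble in the format of
#'   [default_roi_models()].
#' @param log_normal_rois Character vector of ROI names simulated with
#'   multiplicative log-scale residuals; overrides the `log_normal` column
#'   when supplied. Names must exist in `roi_models`.
#' @param age_bounds Inclusion bounds on age in years; must lie within
#'   `[18, 90]`.
#' @param scans_per_visit_range Integer range of 3D scans per MRI session.
#' @param visits_per_subject_range Integer range of visits per subject.
#' @param qc_shape1,qc_shape2 Beta distribution parameters of the QC score
#'   for subjects with usable imaging; the default Beta(8, 1.5)
#'   concentrates mass above the 0.75 analysis threshold.
#' @param fail_frac Fraction of all-failing subjects planted on top of the
#'   analysis sample, exercising subject exclusion. Default 23/5977.
#' @param scan_jitter_frac Multiplicative Gaussian measurement jitter per
#'   scan (SD as a fraction of the volume); small relative to
#'   between-subject spread.
#' @param anchor_ages,degree Basis settings for the generative trajectories
#'   (shared with the fitted model by default).
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(group_stats = default_group_stats(),
                        roi_models = default_roi_models(),
                        log_normal_rois = NULL,
                        age_bounds = c(18, 90),
                        scans_per_visit_range = c(1L, 4L),
                        visits_per_subject_range = c(1L, 3L),
                        qc_shape1 = 8,
                        qc_shape2 = 1.5,
                        fail_frac = 23 / 5977,
                        scan_jitter_frac = 0.002,
                        anchor_ages = c(27, 45, 63, 81),
                        degree = 3L,
                        seed = 1L) {
  group_stats <- tibble::as_tibble(group_stats)
  req <- c("race", "sex", "n", "age_mean", "age_sd", "icv_mean", "icv_sd")
  if (!all(req %in% names(group_stats))) {
    stop("`group_stats` needs columns: ", paste(req, collapse = ", "))
  }
  if (any(group_stats$n < 0)) stop("group sizes must be >= 0")
  if (any(group_stats$icv_sd < 0) || any(group_stats$age_sd < 0)) {
    stop("SDs must be nonnegative (zero is the degenerate no-variance case)")
  }
  known <- dplyr::inner_join(group_stats, group_labels(),
                             by = c("race", "sex"))
  if (nrow(known) != nrow(group_stats)) {
    stop("race/sex labels must come from the six closed race-by-sex cells")
  }
  if (age_bounds[1] < 18 || age_bounds[2] > 90 || age_bounds[1] >= age_bounds[2]) {
    stop("`age_bounds` must be an increasing pair within [18, 90]")
  }
  roi_models <- tibble::as_tibble(roi_models)
  if (!is.null(log_normal_rois)) {
    unknown <- setdiff(log_normal_rois, roi_models$roi)
    if (length(unknown)) {
      stop("unknown ROI name(s) in `log_normal_rois`: ",
           paste(unknown, collapse = ", "))
    }
    roi_models$log_normal <- roi_models$roi %in% log_normal_rois
  }
  bad_scale <- vapply(roi_models$scale_frac,
                      function(s) any(s < 0), logical(1))
  if (any(bad_scale)) stop("residual scale fractions must be >= 0")
  stopifnot(fail_frac >= 0, fail_frac < 1,
            scan_jitter_frac >= 0,
            scans_per_visit_range[1] >= 1,
            visits_per_subject_range[1] >= 1)
  structure(
    list(group_stats = group_stats,
         roi_models = roi_models,
         age_bounds = as.numeric(age_bounds),
         scans_per_visit_range = as.integer(scans_per_visit_range),
         visits_per_subject_range = as.integer(visits_per_subject_range),
         qc_shape1 = qc_shape1, qc_shape2 = qc_shape2,
         fail_frac = fail_frac,
         scan_jitter_frac = scan_jitter_frac,
         anchor_ages = as.numeric(anchor_ages),
         degree = as.integer(degree),
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort spec:",
      sum(x$group_stats$n), "analysis subjects in",
      nrow(x$group_stats), "race-by-sex cells;",
      nrow(x$roi_models), "ROIs; seed", x$seed, "\n")
  invisible(x)
}

#' Write or build a cohort-spec template
#'
#' Serializes a [cohort_spec()] (by default the built-in calibration) to a
#' YAML file so cohort definitions can be versioned alongside analysis
#' configs, or returns the YAML text when `path` is `NULL`.
#'
#' @param path Output file, or `NULL` to return the YAML string.
#' @param spec The spec to serialize; default [cohort_spec()].
#' @return The YAML string, invisibly when written to a file.
#' @seealso [read_cohort_spec()]
#' @export
cohort_spec_template <- function(path = NULL, spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  x <- unclass(spec)
  x$group_stats <- as.list(as.data.frame(spec$group_stats))
  x$roi_models <- list(
    roi = spec$roi_models$roi,
    anchors = spec$roi_models$anchors,
    scale_frac = spec$roi_models$scale_frac,
    log_normal = spec$roi_models$log_normal
  )
  txt <- yaml::as.yaml(x, precision = 12)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a cohort spec from a YAML file
#'
#' @param path YAML file written by [cohort_spec_template()].
#' @return A validated [cohort_spec()].
#' @export
read_cohort_spec <- function(path) {
  x <- yaml::read_yaml(path)
  gs <- tibble::as_tibble(x$group_stats)
  rm_ <- tibble::tibble(
    roi = as.character(x$roi_models$roi),
    anchors = lapply(x$roi_models$anchors, as.numeric),
    scale_frac = lapply(x$roi_models$scale_frac, as.numeric),
    log_normal = as.logical(x$roi_models$log_normal)
  )
  cohort_spec(
    group_stats = gs, roi_models = rm_,
    age_bounds = x$age_bounds,
    scans_per_visit_range = x$scans_per_visit_range,
    visits_per_subject_range = x$visits_per_subject_range,
    qc_shape1 = x$qc_shape1, qc_shape2 = x$qc_shape2,
    fail_frac = x$fail_frac,
    scan_jitter_frac = x$scan_jitter_frac,
    anchor_ages = x$anchor_ages, degree = x$degree, seed = x$seed
  )
}
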