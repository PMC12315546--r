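#' Identify ROI volume columns of a cohort table
#'
#' Every column that is not one of the scan/subject metadata columns is
#' treated as an ROI volume column (including the ICV column).
#'
#' @param data A scan-level or subject-level tibble.
#' @return Character vector of ROI column names.
#' @export
roi_columns <- function(data) {
  meta <- c("subject_id", "visit_id", "scan_id", "age", "sex", "race", "qc",
            "n_scans_used", "n_visits_used")
  setdiff(names(data), meta)
}

#' Filter scans by QC score
#'
#' Keeps exactly the scans whose automatic quality-control score is
#' strictly greater than the threshold (the analysis rule is `qc > 0.75`).
#' Input order is preserved.
#'
#' @param scans Scan-level tibble with a `qc` column.
#' @param qc_threshold QC threshold in `[0, 1]`; default 0.75.
#' @return The retained scans (possibly zero rows).
#' @export
filter_scans <- function(scans, qc_threshold = 0.75) {
  if (!is.numeric(qc_threshold) || length(qc_threshold) != 1 ||
      qc_threshold < 0 || qc_threshold > 1) {
    stop("`qc_threshold` must be a single number in [0, 1]")
  }
  dplyr::filter(scans, .data$qc > qc_threshold)
}

#' Select the top-k scans of one MRI session
#'
#' When a session has more than `k` scans passing QC, only the `k` with the
#' highest QC scores are analysed (default `k = 3`). Ties at the k-th rank
#' are broken by `scan_id` lexicographic order for determinism.
#'
#' @param scans Scans of a single subject visit (same `subject_id` and
#'   `visit_id` throughout; mixed sessions are an error).
#' @param k Maximum number of scans to keep; default 3.
#' @return The selected scans, ordered by decreasing QC.
#' @export
select_top_scans <- function(scans, k = 3) {
  if (k < 1) stop("`k` must be >= 1")
  if (nrow(scans) > 0 &&
      (dplyr::n_distinct(scans$subject_id) > 1 ||
       dplyr::n_distinct(scans$visit_id) > 1)) {
    stop("`select_top_scans()` expects scans of a single visit")
  }
  scans <- dplyr::arrange(scans, dplyr::desc(.data$qc), .data$scan_id)
  dplyr::slice_head(scans, n = k)
}

#' Aggregate scan-level records to one record per subject
#'
#' Applies the full per-subject reduction: scans failing QC are dropped
#' ([filter_scans()]); within each session at most the top `top_k` scans by
#' QC are kept ([select_top_scans()]); ROI volumes are averaged over the
#' retained scans of each visit; then volumes and ages are averaged over
#' visits with equal weight per visit, so the estimate is independent of
#' the number of visits (and of each visit's scan count). A session whose
#' scans all fail contributes nothing. Subjects with no retained scans in
#' any visit are excluded, not emitted; they are recorded in the
#' `excluded` attribute (see [excluded_subjects()]).
#'
#' @param scans Scan-level tibble (see [simulate_cohort()] for the format).
#' @param qc_threshold QC threshold; default 0.75.
#' @param top_k Scans retained per session; default 3.
#' @param pool_scans If `TRUE`, average all retained scans directly instead
#'   of the two-stage visit-then-subject mean (exposed for sensitivity
#'   analysis; the two-stage mean is the default).
#' @return A tibble with one row per retained subject: `subject_id`,
#'   `race`, `sex`, `age`, `n_scans_used`, `n_visits_used`, then the ROI
#'   columns. Attributes: `excluded` (tibble of `subject_id`, `reason`) and
#'   `volume_unit` (propagated).
#' @export
aggregate_subjects <- function(scans, qc_threshold = 0.75, top_k = 3,
                               pool_scans = FALSE) {
  label_chk <- dplyr::summarise(
    dplyr::group_by(scans, .data$subject_id),
    n_lab = dplyr::n_distinct(.data$race, .data$sex), .groups = "drop")
  if (any(label_chk$n_lab > 1)) {
    stop("conflicting race/sex labels within subject(s): ",
         paste(label_chk$subject_id[label_chk$n_lab > 1], collapse = ", "))
  }
  rois <- roi_columns(scans)
  passing <- filter_scans(scans, qc_threshold)
  passing <- dplyr::distinct(passing, .data$scan_id, .keep_all = TRUE)
  kept <- dplyr::slice_head(
    dplyr::arrange(
      dplyr::group_by(passing, .data$subject_id, .data$visit_id),
      dplyr::desc(.data$qc), .data$scan_id, .by_group = TRUE),
    n = top_k)

  if (pool_scans) {
    subj <- dplyr::summarise(
      dplyr::group_by(kept, .data$subject_id, .data$race, .data$sex),
      age = mean(.data$age),
      n_scans_used = dplyr::n(),
      n_visits_used = dplyr::n_distinct(.data$visit_id),
      dplyr::across(dplyr::all_of(rois), mean),
      .groups = "drop")
  } else {
    visit <- dplyr::summarise(
      dplyr::group_by(kept, .data$subject_id, .data$race, .data$sex,
                      .data$visit_id),
      age = mean(.data$age),
      n_scans = dplyr::n(),
      dplyr::across(dplyr::all_of(rois), mean),
      .groups = "drop")
    subj <- dplyr::summarise(
      dplyr::group_by(visit, .data$subject_id, .data$race, .data$sex),
      age = mean(.data$age),
      n_scans_used = sum(.data$n_scans),
      n_visits_used = dplyr::n(),
      dplyr::across(dplyr::all_of(rois), mean),
      .groups = "drop")
  }
  subj <- dplyr::arrange(subj, .data$subject_id)
  subj <- dplyr::relocate(subj, "subject_id", "race", "sex", "age",
                          "n_scans_used", "n_visits_used")

  all_ids <- sort(unique(scans$subject_id))
  excl <- setdiff(all_ids, subj$subject_id)
  attr(subj, "excluded") <- tibble::tibble(
    subject_id = excl,
    reason = rep("no scans passed QC", length(excl)))
  attr(subj, "volume_unit") <- attr(scans, "volume_unit")
  attr(subj, "log_rois") <- attr(scans, "log_rois")
  subj
}

#' Exclusion log of an aggregated cohort
#'
#' @param subjects Output of [aggregate_subjects()].
#' @return A tibble with columns `subject_id`, `reason`.
#' @export
excluded_subjects <- function(subjects) {
  out <- attr(subjects, "excluded")
  if (is.null(out)) {
    out <- tibble::tibble(subject_id = character(), reason = character())
  }
  out
}
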