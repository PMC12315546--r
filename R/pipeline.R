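#' Configure a full analysis run
#'
#' Bundles every setting of the end-to-end pipeline. The defaults are the
#' analysis settings of the reference study: QC threshold 0.75, top-3
#' scans per session, division ICV correction, log-transformed ventricles,
#' cubic trajectory splines anchored at ages 27/45/63/81, and a 1-year
#' effect-size age grid over 18--90.
#'
#' @param input A [cohort_spec()] to simulate, or the path of a per-scan
#'   cohort CSV ([read_cohort_csv()] format). Default: the built-in
#'   calibrated spec with `seed`.
#' @param qc_threshold QC cutoff; default 0.75.
#' @param top_k Scans retained per session; default 3.
#' @param normalization One of `"division"`, `"residual"`, `"covariate"`,
#'   `"matching"`, `"none"`; default `"division"`.
#' @param log_rois ROIs modelled on the log scale; default
#'   `"ventricles"`.
#' @param rois ROI columns to fit; default all non-ICV ROIs present.
#' @param control_ages,degree Trajectory basis settings.
#' @param age_grid Effect-size age grid; default `18:90`.
#' @param caliper Matching caliper in the cohort volume unit (mL for
#'   generated cohorts); used only when `normalization = "matching"`.
#' @param out_dir Output directory for the report bundle.
#' @param seed Seed for cohort simulation (overrides the spec's seed).
#' @param make_plots Also write trajectory/effect-size figures; default
#'   `FALSE`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL,
                            qc_threshold = 0.75,
                            top_k = 3,
                            normalization = c("division", "residual",
                                              "covariate", "matching",
                                              "none"),
                            log_rois = "ventricles",
                            rois = NULL,
                            control_ages = c(27, 45, 63, 81),
                            degree = 3L,
                            age_grid = 18:90,
                            caliper = 100,
                            out_dir = "icvnorm-output",
                            seed = 1L,
                            make_plots = FALSE) {
  normalization <- match.arg(normalization)
  if (is.null(input)) input <- cohort_spec(seed = seed)
  if (inherits(input, "cohort_spec")) input$seed <- as.integer(seed)
  structure(
    list(input = input, qc_threshold = qc_threshold, top_k = top_k,
         normalization = normalization, log_rois = log_rois, rois = rois,
         control_ages = control_ages, degree = as.integer(degree),
         age_grid = age_grid, caliper = caliper, out_dir = out_dir,
         seed = as.integer(seed), make_plots = isTRUE(make_plots)),
    class = "pipeline_config"
  )
}

#' Run the full ICV-normalization trajectory analysis
#'
#' Executes the pipeline end to end: simulate or ingest the per-scan
#' cohort; QC-filter, top-k-select and aggregate to one record per
#' subject; apply the configured ICV correction and the ventricle
#' log-transform; fit the Laplace trajectory model per ROI and
#' race-by-sex group on both raw and corrected volumes; compute
#' effect-size curves, maxima and correction reduction factors; and write
#' the report bundle. Runs are deterministic given the config: identical
#' seeds yield byte-identical output files.
#'
#' Output files (all CSV/JSON, UTF-8): `subjects.csv`, `exclusions.csv`,
#' `group_summary.csv`, `icv_ratios.csv`, `fits/` (one JSON per
#' ROI-by-group fit, raw and corrected), `effects.csv` (tidy curves),
#' `effects_summary.csv` (per-pair `d_max` and reduction ratios), a
#' matching report when applicable, and `manifest.json` (config hash,
#' seed, file list, convergence warnings).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with elements `subjects`, `summary`,
#'   `ratios`, `fits_raw`, `fits_corrected`, `effects`,
#'   `effects_summary`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  warnings_log <- character()

  scans <- if (inherits(config$input, "cohort_spec")) {
    simulate_cohort(config$input)
  } else {
    read_cohort_csv(config$input)
  }

  subjects <- aggregate_subjects(scans, config$qc_threshold, config$top_k)
  readr::write_csv(subjects, out("subjects.csv"))
  readr::write_csv(excluded_subjects(subjects), out("exclusions.csv"))

  summary_tbl <- group_summary_table(subjects)
  readr::write_csv(summary_tbl, out("group_summary.csv"))
  ratios <- format_ratio_table(icv_ratio_table(summary_tbl))
  readr::write_csv(ratios, out("icv_ratios.csv"))

  rois <- config$rois %||% setdiff(roi_columns(subjects), icv_roi())
  log_rois <- intersect(config$log_rois, rois)

  corrected <- switch(
    config$normalization,
    division = normalize_division(subjects),
    residual = normalize_residual(subjects),
    covariate = subjects,  # adjustment happens inside the fit
    none = subjects,
    matching = {
      cells <- dplyr::distinct(subjects[, c("race", "sex")])
      matched <- purrr::map(unique(cells$race), function(r) {
        m <- match_groups(subjects, c(r, "Female"), c(r, "Male"),
                          config$caliper)
        tibble::tibble(race = r,
                       smd = attr(m, "balance"),
                       n_pairs = nrow(attr(m, "matched_pairs")),
                       ids = list(m$subject_id))
      })
      matched <- dplyr::bind_rows(matched)
      readr::write_csv(matched[, c("race", "smd", "n_pairs")],
                       out("matching_report.csv"))
      keep <- unique(unlist(matched$ids))
      res <- subjects[subjects$subject_id %in% keep, ]
      attr(res, "volume_unit") <- attr(subjects, "volume_unit")
      res
    })

  # division first, then the ventricle log-transform
  subjects_t <- log_transform_rois(subjects, log_rois)
  corrected_t <- log_transform_rois(corrected, log_rois)

  basis <- bspline_basis(config$control_ages, config$degree)
  adjust <- if (config$normalization == "covariate") covariate_adjust()

  fit_quiet <- function(d, ...) {
    withCallingHandlers(
      fit_trajectories(d, rois = rois, basis = basis, ...),
      warning = function(w) {
        warnings_log <<- c(warnings_log, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }
  fits_raw <- fit_quiet(subjects_t)
  fits_cor <- fit_quiet(corrected_t, adjust = adjust)
  write_fit_json(dplyr::mutate(fits_raw, roi = paste0("raw_", .data$roi)),
                 out("fits"))
  write_fit_json(fits_cor, out("fits"))

  effects <- effect_size_curves(fits_cor, config$age_grid)
  readr::write_csv(effects, out("effects.csv"))
  esum <- normalization_effect_ratio(fits_raw, fits_cor, config$age_grid)
  readr::write_csv(esum, out("effects_summary.csv"))

  if (config$make_plots) {
    for (r in rois) {
      p <- plot_trajectories(fits_cor, rois = r)
      ggplot2::ggsave(out(paste0("trajectories_",
                                 gsub("[^A-Za-z0-9]+", "_", r), ".png")),
                      p, width = 7, height = 5, dpi = 150)
    }
  }

  n_nonconv <- sum(!fits_raw$converged) + sum(!fits_cor$converged)
  manifest <- list(
    package = "icvnorm",
    version = as.character(utils::packageVersion("icvnorm")),
    seed = config$seed,
    normalization = config$normalization,
    config_hash = digest::digest(
      config[setdiff(names(config), "out_dir")]),
    n_subjects = nrow(subjects),
    n_excluded = nrow(excluded_subjects(subjects)),
    n_fits = nrow(fits_raw) + nrow(fits_cor),
    n_nonconverged = n_nonconv,
    warnings = warnings_log,
    files = sort(setdiff(list.files(config$out_dir, recursive = TRUE),
                         "manifest.json")))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  if (n_nonconv > 0) {
    warning(n_nonconv, " trajectory fit(s) did not converge; see manifest")
  }

  invisible(list(subjects = subjects, summary = summary_tbl,
                 ratios = ratios, fits_raw = fits_raw,
                 fits_corrected = fits_cor, effects = effects,
                 effects_summary = esum, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
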