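#' Per-group demographic and ICV summary
#'
#' Counts, age mean and SD, and ICV mean and SD per race-by-sex cell of an
#' aggregated cohort. ICV is reported in litres regardless of the cohort's
#' internal unit (the generated cohorts carry volumes in millilitres and a
#' `volume_unit` attribute).
#'
#' @param subjects Subject-level tibble with `race`, `sex`, `age` and the
#'   [icv_roi()] column.
#' @return A tibble: `race`, `sex`, `n`, `age_mean`, `age_sd`,
#'   `icv_mean`, `icv_sd` (ICV in litres) — the same format as
#'   [default_group_stats()], so it feeds [icv_ratio_table()] directly.
#' @export
group_summary_table <- function(subjects) {
  unit <- attr(subjects, "volume_unit")
  to_l <- if (identical(unit, "mL")) 1e-3 else 1
  icv <- subjects[[icv_roi()]]
  if (is.null(icv)) stop("no \"", icv_roi(), "\" column")
  dplyr::summarise(
    dplyr::group_by(subjects, .data$race, .data$sex),
    n = dplyr::n(),
    age_mean = mean(.data$age),
    age_sd = stats::sd(.data$age),
    icv_mean = mean(.data[[icv_roi()]]) * to_l,
    icv_sd = stats::sd(.data[[icv_roi()]]) * to_l,
    .groups = "drop")
}

ratio_or_na <- function(num, den) {
  if (length(num) != 1 || length(den) != 1 || is.na(num) || is.na(den) ||
      den == 0) {
    NA_real_
  } else {
    num / den
  }
}

#' Between-group ICV ratio block
#'
#' The in-text ratio summary of a group table: the male/female mean-ICV
#' ratio within each race; the Asian/Black, Black/White and Asian/White
#' ratios within each sex; and the count-weighted global male/female
#' ratio. An empty cell yields a missing ratio, never zero.
#'
#' @param summary A group summary in the format of
#'   [group_summary_table()] / [default_group_stats()].
#' @return A tidy tibble: `comparison`, `stratum`, `ratio`. Per-group
#'   ratios print at 3 decimals and the global ratio at 2 in reports
#'   ([format_ratio_table()]); the returned values are unrounded.
#' @export
icv_ratio_table <- function(summary) {
  req <- c("race", "sex", "n", "icv_mean")
  if (!all(req %in% names(summary))) {
    stop("`summary` needs columns: ", paste(req, collapse = ", "))
  }
  cell <- function(race, sex) {
    x <- summary$icv_mean[summary$race == race & summary$sex == sex]
    if (length(x) == 0) NA_real_ else x
  }
  races <- c("Asian", "Black", "White")
  sexes <- c("Female", "Male")
  mf <- purrr::map_dfr(races, function(r) tibble::tibble(
    comparison = "Male/Female", stratum = r,
    ratio = ratio_or_na(cell(r, "Male"), cell(r, "Female"))))
  race_pairs <- list(c("Asian", "Black"), c("Black", "White"),
                     c("Asian", "White"))
  rr <- purrr::map_dfr(sexes, function(s) {
    purrr::map_dfr(race_pairs, function(p) tibble::tibble(
      comparison = paste0(p[1], "/", p[2]), stratum = s,
      ratio = ratio_or_na(cell(p[1], s), cell(p[2], s))))
  })
  wmean <- function(sex) {
    sel <- summary$sex == sex & !is.na(summary$icv_mean)
    if (!any(sel) || sum(summary$n[sel]) == 0) return(NA_real_)
    stats::weighted.mean(summary$icv_mean[sel], summary$n[sel])
  }
  glob <- tibble::tibble(
    comparison = "Male/Female", stratum = "All (count-weighted)",
    ratio = ratio_or_na(wmean("Male"), wmean("Female")))
  dplyr::bind_rows(mf, rr, glob)
}

#' Format the ratio block for reports
#'
#' Per-group ratios are printed at 3 decimals and the global
#' count-weighted ratio at 2, matching the conventional reporting
#' precision.
#'
#' @param ratios Output of [icv_ratio_table()].
#' @return The tibble with a character `printed` column added.
#' @export
format_ratio_table <- function(ratios) {
  dplyr::mutate(
    ratios,
    printed = ifelse(
      .data$stratum == "All (count-weighted)",
      sprintf("%.2f", .data$ratio),
      sprintf("%.3f", .data$ratio)))
}
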