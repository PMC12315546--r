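#' Pooled-scale effect size between two trajectories at given ages
#'
#' The robust between-group effect size at age `a`:
#' `d(a) = 2 |mu_1(a) - mu_2(a)| / (b_1(a) + b_2(a))`, the absolute
#' location difference divided by the pooled (average) Laplace scales.
#' Symmetric in its two fits; both fits must share transform status (a
#' raw-volume fit cannot be compared with a log-volume fit).
#'
#' @param fit1,fit2 `laplace_fit` objects for the two groups.
#' @param age Ages (years) within both fit domains.
#' @return Numeric vector of nonnegative effect sizes, one per age.
#' @export
effect_size_at <- function(fit1, fit2, age) {
  stopifnot(inherits(fit1, "laplace_fit"), inherits(fit2, "laplace_fit"))
  if (!identical(fit1$log_volume, fit2$log_volume)) {
    stop("cannot compare a raw-volume fit with a log-volume fit")
  }
  p1 <- predict(fit1, age)
  p2 <- predict(fit2, age)
  2 * abs(p1$location - p2$location) / (p1$scale + p2$scale)
}

# default comparison pairs: sexes within each race, races within each sex
default_pairs <- function(groups) {
  g <- dplyr::arrange(groups, .data$race, .data$sex)
  idx <- utils::combn(nrow(g), 2)
  keep <- apply(idx, 2, function(ij) {
    same_race <- g$race[ij[1]] == g$race[ij[2]]
    same_sex <- g$sex[ij[1]] == g$sex[ij[2]]
    xor(same_race, same_sex)
  })
  idx[, keep, drop = FALSE]
}

#' Effect-size curves across group pairs and ages
#'
#' Evaluates [effect_size_at()] for group pairs of a fitted trajectory set
#' over an age grid, in tidy long format. By default sex comparisons are
#' made within race and race comparisons within sex (the figure-panel
#' pairing); `pairs = "all"` compares every unordered pair.
#'
#' @param fits Output of [fit_trajectories()] (grouped by race and sex).
#' @param age_grid Ages to evaluate; default 1-year steps over 18--90
#'   intersected with the fit domain.
#' @param pairs `"panel"` (default) or `"all"`.
#' @return A tidy tibble: `roi`, `group1`, `group2`, `age`, `d`.
#' @export
effect_size_curves <- function(fits, age_grid = NULL, pairs = c("panel", "all")) {
  pairs <- match.arg(pairs)
  if (!all(c("race", "sex", "roi", "fit") %in% names(fits))) {
    stop("`fits` must come from fit_trajectories() grouped by race and sex")
  }
  purrr::map_dfr(unique(fits$roi), function(r) {
    fr <- dplyr::arrange(fits[fits$roi == r, ], .data$race, .data$sex)
    if (nrow(fr) < 2) stop("need at least two groups per ROI")
    dom <- fr$fit[[1]]$basis$domain
    grid <- if (is.null(age_grid)) {
      seq(max(18, dom[1]), min(90, dom[2]), by = 1)
    } else {
      age_grid
    }
    idx <- if (pairs == "panel") {
      default_pairs(fr[, c("race", "sex")])
    } else {
      utils::combn(nrow(fr), 2)
    }
    purrr::map_dfr(seq_len(ncol(idx)), function(k) {
      i <- idx[1, k]; j <- idx[2, k]
      tibble::tibble(
        roi = r,
        group1 = paste(fr$race[i], fr$sex[i]),
        group2 = paste(fr$race[j], fr$sex[j]),
        age = grid,
        d = effect_size_at(fr$fit[[i]], fr$fit[[j]], grid))
    })
  })
}

#' Maximum effect size over ages and group pairs
#'
#' Summarises [effect_size_curves()]: per ROI and group pair, the largest
#' effect size over the age grid (`d_max`) and the age attaining it; the
#' attribute `global` holds the single largest row per ROI (the `d_max`
#' annotated on trajectory figures).
#'
#' @inheritParams effect_size_curves
#' @return A tibble: `roi`, `group1`, `group2`, `d_max`, `age_at_max`.
#' @export
max_effect_size <- function(fits, age_grid = NULL, pairs = c("panel", "all")) {
  curves <- effect_size_curves(fits, age_grid, pairs)
  out <- dplyr::summarise(
    dplyr::group_by(curves, .data$roi, .data$group1, .data$group2),
    d_max = max(.data$d),
    age_at_max = .data$age[which.max(.data$d)],
    .groups = "drop")
  attr(out, "global") <- dplyr::slice_max(
    dplyr::group_by(out, .data$roi), .data$d_max, n = 1, with_ties = FALSE)
  out
}

#' Effect-size reduction achieved by a normalization
#'
#' Compares the maximum effect sizes of two trajectory sets fitted to the
#' same ROIs and groups — typically raw versus ICV-corrected volumes — and
#' reports the per-pair reduction factor `d_max(raw) / d_max(corrected)`.
#' A zero corrected `d_max` yields an infinite ratio with the `infinite`
#' flag set, not an error.
#'
#' @param fits_raw,fits_corrected Outputs of [fit_trajectories()] on the
#'   uncorrected and corrected cohorts (same ROIs and groups).
#' @inheritParams effect_size_curves
#' @return A tibble: `roi`, `group1`, `group2`, `d_max_raw`,
#'   `d_max_corrected`, `ratio`, `infinite`.
#' @export
normalization_effect_ratio <- function(fits_raw, fits_corrected,
                                       age_grid = NULL,
                                       pairs = c("panel", "all")) {
  pairs <- match.arg(pairs)
  raw <- max_effect_size(fits_raw, age_grid, pairs)
  cor <- max_effect_size(fits_corrected, age_grid, pairs)
  joined <- dplyr::inner_join(
    dplyr::rename(raw, d_max_raw = "d_max", age_raw = "age_at_max"),
    dplyr::rename(cor, d_max_corrected = "d_max", age_cor = "age_at_max"),
    by = c("roi", "group1", "group2"))
  if (nrow(joined) != nrow(raw)) {
    stop("raw and corrected fit sets do not share the same ROIs and groups")
  }
  dplyr::mutate(
    joined[, c("roi", "group1", "group2", "d_max_raw", "d_max_corrected")],
    ratio = dplyr::case_when(
      .data$d_max_corrected > 0 ~ .data$d_max_raw / .data$d_max_corrected,
      .data$d_max_raw == 0 ~ 1,  # no effect before or after correction
      TRUE ~ Inf),
    infinite = .data$d_max_corrected == 0 & .data$d_max_raw > 0)
}
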