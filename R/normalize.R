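#' Division-based ICV normalization
#'
#' The primary head-size correction: each ROI volume is divided by the
#' subject's intracranial volume and multiplied back by the cohort's
#' average ICV, which removes proportional head-size effects while
#' preserving volume units and (approximately) the cohort mean volume.
#' The ICV column itself maps to the constant reference mean.
#'
#' @param subjects Subject-level tibble ([aggregate_subjects()] output or
#'   compatible) containing the [icv_roi()] column.
#' @return The corrected tibble, with attributes `normalization`
#'   (`"division"`) and `reference_mean_icv` (the unweighted grand mean
#'   ICV of the input, in the cohort's volume unit).
#' @export
normalize_division <- function(subjects) {
  icv <- subjects[[icv_roi()]]
  if (is.null(icv)) stop("no \"", icv_roi(), "\" column")
  bad <- which(!(icv > 0))
  if (length(bad)) {
    stop("nonpositive ICV for subject(s): ",
         paste(subjects$subject_id[bad], collapse = ", "))
  }
  m <- mean(icv)
  rois <- roi_columns(subjects)
  out <- dplyr::mutate(
    subjects,
    dplyr::across(dplyr::all_of(rois), ~ .x / icv * m))
  out[[icv_roi()]] <- rep(m, nrow(out))
  attr(out, "normalization") <- "division"
  attr(out, "reference_mean_icv") <- m
  attr(out, "volume_unit") <- attr(subjects, "volume_unit")
  out
}

#' Least-absolute-deviation slope of y on x
#'
#' One-dimensional robust (L1) regression slope used by
#' [normalize_residual()]: minimizes `sum |y - a - beta x|` jointly over
#' intercept and slope, by convex line search over the slope with the
#' median as the profiled intercept.
#'
#' @param x,y Numeric vectors of equal length (`x` non-constant).
#' @return The LAD slope estimate.
#' @export
lad_slope <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (stats::sd(x) == 0) stop("`x` is constant; LAD slope undefined")
  obj <- function(beta) {
    r <- y - beta * x
    sum(abs(r - stats::median(r)))
  }
  b0 <- stats::cov(x, y) / stats::var(x)
  half <- 10 * (stats::mad(y) + stats::sd(y)) / (stats::mad(x) + stats::sd(x)) +
    abs(b0) + 1
  stats::optimize(obj, interval = c(b0 - half, b0 + half),
                  tol = 1e-10)$minimum
}

#' Residual-based ICV normalization
#'
#' Subtracts each ROI's fitted linear dependence on ICV:
#' `v' = v - beta_hat (ICV - mean ICV)`, with `beta_hat` the
#' least-absolute-deviation slope of volume on ICV estimated on a
#' reference subset (default: the whole cohort), consistent with the
#' robust Laplace modelling downstream. The mean volume is approximately
#' preserved.
#'
#' @param subjects Subject-level tibble.
#' @param reference Optional reference subset (rows of `subjects`) on
#'   which slopes and the reference mean ICV are estimated; default the
#'   full cohort. Must have non-constant ICV.
#' @return Corrected tibble with attributes `normalization`
#'   (`"residual"`), `reference_mean_icv`, and `icv_slopes` (named vector
#'   of fitted slopes).
#' @export
normalize_residual <- function(subjects, reference = NULL) {
  if (is.null(reference)) reference <- subjects
  if (nrow(reference) == 0) stop("`reference` is empty")
  icv_ref <- reference[[icv_roi()]]
  if (stats::sd(icv_ref) == 0) {
    stop("degenerate reference: ICV is constant")
  }
  m <- mean(icv_ref)
  icv <- subjects[[icv_roi()]]
  rois <- roi_columns(subjects)
  slopes <- vapply(rois, function(r) lad_slope(icv_ref, reference[[r]]),
                   numeric(1))
  out <- subjects
  for (r in rois) out[[r]] <- out[[r]] - slopes[[r]] * (icv - m)
  attr(out, "normalization") <- "residual"
  attr(out, "reference_mean_icv") <- m
  attr(out, "icv_slopes") <- slopes
  attr(out, "volume_unit") <- attr(subjects, "volume_unit")
  out
}

#' Request covariate-style ICV adjustment inside the trajectory fit
#'
#' Returns a configuration token consumed by [fit_trajectories()]: instead
#' of pre-correcting volumes, the fitted location predictor gains a linear
#' ICV term with a single coefficient shared across ages, handling head
#' size as a nuisance variable inside the model.
#'
#' @return An object of class `covariate_adjust`.
#' @export
covariate_adjust <- function() {
  structure(list(covariate = icv_roi()), class = "covariate_adjust")
}

#' ICV matching between two demographic groups
#'
#' Greedy 1:1 nearest-neighbour matching without replacement on ICV within
#' a caliper, producing head-size-balanced subsets of two groups. Volumes
#' are never altered; the output is a subset. Subjects of the first group
#' are processed in `subject_id` order for determinism.
#'
#' @param subjects Subject-level tibble.
#' @param group_a,group_b Length-2 character vectors `c(race, sex)`.
#' @param caliper Maximum |ICV difference| for a valid pair, in the
#'   cohort's volume unit (mL for generated cohorts).
#' @return The matched subset (rows of both groups), with attributes
#'   `matched_pairs` (tibble `id_a`, `id_b`, `icv_a`, `icv_b`) and
#'   `balance` (post-matching standardized mean ICV difference). An empty
#'   matched set produces a warning, not an error.
#' @export
match_groups <- function(subjects, group_a, group_b, caliper) {
  stopifnot(length(group_a) == 2, length(group_b) == 2, caliper > 0)
  pick <- function(g) dplyr::filter(subjects, .data$race == g[1],
                                    .data$sex == g[2])
  a <- dplyr::arrange(pick(group_a), .data$subject_id)
  b <- dplyr::arrange(pick(group_b), .data$subject_id)
  if (nrow(a) == 0 || nrow(b) == 0) {
    stop("both groups must be nonempty")
  }
  icv_a <- a[[icv_roi()]]; icv_b <- b[[icv_roi()]]
  taken <- rep(FALSE, nrow(b))
  ia <- integer(0); ib <- integer(0)
  for (i in seq_len(nrow(a))) {
    d <- abs(icv_b - icv_a[i])
    d[taken] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= caliper) {
      taken[j] <- TRUE
      ia <- c(ia, i); ib <- c(ib, j)
    }
  }
  if (!length(ia)) {
    warning("no matches within caliper; returning an empty matched set")
    out <- a[0, ]
    attr(out, "matched_pairs") <- tibble::tibble(
      id_a = character(), id_b = character(),
      icv_a = numeric(), icv_b = numeric())
    attr(out, "balance") <- NA_real_
    return(out)
  }
  pairs <- tibble::tibble(
    id_a = a$subject_id[ia], id_b = b$subject_id[ib],
    icv_a = icv_a[ia], icv_b = icv_b[ib])
  out <- dplyr::bind_rows(a[ia, ], b[ib, ])
  s_pool <- sqrt((stats::var(pairs$icv_a) + stats::var(pairs$icv_b)) / 2)
  smd <- if (isTRUE(s_pool > 0)) {
    (mean(pairs$icv_a) - mean(pairs$icv_b)) / s_pool
  } else {
    0
  }
  attr(out, "matched_pairs") <- pairs
  attr(out, "balance") <- smd
  attr(out, "normalization") <- "matching"
  attr(out, "volume_unit") <- attr(subjects, "volume_unit")
  out
}

#' Log-transform selected ROIs
#'
#' Replaces the listed ROI volumes by their natural logarithm. Used for
#' the ventricles, whose cross-sectional volume distribution at any age is
#' strongly right-skewed; the trajectory model is then fit on the log
#' scale. The transform is recorded in the `log_rois` attribute so
#' downstream predictions can be inverted back to volume units.
#'
#' @param subjects Subject-level tibble.
#' @param rois ROI names to transform; default `"ventricles"`. An empty
#'   set is the identity.
#' @return The transformed tibble with attribute `log_rois`.
#' @export
log_transform_rois <- function(subjects, rois = "ventricles") {
  if (length(rois) == 0) return(subjects)
  missing <- setdiff(rois, names(subjects))
  if (length(missing)) {
    stop("ROI column(s) not present: ", paste(missing, collapse = ", "))
  }
  out <- subjects
  for (r in rois) {
    v <- out[[r]]
    if (any(!(v > 0))) {
      stop("nonpositive volumes in ROI \"", r, "\"; cannot log-transform")
    }
    out[[r]] <- log(v)
  }
  attr(out, "log_rois") <- union(attr(subjects, "log_rois"), rois)
  out
}
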