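#' Laplace (double-exponential) random draws
#'
#' @param n Number of draws.
#' @param location Location (median) parameter.
#' @param scale Scale parameter `b` (> 0); the mean absolute deviation of
#'   the law equals `b`.
#' @return Numeric vector of draws.
#' @export
rlaplace <- function(n, location = 0, scale = 1) {
  if (any(scale <= 0)) stop("`scale` must be > 0")
  u <- stats::runif(n) - 0.5
  location - scale * sign(u) * log1p(-2 * abs(u))
}

#' Laplace density
#'
#' @param x Quantiles.
#' @param location,scale Laplace parameters (`scale` > 0).
#' @param log Return the log-density.
#' @return Density values.
#' @export
dlaplace <- function(x, location = 0, scale = 1, log = FALSE) {
  if (any(scale <= 0)) stop("`scale` must be > 0")
  ld <- -log(2 * scale) - abs(x - location) / scale
  if (log) ld else exp(ld)
}

# truncated-normal draw by rejection; truncation is far in the tail for all
# default parameters, so rejection is effectively free
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) {
    if (mean < lower || mean > upper) {
      stop("degenerate (sd = 0) distribution lies outside its bounds")
    }
    return(rep(mean, n))
  }
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}

# age-varying residual scale fraction: scalar = constant, length-4 = spline
# through the anchor ages
scale_frac_at <- function(sf, ages, basis) {
  if (length(sf) == 1L) return(rep(sf, length(ages)))
  drop(eval_basis(basis, ages) %*% trajectory_coef_from_anchors(basis, sf))
}

#' Generative trajectory truth for a synthetic cohort
#'
#' Ground-truth accessor for parameter-recovery tests: the exact location
#' (population median volume, in mL, at the group's mean ICV) and residual
#' scale implied by a [cohort_spec()] for one ROI, group and set of ages.
#' For additive-residual ROIs the scale is in mL; for log-residual ROIs
#' (`log_normal = TRUE`) the scale is the Laplace scale of the log-volume
#' and `log_scale` is `TRUE`.
#'
#' @param spec A [cohort_spec()].
#' @param roi ROI name present in `spec$roi_models`.
#' @param race,sex Group labels present in `spec$group_stats`.
#' @param ages Ages (years) within the spec's age bounds.
#' @return A tibble with columns `age`, `location`, `scale`, `log_scale`.
#' @export
true_trajectory <- function(spec, roi, race, sex, ages) {
  stopifnot(inherits(spec, "cohort_spec"))
  i <- which(spec$roi_models$roi == roi)
  if (!length(i)) stop("unknown ROI: ", roi)
  g <- spec$group_stats[spec$group_stats$race == race &
                          spec$group_stats$sex == sex, ]
  if (!nrow(g)) stop("unknown group: ", race, " ", sex)
  basis <- bspline_basis(spec$anchor_ages, spec$degree, spec$age_bounds)
  theta <- trajectory_coef_from_anchors(basis, spec$roi_models$anchors[[i]])
  f <- drop(eval_basis(basis, ages) %*% theta)
  loc <- g$icv_mean * 1000 * f
  sf <- scale_frac_at(spec$roi_models$scale_frac[[i]], ages, basis)
  log_sc <- spec$roi_models$log_normal[i]
  tibble::tibble(
    age = as.numeric(ages),
    location = loc,
    scale = if (log_sc) sf else sf * loc,
    log_scale = log_sc
  )
}

#' Simulate a scan-level synthetic cohort
#'
#' Generates one row per 3D scan with the statistical structure the
#' downstream analysis assumes. Per race-by-sex group, subject ICVs are
#' drawn from the group's normal law (truncated at zero, a formality at
#' these parameters) and baseline ages from the group's normal law
#' truncated to the age bounds. Each subject receives a number of visits
#' and scans-per-visit drawn uniformly from the configured ranges; visits
#' are 0.5--2 years apart. A scan's ROI volume is
#' `ICV x trajectory(age) x residual`: the trajectory is the spec's
#' B-spline fraction-of-ICV curve, and the residual is a subject-level
#' Laplace deviate (additive by default, multiplicative on the log scale
#' for `log_normal` ROIs) plus small per-scan multiplicative Gaussian
#' jitter. QC scores for analysis subjects follow Beta(`qc_shape1`,
#' `qc_shape2`); on top of the requested group sizes, a fraction
#' `fail_frac` of extra subjects is planted whose scans all score below
#' 0.75, so QC aggregation excludes exactly those subjects.
#'
#' Generation is fully deterministic given the spec (including its seed).
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with columns `subject_id`, `visit_id`, `scan_id`,
#'   `age`, `sex`, `race`, `qc`, then one column per ROI in millilitres
#'   including [icv_roi()]. Attributes: `volume_unit` (`"mL"`) and
#'   `planted_failures` (subject ids whose scans all fail QC).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  gs <- spec$group_stats
  if (sum(gs$n) == 0) stop("empty cohort: all group sizes are zero")
  set.seed(spec$seed)
  basis <- bspline_basis(spec$anchor_ages, spec$degree, spec$age_bounds)
  roi_tbl <- spec$roi_models
  roi_coef <- lapply(roi_tbl$anchors,
                     function(a) trajectory_coef_from_anchors(basis, a))

  groups <- purrr::map(seq_len(nrow(gs)), function(gi) {
    g <- gs[gi, ]
    n_fail <- round(spec$fail_frac * g$n)
    n_tot <- g$n + n_fail
    if (n_tot == 0) return(NULL)
    prefix <- paste0(substr(g$race, 1, 1), substr(g$sex, 1, 1))
    sid <- sprintf("%s%05d", prefix, seq_len(n_tot))
    failing <- rep(c(FALSE, TRUE), c(g$n, n_fail))

    icv_l <- rnorm_trunc(n_tot, g$icv_mean, g$icv_sd, lower = 0)
    age0 <- rnorm_trunc(n_tot, g$age_mean, g$age_sd,
                        spec$age_bounds[1], spec$age_bounds[2])
    nv <- sample(seq(spec$visits_per_subject_range[1],
                     spec$visits_per_subject_range[2]),
                 n_tot, replace = TRUE)
    # subject-level Laplace deviates, shared across that subject's scans
    z <- matrix(rlaplace(n_tot * nrow(roi_tbl)), n_tot, nrow(roi_tbl))

    # visit table
    vis <- tibble::tibble(
      si = rep(seq_len(n_tot), nv),
      visit = sequence(nv)
    )
    gap <- stats::runif(nrow(vis), 0.5, 2)
    vis$age <- pmin(
      age0[vis$si] + stats::ave(gap, vis$si, FUN = function(x) {
        cumsum(x) - x[1]
      }),
      spec$age_bounds[2]
    )
    ns <- sample(seq(spec$scans_per_visit_range[1],
                     spec$scans_per_visit_range[2]),
                 nrow(vis), replace = TRUE)

    # per-visit trajectory fractions, one column per ROI
    Bv <- eval_basis(basis, vis$age)
    frac <- vapply(roi_coef, function(th) drop(Bv %*% th),
                   numeric(nrow(vis)))
    sfv <- vapply(seq_len(nrow(roi_tbl)), function(ri) {
      scale_frac_at(roi_tbl$scale_frac[[ri]], vis$age, basis)
    }, numeric(nrow(vis)))

    # expand visits to scans
    scan <- tibble::tibble(
      vi = rep(seq_len(nrow(vis)), ns),
      scan = sequence(ns)
    )
    si <- vis$si[scan$vi]
    icv_ml <- icv_l[si] * 1000
    icv_scan <- icv_ml * stats::rnorm(nrow(scan), 1, spec$scan_jitter_frac)

    vols <- matrix(NA_real_, nrow(scan), nrow(roi_tbl))
    for (ri in seq_len(nrow(roi_tbl))) {
      med <- icv_ml * frac[scan$vi, ri]
      sf <- sfv[scan$vi, ri]
      v <- if (roi_tbl$log_normal[ri]) {
        med * exp(z[si, ri] * sf)
      } else {
        med * (1 + z[si, ri] * sf)
      }
      v <- v * stats::rnorm(nrow(scan), 1, spec$scan_jitter_frac)
      # physical guards: positive and strictly inside the cranium
      vols[, ri] <- pmin(pmax(v, 1e-6), 0.99 * icv_scan)
    }

    qc <- stats::rbeta(nrow(scan), spec$qc_shape1, spec$qc_shape2)
    fail_scan <- failing[si]
    if (any(fail_scan)) {
      qc[fail_scan] <- 0.75 * stats::rbeta(sum(fail_scan), 2, 2)
    }
    # guarantee every analysis subject keeps at least one passing scan
    first <- !duplicated(si) & !fail_scan
    if (any(first)) {
      p0 <- stats::pbeta(0.75, spec$qc_shape1, spec$qc_shape2)
      qc[first] <- stats::qbeta(stats::runif(sum(first), p0, 1),
                                spec$qc_shape1, spec$qc_shape2)
    }

    out <- tibble::tibble(
      subject_id = sid[si],
      visit_id = sprintf("%s-v%02d", sid[si], vis$visit[scan$vi]),
      scan_id = sprintf("%s-v%02d-s%02d", sid[si], vis$visit[scan$vi],
                        scan$scan),
      age = vis$age[scan$vi],
      sex = g$sex, race = g$race,
      qc = qc
    )
    out <- dplyr::bind_cols(
      out,
      tibble::as_tibble(stats::setNames(as.data.frame(vols), roi_tbl$roi))
    )
    out[[icv_roi()]] <- icv_scan
    attr(out, "planted") <- sid[failing]
    out
  })

  planted <- unlist(lapply(groups, attr, "planted"))
  cohort <- dplyr::bind_rows(groups)
  attr(cohort, "volume_unit") <- "mL"
  attr(cohort, "planted_failures") <- planted
  cohort
}

#' Simulate data directly from the Laplace trajectory model
#'
#' Model-exact simulator for calibration and parameter-recovery work:
#' given basis coefficients for the location and the log-scale curves,
#' draws `v = mu(a) + Laplace(0, b(a))` at ages uniform over the basis
#' domain (or at supplied ages). Uses the caller's RNG state.
#'
#' @param n Number of observations (ignored when `ages` supplied).
#' @param basis A [bspline_basis()].
#' @param theta_mu,theta_b Coefficient vectors of length `basis$n_basis`;
#'   `theta_b` parameterizes the spline of `log b`.
#' @param ages Optional ages; default uniform over the basis domain.
#' @return A tibble with columns `age`, `volume`.
#' @export
simulate_laplace_data <- function(n, basis, theta_mu, theta_b, ages = NULL) {
  stopifnot(inherits(basis, "bspline_basis"))
  if (is.null(ages)) {
    ages <- stats::runif(n, basis$domain[1], basis$domain[2])
  }
  B <- eval_basis(basis, ages)
  mu <- drop(B %*% theta_mu)
  b <- exp(drop(B %*% theta_b))
  tibble::tibble(age = ages, volume = mu + rlaplace(length(ages), 0, b))
}

#' Write / read the per-scan cohort CSV
#'
#' The cohort interchange format is a SynthSeg+-style UTF-8 CSV with a
#' header row and "." decimal separator: columns `subject_id`, `visit_id`,
#' `scan_id`, `age`, `sex`, `race`, `qc`, then one column per ROI including
#' `"total intracranial"`. Volumes are in millilitres.
#'
#' @param scans Scan-level tibble as produced by [simulate_cohort()].
#' @param path CSV file path.
#' @return `write_cohort_csv` returns `scans` invisibly; `read_cohort_csv`
#'   returns the scan tibble with the `volume_unit` attribute set.
#' @export
write_cohort_csv <- function(scans, path) {
  readr::write_csv(scans, path)
  invisible(scans)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  meta <- c("subject_id", "visit_id", "scan_id", "age", "sex", "race", "qc")
  missing <- setdiff(meta, names(out))
  if (length(missing)) {
    stop("cohort CSV is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!icv_roi() %in% names(out)) {
    stop("cohort CSV has no \"", icv_roi(), "\" (ICV) column")
  }
  attr(out, "volume_unit") <- "mL"
  out
}
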