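#' Exact Laplace trajectory log-likelihood
#'
#' The objective of the robust trajectory model: with location
#' `mu(a) = B(a) theta_mu` and scale `b(a) = exp(B(a) theta_b)` (the
#' log-scale parameterization guarantees positivity),
#' `L = sum_n [ -log(2 b_n) - |v_n - mu_n| / b_n ]` — the exact Laplace
#' log-density summed over observations, no constants dropped.
#'
#' @param theta_mu,theta_b Coefficient vectors of length `basis$n_basis`.
#' @param ages,volumes Observation vectors of equal, nonzero length; ages
#'   must lie in the basis domain.
#' @param basis A [bspline_basis()].
#' @param covariate Optional centred covariate vector (ICV adjustment);
#'   adds `gamma * covariate` to the location.
#' @param gamma Covariate coefficient; default 0.
#' @return The log-likelihood (a single number).
#' @export
laplace_log_likelihood <- function(theta_mu, theta_b, ages, volumes,
                                   basis = bspline_basis(),
                                   covariate = NULL, gamma = 0) {
  stopifnot(length(ages) == length(volumes), length(ages) > 0)
  B <- eval_basis(basis, ages)
  mu <- drop(B %*% theta_mu)
  if (!is.null(covariate)) mu <- mu + gamma * covariate
  b <- exp(drop(B %*% theta_b))
  if (any(!(b > 0))) stop("implied scale is nonpositive")
  sum(-log(2 * b) - abs(volumes - mu) / b)
}

#' Optimizer settings for the trajectory fit
#'
#' @param max_iter Maximum gradient-ascent iterations; default 5000.
#' @param tol_obj Relative objective-change tolerance; default 1e-8.
#' @param tol_grad Gradient sup-norm tolerance (on the internally
#'   standardized problem); default 1e-6.
#' @param eps_frac Smoothing width of `|.|` as a fraction of the volume
#'   scale; default 1e-6.
#' @return A list of class `laplace_control`.
#' @export
laplace_control <- function(max_iter = 5000L, tol_obj = 1e-8,
                            tol_grad = 1e-6, eps_frac = 1e-6) {
  structure(list(max_iter = as.integer(max_iter), tol_obj = tol_obj,
                 tol_grad = tol_grad, eps_frac = eps_frac),
            class = "laplace_control")
}

# resolve a column given as a bare name or a character scalar
col_name <- function(q) {
  if (rlang::quo_is_null(q)) return(NULL)
  if (rlang::quo_is_symbol(q)) return(rlang::as_name(q))
  val <- rlang::eval_tidy(q)
  if (is.null(val)) return(NULL)
  if (!is.character(val) || length(val) != 1) {
    stop("column must be given as a bare name or a single string")
  }
  val
}

# gradient ascent with backtracking (Armijo) line search on the smoothed
# mean log-likelihood of the standardized problem; deterministic, no RNG
laplace_ascent <- function(B, v, xc = NULL, control = laplace_control()) {
  n <- length(v); nb <- ncol(B)
  has_cov <- !is.null(xc)

  obj <- function(p, eps) {
    mu <- drop(B %*% p$tm); if (has_cov) mu <- mu + p$g * xc
    lb <- drop(B %*% p$tb)
    r <- v - mu
    mean(-log(2) - lb - sqrt(r * r + eps * eps) / exp(lb))
  }
  grad <- function(p, eps) {
    mu <- drop(B %*% p$tm); if (has_cov) mu <- mu + p$g * xc
    lb <- drop(B %*% p$tb); b <- exp(lb)
    r <- v - mu
    s <- sqrt(r * r + eps * eps)
    w_mu <- (r / s) / b       # d/dmu of -s/b is +(r/s)/b
    w_b <- s / b - 1          # d/d(lb)
    list(tm = drop(crossprod(B, w_mu)) / n,
         tb = drop(crossprod(B, w_b)) / n,
         g = if (has_cov) sum(w_mu * xc) / n else 0)
  }

  # deterministic initialization: L2 spline for the location, constant
  # log-scale at the mean absolute L2 residual
  tm0 <- qr.coef(qr(B), v)
  tm0[is.na(tm0)] <- 0
  r0 <- v - drop(B %*% tm0)
  b0 <- mean(abs(r0)); if (!(b0 > 0)) b0 <- control$eps_frac + 1e-8
  p <- list(tm = tm0, tb = rep(log(b0), nb), g = 0)

  # graduated smoothing: anneal the |.| smoothing width down to eps_frac,
  # warm-starting each stage, so the ascent is never trapped by the near-
  # kink stiffness of the final objective
  eps_stages <- 10^seq(-2, log10(control$eps_frac), by = -1)
  if (eps_stages[length(eps_stages)] > control$eps_frac) {
    eps_stages <- c(eps_stages, control$eps_frac)
  }
  trace <- numeric(0)
  it_total <- 0L
  converged <- FALSE
  for (eps in eps_stages) {
    last <- eps == eps_stages[length(eps_stages)]
    f <- obj(p, eps)
    trace <- c(trace, f)
    step <- 1
    stall <- 0L
    converged <- FALSE
    while (it_total < control$max_iter) {
      it_total <- it_total + 1L
      gr <- grad(p, eps)
      gnorm2 <- sum(gr$tm^2) + sum(gr$tb^2) + gr$g^2
      gsup <- max(abs(c(gr$tm, gr$tb, gr$g)))
      if (gsup <= control$tol_grad) { converged <- TRUE; break }
      step <- min(step * 2, 1e6)
      accepted <- FALSE
      while (step > 1e-14) {
        cand <- list(tm = p$tm + step * gr$tm,
                     tb = p$tb + step * gr$tb,
                     g = p$g + step * gr$g)
        fc <- obj(cand, eps)
        if (is.finite(fc) && fc >= f + 1e-4 * step * gnorm2) {
          accepted <- TRUE
          break
        }
        step <- step / 2
      }
      if (!accepted) { converged <- TRUE; break }  # numerical optimum
      rel <- (fc - f) / (abs(f) + 1)
      p <- cand; f <- fc
      trace <- c(trace, f)
      # require sustained stagnation before declaring convergence, so a
      # single short zigzag step cannot stop the ascent early
      stall <- if (rel <= control$tol_obj) stall + 1L else 0L
      if (stall >= 5L) { converged <- TRUE; break }
    }
    if (!converged && !last) next
  }
  list(p = p, n_iter = it_total, converged = converged, trace = trace)
}

#' Fit a robust Laplace location-scale aging trajectory
#'
#' Fits the trajectory model by maximum likelihood: volumes follow a
#' Laplace law whose location `mu(age)` and scale `b(age)` are B-splines
#' (the scale through a log link, so it is positive for any
#' coefficients). The location is the age-varying median, making the fit
#' robust to segmentation outliers; the `mu(age) +/- 3 b(age)` band is the
#' population 95% spread band of the Laplace law. The likelihood is
#' maximized by gradient ascent with backtracking line search on a
#' smoothed |.| (the objective is monotone nondecreasing across accepted
#' steps); internally the data are standardized (median/MAD) and the
#' coefficients mapped back exactly, so the optimizer is unit-free. The
#' fit is deterministic: fixed initialization from an L2 spline fit, no
#' randomness.
#'
#' @param data A data frame of observations.
#' @param volume Column holding the response volume (bare name or string).
#' @param age Column holding age in years; default `age`.
#' @param basis A [bspline_basis()]; default cubic with anchors
#'   27/45/63/81 over ages 18--90.
#' @param covariate Optional column (bare name or string) to include as a
#'   linear nuisance term in the location, with one coefficient shared
#'   across ages (the covariate-adjustment ICV scheme). Centred
#'   internally.
#' @param log_volume Mark the response as a log-transformed volume (used
#'   by [predict.laplace_fit()] and effect-size bookkeeping).
#' @param control A [laplace_control()].
#' @return An object of class `laplace_fit`: coefficients `theta_mu`
#'   (volume units) and `theta_b` (log-scale), optional `covariate_coef`,
#'   the exact (unsmoothed) `log_lik`, `converged`, `n_iter`, `n`, the
#'   `basis`, and the per-iteration objective `trace`.
#' @examples
#' basis <- bspline_basis()
#' set.seed(1)
#' d <- simulate_laplace_data(500, basis,
#'                            theta_mu = c(8, 7.8, 7.4, 6.6),
#'                            theta_b = log(c(0.5, 0.5, 0.6, 0.7)))
#' fit <- fit_laplace_trajectory(d, volume)
#' predict(fit, ages = c(30, 60, 85))
#' @export
fit_laplace_trajectory <- function(data, volume, age = age,
                                   basis = bspline_basis(),
                                   covariate = NULL,
                                   log_volume = FALSE,
                                   control = laplace_control()) {
  vcol <- col_name(rlang::enquo(volume))
  acol <- col_name(rlang::enquo(age))
  ccol <- col_name(rlang::enquo(covariate))

  v_raw <- as.numeric(data[[vcol]])
  a_raw <- as.numeric(data[[acol]])
  keep <- is.finite(v_raw) & is.finite(a_raw)
  v_raw <- v_raw[keep]; a_raw <- a_raw[keep]
  if (!length(v_raw)) stop("no complete observations")
  if (length(v_raw) < 5 * basis$n_basis) {
    warning("only ", length(v_raw), " observations for ", basis$n_basis,
            " basis functions; fit may be unstable")
  }
  B <- eval_basis(basis, a_raw)

  # unit-free standardization; mapped back exactly below
  c0 <- stats::median(v_raw)
  s0 <- stats::mad(v_raw)
  if (!(s0 > 0)) s0 <- stats::sd(v_raw)
  if (!(is.finite(s0) && s0 > 0)) s0 <- 1
  v <- (v_raw - c0) / s0

  xc <- NULL; cx_mean <- 0; cx_sd <- 1
  if (!is.null(ccol)) {
    x <- as.numeric(data[[ccol]])[keep]
    cx_mean <- mean(x); cx_sd <- stats::sd(x)
    if (!(cx_sd > 0)) stop("covariate \"", ccol, "\" is constant")
    xc <- (x - cx_mean) / cx_sd
  }

  res <- laplace_ascent(B, v, xc, control)
  if (!res$converged) {
    warning("gradient ascent did not converge in ", res$n_iter,
            " iterations")
  }

  # back-transform: mu = s0*mu_std + c0 (partition of unity), b = s0*b_std
  theta_mu <- s0 * res$p$tm + c0
  theta_b <- res$p$tb + log(s0)
  gamma <- if (!is.null(xc)) s0 * res$p$g / cx_sd else NULL

  ll <- laplace_log_likelihood(
    theta_mu, theta_b, a_raw, v_raw, basis,
    covariate = if (!is.null(xc)) xc * cx_sd else NULL,
    gamma = if (!is.null(gamma)) gamma else 0)

  structure(
    list(theta_mu = theta_mu, theta_b = theta_b,
         covariate_coef = gamma, covariate = ccol,
         covariate_mean = if (!is.null(ccol)) cx_mean else NULL,
         log_lik = ll, converged = res$converged, n_iter = res$n_iter,
         n = length(v_raw), basis = basis, log_volume = isTRUE(log_volume),
         trace = res$trace, volume_col = vcol),
    class = "laplace_fit"
  )
}

#' Predict trajectory location, scale and 95% band
#'
#' Evaluates the fitted median `mu(a)`, scale `b(a)` and the Laplace 95%
#' population band `mu(a) +/- 3 b(a)` (the exact 95% multiple is
#' `-log(0.05) = 2.9957`, i.e. almost exactly 3; see
#' [laplace_interval_multiple()]). For fits on log-transformed volumes,
#' `backtransform = TRUE` exponentiates the location and band back to
#' volume units (the scale column stays on the log scale).
#'
#' @param object A `laplace_fit`.
#' @param ages Ages to evaluate; ages outside the basis domain are an
#'   error unless `allow_extrapolation = TRUE`.
#' @param backtransform Exponentiate predictions of a log-volume fit.
#' @param allow_extrapolation Permit ages outside the fit domain.
#' @param ... Unused.
#' @return A tibble with columns `age`, `location`, `scale`, `lower95`,
#'   `upper95`.
#' @export
predict.laplace_fit <- function(object, ages, backtransform = FALSE,
                                allow_extrapolation = FALSE, ...) {
  B <- eval_basis(object$basis, ages, allow_extrapolation)
  mu <- drop(B %*% object$theta_mu)
  b <- exp(drop(B %*% object$theta_b))
  lo <- mu - 3 * b; hi <- mu + 3 * b
  if (backtransform) {
    if (!object$log_volume) {
      stop("`backtransform = TRUE` only applies to log-volume fits")
    }
    mu <- exp(mu); lo <- exp(lo); hi <- exp(hi)
  }
  tibble::tibble(age = as.numeric(ages), location = mu, scale = b,
                 lower95 = lo, upper95 = hi)
}

#' The exact Laplace central-interval multiple of the scale
#'
#' The central interval `mu +/- m b` of a Laplace law has coverage
#' `1 - exp(-m)`, so the exact multiple for a given coverage level is
#' `-log(1 - level)`; at 95% this is 2.9957, i.e. almost exactly the 3
#' used for the plotted bands.
#'
#' @param level Coverage level; default 0.95.
#' @return The multiple `m`.
#' @export
laplace_interval_multiple <- function(level = 0.95) {
  stopifnot(level > 0, level < 1)
  -log(1 - level)
}

#' @export
print.laplace_fit <- function(x, ...) {
  cat("Laplace location-scale trajectory fit (", x$volume_col, ")\n",
      sep = "")
  cat("  n =", x$n, "; logLik =", format(x$log_lik, digits = 6),
      "; iterations =", x$n_iter,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  if (!is.null(x$covariate_coef)) {
    cat("  covariate", x$covariate, "coefficient:",
        format(x$covariate_coef, digits = 4), "\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Laplace trajectory fit
#'
#' @param x A `laplace_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `curve` (`"location"`, `"log_scale"` or `"covariate"`) and
#'   `anchor_age` where applicable.
#' @method tidy laplace_fit
#' @export
tidy.laplace_fit <- function(x, ...) {
  nb <- x$basis$n_basis
  out <- tibble::tibble(
    term = c(paste0("mu_", seq_len(nb)), paste0("logb_", seq_len(nb))),
    curve = rep(c("location", "log_scale"), each = nb),
    anchor_age = rep(x$basis$control_ages, 2),
    estimate = c(x$theta_mu, x$theta_b))
  if (!is.null(x$covariate_coef)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = paste0("coef_", x$covariate), curve = "covariate",
      anchor_age = NA_real_, estimate = x$covariate_coef))
  }
  out
}

#' Glance at a Laplace trajectory fit
#'
#' @param x A `laplace_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `log_lik`, `n`, `df`, `converged`, `n_iter`.
#' @method glance laplace_fit
#' @export
glance.laplace_fit <- function(x, ...) {
  tibble::tibble(
    log_lik = x$log_lik, n = x$n,
    df = 2 * x$basis$n_basis + !is.null(x$covariate_coef),
    converged = x$converged, n_iter = x$n_iter)
}

#' Fit trajectories per ROI and demographic group
#'
#' Maps [fit_laplace_trajectory()] over every requested ROI within every
#' race-by-sex cell (or other grouping) of a subject-level cohort. ROIs
#' listed in the cohort's `log_rois` attribute are flagged as log-volume
#' fits. Non-convergent fits produce a warning and are flagged, never
#' dropped.
#'
#' @param subjects Subject-level tibble.
#' @param rois ROI columns to fit; default all non-ICV ROI columns.
#' @param by Grouping columns; default `c("race", "sex")`. `NULL` fits
#'   one pooled trajectory per ROI.
#' @param basis A [bspline_basis()].
#' @param adjust Optional [covariate_adjust()] token: include ICV as a
#'   shared linear nuisance term in each location predictor.
#' @param control A [laplace_control()].
#' @return A tibble with one row per ROI-by-group fit: the grouping
#'   columns, `roi`, `n`, `converged`, `log_lik` and a `fit` list-column
#'   of `laplace_fit` objects.
#' @export
fit_trajectories <- function(subjects, rois = NULL, by = c("race", "sex"),
                             basis = bspline_basis(), adjust = NULL,
                             control = laplace_control()) {
  if (is.null(rois)) rois <- setdiff(roi_columns(subjects), icv_roi())
  missing <- setdiff(rois, names(subjects))
  if (length(missing)) {
    stop("ROI column(s) not present: ", paste(missing, collapse = ", "))
  }
  log_rois <- attr(subjects, "log_rois")
  use_cov <- inherits(adjust, "covariate_adjust")
  if (is.null(by)) {
    grid <- tibble::tibble(roi = rois)
  } else {
    cells <- dplyr::distinct(subjects[, by, drop = FALSE])
    cells <- dplyr::arrange(cells, !!!rlang::syms(by))
    grid <- tidyr::expand_grid(cells, roi = rois)
  }
  fits <- purrr::pmap(grid, function(...) {
    row <- list(...)
    d <- subjects
    if (!is.null(by)) {
      for (col in by) d <- d[d[[col]] == row[[col]], , drop = FALSE]
    }
    fit_laplace_trajectory(
      d, volume = row$roi, basis = basis,
      covariate = if (use_cov) icv_roi() else NULL,
      log_volume = row$roi %in% log_rois,
      control = control)
  })
  grid$n <- vapply(fits, `[[`, integer(1), "n")
  grid$converged <- vapply(fits, `[[`, logical(1), "converged")
  grid$log_lik <- vapply(fits, `[[`, numeric(1), "log_lik")
  grid$fit <- fits
  grid
}

#' Serialize trajectory fits to JSON
#'
#' Writes one JSON file per fit, named `{roi}__{race}_{sex}.json` (spaces
#' in names become underscores), containing coefficients, knots, degree
#' and convergence metadata; [read_fit_json()] restores a working
#' `laplace_fit`.
#'
#' @param fits Output of [fit_trajectories()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_fit_json <- function(fits, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  slug <- function(x) gsub("[^A-Za-z0-9]+", "_", x)
  paths <- character(nrow(fits))
  for (i in seq_len(nrow(fits))) {
    f <- fits$fit[[i]]
    grp <- if (all(c("race", "sex") %in% names(fits))) {
      paste0(slug(fits$race[i]), "_", slug(fits$sex[i]))
    } else {
      "pooled"
    }
    paths[i] <- file.path(dir, paste0(slug(fits$roi[i]), "__", grp, ".json"))
    payload <- list(
      roi = fits$roi[i],
      race = if ("race" %in% names(fits)) fits$race[i] else NULL,
      sex = if ("sex" %in% names(fits)) fits$sex[i] else NULL,
      theta_mu = f$theta_mu, theta_b = f$theta_b,
      covariate_coef = f$covariate_coef,
      log_lik = f$log_lik, converged = f$converged,
      n_iter = f$n_iter, n = f$n, log_volume = f$log_volume,
      basis = list(degree = f$basis$degree,
                   control_ages = f$basis$control_ages,
                   knots = f$basis$knots,
                   domain = f$basis$domain))
    jsonlite::write_json(payload, paths[i], auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(paths)
}

#' @rdname write_fit_json
#' @param path A JSON file written by [write_fit_json()].
#' @export
read_fit_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  basis <- bspline_basis(x$basis$control_ages, x$basis$degree,
                         x$basis$domain)
  structure(
    list(theta_mu = x$theta_mu, theta_b = x$theta_b,
         covariate_coef = x$covariate_coef, covariate = NULL,
         covariate_mean = NULL,
         log_lik = x$log_lik, converged = x$converged,
         n_iter = x$n_iter, n = x$n, basis = basis,
         log_volume = isTRUE(x$log_volume), trace = NULL,
         volume_col = x$roi),
    class = "laplace_fit"
  )
}
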