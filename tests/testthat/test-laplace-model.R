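test_that("the log-likelihood is the exact Laplace log-density, summed", {
  basis <- bspline_basis()
  # single datum at the fitted median with b = 0.5: -log(2 * 0.5) - 0 = 0
  theta_mu <- rep(7, 4); theta_b <- rep(log(0.5), 4)
  expect_equal(
    laplace_log_likelihood(theta_mu, theta_b, 50, 7, basis), 0)
  # additivity over identical data points
  one <- laplace_log_likelihood(theta_mu, theta_b, 43, 6.2, basis)
  many <- laplace_log_likelihood(theta_mu, theta_b, rep(43, 9),
                                 rep(6.2, 9), basis)
  expect_equal(many, 9 * one)
  # oracle: textbook density p(x; mu, b) = exp(-|x - mu|/b) / (2b)
  set.seed(61)
  tm <- rnorm(4, 7, 1); tb <- rnorm(4, log(0.5), 0.3)
  ages <- runif(50, 18, 90); v <- rnorm(50, 7, 1)
  B <- eval_basis(basis, ages)
  expect_equal(
    laplace_log_likelihood(tm, tb, ages, v, basis),
    laplace_ll_oracle(drop(B %*% tm), exp(drop(B %*% tb)), v),
    tolerance = 1e-10)
})

test_that("a constant (degree-0) fit returns the sample median and MAD about it", {
  set.seed(62)
  v <- rlaplace(2001, 5, 0.8)  # odd n: the L1 location optimum is unique
  d <- tibble::tibble(age = runif(2001, 18, 90), volume = v)
  b0 <- bspline_basis(50, degree = 0)
  fit <- fit_laplace_trajectory(
    d, volume, basis = b0,
    control = laplace_control(tol_obj = 1e-12, tol_grad = 1e-8))
  expect_lt(abs(fit$theta_mu - median(v)) / abs(median(v)), 1e-6)
  mad_med <- mean(abs(v - median(v)))
  expect_lt(abs(exp(fit$theta_b) - mad_med) / mad_med, 1e-6)
})

test_that("the fit is deterministic, duplication-invariant and affine-equivariant", {
  basis <- bspline_basis()
  set.seed(63)
  d <- simulate_laplace_data(
    800, basis,
    trajectory_coef_from_anchors(basis, c(8, 7.8, 7.3, 6.4)),
    rep(log(0.5), 4))
  f1 <- fit_laplace_trajectory(d, volume)
  f2 <- fit_laplace_trajectory(d, volume)
  expect_identical(f1$theta_mu, f2$theta_mu)
  doubled <- dplyr::bind_rows(d, d)
  fd <- fit_laplace_trajectory(doubled, volume)
  expect_equal(fd$theta_mu, f1$theta_mu, tolerance = 1e-8)
  expect_equal(fd$theta_b, f1$theta_b, tolerance = 1e-8)
  expect_equal(fd$log_lik, 2 * f1$log_lik, tolerance = 1e-6)
  # shift: location shifts, scale unchanged
  fs <- fit_laplace_trajectory(dplyr::mutate(d, volume = volume + 100), volume)
  expect_equal(fs$theta_mu, f1$theta_mu + 100, tolerance = 1e-8)
  expect_equal(fs$theta_b, f1$theta_b, tolerance = 1e-8)
  # scaling: both location and scale scale
  fk <- fit_laplace_trajectory(dplyr::mutate(d, volume = volume * 3), volume)
  expect_equal(fk$theta_mu, 3 * f1$theta_mu, tolerance = 1e-8)
  expect_equal(fk$theta_b, f1$theta_b + log(3), tolerance = 1e-8)
})

test_that("the ascent objective never decreases and matches an independent optimizer", {
  basis <- bspline_basis()
  set.seed(64)
  d <- simulate_laplace_data(
    600, basis,
    trajectory_coef_from_anchors(basis, c(8, 7.8, 7.3, 6.4)),
    trajectory_coef_from_anchors(basis, log(c(0.45, 0.5, 0.55, 0.7))))
  fit <- fit_laplace_trajectory(d, volume)
  expect_true(fit$converged)
  expect_true(all(diff(fit$trace) >= 0))
  # independent check: Nelder-Mead refinement cannot beat the optimum by
  # more than numerical slack
  nll <- function(th) {
    -laplace_log_likelihood(th[1:4], th[5:8], d$age, d$volume, basis)
  }
  o <- optim(c(fit$theta_mu, fit$theta_b), nll,
             control = list(maxit = 5000, reltol = 1e-10))
  expect_lt(-o$value - fit$log_lik, 1e-2)
})

test_that("the L1 location resists outliers better than a least-squares spline", {
  basis <- bspline_basis()
  tm <- trajectory_coef_from_anchors(basis, c(8, 7.8, 7.3, 6.4))
  tb <- trajectory_coef_from_anchors(basis, log(c(0.5, 0.5, 0.55, 0.65)))
  set.seed(65)
  d <- simulate_laplace_data(4000, basis, tm, tb)
  n_out <- round(0.05 * nrow(d))
  idx <- sample(nrow(d), n_out)
  b_at <- exp(drop(eval_basis(basis, d$age[idx]) %*% tb))
  dc <- d
  dc$volume[idx] <- d$volume[idx] + sample(c(-1, 1), n_out, TRUE) * 10 * b_at
  mid <- c(35, 45, 55, 65, 75)
  move_l1 <- mean(abs(
    predict(fit_laplace_trajectory(dc, volume), mid)$location -
      predict(fit_laplace_trajectory(d, volume), mid)$location))
  Bm <- eval_basis(basis, mid)
  l2 <- function(dd) drop(Bm %*% qr.coef(qr(eval_basis(basis, dd$age)),
                                         dd$volume))
  move_l2 <- mean(abs(l2(dc) - l2(d)))
  expect_lt(move_l1, move_l2)
})

test_that("predicted bands are the median plus/minus three scales with Laplace coverage", {
  basis <- bspline_basis()
  fit <- structure(
    list(theta_mu = rep(5, 4), theta_b = rep(0, 4), covariate_coef = NULL,
         log_lik = 0, converged = TRUE, n_iter = 0L, n = 0L,
         basis = basis, log_volume = FALSE, trace = NULL,
         volume_col = "x"),
    class = "laplace_fit")
  p <- predict(fit, c(20, 50, 88))
  expect_equal(p$upper95 - p$location, rep(3, 3))  # b = 1 everywhere
  expect_equal(p$location - p$lower95, rep(3, 3))
  expect_error(predict(fit, 95), "domain")
  expect_equal(nrow(predict(fit, 95, allow_extrapolation = TRUE)), 1)
  # exact 95% multiple is -log(0.05), i.e. almost exactly 3
  expect_equal(laplace_interval_multiple(0.95), -log(0.05))
  expect_equal(round(laplace_interval_multiple(0.95)), 3)
  # Monte-Carlo coverage of mu +/- 3b on model-simulated draws
  set.seed(66)
  draws <- rlaplace(1e5, 5, 1)
  cover <- mean(draws > 5 - 3 & draws < 5 + 3)
  expect_equal(cover, 1 - exp(-3), tolerance = 0.01)
  expect_gt(cover, 0.944); expect_lt(cover, 0.956)
})

test_that("log-volume fits back-transform and tidy/glance expose the fit", {
  basis <- bspline_basis()
  set.seed(67)
  d <- simulate_laplace_data(400, basis, rep(log(20), 4), rep(log(0.3), 4))
  fit <- fit_laplace_trajectory(d, volume, log_volume = TRUE)
  p <- predict(fit, 50, backtransform = TRUE)
  expect_gt(p$location, 0)
  expect_equal(log(p$location),
               predict(fit, 50)$location, tolerance = 1e-12)
  raw_fit <- fit_laplace_trajectory(d, volume)
  expect_error(predict(raw_fit, 50, backtransform = TRUE), "log-volume")
  td <- tidy(fit)
  expect_equal(nrow(td), 8)
  expect_setequal(unique(td$curve), c("location", "log_scale"))
  g <- glance(fit)
  expect_equal(g$n, 400L)
  expect_equal(g$df, 8)
  expect_true(g$converged)
})

test_that("fit JSON serialization round-trips predictions", {
  basis <- bspline_basis()
  set.seed(68)
  gs <- default_group_stats()[1:4, ]; gs$n <- rep(60L, 4)
  spec <- cohort_spec(
    group_stats = gs,
    roi_models = default_roi_models()[5, ],
    scans_per_visit_range = c(1L, 1L), visits_per_subject_range = c(1L, 1L),
    fail_frac = 0, seed = 8)
  subj <- aggregate_subjects(simulate_cohort(spec))
  fits <- fit_trajectories(subj, "hippocampus")
  expect_equal(nrow(fits), 4)
  dir <- withr::local_tempdir()
  paths <- write_fit_json(fits, dir)
  back <- read_fit_json(paths[1])
  expect_equal(predict(back, c(30, 60))$location,
               predict(fits$fit[[1]], c(30, 60))$location, tolerance = 1e-12)
})
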