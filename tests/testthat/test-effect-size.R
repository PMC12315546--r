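make_fit <- function(mu_anchors, b_anchors, log_volume = FALSE,
                     basis = bspline_basis()) {
  structure(
    list(theta_mu = trajectory_coef_from_anchors(basis, mu_anchors),
         theta_b = trajectory_coef_from_anchors(basis, log(b_anchors)),
         covariate_coef = NULL, log_lik = 0, converged = TRUE,
         n_iter = 0L, n = 0L, basis = basis, log_volume = log_volume,
         trace = NULL, volume_col = "x"),
    class = "laplace_fit")
}

fits_table <- function(fit_of) {
  g <- group_labels()
  g$roi <- "x"
  g$n <- 0L; g$converged <- TRUE; g$log_lik <- 0
  g$fit <- lapply(seq_len(nrow(g)), function(i) fit_of(g$race[i], g$sex[i]))
  g
}

test_that("the pooled-scale effect size follows its closed form and symmetry", {
  f1 <- make_fit(c(8, 8, 8, 8), c(1, 1, 1, 1))
  f2 <- make_fit(c(7, 7, 7, 7), c(1, 1, 1, 1))
  # identical fits: zero at every age
  expect_equal(effect_size_at(f1, f1, c(20, 50, 85)), rep(0, 3))
  # offset 1 with b1 = b2 = 1: d = 2*1/(1+1) = 1
  expect_equal(effect_size_at(f1, f2, c(20, 50, 85)), rep(1, 3))
  expect_equal(effect_size_at(f1, f2, 40), effect_size_at(f2, f1, 40))
  # formula oracle on random fits across 100 ages
  set.seed(71)
  g1 <- make_fit(rnorm(4, 8, 0.5), exp(rnorm(4, log(0.5), 0.2)))
  g2 <- make_fit(rnorm(4, 7.5, 0.5), exp(rnorm(4, log(0.6), 0.2)))
  ages <- runif(100, 18, 90)
  B <- eval_basis(bspline_basis(), ages)
  d_oracle <- 2 * abs(drop(B %*% (g1$theta_mu - g2$theta_mu))) /
    (exp(drop(B %*% g1$theta_b)) + exp(drop(B %*% g2$theta_b)))
  expect_equal(effect_size_at(g1, g2, ages), d_oracle, tolerance = 1e-12)
  # transform mismatch is an error
  f_log <- make_fit(c(2, 2, 2, 2), c(0.3, 0.3, 0.3, 0.3), log_volume = TRUE)
  expect_error(effect_size_at(f1, f_log, 50), "log-volume")
})

test_that("effect sizes are invariant under a common affine transform", {
  g1 <- make_fit(c(8, 7.8, 7.4, 6.8), c(0.5, 0.5, 0.6, 0.7))
  g2 <- make_fit(c(7.6, 7.5, 7.0, 6.2), c(0.45, 0.5, 0.55, 0.75))
  shift_scale <- function(f, a, k) {
    f$theta_mu <- k * f$theta_mu + a
    f$theta_b <- f$theta_b + log(k)
    f
  }
  ages <- c(25, 50, 80)
  expect_equal(
    effect_size_at(shift_scale(g1, 100, 2.5), shift_scale(g2, 100, 2.5), ages),
    effect_size_at(g1, g2, ages), tolerance = 1e-12)
})

test_that("d_max scans group pairs and ages, with a refinement oracle", {
  # all groups identical: d_max is zero everywhere
  same <- fits_table(function(r, s) make_fit(rep(8, 4), rep(0.5, 4)))
  ms <- max_effect_size(same)
  expect_equal(ms$d_max, rep(0, nrow(ms)))
  # constant offset delta with equal constant scale b: d = delta / b always
  offset <- fits_table(function(r, s) {
    mu <- if (s == "Male") rep(8.5, 4) else rep(8, 4)
    make_fit(mu, rep(0.5, 4))
  })
  mo <- max_effect_size(offset)
  sex_pairs <- mo[substr(mo$group1, 1, 5) == substr(mo$group2, 1, 5), ]
  expect_equal(sex_pairs$d_max, rep(0.5 / 0.5 * 1, 3))
  # default pairing: sexes within race, races within sex -> 9 pairs
  expect_equal(nrow(mo), 9)
  expect_equal(nrow(max_effect_size(offset, pairs = "all")), 15)
  # grid maximum agrees with a 10x finer grid within grid resolution
  set.seed(72)
  wavy <- fits_table(function(r, s) {
    make_fit(rnorm(4, 8, 0.4), exp(rnorm(4, log(0.5), 0.2)))
  })
  coarse <- max_effect_size(wavy, age_grid = seq(18, 90, by = 1))
  fine <- max_effect_size(wavy, age_grid = seq(18, 90, by = 0.1))
  expect_equal(coarse$d_max, fine$d_max, tolerance = 0.02)
  # single group errors
  single <- wavy[1, ]
  expect_error(max_effect_size(single), "two groups")
})

test_that("normalization reduction ratios flag degenerate denominators", {
  raw <- fits_table(function(r, s) {
    mu <- if (s == "Male") rep(9, 4) else rep(8, 4)
    make_fit(mu, rep(0.5, 4))
  })
  # identical raw and corrected: all ratios 1
  r1 <- normalization_effect_ratio(raw, raw)
  expect_equal(r1$ratio, rep(1, 9))
  # corrected with zero group difference: infinite ratio, flagged
  flat <- fits_table(function(r, s) make_fit(rep(8, 4), rep(0.5, 4)))
  r2 <- normalization_effect_ratio(raw, flat)
  expect_true(all(is.infinite(r2$ratio[r2$infinite])))
  expect_setequal(which(r2$infinite), which(r2$d_max_raw > 0))
  # pairs with no effect in either fit set keep a ratio of 1, unflagged
  expect_true(all(r2$ratio[r2$d_max_raw == 0] == 1))
})
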