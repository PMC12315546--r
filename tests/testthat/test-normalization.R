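subjects_from <- function(volumes, icv, roi = "hippocampus") {
  out <- tibble::tibble(
    subject_id = sprintf("s%03d", seq_along(icv)),
    race = "Asian", sex = "Female",
    age = seq(30, 70, length.out = length(icv)),
    n_scans_used = 1L, n_visits_used = 1L)
  out[[roi]] <- volumes
  out[[icv_roi()]] <- icv
  out
}

test_that("division normalization collapses proportional volumes and preserves the mean", {
  # equal ICVs: identity on every ROI
  s <- subjects_from(c(4.0, 4.4, 3.9), rep(1500, 3))
  d <- normalize_division(s)
  expect_equal(d$hippocampus, s$hippocampus)
  # exact proportionality collapses to the cohort mean
  s2 <- subjects_from(c(1.0, 1.1), c(1.0, 1.1))
  expect_equal(normalize_division(s2)$hippocampus, c(1.05, 1.05))
  expect_equal(attr(normalize_division(s2), "reference_mean_icv"), 1.05)
  # proportional + Laplace noise: residual ICV correlation vanishes
  set.seed(41)
  icv <- rnorm(5000, 1500, 110)
  v <- icv * 0.0056 * (1 + rlaplace(5000, 0, 0.05))
  corrected <- normalize_division(subjects_from(v, icv))$hippocampus
  expect_lt(abs(cor(corrected, icv)), 0.05)
  # approximate mean preservation
  expect_lt(abs(mean(corrected) - mean(v)) / mean(v), 0.02)
  # idempotence: a second pass divides by a constant and multiplies it back
  once <- normalize_division(subjects_from(v, icv))
  expect_equal(normalize_division(once)$hippocampus, once$hippocampus)
  bad <- subjects_from(c(1, 2), c(1.5, 0))
  expect_error(normalize_division(bad), "s002")
})

test_that("residual normalization removes the fitted L1 line", {
  # exact line: all corrected values equal a + b * mean(ICV)
  icv <- seq(1300, 1700, length.out = 21)
  v <- 2 + 0.003 * icv
  r <- normalize_residual(subjects_from(v, icv))
  expect_equal(r$hippocampus, rep(2 + 0.003 * mean(icv), 21),
               tolerance = 1e-6)
  # volume independent of ICV: near identity
  set.seed(42)
  v2 <- rnorm(400, 5, 0.3)
  icv2 <- rnorm(400, 1500, 110)
  r2 <- normalize_residual(subjects_from(v2, icv2))
  expect_lt(max(abs(r2$hippocampus - v2)), 0.15)
  expect_error(normalize_residual(subjects_from(v2[1:5], rep(1500, 5))),
               "degenerate")
})

test_that("the LAD slope matches a brute-force grid oracle", {
  set.seed(43)
  x <- rnorm(300, 1500, 100)
  y <- 1 + 0.004 * x + rlaplace(300, 0, 0.4)
  slope <- lad_slope(x, y)
  grid <- seq(0.002, 0.006, length.out = 4001)
  obj <- vapply(grid, function(b) {
    r <- y - b * x
    sum(abs(r - median(r)))
  }, numeric(1))
  oracle <- grid[which.min(obj)]
  expect_lt(abs(slope - oracle) / abs(oracle), 0.01)
})

test_that("ICV matching balances head size and never alters volumes", {
  # identical groups: everyone matches with zero mean difference
  a <- subjects_from(1:10, seq(1400, 1490, 10))
  b <- dplyr::mutate(a, subject_id = paste0(subject_id, "b"),
                     race = "Black")
  both <- dplyr::bind_rows(a, b)
  m <- match_groups(both, c("Asian", "Female"), c("Black", "Female"),
                    caliper = 1)
  expect_equal(nrow(attr(m, "matched_pairs")), 10)
  expect_equal(attr(m, "balance"), 0)
  expect_equal(sort(m$hippocampus), sort(both$hippocampus))
  # vanishing caliper with no exactly equal ICVs: empty set plus warning
  b2 <- dplyr::mutate(b, `total intracranial` = `total intracranial` + 0.5)
  expect_warning(
    m0 <- match_groups(dplyr::bind_rows(a, b2), c("Asian", "Female"),
                       c("Black", "Female"), caliper = 1e-9),
    "no matches")
  expect_equal(nrow(m0), 0)
  # calibrated ICV laws: 0.05 L caliper balances Asian vs Black females
  set.seed(44)
  gs <- default_group_stats()
  af <- subjects_from(rnorm(200, 8, 0.5),
                      rnorm(200, gs$icv_mean[1] * 1000, gs$icv_sd[1] * 1000))
  bf <- dplyr::mutate(
    subjects_from(rnorm(200, 8, 0.5),
                  rnorm(200, gs$icv_mean[3] * 1000, gs$icv_sd[3] * 1000)),
    subject_id = paste0(subject_id, "b"), race = "Black")
  mm <- match_groups(dplyr::bind_rows(af, bf), c("Asian", "Female"),
                     c("Black", "Female"), caliper = 50)
  expect_lt(abs(attr(mm, "balance")), 0.1)
  # oracle: rank-wise pairing of sorted ICVs is the optimal 1:1 assignment
  # on a scalar; greedy matching must come close to its cost
  pairs <- attr(mm, "matched_pairs")
  opt_diff <- abs(sort(af[[icv_roi()]]) - sort(bf[[icv_roi()]]))
  oracle_cost <- mean(opt_diff[opt_diff <= 50])
  greedy_cost <- mean(abs(pairs$icv_a - pairs$icv_b))
  expect_lt(greedy_cost, 2 * oracle_cost + 5)
  # matching returns a subset: volumes untouched
  expect_true(all(mm$hippocampus %in% c(af$hippocampus, bf$hippocampus)))
})

test_that("log transform is exact, invertible and guarded", {
  s <- subjects_from(c(1, 2.5, 10), c(1500, 1510, 1490))
  expect_identical(log_transform_rois(s, character(0)), s)
  lt <- log_transform_rois(s, "hippocampus")
  expect_equal(lt$hippocampus, log(s$hippocampus))
  expect_equal(lt$hippocampus[1], 0)  # ln 1
  expect_equal(exp(lt$hippocampus), s$hippocampus)
  expect_equal(attr(lt, "log_rois"), "hippocampus")
  s$hippocampus[2] <- -1
  expect_error(log_transform_rois(s, "hippocampus"), "nonpositive")
  expect_error(log_transform_rois(s, "thalamus"), "not present")
})

test_that("covariate adjustment recovers the sign and null of the ICV effect", {
  basis <- bspline_basis(c(30, 70), degree = 1)
  gammas_prop <- gammas_null <- numeric(6)
  for (i in 1:6) {
    set.seed(50 + i)
    icv <- rnorm(500, 1500, 110)
    age <- runif(500, 18, 90)
    f <- 0.0056 - 1e-5 * (age - 50)
    prop <- tibble::tibble(age = age, v = icv * f * (1 + rlaplace(500, 0, 0.05)),
                           icv = icv)
    null <- tibble::tibble(age = age, v = 8.4 * f / 0.0056 *
                             (1 + rlaplace(500, 0, 0.05)), icv = icv)
    gammas_prop[i] <- fit_laplace_trajectory(prop, v, basis = basis,
                                             covariate = icv)$covariate_coef
    gammas_null[i] <- fit_laplace_trajectory(null, v, basis = basis,
                                             covariate = icv)$covariate_coef
  }
  expect_true(all(gammas_prop > 0))
  # ICV-independent data: mean coefficient within 3 SEs of zero
  se <- sd(gammas_null) / sqrt(6)
  expect_lt(abs(mean(gammas_null)), 3 * se + 1e-12)
  # token absent: base model has no covariate coefficient
  f0 <- fit_laplace_trajectory(tibble::tibble(age = age, v = null$v), v,
                               basis = basis)
  expect_null(f0$covariate_coef)
})
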