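# Independent oracles used across the suite.

# Direct Cox-de Boor recursion, written independently of the package's
# splineDesign-based evaluator. Half-open support intervals with the usual
# right-endpoint closure at the last knot.
cdb_basis <- function(knots, degree, x) {
  n_basis <- length(knots) - degree - 1L
  tmax <- max(knots)
  N <- function(i, d, x) {
    if (d == 0) {
      lo <- knots[i]; hi <- knots[i + 1]
      return(as.numeric((x >= lo & x < hi) | (x == tmax & hi == tmax & lo < hi)))
    }
    a <- 0
    den1 <- knots[i + d] - knots[i]
    if (den1 > 0) a <- (x - knots[i]) / den1 * N(i, d - 1, x)
    b <- 0
    den2 <- knots[i + d + 1] - knots[i + 1]
    if (den2 > 0) b <- (knots[i + d + 1] - x) / den2 * N(i + 1, d - 1, x)
    a + b
  }
  vapply(seq_len(n_basis), function(i) N(i, degree, x),
         numeric(length(x)))
}

# textbook Laplace log-density, summed
laplace_ll_oracle <- function(mu, b, v) {
  sum(log(1 / (2 * b) * exp(-abs(v - mu) / b)))
}

# a small hand-built scan table: 2 subjects, mixed visits/scans
tiny_scans <- function() {
  tibble::tibble(
    subject_id = c("s1", "s1", "s1", "s1", "s2"),
    visit_id = c("s1-v1", "s1-v1", "s1-v2", "s1-v2", "s2-v1"),
    scan_id = c("s1-v1-a", "s1-v1-b", "s1-v2-a", "s1-v2-b", "s2-v1-a"),
    age = c(60, 60, 62, 62, 40),
    sex = c("Female", "Female", "Female", "Female", "Male"),
    race = c("Asian", "Asian", "Asian", "Asian", "Black"),
    qc = c(0.9, 0.95, 0.85, 0.2, 0.99),
    hippocampus = c(4.0, 4.2, 4.1, 9.9, 5.0),
    `total intracranial` = c(1500, 1500, 1520, 1520, 1600)
  )
}

# one-group spec for fast simulation
one_group_spec <- function(n, seed = 1, icv_sd = NULL, scale_frac = 0.05,
                           jitter = 0, anchors = rep(0.0056, 4),
                           visits = c(1L, 1L), scans = c(1L, 1L),
                           fail_frac = 0) {
  gs <- default_group_stats()[1, ]
  gs$n <- as.integer(n)
  if (!is.null(icv_sd)) gs$icv_sd <- icv_sd
  cohort_spec(
    group_stats = gs,
    roi_models = tibble::tibble(
      roi = "hippocampus", anchors = list(anchors),
      scale_frac = list(scale_frac), log_normal = FALSE),
    scans_per_visit_range = scans,
    visits_per_subject_range = visits,
    fail_frac = fail_frac,
    scan_jitter_frac = jitter,
    seed = seed)
}
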