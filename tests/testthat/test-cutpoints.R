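test_that("a perfectly separable sample yields the midpoint and J = 1", {
  res <- youden_optimal_cutpoint(c(1, 2, 3, 10, 11, 12),
                                 c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
                                 "flag_if_greater")
  expect_equal(res$cutpoint, 6.5)
  expect_equal(res$youden, 1)
  res <- youden_optimal_cutpoint(c(1, 2, 3, 10, 11, 12),
                                 c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                                 "flag_if_less")
  expect_equal(res$cutpoint, 6.5)
  expect_equal(res$youden, 1)
})

test_that("single-class labels are rejected", {
  expect_error(youden_optimal_cutpoint(1:5, rep(TRUE, 5), "flag_if_less"),
               class = "pv_degenerate_error")
  expect_error(youden_optimal_cutpoint(1:5, rep(FALSE, 5), "flag_if_less"),
               class = "pv_degenerate_error")
})

test_that("fast scan equals the brute-force oracle, ties included", {
  set.seed(101)
  for (i in 1:30) {
    n <- sample(10:150, 1)
    # integer-valued draws force ties between observations
    values <- if (i %% 2 == 0) rnorm(n) else sample(0:20, n, replace = TRUE)
    labels <- runif(n) < plogis(scale(values) * runif(1, -2, 2))
    if (!any(labels) || all(labels)) next
    for (dir in c("flag_if_less", "flag_if_greater")) {
      got <- youden_optimal_cutpoint(values, labels, dir)
      want <- brute_force_youden(values, labels, dir)
      expect_equal(got$youden, want$youden, tolerance = 1e-12)
      expect_equal(got$cutpoint, want$cutpoint)
    }
  }
})

test_that("cutpoints shift exactly with a constant added to z", {
  set.seed(5)
  z <- rnorm(400)
  labels <- runif(400) < plogis(-2 + z^2)
  base <- derive_two_sided_cutpoints(z, labels)
  shifted <- derive_two_sided_cutpoints(z + 3, labels)
  expect_equal(shifted$z_low, base$z_low + 3)
  expect_equal(shifted$z_high, base$z_high + 3)
  expect_equal(shifted$median_z, base$median_z + 3)
})

test_that("derivation is invariant to input order", {
  set.seed(6)
  z <- rnorm(500)
  labels <- runif(500) < plogis(-2 + z^2)
  perm <- sample(500)
  expect_equal(derive_two_sided_cutpoints(z, labels),
               derive_two_sided_cutpoints(z[perm], labels[perm]))
})

test_that("median split records counts and its invariant ordering", {
  set.seed(8)
  z <- rnorm(1001)
  labels <- runif(1001) < plogis(-2 + z^2)
  cp <- derive_two_sided_cutpoints(z, labels, vital = "heart_rate")
  expect_equal(cp$n_below + cp$n_above, 1001)
  expect_true(cp$z_low <= cp$median_z)
  expect_true(cp$z_high >= cp$median_z)
  expect_true(cp$youden_low >= 0 && cp$youden_high >= 0)
})

test_that("a side with a single outcome class is reported by name", {
  z <- c(-2, -1.5, -1, -0.5, 0.5, 1, 1.5, 2)
  labels <- c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE)
  expect_error(derive_two_sided_cutpoints(z, labels),
               regexp = "below-median", class = "pv_degenerate_error")
})

test_that("uninformative labels give near-zero Youden", {
  set.seed(9)
  z <- rnorm(20000)
  labels <- runif(20000) < 0.2
  cp <- derive_two_sided_cutpoints(z, labels)
  expect_lt(cp$youden_low, 0.05)
  expect_lt(cp$youden_high, 0.05)
})

test_that("band simplification is analytic under a constant distribution", {
  d <- vital_dist(tibble::tibble(age = c(0, 17), location = 100, scale = 10))
  pair <- list(z_low = -1, z_high = 1)
  bands <- simplify_to_age_bands(d, pair)
  expect_equal(bands$lower, rep(90, 9))
  expect_equal(bands$upper, rep(110, 9))
})

test_that("band limits track a falling location", {
  d <- vital_dist(tibble::tibble(age = c(0, 17), location = c(140, 75),
                                 scale = 15))
  bands <- simplify_to_age_bands(d, list(z_low = -1.3, z_high = 0.85))
  expect_true(all(diff(bands$lower) <= 0))
  expect_true(all(diff(bands$upper) <= 0))
  expect_true(all(bands$lower == round(bands$lower)))
})

test_that("non-partitioning bands are rejected", {
  d <- vital_dist(tibble::tibble(age = c(0, 17), location = 100, scale = 10))
  expect_error(
    simplify_to_age_bands(d, list(z_low = -1, z_high = 1),
                          bands = tibble::tibble(age_lo = c(0, 6),
                                                 age_hi = c(5, 18))),
    class = "pv_config_error")
})

test_that("rounding halves go away from zero", {
  d <- vital_dist(tibble::tibble(age = c(0, 17), location = 100, scale = 10))
  bands <- simplify_to_age_bands(
    d, list(z_low = -0.45, z_high = 0.45),
    bands = tibble::tibble(age_lo = 0, age_hi = 18))
  expect_equal(bands$lower, 96)  # 95.5 rounds up (away from zero)
  expect_equal(bands$upper, 105) # 104.5 rounds up
})

test_that("the published reference z cutoffs are carried verbatim", {
  ref <- reference_z_cutoffs()
  expect_equal(ref$z_low[ref$vital == "heart_rate"], -1.31)
  expect_equal(ref$z_high[ref$vital == "heart_rate"], 0.84)
  expect_equal(ref$z_low[ref$vital == "resp_rate"], -1.01)
  expect_equal(ref$z_high[ref$vital == "resp_rate"], 1.28)
  expect_equal(ref$z_low[ref$vital == "sbp"], -1.03)
  expect_equal(ref$z_high[ref$vital == "sbp"], 1.32)
})

test_that("derive_ruleset yields a classifiable rule set plus cutpoints", {
  reg <- generate_registry(sim_config(n = 20000), seed = 12)
  enc <- add_outcomes(apply_exclusions(reg)$encounters)
  rs <- derive_ruleset(enc, sim_dist_table())
  expect_s3_class(rs, "pv_ruleset")
  cp <- tidy(rs)
  expect_setequal(cp$vital, c("heart_rate", "resp_rate", "sbp"))
  cls <- classify_vitals(enc, rs)
  expect_true(all(!is.na(cls$hr_class[!is.na(enc$heart_rate)])))
})
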