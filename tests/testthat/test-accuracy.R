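test_that("confusion cross-tabulates and drops undefined pairs", {
  ct <- confusion(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(unclass(ct)[c("tp", "fp", "fn", "tn")],
               list(tp = 1L, fp = 1L, fn = 1L, tn = 1L))
  same <- confusion(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))
  expect_equal(same$fp + same$fn, 0L)
  ct <- confusion(c(TRUE, NA, FALSE), c(TRUE, TRUE, NA))
  expect_equal(ct$tp + ct$fp + ct$fn + ct$tn, 1L)
  expect_error(confusion(NA, TRUE), class = "pv_degenerate_error")
  expect_error(confusion(c(TRUE, TRUE), TRUE), class = "pv_domain_error")
})

test_that("confusion matches a hand loop on random pairs", {
  set.seed(41)
  flags <- sample(c(TRUE, FALSE, NA), 1000, replace = TRUE,
                  prob = c(0.45, 0.45, 0.1))
  truth <- sample(c(TRUE, FALSE), 1000, replace = TRUE)
  ct <- confusion(flags, truth)
  hand <- c(tp = 0, fp = 0, fn = 0, tn = 0)
  for (i in seq_len(1000)) {
    if (is.na(flags[i])) next
    cell <- if (flags[i] && truth[i]) "tp" else if (flags[i]) "fp"
            else if (truth[i]) "fn" else "tn"
    hand[cell] <- hand[cell] + 1
  }
  expect_equal(c(tp = ct$tp, fp = ct$fp, fn = ct$fn, tn = ct$tn), hand)
})

test_that("accuracy metrics are the standard fractions", {
  acc <- diagnostic_accuracy(confusion(
    rep(c(TRUE, TRUE, FALSE, FALSE), c(8, 10, 2, 80)),
    rep(c(TRUE, FALSE, TRUE, FALSE), c(8, 10, 2, 80))
  ))
  expect_equal(acc$sens, 0.8)
  expect_equal(acc$spec, 80 / 90)
  expect_equal(acc$ppv, 8 / 18)
  expect_equal(acc$npv, 80 / 82)
  expect_equal(acc$plr, 0.8 / (1 - 80 / 90))
  expect_equal(acc$nlr, 0.2 / (80 / 90))
  expect_equal(acc$n_analyzed, 100)
})

test_that("Wilson intervals match the closed form", {
  ci <- proportion_ci(80, 100)
  expect_equal(round(c(ci$conf_low, ci$conf_high), 3), c(0.711, 0.867))
  set.seed(42)
  for (i in 1:20) {
    n <- sample(5:500, 1)
    x <- sample(0:n, 1)
    ci <- proportion_ci(x, n)
    expect_equal(c(ci$conf_low, ci$conf_high), wilson_ci(x, n),
                 tolerance = 1e-9)
  }
})

test_that("zero denominators leave that metric undefined, others intact", {
  ct <- structure(list(tp = 0, fp = 0, fn = 3, tn = 7),
                  class = "pv_confusion")
  acc <- diagnostic_accuracy(ct)
  expect_equal(acc$sens, 0)
  expect_true(is.na(acc$ppv))
  expect_equal(acc$spec, 1)
  expect_true(is.na(acc$plr)) # spec = 1 makes the PLR denominator zero
  expect_equal(acc$npv, 0.7)
})

test_that("AUROC equals brute-force pairwise concordance", {
  set.seed(43)
  for (i in 1:10) {
    n <- sample(20:300, 1)
    pred <- if (i %% 2) rnorm(n) else sample(1:5, n, replace = TRUE)
    truth <- runif(n) < plogis(pred - mean(pred))
    if (!any(truth) || all(truth)) next
    pos <- pred[truth]
    neg <- pred[!truth]
    conc <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(auroc(pred, truth), mean(conc))
  }
})

test_that("a null model discriminates at one half", {
  set.seed(44)
  n <- 100000
  truth <- runif(n) < 0.05
  m <- fit_criteria_model(runif(n) < 0.3, runif(n) < 0.25, runif(n) < 0.5,
                          truth)
  expect_lt(abs(m$auroc - 0.5), 0.01)
  expect_equal(m$n, n)
})

test_that("three binary predictors give at most eight fitted risks", {
  set.seed(45)
  n <- 4000
  hr <- runif(n) < 0.3
  rr <- runif(n) < 0.3
  sbp <- runif(n) < 0.3
  truth <- runif(n) < plogis(-3 + hr + 0.5 * rr + 0.5 * sbp)
  m <- fit_criteria_model(hr, rr, sbp, truth)
  expect_lte(length(unique(round(m$fit$fitted.values, 12))), 8)
  td <- tidy(m)
  expect_equal(td$term, c("(Intercept)", "hrTRUE", "rrTRUE", "sbpTRUE"))
  expect_equal(glance(m)$auroc, m$auroc)
})

test_that("separation is flagged with a warning", {
  truth <- rep(c(TRUE, FALSE), each = 20)
  expect_warning(
    m <- fit_criteria_model(truth, rep(FALSE, 40), rep(FALSE, 40), truth),
    class = "pv_separation_warning")
  expect_true(m$separation)
})

test_that("comparing a predictor with itself gives delta 0, p 1", {
  set.seed(46)
  pred <- rnorm(200)
  truth <- runif(200) < plogis(pred)
  cmp <- compare_auroc(pred, pred, truth)
  expect_equal(cmp$delta, 0)
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$auroc_a, auroc(pred, truth))
  expect_true(cmp$auroc_a_lo <= cmp$auroc_a & cmp$auroc_a <= cmp$auroc_a_hi)
})

test_that("AUROC comparison is antisymmetric", {
  set.seed(47)
  truth <- runif(300) < 0.3
  pred_a <- rnorm(300) + truth
  pred_b <- rnorm(300) + 0.5 * truth
  ab <- compare_auroc(pred_a, pred_b, truth)
  ba <- compare_auroc(pred_b, pred_a, truth)
  expect_equal(ab$delta, -ba$delta)
  expect_equal(ab$p_value, ba$p_value)
})

test_that("spline curve recovers a U and stays flat under the null", {
  set.seed(48)
  n <- 30000
  z <- rnorm(n)
  truth <- runif(n) < plogis(-3.5 + 0.8 * z^2)
  curve <- spline_risk_curve(z, truth)
  m <- which.min(curve$prob)
  expect_gt(m, 1)
  expect_lt(m, nrow(curve))
  expect_true(all(curve$prob > 0 & curve$prob < 1))

  flat_truth <- runif(n) < 0.05
  flat <- spline_risk_curve(z, flat_truth)
  expect_true(all(abs(flat$prob - mean(flat_truth)) < 0.02))

  mono_truth <- runif(n) < plogis(-3.5 + 1.2 * z)
  mono <- spline_risk_curve(z, mono_truth)
  expect_true(all(diff(mono$prob) > -0.002))
})

test_that("spline guards degenerate inputs", {
  expect_error(spline_risk_curve(rnorm(50), runif(50) < 0.5),
               class = "pv_degenerate_error")
  expect_error(spline_risk_curve(rep(1, 200), runif(200) < 0.5),
               class = "pv_degenerate_error")
})

test_that("calibration bins conserve observations and detect calibration", {
  set.seed(49)
  n <- 100000
  pred <- plogis(rnorm(n, -2, 1))
  truth <- runif(n) < pred
  cal <- calibration_bins(pred, truth)
  expect_equal(sum(cal$n), n)
  expect_true(all(abs(cal$mean_pred - cal$observed_rate) < 0.02))

  truth_c <- runif(500) < 0.4
  const <- calibration_bins(rep(0.3, 500), truth_c)
  expect_equal(nrow(const), 1)
  expect_equal(const$observed_rate, mean(truth_c))
  expect_equal(const$n, 500L)
})

test_that("evaluate_ruleset reports per-vital and any-abnormal rows", {
  reg <- generate_registry(sim_config(n = 20000), seed = 51)
  enc <- add_outcomes(apply_exclusions(reg)$encounters)
  rep_pals <- evaluate_ruleset(enc, ruleset_pals())
  expect_setequal(rep_pals$criterion,
                  c("heart_rate", "resp_rate", "sbp", "any_abnormal"))
  # available-case per vital: SBP row analyzes fewer encounters than RR row
  expect_lt(rep_pals$n_analyzed[rep_pals$criterion == "sbp"],
            rep_pals$n_analyzed[rep_pals$criterion == "resp_rate"])
  expect_true(all(rep_pals$sens_lo <= rep_pals$sens &
                    rep_pals$sens <= rep_pals$sens_hi))
  expect_equal(rep_pals$plr, rep_pals$sens / (1 - rep_pals$spec))
})
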