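#' Cross-tabulate a classifier flag against the outcome
#'
#' Pairs with an undefined flag or outcome are excluded before tabulation
#' (available-case analysis).
#'
#' @param flags Logical classifier output (`NA` = undefined).
#' @param truth Logical outcome.
#' @return A `pv_confusion` list with counts `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(flags, truth) {
  if (length(flags) != length(truth)) {
    abort("flags and truth must have equal length", class = "pv_domain_error")
  }
  keep <- !is.na(flags) & !is.na(truth)
  flags <- as.logical(flags[keep])
  truth <- as.logical(truth[keep])
  if (length(flags) == 0) {
    abort("no complete flag/outcome pairs", class = "pv_degenerate_error")
  }
  structure(list(
    tp = sum(flags & truth), fp = sum(flags & !truth),
    fn = sum(!flags & truth), tn = sum(!flags & !truth)
  ), class = "pv_confusion")
}

#' Wilson score interval for a proportion
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble with `estimate`, `conf_low`, `conf_high`.
#' @examples
#' proportion_ci(3223, 70748) # STAT prevalence with 95% CI
#' @export
proportion_ci <- function(x, n, conf_level = 0.95) {
  if (n <= 0 || x < 0 || x > n) {
    abort("need 0 <= x <= n with n > 0", class = "pv_domain_error")
  }
  ci <- suppressWarnings(
    prop.test(x, n, conf.level = conf_level, correct = FALSE)$conf.int
  )
  tibble::tibble(estimate = x / n, conf_low = ci[1], conf_high = ci[2])
}

# log-method CI for a likelihood ratio; any zero cell makes it undefined
pv_lr_ci <- function(lr, num_x, num_n, den_x, den_n, conf_level) {
  if (!is.finite(lr) || lr <= 0 ||
      num_x == 0 || den_x == 0 || num_n == 0 || den_n == 0) {
    return(c(NA_real_, NA_real_))
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(1 / num_x - 1 / num_n + 1 / den_x - 1 / den_n)
  exp(log(lr) + c(-1, 1) * z * se)
}

#' Diagnostic accuracy report from a confusion table
#'
#' Sensitivity, specificity, positive and negative predictive values with
#' Wilson score confidence intervals, and positive and negative likelihood
#' ratios with log-method confidence intervals. A metric whose denominator
#' is zero is reported `NA` (with `NA` interval); the others are still
#' computed.
#'
#' @param ct A [confusion()] table.
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row `pv_accuracy` tibble with columns `sens`, `spec`,
#'   `ppv`, `npv` (each with `_lo`/`_hi`), `plr`, `nlr` (each with
#'   `_lo`/`_hi`), and `n_analyzed`.
#' @export
diagnostic_accuracy <- function(ct, conf_level = 0.95) {
  n <- ct$tp + ct$fp + ct$fn + ct$tn
  if (n <= 0) abort("empty confusion table", class = "pv_degenerate_error")
  prop <- function(x, d) {
    if (d == 0) {
      tibble::tibble(estimate = NA_real_, conf_low = NA_real_,
                     conf_high = NA_real_)
    } else {
      proportion_ci(x, d, conf_level)
    }
  }
  sens <- prop(ct$tp, ct$tp + ct$fn)
  spec <- prop(ct$tn, ct$tn + ct$fp)
  ppv <- prop(ct$tp, ct$tp + ct$fp)
  npv <- prop(ct$tn, ct$tn + ct$fn)
  plr <- if (!is.na(sens$estimate) && !is.na(spec$estimate) &&
             spec$estimate < 1) sens$estimate / (1 - spec$estimate)
         else NA_real_
  nlr <- if (!is.na(sens$estimate) && !is.na(spec$estimate) &&
             spec$estimate > 0) (1 - sens$estimate) / spec$estimate
         else NA_real_
  plr_ci <- pv_lr_ci(plr, ct$tp, ct$tp + ct$fn, ct$fp, ct$fp + ct$tn,
                     conf_level)
  nlr_ci <- pv_lr_ci(nlr, ct$fn, ct$tp + ct$fn, ct$tn, ct$fp + ct$tn,
                     conf_level)
  row <- c(
    sens = unlist(sens, use.names = FALSE),
    spec = unlist(spec, use.names = FALSE),
    ppv = unlist(ppv, use.names = FALSE),
    npv = unlist(npv, use.names = FALSE),
    plr = c(plr, plr_ci), nlr = c(nlr, nlr_ci)
  )
  names(row) <- paste0(rep(c("sens", "spec", "ppv", "npv", "plr", "nlr"),
                           each = 3),
                       rep(c("", "_lo", "_hi"), times = 6))
  structure(
    dplyr::bind_cols(tibble::as_tibble(as.list(row)),
                     tibble::tibble(n_analyzed = n)),
    class = c("pv_accuracy", class(tibble::tibble()))
  )
}

#' Area under the ROC curve by the rank (Mann-Whitney) formulation
#'
#' Equals the probability that a random outcome-positive observation's
#' prediction exceeds a random negative's, counting ties as one half
#' (midranks provide the tie correction).
#'
#' @param pred Numeric predictions or scores.
#' @param truth Logical outcome.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(pred, truth) {
  keep <- !is.na(pred) & !is.na(truth)
  pred <- pred[keep]
  truth <- as.logical(truth[keep])
  n1 <- sum(truth)
  n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) {
    abort("both outcome classes must be present",
          class = "pv_degenerate_error")
  }
  r <- rank(pred)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fit the three-criteria multivariable model
#'
#' Logistic regression of the outcome on the three per-vital abnormality
#' indicators (intercept plus three slopes, maximum likelihood), restricted
#' to encounters where all three indicators and the outcome are defined
#' (the complete-vitals subset). The model's discrimination is summarized
#' by the AUROC of its linear predictor, computed by the rank formulation.
#' Perfect or quasi-perfect separation is flagged with a warning and in
#' the returned object.
#'
#' @param hr_abn,rr_abn,sbp_abn Logical abnormality indicators.
#' @param truth Logical outcome.
#' @return A `pv_criteria_model` list with elements `fit` (the `glm`),
#'   `auroc`, `n` and `separation`. Supports [tidy()] and [glance()].
#' @export
fit_criteria_model <- function(hr_abn, rr_abn, sbp_abn, truth) {
  df <- tibble::tibble(
    truth = as.logical(truth), hr = as.logical(hr_abn),
    rr = as.logical(rr_abn), sbp = as.logical(sbp_abn)
  )
  df <- df[complete.cases(df), ]
  if (nrow(df) == 0 || !any(df$truth) || all(df$truth)) {
    abort("both outcome classes must be present",
          class = "pv_degenerate_error")
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(truth ~ hr + rr + sbp, data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  eps <- 1e-10
  if (any(fit$fitted.values < eps | fit$fitted.values > 1 - eps)) {
    separation <- TRUE
  }
  if (separation) {
    warn("possible separation: fitted probabilities numerically 0 or 1",
         class = "pv_separation_warning")
  }
  structure(
    list(fit = fit, auroc = auroc(fit$linear.predictors, df$truth),
         n = nrow(df), separation = separation),
    class = "pv_criteria_model"
  )
}

#' @export
print.pv_criteria_model <- function(x, ...) {
  cat("<three-criteria logistic model: n = ", x$n,
      ", AUROC = ", formatC(x$auroc, digits = 3, format = "f"),
      if (x$separation) ", separation flagged" else "", ">\n", sep = "")
  invisible(x)
}

#' @rdname fit_criteria_model
#' @param x A `pv_criteria_model`.
#' @param ... Unused.
#' @method tidy pv_criteria_model
#' @export
tidy.pv_criteria_model <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(s), estimate = s[, 1], std_error = s[, 2],
    statistic = s[, 3], p_value = s[, 4],
    odds_ratio = exp(s[, 1])
  )
}

#' @rdname fit_criteria_model
#' @method glance pv_criteria_model
#' @export
glance.pv_criteria_model <- function(x, ...) {
  tibble::tibble(
    auroc = x$auroc, n = x$n, separation = x$separation,
    aic = x$fit$aic, deviance = x$fit$deviance,
    null_deviance = x$fit$null.deviance
  )
}

#' Compare two paired AUROCs
#'
#' DeLong's test for two correlated ROC curves built on the same
#' encounters, with DeLong 95% confidence intervals for each AUROC. When
#' the two predictors are identical the difference is zero and the p-value
#' is 1 by convention.
#'
#' @param pred_a,pred_b Numeric predictions for the same encounters.
#' @param truth Logical outcome.
#' @param conf_level Confidence level for the AUROC intervals.
#' @return A one-row `pv_model_comparison` tibble: `auroc_a` (`_lo`/`_hi`),
#'   `auroc_b` (`_lo`/`_hi`), `delta` (= `auroc_a - auroc_b`), `p_value`,
#'   `n`.
#' @export
compare_auroc <- function(pred_a, pred_b, truth, conf_level = 0.95) {
  keep <- !is.na(pred_a) & !is.na(pred_b) & !is.na(truth)
  pred_a <- pred_a[keep]
  pred_b <- pred_b[keep]
  truth <- as.logical(truth[keep])
  if (!any(truth) || all(truth)) {
    abort("both outcome classes must be present",
          class = "pv_degenerate_error")
  }
  roc_a <- pROC::roc(truth, pred_a, levels = c(FALSE, TRUE),
                     direction = "<", quiet = TRUE)
  roc_b <- pROC::roc(truth, pred_b, levels = c(FALSE, TRUE),
                     direction = "<", quiet = TRUE)
  ci_a <- as.numeric(pROC::ci.auc(roc_a, conf.level = conf_level,
                                  method = "delong"))
  ci_b <- as.numeric(pROC::ci.auc(roc_b, conf.level = conf_level,
                                  method = "delong"))
  delta <- ci_a[2] - ci_b[2]
  p <- suppressWarnings(
    tryCatch(pROC::roc.test(roc_a, roc_b, method = "delong",
                            paired = TRUE)$p.value,
             error = function(e) NaN)
  )
  if (is.nan(p)) p <- if (abs(delta) < 1e-12) 1 else NA_real_
  structure(
    tibble::tibble(
      auroc_a = ci_a[2], auroc_a_lo = ci_a[1], auroc_a_hi = ci_a[3],
      auroc_b = ci_b[2], auroc_b_lo = ci_b[1], auroc_b_hi = ci_b[3],
      delta = delta, p_value = p, n = length(truth)
    ),
    class = c("pv_model_comparison", class(tibble::tibble()))
  )
}

#' Spline risk curve of outcome probability against a z-score
#'
#' Logistic regression of the outcome on a restricted (natural) cubic
#' spline of the z-score with 4 knots at the 5th/35th/65th/95th
#' percentiles, evaluated on an even grid spanning the 1st-99th percentile
#' of z (the tails are clipped for stability), with pointwise Wald
#' confidence bands. A U-shaped relation shows as an interior minimum of
#' the fitted curve.
#'
#' @param z Numeric z-scores (>= 100 observations).
#' @param truth Logical outcome (both classes present).
#' @param grid_size Number of grid points (default 100).
#' @param conf_level Confidence level for the band.
#' @return A `pv_spline_curve` tibble with columns `z`, `prob`,
#'   `conf_low`, `conf_high`; the fitted `glm` is attached as attribute
#'   `"fit"`. Supports [autoplot()].
#' @export
spline_risk_curve <- function(z, truth, grid_size = 100, conf_level = 0.95) {
  keep <- !is.na(z) & !is.na(truth)
  z <- z[keep]
  truth <- as.logical(truth[keep])
  if (length(z) < 100) {
    abort("need at least 100 observations", class = "pv_degenerate_error")
  }
  if (!any(truth) || all(truth)) {
    abort("both outcome classes must be present",
          class = "pv_degenerate_error")
  }
  k <- unname(quantile(z, c(0.05, 0.35, 0.65, 0.95)))
  if (length(unique(k)) < 4) {
    abort("insufficient spread in z for spline knots",
          class = "pv_degenerate_error")
  }
  basis <- splines::ns(z, knots = k[2:3], Boundary.knots = k[c(1, 4)])
  df <- data.frame(truth = truth)
  fit <- glm(truth ~ basis, data = df, family = binomial())
  grid <- seq(quantile(z, 0.01), quantile(z, 0.99), length.out = grid_size)
  gb <- predict(basis, grid)
  eta <- cbind(1, gb) %*% coef(fit)
  se <- sqrt(rowSums((cbind(1, gb) %*% vcov(fit)) * cbind(1, gb)))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  out <- tibble::tibble(
    z = grid,
    prob = plogis(as.numeric(eta)),
    conf_low = plogis(as.numeric(eta) - zq * se),
    conf_high = plogis(as.numeric(eta) + zq * se)
  )
  attr(out, "fit") <- fit
  class(out) <- c("pv_spline_curve", class(tibble::tibble()))
  out
}

#' Calibration by equal-frequency bins of predicted probability
#'
#' @param pred Predicted probabilities in (0, 1).
#' @param truth Logical outcome.
#' @param nbins Number of equal-frequency bins (default 10); duplicate
#'   quantile breaks collapse, so a constant predictor yields one bin.
#' @return A `pv_calibration` tibble with `bin`, `mean_pred`,
#'   `observed_rate`, `n` (bin counts sum to the number of observations).
#'   Supports [autoplot()].
#' @export
calibration_bins <- function(pred, truth, nbins = 10) {
  if (nbins < 2) abort("nbins must be >= 2", class = "pv_domain_error")
  keep <- !is.na(pred) & !is.na(truth)
  pred <- pred[keep]
  truth <- as.logical(truth[keep])
  breaks <- unique(quantile(pred, probs = seq(0, 1, length.out = nbins + 1)))
  bin <- if (length(breaks) < 2) rep(1L, length(pred))
         else as.integer(cut(pred, breaks, include.lowest = TRUE))
  out <- tibble::tibble(bin = bin, pred = pred, truth = truth) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean_pred = mean(.data$pred),
                     observed_rate = mean(.data$truth),
                     n = dplyr::n(), .groups = "drop")
  class(out) <- c("pv_calibration", class(tibble::tibble()))
  out
}

#' Evaluate a rule set's diagnostic accuracy against an outcome
#'
#' Produces a Table-3-style accuracy report: one row per vital sign
#' (available-case analysis — encounters missing that vital are dropped
#' for that row only, mirroring per-vital documentation), plus an
#' `any_abnormal` row restricted to the complete-vitals subset. Abnormal
#' means classifying low or high (the single flagged side for one-sided
#' rules).
#'
#' @param data Encounter tibble with vitals, `age_years` and the outcome
#'   column (see [add_outcomes()]).
#' @param rules A `pv_ruleset`.
#' @param outcome Outcome column name (default `"stat"`).
#' @return A tibble with columns `criterion`, `ruleset`, the
#'   [diagnostic_accuracy()] metrics, and the confusion counts.
#' @export
evaluate_ruleset <- function(data, rules, outcome = "stat") {
  if (!outcome %in% names(data)) {
    abort(paste0("outcome column not found: ", outcome),
          class = "pv_schema_error")
  }
  cls <- classify_vitals(data, rules)
  truth <- cls[[outcome]]
  abn <- function(x) dplyr::if_else(is.na(x), NA, x != "normal")
  rows <- list(
    heart_rate = abn(cls$hr_class),
    resp_rate = abn(cls$rr_class),
    sbp = abn(cls$sbp_class),
    any_abnormal = cls$any_abnormal
  )
  dplyr::bind_rows(lapply(names(rows), function(nm) {
    ct <- confusion(rows[[nm]], truth)
    dplyr::bind_cols(
      tibble::tibble(criterion = nm, ruleset = attr(rules, "name") %||% "user"),
      diagnostic_accuracy(ct),
      tibble::tibble(tp = ct$tp, fp = ct$fp, fn = ct$fn, tn = ct$tn)
    )
  }))
}
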