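#' Youden-optimal cutpoint for one direction of abnormality
#'
#' Scans all candidate thresholds — midpoints between adjacent distinct
#' observed values, plus infinite sentinels at either end — and returns the
#' one maximizing Youden's J (sensitivity + specificity - 1) for flagging
#' values strictly below (`flag_if_less`) or strictly above
#' (`flag_if_greater`) the cutpoint. Ties are broken toward the
#' least-extreme candidate (closest to the sample median). Pairs with a
#' missing value or label are dropped.
#'
#' @param values Numeric observations (the exposure, e.g. z-scores).
#' @param labels Logical outcome labels.
#' @param direction `"flag_if_less"` or `"flag_if_greater"`.
#' @return A list with `cutpoint` and `youden`.
#' @export
youden_optimal_cutpoint <- function(values,
                                    labels,
                                    direction = c("flag_if_less",
                                                  "flag_if_greater")) {
  direction <- match.arg(direction)
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]
  labels <- as.logical(labels[keep])
  if (length(values) == 0 || !any(labels) || all(labels)) {
    abort("both outcome classes must be present",
          class = "pv_degenerate_error")
  }
  if (any(!is.finite(values))) {
    abort("values must be finite", class = "pv_degenerate_error")
  }
  n_pos <- sum(labels)
  n_neg <- sum(!labels)

  d <- sort(unique(values))
  # positives/negatives with value <= d[j], cumulatively
  tab_pos <- cumsum(tabulate(findInterval(values[labels], d),
                             nbins = length(d)))
  tab_neg <- cumsum(tabulate(findInterval(values[!labels], d),
                             nbins = length(d)))
  # candidate j = 0..m: threshold below d[1] (j = 0, -Inf sentinel),
  # between d[j] and d[j+1], or above d[m] (j = m, +Inf sentinel);
  # flagged-below counts at candidate j are tab_*[j]
  below_pos <- c(0, tab_pos)
  below_neg <- c(0, tab_neg)
  cand <- c(-Inf, (d[-length(d)] + d[-1]) / 2, Inf)
  if (length(d) == 1) cand <- c(-Inf, Inf)

  j <- if (direction == "flag_if_less") {
    below_pos / n_pos + (n_neg - below_neg) / n_neg - 1
  } else {
    (n_pos - below_pos) / n_pos + below_neg / n_neg - 1
  }
  best <- which(j >= max(j) - 1e-12)
  if (length(best) > 1) {
    ctr <- median(values)
    best <- best[order(abs(cand[best] - ctr), cand[best])][1]
  }
  list(cutpoint = cand[best], youden = j[best])
}

#' Derive two-sided z-score cutoffs by median-split ROC analysis
#'
#' Splits the z-scores at their sample median, then finds the
#' Youden-optimal lower cutoff (flagging low values) on the below-median
#' subset and the optimal upper cutoff (flagging high values) on the
#' above-median subset. This mirrors constructing one ROC curve for each
#' half of a U-shaped exposure-risk relation.
#'
#' @param z Numeric z-scores (pooled across ages).
#' @param labels Logical outcome labels (e.g. STAT major trauma).
#' @param vital Optional vital name recorded in the result.
#' @return A one-row `pv_cutpoints` tibble with columns `vital`, `z_low`,
#'   `z_high`, `median_z`, `n_below`, `n_above`, `youden_low`,
#'   `youden_high`.
#' @export
derive_two_sided_cutpoints <- function(z, labels, vital = NA_character_) {
  keep <- !is.na(z) & !is.na(labels)
  z <- z[keep]
  labels <- as.logical(labels[keep])
  if (length(z) == 0) {
    abort("no complete observations", class = "pv_degenerate_error")
  }
  med <- median(z)
  below <- z <= med
  check_side <- function(side, lab) {
    if (sum(labels[side]) < 2 || sum(!labels[side]) < 2) {
      abort(paste0(lab, "-median side needs at least 2 observations of ",
                   "each outcome class"),
            class = "pv_degenerate_error")
    }
  }
  check_side(below, "below")
  check_side(!below, "above")
  lo <- youden_optimal_cutpoint(z[below], labels[below], "flag_if_less")
  hi <- youden_optimal_cutpoint(z[!below], labels[!below], "flag_if_greater")
  structure(
    tibble::tibble(
      vital = vital, z_low = lo$cutpoint, z_high = hi$cutpoint,
      median_z = med, n_below = sum(below), n_above = sum(!below),
      youden_low = lo$youden, youden_high = hi$youden
    ),
    class = c("pv_cutpoints", class(tibble::tibble()))
  )
}

#' Published z-score cutoffs
#'
#' The optimal z-score cutoffs reported from the 2021 national
#' trauma-registry derivation (full restricted data; not reproducible at
#' desk scale), shipped as reference constants: heart rate (-1.31, 0.84),
#' respiratory rate (-1.01, 1.28), systolic blood pressure (-1.03, 1.32).
#'
#' @return A tibble with columns `vital`, `z_low`, `z_high`.
#' @export
reference_z_cutoffs <- function() {
  tibble::tibble(
    vital = c("heart_rate", "resp_rate", "sbp"),
    z_low = c(-1.31, -1.01, -1.03),
    z_high = c(0.84, 1.28, 1.32)
  )
}

# nearest integer, half away from zero (integer limits are printed this way)
pv_round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Simplify z-score cutoffs into age-banded integer limits
#'
#' Converts a z-score cutoff pair to vital-sign limits within each age
#' band by evaluating the inverse z-transform at the band midpoint and
#' rounding to the nearest integer (half away from zero).
#'
#' @param dist A [vital_dist()] for the vital.
#' @param pair A `pv_cutpoints` row (or any list with `z_low`, `z_high`).
#' @param bands A data frame of half-open age bands (`age_lo`, `age_hi`)
#'   partitioning \[0, 18); defaults to the nine simplified age groups.
#' @return A tibble with `age_lo`, `age_hi`, `lower`, `upper`.
#' @export
simplify_to_age_bands <- function(dist, pair, bands = pv_empirical_bands()) {
  bands <- tibble::as_tibble(bands)[c("age_lo", "age_hi")]
  bands <- dplyr::arrange(bands, .data$age_lo)
  if (bands$age_lo[1] != 0 || bands$age_hi[nrow(bands)] != 18 ||
      (nrow(bands) > 1 &&
       any(abs(bands$age_hi[-nrow(bands)] - bands$age_lo[-1]) > 1e-9))) {
    abort("bands must partition [0, 18)", class = "pv_config_error")
  }
  mid <- (bands$age_lo + bands$age_hi) / 2
  bands$lower <- pv_round_half_away(z_to_vital(dist, pair$z_low, mid))
  bands$upper <- pv_round_half_away(z_to_vital(dist, pair$z_high, mid))
  bands
}

#' Derive an age-banded empirical rule set from an encounter table
#'
#' End-to-end derivation: converts each vital to age-adjusted z-scores
#' under `dists`, derives two-sided Youden-optimal z cutoffs against the
#' chosen outcome by median-split ROC analysis (available-case per vital),
#' and simplifies them into an age-banded integer rule set directly usable
#' by [classify_vitals()].
#'
#' @param data Encounter tibble with vitals, `age_years` and outcome
#'   columns (see [add_outcomes()]).
#' @param dists A [dist_table()] with entries for the three vitals.
#' @param outcome Outcome column name: `"stat"`, `"cm"`, `"nfti"` or
#'   `"nei6"`.
#' @param bands Age bands for simplification (default: the nine simplified
#'   age groups).
#' @return A `pv_ruleset` named `"EMPIRICAL_DERIVED"`, with the per-vital
#'   `pv_cutpoints` tibble attached as attribute `"cutpoints"` (also
#'   retrievable with [tidy()]).
#' @export
derive_ruleset <- function(data, dists, outcome = "stat",
                           bands = pv_empirical_bands()) {
  if (!outcome %in% names(data)) {
    abort(paste0("outcome column not found: ", outcome),
          class = "pv_schema_error")
  }
  data <- add_zscores(data, dists)
  zcols <- c(heart_rate = "hr_z", resp_rate = "rr_z", sbp = "sbp_z")
  pairs <- dplyr::bind_rows(lapply(names(zcols), function(v) {
    derive_two_sided_cutpoints(data[[zcols[[v]]]], data[[outcome]],
                               vital = v)
  }))
  limits <- dplyr::bind_rows(lapply(names(zcols), function(v) {
    dplyr::mutate(
      simplify_to_age_bands(dists[[v]], pairs[pairs$vital == v, ], bands),
      vital = v
    )
  }))
  out <- ruleset(limits, name = "EMPIRICAL_DERIVED")
  attr(out, "cutpoints") <- pairs
  out
}

#' @rdname derive_ruleset
#' @param x A derived `pv_ruleset`.
#' @param ... Unused.
#' @method tidy pv_ruleset
#' @export
tidy.pv_ruleset <- function(x, ...) {
  cp <- attr(x, "cutpoints")
  if (is.null(cp)) tibble::as_tibble(x) else cp
}
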