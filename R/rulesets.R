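#' Vital-sign rule sets
#'
#' A rule set is an age-banded table of lower/upper limits for heart rate
#' (beats/min), respiratory rate (breaths/min) and systolic blood pressure
#' (mm Hg). A value is classified abnormal when it falls strictly outside
#' its age band's limits; the limits themselves are normal. One-sided rules
#' (ATLS) leave the unused side `NA`, which never fires.
#'
#' Age bands are half-open intervals `[age_lo, age_hi)` in years and must
#' partition \[0, 18) within each (rule set, vital). Published band labels
#' such as "1-3 years" followed by "4-6 years" are canonicalized to a
#' contiguous half-open partition, with each boundary age assigned to the
#' band whose printed label starts there (so "4-6 years" owns age 4, and
#' ">= 12 years" starts at exactly 12).
#'
#' @param limits A data frame with columns `vital` (one of `heart_rate`,
#'   `resp_rate`, `sbp`), `age_lo`, `age_hi` (years), `lower`, `upper`
#'   (limit values; `NA` for an absent one-sided limit).
#' @param name Rule-set name.
#' @return A `pv_ruleset` tibble.
#' @seealso [ruleset_pals()], [ruleset_atls()], [ruleset_empirical()],
#'   [classify_vital()]
#' @export
ruleset <- function(limits, name = "user-defined") {
  limits <- tibble::as_tibble(limits)
  required <- c("vital", "age_lo", "age_hi", "lower", "upper")
  missing_cols <- setdiff(required, names(limits))
  if (length(missing_cols) > 0) {
    abort(paste0("ruleset limits lack column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "pv_config_error")
  }
  bad_vital <- setdiff(unique(limits$vital), pv_vital_cols)
  if (length(bad_vital) > 0) {
    abort(paste0("unknown vital(s): ", paste(bad_vital, collapse = ", ")),
          class = "pv_config_error")
  }
  limits <- dplyr::arrange(limits, .data$vital, .data$age_lo)
  for (v in unique(limits$vital)) {
    b <- limits[limits$vital == v, ]
    if (any(b$age_lo >= b$age_hi)) {
      abort(sprintf("%s: empty or inverted age band", v),
            class = "pv_config_error")
    }
    if (b$age_lo[1] != 0 || b$age_hi[nrow(b)] < 18 ||
        (nrow(b) > 1 && any(abs(b$age_hi[-nrow(b)] - b$age_lo[-1]) > 1e-9))) {
      abort(sprintf("%s: age bands must partition [0, 18)", v),
            class = "pv_config_error")
    }
    both <- !is.na(b$lower) & !is.na(b$upper)
    if (any(is.na(b$lower) & is.na(b$upper))) {
      abort(sprintf("%s: a band has neither limit", v),
            class = "pv_config_error")
    }
    if (any(both & b$lower >= b$upper)) {
      abort(sprintf("%s: lower limit must be below upper limit", v),
            class = "pv_config_error")
    }
  }
  structure(limits, name = name,
            class = c("pv_ruleset", class(tibble::tibble())))
}

#' @export
print.pv_ruleset <- function(x, ...) {
  cat("<vital-sign rule set: ", attr(x, "name"), ">\n", sep = "")
  NextMethod()
}

pv_day <- 1 / 365.25
pv_month <- 1 / 12

#' Built-in rule sets
#'
#' `ruleset_pals()` returns the 2020 Pediatric Advanced Life Support normal
#' ranges (two-sided). `ruleset_atls()` returns the 10th-edition Advanced
#' Trauma Life Support abnormality thresholds, which are one-sided: upper
#' limits for heart rate and respiratory rate (tachycardia, tachypnea) and
#' lower limits for systolic blood pressure (hypotension).
#' `ruleset_empirical()` returns the simplified age-banded ranges derived
#' empirically against the STAT major-trauma outcome on the 2021 national
#' trauma registry (nine age groups from 0-3 months to 12-18 years).
#'
#' @return A `pv_ruleset` tibble.
#' @examples
#' classify_vital(ruleset_pals(), "heart_rate", 90, age = 2) # low
#' @export
ruleset_pals <- function() {
  hr <- tibble::tribble(
    ~age_lo,        ~age_hi,       ~lower, ~upper,
    0,              28 * pv_day,   100,    125,
    28 * pv_day,    1,             100,    180,
    1,              4,             98,     140,
    4,              6,             80,     120,
    6,              12,            75,     118,
    12,             18,            60,     100
  )
  rr <- tibble::tribble(
    ~age_lo, ~age_hi, ~lower, ~upper,
    0,       1,       30,     53,
    1,       3,       22,     37,
    3,       6,       20,     28,
    6,       12,      18,     25,
    12,      18,      12,     20
  )
  sbp <- tibble::tribble(
    ~age_lo,      ~age_hi,      ~lower, ~upper,
    0,            4 * pv_day,   39,     59,
    4 * pv_day,   pv_month,     67,     84,
    pv_month,     1,            72,     104,
    1,            3,            86,     106,
    3,            6,            89,     112,
    6,            10,           97,     115,
    10,           12,           102,    120,
    12,           18,           110,    131
  )
  ruleset(dplyr::bind_rows(
    dplyr::mutate(hr, vital = "heart_rate"),
    dplyr::mutate(rr, vital = "resp_rate"),
    dplyr::mutate(sbp, vital = "sbp")
  ), name = "PALS")
}

#' @rdname ruleset_pals
#' @export
ruleset_atls <- function() {
  hr <- tibble::tribble(
    ~age_lo, ~age_hi, ~upper,
    0,       1,       160,
    1,       3,       150,
    3,       6,       140,
    6,       13,      120,
    13,      18,      100
  )
  rr <- tibble::tribble(
    ~age_lo, ~age_hi, ~upper,
    0,       1,       60,
    1,       3,       40,
    3,       6,       35,
    6,       18,      30
  )
  sbp <- tibble::tribble(
    ~age_lo, ~age_hi, ~lower,
    0,       1,       60,
    1,       3,       70,
    3,       6,       75,
    6,       13,      80,
    13,      18,      90
  )
  ruleset(dplyr::bind_rows(
    dplyr::mutate(hr, vital = "heart_rate", lower = NA_real_),
    dplyr::mutate(rr, vital = "resp_rate", lower = NA_real_),
    dplyr::mutate(sbp, vital = "sbp", upper = NA_real_)
  ), name = "ATLS")
}

# Nine simplified age groups shared by all three vitals.
pv_empirical_bands <- function() {
  tibble::tibble(
    age_lo = c(0, 0.25, 0.5, 0.75, 1, 3, 6, 9, 12),
    age_hi = c(0.25, 0.5, 0.75, 1, 3, 6, 9, 12, 18)
  )
}

#' @rdname ruleset_pals
#' @export
ruleset_empirical <- function() {
  bands <- pv_empirical_bands()
  lims <- function(v, lo, hi) {
    dplyr::mutate(bands, vital = v, lower = lo, upper = hi)
  }
  ruleset(dplyr::bind_rows(
    lims("heart_rate",
         c(101, 109, 107, 105, 98, 87, 80, 77, 71),
         c(163, 160, 156, 156, 152, 133, 122, 117, 113)),
    lims("resp_rate",
         c(22, 23, 22, 22, 21, 18, 17, 16, 15),
         c(51, 46, 42, 40, 36, 30, 26, 24, 22)),
    lims("sbp",
         c(74, 81, 84, 86, 90, 94, 99, 103, 110),
         c(140, 127, 129, 131, 134, 131, 133, 138, 148))
  ), name = "EMPIRICAL_SIMPLIFIED")
}

#' Resolve the age band for one vital sign
#'
#' @param rules A `pv_ruleset`.
#' @param vital One of `"heart_rate"`, `"resp_rate"`, `"sbp"`.
#' @param age Age in years, in \[0, 18).
#' @return The matching one-row band tibble (`age_lo`, `age_hi`, `lower`,
#'   `upper`).
#' @export
resolve_age_band <- function(rules, vital, age) {
  if (!vital %in% pv_vital_cols) {
    abort(paste0("unknown vital: ", vital), class = "pv_domain_error")
  }
  if (any(is.na(age)) || any(age < 0 | age >= 18)) {
    abort("age must be in [0, 18)", class = "pv_domain_error")
  }
  b <- rules[rules$vital == vital, ]
  idx <- findInterval(age, c(b$age_lo, 18), rightmost.closed = FALSE)
  b[idx, c("age_lo", "age_hi", "lower", "upper")]
}

#' Classify a vital-sign value against a rule set
#'
#' A value below the resolved band's lower limit classifies `low`, above
#' the upper limit `high`, otherwise `normal` (limits inclusive). Missing
#' values classify missing (`NA`). An absent one-sided limit never fires.
#' Vectorized over `value` and `age`.
#'
#' @inheritParams resolve_age_band
#' @param value Vital-sign value(s); `NA` allowed.
#' @return A factor with levels `low < normal < high` (`NA` for missing).
#' @export
classify_vital <- function(rules, vital, value, age) {
  n <- max(length(value), length(age))
  value <- rep_len(as.numeric(value), n)
  age <- rep_len(age, n)
  band <- resolve_age_band(rules, vital, age)
  cls <- rep(NA_character_, n)
  ok <- !is.na(value)
  low <- ok & !is.na(band$lower) & value < band$lower
  high <- ok & !is.na(band$upper) & value > band$upper
  cls[ok] <- "normal"
  cls[low] <- "low"
  cls[high] <- "high"
  factor(cls, levels = c("low", "normal", "high"), ordered = TRUE)
}

#' Classify all vitals in an encounter table
#'
#' Adds `hr_class`, `rr_class`, `sbp_class` and `any_abnormal` columns.
#' `any_abnormal` mirrors the complete-vitals analysis: it is defined only
#' for encounters with all three vitals documented, and is `TRUE` when at
#' least one classifies low or high; encounters missing any vital get `NA`.
#'
#' @param data Encounter tibble with `age_years` and vital columns.
#' @param rules A `pv_ruleset`.
#' @return `data` with the four classification columns appended.
#' @export
classify_vitals <- function(data, rules) {
  data$hr_class <- classify_vital(rules, "heart_rate", data$heart_rate,
                                  data$age_years)
  data$rr_class <- classify_vital(rules, "resp_rate", data$resp_rate,
                                  data$age_years)
  data$sbp_class <- classify_vital(rules, "sbp", data$sbp, data$age_years)
  abn <- function(cl) !is.na(cl) & cl != "normal"
  complete <- !is.na(data$hr_class) & !is.na(data$rr_class) &
    !is.na(data$sbp_class)
  data$any_abnormal <- dplyr::if_else(
    complete,
    abn(data$hr_class) | abn(data$rr_class) | abn(data$sbp_class),
    NA
  )
  data
}

#' Flag an encounter as having any abnormal vital sign
#'
#' Defined only when all three vitals are documented; otherwise `NA` (the
#' encounter falls outside the complete-vitals subset).
#'
#' @param rules A `pv_ruleset`.
#' @param encounter A one-row encounter tibble (or a full table; vectorized).
#' @return Logical (`NA` when any vital is missing).
#' @export
flag_any_abnormal <- function(rules, encounter) {
  classify_vitals(encounter, rules)$any_abnormal
}
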