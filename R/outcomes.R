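#' Default NFTI criterion set
#'
#' The Need for Trauma Intervention composite is positive when any of its
#' criteria holds. The default set follows the original publication: blood
#' product within 4 h of arrival, ED-to-OR within 90 min, ED discharge to
#' interventional radiology, >= 3 ventilator days (counting ED intubation),
#' >= 3 ICU days, or death within 60 h. Override to match a local registry's
#' definition.
#'
#' @return A named list: logical component names to use, plus integer day
#'   thresholds `icu_days_min` and `ventilator_days_min`.
#' @export
nfti_default_criteria <- function() {
  list(
    flags = c("blood_product_within_4h", "ed_to_or_within_90min",
              "ed_to_interventional_radiology", "death_within_60h"),
    icu_days_min = 3,
    ventilator_days_min = 3
  )
}

#' Cribari matrix high-severity criterion
#'
#' High injury severity under the conventional major-trauma threshold:
#' Injury Severity Score above 15. Vectorized; missing ISS gives `NA`
#' (such encounters are excluded upstream for lacking outcome data).
#'
#' @param iss Injury Severity Score(s), 0-75.
#' @param threshold Severity threshold (default 15; `iss > threshold` is
#'   high severity).
#' @return Logical.
#' @export
cribari_high_severity <- function(iss, threshold = 15) {
  ifelse(is.na(iss), NA, iss > threshold)
}

#' Need for Trauma Intervention composite
#'
#' Any-of composite over the configured criterion set. Missing component
#' values conservatively count as criterion not met.
#'
#' @param components Data frame (or one-row tibble) with the outcome
#'   component columns (see [read_registry()]).
#' @param criteria Criterion set, as from [nfti_default_criteria()].
#' @return Logical, one per row.
#' @export
nfti_positive <- function(components, criteria = nfti_default_criteria()) {
  hit <- rep(FALSE, nrow(components))
  for (f in criteria$flags) {
    x <- components[[f]]
    if (!is.null(x)) hit <- hit | (!is.na(x) & x)
  }
  icu <- components$icu_days
  if (!is.null(icu)) hit <- hit | (!is.na(icu) & icu >= criteria$icu_days_min)
  vent <- components$ventilator_days
  if (!is.null(vent)) {
    hit <- hit | (!is.na(vent) & vent >= criteria$ventilator_days_min)
  }
  hit
}

#' Need for Emergent Intervention within 6 hours
#'
#' Carried as an ingested/generated flag (the procedure-code logic that
#' defines it lives upstream of this package); missing counts as not met.
#'
#' @inheritParams nfti_positive
#' @return Logical, one per row.
#' @export
nei6_positive <- function(components) {
  x <- components$emergent_intervention_within_6h
  if (is.null(x)) return(rep(FALSE, nrow(components)))
  !is.na(x) & x
}

#' STAT major-trauma definition
#'
#' Major trauma under the Standard Triage Assessment Tool: both high
#' injury severity (Cribari matrix) and need for intervention (NFTI).
#'
#' @param iss Injury Severity Score(s).
#' @param components Outcome component data frame (same length).
#' @param criteria NFTI criterion set.
#' @param iss_threshold Cribari severity threshold.
#' @return Logical, one per row.
#' @export
stat_major_trauma <- function(iss, components,
                              criteria = nfti_default_criteria(),
                              iss_threshold = 15) {
  cribari_high_severity(iss, iss_threshold) & nfti_positive(components, criteria)
}

#' Add composite outcome columns to an encounter table
#'
#' Appends logical columns `cm` (Cribari high severity), `nfti`, `nei6`
#' and `stat` (= `cm & nfti`).
#'
#' @param data Encounter tibble with `iss` and the outcome component
#'   columns.
#' @param criteria NFTI criterion set (see [nfti_default_criteria()]).
#' @param iss_threshold Cribari severity threshold.
#' @return `data` with the four outcome columns appended.
#' @export
add_outcomes <- function(data, criteria = nfti_default_criteria(),
                         iss_threshold = 15) {
  data$cm <- cribari_high_severity(data$iss, iss_threshold)
  data$nfti <- nfti_positive(data, criteria)
  data$nei6 <- nei6_positive(data)
  data$stat <- data$cm & data$nfti
  data
}
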