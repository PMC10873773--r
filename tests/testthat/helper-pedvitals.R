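# Build a minimal canonical encounter table; any field can be overridden
# with a vector recycled to n.
make_encounters <- function(n = 1, ...) {
  base <- tibble::tibble(
    encounter_id = sprintf("T%03d", seq_len(n)),
    age_years = 10,
    weight_kg = NA_real_,
    heart_rate = 100,
    resp_rate = 20,
    sbp = 110,
    gcs = 15,
    iss = 5,
    ohca = FALSE,
    mech_vent_at_arrival = FALSE,
    interfacility_transfer = FALSE,
    blood_product_within_4h = FALSE,
    ed_to_or_within_90min = FALSE,
    ed_to_interventional_radiology = FALSE,
    icu_days = 0,
    ventilator_days = 0,
    death_within_60h = FALSE,
    in_hospital_death = FALSE,
    emergent_intervention_within_6h = FALSE
  )
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- rep_len(over[[nm]], n)
  base
}

# Independent O(n^2) scan over all candidate thresholds (midpoints between
# adjacent distinct values plus infinite sentinels), with the same
# tie-break rule stated for the implementation: least-extreme optimum.
brute_force_youden <- function(values, labels, direction) {
  d <- sort(unique(values))
  cand <- c(-Inf, if (length(d) > 1) (d[-length(d)] + d[-1]) / 2, Inf)
  j <- vapply(cand, function(cc) {
    flag <- if (direction == "flag_if_less") values < cc else values > cc
    sens <- sum(flag & labels) / sum(labels)
    spec <- sum(!flag & !labels) / sum(!labels)
    sens + spec - 1
  }, numeric(1))
  best <- which(j >= max(j) - 1e-12)
  if (length(best) > 1) {
    ctr <- stats::median(values)
    best <- best[order(abs(cand[best] - ctr), cand[best])][1]
  }
  list(cutpoint = cand[best], youden = j[best])
}

# closed-form Wilson score interval, independent of prop.test
wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(centre - half, centre + half)
}
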