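#' Distribution table used by the synthetic registry
#'
#' Plausible pediatric anchors for the age-varying location and scale of
#' each vital sign (heart rate falling from ~140 beats/min at birth to ~75
#' at 17 years, respiratory rate from ~40 to ~14 breaths/min, systolic
#' blood pressure rising from ~70 to ~115 mm Hg). These serve purely as the
#' generator's own coordinate system — they are the known ground truth that
#' derivation tests recover, and are not estimates of any published
#' reference distribution.
#'
#' @return A [dist_table()] with entries `heart_rate`, `resp_rate`, `sbp`.
#' @export
sim_dist_table <- function() {
  dist_table(tibble::tibble(
    vital = rep(c("heart_rate", "resp_rate", "sbp"), each = 6),
    age = rep(c(0, 1, 3, 6, 12, 17), times = 3),
    location = c(140, 125, 110, 100, 85, 75,
                 40, 30, 24, 20, 16, 14,
                 70, 90, 95, 100, 110, 115),
    scale = c(18, 17, 16, 15, 14, 13,
              8, 6, 5, 4.5, 4, 3.5,
              10, 10, 11, 11, 12, 12),
    skew = 0
  ))
}

#' Configuration for the synthetic trauma registry
#'
#' The defaults emulate the structure of the 2021 national pediatric
#' trauma-registry derivation sample: age median 11 years with IQR 5-15,
#' documentation of heart rate in 99.7%, respiratory rate in 100% and SBP
#' in 91.1% of encounters, STAT major-trauma prevalence 4.6%, Cribari 9.5%,
#' NFTI 14.5% and NEI-6 17.6%, and a U-shaped relation between
#' age-adjusted vital-sign z-scores and major trauma.
#'
#' Under `risk_link = "jump"` the probability of major trauma given any
#' one vital's z-score is piecewise constant — a low interior risk between
#' `jump_points` and a tail risk `risk_ratio_at_tail` times higher outside
#' them — so the population-optimal two-sided Youden cutoffs sit exactly at
#' `jump_points`. `"quadratic"` gives a smooth U (logit risk quadratic in
#' z) for spline tests; `"null"` makes the outcome independent of vitals.
#'
#' @param n Number of encounters.
#' @param stat_prevalence Marginal STAT (major trauma) prevalence.
#' @param cm_prevalence,nfti_prevalence,nei6_prevalence Marginal
#'   prevalences of the alternative composite outcomes (each must be at
#'   least `stat_prevalence`; STAT encounters meet all of them).
#' @param vital_documentation Named fractions of encounters with each
#'   vital documented (missingness is completely at random).
#' @param risk_link `"jump"`, `"quadratic"` or `"null"`.
#' @param jump_points Length-2 ordered z values where the jump-link risk
#'   steps (the true optimal cutoffs).
#' @param risk_ratio_at_tail Tail-to-interior risk ratio for the jump link.
#' @param quad_strength Coefficient on mean squared z in the quadratic
#'   link's logit.
#' @param exclusion_fractions Named fractions for `ohca`, `vent`,
#'   `transfer` flags and `missing_iss` (all completely at random).
#' @param dists Generator distribution table mapping z to raw vitals.
#' @return A validated `pv_sim_config` list.
#' @seealso [generate_registry()], [true_optimal_cutpoints()]
#' @export
sim_config <- function(n,
                       stat_prevalence = 0.046,
                       cm_prevalence = 0.095,
                       nfti_prevalence = 0.145,
                       nei6_prevalence = 0.176,
                       vital_documentation = c(heart_rate = 0.997,
                                               resp_rate = 1.0,
                                               sbp = 0.911),
                       risk_link = c("jump", "quadratic", "null"),
                       jump_points = c(-1.3, 0.85),
                       risk_ratio_at_tail = 4,
                       quad_strength = 0.6,
                       exclusion_fractions = c(ohca = 0.005, vent = 0.01,
                                               transfer = 0.02,
                                               missing_iss = 0.01),
                       dists = sim_dist_table()) {
  risk_link <- match.arg(risk_link)
  if (n < 1) abort("n must be >= 1", class = "pv_config_error")
  fracs <- c(stat_prevalence, cm_prevalence, nfti_prevalence, nei6_prevalence,
             vital_documentation, exclusion_fractions)
  if (any(fracs < 0 | fracs > 1)) {
    abort("all fractions must be in [0, 1]", class = "pv_config_error")
  }
  if (any(c(cm_prevalence, nfti_prevalence, nei6_prevalence) <
          stat_prevalence)) {
    abort("composite outcome prevalences cannot be below STAT's",
          class = "pv_config_error")
  }
  if (risk_link == "jump") {
    if (length(jump_points) != 2 || jump_points[1] >= jump_points[2]) {
      abort("jump_points must be two ordered z values",
            class = "pv_config_error")
    }
    if (risk_ratio_at_tail <= 1) {
      abort("risk_ratio_at_tail must exceed 1", class = "pv_config_error")
    }
    p_in <- pnorm(jump_points[2]) - pnorm(jump_points[1])
    r_in <- stat_prevalence / (p_in + risk_ratio_at_tail * (1 - p_in))
    if (risk_ratio_at_tail * r_in >= 1) {
      abort("tail risk exceeds 1; lower the prevalence or risk ratio",
            class = "pv_config_error")
    }
  }
  structure(list(
    n = as.integer(n), stat_prevalence = stat_prevalence,
    cm_prevalence = cm_prevalence, nfti_prevalence = nfti_prevalence,
    nei6_prevalence = nei6_prevalence,
    vital_documentation = vital_documentation, risk_link = risk_link,
    jump_points = jump_points, risk_ratio_at_tail = risk_ratio_at_tail,
    quad_strength = quad_strength,
    exclusion_fractions = exclusion_fractions, dists = dists
  ), class = "pv_sim_config")
}

#' True optimal z cutoffs of a generator configuration
#'
#' Under the jump link the conditional risk is piecewise constant with a
#' single step on each side of the interior, so the population Youden
#' optimum on each median-split side coincides with the step location.
#' This is the oracle that parameter-recovery tests compare derived
#' cutoffs against.
#'
#' @param config A [sim_config()].
#' @return A list with `z_low` and `z_high`.
#' @export
true_optimal_cutpoints <- function(config) {
  if (config$risk_link != "jump") {
    abort("true cutpoints are only defined for the jump risk link",
          class = "pv_config_error")
  }
  list(z_low = config$jump_points[1], z_high = config$jump_points[2])
}

# inverse-CDF draw from a standard normal truncated to the interior
# [z0, z1] (inside = TRUE) or to the two tails (inside = FALSE)
pv_rtrunc_norm <- function(n, z0, z1, inside) {
  p0 <- pnorm(z0)
  p1 <- pnorm(z1)
  if (inside) {
    qnorm(runif(n, p0, p1))
  } else {
    u <- runif(n, 0, p0 + (1 - p1))
    qnorm(ifelse(u < p0, u, u + (p1 - p0)))
  }
}

# z | label draws under the jump link: mixture of interior/tail truncated
# normals with weights chosen so P(label | z) is piecewise constant at
# r_in inside the jump points and risk_ratio * r_in outside
pv_draw_jump_z <- function(label, config) {
  z0 <- config$jump_points[1]
  z1 <- config$jump_points[2]
  p <- config$stat_prevalence
  p_in <- pnorm(z1) - pnorm(z0)
  r_in <- p / (p_in + config$risk_ratio_at_tail * (1 - p_in))
  r_out <- config$risk_ratio_at_tail * r_in
  w_in <- ifelse(label, r_in * p_in / p, (1 - r_in) * p_in / (1 - p))
  inside <- runif(length(label)) < w_in
  z <- numeric(length(label))
  z[inside] <- pv_rtrunc_norm(sum(inside), z0, z1, inside = TRUE)
  z[!inside] <- pv_rtrunc_norm(sum(!inside), z0, z1, inside = FALSE)
  z
}

# ages with population median 11 and IQR 5-15: piecewise uniform with
# quartile mass on [0,5), [5,11), [11,15), [15,18)
pv_draw_ages <- function(n) {
  breaks <- c(0, 5, 11, 15, 18)
  u <- runif(n)
  seg <- pmin(findInterval(u, c(0, 0.25, 0.5, 0.75)), 4)
  lo <- breaks[seg]
  hi <- breaks[seg + 1]
  lo + (u - (seg - 1) * 0.25) / 0.25 * (hi - lo)
}

# outcome components consistent with the encounter's composite-outcome
# membership: STAT rows meet both Cribari and NFTI, fringe rows meet one
pv_build_outcomes <- function(stat, cm, nfti, nei6) {
  n <- length(stat)
  comp <- tibble::tibble(
    blood_product_within_4h = rep(FALSE, n),
    ed_to_or_within_90min = FALSE,
    ed_to_interventional_radiology = FALSE,
    icu_days = 0L,
    ventilator_days = 0L,
    death_within_60h = FALSE,
    in_hospital_death = FALSE,
    emergent_intervention_within_6h = nei6
  )
  idx <- which(nfti)
  if (length(idx) > 0) {
    # draw each criterion independently, then force one where none fired
    draw <- matrix(runif(length(idx) * 4) < 0.3, ncol = 4)
    none <- rowSums(draw) == 0
    draw[cbind(which(none), sample(4, sum(none), replace = TRUE))] <- TRUE
    comp$blood_product_within_4h[idx] <- draw[, 1]
    comp$ed_to_or_within_90min[idx] <- draw[, 2]
    comp$icu_days[idx] <- ifelse(draw[, 3],
                                 sample(3:14, length(idx), replace = TRUE), 0L)
    comp$ventilator_days[idx] <- ifelse(
      draw[, 4], sample(3:10, length(idx), replace = TRUE), 0L)
    died <- runif(length(idx)) < 0.05
    comp$death_within_60h[idx] <- died
    comp$in_hospital_death[idx] <- died | (runif(length(idx)) < 0.02)
  }
  iss <- integer(n)
  iss[cm] <- sample(16:75, sum(cm), replace = TRUE)
  iss[!cm] <- sample(0:15, sum(!cm), replace = TRUE)
  list(components = comp, iss = iss)
}

#' Generate a synthetic pediatric trauma registry
#'
#' Draws an encounter table with known ground truth: a latent major-trauma
#' label at the configured prevalence; per-vital age-adjusted z-scores
#' whose dependence on the label follows the configured risk link; raw
#' vitals obtained by mapping z through the generator's distribution table
#' at the drawn age; completely-at-random missingness at the configured
#' documentation rates; outcome components and ISS reverse-engineered so
#' that the STAT composite equals the latent label exactly (with
#' Cribari-only and NFTI-only fringe encounters making the alternative
#' outcomes more prevalent than STAT); and completely-at-random exclusion
#' flags. Deterministic given `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return An encounter tibble in the canonical [read_registry()] schema.
#' @examples
#' reg <- generate_registry(sim_config(n = 1000), seed = 1)
#' mean(add_outcomes(apply_exclusions(reg)$encounters)$stat)
#' @export
generate_registry <- function(config, seed = 1L) {
  stopifnot(inherits(config, "pv_sim_config"))
  withr::with_seed(seed, pv_generate_registry_impl(config))
}

pv_generate_registry_impl <- function(config) {
  n <- config$n
  age <- pv_draw_ages(n)

  if (config$risk_link == "jump") {
    label <- runif(n) < config$stat_prevalence
    z <- list(heart_rate = pv_draw_jump_z(label, config),
              resp_rate = pv_draw_jump_z(label, config),
              sbp = pv_draw_jump_z(label, config))
  } else {
    z <- list(heart_rate = rnorm(n), resp_rate = rnorm(n), sbp = rnorm(n))
    if (config$risk_link == "quadratic") {
      q <- config$quad_strength *
        (z$heart_rate^2 + z$resp_rate^2 + z$sbp^2) / 3
      # intercept calibrated on the realized draw to hit the target
      # marginal prevalence
      b0 <- tryCatch(
        uniroot(function(b) mean(plogis(b + q)) - config$stat_prevalence,
                c(-30, 10))$root,
        error = function(e) abort("cannot calibrate quadratic link",
                                  class = "pv_config_error"))
      label <- runif(n) < plogis(b0 + q)
    } else {
      label <- runif(n) < config$stat_prevalence
    }
  }

  vital <- lapply(pv_vital_cols, function(v) {
    doc <- runif(n) < config$vital_documentation[[v]]
    val <- pmax(z_to_vital(config$dists[[v]], z[[v]], pmin(age, 18 - 1e-9)), 1)
    ifelse(doc, val, NA_real_)
  })
  names(vital) <- pv_vital_cols

  # fringe memberships among non-STAT rows keep the prevalence ordering
  # STAT < CM < NFTI < NEI-6
  share <- function(target) {
    (target - config$stat_prevalence) / (1 - config$stat_prevalence)
  }
  u_cm <- runif(n)
  u_nfti <- runif(n)
  cm <- label | (!label & u_cm < share(config$cm_prevalence))
  nfti <- label | (!label & u_cm >= share(config$cm_prevalence) &
                     u_nfti < share(config$nfti_prevalence))
  nei6 <- label | (!label & runif(n) < share(config$nei6_prevalence))
  built <- pv_build_outcomes(label, cm, nfti, nei6)

  ex <- config$exclusion_fractions
  iss <- built$iss
  iss[runif(n) < ex[["missing_iss"]]] <- NA_integer_

  gcs <- ifelse(label, sample(3:15, n, replace = TRUE, prob = c(rep(2, 6), rep(1, 7))),
                sample(12:15, n, replace = TRUE, prob = c(1, 1, 2, 16)))

  out <- tibble::tibble(
    encounter_id = sprintf("S%07d", seq_len(n)),
    age_years = age,
    weight_kg = ifelse(age < 1, (age * 12 + 9) / 2, NA_real_),
    heart_rate = vital$heart_rate,
    resp_rate = vital$resp_rate,
    sbp = vital$sbp,
    gcs = as.numeric(gcs),
    iss = as.numeric(iss),
    ohca = runif(n) < ex[["ohca"]],
    mech_vent_at_arrival = runif(n) < ex[["vent"]],
    interfacility_transfer = runif(n) < ex[["transfer"]]
  )
  dplyr::bind_cols(out, built$components)
}
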