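#' Age-varying reference distribution for a vital sign
#'
#' Represents the age-specific location, scale and (optional) skew of a
#' vital sign as piecewise-linear functions of age between knots, constant
#' beyond the outermost knots. With `skew = 0` everywhere the model is a
#' plain location-scale (Gaussian-quantile) transform,
#' `z = (value - location(age)) / scale(age)`. With nonzero skew `lambda`
#' the LMS (Box-Cox) convention is used:
#' `z = ((value / location)^lambda - 1) / (lambda * scale)`.
#'
#' Reference parameter tables are pluggable — they are supplied as data,
#' not re-fit here. The synthetic registry generator ships its own table
#' (see [sim_dist_table()]) which the derivation tests use as ground truth.
#'
#' @param knots A data frame with columns `age` (years, strictly
#'   increasing), `location`, `scale` (positive) and optionally `skew`
#'   (default 0).
#' @param vital Vital-sign name the table describes.
#' @return A `pv_dist` object.
#' @seealso [vital_to_z()], [z_to_vital()], [dist_table()]
#' @export
vital_dist <- function(knots, vital = "vital") {
  knots <- tibble::as_tibble(knots)
  if (!all(c("age", "location", "scale") %in% names(knots))) {
    abort("knots need columns age, location, scale", class = "pv_config_error")
  }
  if (!"skew" %in% names(knots)) knots$skew <- 0
  knots <- dplyr::arrange(knots, .data$age)
  if (any(duplicated(knots$age))) {
    abort("knot ages must be strictly increasing", class = "pv_config_error")
  }
  if (any(knots$scale <= 0)) {
    abort("scale must be positive at every knot", class = "pv_config_error")
  }
  structure(list(vital = vital, knots = knots), class = "pv_dist")
}

#' @export
print.pv_dist <- function(x, ...) {
  cat("<age-varying distribution: ", x$vital, ", ",
      nrow(x$knots), " knots>\n", sep = "")
  print(x$knots)
  invisible(x)
}

# Interpolate (location, scale, skew) at given ages: linear between knots,
# constant beyond the outermost knots (rule = 2 avoids extrapolating the
# scale below zero at extreme ages).
pv_dist_params <- function(dist, age) {
  k <- dist$knots
  interp <- function(y) {
    if (nrow(k) == 1) rep(y, length(age))
    else approx(k$age, y, xout = age, rule = 2)$y
  }
  list(location = interp(k$location), scale = interp(k$scale),
       skew = interp(k$skew))
}

#' Convert vital-sign values to age-adjusted z-scores
#'
#' @param dist A [vital_dist()] object.
#' @param value Vital-sign value(s).
#' @param age Age(s) in years, in \[0, 18).
#' @return z-score(s); `NA` in gives `NA` out.
#' @examples
#' d <- vital_dist(data.frame(age = c(0, 17), location = 100, scale = 10))
#' vital_to_z(d, 110, age = 5) # 1
#' @export
vital_to_z <- function(dist, value, age) {
  n <- max(length(value), length(age))
  value <- rep_len(as.numeric(value), n)
  age <- rep_len(age, n)
  if (any(!is.na(age) & (age < 0 | age >= 18))) {
    abort("age must be in [0, 18)", class = "pv_domain_error")
  }
  p <- pv_dist_params(dist, age)
  if (any(p$scale <= 0, na.rm = TRUE)) {
    abort("interpolated scale must be positive", class = "pv_config_error")
  }
  lms <- !is.na(p$skew) & p$skew != 0
  z <- (value - p$location) / p$scale
  if (any(lms)) {
    z[lms] <- ((value[lms] / p$location[lms])^p$skew[lms] - 1) /
      (p$skew[lms] * p$scale[lms])
  }
  z
}

#' Convert age-adjusted z-scores back to vital-sign values
#'
#' Exact inverse of [vital_to_z()] at the same age (round trip within 1e-9
#' relative tolerance).
#'
#' @param dist A [vital_dist()] object.
#' @param z z-score(s).
#' @param age Age(s) in years, in \[0, 18).
#' @return Vital-sign value(s) on the measurement scale.
#' @export
z_to_vital <- function(dist, z, age) {
  n <- max(length(z), length(age))
  z <- rep_len(as.numeric(z), n)
  age <- rep_len(age, n)
  if (any(!is.na(age) & (age < 0 | age >= 18))) {
    abort("age must be in [0, 18)", class = "pv_domain_error")
  }
  p <- pv_dist_params(dist, age)
  lms <- !is.na(p$skew) & p$skew != 0
  v <- p$location + z * p$scale
  if (any(lms)) {
    base <- 1 + p$skew[lms] * p$scale[lms] * z[lms]
    if (any(base <= 0, na.rm = TRUE)) {
      abort("inverse undefined for this skew (non-positive argument)",
            class = "pv_domain_error")
    }
    v[lms] <- p$location[lms] * base^(1 / p$skew[lms])
  }
  v
}

#' Assemble a multi-vital distribution table
#'
#' Bundles one [vital_dist()] per vital sign, read from a long data frame
#' with columns `vital`, `age`, `location`, `scale` and optionally `skew`
#' (the same layout the CSV interface uses).
#'
#' @param params Long-format parameter data frame.
#' @return A named list of `pv_dist`, classed `pv_dist_table`.
#' @export
dist_table <- function(params) {
  params <- tibble::as_tibble(params)
  out <- lapply(split(params, params$vital), function(k) {
    vital_dist(k[setdiff(names(k), "vital")], vital = k$vital[1])
  })
  structure(out, class = "pv_dist_table")
}

#' Add age-adjusted z-score columns to an encounter table
#'
#' Adds `hr_z`, `rr_z` and `sbp_z` computed from the encounter's vitals and
#' age under the supplied distribution table.
#'
#' @param data Encounter tibble with `age_years` and vital columns.
#' @param dists A [dist_table()] with entries `heart_rate`, `resp_rate`,
#'   `sbp`.
#' @return `data` with three z-score columns appended.
#' @export
add_zscores <- function(data, dists) {
  data$hr_z <- vital_to_z(dists$heart_rate, data$heart_rate, data$age_years)
  data$rr_z <- vital_to_z(dists$resp_rate, data$resp_rate, data$age_years)
  data$sbp_z <- vital_to_z(dists$sbp, data$sbp, data$age_years)
  data
}
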