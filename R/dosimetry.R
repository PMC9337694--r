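# Dosimetry: depth-dose interpolation, distance-bin assignment, per-organ
# neutron equivalent dose, depth classification.

#' Interpolate a neutron depth-dose curve
#'
#' Evaluates the tabulated dose density at arbitrary depths.  Two
#' interpolants are offered: `"linear"` (chords in dose space) and
#' `"log-linear"` (chords in log-dose space, i.e. piecewise exponential —
#' exact if the true curve is exponential attenuation).  Both reproduce the
#' tabulated values at grid points.
#'
#' Depths above the deepest grid point are clamped to the deepest tabulated
#' value with a warning; depths below the shallowest grid point are an
#' error, since extrapolating the build-up region toward the surface is not
#' physically defensible.
#'
#' @param curve A [depth_dose_curve()].
#' @param depth_cm Depths at which to evaluate (cm); vectorized.
#' @param scheme `"linear"` or `"log-linear"`.
#' @return Dose densities at `depth_cm` (same units as the curve).
#' @examples
#' curve <- reference_tables()$depth_dose
#' interpolate_depth_dose(curve, 2)            # 16.11, a grid point
#' interpolate_depth_dose(curve, 9.5)          # 1.7475, linear chord
#' @export
interpolate_depth_dose <- function(curve, depth_cm,
                                   scheme = c("linear", "log-linear")) {
  scheme <- rlang::arg_match(scheme)
  curve <- as_depth_dose_curve(curve, reference_depth_cm = reference_depth(curve))
  if (any(!is.finite(depth_cm))) {
    abort_validation("depth_cm must be finite")
  }
  d_min <- min(curve$depth_cm)
  d_max <- max(curve$depth_cm)
  if (any(depth_cm < d_min)) {
    abort_validation(sprintf(
      "depth %g cm is below the curve minimum (%g cm); no extrapolation toward the surface",
      min(depth_cm), d_min))
  }
  if (any(depth_cm > d_max)) {
    rlang::warn(sprintf(
      "depth beyond the tabulated maximum (%g cm); clamping to the deepest value",
      d_max))
    depth_cm <- pmin(depth_cm, d_max)
  }
  if (scheme == "linear") {
    stats::approx(curve$depth_cm, curve$dose_density, xout = depth_cm,
                  method = "linear", ties = "ordered")$y
  } else {
    exp(stats::approx(curve$depth_cm, log(curve$dose_density), xout = depth_cm,
                      method = "linear", ties = "ordered")$y)
  }
}

#' Depth correction factor
#'
#' Ratio of the interpolated dose density at an organ's depth to the value
#' at the curve's reference depth (1 cm by default, where H*(10) is
#' defined).  Multiplying a surface-referenced H*(10) by this factor
#' corrects it to the organ's depth.
#'
#' @inheritParams interpolate_depth_dose
#' @return Dimensionless correction factors; 1 at the reference depth.
#' @export
depth_correction_factor <- function(curve, depth_cm,
                                    scheme = c("linear", "log-linear")) {
  scheme <- rlang::arg_match(scheme)
  ref <- interpolate_depth_dose(curve, reference_depth(curve), scheme)
  interpolate_depth_dose(curve, depth_cm, scheme) / ref
}

# ---- Distance bins ----------------------------------------------------------

#' Distance-bin rule mapping organ distances to measurement points
#'
#' Out-of-field neutron spectra vary slowly with lateral distance, so a
#' single measurement point can represent a whole distance bin.  A rule is
#' an ordered set of non-overlapping bins, each with the representative
#' distance at which H*(10) was actually measured.
#'
#' The first bin includes its lower bound; each bin includes its upper
#' bound.  Distances below the first lower bound are always an error (organs
#' that close to the field edge are inside the model's validity limit);
#' distances beyond the last bin follow `out_of_range`.
#'
#' @param lower_cm,upper_cm,representative_cm Parallel vectors defining the
#'   bins (cm).
#' @param out_of_range `"clamp"` (distances beyond the last bin use the last
#'   bin) or `"error"`.
#' @return A `distance_bin_rule` tibble.
#' @export
distance_bin_rule <- function(lower_cm, upper_cm, representative_cm,
                              out_of_range = c("clamp", "error")) {
  out_of_range <- rlang::arg_match(out_of_range)
  bins <- tibble::tibble(
    lower_cm = as.numeric(lower_cm),
    upper_cm = as.numeric(upper_cm),
    representative_cm = as.numeric(representative_cm)
  )
  if (nrow(bins) < 1L) abort_validation("bin rule needs at least one bin")
  if (any(bins$upper_cm <= bins$lower_cm)) {
    abort_validation("each bin needs upper_cm > lower_cm")
  }
  if (is.unsorted(bins$lower_cm, strictly = TRUE) ||
      any(diff(bins$upper_cm) <= 0) ||
      any(bins$lower_cm[-1L] < bins$upper_cm[-nrow(bins)])) {
    abort_validation("bins must be ordered and non-overlapping")
  }
  if (any(bins$representative_cm < bins$lower_cm |
          bins$representative_cm > bins$upper_cm)) {
    abort_validation("each representative distance must lie inside its bin")
  }
  out <- new_subclass_tbl(bins, class = "distance_bin_rule")
  attr(out, "out_of_range") <- out_of_range
  out
}

#' Default bin rule for the reference campaign
#'
#' Bins \[5, 40\] cm and (40, 80\] cm, represented by the 20 cm and 60 cm
#' measurement points respectively, with clamping beyond 80 cm (the femoral
#' head at 83.9 cm lies just outside the far bin).
#'
#' @return A `distance_bin_rule`.
#' @export
default_bin_rule <- function() {
  distance_bin_rule(lower_cm = c(5, 40), upper_cm = c(40, 80),
                    representative_cm = c(20, 60), out_of_range = "clamp")
}

#' Assign organ distances to measurement points
#'
#' @param rule A [distance_bin_rule()].
#' @param measurements A [measurement_set()] containing a point at every
#'   representative distance of `rule`.
#' @param distance_cm Organ distances from the isocenter (cm); vectorized.
#' @return A tibble with one row per input distance: `distance_cm`,
#'   `bin_distance_cm` (the representative distance used), `h10_per_gray`,
#'   `sd_per_gray`.
#' @export
assign_distance_bin <- function(rule, measurements, distance_cm) {
  measurements <- as_measurement_set(measurements)
  policy <- attr(rule, "out_of_range", exact = TRUE) %||% "clamp"
  missing_rep <- setdiff(rule$representative_cm, measurements$distance_cm)
  if (length(missing_rep) > 0L) {
    abort_validation(sprintf(
      "no measurement point at representative distance %g cm", missing_rep[[1L]]))
  }
  if (any(!is.finite(distance_cm))) abort_validation("distance_cm must be finite")
  if (any(distance_cm < rule$lower_cm[[1L]])) {
    abort_validation(sprintf(
      "distance %g cm is inside the treatment field margin (< %g cm); the bin model does not apply",
      min(distance_cm), rule$lower_cm[[1L]]))
  }
  beyond <- distance_cm > rule$upper_cm[[nrow(rule)]]
  if (any(beyond) && policy == "error") {
    abort_validation(sprintf(
      "distance %g cm is beyond the last bin (> %g cm)",
      max(distance_cm), rule$upper_cm[[nrow(rule)]]))
  }
  rep_cm <- vapply(distance_cm, function(d) {
    if (d > rule$upper_cm[[nrow(rule)]]) return(rule$representative_cm[[nrow(rule)]])
    idx <- which(d >= rule$lower_cm & d <= rule$upper_cm)[[1L]]
    rule$representative_cm[[idx]]
  }, numeric(1))
  i <- match(rep_cm, measurements$distance_cm)
  tibble::tibble(
    distance_cm = as.numeric(distance_cm),
    bin_distance_cm = rep_cm,
    h10_per_gray = measurements$h10_per_gray[i],
    sd_per_gray = measurements$sd_per_gray[i]
  )
}

# ---- Depth classes ----------------------------------------------------------

depth_class_levels <- c("surface", "middle", "deep", "unclassified")

#' Classify organ depth
#'
#' Surface: 0-5 cm (inclusive); middle: (5, 10\] cm; deep: (10, 15\] cm;
#' anything deeper is `unclassified`.
#'
#' @param depth_cm Depths (cm, >= 0); vectorized.
#' @return A factor with levels surface, middle, deep, unclassified.
#' @export
classify_depth <- function(depth_cm) {
  if (any(!is.finite(depth_cm) | depth_cm < 0)) {
    abort_validation("depth_cm must be >= 0")
  }
  cls <- cut(depth_cm, breaks = c(0, 5, 10, 15, Inf),
             labels = depth_class_levels,
             include.lowest = TRUE, right = TRUE)
  factor(as.character(cls), levels = depth_class_levels)
}

# ---- Organ equivalent dose --------------------------------------------------

#' Neutron equivalent dose per organ
#'
#' Core dosimetry step: each organ's dose per photon gray is the measured
#' H*(10) of its distance bin times the depth correction factor at the
#' organ's depth,
#' \deqn{H_T/\mathrm{Gy} = H^*(10)(\mathrm{bin}) \times
#'       D_n(\mathrm{depth}) / D_n(\mathrm{reference\ depth}),}
#' and the course total is that value times the prescribed dose.
#'
#' In `rounding = "reported"` the per-gray dose is rounded to two decimals
#' (half-even) *before* the course multiplication, which is how the
#' reference campaign's published per-course totals were tabulated; the
#' default `"precise"` applies no intermediate rounding.  The one-sigma
#' uncertainty scales the total by the relative standard deviation of the
#' bin's measurement.
#'
#' @param organs An [organ_geometry()] table (data frame first, pipe
#'   friendly).
#' @param measurements A [measurement_set()].
#' @param curve A [depth_dose_curve()].
#' @param prescription A [treatment_prescription()].
#' @param bin_rule A [distance_bin_rule()]; defaults to [default_bin_rule()].
#' @param scheme Interpolation scheme, `"linear"` (default) or
#'   `"log-linear"`.
#' @param rounding `"precise"` (default) or `"reported"`.
#' @return An `organ_dose_tbl` tibble with columns `organ_name`,
#'   `distance_cm`, `depth_cm`, `depth_class`, `bin_distance_cm`,
#'   `depth_factor`, `per_gray` (mSv/Gy), `total_mSv`, `sd_mSv`.
#' @examples
#' ref <- reference_tables()
#' organ_equivalent_dose(ref$organ_geometry, ref$measurements,
#'                       ref$depth_dose, ref$prescription,
#'                       rounding = "reported")
#' @export
organ_equivalent_dose <- function(organs, measurements, curve, prescription,
                                  bin_rule = default_bin_rule(),
                                  scheme = c("linear", "log-linear"),
                                  rounding = c("precise", "reported")) {
  scheme <- rlang::arg_match(scheme)
  rounding <- rlang::arg_match(rounding)
  organs <- as_organ_geometry(organs)
  if (!inherits(prescription, "treatment_prescription")) {
    prescription <- treatment_prescription(prescription)
  }
  bins <- assign_distance_bin(bin_rule, measurements, organs$distance_cm)
  depth_factor <- depth_correction_factor(curve, organs$depth_cm, scheme)
  per_gray <- bins$h10_per_gray * depth_factor
  if (rounding == "reported") per_gray <- round(per_gray, 2L)
  total <- per_gray * prescription$prescribed_dose_gray
  rel_sd <- bins$sd_per_gray / bins$h10_per_gray
  out <- tibble::tibble(
    organ_name = organs$organ_name,
    distance_cm = organs$distance_cm,
    depth_cm = organs$depth_cm,
    depth_class = classify_depth(organs$depth_cm),
    bin_distance_cm = bins$bin_distance_cm,
    depth_factor = depth_factor,
    per_gray = per_gray,
    total_mSv = total,
    sd_mSv = total * rel_sd
  )
  new_subclass_tbl(out, class = "organ_dose_tbl")
}

#' Mean per-gray dose by depth class
#'
#' Arithmetic mean of the per-gray equivalent dose over the organs in each
#' depth class.  Organs deeper than the deepest class are excluded from the
#' three named classes and reported on their own `unclassified` row.
#'
#' @param doses An `organ_dose_tbl` (e.g. from [organ_equivalent_dose()]).
#' @return A tibble with columns `depth_class`, `mean_per_gray`, `n_organs`.
#' @export
depth_class_means <- function(doses) {
  check_columns(doses, c("depth_class", "per_gray"), "organ dose table")
  if (nrow(doses) == 0L) abort_validation("organ dose table is empty")
  doses |>
    dplyr::mutate(depth_class = factor(as.character(.data$depth_class),
                                       levels = depth_class_levels)) |>
    dplyr::group_by(.data$depth_class) |>
    dplyr::summarise(mean_per_gray = mean(.data$per_gray),
                     n_organs = dplyr::n(), .groups = "drop")
}
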