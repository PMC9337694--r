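# Synthetic measurement campaigns, depth-dose curves and organ tables with
# known ground truth.

#' Specify a synthetic measurement campaign
#'
#' The noiseless distance profile is exponential-plus-floor,
#' \deqn{h(d) = \mathrm{floor} + (h_0 - \mathrm{floor}) e^{-d/L},}
#' which reproduces the observed rapid-then-smooth decay of out-of-field
#' H*(10) with two interpretable parameters.  Measurement noise is
#' multiplicative Gaussian with coefficient of variation `noise_cv`,
#' truncated at zero; each reported point is the mean of `replicates`
#' draws.  The defaults emulate the reference campaign: 1.30 mSv/Gy at the
#' isocenter decaying toward a 0.55 mSv/Gy far-field floor with an 11 cm
#' decay length, sampled at 0, 20 and 60 cm with three replicates and 5%
#' noise.
#'
#' @param h0 H*(10) at the isocenter (mSv/Gy).
#' @param floor Asymptotic far-field level (mSv/Gy); `h0 > floor >= 0`.
#' @param decay_length_cm Exponential decay scale (cm, > 0).
#' @param noise_cv Coefficient of variation of measurement noise (>= 0).
#' @param distances_cm Sampling distances (cm).
#' @param replicates Repeats per distance (>= 1).
#' @param seed Random seed (integer).
#' @return A `campaign_spec` list.
#' @export
campaign_spec <- function(h0 = 1.30, floor = 0.55, decay_length_cm = 11,
                          noise_cv = 0.05, distances_cm = c(0, 20, 60),
                          replicates = 3L, seed = 1L) {
  if (!is.numeric(h0) || !is.numeric(floor) || h0 <= floor || floor < 0) {
    abort_validation("need h0 > floor >= 0")
  }
  if (!is.numeric(decay_length_cm) || decay_length_cm <= 0) {
    abort_validation("decay_length_cm must be > 0")
  }
  if (!is.numeric(noise_cv) || noise_cv < 0) {
    abort_validation("noise_cv must be >= 0")
  }
  if (length(distances_cm) < 2L || any(distances_cm < 0) ||
      anyDuplicated(distances_cm) > 0L) {
    abort_validation("distances_cm must be >= 2 distinct non-negative distances")
  }
  if (!is.numeric(replicates) || replicates < 1L) {
    abort_validation("replicates must be >= 1")
  }
  structure(
    list(h0 = h0, floor = floor, decay_length_cm = decay_length_cm,
         noise_cv = noise_cv, distances_cm = sort(as.numeric(distances_cm)),
         replicates = as.integer(replicates), seed = as.integer(seed)),
    class = "campaign_spec"
  )
}

#' Noiseless distance profile of a campaign spec
#'
#' @param spec A [campaign_spec()].
#' @param distance_cm Distances (cm); defaults to the spec's sampling
#'   distances.
#' @return True H*(10) values (mSv/Gy).
#' @export
true_profile <- function(spec, distance_cm = spec$distances_cm) {
  spec$floor + (spec$h0 - spec$floor) * exp(-distance_cm / spec$decay_length_cm)
}

# Normal(mean, cv*mean) draws truncated at zero, by rejection.
rtruncnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

#' Generate a synthetic measurement campaign
#'
#' Each point's reported H*(10) is the mean of the replicate draws; its
#' reported dispersion is the population (divide-by-n) standard deviation
#' of the replicates about their mean, the plug-in estimate of the draw
#' sigma.  Fully deterministic under the spec's seed; the caller's RNG
#' state is left untouched.
#'
#' @param spec A [campaign_spec()].
#' @return A list with `measurements` (a [measurement_set()]) and `truth`
#'   (tibble of `distance_cm`, `h10_true` plus the spec as attribute).
#' @export
generate_campaign <- function(spec) {
  if (!inherits(spec, "campaign_spec")) abort_validation("spec must be a campaign_spec")
  mu <- true_profile(spec)
  draws <- withr::with_seed(spec$seed, {
    lapply(mu, function(m) {
      if (spec$noise_cv == 0) rep(m, spec$replicates)
      else rtruncnorm_pos(spec$replicates, m, spec$noise_cv * m)
    })
  })
  h10 <- vapply(draws, mean, numeric(1))
  sdv <- vapply(draws, function(x) sqrt(mean((x - mean(x))^2)), numeric(1))
  truth <- tibble::tibble(distance_cm = spec$distances_cm, h10_true = mu)
  attr(truth, "spec") <- spec
  list(
    measurements = measurement_set(spec$distances_cm, h10, sdv),
    truth = truth
  )
}

#' Generate an exponential depth-dose curve
#'
#' dose_density(z) = amplitude * exp(-mu * z) sampled on the grid; the
#' exact depth correction factor of such a curve is
#' exp(-mu * (z - reference depth)), which makes it the natural ground
#' truth for interpolation tests.
#'
#' @param mu_per_cm Attenuation coefficient (1/cm, > 0).
#' @param amplitude Dose density at zero depth (> 0).
#' @param depth_cm Depth grid (cm); defaults to the 1-16 cm reference grid.
#' @param reference_depth_cm Reference depth (cm).
#' @return A [depth_dose_curve()].
#' @export
generate_depth_dose_curve <- function(mu_per_cm, amplitude = 25,
                                      depth_cm = c(1:6, seq(8, 16, by = 2)),
                                      reference_depth_cm = 1.0) {
  if (!is.numeric(mu_per_cm) || mu_per_cm <= 0) {
    abort_validation("mu_per_cm must be > 0")
  }
  if (!is.numeric(amplitude) || amplitude <= 0) {
    abort_validation("amplitude must be > 0")
  }
  depth_dose_curve(depth_cm, amplitude * exp(-mu_per_cm * depth_cm),
                   reference_depth_cm = reference_depth_cm)
}

#' Generate a random organ geometry table
#'
#' Uniformly sampled distances and depths with unique synthetic names;
#' seed-deterministic.
#'
#' @param n_organs Number of organs (>= 1).
#' @param distance_range,depth_range Sampling ranges (cm); defaults cover
#'   the reference phantom extremes.
#' @param seed Random seed.
#' @return An [organ_geometry()] table.
#' @export
generate_organ_table <- function(n_organs, distance_range = c(5, 83.88),
                                 depth_range = c(1, 16), seed = 1L) {
  if (!is.numeric(n_organs) || n_organs < 1L) {
    abort_validation("n_organs must be >= 1")
  }
  if (distance_range[1] < 0 || diff(distance_range) < 0 ||
      depth_range[1] < 0 || diff(depth_range) < 0) {
    abort_validation("ranges must be non-negative and ordered")
  }
  withr::with_seed(as.integer(seed), {
    organ_geometry(
      organ_name = sprintf("organ_%02d", seq_len(n_organs)),
      distance_cm = stats::runif(n_organs, distance_range[1], distance_range[2]),
      depth_cm = stats::runif(n_organs, depth_range[1], depth_range[2])
    )
  })
}

#' Exact organ doses under the noiseless profile
#'
#' Evaluates the pipeline dose formula on the noiseless campaign profile:
#' the ground truth against which estimates from noisy campaigns are
#' compared.
#'
#' @param spec A [campaign_spec()].
#' @param curve A [depth_dose_curve()].
#' @param organs An [organ_geometry()] table.
#' @param prescription A [treatment_prescription()].
#' @inheritParams organ_equivalent_dose
#' @return An `organ_dose_tbl` of exact doses (zero sd).
#' @export
synthetic_truth_doses <- function(spec, curve, organs, prescription,
                                  bin_rule = default_bin_rule(),
                                  scheme = "linear") {
  truth_ms <- measurement_set(spec$distances_cm,
                              true_profile(spec),
                              rep(0, length(spec$distances_cm)))
  organ_equivalent_dose(organs, truth_ms, curve, prescription,
                        bin_rule = bin_rule, scheme = scheme,
                        rounding = "precise")
}
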