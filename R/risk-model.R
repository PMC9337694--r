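# Risk model: effective dose, secondary-cancer risk, genetic effects,
# first-order uncertainty propagation.

resolve_named <- function(doses, coefficients) {
  parts <- partition_remainder(doses, coefficients)
  tw <- coefficients$tissue_weights
  i <- match(canonical_organ(tw$organ_name), canonical_organ(parts$named$organ_name))
  if (anyNA(i)) {
    abort_validation(sprintf(
      "no dose available for named organ %s",
      tw$organ_name[[which(is.na(i))[[1L]]]]))
  }
  list(
    named = tibble::tibble(
      organ_name = tw$organ_name,
      total_mSv = parts$named$total_mSv[i],
      sd_mSv = if ("sd_mSv" %in% names(parts$named)) parts$named$sd_mSv[i] else 0,
      bin_distance_cm = if ("bin_distance_cm" %in% names(parts$named))
        parts$named$bin_distance_cm[i] else NA_real_,
      w_t = tw$w_t,
      risk_coefficient = tw$risk_coefficient
    ),
    remainder = parts$remainder
  )
}

#' Effective dose from per-organ neutron equivalent doses
#'
#' Implements \eqn{E = \sum_T W_T H_T}: each organ with an individual
#' tissue weighting factor contributes \eqn{W_T \times H_T}; the remainder
#' organs contribute as one compartment whose dose is, by default, the
#' arithmetic *mean* of the remainder-organ doses, weighted by the shared
#' remainder W_T.
#'
#' @param doses An organ dose table (columns `organ_name`, `total_mSv`, and
#'   optionally `sd_mSv`, `bin_distance_cm`).
#' @param coefficients A [dose_coefficients()] object.
#' @param remainder_rule How the remainder compartment collapses its organ
#'   doses: `"mean"` (default) or `"sum"`.
#' @return An `effective_dose` object with elements `effective_dose_mSv`,
#'   `contributions` (tibble: `compartment`, `h_t_mSv`, `w_t`,
#'   `contribution_mSv`, `share_pct`), `remainder_organs`, and the rule
#'   used.  Supports [generics::tidy()] and [generics::glance()].
#' @examples
#' ref <- reference_tables()
#' doses <- ref$organ_geometry |>
#'   organ_equivalent_dose(ref$measurements, ref$depth_dose, ref$prescription)
#' doses <- dplyr::bind_rows(
#'   doses,
#'   skin_dose(ref$measurements, ref$prescription),
#'   red_marrow_dose(doses, ref$coefficients),
#'   bone_surface_dose(doses))
#' effective_dose(doses, ref$coefficients)
#' @export
effective_dose <- function(doses, coefficients,
                           remainder_rule = c("mean", "sum")) {
  remainder_rule <- rlang::arg_match(remainder_rule)
  parts <- resolve_named(doses, coefficients)
  rem <- parts$remainder
  rem_dose <- if (nrow(rem) == 0L) 0
  else switch(remainder_rule, mean = mean(rem$total_mSv), sum = sum(rem$total_mSv))
  contrib <- tibble::tibble(
    compartment = c(parts$named$organ_name, "Remainder"),
    h_t_mSv = c(parts$named$total_mSv, rem_dose),
    w_t = c(parts$named$w_t, coefficients$remainder_w_t)
  )
  contrib$contribution_mSv <- contrib$h_t_mSv * contrib$w_t
  total <- sum(contrib$contribution_mSv)
  contrib$share_pct <- if (total > 0) 100 * contrib$contribution_mSv / total else 0
  structure(
    list(effective_dose_mSv = total,
         contributions = contrib,
         remainder_organs = rem$organ_name,
         remainder_rule = remainder_rule),
    class = "effective_dose"
  )
}

#' @export
print.effective_dose <- function(x, ...) {
  cat(sprintf("Neutron effective dose: %.2f mSv (%d named organs + %d remainder, remainder rule: %s)\n",
              x$effective_dose_mSv,
              nrow(x$contributions) - 1L, length(x$remainder_organs),
              x$remainder_rule))
  top <- dplyr::arrange(x$contributions, dplyr::desc(.data$contribution_mSv))
  top <- utils::head(top, 4L)
  cat(sprintf("  leading contributions: %s\n",
              paste(sprintf("%s %.2f mSv (%.0f%%)", top$compartment,
                            top$contribution_mSv, top$share_pct),
                    collapse = ", ")))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an effective-dose result
#' @param x An `effective_dose` object.
#' @param ... Unused.
#' @return The contributions tibble.
#' @method tidy effective_dose
#' @export
tidy.effective_dose <- function(x, ...) x$contributions

#' @rdname tidy.effective_dose
#' @method glance effective_dose
#' @export
glance.effective_dose <- function(x, ...) {
  tibble::tibble(effective_dose_mSv = x$effective_dose_mSv,
                 n_named = nrow(x$contributions) - 1L,
                 n_remainder = length(x$remainder_organs),
                 remainder_rule = x$remainder_rule)
}

#' Expected fatal-cancer cases for one organ
#'
#' cases = (H_T in Sv) x (coefficient x 1e-2 per Sv) x population.
#'
#' @param dose_mSv Organ equivalent dose (mSv, >= 0); vectorized.
#' @param coefficient Risk coefficient in units of 1e-2 per Sv (>= 0).
#' @param population Reference population size (default 1e6 persons).
#' @return Expected cases in `population` persons.
#' @examples
#' organ_cancer_risk(37.2, 0.20)  # 74.4 cases per million
#' @export
organ_cancer_risk <- function(dose_mSv, coefficient, population = 1e6) {
  if (any(!is.finite(dose_mSv) | dose_mSv < 0)) {
    abort_validation("dose_mSv must be >= 0")
  }
  if (any(!is.finite(coefficient) | coefficient < 0)) {
    abort_validation("coefficient must be >= 0")
  }
  if (any(!is.finite(population) | population < 0)) {
    abort_validation("population must be >= 0")
  }
  (dose_mSv / 1000) * (coefficient * 1e-2) * population
}

#' Total secondary-cancer risk
#'
#' Named organs use their own risk coefficients; the remainder compartment
#' applies the shared remainder coefficient to, by default, the *sum* of
#' the remainder-organ doses.  (Note the deliberate asymmetry with
#' [effective_dose()], whose remainder uses the mean; both defaults follow
#' the reference campaign's aggregation and both are overridable.)
#'
#' @inheritParams effective_dose
#' @param remainder_rule `"sum"` (default) or `"mean"`.
#' @param population Reference population (default 1e6 persons).
#' @return A `risk_result` object with `per_organ` (tibble: `compartment`,
#'   `h_t_mSv`, `risk_coefficient`, `cases_per_million`),
#'   `total_cases_per_million`, and `population`.  Supports `tidy()` and
#'   `glance()`.
#' @export
total_cancer_risk <- function(doses, coefficients,
                              remainder_rule = c("sum", "mean"),
                              population = 1e6) {
  remainder_rule <- rlang::arg_match(remainder_rule)
  parts <- resolve_named(doses, coefficients)
  rem <- parts$remainder
  rem_dose <- if (nrow(rem) == 0L) 0
  else switch(remainder_rule, mean = mean(rem$total_mSv), sum = sum(rem$total_mSv))
  per_organ <- tibble::tibble(
    compartment = c(parts$named$organ_name, "Remainder"),
    h_t_mSv = c(parts$named$total_mSv, rem_dose),
    risk_coefficient = c(parts$named$risk_coefficient,
                         coefficients$remainder_risk_coefficient)
  )
  per_organ$cases_per_million <- organ_cancer_risk(
    per_organ$h_t_mSv, per_organ$risk_coefficient, population
  ) * 1e6 / population
  cases <- organ_cancer_risk(per_organ$h_t_mSv, per_organ$risk_coefficient,
                             population)
  structure(
    list(per_organ = dplyr::mutate(per_organ, cases = cases),
         total_cases_per_million = sum(per_organ$cases_per_million),
         total_cases = sum(cases),
         population = population,
         remainder_rule = remainder_rule),
    class = "risk_result"
  )
}

#' @export
print.risk_result <- function(x, ...) {
  cat(sprintf("Secondary-cancer risk: %.2f cases per 1 million persons (population %g)\n",
              x$total_cases_per_million, x$population))
  top <- dplyr::arrange(x$per_organ, dplyr::desc(.data$cases_per_million))
  top <- utils::head(top, 4L)
  cat(sprintf("  leading organs: %s\n",
              paste(sprintf("%s %.2f", top$compartment, top$cases_per_million),
                    collapse = ", ")))
  invisible(x)
}

#' Tidy a risk result
#' @param x A `risk_result` object.
#' @param ... Unused.
#' @return The per-organ risk tibble.
#' @method tidy risk_result
#' @export
tidy.risk_result <- function(x, ...) x$per_organ

#' @rdname tidy.risk_result
#' @method glance risk_result
#' @export
glance.risk_result <- function(x, ...) {
  tibble::tibble(total_cases_per_million = x$total_cases_per_million,
                 population = x$population,
                 remainder_rule = x$remainder_rule)
}

#' Expected genetic-effects cases from the gonad dose
#'
#' cases = (gonad dose in Sv) x (genetic coefficient x 1e-2 per Sv) x
#' population.
#'
#' @param gonad_dose_mSv Gonad equivalent dose (mSv, >= 0).
#' @param genetic_coefficient Genetic-effects coefficient (1e-2 per Sv,
#'   default 1.00).
#' @param population Reference population (default 1e6 persons).
#' @return Expected cases.
#' @examples
#' genetic_effects(34.8)  # 348 cases per million
#' @export
genetic_effects <- function(gonad_dose_mSv, genetic_coefficient = 1.00,
                            population = 1e6) {
  organ_cancer_risk(gonad_dose_mSv, genetic_coefficient, population)
}

#' First-order uncertainty propagation for the aggregates
#'
#' Propagates the per-organ one-sigma dose uncertainties into the effective
#' dose and total cancer risk.  Correlation model: doses derived from the
#' same measurement bin are fully correlated (their weighted sds add
#' linearly), doses from different bins — or with no bin provenance — are
#' independent (added in quadrature).  Coefficient uncertainties are taken
#' as zero.
#'
#' @inheritParams effective_dose
#' @param remainder_rule_effective,remainder_rule_risk Remainder collapse
#'   rules matching those used in the point estimates.
#' @param population Reference population for the risk sd.
#' @return A list with `effective_dose_sd_mSv` and
#'   `total_risk_sd_per_million`.
#' @export
propagate_uncertainty <- function(doses, coefficients,
                                  remainder_rule_effective = "mean",
                                  remainder_rule_risk = "sum",
                                  population = 1e6) {
  check_columns(doses, c("organ_name", "total_mSv", "sd_mSv"), "organ dose table")
  if (any(!is.finite(doses$sd_mSv) | doses$sd_mSv < 0)) {
    abort_validation("sd_mSv must be >= 0")
  }
  parts <- resolve_named(doses, coefficients)
  rem <- parts$remainder
  n_rem <- nrow(rem)
  rem_sd <- if ("sd_mSv" %in% names(rem)) rem$sd_mSv else rep(0, n_rem)
  rem_bin <- if ("bin_distance_cm" %in% names(rem)) rem$bin_distance_cm
             else rep(NA_real_, n_rem)

  # effective dose: named organs weighted by W_T, each remainder organ by
  # remainder_w_t / n (mean rule) or remainder_w_t (sum rule)
  rem_w_eff <- if (n_rem == 0L) numeric(0)
  else rep(coefficients$remainder_w_t /
             if (remainder_rule_effective == "mean") n_rem else 1, n_rem)
  sd_eff <- combine_sd(
    c(parts$named$w_t, rem_w_eff),
    c(parts$named$sd_mSv, rem_sd),
    c(parts$named$bin_distance_cm, rem_bin)
  )

  # risk, in cases: weight per mSv of organ dose
  risk_w <- function(coef) (coef * 1e-2) / 1000 * population
  rem_w_risk <- if (n_rem == 0L) numeric(0)
  else rep(risk_w(coefficients$remainder_risk_coefficient) /
             if (remainder_rule_risk == "mean") n_rem else 1, n_rem)
  sd_risk <- combine_sd(
    c(risk_w(parts$named$risk_coefficient), rem_w_risk),
    c(parts$named$sd_mSv, rem_sd),
    c(parts$named$bin_distance_cm, rem_bin)
  )

  list(effective_dose_sd_mSv = sd_eff,
       total_risk_sd_per_million = sd_risk * 1e6 / population)
}
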