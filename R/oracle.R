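# Independent brute-force reimplementation of the whole dose/risk
# arithmetic, used only as an equivalence oracle in tests.  Deliberately
# written in plain base R with its own interpolation, binning, rounding and
# aggregation code paths: nothing here is shared with the main modules.

#' Brute-force oracle pipeline
#'
#' Recomputes every pipeline output (per-organ doses including skin, red
#' bone marrow and bone surface, effective dose, per-organ and total
#' cancer risk, genetic effects) by direct arithmetic on plain vectors.
#' Its only purpose is dual-route verification of the main implementation;
#' it deliberately duplicates the maths rather than calling it.
#'
#' @param measurements Data frame with `distance_cm`, `h10_per_gray`,
#'   `sd_per_gray`.
#' @param curve Data frame with `depth_cm`, `dose_density`; reference depth
#'   taken from its attribute or 1 cm.
#' @param organs Data frame with `organ_name`, `distance_cm`, `depth_cm`.
#' @param coefficients A [dose_coefficients()] object.
#' @param prescription A [treatment_prescription()] or a number (Gy).
#' @param bin_lower,bin_upper,bin_representative Bin rule vectors (cm).
#' @param scheme `"linear"` or `"log-linear"`.
#' @param rounding `"precise"` or `"reported"`.
#' @param marrow_normalization `"as-printed"` or `"renormalized"`.
#' @param population Reference population.
#' @return A list: `organ_doses` (data.frame `organ_name`, `per_gray`,
#'   `total_mSv`), `effective_dose_mSv`, `per_organ_risk` (named vector),
#'   `total_risk_per_million`, `genetic_per_million`.
#' @export
oracle_pipeline <- function(measurements, curve, organs, coefficients,
                            prescription,
                            bin_lower = c(5, 40), bin_upper = c(40, 80),
                            bin_representative = c(20, 60),
                            scheme = "linear", rounding = "precise",
                            marrow_normalization = "as-printed",
                            population = 1e6) {
  dose_gy <- if (is.list(prescription)) prescription$prescribed_dose_gray
             else as.numeric(prescription)
  ref_depth <- attr(curve, "reference_depth_cm", exact = TRUE)
  if (is.null(ref_depth)) ref_depth <- 1.0
  gd <- curve$depth_cm
  gv <- curve$dose_density

  interp <- function(z) {
    if (z < gd[1]) stop("oracle: depth below grid")
    if (z > gd[length(gd)]) z <- gd[length(gd)]
    k <- length(gd)
    for (i in seq_len(length(gd) - 1)) {
      if (z <= gd[i + 1]) { k <- i; break }
    }
    if (z == gd[k]) return(gv[k])
    t <- (z - gd[k]) / (gd[k + 1] - gd[k])
    if (scheme == "linear") {
      gv[k] + t * (gv[k + 1] - gv[k])
    } else {
      gv[k] * (gv[k + 1] / gv[k])^t
    }
  }

  pick_h10 <- function(d) {
    nb <- length(bin_lower)
    if (d < bin_lower[1]) stop("oracle: distance inside field margin")
    rep_cm <- bin_representative[nb]
    for (i in seq_len(nb)) {
      if (d >= bin_lower[i] && d <= bin_upper[i]) { rep_cm <- bin_representative[i]; break }
    }
    measurements$h10_per_gray[measurements$distance_cm == rep_cm]
  }

  f_ref <- interp(ref_depth)
  n <- nrow(organs)
  per_gray <- numeric(n)
  for (i in seq_len(n)) {
    pg <- pick_h10(organs$distance_cm[i]) * interp(organs$depth_cm[i]) / f_ref
    per_gray[i] <- if (rounding == "reported") round(pg, 2) else pg
  }
  total <- per_gray * dose_gy
  names(total) <- organs$organ_name
  key <- tolower(trimws(organs$organ_name))
  names(per_gray) <- key
  tot <- total
  names(tot) <- key

  # skin: mean of the representative-point measurements, no depth correction
  h_rep <- vapply(bin_representative, function(r)
    measurements$h10_per_gray[measurements$distance_cm == r], numeric(1))
  skin_total <- mean(h_rep) * dose_gy

  # marrow and bone surface from surrogate organs, when all surrogates exist
  sur <- c(head = "brain", `upper limb-girdle` = "breast", sternum = "heart",
           ribs = "heart", vertebrae = "cord", sacrum = "femoral head",
           `lower girdle` = "femoral head")
  all_tot <- c(tot, skin = skin_total)
  all_names <- c(organs$organ_name, "Skin")
  if (all(unname(sur) %in% key)) {
    md <- coefficients$marrow_distribution
    w <- md$fraction
    if (marrow_normalization == "renormalized") w <- w / sum(w)
    marrow_total <- 0
    for (i in seq_along(w)) {
      marrow_total <- marrow_total + w[i] * tot[[sur[[md$region[i]]]]]
    }
    bs_regions <- c("upper limb-girdle", "sternum", "ribs", "vertebrae",
                    "sacrum", "lower girdle")
    bs_total <- 0
    for (r in bs_regions) bs_total <- bs_total + tot[[sur[[r]]]]
    bs_total <- bs_total / length(bs_regions)
    all_tot <- c(all_tot, `bone marrow` = marrow_total, `bone surface` = bs_total)
    all_names <- c(all_names, "Bone marrow", "Bone surface")
  }

  tw <- coefficients$tissue_weights
  named_key <- tolower(trimws(tw$organ_name))
  if (all(named_key %in% names(all_tot))) {
    rem_key <- setdiff(names(all_tot), named_key)
    e <- 0
    for (i in seq_along(named_key)) e <- e + tw$w_t[i] * all_tot[[named_key[i]]]
    rem_doses <- unlist(all_tot[rem_key], use.names = FALSE)
    e <- e + coefficients$remainder_w_t * mean(rem_doses)

    risk <- numeric(length(named_key))
    for (i in seq_along(named_key)) {
      risk[i] <- all_tot[[named_key[i]]] / 1000 * tw$risk_coefficient[i] * 1e-2 * population
    }
    names(risk) <- tw$organ_name
    rem_risk <- sum(rem_doses) / 1000 * coefficients$remainder_risk_coefficient *
      1e-2 * population
    risk <- c(risk, Remainder = rem_risk)
    total_risk <- sum(risk)
  } else {
    # aggregates are undefined when a named-W_T organ is missing a dose
    e <- NA_real_
    risk <- NA_real_
    total_risk <- NA_real_
  }

  genetic <- if ("gonads" %in% names(all_tot)) {
    all_tot[["gonads"]] / 1000 * coefficients$genetic_coefficient *
      1e-2 * population
  } else NA_real_

  pg_extra <- c(mean(h_rep), rep(NA_real_, length(all_names) - n - 1L))
  list(
    organ_doses = data.frame(
      organ_name = all_names,
      per_gray = c(unname(per_gray), pg_extra),
      total_mSv = unname(unlist(all_tot)),
      stringsAsFactors = FALSE
    ),
    effective_dose_mSv = e,
    per_organ_risk = risk * 1e6 / population,
    total_risk_per_million = total_risk * 1e6 / population,
    genetic_per_million = genetic * 1e6 / population
  )
}
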