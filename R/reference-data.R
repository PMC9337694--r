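# Typed reference tables: measurement sets, depth-dose curves, organ
# geometry, dose/risk coefficients, treatment prescriptions.

abort_validation <- function(msg, ...) {
  rlang::abort(msg, class = "neutrondose_validation_error", ...)
}

abort_schema <- function(msg, ...) {
  rlang::abort(msg, class = "neutrondose_schema_error", ...)
}

#' Canonicalize organ names
#'
#' Organ names are matched case-insensitively after trimming and collapsing
#' internal whitespace, so `"Femoral head"`, `" femoral  HEAD "` and
#' `"femoral head"` refer to the same organ.
#'
#' @param x Character vector of organ names.
#' @return Canonical (lower-case, squished) names.
#' @export
canonical_organ <- function(x) {
  tolower(gsub("\\s+", " ", trimws(as.character(x))))
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort_schema(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1L) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

new_subclass_tbl <- function(df, class) {
  tibble::new_tibble(df, class = class)
}

# ---- MeasurementSet ---------------------------------------------------------

#' Construct a measurement set of H*(10) values
#'
#' A measurement set holds neutron ambient dose equivalent readings at the
#' patient table, normalized per gray of photon dose delivered at the
#' isocenter, indexed by horizontal distance from the isocenter.
#'
#' @param distance_cm Horizontal distances from the isocenter (cm, >= 0).
#' @param h10_per_gray H*(10) per delivered photon gray (mSv/Gy, > 0).
#' @param sd_per_gray One-standard-deviation uncertainties (mSv/Gy, >= 0).
#' @param normalization_note Free-text note recording the normalization.
#' @return A `measurement_set` tibble sorted by distance.
#' @examples
#' measurement_set(c(0, 20, 60), c(1.30, 0.71, 0.58), c(0.14, 0.12, 0.10))
#' @export
measurement_set <- function(distance_cm, h10_per_gray, sd_per_gray,
                            normalization_note = "per Gy of photon dose at isocenter") {
  as_measurement_set(
    tibble::tibble(
      distance_cm = as.numeric(distance_cm),
      h10_per_gray = as.numeric(h10_per_gray),
      sd_per_gray = as.numeric(sd_per_gray)
    ),
    normalization_note = normalization_note
  )
}

#' Validate a data frame as a measurement set
#'
#' @param df Data frame with columns `distance_cm`, `h10_per_gray`,
#'   `sd_per_gray`.
#' @inheritParams measurement_set
#' @return A validated `measurement_set` tibble sorted by distance.
#' @export
as_measurement_set <- function(df, normalization_note = "per Gy of photon dose at isocenter") {
  check_columns(df, c("distance_cm", "h10_per_gray", "sd_per_gray"),
                "measurement set")
  df <- tibble::as_tibble(df)[, c("distance_cm", "h10_per_gray", "sd_per_gray")]
  if (nrow(df) < 2L) {
    abort_validation(sprintf(
      "a measurement set needs at least two points, got %d", nrow(df)))
  }
  df <- dplyr::arrange(df, .data$distance_cm)
  bad <- which(!is.finite(df$distance_cm) | df$distance_cm < 0)
  if (length(bad) > 0L) {
    abort_validation(sprintf("row %d: distance_cm must be >= 0", bad[[1L]]))
  }
  bad <- which(!is.finite(df$h10_per_gray) | df$h10_per_gray <= 0)
  if (length(bad) > 0L) {
    abort_validation(sprintf(
      "row %d (distance %g cm): h10_per_gray must be > 0", bad[[1L]],
      df$distance_cm[[bad[[1L]]]]))
  }
  bad <- which(!is.finite(df$sd_per_gray) | df$sd_per_gray < 0)
  if (length(bad) > 0L) {
    abort_validation(sprintf(
      "row %d (distance %g cm): sd_per_gray must be >= 0", bad[[1L]],
      df$distance_cm[[bad[[1L]]]]))
  }
  if (anyDuplicated(df$distance_cm) > 0L) {
    abort_validation("distances must be strictly increasing (duplicate distance found)")
  }
  out <- new_subclass_tbl(df, class = "measurement_set")
  attr(out, "normalization_note") <- normalization_note
  out
}

#' Read / write a measurement set as CSV
#'
#' CSV schema: comma-separated, UTF-8, header row with columns
#' `distance_cm`, `h10_per_gray`, `sd_per_gray`, `"."` decimal separator.
#'
#' @param path File path.
#' @return `read_measurement_set()` returns a validated `measurement_set`;
#'   `write_measurement_set()` returns `path` invisibly.
#' @export
read_measurement_set <- function(path) {
  if (!file.exists(path)) abort_schema(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_measurement_set(df)
}

#' @rdname read_measurement_set
#' @param x A `measurement_set`.
#' @export
write_measurement_set <- function(x, path) {
  x <- as_measurement_set(x)
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

# ---- DepthDoseCurve ---------------------------------------------------------

#' Construct a neutron depth-dose curve
#'
#' Tabulated neutron absorbed dose density versus depth in tissue for a
#' fixed incident energy.  The curve is only ever used as a ratio (organ
#' depth over reference depth), so its absolute units cancel.
#'
#' @param depth_cm Strictly increasing grid of tissue depths (cm).
#' @param dose_density Absorbed dose per unit fluence at each depth
#'   (pGy cm^2, > 0).
#' @param reference_depth_cm Depth at which H*(10) is defined (cm); defaults
#'   to 1.0 cm, the 10 mm depth of the ICRU-sphere definition.  Must lie
#'   within the grid.
#' @return A `depth_dose_curve` tibble with a `reference_depth_cm` attribute.
#' @export
depth_dose_curve <- function(depth_cm, dose_density, reference_depth_cm = 1.0) {
  as_depth_dose_curve(
    tibble::tibble(depth_cm = as.numeric(depth_cm),
                   dose_density = as.numeric(dose_density)),
    reference_depth_cm = reference_depth_cm
  )
}

#' @rdname depth_dose_curve
#' @param df Data frame with columns `depth_cm`, `dose_density`.
#' @export
as_depth_dose_curve <- function(df, reference_depth_cm = 1.0) {
  check_columns(df, c("depth_cm", "dose_density"), "depth-dose curve")
  df <- tibble::as_tibble(df)[, c("depth_cm", "dose_density")]
  if (nrow(df) < 2L) {
    abort_validation("a depth-dose curve needs at least two grid points")
  }
  if (any(!is.finite(df$depth_cm))) abort_validation("depth_cm must be finite")
  if (any(diff(df$depth_cm) <= 0)) {
    abort_validation("depths must be strictly increasing")
  }
  bad <- which(!is.finite(df$dose_density) | df$dose_density <= 0)
  if (length(bad) > 0L) {
    abort_validation(sprintf(
      "row %d (depth %g cm): dose_density must be > 0", bad[[1L]],
      df$depth_cm[[bad[[1L]]]]))
  }
  if (!is.numeric(reference_depth_cm) || length(reference_depth_cm) != 1L ||
      reference_depth_cm < min(df$depth_cm) || reference_depth_cm > max(df$depth_cm)) {
    abort_validation(sprintf(
      "reference_depth_cm (%s) must lie within the depth grid [%g, %g]",
      format(reference_depth_cm), min(df$depth_cm), max(df$depth_cm)))
  }
  out <- new_subclass_tbl(df, class = "depth_dose_curve")
  attr(out, "reference_depth_cm") <- as.numeric(reference_depth_cm)
  out
}

#' Reference depth of a depth-dose curve
#' @param curve A `depth_dose_curve`.
#' @return The reference depth (cm).
#' @export
reference_depth <- function(curve) {
  ref <- attr(curve, "reference_depth_cm", exact = TRUE)
  if (is.null(ref)) 1.0 else ref
}

#' Read / write a depth-dose curve as CSV
#'
#' CSV schema: columns `depth_cm`, `dose_density`.
#'
#' @param path File path.
#' @param reference_depth_cm Reference depth passed to [as_depth_dose_curve()].
#' @return A validated `depth_dose_curve` (reading) or `path` (writing).
#' @export
read_depth_dose_curve <- function(path, reference_depth_cm = 1.0) {
  if (!file.exists(path)) abort_schema(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_depth_dose_curve(df, reference_depth_cm = reference_depth_cm)
}

#' @rdname read_depth_dose_curve
#' @param x A `depth_dose_curve`.
#' @export
write_depth_dose_curve <- function(x, path) {
  x <- as_depth_dose_curve(x, reference_depth_cm = reference_depth(x))
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

# ---- OrganGeometry ----------------------------------------------------------

#' Construct an organ geometry table
#'
#' Per-organ location of the organ center: horizontal distance from the
#' beam central axis and depth below the body surface.
#'
#' @param organ_name Organ identifiers (unique after canonicalization).
#' @param distance_cm Horizontal distance from the central axis (cm, >= 0).
#' @param depth_cm Depth below the body surface (cm, >= 0).
#' @return An `organ_geometry` tibble.
#' @export
organ_geometry <- function(organ_name, distance_cm, depth_cm) {
  as_organ_geometry(tibble::tibble(
    organ_name = as.character(organ_name),
    distance_cm = as.numeric(distance_cm),
    depth_cm = as.numeric(depth_cm)
  ))
}

#' @rdname organ_geometry
#' @param df Data frame with columns `organ_name`, `distance_cm`, `depth_cm`.
#' @export
as_organ_geometry <- function(df) {
  check_columns(df, c("organ_name", "distance_cm", "depth_cm"), "organ geometry table")
  df <- tibble::as_tibble(df)[, c("organ_name", "distance_cm", "depth_cm")]
  if (nrow(df) < 1L) abort_validation("organ geometry table is empty")
  df$organ_name <- gsub("\\s+", " ", trimws(df$organ_name))
  dup <- df$organ_name[duplicated(canonical_organ(df$organ_name))]
  if (length(dup) > 0L) {
    abort_validation(sprintf("duplicate organ name: %s", dup[[1L]]))
  }
  bad <- which(!is.finite(df$distance_cm) | df$distance_cm < 0)
  if (length(bad) > 0L) {
    abort_validation(sprintf("organ %s: distance_cm must be >= 0",
                             df$organ_name[[bad[[1L]]]]))
  }
  bad <- which(!is.finite(df$depth_cm) | df$depth_cm < 0)
  if (length(bad) > 0L) {
    abort_validation(sprintf("organ %s: depth_cm must be >= 0",
                             df$organ_name[[bad[[1L]]]]))
  }
  new_subclass_tbl(df, class = "organ_geometry")
}

#' Read / write an organ geometry table as CSV
#'
#' CSV schema: columns `organ_name`, `distance_cm`, `depth_cm`.
#'
#' @param path File path.
#' @return A validated `organ_geometry` (reading) or `path` (writing).
#' @export
read_organ_geometry <- function(path) {
  if (!file.exists(path)) abort_schema(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0L) abort_validation(sprintf("organ geometry file is empty: %s", path))
  as_organ_geometry(df)
}

#' @rdname read_organ_geometry
#' @param x An `organ_geometry`.
#' @export
write_organ_geometry <- function(x, path) {
  x <- as_organ_geometry(x)
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

# ---- DoseCoefficients -------------------------------------------------------

#' Construct a dose/risk coefficient table
#'
#' Bundles the NCRP-116 tissue weighting factors and fatal-cancer risk
#' coefficients for organs with an individual W_T, the shared weight and
#' risk coefficient of the remainder compartment, the gonad genetic-effects
#' coefficient, and the anatomical distribution of active red bone marrow
#' used by the composite-organ rules.
#'
#' @param tissue_weights Tibble with columns `organ_name`, `w_t`
#'   (dimensionless tissue weighting factor) and `risk_coefficient`
#'   (fatal-cancer risk, 1e-2 per Sv).
#' @param marrow_distribution Tibble with columns `region`, `fraction`
#'   (fraction of active red bone marrow in each skeletal region; each in
#'   \[0, 1\]).
#' @param remainder_w_t W_T applied to the remainder compartment.
#' @param remainder_risk_coefficient Risk coefficient of the remainder
#'   compartment (1e-2 per Sv).
#' @param genetic_coefficient Gonad genetic-effects coefficient (1e-2 per Sv).
#' @return A `dose_coefficients` object (a validated list).
#' @export
dose_coefficients <- function(tissue_weights, marrow_distribution,
                              remainder_w_t = 0.05,
                              remainder_risk_coefficient = 0.05,
                              genetic_coefficient = 1.00) {
  check_columns(tissue_weights, c("organ_name", "w_t", "risk_coefficient"),
                "tissue weight table")
  check_columns(marrow_distribution, c("region", "fraction"),
                "marrow distribution table")
  tw <- tibble::as_tibble(tissue_weights)[, c("organ_name", "w_t", "risk_coefficient")]
  tw$organ_name <- gsub("\\s+", " ", trimws(tw$organ_name))
  if (anyDuplicated(canonical_organ(tw$organ_name)) > 0L) {
    abort_validation("duplicate organ in tissue weight table")
  }
  if (any(!is.finite(tw$w_t) | tw$w_t < 0)) {
    abort_validation("tissue weighting factors must be >= 0")
  }
  if (any(!is.finite(tw$risk_coefficient) | tw$risk_coefficient < 0)) {
    abort_validation("risk coefficients must be >= 0")
  }
  md <- tibble::as_tibble(marrow_distribution)[, c("region", "fraction")]
  md$region <- canonical_organ(md$region)
  if (any(!is.finite(md$fraction) | md$fraction < 0 | md$fraction > 1)) {
    abort_validation("marrow distribution fractions must lie in [0, 1]")
  }
  scalars <- c(remainder_w_t, remainder_risk_coefficient, genetic_coefficient)
  if (any(!is.finite(scalars) | scalars < 0)) {
    abort_validation("coefficients must be finite and >= 0")
  }
  structure(
    list(
      tissue_weights = tw,
      marrow_distribution = md,
      remainder_w_t = remainder_w_t,
      remainder_risk_coefficient = remainder_risk_coefficient,
      genetic_coefficient = genetic_coefficient
    ),
    class = "dose_coefficients"
  )
}

#' Read a dose/risk coefficient set from CSV files
#'
#' @param tissue_path CSV with columns `organ_name`, `w_t`, `risk_coefficient`.
#' @param marrow_path CSV with columns `region`, `fraction`.
#' @inheritParams dose_coefficients
#' @return A `dose_coefficients` object.
#' @export
read_dose_coefficients <- function(tissue_path, marrow_path,
                                   remainder_w_t = 0.05,
                                   remainder_risk_coefficient = 0.05,
                                   genetic_coefficient = 1.00) {
  for (p in c(tissue_path, marrow_path)) {
    if (!file.exists(p)) abort_schema(sprintf("file not found: %s", p))
  }
  dose_coefficients(
    readr::read_csv(tissue_path, show_col_types = FALSE, progress = FALSE),
    readr::read_csv(marrow_path, show_col_types = FALSE, progress = FALSE),
    remainder_w_t = remainder_w_t,
    remainder_risk_coefficient = remainder_risk_coefficient,
    genetic_coefficient = genetic_coefficient
  )
}

#' Read an organ-dose override table
#'
#' Overrides replace computed per-organ total doses before the aggregation
#' stage (see [apply_dose_overrides()]).  CSV schema: `organ_name`,
#' `total_mSv`, `sd_mSv`.
#'
#' @param path File path.
#' @return A tibble with columns `organ_name`, `total_mSv`, `sd_mSv`.
#' @export
read_organ_dose_overrides <- function(path) {
  if (!file.exists(path)) abort_schema(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("organ_name", "total_mSv", "sd_mSv"), "organ dose override table")
  df <- tibble::as_tibble(df)[, c("organ_name", "total_mSv", "sd_mSv")]
  df$organ_name <- gsub("\\s+", " ", trimws(df$organ_name))
  if (any(!is.finite(df$total_mSv) | df$total_mSv < 0)) {
    abort_validation("override total_mSv must be >= 0")
  }
  df
}

# ---- TreatmentPrescription --------------------------------------------------

#' Construct a treatment prescription
#'
#' @param prescribed_dose_gray Total photon dose at the isocenter (Gy, > 0).
#' @param dose_per_fraction_gray Fraction size (Gy, > 0), optional.  When
#'   both are supplied the total must be an integer multiple of the
#'   fraction size.
#' @return A `treatment_prescription` list.
#' @export
treatment_prescription <- function(prescribed_dose_gray,
                                   dose_per_fraction_gray = NULL) {
  if (!is.numeric(prescribed_dose_gray) || length(prescribed_dose_gray) != 1L ||
      !is.finite(prescribed_dose_gray) || prescribed_dose_gray <= 0) {
    abort_validation("prescribed_dose_gray must be a single positive number")
  }
  if (!is.null(dose_per_fraction_gray)) {
    if (!is.numeric(dose_per_fraction_gray) || length(dose_per_fraction_gray) != 1L ||
        !is.finite(dose_per_fraction_gray) || dose_per_fraction_gray <= 0) {
      abort_validation("dose_per_fraction_gray must be a single positive number")
    }
    n_frac <- prescribed_dose_gray / dose_per_fraction_gray
    if (abs(n_frac - round(n_frac)) > 1e-9) {
      abort_validation(sprintf(
        "prescribed dose (%g Gy) is not an integer multiple of the fraction size (%g Gy)",
        prescribed_dose_gray, dose_per_fraction_gray))
    }
  }
  structure(
    list(prescribed_dose_gray = prescribed_dose_gray,
         dose_per_fraction_gray = dose_per_fraction_gray),
    class = "treatment_prescription"
  )
}

# ---- Bundled reference tables ----------------------------------------------

#' Path to a bundled reference data file
#'
#' @param file File name under the package's `extdata` directory; `NULL`
#'   lists the directory.
#' @return A file path.
#' @export
neutron_extdata <- function(file = NULL) {
  if (is.null(file)) {
    system.file("extdata", package = "neutrondose")
  } else {
    path <- system.file("extdata", file, package = "neutrondose")
    if (identical(path, "")) abort_schema(sprintf("no bundled file named %s", file))
    path
  }
}

#' Bundled reference tables for the 18-MV brain radiotherapy campaign
#'
#' In-memory copies of the reference measurement campaign and coefficient
#' tables used throughout the package, exactly as tabulated:
#'
#' * `measurements`: H*(10) at the patient table at 0, 20 and 60 cm from
#'   the isocenter (1.30, 0.71, 0.58 mSv/Gy) with their one-sigma
#'   uncertainties, for an 18-MV 10 x 10 cm^2 field.
#' * `depth_dose`: neutron absorbed dose density versus depth (1-16 cm) in
#'   a tissue phantom for 0.5 MeV incident neutrons (d'Errico et al.),
#'   reference depth 1 cm.
#' * `organ_geometry`: horizontal distance and depth of 18 organ centers in
#'   an Alderson female phantom (Howell et al.).
#' * `coefficients`: NCRP-116 tissue weighting factors and fatal-cancer
#'   risk coefficients for the 12 organs with individual W_T, the
#'   remainder-compartment weight and coefficient (0.05 each), the gonad
#'   genetic-effects coefficient (1.00e-2 per Sv), and the active red-marrow
#'   distribution of a 40-year-old male.
#' * `prescription`: 60 Gy at 2 Gy per fraction.
#' * `reported_organ_doses`: the campaign's published per-organ neutron
#'   equivalent doses (mSv over the 60-Gy course), usable as an organ-dose
#'   override for validating the aggregation stage.
#'
#' @return A named list with the six elements above.
#' @export
reference_tables <- function() {
  measurements <- measurement_set(
    distance_cm = c(0, 20, 60),
    h10_per_gray = c(1.30, 0.71, 0.58),
    sd_per_gray = c(0.14, 0.12, 0.10)
  )

  depth_dose <- depth_dose_curve(
    depth_cm = c(1, 2, 3, 4, 5, 6, 8, 10, 12, 14, 16),
    dose_density = c(18.39, 16.11, 12.50, 9.31, 7.16, 5.75, 2.79, 1.40,
                     0.69, 0.43, 0.15),
    reference_depth_cm = 1.0
  )

  organs <- organ_geometry(
    organ_name = c("Brain", "Salivary glands", "Thyroid", "Esophagus",
                   "Breast", "Lung", "Cord", "Heart", "Stomach", "Spleen",
                   "Liver", "Pancreas", "Kidney", "Colon", "Bladder",
                   "Gonads", "Rectum", "Femoral head"),
    distance_cm = c(5, 8.38, 15.28, 29.88, 29.88, 30.88, 32.28, 34.88,
                    43.88, 43.88, 44.38, 45.88, 48.88, 57.88, 78.18,
                    79.88, 79.38, 83.88),
    depth_cm = c(13.0, 6.0, 2.0, 13.5, 2.0, 12.5, 16.0, 9.5, 10.5, 9.0,
                 8.0, 11.0, 12.5, 9.5, 8.5, 1.0, 14.0, 11.5)
  )

  coefficients <- dose_coefficients(
    tissue_weights = tibble::tibble(
      organ_name = c("Bladder", "Bone marrow", "Bone surface", "Breast",
                     "Esophagus", "Colon", "Liver", "Lung", "Gonads",
                     "Skin", "Stomach", "Thyroid"),
      w_t = c(0.05, 0.12, 0.01, 0.05, 0.05, 0.12, 0.05, 0.12, 0.20,
              0.01, 0.12, 0.05),
      risk_coefficient = c(0.30, 0.50, 0.05, 0.20, 0.30, 0.85, 0.15, 0.85,
                           0.10, 0.02, 1.10, 0.08)
    ),
    marrow_distribution = tibble::tibble(
      region = c("head", "upper limb-girdle", "sternum", "ribs",
                 "vertebrae", "sacrum", "lower girdle"),
      fraction = c(0.131, 0.062, 0.034, 0.141, 0.109, 0.139, 0.261)
    ),
    remainder_w_t = 0.05,
    remainder_risk_coefficient = 0.05,
    genetic_coefficient = 1.00
  )

  prescription <- treatment_prescription(60, 2)

  reported_organ_doses <- tibble::tibble(
    organ_name = c("Bladder", "Bone marrow", "Bone surface", "Breast",
                   "Esophagus", "Colon", "Liver", "Lung", "Gonads", "Skin",
                   "Stomach", "Thyroid", "Rectum", "Femoral head",
                   "Salivary glands", "Spleen", "Heart", "Pancreas",
                   "Kidney", "Brain", "Cord"),
    total_mSv = c(4.20, 6.00, 9.00, 37.20, 1.20, 3.00, 5.40, 1.20, 34.80,
                  38.70, 2.40, 37.20, 0.60, 1.20, 13.20, 3.60, 4.20, 2.40,
                  0.60, 1.20, 0.60),
    sd_mSv = c(0.42, 0.80, 1.20, 1.16, 0.15, 0.30, 0.54, 0.15, 3.50, 0.22,
               0.24, 4.00, 0.10, 0.20, 1.70, 0.40, 0.54, 0.30, 0.10, 0.15,
               0.08)
  )

  list(
    measurements = measurements,
    depth_dose = depth_dose,
    organ_geometry = organs,
    coefficients = coefficients,
    prescription = prescription,
    reported_organ_doses = reported_organ_doses
  )
}
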