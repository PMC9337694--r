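# Composite organs: skin, red bone marrow, bone surface; partition into
# named-W_T and remainder compartments; dose overrides.

#' Default skeletal region to surrogate-organ map
#'
#' Red bone marrow and bone surface cannot be located as single points, so
#' their doses are assembled from skeletal regions, each represented by the
#' dose of a surrogate organ at a comparable position: head by the brain,
#' upper limb-girdle by the breast, sternum and ribs by the heart,
#' vertebrae by the spinal cord, sacrum and lower girdle by the femoral
#' head.
#'
#' @return A tibble with columns `region`, `surrogate_organ`.
#' @export
skeletal_region_map <- function() {
  tibble::tibble(
    region = c("head", "upper limb-girdle", "sternum", "ribs", "vertebrae",
               "sacrum", "lower girdle"),
    surrogate_organ = c("Brain", "Breast", "Heart", "Heart", "Cord",
                        "Femoral head", "Femoral head")
  )
}

# Combine weighted per-organ sds under the same-bin full-correlation model:
# contributions sharing a bin add linearly, different bins (or NA bins) in
# quadrature.
combine_sd <- function(weights, sds, bins) {
  stopifnot(length(weights) == length(sds), length(sds) == length(bins))
  term <- weights * sds
  key <- ifelse(is.na(bins), paste0("indep_", seq_along(bins)), paste0("bin_", bins))
  sqrt(sum(tapply(term, key, sum)^2))
}

one_row_dose <- function(organ_name, per_gray, total, sd_total,
                         depth_class = NA_character_,
                         bin_distance_cm = NA_real_) {
  out <- tibble::tibble(
    organ_name = organ_name,
    distance_cm = NA_real_,
    depth_cm = NA_real_,
    depth_class = factor(depth_class, levels = depth_class_levels),
    bin_distance_cm = bin_distance_cm,
    depth_factor = NA_real_,
    per_gray = per_gray,
    total_mSv = total,
    sd_mSv = sd_total
  )
  new_subclass_tbl(out, class = "organ_dose_tbl")
}

#' Skin neutron equivalent dose
#'
#' The skin extends over the whole body at negligible depth, so its dose is
#' taken as the unweighted mean of the out-of-field H*(10) measurements at
#' the bin representative distances, with no depth correction and no
#' intermediate rounding before the course multiplication.  The in-field
#' skin area is ignored.
#'
#' @inheritParams organ_equivalent_dose
#' @return A one-row `organ_dose_tbl` for the skin.
#' @export
skin_dose <- function(measurements, prescription, bin_rule = default_bin_rule()) {
  measurements <- as_measurement_set(measurements)
  if (!inherits(prescription, "treatment_prescription")) {
    prescription <- treatment_prescription(prescription)
  }
  reps <- bin_rule$representative_cm
  i <- match(reps, measurements$distance_cm)
  if (anyNA(i)) {
    abort_validation(sprintf(
      "no measurement point at representative distance %g cm",
      reps[[which(is.na(i))[[1L]]]]))
  }
  per_gray <- mean(measurements$h10_per_gray[i])
  # points at different distances are independent measurements
  sd_per_gray <- sqrt(sum(measurements$sd_per_gray[i]^2)) / length(i)
  one_row_dose("Skin",
               per_gray = per_gray,
               total = per_gray * prescription$prescribed_dose_gray,
               sd_total = sd_per_gray * prescription$prescribed_dose_gray,
               depth_class = "surface")
}

surrogate_doses <- function(doses, region_map, regions) {
  check_columns(doses, c("organ_name", "total_mSv"), "organ dose table")
  region_map <- tibble::as_tibble(region_map)
  region_map$region <- canonical_organ(region_map$region)
  i <- match(regions, region_map$region)
  if (anyNA(i)) {
    abort_validation(sprintf("skeletal region %s has no surrogate in the region map",
                             regions[[which(is.na(i))[[1L]]]]))
  }
  j <- match(canonical_organ(region_map$surrogate_organ[i]),
             canonical_organ(doses$organ_name))
  if (anyNA(j)) {
    k <- which(is.na(j))[[1L]]
    abort_validation(sprintf(
      "no dose available for surrogate organ %s (skeletal region %s)",
      region_map$surrogate_organ[i][[k]], regions[[k]]))
  }
  tibble::tibble(
    region = regions,
    surrogate_organ = region_map$surrogate_organ[i],
    total_mSv = doses$total_mSv[j],
    sd_mSv = if ("sd_mSv" %in% names(doses)) doses$sd_mSv[j] else 0,
    per_gray = if ("per_gray" %in% names(doses)) doses$per_gray[j] else NA_real_,
    bin_distance_cm = if ("bin_distance_cm" %in% names(doses))
      doses$bin_distance_cm[j] else NA_real_
  )
}

#' Red bone marrow neutron equivalent dose
#'
#' Weighted sum of surrogate-organ doses over skeletal regions, the weights
#' being the anatomical distribution of active red bone marrow (40-year-old
#' male: head 13.1%, upper limb-girdle 6.2%, sternum 3.4%, ribs 14.1%,
#' vertebrae 10.9%, sacrum 13.9%, lower girdle 26.1%).  Those published
#' fractions sum to 0.877, not 1; `normalization = "as-printed"` uses them
#' as given, `"renormalized"` divides by their sum first.
#'
#' @param doses An `organ_dose_tbl` containing the surrogate organs.
#' @param marrow_distribution Tibble with columns `region`, `fraction`, or a
#'   [dose_coefficients()] object.
#' @param region_map Region-to-surrogate map; defaults to
#'   [skeletal_region_map()].
#' @param normalization `"as-printed"` (default) or `"renormalized"`.
#' @return A one-row `organ_dose_tbl` for the bone marrow.
#' @export
red_marrow_dose <- function(doses, marrow_distribution,
                            region_map = skeletal_region_map(),
                            normalization = c("as-printed", "renormalized")) {
  normalization <- rlang::arg_match(normalization)
  if (inherits(marrow_distribution, "dose_coefficients")) {
    marrow_distribution <- marrow_distribution$marrow_distribution
  }
  check_columns(marrow_distribution, c("region", "fraction"),
                "marrow distribution table")
  md <- tibble::as_tibble(marrow_distribution)
  md$region <- canonical_organ(md$region)
  w <- md$fraction
  if (normalization == "renormalized") w <- w / sum(w)
  sur <- surrogate_doses(doses, region_map, md$region)
  one_row_dose("Bone marrow",
               per_gray = if (anyNA(sur$per_gray)) NA_real_ else sum(w * sur$per_gray),
               total = sum(w * sur$total_mSv),
               sd_total = combine_sd(w, sur$sd_mSv, sur$bin_distance_cm))
}

#' Bone surface neutron equivalent dose
#'
#' Unweighted mean of the surrogate doses over the six trunk/limb skeletal
#' regions (upper limb-girdle, sternum, ribs, vertebrae, sacrum, lower
#' girdle); the head is excluded.  Regions sharing a surrogate organ are
#' each counted once per region.
#'
#' @inheritParams red_marrow_dose
#' @param regions Skeletal regions to average over.
#' @return A one-row `organ_dose_tbl` for the bone surface.
#' @export
bone_surface_dose <- function(doses, region_map = skeletal_region_map(),
                              regions = c("upper limb-girdle", "sternum",
                                          "ribs", "vertebrae", "sacrum",
                                          "lower girdle")) {
  regions <- canonical_organ(regions)
  sur <- surrogate_doses(doses, region_map, regions)
  n <- nrow(sur)
  one_row_dose("Bone surface",
               per_gray = if (anyNA(sur$per_gray)) NA_real_ else mean(sur$per_gray),
               total = mean(sur$total_mSv),
               sd_total = combine_sd(rep(1 / n, n), sur$sd_mSv, sur$bin_distance_cm))
}

#' Partition organ doses into named and remainder compartments
#'
#' Organs with an individual tissue weighting factor form the named
#' compartment; all other dosed organs form the remainder compartment,
#' which shares a single W_T and risk coefficient.
#'
#' @param doses An organ dose table with at least `organ_name`.
#' @param coefficients A [dose_coefficients()] object.
#' @return A list with elements `named` and `remainder`, each a tibble of
#'   the corresponding rows of `doses`; the union is `doses`, the
#'   intersection empty.
#' @export
partition_remainder <- function(doses, coefficients) {
  check_columns(doses, "organ_name", "organ dose table")
  if (!inherits(coefficients, "dose_coefficients")) {
    abort_validation("coefficients must be a dose_coefficients object")
  }
  if (anyDuplicated(canonical_organ(doses$organ_name)) > 0L) {
    abort_validation("duplicate organ in dose table")
  }
  named_set <- canonical_organ(coefficients$tissue_weights$organ_name)
  is_named <- canonical_organ(doses$organ_name) %in% named_set
  list(named = doses[is_named, , drop = FALSE],
       remainder = doses[!is_named, , drop = FALSE])
}

#' Override computed organ doses
#'
#' Replaces the total dose (and its sd) of listed organs with externally
#' supplied values before the aggregation stage; organs in the override
#' table that are absent from `doses` are appended.  Used e.g. to inject
#' published composite-organ doses whose derivation is not reproducible
#' from the stated procedure.
#'
#' @param doses An `organ_dose_tbl`.
#' @param overrides Tibble with columns `organ_name`, `total_mSv`, `sd_mSv`
#'   (see [read_organ_dose_overrides()]).
#' @param prescription Optional [treatment_prescription()]; when supplied,
#'   the per-gray dose of overridden rows is recomputed as total / dose.
#' @return The updated `organ_dose_tbl`.
#' @export
apply_dose_overrides <- function(doses, overrides, prescription = NULL) {
  check_columns(overrides, c("organ_name", "total_mSv", "sd_mSv"),
                "organ dose override table")
  per_gray_of <- function(total) {
    if (is.null(prescription)) NA_real_
    else total / prescription$prescribed_dose_gray
  }
  i <- match(canonical_organ(overrides$organ_name),
             canonical_organ(doses$organ_name))
  hit <- !is.na(i)
  doses$total_mSv[i[hit]] <- overrides$total_mSv[hit]
  doses$sd_mSv[i[hit]] <- overrides$sd_mSv[hit]
  doses$per_gray[i[hit]] <- per_gray_of(overrides$total_mSv[hit])
  doses$bin_distance_cm[i[hit]] <- NA_real_  # provenance no longer a single bin
  if (any(!hit)) {
    extra <- overrides[!hit, , drop = FALSE]
    add <- one_row_dose(extra$organ_name,
                        per_gray = per_gray_of(extra$total_mSv),
                        total = extra$total_mSv,
                        sd_total = extra$sd_mSv)
    doses <- dplyr::bind_rows(doses, add)
  }
  new_subclass_tbl(doses, class = "organ_dose_tbl")
}
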