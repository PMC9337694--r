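# Shared fixtures: the bundled reference campaign and a full 21-organ dose
# table built from it.

ref <- reference_tables()

full_dose_table <- function(rounding = "reported", scheme = "linear",
                            overrides = NULL) {
  d <- organ_equivalent_dose(ref$organ_geometry, ref$measurements,
                             ref$depth_dose, ref$prescription,
                             scheme = scheme, rounding = rounding)
  d <- dplyr::bind_rows(
    d,
    skin_dose(ref$measurements, ref$prescription),
    red_marrow_dose(d, ref$coefficients),
    bone_surface_dose(d)
  )
  if (!is.null(overrides)) {
    d <- apply_dose_overrides(d, overrides, ref$prescription)
  }
  d
}

dose_of <- function(doses, organ) {
  doses$total_mSv[[match(canonical_organ(organ),
                         canonical_organ(doses$organ_name))]]
}

per_gray_of <- function(doses, organ) {
  doses$per_gray[[match(canonical_organ(organ),
                        canonical_organ(doses$organ_name))]]
}
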