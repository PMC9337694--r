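# Depth-dose interpolation, bin assignment, organ equivalent dose.

curve <- ref$depth_dose

test_that("interpolation is exact at grid points and matches hand values between", {
  for (scheme in c("linear", "log-linear")) {
    expect_equal(interpolate_depth_dose(curve, curve$depth_cm, scheme),
                 curve$dose_density)
  }
  expect_equal(interpolate_depth_dose(curve, 2.0, "linear"), 16.11)
  expect_equal(interpolate_depth_dose(curve, 2.0, "log-linear"), 16.11)
  # hand interpolation between (8, 2.79) and (10, 1.40)
  expect_equal(interpolate_depth_dose(curve, 9.5, "linear"), 1.7475)
  expect_equal(interpolate_depth_dose(curve, 9.5, "log-linear"),
               2.79 * (1.40 / 2.79)^0.75, tolerance = 1e-12)
})

test_that("interpolation is bounded by bracketing grid values for both schemes", {
  depths <- seq(1, 16, by = 0.05)
  for (scheme in c("linear", "log-linear")) {
    y <- interpolate_depth_dose(curve, depths, scheme)
    k <- findInterval(depths, curve$depth_cm, rightmost.closed = TRUE)
    lo <- pmin(curve$dose_density[k], curve$dose_density[pmin(k + 1, 11)])
    hi <- pmax(curve$dose_density[k], curve$dose_density[pmin(k + 1, 11)])
    expect_true(all(y >= lo - 1e-12 & y <= hi + 1e-12))
  }
})

test_that("depth correction factor is a ratio anchored at the reference depth", {
  expect_equal(depth_correction_factor(curve, 1.0), 1.0)
  expect_equal(depth_correction_factor(curve, 2.0), 16.11 / 18.39)
  expect_equal(depth_correction_factor(curve, 16.0), 0.15 / 18.39)
})

test_that("depth factor is <= 1 beyond the reference depth and strictly decreasing", {
  depths <- seq(1, 16, by = 0.01)
  for (scheme in c("linear", "log-linear")) {
    f <- depth_correction_factor(curve, depths, scheme)
    expect_true(all(f <= 1 + 1e-12))
    expect_true(all(diff(f) < 0))
  }
})

test_that("extrapolation rules: error toward the surface, clamp-with-warning beyond", {
  expect_error(interpolate_depth_dose(curve, 0.5),
               "below the curve minimum", class = "neutrondose_validation_error")
  expect_warning(res <- interpolate_depth_dose(curve, 20), "clamping")
  expect_equal(res, 0.15)
})

test_that("distance bins route organs to the measured points", {
  rule <- default_bin_rule()
  hit <- assign_distance_bin(rule, ref$measurements, c(15.28, 79.88, 83.88))
  expect_equal(hit$bin_distance_cm, c(20, 60, 60))  # far organ clamps
  expect_equal(hit$h10_per_gray, c(0.71, 0.58, 0.58))
  # boundary 40 cm belongs to the near bin, 40.01 to the far bin
  b <- assign_distance_bin(rule, ref$measurements, c(40, 40.01))
  expect_equal(b$bin_distance_cm, c(20, 60))

  expect_error(assign_distance_bin(rule, ref$measurements, 3),
               "inside the treatment field",
               class = "neutrondose_validation_error")
  strict <- distance_bin_rule(c(5, 40), c(40, 80), c(20, 60),
                              out_of_range = "error")
  expect_error(assign_distance_bin(strict, ref$measurements, 83.88),
               "beyond the last bin", class = "neutrondose_validation_error")
  # representative distance must have a measurement point
  bad_rule <- distance_bin_rule(5, 40, 30)
  expect_error(assign_distance_bin(bad_rule, ref$measurements, 10),
               "representative distance", class = "neutrondose_validation_error")
})

test_that("depth classification uses half-open intervals with closed upper bounds", {
  expect_equal(as.character(classify_depth(c(0, 2, 5, 5.01, 10, 10.01, 15, 15.5, 16))),
               c("surface", "surface", "surface", "middle", "middle",
                 "deep", "deep", "unclassified", "unclassified"))
  expect_error(classify_depth(-1), class = "neutrondose_validation_error")
})

test_that("organ equivalent dose reproduces the published per-organ values (reported mode)", {
  d <- full_dose_table(rounding = "reported")
  expect_equal(per_gray_of(d, "Thyroid"), 0.62)
  expect_equal(dose_of(d, "Thyroid"), 37.2)
  expect_equal(per_gray_of(d, "Breast"), 0.62)
  expect_equal(per_gray_of(d, "Gonads"), 0.58)
  expect_equal(dose_of(d, "Gonads"), 34.8)
  expect_equal(dose_of(d, "Salivary glands"), 13.2)
  expect_equal(dose_of(d, "Liver"), 5.4)
  expect_equal(dose_of(d, "Heart"), 4.2)       # matches only the linear scheme
  expect_equal(dose_of(d, "Stomach"), 2.4)
  expect_equal(dose_of(d, "Brain"), 1.2)
  expect_equal(dose_of(d, "Esophagus"), 1.2)
  expect_equal(dose_of(d, "Lung"), 1.2)
  expect_equal(dose_of(d, "Cord"), 0.6)
  expect_equal(dose_of(d, "Rectum"), 0.6)
})

test_that("precise mode applies no intermediate rounding", {
  d <- organ_equivalent_dose(ref$organ_geometry, ref$measurements, curve,
                             ref$prescription, rounding = "precise")
  breast <- per_gray_of(d, "Breast")
  expect_equal(breast, 0.71 * 16.11 / 18.39, tolerance = 1e-12)
  expect_equal(dose_of(d, "Breast"), breast * 60, tolerance = 1e-12)
  # an organ at the reference depth in the near bin gets the bin H*(10) exactly
  probe <- organ_geometry("probe", 20, 1.0)
  dp <- organ_equivalent_dose(probe, ref$measurements, curve, ref$prescription)
  expect_equal(dp$per_gray, 0.71)
  expect_equal(dp$depth_factor, 1.0)
})

test_that("reported and precise totals differ by at most the rounding bound", {
  dr <- full_dose_table(rounding = "reported")
  dp <- full_dose_table(rounding = "precise")
  gap <- abs(dr$total_mSv - dp$total_mSv)
  expect_true(all(gap <= 0.005 * 60 + 1e-9))
})

test_that("dose is monotone non-increasing in depth and across bin boundaries", {
  depths <- seq(1, 16, by = 0.5)
  probes <- organ_geometry(sprintf("p%02d", seq_along(depths)),
                           rep(20, length(depths)), depths)
  for (scheme in c("linear", "log-linear")) {
    d <- organ_equivalent_dose(probes, ref$measurements, curve,
                               ref$prescription, scheme = scheme)
    expect_true(all(diff(d$per_gray) <= 1e-12))
  }
  # fixed depth, increasing distance across the bin boundary
  dists <- c(10, 39, 41, 79, 83)
  probes <- organ_geometry(sprintf("q%02d", seq_along(dists)), dists,
                           rep(3, length(dists)))
  d <- organ_equivalent_dose(probes, ref$measurements, curve, ref$prescription)
  expect_true(all(diff(d$per_gray) <= 1e-12))
})

test_that("uncertainty scales with the bin measurement's relative sd", {
  d <- full_dose_table(rounding = "precise")
  thy <- d[d$organ_name == "Thyroid", ]
  expect_equal(thy$sd_mSv, thy$total_mSv * 0.12 / 0.71)
  gon <- d[d$organ_name == "Gonads", ]
  expect_equal(gon$sd_mSv, gon$total_mSv * 0.10 / 0.58)
})

test_that("depth-class means reproduce the published class averages", {
  d <- full_dose_table(rounding = "reported")
  m <- depth_class_means(d[!is.na(d$depth_cm), ])
  get <- function(cls) m$mean_per_gray[m$depth_class == cls]
  expect_equal(round(get("surface"), 2), 0.61)   # {0.62, 0.62, 0.58}
  expect_equal(round(get("deep"), 2), 0.02)
  expect_equal(m$n_organs[m$depth_class == "unclassified"], 1L)  # cord, 16 cm
  # single-organ class is the identity
  one <- depth_class_means(organ_equivalent_dose(
    organ_geometry("solo", 20, 2), ref$measurements, curve, ref$prescription))
  expect_equal(one$mean_per_gray[one$depth_class == "surface"],
               0.71 * 16.11 / 18.39)
})
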