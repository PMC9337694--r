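# Effective dose, cancer risk, genetic effects, uncertainty propagation.

published_doses <- full_dose_table(rounding = "reported",
                                   overrides = ref$reported_organ_doses)

test_that("effective dose closes at the published 13.36 mSv with the mean remainder rule", {
  e <- effective_dose(published_doses, ref$coefficients)
  expect_equal(round(e$effective_dose_mSv, 2), 13.36)
  ct <- e$contributions
  get <- function(o) ct$contribution_mSv[ct$compartment == o]
  expect_equal(get("Gonads"), 6.96)
  expect_equal(get("Thyroid"), 1.86)
  expect_equal(get("Breast"), 1.86)
  expect_equal(round(ct$share_pct[ct$compartment == "Gonads"]), 52)
  # remainder contribution = 0.05 x mean of the nine remainder doses
  expect_equal(get("Remainder"), 0.05 * 27.6 / 9, tolerance = 1e-12)
  # shares sum to 100
  expect_equal(sum(ct$share_pct), 100)
  expect_true(all(ct$share_pct >= 0 & ct$share_pct <= 100))
  # the invariant E = sum of contributions
  expect_equal(e$effective_dose_mSv, sum(ct$contribution_mSv),
               tolerance = 1e-9)
})

test_that("effective dose errors when a named organ lacks a dose", {
  d <- published_doses[canonical_organ(published_doses$organ_name) != "thyroid", ]
  expect_error(effective_dose(d, ref$coefficients), "Thyroid",
               class = "neutrondose_validation_error")
})

test_that("per-organ cancer risk follows the coefficient product", {
  expect_equal(organ_cancer_risk(37.2, 0.20), 74.4)
  expect_equal(organ_cancer_risk(37.2, 0.08), 29.76)
  expect_equal(organ_cancer_risk(0, 0.85), 0)
  expect_error(organ_cancer_risk(-1, 0.2), class = "neutrondose_validation_error")
})

test_that("total risk uses the sum remainder rule and closes at 281.4 per million", {
  r <- total_cancer_risk(published_doses, ref$coefficients)
  expect_equal(r$total_cases_per_million, 281.4)
  po <- r$per_organ
  get <- function(o) po$cases_per_million[po$compartment == o]
  expect_equal(get("Breast"), 74.4)
  expect_equal(get("Gonads"), 34.8)
  expect_equal(get("Thyroid"), 29.76)
  expect_equal(get("Stomach"), 26.4)
  expect_equal(get("Colon"), 25.5)
  expect_equal(get("Bladder"), 12.6)
  expect_equal(get("Lung"), 10.2)
  expect_equal(get("Liver"), 8.1)
  expect_equal(get("Skin"), 7.74)
  expect_equal(get("Bone surface"), 4.5)
  expect_equal(get("Esophagus"), 3.6)
  expect_equal(get("Remainder"), 13.8)   # 0.05e-2 applied to the 27.6 mSv sum
  expect_equal(r$total_cases_per_million, sum(po$cases_per_million))
})

test_that("aggregates are linear and permutation-invariant in the dose vector", {
  doubled <- dplyr::mutate(published_doses, total_mSv = 2 * total_mSv)
  expect_equal(effective_dose(doubled, ref$coefficients)$effective_dose_mSv,
               2 * effective_dose(published_doses, ref$coefficients)$effective_dose_mSv)
  expect_equal(total_cancer_risk(doubled, ref$coefficients)$total_cases_per_million,
               2 * total_cancer_risk(published_doses, ref$coefficients)$total_cases_per_million)
  perm <- published_doses[sample.int(nrow(published_doses)), ]
  expect_equal(effective_dose(perm, ref$coefficients)$effective_dose_mSv,
               effective_dose(published_doses, ref$coefficients)$effective_dose_mSv)
  expect_equal(total_cancer_risk(perm, ref$coefficients)$total_cases_per_million,
               total_cancer_risk(published_doses, ref$coefficients)$total_cases_per_million)
  zero <- dplyr::mutate(published_doses, total_mSv = 0)
  expect_equal(effective_dose(zero, ref$coefficients)$effective_dose_mSv, 0)
})

test_that("population size rescales risks proportionally", {
  r1 <- total_cancer_risk(published_doses, ref$coefficients, population = 1e6)
  r2 <- total_cancer_risk(published_doses, ref$coefficients, population = 2.5e5)
  expect_equal(r2$total_cases, r1$total_cases * 0.25)
  expect_equal(r2$total_cases_per_million, r1$total_cases_per_million)
  expect_equal(genetic_effects(100, 1.00, 1e6), 1000)
  expect_equal(genetic_effects(100, 1.00, 1e5), 100)
})

test_that("genetic effects follow the gonad-dose coefficient product", {
  expect_equal(genetic_effects(34.8), 348)   # the published row prints 384
  expect_equal(genetic_effects(0), 0)
  expect_equal(genetic_effects(100), 1000)
})

test_that("uncertainty propagation follows the same-bin correlation model", {
  cf <- dose_coefficients(
    tibble::tibble(organ_name = c("A", "B"), w_t = c(0.1, 0.3),
                   risk_coefficient = c(0.5, 0.5)),
    ref$coefficients$marrow_distribution)
  base <- tibble::tibble(organ_name = c("A", "B"),
                         total_mSv = c(10, 20), sd_mSv = c(1, 2))
  # all sds zero -> zero output
  z <- propagate_uncertainty(dplyr::mutate(base, sd_mSv = 0,
                                           bin_distance_cm = c(20, 60)), cf)
  expect_equal(z$effective_dose_sd_mSv, 0)
  # single organ: sd = w * s
  solo <- tibble::tibble(organ_name = "A", total_mSv = 10, sd_mSv = 2,
                         bin_distance_cm = 20)
  cf1 <- dose_coefficients(
    tibble::tibble(organ_name = "A", w_t = 0.1, risk_coefficient = 0.5),
    ref$coefficients$marrow_distribution)
  expect_equal(propagate_uncertainty(solo, cf1)$effective_dose_sd_mSv, 0.2)
  # two same-bin organs: full correlation, weighted sds add linearly
  same <- dplyr::mutate(base, bin_distance_cm = c(20, 20))
  expect_equal(propagate_uncertainty(same, cf)$effective_dose_sd_mSv,
               0.1 * 1 + 0.3 * 2)
  # different bins: quadrature
  diff_bin <- dplyr::mutate(base, bin_distance_cm = c(20, 60))
  expect_equal(propagate_uncertainty(diff_bin, cf)$effective_dose_sd_mSv,
               sqrt(0.1^2 + 0.6^2))
})

test_that("tidiers return the documented tibbles", {
  e <- effective_dose(published_doses, ref$coefficients)
  expect_s3_class(tidy(e), "tbl_df")
  expect_named(tidy(e), c("compartment", "h_t_mSv", "w_t",
                          "contribution_mSv", "share_pct"))
  expect_equal(glance(e)$effective_dose_mSv, e$effective_dose_mSv)
  r <- total_cancer_risk(published_doses, ref$coefficients)
  expect_s3_class(tidy(r), "tbl_df")
  expect_equal(glance(r)$total_cases_per_million, r$total_cases_per_million)
})
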