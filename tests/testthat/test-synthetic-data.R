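# Synthetic generators, ground truth, and dual-route oracle equivalence.

test_that("campaign generation is seed-deterministic and noiseless at cv = 0", {
  spec <- campaign_spec(seed = 7)
  a <- generate_campaign(spec)
  b <- generate_campaign(spec)
  expect_identical(a$measurements, b$measurements)
  c2 <- generate_campaign(campaign_spec(seed = 8))
  expect_false(identical(a$measurements$h10_per_gray,
                         c2$measurements$h10_per_gray))

  noiseless <- generate_campaign(campaign_spec(noise_cv = 0, seed = 1))
  expect_equal(noiseless$measurements$h10_per_gray,
               true_profile(campaign_spec(noise_cv = 0, seed = 1)))
  expect_equal(noiseless$measurements$sd_per_gray, c(0, 0, 0))
})

test_that("default profile emulates the reference campaign within 10%", {
  spec <- campaign_spec()
  truth <- true_profile(spec, c(0, 20, 60))
  observed <- c(1.30, 0.71, 0.58)
  expect_true(all(abs(truth - observed) / observed < 0.10))
})

test_that("campaign spec rejects invalid parameters", {
  expect_error(campaign_spec(h0 = 0.5, floor = 0.6),
               class = "neutrondose_validation_error")
  expect_error(campaign_spec(noise_cv = -0.1),
               class = "neutrondose_validation_error")
  expect_error(campaign_spec(replicates = 0),
               class = "neutrondose_validation_error")
  expect_error(generate_depth_dose_curve(mu_per_cm = -1),
               class = "neutrondose_validation_error")
})

test_that("exponential synthetic curves have closed-form depth factors", {
  # mu solving value(16)/value(1) = 0.15/18.39
  mu <- log(18.39 / 0.15) / 15
  expect_equal(mu, 0.3206, tolerance = 1e-4)
  curve <- generate_depth_dose_curve(mu)
  # log-linear interpolation is exact on an exponential curve
  depths <- seq(1, 16, by = 0.13)
  expect_equal(depth_correction_factor(curve, depths, "log-linear"),
               exp(-mu * (depths - 1)), tolerance = 1e-9)
  # linear interpolation is within the chord bound and exact at nodes
  f_lin <- depth_correction_factor(curve, depths, "linear")
  expect_true(all(f_lin >= exp(-mu * (depths - 1)) - 1e-12))  # chord above convex curve
  expect_equal(depth_correction_factor(curve, c(1, 5, 16), "linear"),
               exp(-mu * (c(1, 5, 16) - 1)), tolerance = 1e-12)
  # amplitude scaling leaves depth factors unchanged
  curve2 <- generate_depth_dose_curve(mu, amplitude = 1000)
  expect_equal(depth_correction_factor(curve2, depths, "linear"), f_lin)
})

test_that("random organ tables are valid, reproducible and pipeline-admissible", {
  og <- generate_organ_table(18, seed = 3)
  expect_equal(nrow(og), 18L)
  expect_identical(og, generate_organ_table(18, seed = 3))
  expect_equal(nrow(generate_organ_table(1, seed = 1)), 1L)
  d <- organ_equivalent_dose(og, ref$measurements, ref$depth_dose,
                             ref$prescription)
  expect_true(all(d$per_gray > 0))
  expect_error(generate_organ_table(3, distance_range = c(-5, 10)),
               class = "neutrondose_validation_error")
})

test_that("zero-noise campaigns reproduce the synthetic truth exactly", {
  spec <- campaign_spec(noise_cv = 0, distances_cm = c(0, 20, 60), seed = 1)
  camp <- generate_campaign(spec)
  og <- generate_organ_table(10, seed = 5)
  est <- organ_equivalent_dose(og, camp$measurements, ref$depth_dose,
                               ref$prescription)
  truth <- synthetic_truth_doses(spec, ref$depth_dose, og, ref$prescription)
  expect_equal(est$total_mSv, truth$total_mSv, tolerance = 1e-12)
})

test_that("oracle matches the pipeline on the reference fixtures in both modes and schemes", {
  for (rounding in c("precise", "reported")) {
    for (scheme in c("linear", "log-linear")) {
      d <- full_dose_table(rounding = rounding, scheme = scheme)
      orc <- oracle_pipeline(ref$measurements, ref$depth_dose,
                             ref$organ_geometry, ref$coefficients,
                             ref$prescription, scheme = scheme,
                             rounding = rounding)
      i <- match(canonical_organ(orc$organ_doses$organ_name),
                 canonical_organ(d$organ_name))
      expect_false(anyNA(i))
      expect_equal(d$total_mSv[i], orc$organ_doses$total_mSv,
                   tolerance = 1e-12)
      e <- effective_dose(d, ref$coefficients)
      r <- total_cancer_risk(d, ref$coefficients)
      expect_equal(e$effective_dose_mSv, orc$effective_dose_mSv,
                   tolerance = 1e-12)
      expect_equal(r$total_cases_per_million, orc$total_risk_per_million,
                   tolerance = 1e-12)
      expect_equal(genetic_effects(dose_of(d, "Gonads")),
                   orc$genetic_per_million, tolerance = 1e-12)
    }
  }
})

test_that("oracle matches the pipeline on random synthetic configurations", {
  n_cases <- 30
  withr::with_seed(2024, {
    seeds <- sample.int(1e6, n_cases)
  })
  for (k in seq_len(n_cases)) {
    s <- seeds[k]
    spec <- withr::with_seed(s, campaign_spec(
      h0 = stats::runif(1, 1.0, 2.0),
      floor = stats::runif(1, 0.2, 0.6),
      decay_length_cm = stats::runif(1, 5, 25),
      noise_cv = stats::runif(1, 0, 0.1),
      seed = s))
    camp <- generate_campaign(spec)
    mu <- withr::with_seed(s + 1L, stats::runif(1, 0.1, 0.5))
    curve <- generate_depth_dose_curve(mu)
    og <- generate_organ_table(withr::with_seed(s + 2L, sample(3:12, 1)),
                               seed = s + 3L)
    scheme <- if (k %% 2 == 0) "linear" else "log-linear"
    rounding <- if (k %% 3 == 0) "reported" else "precise"
    d <- organ_equivalent_dose(og, camp$measurements, curve,
                               ref$prescription, scheme = scheme,
                               rounding = rounding)
    orc <- oracle_pipeline(camp$measurements, curve, og, ref$coefficients,
                           ref$prescription, scheme = scheme,
                           rounding = rounding)
    i <- seq_len(nrow(og))
    expect_equal(d$total_mSv, orc$organ_doses$total_mSv[i], tolerance = 1e-12)
    # doubling H*(10) doubles every oracle dose (linearity; precise mode)
    if (rounding == "precise") {
      ms2 <- as_measurement_set(dplyr::mutate(
        camp$measurements, h10_per_gray = 2 * h10_per_gray))
      orc2 <- oracle_pipeline(ms2, curve, og, ref$coefficients,
                              ref$prescription, scheme = scheme,
                              rounding = rounding)
      expect_equal(orc2$organ_doses$total_mSv[i],
                   2 * orc$organ_doses$total_mSv[i], tolerance = 1e-12)
    }
  }
})

test_that("noisy campaigns recover true organ doses with near-nominal coverage", {
  # 3 replicates at 5% noise; quick in-suite check on 120 seeds (the
  # acceptance suite runs the full 500-seed study)
  spec0 <- campaign_spec(noise_cv = 0.05, replicates = 3)
  og <- ref$organ_geometry
  truth <- synthetic_truth_doses(spec0, ref$depth_dose, og, ref$prescription)
  n_seeds <- 120
  rel_err <- matrix(NA_real_, n_seeds, nrow(og))
  covered <- matrix(NA, n_seeds, nrow(og))
  for (s in seq_len(n_seeds)) {
    camp <- generate_campaign(campaign_spec(noise_cv = 0.05, replicates = 3,
                                            seed = s))
    est <- organ_equivalent_dose(og, camp$measurements, ref$depth_dose,
                                 ref$prescription)
    rel_err[s, ] <- (est$total_mSv - truth$total_mSv) / truth$total_mSv
    covered[s, ] <- abs(est$total_mSv - truth$total_mSv) <= est$sd_mSv
  }
  expect_lt(max(abs(colMeans(rel_err))), 0.02)
  expect_gt(mean(covered), 0.55)
  expect_lt(mean(covered), 0.85)
})
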