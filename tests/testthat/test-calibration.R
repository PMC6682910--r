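test_that("noiseless data recover the generating line exactly", {
  st <- generate_calibration_dataset(c(5, 10, 25, 50, 100), 5, noise_sd = 0)
  curve <- suppressWarnings(fit_calibration(st))
  expect_lt(abs(curve$slope - 47.01) / 47.01, 1e-9)
  expect_lt(abs(curve$intercept - 126.18) / 126.18, 1e-9)
  expect_equal(curve$r_squared, 1, tolerance = 1e-12)
})

test_that("fit errors and warnings cover degenerate standards", {
  two <- calibration_standards(c(5, 10), c(150, 170))
  expect_error(fit_calibration(two), class = "fp_insufficient_data")
  # zero-concentration rows are dropped from the fit, so three zeros + two
  # levels is still insufficient
  withzero <- calibration_standards(c(0, 0, 0, 5, 10), c(99, 101, 100, 150, 170))
  expect_error(fit_calibration(withzero), class = "fp_insufficient_data")
  falling <- generate_calibration_dataset(c(5, 10, 25), 2, slope = -20,
                                          intercept = 200)
  expect_warning(fit_calibration(falling), "not positive")
})

test_that("noisy fit agrees with a closed-form OLS oracle on the same numbers", {
  st <- generate_calibration_dataset(c(5, 10, 25, 50, 100), 5, noise_sd = 3,
                                     seed = 201)
  curve <- fit_calibration(st)
  oracle <- ols_oracle(log10(st$concentration), st$intensity)
  expect_equal(curve$slope, oracle$slope, tolerance = 1e-10)
  expect_equal(curve$intercept, oracle$intercept, tolerance = 1e-10)
  expect_equal(curve$r_squared, oracle$r_squared, tolerance = 1e-10)
})

test_that("slope confidence intervals cover the generating slope", {
  # 200 seeded synthetic calibrations at noise typical of replicate spots;
  # the 95% CI for the slope should cover the truth ~95% of the time
  covered <- 0L
  for (i in 1:200) {
    st <- generate_calibration_dataset(c(5, 10, 25, 50, 100), 5,
                                       noise_sd = 5, seed = 300 + i)
    fit <- lm(intensity ~ log10(concentration), data = st)
    ci <- confint(fit)["log10(concentration)", ]
    if (ci[1] <= 47.01 && 47.01 <= ci[2]) covered <- covered + 1L
  }
  expect_gte(covered, 180L)
})

test_that("working range follows the linearity rule", {
  # plateau below 5 ug/mL at the blank level, linear in log c from 5 to 100
  st <- generate_calibration_dataset(c(0.5, 1, 2.5, 5, 10, 25, 50, 100), 5,
                                     noise_sd = 0, flat_below = 5)
  rng <- determine_working_range(st)
  expect_equal(unname(rng), c(5, 100))

  # perfectly linear across all levels: full span
  lin <- generate_calibration_dataset(c(0.5, 1, 2.5, 5, 10, 25, 50, 100), 3,
                                      noise_sd = 0)
  expect_equal(unname(determine_working_range(lin)), c(0.5, 100))

  # flat response everywhere: no qualifying run
  flat <- calibration_standards(rep(c(5, 10, 25, 50), each = 3),
                                rep(140, 12) + rep(c(-1, 0, 1), 4))
  expect_error(determine_working_range(flat), class = "fp_no_working_range")
})

test_that("LOD follows blank mean + 3 sigma through the curve", {
  curve <- paper_curve()
  # zero-sd blanks at the intercept: threshold = intercept, so LOD = 1 ug/mL
  expect_equal(compute_lod(rep(126.18, 20), curve), 1, tolerance = 1e-9)
  # blanks standardised to mean 126.18, sd 10: LOD = 10^(30 / 47.01)
  set.seed(202)
  z <- rnorm(20)
  blanks <- 126.18 + 10 * (z - mean(z)) / sd(z)
  expect_equal(compute_lod(blanks, curve), 10^(30 / 47.01),
               tolerance = 1e-6)
  expect_error(compute_lod(c(120), curve), class = "fp_insufficient_data")
})

test_that("LOD is monotone in blank mean and blank sd", {
  curve <- paper_curve()
  set.seed(203)
  z <- rnorm(20); z <- (z - mean(z)) / sd(z)
  lods_sd <- sapply(c(0.5, 2, 5, 10), function(s) compute_lod(120 + s * z, curve))
  expect_true(all(diff(lods_sd) > 0))
  lods_mean <- sapply(c(100, 110, 120, 130), function(m) compute_lod(m + 3 * z, curve))
  expect_true(all(diff(lods_mean) > 0))
})

test_that("LOD mass is concentration times deposited volume in ng", {
  expect_equal(lod_mass(3.691, 5), 18.5)
  expect_equal(lod_mass(1, 1), 1)
  expect_equal(lod_mass(10, 5), 50)
  expect_error(lod_mass(-1, 5), class = "fp_invalid_input")
})

test_that("sensitivity is the response change per unit concentration", {
  st <- calibration_standards(rep(c(5, 25, 100), each = 2),
                              c(150, 150, 200, 200, 245, 245))
  expect_equal(sensitivity(st, c(5, 100)), 1)
  flat <- calibration_standards(rep(c(5, 25, 100), each = 2), rep(140, 6))
  expect_equal(sensitivity(flat, c(5, 100)), 0)
  # noiseless generator: closed form from the generating line's endpoints
  gen <- generate_calibration_dataset(c(5, 10, 25, 50, 100), 5, noise_sd = 0)
  expect_equal(sensitivity(gen, c(5, 100)),
               47.01 * (log10(100) - log10(5)) / 95, tolerance = 1e-12)
  expect_error(sensitivity(st, c(5, 60)), class = "fp_invalid_input")
})

test_that("inverse prediction inverts the curve algebraically", {
  curve <- paper_curve()
  expect_equal(inverse_predict(curve, curve$intercept), 1, tolerance = 1e-9)
  for (conc in c(5, 20, 100)) {
    fwd <- curve$slope * log10(conc) + curve$intercept
    expect_lt(abs(inverse_predict(curve, fwd) - conc) / conc, 1e-9)
  }
  expect_equal(inverse_predict(curve, 220.20), 100,
               tolerance = 1e-4)  # 10^(94.02 / 47.01)
  bad <- suppressWarnings(fit_calibration(generate_calibration_dataset(
    c(5, 10, 25), 2, slope = -5, intercept = 150)))
  expect_error(inverse_predict(bad, 140), class = "fp_unusable_curve")
})

test_that("out-of-range predictions are flagged, not rejected", {
  curve <- paper_curve()
  curve$range_low <- 5; curve$range_high <- 100
  expect_warning(v <- inverse_predict(curve, curve$intercept),
                 "working range")
  expect_equal(v, 1, tolerance = 1e-9)
  q <- suppressWarnings(quantify_sample(curve, curve$intercept,
                                        sample_prep(2.5, 10)))
  expect_false(q$in_range)
})

test_that("quantification applies the prep dilution arithmetic", {
  curve <- paper_curve()
  i10 <- curve$slope * log10(10) + curve$intercept
  q <- quantify_sample(curve, i10, sample_prep(2.5, 10))
  expect_equal(q$extract_concentration, 10, tolerance = 1e-9)
  expect_equal(q$food_concentration, 40, tolerance = 1e-9)

  # identical replicates: zero CV
  q2 <- quantify_sample(curve, rep(i10, 4), sample_prep(2.5, 10))
  expect_equal(q2$cv_percent, 0)

  # replicates equivalent to {36, 40, 44} ug/g with the same prep
  ints <- curve$slope * log10(c(36, 40, 44) / 4) + curve$intercept
  q3 <- quantify_sample(curve, ints, sample_prep(2.5, 10))
  expect_equal(q3$food_concentration, 40, tolerance = 1e-9)
  expect_equal(q3$cv_percent, 100 * sd(c(36, 40, 44)) / 40, tolerance = 1e-9)

  expect_error(quantify_sample(curve, numeric(0), sample_prep(2.5, 10)),
               class = "fp_invalid_input")
})

test_that("quantification scales linearly with the dilution factors", {
  curve <- paper_curve()
  ints <- curve$slope * log10(c(8, 10, 12)) + curve$intercept
  base <- quantify_sample(curve, ints, sample_prep(2.5, 10))
  dil <- quantify_sample(curve, ints, sample_prep(2.5, 10, extra_dilution = 4))
  expect_equal(dil$food_concentration, 4 * base$food_concentration)
  vol <- quantify_sample(curve, ints, sample_prep(2.5, 30))
  expect_equal(vol$food_concentration, 3 * base$food_concentration)
  mass <- quantify_sample(curve, ints, sample_prep(5, 10))
  expect_equal(mass$food_concentration, base$food_concentration / 2)
})

test_that("intensity-space averaging is available as an option", {
  curve <- paper_curve()
  ints <- curve$slope * log10(c(5, 50)) + curve$intercept
  qc <- quantify_sample(curve, ints, sample_prep(2.5, 10))
  qi <- quantify_sample(curve, ints, sample_prep(2.5, 10),
                        average = "intensity")
  expect_equal(qc$extract_concentration, mean(c(5, 50)))
  # geometric-style mean through the log curve: 10^mean(log10 c)
  expect_equal(qi$extract_concentration, 10^mean(log10(c(5, 50))),
               tolerance = 1e-9)
})

test_that("curve JSON and input files round-trip", {
  curve <- paper_curve()
  curve$range_low <- 5; curve$range_high <- 100; curve$lod <- 3.7
  curve$grayscale_method <- "unweighted_mean"
  tmp <- withr::local_tempfile(fileext = ".json")
  write_calibration_json(curve, tmp)
  back <- read_calibration_json(tmp)
  expect_equal(back$slope, curve$slope)
  expect_equal(back$intercept, curve$intercept)
  expect_equal(back$range_high, 100)
  expect_equal(back$lod, 3.7)
  expect_equal(back$grayscale_method, "unweighted_mean")

  csv <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(concentration_ug_per_ml = c(5, 5, 10),
                       intensity = c(159, 160, 173)), csv, row.names = FALSE)
  st <- read_standards_csv(csv)
  expect_equal(st$concentration, c(5, 5, 10))
  expect_equal(st$intensity, c(159, 160, 173))

  yml <- withr::local_tempfile(lines = c("sample_mass_g: 2.5",
                                         "extraction_volume_ml: 10"))
  prep <- read_prep_yaml(yml)
  expect_equal(prep$extraction_volume_ml, 10)
  expect_equal(prep$extra_dilution, 1)
  expect_equal(prep$deposition_volume_ul, 5)
})

test_that("standards CSVs can reference images with ROIs", {
  dir <- withr::local_tempdir()
  manifest <- simulate_spot_images(dir, c(10, 50), reps = 2, noise_sd = 0,
                                   seed = 5)
  df <- read.csv(manifest, stringsAsFactors = FALSE)
  st <- read_standards_csv(local({
    p <- file.path(dir, "standards.csv")
    write.csv(df, p, row.names = FALSE)
    p
  }))
  expect_equal(nrow(st), 4)
  curvepts <- 47.01 * log10(st$concentration) + 126.18
  expect_true(all(abs(st$intensity - curvepts) < 1))
})
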