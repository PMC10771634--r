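test_that("TUG duration is frames over rate", {
  expect_equal(tug_duration(300, 20), 15)
  expect_equal(tug_duration(1, 20), 0.05)
  expect_equal(tug_duration(240, 20), tug_duration(480, 40))
  expect_error(tug_duration(10, 0), class = "tug_parameter_error")
})

test_that("vertical velocity is the signed rate of shoulder-center change", {
  expect_equal(vertical_velocity(0.9, 1.3, 0, 2), 0.2)
  expect_equal(vertical_velocity(1.1, 1.1, 0, 3), 0)
  expect_equal(vertical_velocity(1.3, 0.9, 0, 2), -0.2)
  expect_error(vertical_velocity(1, 2, 5, 5), class = "tug_parameter_error")
})

test_that("coefficient of variation matches its closed form", {
  expect_equal(coefficient_of_variation(c(5, 5, 5, 5)), 0)
  expect_equal(coefficient_of_variation(c(2, 4)), sqrt(2) / 3 * 100,
               tolerance = 1e-12)
  x <- c(1.2, 3.4, 2.2, 5.1)
  expect_equal(coefficient_of_variation(x * 7),
               coefficient_of_variation(x), tolerance = 1e-12)
  expect_error(coefficient_of_variation(c(3)), class = "tug_length_error")
  expect_error(coefficient_of_variation(c(-1, 1)),
               class = "tug_undefined_cov_error")
})

test_that("similarity index matches its closed form and is symmetric", {
  expect_equal(similarity_index(0.42, 0.42), 1)
  expect_equal(similarity_index(0.4, 0.5), 0.8)
  expect_equal(similarity_index(0.5, 0.4), similarity_index(0.4, 0.5))
  set.seed(2)
  a <- runif(20, 0.1, 2); b <- runif(20, 0.1, 2)
  si <- similarity_index(a, b)
  expect_true(all(si >= 0 & si <= 1))
  expect_error(similarity_index(0, 1), class = "tug_parameter_error")
})

test_that("the feature catalog has the advertised structure", {
  fn <- feature_names()
  expect_length(fn, 61)
  expect_false(anyDuplicated(fn) > 0)
  expect_length(walking_feature_names(), 54)
  expect_length(grep("_variability$", fn), 16)
  expect_length(grep("_mean$", fn), 16)
  expect_length(grep("_median$", fn), 16)
  # the five non-triple walking quantities
  others <- setdiff(walking_feature_names(),
                    c(grep("_mean$|_variability$|_median$", fn, value = TRUE),
                      "walking_duration_s"))
  expect_setequal(others, c("gait_velocity_mps", "step_number",
                            "step_frequency_spm", "stride_number",
                            "stride_frequency_spm"))
})

test_that("extraction returns exactly the 61 named features", {
  fv <- default_sim()$features
  expect_length(fv, 61)
  expect_identical(names(fv), feature_names())
  expect_true(all(is.finite(fv)))
  # non-negativity of times and CoVs, boundedness of similarity features
  expect_true(all(fv[grep("_s$|duration", names(fv))] >= 0))
  expect_true(all(fv[grep("_variability$", names(fv))] >= 0))
  sym <- fv[grep("symmetry_mean|symmetry_median|regularity_mean|regularity_median",
                 names(fv))]
  expect_true(all(sym >= 0 & sym <= 1))
})

test_that("extraction recovers the generating parameters", {
  s <- default_sim()
  fv <- s$features
  p <- s$gt$params
  rel <- function(a, b) abs(a - b) / b
  expect_lt(rel(fv[["gait_velocity_mps"]], p$gait_speed_mps), 0.10)
  expect_lt(rel(fv[["step_length_mean"]], 100 * p$step_length_m), 0.10)
  expect_lt(rel(fv[["step_frequency_spm"]], p$cadence_steps_per_min), 0.10)
  expect_lt(rel(fv[["sit_to_stand_duration_s"]], p$sit_to_stand_s), 0.12)
  expect_lt(rel(fv[["turning_duration_s"]], p$turning_s), 0.12)
  expect_equal(fv[["step_number"]], 2 * p$n_steps_per_leg)
})

test_that("symmetric, low-noise gait scores near-perfect symmetry", {
  sim <- generate_recording(tug_profile(left_right_asymmetry = 0,
                                        noise_sd_m = 0.001), seed = 55)
  rec <- filter_recording(sim$recording)
  fv <- extract_features(rec)
  expect_gt(fv[["step_length_symmetry_mean"]], 0.9)
  expect_lt(fv[["step_length_variability"]], 10)
  # asymmetric gait scores its designed symmetry index
  sim2 <- generate_recording(tug_profile(left_right_asymmetry = 0.25,
                                         noise_sd_m = 0.001), seed = 55)
  fv2 <- extract_features(filter_recording(sim2$recording))
  expect_equal(fv2[["step_length_symmetry_mean"]], 0.75, tolerance = 0.08)
})

test_that("feature extraction is deterministic and translation invariant", {
  s <- default_sim()
  again <- extract_features(s$rec, s$seg)
  expect_identical(unclass(s$features), unclass(again))
  shifted <- s$rec
  shifted$xyz <- shifted$xyz + 0.5
  fv2 <- extract_features(shifted)
  expect_equal(unclass(fv2), unclass(s$features), tolerance = 1e-6)
})
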