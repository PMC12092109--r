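test_that("generation is deterministic given the spec seed", {
  spec <- synthetic_series_spec(30, 20, 4, 0.92, tp_true = 10,
                                noise_rel = 0.03, seed = 99)
  a <- generate_series(spec)
  b <- generate_series(spec)
  expect_identical(a$records, b$records)
  # a different seed perturbs the measurements
  spec2 <- synthetic_series_spec(30, 20, 4, 0.92, tp_true = 10,
                                 noise_rel = 0.03, seed = 100)
  expect_false(identical(generate_series(spec2)$records, a$records))
})

test_that("generation does not disturb the caller's RNG stream", {
  spec <- synthetic_series_spec(30, 20, 4, 0.92, tp_true = 10,
                                noise_rel = 0.03, seed = 99)
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  generate_series(spec)
  expect_identical(runif(1), before)
})

test_that("invalid specs are rejected", {
  expect_error(synthetic_series_spec(2, 20, 4, 0.9, 1), "n_vertebrae")
  expect_error(synthetic_series_spec(30, 20, 4, 0.9, 30), "tp_true")
  expect_error(synthetic_series_spec(30, 20, 4, 1.0, 10), "height_taper")
  expect_error(synthetic_series_spec(30, 20, 25, 0.9, 10), "below")
  expect_error(synthetic_series_spec(30, 20, 4, 0.9, 10,
                                     missing_positions = 30), "interior")
})

test_that("the noiseless crossing lands exactly on tp_true everywhere", {
  n <- 20
  for (tp in 2:(n - 1)) {
    spec <- synthetic_series_spec(n, 20, 5, 0.9, tp_true = tp)
    vs <- generate_series(spec)
    expect_equal(find_transition_point(vs), tp)
    # strictness margins: the previous vertebra is still below 1
    prof <- tail_profile(vs)
    expect_lt(prof$ratio[tp - 1], 1)
    expect_gt(prof$ratio[tp], 1)
  }
})

test_that("pipeline output matches the closed-form ground truth", {
  spec <- synthetic_series_spec(35, 22, 6, 0.93, tp_true = 14)
  tissue <- tissue_model(0.359, 0.057)
  cfg <- scenario_config("custom", v_whole_m_s = 3, v_whip_m_s = 12,
                         efficiency = 0.85)
  gt <- ground_truth(spec, density_kg_per_litre = 0.8, tissue = tissue,
                     config = cfg)

  vs <- generate_series(spec)
  tp <- find_transition_point(vs)
  seg <- segment_whip(vs, tp)
  mm <- tail_mass(vs, seg, tissue = tissue)
  en <- evaluate_scenarios(mm, cfg)

  expect_equal(tp, gt$tp_position)
  expect_equal(seg$total_length_cm, gt$total_length_cm, tolerance = 1e-9)
  expect_equal(seg$whip_length_cm, gt$whip_length_cm, tolerance = 1e-9)
  expect_equal(seg$whip_fraction, gt$whip_fraction, tolerance = 1e-9)
  expect_equal(mm$whole$mass_kg, gt$whole_mass_kg, tolerance = 1e-9)
  expect_equal(mm$whip$mass_kg, gt$whip_mass_kg, tolerance = 1e-9)
  expect_equal(en$whole_tail_J, gt$whole_tail_J, tolerance = 1e-9)
  expect_equal(en$whip_transferred_J, gt$whip_transferred_J, tolerance = 1e-9)
  expect_equal(en$quick_whiplash_J, gt$quick_whiplash_J, tolerance = 1e-9)

  # soft/bone mass ratio is exactly the squared factor
  gt_bone <- ground_truth(spec, tissue = NULL, config = cfg)
  expect_identical(gt$whole_mass_kg / gt_bone$whole_mass_kg,
                   tissue$radius_scaling_factor^2)
})

test_that("imputation error on noiseless gaps is bounded by the curvature", {
  spec <- synthetic_series_spec(30, 20, 5, 0.92, tp_true = 12,
                                missing_positions = c(7L, 18L))
  prof <- caudawhip:::synthetic_profile(spec)
  vs <- generate_series(spec)
  filled <- impute_missing(vs)
  for (gap in spec$missing_positions) {
    got <- filled$records$length_cm[filled$records$position == gap]
    truth <- prof$length_cm[gap]
    second_diff <- abs(prof$length_cm[gap + 1] - 2 * prof$length_cm[gap] +
                         prof$length_cm[gap - 1])
    expect_lte(abs(got - truth), second_diff)
  }
})

test_that("generated series survive the file roundtrip losslessly", {
  spec <- synthetic_series_spec(25, 18, 4, 0.91, tp_true = 9,
                                noise_rel = 0.02,
                                missing_positions = 5L, seed = 11)
  vs <- generate_series(spec)
  f <- tempfile(fileext = ".csv")
  write_measurements(vs, f)
  back <- read_measurements(f)
  expect_equal(back$records$length_cm, vs$records$length_cm)
  expect_equal(back$records$height_cm, vs$records$height_cm)
  expect_identical(back$missing_positions, vs$missing_positions)
})

test_that("the reference-shaped spec reproduces the headline geometry", {
  spec <- vienna_like_spec()
  vs <- generate_series(spec)
  expect_equal(total_length(vs, include_imputed = FALSE), 196,
               tolerance = 1e-8)
  expect_identical(vs$missing_positions, c(4L, 9L, 27L, 37L))

  filled <- impute_missing(vs)
  suppressWarnings(tp <- find_transition_point(filled))
  expect_equal(tp, 25L)
  seg <- segment_whip(filled, tp)
  mm_bone <- tail_mass(filled, seg, include_imputed = FALSE)
  mm_full <- tail_mass(filled, seg)
  # bone-only cone mass lands within 5% of the published 26.5 kg
  expect_lt(abs(mm_bone$whole$mass_kg - 26.5) / 26.5, 0.05)
  expect_lt(abs(mm_full$whole$mass_kg - 28.4) / 28.4, 0.05)
  # whip mass has the published order of magnitude (~0.3 kg)
  expect_gt(mm_full$whip$mass_kg, 0.03)
  expect_lt(mm_full$whip$mass_kg, 3)
})
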