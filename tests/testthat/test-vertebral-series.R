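test_that("delimited measurement files parse into ordered series", {
  f <- write_series_csv(c("position,length_cm,height_cm",
                          "1,10,25", "3,8,15", "2,9,20"))
  vs <- read_measurements(f)
  expect_s3_class(vs, "vertebral_series")
  expect_equal(vs$records$position, 1:3)
  expect_equal(vs$records$length_cm, c(10, 9, 8))
  expect_equal(vs$records$height_cm, c(25, 20, 15))
  expect_true(all(vs$records$preserved))
  expect_length(vs$missing_positions, 0)

  # tab separation is auto-detected
  ft <- write_series_csv(c("position\tlength_cm\theight_cm",
                           "1\t10\t25", "2\t9\t20"))
  expect_equal(read_measurements(ft)$records$length_cm, c(10, 9))

  # arbitrary column names resolve through the schema mapping
  fs <- write_series_csv(c("Ca,centrum (cm),total height (cm)",
                           "1,10,25", "2,9,20"))
  vs2 <- read_measurements(fs, schema = c(position = "Ca",
                                          length = "centrum (cm)",
                                          height = "total height (cm)"))
  expect_equal(vs2$records$height_cm, c(25, 20))
})

test_that("blank measurements become missing positions, not records", {
  f <- write_series_csv(c("position,length_cm,height_cm",
                          "1,10,25", "2,9,20", "3,8,15", "4,,", "5,7,12"))
  vs <- read_measurements(f)
  expect_equal(vs$missing_positions, 4L)
  expect_equal(vs$records$position, c(1:3, 5L))
})

test_that("malformed measurement files fail with informative errors", {
  f1 <- write_series_csv(c("position,length_cm", "1,10"))
  expect_error(read_measurements(f1), "height_cm")

  f2 <- write_series_csv(c("position,length_cm,height_cm",
                           "1,10,25", "2,-3,20"))
  expect_error(read_measurements(f2), "row\\(s\\) 2")

  f3 <- write_series_csv(c("position,length_cm,height_cm",
                           "1,10,25", "1,9,20"))
  expect_error(read_measurements(f3), "duplicate")

  # comma decimals are rejected, not silently misparsed
  f4 <- write_series_csv(c("position\tlength_cm\theight_cm",
                           "1\t10,5\t25"))
  expect_error(read_measurements(f4), "decimal")

  expect_error(read_measurements(tempfile()), "not found")
})

test_that("series validation enforces the record invariants", {
  expect_error(make_series(c(10, 9), c(25, 20), positions = c(0, 1)), ">= 1")
  expect_error(make_series(c(10, 9), c(25, 20), positions = c(2, 2)),
               "duplicate")
  expect_error(make_series(c(10, -9), c(25, 20)), "non-positive")
  expect_error(vertebral_series(
    data.frame(position = 1, length_cm = 1, height_cm = 1,
               preserved = TRUE, imputed = TRUE)),
    "both preserved and imputed")
  expect_error(make_series(c(10, 9), c(25, 20), missing = 1L), "overlap")
})

test_that("total length sums centrum lengths with no spacing allowance", {
  vs <- make_series(c(10, 9, 8), c(25, 20, 15))
  expect_identical(total_length(vs), 27)

  # imputed records only count when asked for
  gap <- make_series(c(5, 5, 7), c(12, 11, 9), positions = c(1, 2, 4),
                     missing = 3L)
  filled <- impute_missing(gap)
  expect_equal(total_length(filled, include_imputed = FALSE), 17)
  expect_equal(total_length(filled, include_imputed = TRUE), 23)
  expect_gte(total_length(filled, TRUE), total_length(filled, FALSE))
})

test_that("profiles report the length/height ratio in position order", {
  vs <- make_series(10, 25)
  p <- tail_profile(vs)
  expect_equal(p$ratio, 0.4)

  # monotone generator heights stay monotone in the profile
  syn <- tapering_series()
  prof <- tail_profile(syn)
  expect_true(all(diff(prof$height_cm) < 0))
  expect_equal(prof$position, sort(prof$position))
})

test_that("write -> read roundtrips preserve every field", {
  gap <- make_series(c(5, 5, 7, 6), c(12, 11, 9, 8),
                     positions = c(1, 2, 4, 5), missing = 3L)
  filled <- impute_missing(gap)
  f <- tempfile(fileext = ".csv")
  write_measurements(filled, f)
  back <- read_measurements(f, specimen_id = filled$specimen_id)
  expect_identical(back$records$position, filled$records$position)
  expect_identical(back$records$length_cm, filled$records$length_cm)
  expect_identical(back$records$height_cm, filled$records$height_cm)
  expect_identical(back$records$preserved, filled$records$preserved)
  expect_identical(back$records$imputed, filled$records$imputed)

  # a series with an open gap roundtrips the gap too
  f2 <- tempfile(fileext = ".csv")
  write_measurements(gap, f2)
  back2 <- read_measurements(f2)
  expect_identical(back2$missing_positions, 3L)
})
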