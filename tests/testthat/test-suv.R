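meta_no_gap <- function(activity = 185, weight = 70)
  acquisition_meta(activity, weight, "2020-01-01T10:00:00",
                   "2020-01-01T10:00:00")

test_that("decay factor matches hand-evaluated values", {
  expect_identical(decay_factor(0, 109.77), 1)
  expect_identical(decay_factor(109.77, 109.77), 2)
  # the cohort-scale inter-scanner gap of ~56 minutes
  expect_equal(decay_factor(55.7, 109.77), 2^(55.7 / 109.77))
  expect_equal(decay_factor(55.7, 109.77), 1.4216, tolerance = 1e-4)
  expect_error(decay_factor(Inf), "finite")
  expect_error(decay_factor(10, -1), "positive")
})

test_that("decay factor composes and round-trips", {
  set.seed(3)
  for (i in 1:20) {
    a <- runif(1, -300, 300); b <- runif(1, -300, 300)
    hl <- runif(1, 10, 200)
    expect_equal(decay_factor(a + b, hl),
                 decay_factor(a, hl) * decay_factor(b, hl),
                 tolerance = 1e-12)
    expect_equal(decay_factor(a, hl) * decay_factor(-a, hl), 1,
                 tolerance = 1e-12)
  }
})

test_that("body-weight SUV normalizes activity concentration", {
  meta <- meta_no_gap()
  conc <- meta$injected_activity_MBq * 1000 / (meta$patient_weight_kg * 1000)
  act <- image_volume(array(conc, c(4, 4, 4)), unit = "activity_kBq_per_mL")
  suv <- compute_suv(act, meta)
  expect_equal(suv$data, array(1, c(4, 4, 4)))
  expect_identical(suv$unit, "SUV")

  act10 <- image_volume(array(10, c(2, 2, 2)), unit = "activity_kBq_per_mL")
  expect_equal(compute_suv(act10, meta_no_gap(185, 70))$data[1],
               10 / (185000 / 70000))
  # linear in weight
  expect_equal(compute_suv(act10, meta_no_gap(185, 140))$data[1],
               2 * compute_suv(act10, meta_no_gap(185, 70))$data[1])
})

test_that("injected activity is decay-corrected to acquisition time", {
  # one half-life between injection and acquisition halves the available
  # activity, doubling every SUV
  m0 <- meta_no_gap()
  m1 <- acquisition_meta(185, 70, "2020-01-01T10:00:00",
                         "2020-01-01T11:49:46.2", half_life_min = 109.77)
  expect_equal(activity_at_acquisition_MBq(m1), 185 / 2, tolerance = 1e-4)
  act <- image_volume(array(10, c(2, 2, 2)), unit = "activity_kBq_per_mL")
  expect_equal(compute_suv(act, m1)$data[1],
               2 * compute_suv(act, m0)$data[1], tolerance = 1e-4)
})

test_that("unit and validity guards on SUV computation", {
  suv_in <- image_volume(array(1, c(2, 2, 2)), unit = "SUV")
  expect_error(compute_suv(suv_in, meta_no_gap()), "kBq/mL")
  expect_error(acquisition_meta(-5, 70, "2020-01-01T10:00:00",
                                "2020-01-01T10:30:00"), "positive")
  expect_error(acquisition_meta(185, 70, "2020-01-01T10:00:00",
                                "2020-01-01T09:00:00"), "precedes")
})

test_that("sphere ROI follows the center-inclusion rule", {
  grid <- image_volume(array(0, c(21, 21, 21)))
  # degenerate: diameter below voxel size centered on a voxel center
  roi <- place_sphere_roi(grid, c(10, 10, 10), diameter_mm = 0.5)
  expect_identical(sum(roi$data), 1L)

  # 10 mm sphere on a 1 mm grid vs brute-force center counting
  roi10 <- place_sphere_roi(grid, c(10, 10, 10), diameter_mm = 10)
  ax <- (0:20)
  d2 <- outer(outer((ax - 10)^2, (ax - 10)^2, "+"), (ax - 10)^2, "+")
  expect_identical(sum(roi10$data), sum(d2 <= 25))
  # analytic sphere volume within discretization error
  expect_equal(mask_volume_cc(roi10), 4 / 3 * pi * 0.5^3,
               tolerance = 0.05)
  expect_error(place_sphere_roi(grid, c(500, 500, 500), 10), "outside")
})

test_that("ROI statistics equal the brute-force loop", {
  expect_equal(
    roi_stats(image_volume(array(2, c(3, 3, 3))),
              mk_mask(array(TRUE, c(3, 3, 3))))[c("mean", "max")],
    list(mean = 2, max = 2))
  two <- array(0, c(3, 1, 1)); two[1] <- 1; two[3] <- 3
  roi <- mk_mask(array(c(TRUE, FALSE, TRUE), c(3, 1, 1)))
  st <- roi_stats(image_volume(two), roi)
  expect_equal(st$mean, 2)
  expect_equal(st$max, 3)
  expect_identical(st$voxel_count, 2L)

  set.seed(5)
  img <- image_volume(array(rnorm(20^3), c(20, 20, 20)))
  roi <- rand_mask()
  st <- roi_stats(img, roi)
  vals <- img$data[roi$data]
  expect_equal(st$mean, mean(vals))
  expect_equal(st$max, max(vals))
  expect_error(roi_stats(img, mk_mask(array(FALSE, c(20, 20, 20)))), "empty")
})

test_that("acquisition metadata round-trips through its JSON sidecar", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(injected_activity_MBq = 185,
                            patient_weight_kg = 70,
                            t_injection = "2020-01-01T10:00:00",
                            t_acquisition = "2020-01-01T10:30:00"),
                       f, auto_unbox = TRUE)
  m <- read_acquisition_meta(f)
  expect_equal(m$injected_activity_MBq, 185)
  expect_equal(m$half_life_min, 109.77)
})
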