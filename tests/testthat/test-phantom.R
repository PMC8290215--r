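test_that("phantom generation is deterministic; seed touches only noise", {
  spec <- small_spec(seed = 7)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$suv$data, b$suv$data)
  expect_identical(a$masks$gtv$data, b$masks$gtv$data)
  c2 <- generate_phantom(small_spec(seed = 8))
  expect_false(identical(a$suv$data, c2$suv$data))
  for (nm in names(a$masks))
    expect_identical(a$masks[[nm]]$data, c2$masks[[nm]]$data)
})

test_that("step-profile phantom is recovered exactly at any sub-peak ratio", {
  spec <- small_noiseless_spec(
    tumor = list(offset_mm = c(24, -14, 4), enhancement_radius_mm = 9,
                 infiltration_radius_mm = 16, peak_tn_ratio = 3.0,
                 profile = "step"))
  ph <- generate_phantom(spec)
  for (ratio in c(1.7, 2.0, 3.0)) {
    btv <- segment_btv(ph$suv, tn_threshold(ratio, spec$background_suv),
                       ph$masks$brain,
                       exclusions = list(ph$masks$basal_ganglia))
    expect_equal(dice(btv, true_btv_mask(spec, ratio)), 1.0)
  }
})

test_that("analytic iso-radius formulas match the sampled profiles", {
  spec <- small_noiseless_spec()
  # linear: R (p - t) / (p - 1) with p = 3, R = 20
  expect_equal(tn_iso_radius(spec, 1.7), 20 * (3 - 1.7) / 2)
  expect_equal(tn_iso_radius(spec, 1.7), 13.0)
  expect_equal(tn_iso_radius(spec, 2.0), 10.0)
  expect_equal(true_btv_cc(spec, 1.7), 4 / 3 * pi * 1.3^3)
  # ground-truth masks nest with decreasing ratio
  m20 <- true_btv_mask(spec, 2.0)
  m17 <- true_btv_mask(spec, 1.7)
  expect_true(all(!m20$data | m17$data))
  expect_error(tn_iso_radius(spec, 1.0), "ratio")
  expect_error(tn_iso_radius(spec, 3.5), "ratio")
})

test_that("a tumor protruding from the brain is rejected", {
  spec <- small_spec(tumor = list(offset_mm = c(45, 0, 0),
                                  enhancement_radius_mm = 9,
                                  infiltration_radius_mm = 20,
                                  peak_tn_ratio = 3.0,
                                  profile = "radial_linear"))
  expect_error(generate_phantom(spec), "outside the brain")
})

test_that("invalid phantom specs are rejected at construction", {
  expect_error(small_spec(tumor = list(offset_mm = c(0, 0, 0),
                                       enhancement_radius_mm = 20,
                                       infiltration_radius_mm = 10,
                                       peak_tn_ratio = 3,
                                       profile = "step")), "infiltration")
  expect_error(small_spec(tumor = list(offset_mm = c(0, 0, 0),
                                       enhancement_radius_mm = 5,
                                       infiltration_radius_mm = 10,
                                       peak_tn_ratio = 1,
                                       profile = "step")), "peak")
  expect_error(small_spec(noise_sigma_fraction = -0.1), "non-negative")
})

test_that("recurrence blobs hit their designed outside fractions", {
  ph <- generate_phantom(small_noiseless_spec())
  ref <- ph$masks$gtv
  vox_frac <- 1 / 500  # generous: blobs here have >500 voxels

  rec0 <- make_recurrence(ref, 0, radius_mm = 6)
  expect_equal(attr(rec0, "achieved_outside_fraction"), 0)
  expect_true(all(!rec0$data | ref$data))

  rec1 <- make_recurrence(ref, 1, radius_mm = 6)
  expect_equal(attr(rec1, "achieved_outside_fraction"), 1)
  expect_false(any(rec1$data & ref$data))

  rec3 <- make_recurrence(ref, 0.3, radius_mm = 6)
  ach <- attr(rec3, "achieved_outside_fraction")
  expect_true(abs(ach - 0.3) <= 1 / sum(rec3$data))
  # reported analysis equals the bookkeeping exactly
  out <- recurrence_analysis(rec3, list(REF = ref))
  expect_equal(unname(out["REF"]), ach)
})

test_that("an infeasible containment request errors", {
  thin <- mk_mask(array(rep(c(TRUE, rep(FALSE, 9)), 100), c(10, 10, 10)))
  expect_error(make_recurrence(thin, 0, radius_mm = 8), "infeasible")
})

test_that("phantom dose covers the PTV at prescription", {
  ph <- generate_phantom(small_noiseless_spec())
  cov <- dose_coverage(ph$dose, ph$masks$ptv, ph$spec$prescription_Gy)
  expect_equal(cov$covered_fraction, 1)
  # dose falls to zero beyond the falloff distance
  expect_equal(min(ph$dose$data), 0)
  expect_equal(max(ph$dose$data), ph$spec$prescription_Gy)
})
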