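test_that("surface extraction matches the neighbour-check oracle", {
  single <- mk_mask(array(c(rep(FALSE, 13), TRUE, rep(FALSE, 13)), c(3, 3, 3)))
  expect_identical(surface_voxels(single)$data, single$data)

  block <- array(FALSE, c(5, 5, 5)); block[2:4, 2:4, 2:4] <- TRUE
  surf <- surface_voxels(mk_mask(block))
  expect_identical(sum(surf$data), 26L)  # all but the center

  set.seed(41)
  for (i in 1:5) {
    m <- rand_mask(c(15, 15, 15), spacing = c(1, 1.5, 2))
    expect_identical(surface_voxels(m)$data, oracle_surface(m))
  }
})

test_that("directed HD95 handles the degenerate cases", {
  set.seed(43)
  a <- rand_mask()
  expect_equal(hd95_directed(a, a), 0)

  d <- c(10, 10, 10)
  p <- array(FALSE, d); p[2, 2, 2] <- TRUE
  q <- array(FALSE, d); q[5, 2, 2] <- TRUE  # 3 mm apart on a 1 mm grid
  expect_equal(hd95_directed(mk_mask(p), mk_mask(q)), 3)
  expect_error(hd95_directed(mk_mask(p), mk_mask(array(FALSE, d))),
               "non-empty")
})

test_that("HD95 and SVC agree with all-pairs brute force on random masks", {
  set.seed(45)
  for (i in 1:15) {
    sp <- sample(list(c(1, 1, 1), c(1, 1.5, 2), c(2, 2, 2)), 1)[[1]]
    a <- rand_mask(c(18, 18, 18), spacing = sp)
    b <- rand_mask(c(18, 18, 18), spacing = sp)
    expect_equal(hd95_directed(a, b), oracle_hd95(a, b), tolerance = 1e-9)
    expect_equal(svc_distances(a, b), oracle_svc(a, b), tolerance = 1e-9)
  }
})

test_that("HD95 is directed and monotone in the percentile", {
  set.seed(47)
  a <- rand_mask(); b <- rand_mask()
  p50 <- hd95_directed(a, b, percentile = 50)
  p95 <- hd95_directed(a, b, percentile = 95)
  p100 <- hd95_directed(a, b, percentile = 100)
  expect_true(p50 <= p95 && p95 <= p100)
})

test_that("distances are invariant under a common voxel translation", {
  set.seed(49)
  d <- c(20, 20, 20)
  # content embedded away from the grid boundary so the translated masks
  # carry identical voxel patterns
  embed <- function(small, at) {
    out <- array(FALSE, d)
    ds <- dim(small$data)
    out[at[1]:(at[1] + ds[1] - 1), at[2]:(at[2] + ds[2] - 1),
        at[3]:(at[3] + ds[3] - 1)] <- small$data
    mk_mask(out)
  }
  a_small <- rand_mask(c(12, 12, 12), r_range = c(2, 4))
  b_small <- rand_mask(c(12, 12, 12), r_range = c(2, 4))
  by <- c(2, 1, 3)
  expect_equal(hd95_directed(embed(a_small, c(2, 2, 2) + by),
                             embed(b_small, c(2, 2, 2) + by)),
               hd95_directed(embed(a_small, c(2, 2, 2)),
                             embed(b_small, c(2, 2, 2))),
               tolerance = 1e-12)
  expect_equal(svc_distances(embed(a_small, c(2, 2, 2) + by),
                             embed(b_small, c(2, 2, 2) + by)),
               svc_distances(embed(a_small, c(2, 2, 2)),
                             embed(b_small, c(2, 2, 2))),
               tolerance = 1e-12)
})

test_that("SVC distances cover the subset and one-voxel cases", {
  d <- c(12, 12, 12)
  g <- array(FALSE, d); g[4:8, 4:8, 4:8] <- TRUE
  gtv <- mk_mask(g)
  inside <- array(FALSE, d); inside[5:7, 5:7, 5:7] <- TRUE
  expect_equal(svc_distances(gtv, mk_mask(inside)),
               c(max_mm = 0, mean_mm = 0))

  g1 <- array(FALSE, d); g1[3, 3, 3] <- TRUE
  b1 <- g1; b1[7, 3, 3] <- TRUE  # extra voxel 4 mm away
  expect_equal(svc_distances(mk_mask(g1), mk_mask(b1)),
               c(max_mm = 4, mean_mm = 4))
  expect_error(svc_distances(mk_mask(array(FALSE, d)), mk_mask(b1)), "empty")
})

test_that("overlap decomposition conserves volume exactly", {
  set.seed(51)
  for (i in 1:10) {
    btv <- rand_mask(spacing = c(1, 2, 1.5))
    gtv <- rand_mask(spacing = c(1, 2, 1.5))
    dec <- overlap_decomposition(btv, gtv)
    expect_identical(dec$within_cc + dec$outside_cc, dec$total_cc)
    expect_true(dec$outside_fraction >= 0 && dec$outside_fraction <= 1)
  }
  a <- rand_mask()
  expect_equal(overlap_decomposition(a, a)$outside_fraction, 0)
  dis_a <- mk_mask(array(c(TRUE, rep(FALSE, 7)), c(2, 2, 2)))
  dis_b <- mk_mask(array(c(FALSE, TRUE, rep(FALSE, 6)), c(2, 2, 2)))
  expect_equal(overlap_decomposition(dis_a, dis_b)$outside_fraction, 1)
})

test_that("decomposition reproduces a printed-table style fraction", {
  # 967 BTV voxels of 0.1 cc with 681 outside: 96.7 cc total, 68.1 outside
  d <- c(20, 10, 10)
  btv <- array(FALSE, d); btv[seq_len(967)] <- TRUE
  gtv <- array(FALSE, d); gtv[682:2000] <- TRUE   # first 681 outside GTV
  dec <- overlap_decomposition(mk_mask(btv, spacing = c(10, 5, 2)),
                               mk_mask(gtv, spacing = c(10, 5, 2)))
  expect_equal(dec$total_cc, 96.7)
  expect_equal(dec$outside_cc, 68.1)
  expect_equal(dec$outside_fraction, 68.1 / 96.7, tolerance = 1e-12)
})

test_that("dose coverage applies the inclusive isodose rule", {
  d <- c(10, 10, 10)
  msk <- mk_mask(array(TRUE, d))
  uniform <- image_volume(array(60, d), unit = "Gy")
  expect_equal(dose_coverage(uniform, msk, 60)$covered_fraction, 1)
  expect_equal(dose_coverage(image_volume(array(0, d), unit = "Gy"),
                             msk, 60)$covered_fraction, 0)
  # half at exactly the 57 Gy level (inclusive), half below
  dd <- array(50, d); dd[1:5, , ] <- 57
  cov <- dose_coverage(image_volume(dd, unit = "Gy"), msk, 60)
  expect_equal(cov$covered_fraction, 0.5)
  expect_equal(cov$iso_level_Gy, 57)
  not_gy <- image_volume(array(60, d), unit = "SUV")
  expect_error(dose_coverage(not_gy, msk, 60), "Gy")
})

test_that("recurrence fractions cover the containment extremes", {
  d <- c(12, 12, 12)
  rec <- array(FALSE, d); rec[5:7, 5:7, 5:7] <- TRUE
  ptv <- array(FALSE, d); ptv[3:9, 3:9, 3:9] <- TRUE
  far <- array(FALSE, d); far[11:12, 11:12, 11:12] <- TRUE
  out <- recurrence_analysis(mk_mask(rec),
                             list(PTV = mk_mask(ptv), GTV = mk_mask(far)))
  expect_equal(unname(out["PTV"]), 0)
  expect_equal(unname(out["GTV"]), 1)
  expect_error(recurrence_analysis(mk_mask(array(FALSE, d)), list()), "empty")
})
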