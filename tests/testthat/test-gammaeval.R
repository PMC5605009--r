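slice_volume <- function(m, spacing = c(2.5, 1, 1)) {
  image_volume(array(m, dim = c(1, nrow(m), ncol(m))), spacing = spacing)
}

test_that("body ROIs are the tightest covering rectangles", {
  m <- array(FALSE, dim = c(1, 10, 12))
  m[1, 6, 8] <- TRUE  # 0-based (5, 7)
  roi <- roi_from_body(binary_mask(m), mode = "2d")
  expect_equal(length(roi$slices), 1L)
  expect_equal(roi$slices[[1]]$lo, c(5L, 7L))
  expect_equal(roi$slices[[1]]$hi, c(6L, 8L))

  full <- array(TRUE, dim = c(1, 4, 6))
  roi <- roi_from_body(binary_mask(full), mode = "2d")
  expect_equal(roi$slices[[1]]$lo, c(0L, 0L))
  expect_equal(roi$slices[[1]]$hi, c(4L, 6L))

  # L-shape occupying rows 2..5, cols 3..8 (0-based)
  L <- array(FALSE, dim = c(1, 10, 10))
  L[1, 3:6, 4] <- TRUE
  L[1, 6, 4:9] <- TRUE
  roi <- roi_from_body(binary_mask(L), mode = "2d")
  expect_equal(roi$slices[[1]]$lo, c(2L, 3L))
  expect_equal(roi$slices[[1]]$hi, c(6L, 9L))

  # 3d box; empty mask errors
  b3 <- roi_from_body(binary_mask(L), mode = "3d")
  expect_equal(b3$lo, c(0L, 2L, 3L))
  expect_equal(b3$hi, c(1L, 6L, 9L))
  expect_error(roi_from_body(binary_mask(array(FALSE, dim = c(1, 2, 2)))),
               "empty")
})

test_that("normalization is the reference dynamic range in the ROI", {
  v <- slice_volume(matrix(seq(-1000, 1000, length.out = 20), 4, 5))
  roi <- rect_roi(c(0, 0, 0), c(1, 4, 5))
  expect_equal(normalization_value(v, roi), 2000)
  crit <- gamma_criteria(3, 3)
  expect_equal(crit$dd_percent / 100 * normalization_value(v, roi), 60)

  v100 <- slice_volume(matrix(seq(0, 100, length.out = 20), 4, 5))
  expect_equal(normalization_value(v100, roi), 100)

  flat <- slice_volume(matrix(5, 4, 5))
  expect_error(normalization_value(flat, roi), "degenerate normalization")
})

test_that("identical volumes give gamma 0 and 100% pass", {
  case <- generate_case(small_spec(), 0L)
  ct <- case$reference_ct
  roi <- roi_from_body(binary_mask(case$truth$labels != 0,
                                   spacing = ct$spacing, origin = ct$origin),
                       mode = "2d")
  g <- gamma_map(ct, ct, gamma_criteria(2, 2), roi)
  expect_true(all(g$gamma[!is.na(g$gamma)] == 0))
  expect_equal(pass_rate(g), 100)
})

test_that("a uniform offset of exactly the dose criterion sits on gamma = 1", {
  ref <- matrix(0, 12, 12)
  ref[12, 12] <- 100  # fixes the dynamic range at 100
  rv <- slice_volume(ref)
  ev <- slice_volume(ref + 2)  # 2% of 100
  roi <- rect_roi(c(0, 0, 0), c(1, 12, 12))
  g <- gamma_map(rv, ev, gamma_criteria(2, 2), roi)
  expect_equal(as.vector(g$gamma[!is.na(g$gamma)]), rep(1, 144),
               tolerance = 1e-12)
})

test_that("a one-voxel edge shift under 2 mm/2% yields max gamma 0.5", {
  n <- 20; k <- 10
  ref <- matrix(0, 1, n); ref[1, k:n] <- 100
  ev <- matrix(0, 1, n); ev[1, (k + 1):n] <- 100
  rv <- slice_volume(ref, spacing = c(2.5, 1, 1))
  evv <- slice_volume(ev, spacing = c(2.5, 1, 1))
  roi <- rect_roi(c(0, 0, 0), c(1, 1, n))
  g <- gamma_map(rv, evv, gamma_criteria(2, 2, search_radius_factor = Inf),
                 roi, norm_value = 100)
  expect_equal(max(g$gamma, na.rm = TRUE), 0.5, tolerance = 1e-12)
  # the independent brute-force oracle agrees
  bf <- brute_force_gamma_2d(ref, ev, 2, 2, c(1, 1))
  expect_equal(matrix(g$gamma[1, , ], 1, n), bf, tolerance = 1e-12)
})

test_that("the search engine matches the brute-force all-pairs gamma", {
  set.seed(23)
  roi <- rect_roi(c(0, 0, 0), c(1, 24, 24))
  for (i in 1:10) {
    ref <- matrix(runif(576, 0, 100), 24, 24)
    ev <- matrix(runif(576, 0, 100), 24, 24)
    rv <- slice_volume(ref, spacing = c(2.5, 1, 1))
    evv <- slice_volume(ev, spacing = c(2.5, 1, 1))
    for (cr in list(c(3, 3), c(2, 2), c(1, 1))) {
      g <- gamma_map(rv, evv,
                     gamma_criteria(cr[1], cr[2], search_radius_factor = Inf),
                     roi, norm_value = 100)
      bf <- brute_force_gamma_2d(ref, ev, cr[1], cr[2], c(1, 1))
      expect_equal(g$gamma[1, , ], bf, tolerance = 1e-12)
    }
  }
})

test_that("tightening criteria never lowers gamma; pass rates are monotone", {
  set.seed(31)
  ref <- matrix(runif(576, 0, 100), 24, 24)
  ev <- ref + matrix(rnorm(576, 0, 3), 24, 24)
  rv <- slice_volume(ref); evv <- slice_volume(ev)
  roi <- rect_roi(c(0, 0, 0), c(1, 24, 24))
  gs <- lapply(list(c(3, 3), c(2, 2), c(1, 1)), function(cr)
    gamma_map(rv, evv, gamma_criteria(cr[1], cr[2]), roi, norm_value = 100))
  expect_true(all(gs[[1]]$gamma <= gs[[2]]$gamma + 1e-12, na.rm = TRUE))
  expect_true(all(gs[[2]]$gamma <= gs[[3]]$gamma + 1e-12, na.rm = TRUE))
  pr <- vapply(gs, pass_rate, numeric(1))
  expect_true(pr[1] >= pr[2] && pr[2] >= pr[3])
  expect_true(all(gs[[3]]$gamma >= 0, na.rm = TRUE))
})

test_that("gamma is invariant when deviations and normalization scale together", {
  set.seed(41)
  ref <- matrix(runif(400, 0, 100), 20, 20)
  ev <- ref + matrix(rnorm(400, 0, 4), 20, 20)
  roi <- rect_roi(c(0, 0, 0), c(1, 20, 20))
  crit <- gamma_criteria(2, 2)
  g1 <- gamma_map(slice_volume(ref), slice_volume(ev), crit, roi,
                  norm_value = 100)
  c0 <- 5
  g2 <- gamma_map(slice_volume(ref * c0), slice_volume(ev * c0), crit, roi,
                  norm_value = 100 * c0)
  expect_equal(g1$gamma, g2$gamma, tolerance = 1e-9)
})

test_that("pass_rate counts gamma <= 1 inclusively", {
  expect_equal(pass_rate(c(0.5, 1.0, 1.5, 2.0)), 50)
  expect_equal(pass_rate(rep(0, 10)), 100)
  expect_error(pass_rate(numeric(0)), "no evaluated voxels")
})

test_that("in-plane upsampling refines the distance-to-agreement search", {
  # half-voxel edge shift: at integer offsets the best match is 1 voxel
  # away, on the 2x grid a half-voxel candidate lowers gamma
  n <- 16; k <- 8
  ref <- matrix(0, 1, n); ref[1, k:n] <- 100
  ev <- matrix(0, 1, n); ev[1, (k + 1):n] <- 100
  rv <- slice_volume(ref, spacing = c(2.5, 2, 2))
  evv <- slice_volume(ev, spacing = c(2.5, 2, 2))
  roi <- rect_roi(c(0, 0, 0), c(1, 1, n))
  g1 <- gamma_map(rv, evv, gamma_criteria(2, 2), roi, norm_value = 100)
  g2 <- gamma_map(rv, evv, gamma_criteria(2, 2, upsample = 2), roi,
                  norm_value = 100)
  expect_lte(max(g2$gamma, na.rm = TRUE), max(g1$gamma, na.rm = TRUE))
  expect_error(gamma_criteria(2, 2, mode = "3d", upsample = 2),
               "2d mode")
})

test_that("criteria validation rejects non-positive tolerances", {
  expect_error(gamma_criteria(0, 3), "positive")
  expect_error(gamma_criteria(3, -1), "positive")
  expect_error(rect_roi(c(0, 0, 0), c(0, 2, 2)), "lo < hi")
})
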