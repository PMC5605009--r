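make_hist <- function(prob, range_hu = c(-1000, 1000)) {
  n <- length(prob)
  structure(list(edges = seq(range_hu[1], range_hu[2], length.out = n + 1L),
                 counts = prob * 1e6, prob = prob, n_voxels = 1e6),
            class = "ct_histogram")
}

test_that("histogram construction conserves mass, clips, and normalizes", {
  v <- image_volume(array(0, dim = c(2, 4, 4)))
  h <- build_histogram(v, n_bins = 256)
  expect_equal(sum(h$prob), 1, tolerance = 1e-9)
  expect_equal(sum(h$counts), 32)           # mass = |roi|
  expect_equal(sum(h$prob > 0), 1L)         # single nonzero bin

  # out-of-range values land in the end bins
  v2 <- image_volume(array(c(-5000, 5000), dim = c(2, 1, 1)))
  h2 <- build_histogram(v2, n_bins = 10)
  expect_equal(h2$counts[1], 1)
  expect_equal(h2$counts[10], 1)

  # a WCT histogram has exactly two occupied bins
  case <- generate_case(small_spec(), 0L)
  body <- binary_mask(case$truth$labels != 0,
                      spacing = case$truth$spacing, origin = case$truth$origin)
  hw <- build_histogram(synthesize_wct(body))
  expect_equal(sum(hw$prob > 0), 2L)

  roi <- binary_mask(array(FALSE, dim = c(2, 4, 4)))
  expect_error(build_histogram(v, roi = roi), "ROI is empty")
  expect_error(build_histogram(v, n_bins = 1), "n_bins")
})

test_that("self-comparison hits the perfect-match anchors", {
  case <- generate_case(small_spec(), 0L)
  h <- build_histogram(case$reference_ct)
  s <- compare_histograms(h, h)
  expect_equal(s$correlation, 1, tolerance = 1e-9)
  expect_equal(s$chi_square, 0, tolerance = 1e-9)
  expect_equal(s$intersection, 1, tolerance = 1e-9)
  expect_equal(s$bhattacharyya, 0, tolerance = 1e-9)
})

test_that("two disjoint single-bin histograms are maximally dissimilar", {
  h1 <- make_hist(c(1, 0)); h2 <- make_hist(c(0, 1))
  expect_equal(hist_correlation(h1, h2), -1)
  expect_equal(hist_chi_square(h1, h2), 2)
  expect_equal(hist_intersection(h1, h2), 0)
  expect_equal(hist_bhattacharyya(h1, h2), 1)
})

test_that("a constant histogram is degenerate for correlation only", {
  u <- make_hist(rep(1 / 8, 8))
  expect_error(hist_correlation(u, u), "degenerate")
  s <- compare_histograms(u, u)
  expect_true(s$degenerate_correlation)
  expect_true(is.na(s$correlation))
  expect_equal(s$chi_square, 0)
  expect_equal(s$intersection, 1)
  expect_equal(s$bhattacharyya, 0, tolerance = 1e-9)
})

test_that("scores are symmetric, bounded, and reject mismatched binning", {
  set.seed(11)
  for (i in 1:1000) {
    p1 <- runif(64); p1 <- p1 / sum(p1)
    p2 <- runif(64); p2 <- p2 / sum(p2)
    h1 <- make_hist(p1); h2 <- make_hist(p2)
    co <- hist_correlation(h1, h2)
    ch <- hist_chi_square(h1, h2)
    it <- hist_intersection(h1, h2)
    bh <- hist_bhattacharyya(h1, h2)
    expect_true(co >= -1 - 1e-12 && co <= 1 + 1e-12)
    expect_true(ch >= 0)
    expect_true(it >= 0 && it <= 1 + 1e-12)
    expect_true(bh >= 0 && bh <= 1 + 1e-12)
    expect_equal(hist_correlation(h2, h1), co)
    expect_equal(hist_chi_square(h2, h1), ch)
    expect_equal(hist_intersection(h2, h1), it)
    expect_equal(hist_bhattacharyya(h2, h1), bh)
  }
  expect_error(compare_histograms(make_hist(c(1, 0)),
                                  make_hist(rep(0.25, 4))),
               "binning mismatch")
})

test_that("blending toward uniform degrades intersection and Bhattacharyya monotonically", {
  set.seed(5)
  p1 <- runif(64)^3; p1 <- p1 / sum(p1)
  u <- rep(1 / 64, 64)
  h1 <- make_hist(p1)
  lams <- seq(0, 1, by = 0.1)
  inter <- vapply(lams, function(l)
    hist_intersection(h1, make_hist((1 - l) * p1 + l * u)), numeric(1))
  bhat <- vapply(lams, function(l)
    hist_bhattacharyya(h1, make_hist((1 - l) * p1 + l * u)), numeric(1))
  expect_true(all(diff(inter) <= 1e-12))
  expect_true(all(diff(bhat) >= -1e-12))
})
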