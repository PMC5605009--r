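test_that("noise-free phantom segments exactly", {
  spec <- small_spec(mr_noise_sd = 0, mr_bias_amp = 0)
  case <- generate_case(spec, 0L)
  body <- segment_body(case$petra)
  truth_body <- case$truth$labels != class_codes()[["air"]]
  expect_identical(body$mask, truth_body)
  labels <- classify_tissues(case$t1, case$t2, case$petra, body)
  # with separable class means and no noise the cascade recovers the truth
  expect_identical(labels$labels, case$truth$labels)
})

test_that("segment_body yields one connected component and fails on empty input", {
  case <- generate_case(small_spec(), 2L)
  body <- segment_body(case$petra)
  cc <- synthct:::label_components_3d(body$mask)
  expect_equal(max(cc), 1L)
  zero <- image_volume(array(0, dim = c(4, 8, 8)))
  expect_error(segment_body(zero), "segmentation failure")
})

test_that("label maps partition the grid and to_masks mirrors that partition", {
  case <- generate_case(small_spec(), 1L)
  body <- segment_body(case$petra)
  labels <- classify_tissues(case$t1, case$t2, case$petra, body)
  masks <- to_masks(labels)
  total <- Reduce(`+`, lapply(masks, function(m) m$mask * 1L))
  expect_true(all(total == 1L))  # disjoint cover
  expect_identical(masks$bone$mask,
                   labels$labels == class_codes()[["bone"]])
  expect_equal(sum(vapply(masks, function(m) sum(m$mask), numeric(1))),
               prod(dim(labels$labels)))
})

test_that("first matching rule wins when class rules overlap", {
  # widen the cavity petra bound so bone-like voxels satisfy both rules
  rules <- default_ruleset(thresholds = list(
    cavity = list(t1_max = 32, t2_max = 32, petra_max = 50)))
  mk <- function(val) image_volume(array(val, dim = c(4, 6, 6)))
  body <- binary_mask(array(TRUE, dim = c(4, 6, 6)))
  # supports spanning the whole grid so only the intensity rules decide
  everywhere <- list(list(center = c(.5, .5, .5), semi = c(2, 2, 2)))
  priors <- default_atlas_prior(classes = list(
    eyeball = everywhere, lens = everywhere, ventricle = everywhere,
    brainstem = everywhere, cavity = everywhere))
  lab <- classify_tissues(mk(15), mk(15), mk(45), body, rules, priors)
  expect_true(all(lab$labels == class_codes()[["bone"]]))
})

test_that("segmentation quality degrades monotonically with MR noise", {
  levels <- c(3, 8, 15)
  mean_dsc <- vapply(levels, function(sd) {
    per_seed <- vapply(0:4, function(id) {
      spec <- small_spec(mr_noise_sd = sd)
      case <- generate_case(spec, id)
      body <- segment_body(case$petra)
      labels <- classify_tissues(case$t1, case$t2, case$petra, body)
      tab <- cohort_overlap_table(list(list(pred = labels,
                                            truth = case$truth)))
      mean(tab$dsc_mean)
    }, numeric(1))
    mean(per_seed)
  }, numeric(1))
  expect_true(all(diff(mean_dsc) <= 0))
})

test_that("bone is the hardest class when bone/soft-tissue contrast is low", {
  # push bone toward the soft-tissue T1/T2 signature so its rule margins
  # shrink while the other classes keep their contrast
  mm <- small_spec()$mr_means
  mm["bone", "t1"] <- 30
  mm["bone", "t2"] <- 30
  spec <- small_spec(mr_means = mm, mr_noise_sd = 5)
  dsc <- rowMeans(vapply(0:2, function(id) {
    case <- generate_case(spec, id)
    body <- segment_body(case$petra)
    labels <- classify_tissues(case$t1, case$t2, case$petra, body)
    cohort_overlap_table(list(list(pred = labels, truth = case$truth)))$dsc_mean
  }, numeric(8)))
  names(dsc) <- names(class_codes())
  expect_equal(names(which.min(dsc)), "bone")
})

test_that("classify_tissues validates its inputs", {
  case <- generate_case(small_spec(), 0L)
  body <- segment_body(case$petra)
  small <- image_volume(case$t1$values[, , 1:10], spacing = case$t1$spacing,
                        origin = case$t1$origin)
  expect_error(classify_tissues(small, case$t2, case$petra, body),
               "grid mismatch")
  empty <- binary_mask(array(FALSE, dim = dim(body$mask)),
                       spacing = body$spacing, origin = body$origin)
  expect_error(classify_tissues(case$t1, case$t2, case$petra, empty),
               "empty")
})
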