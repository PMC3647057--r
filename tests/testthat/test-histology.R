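test_that("requested congestion fractions are realised to within a pixel", {
  ph <- make_kidney_phantom(preset = condition_preset("CD0h", zero_sd = TRUE))
  hs <- make_histology_sample(ph$label_map,
                              c(CTX = 0.1, OS = 0, IS = 0.5, IM = 0.25), seed = 3)
  expect_true(all(ph$label_map[hs$rcc_truth] > 0))
  is_px <- ph$label_map == 3
  expect_lt(abs(sum(hs$rcc_truth & is_px) / sum(is_px) - 0.5), 0.01)
  ctx <- ph$label_map == 1
  expect_lt(abs(sum(hs$rcc_truth & ctx) / sum(ctx) - 0.1), 0.01)
  expect_equal(sum(hs$rcc_truth & (ph$label_map == 2)), 0)
  # all-zero request -> empty truth
  h0 <- make_histology_sample(ph$label_map, 0, seed = 3)
  expect_equal(sum(h0$rcc_truth), 0)
  expect_error(make_histology_sample(ph$label_map, c(CTX = 1.2, OS = 0, IS = 0, IM = 0)),
               "\\[0, 1\\]")
})

test_that("congested pixels render redder than surrounding tissue", {
  ph <- test_phantom()
  hs <- make_histology_sample(ph$label_map, c(CTX = 0, OS = 0, IS = 0.4, IM = 0), seed = 5)
  red <- hs$rgb_image[, , 1]
  tissue <- ph$label_map > 0 & !hs$rcc_truth
  expect_gt(mean(red[hs$rcc_truth]), mean(red[tissue]))
  redness <- red - (hs$rgb_image[, , 2] + hs$rgb_image[, , 3]) / 2
  expect_gt(mean(redness[hs$rcc_truth]), mean(redness[tissue]))
  expect_true(all(hs$rgb_image >= 0 & hs$rgb_image <= 1))
})

test_that("segmentation recovers the generator truth with Dice >= 0.95", {
  ph <- make_kidney_phantom(preset = condition_preset("CD1h", zero_sd = TRUE), seed = 5)
  hs <- make_histology_sample(ph$label_map, c(CTX = 0.02, OS = 0.02, IS = 0.35, IM = 0.02),
                              seed = 7)
  m <- segment_rcc(hs$rgb_image)
  dice <- 2 * sum(m & hs$rcc_truth) / (sum(m) + sum(hs$rcc_truth))
  expect_gte(dice, 0.95)
  # no red content -> empty mask
  h0 <- make_histology_sample(ph$label_map, 0, seed = 2)
  expect_equal(sum(segment_rcc(h0$rgb_image)), 0)
  expect_error(segment_rcc(h0$rgb_image[, , 1:2]), "3")
})

test_that("raising the threshold shrinks the pre-filter mask monotonically", {
  ph <- test_phantom()
  hs <- make_histology_sample(ph$label_map, c(CTX = 0, OS = 0, IS = 0.3, IM = 0), seed = 9)
  lo <- segment_rcc(hs$rgb_image, threshold = 0.3, min_blob = 1)
  hi <- segment_rcc(hs$rgb_image, threshold = 0.45, min_blob = 1)
  expect_true(all(lo[hi]))       # hi-threshold mask is a subset
  expect_lte(sum(hi), sum(lo))
})

test_that("per-compartment fractions conserve counts and hit exact cases", {
  ph <- test_phantom()
  full <- ph$label_map == 3
  q <- area_fractions(full, ph$label_map)
  expect_equal(q$fraction[q$compartment == "IS"], 1)
  expect_equal(q$fraction[q$compartment != "IS"], rep(0, 3))
  expect_equal(sum(q$congested_px), sum(full & ph$label_map > 0))
  q0 <- area_fractions(matrix(FALSE, small_grid[1], small_grid[2]), ph$label_map)
  expect_equal(q0$fraction, rep(0, 4))
  # exactly half the IS pixels
  is_idx <- which(ph$label_map == 3)
  half <- matrix(FALSE, small_grid[1], small_grid[2])
  half[is_idx[seq_len(floor(length(is_idx) / 2))]] <- TRUE
  qh <- area_fractions(half, ph$label_map)
  expect_equal(qh$fraction[qh$compartment == "IS"],
               floor(length(is_idx) / 2) / length(is_idx))
  expect_error(area_fractions(matrix(FALSE, 5, 5), ph$label_map), "grid")
})

test_that("pre-transplant cohorts reproduce the inner-stripe congestion ordering", {
  ph <- make_kidney_phantom(preset = condition_preset("CD0h", zero_sd = TRUE), seed = 1)
  mean_is_fraction <- function(cond, seeds) {
    sev <- condition_preset(cond)$rcc_severity
    mean(vapply(seeds, function(s) {
      hs <- make_histology_sample(ph$label_map, sev, seed = s)
      q <- area_fractions(segment_rcc(hs$rgb_image), hs$compartment_map)
      q$fraction[q$compartment == "IS"]
    }, numeric(1)))
  }
  f0 <- mean_is_fraction("CD0h", 1:3)
  f1 <- mean_is_fraction("CD1h", 4:6)
  f2 <- mean_is_fraction("CD2h", 7:9)
  # massive congestion appears by 1 h and persists: CD1h ~ CD2h >> CD0h
  expect_gt(f1, f0 + 0.2)
  expect_gt(f2, f0 + 0.2)
  expect_lt(abs(f1 - f2), 0.15)
})
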