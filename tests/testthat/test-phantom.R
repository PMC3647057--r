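test_that("default grid reproduces the nominal 0.39 mm pixel and partitions the kidney", {
  ph <- make_kidney_phantom(preset = condition_preset("CD0h", zero_sd = TRUE))
  expect_equal(ph$pixel_size, c(100 / 256, 50 / 128))
  expect_equal(round(ph$pixel_size, 2), c(0.39, 0.39))
  kidney <- ph$label_map > 0
  expect_equal(sum(ph$label_map %in% 1:4), sum(kidney))
  expect_true(all(sort(unique(as.vector(ph$label_map))) == 0:4))
  # physical parameter invariants on kidney pixels
  expect_true(all(ph$t2star_map[kidney] > 0))
  expect_true(all(ph$adc_map[kidney] >= 0))
  expect_true(all(is.na(ph$t2star_map[!kidney])))
})

test_that("compartments are nested: elliptical radius ordering IM < IS < OS < CTX", {
  ph <- test_phantom()
  ij <- which(ph$label_map > 0, arr.ind = TRUE)
  ctr <- colMeans(ij)
  r <- sqrt(((ij[, 1] - ctr[1]) / diff(range(ij[, 1])))^2 +
            ((ij[, 2] - ctr[2]) / diff(range(ij[, 2])))^2)
  lab <- ph$label_map[ph$label_map > 0]
  # every IM pixel sits closer to the centre than every CTX pixel, etc.
  expect_lt(max(r[lab == 4]), min(r[lab == 1]))
  expect_lt(max(r[lab == 4]), min(r[lab == 2]))
  expect_lt(max(r[lab == 3]), min(r[lab == 1]))
})

test_that("rcc mask respects severity: empty at zero, fraction-accurate, kidney-contained", {
  ph0 <- test_phantom("CD0h")
  expect_equal(sum(ph0$rcc_mask), 0)
  ph2 <- make_kidney_phantom(matrix_dims = c(256L, 128L),
                             preset = condition_preset("CD2h", zero_sd = TRUE),
                             seed = 7)
  expect_true(all(ph2$label_map[ph2$rcc_mask] > 0))
  for (k in 1:4) {
    comp <- ph2$label_map == k
    if (sum(comp) >= 1000) {
      sev <- condition_preset("CD2h")$rcc_severity[compartment_names()[k]]
      expect_lt(abs(sum(ph2$rcc_mask & comp) / sum(comp) - sev), 0.01)
    }
  }
  # T2* reduction applied inside lesions only
  is_px <- ph2$label_map == 3
  expect_equal(unique(ph2$t2star_map[is_px & ph2$rcc_mask]),
               0.35 * unique(ph2$t2star_map[is_px & !ph2$rcc_mask]))
})

test_that("phantoms and cohorts are deterministic in the seed", {
  a <- test_phantom("CD1h", zero_sd = FALSE, seed = 11)
  b <- test_phantom("CD1h", zero_sd = FALSE, seed = 11)
  expect_identical(a, b)
  d <- condition_presets("none")
  c1 <- make_cohort(d, seed = 5, matrix_dims = small_grid, fov_mm = small_fov)
  c2 <- make_cohort(d, seed = 5, matrix_dims = small_grid, fov_mm = small_fov)
  expect_identical(c1, c2)
  c3 <- make_cohort(d, seed = 6, matrix_dims = small_grid, fov_mm = small_fov)
  expect_false(identical(c1, c3))
})

test_that("zero-variance presets give identical kidneys; sampled SD matches the preset", {
  coh <- make_cohort(list(condition_preset("CD0h", zero_sd = TRUE)),
                     n_per_condition = 3, seed = 2,
                     matrix_dims = small_grid, fov_mm = small_fov)
  expect_identical(coh[[1]]$adc_map, coh[[2]]$adc_map)
  expect_identical(coh[[2]]$t2star_map, coh[[3]]$t2star_map)
  # 200 kidneys drawn with the published CD0h SDs: empirical SD of the CTX
  # ADC draw must approach the preset SD (0.043) within Monte-Carlo error
  coh <- make_cohort(list(list(preset = condition_preset("CD0h"), n = 200)),
                     seed = 3, matrix_dims = small_grid, fov_mm = small_fov)
  draws <- vapply(coh, function(p) p$params$adc[["CTX"]], numeric(1))
  expect_lt(abs(sd(draws) - 0.043), 3 * 0.043 / sqrt(2 * 199))
})

test_that("degenerate geometry and presets are rejected", {
  expect_error(make_kidney_phantom(matrix_dims = c(16L, 16L)), "32")
  expect_error(make_kidney_phantom(fov_mm = c(-1, 50)), "positive")
  expect_error(condition_preset("CD0h", rcc_severity = c(CTX = 2, OS = 0, IS = 0, IM = 0)),
               "\\[0, 1\\]")
  expect_error(make_cohort(list()), "empty")
})
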