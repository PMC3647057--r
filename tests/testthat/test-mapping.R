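test_that("T2* fit inverts noiseless decay exactly and flags degenerate pixels", {
  ph <- test_phantom("CD1h")
  st <- simulate_gre(ph, test_acq(TE_list = c(10, 30)))
  fit <- fit_t2star(st)
  kidney <- ph$label_map > 0
  expect_true(all(fit$valid[kidney]))
  expect_equal(fit$values[kidney], ph$t2star_map[kidney], tolerance = 1e-12)
  # background (all-zero) pixels: invalid, no exception
  expect_false(any(fit$valid[!kidney]))
  expect_true(all(is.na(fit$values[!kidney])))
  expect_error(fit_t2star(simulate_gre(ph, test_acq(TE_list = 10))), "single|SI|>= 2")
})

test_that("simulate/fit round trip recovers every compartment to <= 1e-9 relative error", {
  for (cond in c("CD0h", "CD1h", "CD2h")) {
    ph <- test_phantom(cond)
    t2 <- fit_t2star(simulate_gre(ph, test_acq()))
    adc <- compute_adc_map(simulate_dwi(ph, test_acq()))
    kidney <- ph$label_map > 0
    expect_lt(max(abs(t2$values[kidney] / ph$t2star_map[kidney] - 1)), 1e-9)
    expect_lt(max(abs(adc$values[kidney] / ph$adc_map[kidney] - 1)), 1e-9)
  }
})

test_that("two-point ADC matches the scalar formula and applies physicality rules", {
  st <- structure(list(
    data = array(c(matrix(1000, 4, 4), matrix(919.54, 4, 4)), c(4, 4, 2)),
    contrast_axis = c(0, 134), contrast_unit = "b_s_per_mm2", kind = "dwi"),
    class = "image_stack")
  m <- compute_adc_map(st, 0, 134)
  expect_equal(unique(m$values[m$valid]), log(1000 / 919.54) / 134 * 1e3)
  expect_equal(round(unique(m$values[m$valid]), 3), 0.626)
  # equal signals -> ADC 0, still valid; inverted signals -> invalid + diagnostics
  st$data[1, 1, 2] <- 1000; st$data[2, 2, 2] <- 1500; st$data[3, 3, 1] <- 0
  m <- compute_adc_map(st, 0, 134)
  expect_equal(m$values[1, 1], 0)
  expect_true(m$valid[1, 1])
  expect_false(m$valid[2, 2])
  expect_lt(m$diagnostics$negative_adc[2, 2], 0)
  expect_false(m$valid[3, 3])
  expect_error(compute_adc_map(st, 0, 200), "not both present")
})

test_that("ADC mapping agrees with an independent per-pixel evaluation on random pixels", {
  set.seed(31)
  ph <- test_phantom("CD2h", zero_sd = FALSE, seed = 17)
  st <- simulate_dwi(ph, test_acq())
  m <- compute_adc_map(st)
  px <- sample(which(ph$label_map > 0), 100)
  for (i in px) {
    expected <- log(st$data[, , 1][i] / st$data[, , 2][i]) / 134 * 1e3
    expect_equal(m$values[i], expected)
  }
})

test_that("estimated ADC is monotone in true ADC on noiseless data", {
  ph1 <- test_phantom("CD0h")
  ph2 <- ph1
  ph2$adc_map <- ph1$adc_map * 1.3
  m1 <- compute_adc_map(simulate_dwi(ph1, test_acq()))
  m2 <- compute_adc_map(simulate_dwi(ph2, test_acq()))
  kidney <- ph1$label_map > 0
  expect_true(all(m2$values[kidney] > m1$values[kidney]))
})

test_that("SI ratio: identity on the reference, closed form on table values, guarded errors", {
  ref <- c(100, 110, 90)
  expect_equal(compute_si_ratio(ref, ref), ref / 100)
  expect_equal(mean(compute_si_ratio(ref, ref)), 1)
  si_is <- 1000 * exp(-10 / 42.3); si_ref <- 1000 * exp(-10 / 146.1)
  expect_equal(round(compute_si_ratio(si_is, rep(si_ref, 3)), 3), 0.845)
  expect_error(compute_si_ratio(ref, numeric(0)), "empty")
  expect_error(compute_si_ratio(ref, c(-1, 1)), "non-zero")
  m <- matrix(1:6, 3, dimnames = list(NULL, c("CTX", "OS")))
  expect_equal(compute_si_ratio(m, m)[, "CTX"], (1:3) / 2)
  expect_error(compute_si_ratio(m, matrix(1:6, 3)), "matching")
})
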