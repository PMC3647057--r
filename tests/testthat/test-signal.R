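test_that("gradient-echo signal follows S0 * exp(-TE/T2*)", {
  ph <- test_phantom()
  ph$t2star_map[ph$label_map > 0] <- 10
  st <- simulate_gre(ph, test_acq(TE_list = 10))
  tissue <- ph$label_map > 0
  expect_equal(unique(st$data[, , 1][tissue]), 1000 * exp(-1))
  expect_equal(unique(st$data[, , 1][!tissue]), 0)
  # TE -> 0 limit recovers the baseline signal
  st0 <- simulate_gre(ph, test_acq(TE_list = 1e-9))
  expect_equal(st0$data[, , 1][tissue], ph$s0_map[tissue], tolerance = 1e-9)
})

test_that("two-compartment signal ratio matches the closed form at TE = 10 ms", {
  ph <- test_phantom()
  ph$t2star_map[ph$label_map == 3] <- 42.3   # inner stripe, 1 h post-mortem
  ph$t2star_map[ph$label_map == 1] <- 146.1
  st <- simulate_gre(ph, test_acq(TE_list = 10))
  r <- unique(st$data[, , 1][ph$label_map == 3]) /
       unique(st$data[, , 1][ph$label_map == 1])
  expect_equal(r, exp(-10 / 42.3) / exp(-10 / 146.1))
  expect_equal(round(r, 3), 0.845)
})

test_that("diffusion signal follows S0 * exp(-b * ADC); b = 0 frame is the baseline", {
  ph <- test_phantom()
  st <- simulate_dwi(ph, test_acq(b_values = c(0, 134)))
  tissue <- ph$label_map > 0
  expect_identical(st$data[, , 1][tissue], ph$s0_map[tissue])
  ctx <- ph$label_map == 1  # carries ADC 0.626e-3 mm^2/s
  expect_equal(unique(st$data[, , 2][ctx] / st$data[, , 1][ctx]),
               exp(-134 * 0.626e-3))
  expect_equal(round(unique(st$data[, , 2][ctx] / 1000), 5), 0.91954)
  # zero diffusivity: all frames identical
  ph$adc_map[tissue] <- 0
  st0 <- simulate_dwi(ph, test_acq(b_values = c(0, 134)))
  expect_identical(st0$data[, , 1], st0$data[, , 2])
})

test_that("noiseless decay is monotone in TE and b", {
  ph <- test_phantom("CD2h")
  gre <- simulate_gre(ph, test_acq(TE_list = c(5, 10, 20, 40)))
  dwi <- simulate_dwi(ph, test_acq(b_values = c(0, 50, 134)))
  tissue <- which(ph$label_map > 0)
  for (f in 2:4) expect_true(all(gre$data[, , f][tissue] < gre$data[, , f - 1][tissue]))
  for (f in 2:3) expect_true(all(dwi$data[, , f][tissue] <= dwi$data[, , f - 1][tissue]))
})

test_that("noise injection: identity at sigma 0, seeded determinism, model validation", {
  ph <- test_phantom()
  st <- simulate_gre(ph, test_acq(TE_list = 10))
  expect_identical(add_noise(st, 0, "gaussian", seed = 1), st)
  n1 <- add_noise(st, 5, "rician", seed = 42)
  n2 <- add_noise(st, 5, "rician", seed = 42)
  expect_identical(n1$data, n2$data)
  expect_false(identical(add_noise(st, 5, "rician", seed = 43)$data, n1$data))
  expect_error(add_noise(st, 5, "salt_pepper"), "arg")
  expect_error(add_noise(st, -1, "gaussian"), ">= 0")
})

test_that("rician floor on a zero-signal frame approaches the Rayleigh mean", {
  zero <- new_stack_for_test(nr = 320, nc = 320)
  sigma <- 7
  noisy <- add_noise(zero, sigma, "rician", seed = 9)
  expect_equal(mean(noisy$data), sigma * sqrt(pi / 2), tolerance = 0.01)
})

test_that("averaging n replicates shrinks gaussian noise SD by sqrt(n)", {
  zero <- new_stack_for_test(nr = 320, nc = 320)
  sigma <- 8
  n4 <- add_noise(zero, sigma, "gaussian", seed = 4, n_averages = 4)
  expect_equal(sd(n4$data), sigma / 2, tolerance = 0.05)
})

test_that("grid mismatch and invalid acquisitions are rejected", {
  ph <- test_phantom()
  expect_error(simulate_gre(ph, acquisition_config(matrix_dims = c(128L, 128L))),
               "does not match")
  expect_error(acquisition_config(TE_list = c(10, 5)), "increasing")
  expect_error(acquisition_config(b_values = c(-1, 134)), "non-negative")
  expect_error(acquisition_config(n_averages = 0), "n_averages")
  expect_error(simulate_dwi(ph, test_acq(b_values = c(10, 134))), "including 0")
})
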