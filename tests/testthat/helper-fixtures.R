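# Small grids keep per-test simulation cheap; the acceptance tests use the
# full 256 x 128 acquisition matrix.
small_grid <- c(64L, 32L)
small_fov <- c(100, 50)

test_phantom <- function(condition = "CD0h", zero_sd = TRUE, seed = 1L,
                         rcc_t2star_factor = 1, grid = small_grid, ...) {
  make_kidney_phantom(matrix_dims = grid, fov_mm = small_fov,
                      preset = condition_preset(condition, zero_sd = zero_sd),
                      seed = seed, rcc_t2star_factor = rcc_t2star_factor, ...)
}

test_acq <- function(TE_list = c(5, 10, 20, 40, 80), grid = small_grid, ...) {
  acquisition_config(TE_list = TE_list, matrix_dims = grid, fov_mm = small_fov, ...)
}

# bare zero-signal stack for noise-statistics checks
new_stack_for_test <- function(nr = 100, nc = 100) {
  structure(list(data = array(0, c(nr, nc, 1)), contrast_axis = 10,
                 contrast_unit = "TE_ms", kind = "gre"),
            class = "image_stack")
}

roi_means <- function(phantom, map) {
  s <- transfer_roi(derive_rois(phantom), map)
  stats::setNames(s$mean, s$compartment)
}
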