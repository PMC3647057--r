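#' Acquisition configuration
#'
#' Bundles the pulse-sequence parameters for the forward simulators. The
#' defaults reproduce the BOLD protocol of the source experiments
#' (gradient-recalled echo, TR 30 ms, TE 10 ms, flip 13 degrees, 256 x 128
#' matrix over a 100 x 50 mm field of view, 1 mm slice, two averages); the
#' diffusion defaults (`b_values`) correspond to the two-point spin-echo
#' protocol at b = 0 and 134 s/mm^2.
#'
#' @param TR repetition time, ms.
#' @param TE_list echo time(s), ms; strictly increasing, positive.
#' @param flip_angle degrees. T1/flip steady-state weighting is not modelled
#'   separately: all of it is absorbed into the phantom's baseline signal
#'   (a single TR/flip setting is used per sequence), so this field is
#'   metadata only.
#' @param b_values diffusion sensitisations, s/mm^2, non-negative; include 0
#'   for two-point ADC work.
#' @param matrix_dims,fov_mm,slice_thickness geometry (must match the
#'   phantom grid when simulating).
#' @param n_averages number of signal averages (>= 1); Gaussian noise SD
#'   shrinks by sqrt(n).
#' @param noise_sigma noise SD in signal units; 0 = noiseless.
#' @param noise_model `"none"`, `"gaussian"` or `"rician"`.
#' @param seed integer seed for the noise stream.
#' @return Object of class `acquisition_config`.
#' @export
acquisition_config <- function(TR = 30, TE_list = 10, flip_angle = 13,
                               b_values = c(0, 134),
                               matrix_dims = c(256L, 128L), fov_mm = c(100, 50),
                               slice_thickness = 1, n_averages = 2L,
                               noise_sigma = 0, noise_model = c("none", "gaussian", "rician"),
                               seed = NULL) {
  noise_model <- match.arg(noise_model)
  if (length(TE_list) < 1 || any(TE_list <= 0) || is.unsorted(TE_list, strictly = TRUE))
    stop("TE_list must be positive and strictly increasing")
  if (any(b_values < 0)) stop("b_values must be non-negative")
  if (n_averages < 1) stop("n_averages must be >= 1")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(TR = TR, TE_list = TE_list, flip_angle = flip_angle,
                 b_values = sort(b_values), matrix_dims = as.integer(matrix_dims),
                 fov_mm = fov_mm, slice_thickness = slice_thickness,
                 n_averages = as.integer(n_averages), noise_sigma = noise_sigma,
                 noise_model = noise_model, seed = seed),
            class = "acquisition_config")
}

new_image_stack <- function(data, contrast_axis, contrast_unit, kind) {
  stopifnot(dim(data)[3] == length(contrast_axis))
  structure(list(data = data, contrast_axis = contrast_axis,
                 contrast_unit = contrast_unit, kind = kind),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Image stack (%s): %d x %d px, %d frame(s) at %s = %s\n",
              x$kind, d[1], d[2], d[3], x$contrast_unit,
              paste(x$contrast_axis, collapse = ", ")))
  invisible(x)
}

.check_grid <- function(phantom, acq) {
  if (!all(dim(phantom$label_map) == acq$matrix_dims))
    stop("phantom grid ", paste(dim(phantom$label_map), collapse = "x"),
         " does not match acquisition matrix ",
         paste(acq$matrix_dims, collapse = "x"))
}

#' Simulate gradient-echo (BOLD / T2*-weighted) signals
#'
#' Noiseless per-pixel signal S(TE) = S0_eff * exp(-TE / T2*), one frame per
#' echo time; background pixels are zero. The phantom's `t2star_map` already
#' carries any red-cell-congestion T2* reduction, so congested pixels appear
#' hypointense. Noise (if configured) is applied via [add_noise()] with the
#' configured averaging.
#'
#' @param phantom a [make_kidney_phantom()] result.
#' @param acq an [acquisition_config()]; its matrix must equal the phantom
#'   grid.
#' @return An `image_stack` of kind `"gre"` with `contrast_axis` = TE (ms).
#' @export
simulate_gre <- function(phantom, acq = acquisition_config()) {
  .check_grid(phantom, acq)
  d <- dim(phantom$label_map)
  kidney <- phantom$label_map > 0
  data <- array(0, dim = c(d, length(acq$TE_list)))
  for (f in seq_along(acq$TE_list)) {
    frame <- matrix(0, d[1], d[2])
    frame[kidney] <- phantom$s0_map[kidney] *
      exp(-acq$TE_list[f] / phantom$t2star_map[kidney])
    data[, , f] <- frame
  }
  stack <- new_image_stack(data, acq$TE_list, "TE_ms", "gre")
  if (acq$noise_model != "none" && acq$noise_sigma > 0)
    stack <- add_noise(stack, acq$noise_sigma, acq$noise_model,
                       seed = acq$seed, n_averages = acq$n_averages)
  stack
}

#' Simulate diffusion-weighted spin-echo signals
#'
#' Noiseless per-pixel signal S(b) = S0_eff * exp(-b * ADC), with ADC taken
#' from the phantom map (10^-3 mm^2/s) and b in s/mm^2; one frame per
#' b-value. The b = 0 frame equals the baseline signal exactly.
#'
#' @inheritParams simulate_gre
#' @return An `image_stack` of kind `"dwi"` with `contrast_axis` = b
#'   (s/mm^2).
#' @export
simulate_dwi <- function(phantom, acq = acquisition_config()) {
  .check_grid(phantom, acq)
  if (length(acq$b_values) < 2 || !any(acq$b_values == 0))
    stop("diffusion simulation needs >= 2 b-values including 0")
  d <- dim(phantom$label_map)
  kidney <- phantom$label_map > 0
  data <- array(0, dim = c(d, length(acq$b_values)))
  for (f in seq_along(acq$b_values)) {
    frame <- matrix(0, d[1], d[2])
    frame[kidney] <- phantom$s0_map[kidney] *
      exp(-acq$b_values[f] * phantom$adc_map[kidney] * 1e-3)
    data[, , f] <- frame
  }
  stack <- new_image_stack(data, acq$b_values, "b_s_per_mm2", "dwi")
  if (acq$noise_model != "none" && acq$noise_sigma > 0)
    stack <- add_noise(stack, acq$noise_sigma, acq$noise_model,
                       seed = acq$seed, n_averages = acq$n_averages)
  stack
}

#' Add measurement noise to an image stack
#'
#' Gaussian noise adds N(0, sigma) per pixel; Rician noise (the magnitude-MRI
#' model) replaces S by sqrt((S + e1)^2 + e2^2) with e1, e2 ~ N(0, sigma).
#' With `n_averages` > 1 the returned stack is the mean of that many
#' independent noisy replicates, so Gaussian noise SD scales as
#' sigma / sqrt(n).
#'
#' @param stack an `image_stack`.
#' @param sigma noise SD (>= 0); 0 returns the input unchanged.
#' @param model `"gaussian"` or `"rician"`.
#' @param seed integer seed; same seed, same noisy stack.
#' @param n_averages number of averaged replicates.
#' @return A noisy `image_stack` with the same geometry and contrast axis.
#' @export
add_noise <- function(stack, sigma, model = c("gaussian", "rician"),
                      seed = NULL, n_averages = 1L) {
  model <- match.arg(model)
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(stack)
  if (n_averages < 1) stop("n_averages must be >= 1")
  d <- dim(stack$data)
  with_seed(seed, {
    acc <- array(0, dim = d)
    for (rep in seq_len(n_averages)) {
      if (model == "gaussian") {
        acc <- acc + stack$data + array(stats::rnorm(prod(d), 0, sigma), d)
      } else {
        e1 <- array(stats::rnorm(prod(d), 0, sigma), d)
        e2 <- array(stats::rnorm(prod(d), 0, sigma), d)
        acc <- acc + sqrt((stack$data + e1)^2 + e2^2)
      }
    }
    out <- stack
    out$data <- acc / n_averages
    out
  })
}
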