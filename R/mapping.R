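new_parameter_map <- function(values, kind, valid, diagnostics = NULL) {
  structure(list(values = values, kind = kind, valid = valid,
                 diagnostics = diagnostics),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  v <- x$values[x$valid]
  cat(sprintf("Parameter map (%s): %d x %d px, %d valid; range %.4g - %.4g\n",
              x$kind, nrow(x$values), ncol(x$values), sum(x$valid),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Fit a T2* map from multi-echo gradient-echo data
#'
#' Per-pixel monoexponential fit ln S = ln S0 - TE / T2* by least squares on
#' the log-signal across echoes (exact on noiseless data). Pixels with any
#' non-positive signal, or whose fitted decay rate is non-negative
#' (estimated T2* <= 0), are marked invalid rather than clipped.
#'
#' @param stack a gradient-echo `image_stack` with at least two distinct
#'   echo times.
#' @return A `parameter_map` of kind `"t2star_ms"`; `diagnostics$s0` holds
#'   the fitted intercept map.
#' @export
fit_t2star <- function(stack) {
  if (!inherits(stack, "image_stack") || stack$kind != "gre")
    stop("fit_t2star expects a gradient-echo image stack")
  te <- stack$contrast_axis
  if (length(unique(te)) < 2)
    stop("T2* fitting needs >= 2 distinct echoes; ",
         "for single-echo data use signal-intensity (SI ratio) analysis")
  d <- dim(stack$data)
  npx <- d[1] * d[2]
  S <- matrix(stack$data, npx, d[3])
  pos <- rowSums(S <= 0) == 0
  tc <- te - mean(te)
  denom <- sum(tc^2)
  slope <- rep(NA_real_, npx); icpt <- rep(NA_real_, npx)
  if (any(pos)) {
    Y <- log(S[pos, , drop = FALSE])
    slope[pos] <- as.vector(Y %*% tc) / denom
    icpt[pos] <- rowMeans(Y) - slope[pos] * mean(te)
  }
  t2 <- -1 / slope
  valid <- pos & !is.na(slope) & slope < 0
  vals <- matrix(NA_real_, d[1], d[2])
  vals[valid] <- t2[valid]
  new_parameter_map(vals, "t2star_ms", matrix(valid, d[1], d[2]),
                    diagnostics = list(s0 = matrix(exp(icpt), d[1], d[2])))
}

#' Compute a two-point ADC map
#'
#' Standard two-point apparent diffusion coefficient from a pair of
#' diffusion-weighted frames: ADC = ln(S_low / S_high) / (b_high - b_low),
#' reported in 10^-3 mm^2/s (numerically 10^-9 m^2/s). Pixels with a
#' non-positive signal in either frame are invalid; pixels where the
#' high-b signal exceeds the low-b signal (negative ADC, unphysical for
#' pure diffusion) are marked invalid but retained in
#' `diagnostics$negative_adc` for inspection.
#'
#' @param stack a diffusion-weighted `image_stack`.
#' @param b_low,b_high the two b-values to use (s/mm^2); both must be
#'   frames of the stack and `b_high > b_low`.
#' @return A `parameter_map` of kind `"adc_e3mm2s"`.
#' @export
compute_adc_map <- function(stack, b_low = 0, b_high = 134) {
  if (!inherits(stack, "image_stack") || stack$kind != "dwi")
    stop("compute_adc_map expects a diffusion-weighted image stack")
  if (b_high <= b_low) stop("b_high must exceed b_low")
  i_lo <- match(b_low, stack$contrast_axis)
  i_hi <- match(b_high, stack$contrast_axis)
  if (is.na(i_lo) || is.na(i_hi))
    stop("requested b-values (", b_low, ", ", b_high,
         ") not both present in stack frames (",
         paste(stack$contrast_axis, collapse = ", "), ")")
  S_lo <- stack$data[, , i_lo]
  S_hi <- stack$data[, , i_hi]
  pos <- S_lo > 0 & S_hi > 0
  adc <- matrix(NA_real_, nrow(S_lo), ncol(S_lo))
  adc[pos] <- log(S_lo[pos] / S_hi[pos]) / (b_high - b_low) * 1e3
  neg <- pos & !is.na(adc) & adc < 0
  valid <- pos & !neg
  vals <- adc; vals[!valid] <- NA_real_
  diag_neg <- matrix(NA_real_, nrow(S_lo), ncol(S_lo))
  diag_neg[neg] <- adc[neg]
  new_parameter_map(vals, "adc_e3mm2s", valid,
                    diagnostics = list(negative_adc = diag_neg))
}

#' Compartmental signal-intensity ratio against a reference group
#'
#' For each kidney and compartment, divides the kidney's T2*-weighted
#' signal-intensity mean by the mean of the reference (CD0h) group for the
#' same compartment: SI ratio = SI(kidney) / mean SI(reference). A ratio
#' below 1 marks signal depression relative to freshly harvested grafts
#' (in the inner stripe, the congestion signature).
#'
#' @param group_values numeric vector (one compartment, one value per
#'   kidney) or matrix (kidneys x compartments) of SI means.
#' @param reference_values same shape contract: the reference group's SI
#'   means; column names must match when matrices are used.
#' @return Ratios with the shape of `group_values`.
#' @export
compute_si_ratio <- function(group_values, reference_values) {
  if (is.matrix(group_values)) {
    if (!is.matrix(reference_values) ||
        !identical(colnames(group_values), colnames(reference_values)))
      stop("matrix inputs need matching compartment columns")
    ref_mean <- colMeans(reference_values)
    if (any(!is.finite(ref_mean)) || any(ref_mean == 0))
      stop("reference SI mean must be finite and non-zero for every compartment")
    return(sweep(group_values, 2, ref_mean, "/"))
  }
  if (length(reference_values) == 0) stop("empty reference group")
  ref_mean <- mean(reference_values)
  if (!is.finite(ref_mean) || ref_mean == 0)
    stop("reference SI mean must be finite and non-zero")
  group_values / ref_mean
}
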