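#' Segment red-cell congestion on an eosin-stained RGB image
#'
#' Classifies a pixel as congested when its redness score
#' r = R - (G + B) / 2 exceeds `threshold`, then removes connected
#' components smaller than `min_blob` pixels (8-connectivity) to suppress
#' isolated stain noise.
#'
#' @param rgb_image rows x cols x 3 array, channel values in \[0, 1\].
#' @param threshold redness threshold; default 0.4 separates the synthetic
#'   erythrocyte red (r around 0.78) from eosin-pink tissue (r around 0.24).
#' @param min_blob minimum connected-component size kept, in pixels.
#' @return Logical matrix: congested pixels.
#' @export
segment_rcc <- function(rgb_image, threshold = 0.4, min_blob = 5L) {
  if (length(dim(rgb_image)) != 3 || dim(rgb_image)[3] != 3)
    stop("rgb_image must be a rows x cols x 3 array")
  redness <- rgb_image[, , 1] - (rgb_image[, , 2] + rgb_image[, , 3]) / 2
  mask <- redness > threshold
  if (min_blob > 1 && any(mask)) {
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    tab <- tabulate(as.integer(lab))
    keep <- which(tab >= min_blob)
    mask <- matrix(as.integer(lab) %in% keep, nrow(mask), ncol(mask))
  }
  mask
}

#' Per-compartment congested-area fractions
#'
#' @param mask logical congestion mask (e.g. from [segment_rcc()]).
#' @param compartment_map integer label map on the same grid.
#' @return Object of class `rcc_quant`: data.frame with one row per
#'   compartment (`compartment`, `congested_px`, `total_px`, `fraction`).
#' @export
area_fractions <- function(mask, compartment_map) {
  if (!all(dim(mask) == dim(compartment_map)))
    stop("mask grid does not match compartment map grid")
  rows <- lapply(seq_len(4), function(k) {
    comp <- compartment_map == k
    tot <- sum(comp)
    cg <- sum(mask & comp)
    data.frame(compartment = compartment_names()[k],
               congested_px = cg, total_px = tot,
               fraction = if (tot > 0) cg / tot else NA_real_)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("rcc_quant", "data.frame")
  out
}
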