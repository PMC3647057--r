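#' Synthesize an eosin-style histology section with known congestion truth
#'
#' Renders an RGB image over a compartment label map: background white,
#' tissue in an eosin-like pink, and red-cell-congestion (RCC) lesions in a
#' saturated erythrocyte red, with mild per-pixel stain noise. Lesions are
#' placed as clustered blobs covering, per compartment, a pixel fraction
#' equal to the request (exact to the nearest pixel). The returned truth
#' mask is the segmentation ground truth for [segment_rcc()].
#'
#' @param compartment_map integer label map (0 background, 1-4 compartments),
#'   e.g. the `label_map` of a [make_kidney_phantom()].
#' @param rcc_fraction named numeric vector in \[0, 1\]: requested congested
#'   area fraction per compartment (CTX/OS/IS/IM); a single number is
#'   recycled to all four.
#' @param seed integer seed.
#' @param stain list of rendering parameters: `tissue` and `rcc` RGB
#'   triples in \[0, 1\], `noise_sd` per-channel Gaussian stain noise.
#' @return Object of class `histology_sample`: `rgb_image`
#'   (rows x cols x 3, in \[0, 1\]), `compartment_map`, `rcc_truth`, `stain`,
#'   `seed`.
#' @export
make_histology_sample <- function(compartment_map,
                                  rcc_fraction = c(CTX = 0, OS = 0, IS = 0, IM = 0),
                                  seed = 1L,
                                  stain = list(tissue = c(0.90, 0.62, 0.70),
                                               rcc = c(0.94, 0.15, 0.18),
                                               noise_sd = 0.02)) {
  if (length(rcc_fraction) == 1) rcc_fraction <- rep(rcc_fraction, 4)
  if (is.null(names(rcc_fraction))) names(rcc_fraction) <- compartment_names()
  rcc_fraction <- rcc_fraction[compartment_names()]
  if (any(is.na(rcc_fraction)) || any(rcc_fraction < 0 | rcc_fraction > 1))
    stop("rcc_fraction must name all four compartments with values in [0, 1]")
  lab <- compartment_map
  nr <- nrow(lab); nc <- ncol(lab)
  with_seed(seed, {
    truth <- matrix(FALSE, nr, nc)
    for (k in seq_len(4)) {
      comp <- lab == k
      kpx <- round(rcc_fraction[k] * sum(comp))
      if (kpx > 0) truth <- truth | clustered_pixels(comp, kpx)
    }
    tissue <- lab > 0
    img <- array(1, dim = c(nr, nc, 3))  # white background
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[tissue] <- stain$tissue[ch]
      plane[truth] <- stain$rcc[ch]
      noise <- matrix(stats::rnorm(nr * nc, 0, stain$noise_sd), nr, nc)
      plane[tissue] <- plane[tissue] + noise[tissue]
      img[, , ch] <- pmin(pmax(plane, 0), 1)
    }
    structure(list(rgb_image = img, compartment_map = lab, rcc_truth = truth,
                   stain = stain, seed = as.integer(seed)),
              class = "histology_sample")
  })
}

#' @export
print.histology_sample <- function(x, ...) {
  d <- dim(x$rgb_image)
  cat(sprintf("Histology sample: %d x %d px, %d congested px (%.1f%% of tissue)\n",
              d[1], d[2], sum(x$rcc_truth),
              100 * sum(x$rcc_truth) / max(1, sum(x$compartment_map > 0))))
  invisible(x)
}
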