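.sidecar_path <- function(path) paste0(sub("\\.(tiff?|nii(\\.gz)?)$", "", path), ".json")

# round to nearest IEEE single precision, keeping dimensions
.as_float32 <- function(x) {
  y <- readBin(writeBin(as.numeric(x), raw(), size = 4L), "numeric",
               n = length(x), size = 4L)
  dim(y) <- dim(x)
  y
}

#' Write an image stack to disk
#'
#' `tiff`: one 32-bit float page per contrast frame. `nifti`: a single
#' 32-bit float volume with the contrast axis as the third dimension. Both
#' formats get a JSON sidecar (same basename, `.json`) carrying the
#' contrast axis, its unit and the stack kind, so a round-trip is lossless
#' at float32 precision.
#'
#' @param stack an `image_stack`.
#' @param path output file (`.tif`/`.tiff` or `.nii`/`.nii.gz`).
#' @param format `"tiff"` or `"nifti"`; default inferred from `path`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, format = c("auto", "tiff", "nifti")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.tiff?$", path)) "tiff"
      else if (grepl("\\.nii(\\.gz)?$", path)) "nifti"
      else stop("cannot infer format from path: ", path)
  # both containers carry the data rescaled to [0, 1] and quantised to
  # float32 before writing, with the affine (lo, hi) in the sidecar. NIfTI
  # stores those float32 values exactly; TIFF's 32-bit integer samples
  # perturb them by < 2^-32, far below half a float32 ulp, so re-rounding
  # to float32 on read makes a TIFF <-> NIfTI conversion bit-exact.
  # the [0.5, 1] band keeps the float32 spacing constant (2^-24), so the
  # stored grid is identical for every pixel regardless of magnitude
  lo <- min(stack$data); hi <- max(stack$data)
  norm <- if (hi > lo) 0.5 + 0.5 * (stack$data - lo) / (hi - lo)
          else array(0.5, dim(stack$data))
  norm <- .as_float32(norm)
  if (format == "tiff") {
    pages <- lapply(seq_along(stack$contrast_axis), function(f) norm[, , f])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  } else {
    RNifti::writeNifti(RNifti::asNifti(norm), path, datatype = "float")
  }
  jsonlite::write_json(
    list(contrast_axis = stack$contrast_axis,
         contrast_unit = stack$contrast_unit, kind = stack$kind,
         scale_lo = lo, scale_hi = hi),
    .sidecar_path(path), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' @param path the image file; its JSON sidecar must sit alongside.
#' @param format `"tiff"`, `"nifti"` or `"auto"`.
#' @return An `image_stack`.
#' @export
read_stack <- function(path, format = c("auto", "tiff", "nifti")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.tiff?$", path)) "tiff"
      else if (grepl("\\.nii(\\.gz)?$", path)) "nifti"
      else stop("cannot infer format from path: ", path)
  sc <- .sidecar_path(path)
  if (!file.exists(sc))
    stop("missing JSON sidecar for ", path, " (expected ", sc, ")")
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (format == "tiff") {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    data <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  } else {
    data <- array(as.numeric(RNifti::readNifti(path)), dim = dim(RNifti::readNifti(path)))
    if (length(dim(data)) == 2) dim(data) <- c(dim(data), 1L)
  }
  if (dim(data)[3] != length(meta$contrast_axis))
    stop("frame count does not match sidecar contrast_axis length")
  if (!is.null(meta$scale_lo))
    data <- (.as_float32(data) - 0.5) * 2 * (meta$scale_hi - meta$scale_lo) +
      meta$scale_lo
  new_image_stack(data, as.numeric(meta$contrast_axis),
                  meta$contrast_unit, meta$kind)
}

#' Export a phantom's maps and masks
#'
#' Writes the label map, ground-truth T2*/ADC maps and RCC mask of one
#' phantom as a multi-frame stack (label and mask as numeric frames).
#'
#' @param phantom a `kidney_phantom`.
#' @param path output file (`.tif` or `.nii`).
#' @return `path`, invisibly.
#' @export
write_phantom <- function(phantom, path) {
  fill0 <- function(m) { m[is.na(m)] <- 0; m }
  data <- array(c(phantom$label_map, phantom$s0_map,
                  fill0(phantom$t2star_map), fill0(phantom$adc_map),
                  phantom$rcc_mask * 1),
                dim = c(dim(phantom$label_map), 5))
  stack <- new_image_stack(data, seq_len(5), "frame",
                           "phantom:label,s0,t2star,adc,rcc")
  write_stack(stack, path)
}
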