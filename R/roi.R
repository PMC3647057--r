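#' Derive compartment ROIs from a reference
#'
#' Mirrors the "restore selection" protocol: regions are defined once on a
#' reference and reused verbatim (pixel indices, no resampling) on every
#' co-registered map. `from_labels` takes the four compartment classes of a
#' label map directly (phantom ground truth). `band_geometry` reconstructs
#' concentric elliptical bands from the kidney silhouette alone: it fits the
#' pixel-coordinate covariance ellipse of the kidney mask, ranks kidney
#' pixels by elliptical (Mahalanobis) radius, and cuts at the default
#' cumulative area fractions (IM innermost 30%, IS 15%, OS 15%, CTX
#' outermost 40%) — the fallback when only an anatomical image is available.
#'
#' @param reference a `kidney_phantom`, or an integer label map, or (for
#'   `band_geometry`) any 2D image in which kidney pixels are non-zero.
#' @param mode `"from_labels"` or `"band_geometry"`.
#' @param area_fractions kidney-area shares used by `band_geometry`.
#' @return Object of class `roi_set`: `indices` (named list of pixel index
#'   vectors for CTX/OS/IS/IM), `dims`.
#' @export
derive_rois <- function(reference, mode = c("from_labels", "band_geometry"),
                        area_fractions = c(CTX = 0.40, OS = 0.15, IS = 0.15, IM = 0.30)) {
  mode <- match.arg(mode)
  if (inherits(reference, "kidney_phantom")) reference <- reference$label_map
  if (!is.matrix(reference)) stop("reference must be a 2D image or label map")
  dims <- dim(reference)
  cmp <- compartment_names()
  if (mode == "from_labels") {
    idx <- lapply(seq_len(4), function(k) which(reference == k))
  } else {
    kidney <- which(reference != 0 & !is.na(reference))
    if (length(kidney) < 4) stop("band_geometry needs a non-trivial kidney mask")
    ij <- arrayInd(kidney, dims)
    ctr <- colMeans(ij)
    cv <- stats::cov(ij)
    ci <- solve(cv)
    dif <- sweep(ij, 2, ctr)
    r2 <- rowSums((dif %*% ci) * dif)
    cum_in <- cumsum(rev(area_fractions))      # IM, +IS, +OS, 1
    qs <- stats::quantile(r2, probs = cum_in[1:3], names = FALSE)
    band <- findInterval(r2, qs, left.open = FALSE) # 0=IM,1=IS,2=OS,3=CTX
    lab_of_band <- c(4L, 3L, 2L, 1L)
    idx <- lapply(seq_len(4), function(k) kidney[lab_of_band[band + 1L] == k])
  }
  names(idx) <- cmp
  structure(list(indices = idx, dims = dims), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("ROI set on %d x %d grid: %s\n", x$dims[1], x$dims[2],
              paste(sprintf("%s=%d", names(x$indices),
                            lengths(x$indices)), collapse = " ")))
  invisible(x)
}

#' Transfer ROIs to a parameter map and summarise per compartment
#'
#' Applies the ROI pixel indices verbatim to a co-registered map (grids must
#' match; no resampling) and computes per-compartment statistics over valid
#' pixels only, reporting how many pixels were excluded as invalid.
#'
#' @param rois an `roi_set`.
#' @param target a `parameter_map`, or a bare numeric matrix (taken as fully
#'   valid, kind `"si_au"` — e.g. a single-TE signal-intensity frame).
#' @param kidney_id optional identifier carried into the summary.
#' @return Object of class `compartment_summary`: a data.frame with one row
#'   per compartment (`compartment`, `mean`, `sd`, `n_pixels`, `n_invalid`)
#'   and attributes `kind`, `kidney_id`. Empty compartments get `NA` mean,
#'   zero counts, no error.
#' @export
transfer_roi <- function(rois, target, kidney_id = NA_character_) {
  stopifnot(inherits(rois, "roi_set"))
  if (is.matrix(target))
    target <- new_parameter_map(target, "si_au",
                                valid = is.finite(target))
  if (!inherits(target, "parameter_map")) stop("target must be a parameter_map or matrix")
  if (!all(dim(target$values) == rois$dims))
    stop("target grid ", paste(dim(target$values), collapse = "x"),
         " does not match ROI reference grid ",
         paste(rois$dims, collapse = "x"),
         " (maps must be co-registered; no resampling is performed)")
  rows <- lapply(names(rois$indices), function(cm) {
    ii <- rois$indices[[cm]]
    ok <- ii[target$valid[ii]]
    v <- target$values[ok]
    data.frame(compartment = cm,
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else if (length(v) == 1) 0 else NA_real_,
               n_pixels = length(ii),
               n_invalid = length(ii) - length(ok))
  })
  out <- do.call(rbind, rows)
  attr(out, "kind") <- target$kind
  attr(out, "kidney_id") <- kidney_id
  class(out) <- c("compartment_summary", "data.frame")
  out
}

#' Summarise a group of kidneys compartment-wise
#'
#' The replicate unit is the kidney, not the pixel: group mean and sample SD
#' (n - 1 denominator) are taken over per-kidney compartment means, so `n`
#' equals the number of kidneys — the convention of the published
#' compartment tables (n = 3).
#'
#' @param summaries list of `compartment_summary` objects (one per kidney).
#' @param label optional group label (e.g. `"CD1h"`).
#' @return Object of class `group_summary_table`: data.frame with one row
#'   per compartment (`compartment`, `mean`, `sd`, `n`); `sd` is `NA` for a
#'   single kidney.
#' @export
summarize_group <- function(summaries, label = NA_character_) {
  if (length(summaries) == 0) stop("empty group")
  cmp <- compartment_names()
  mat <- vapply(summaries, function(s) {
    stats::setNames(s$mean, s$compartment)[cmp]
  }, numeric(4))
  mat <- matrix(mat, nrow = 4, dimnames = list(cmp, NULL))
  out <- data.frame(
    compartment = cmp,
    mean = rowMeans(mat),
    sd = apply(mat, 1, function(r) if (length(r) > 1) stats::sd(r) else NA_real_),
    n = length(summaries)
  )
  attr(out, "label") <- label
  class(out) <- c("group_summary_table", "data.frame")
  out
}

#' Per-kidney compartment means as a kidneys x compartments matrix
#' @param summaries list of `compartment_summary` objects.
#' @return Numeric matrix, rows = kidneys, columns = CTX/OS/IS/IM.
#' @export
compartment_matrix <- function(summaries) {
  cmp <- compartment_names()
  t(vapply(summaries, function(s) stats::setNames(s$mean, s$compartment)[cmp],
           numeric(4)))
}
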