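# Run expr with a private RNG stream; leaves the caller's RNG state intact.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Select exactly k pixels of `candidates` (logical matrix), clustered into
# blob-like lesions: rank candidates by a Gaussian-smoothed white-noise field
# and keep the top k. Exact count by construction.
clustered_pixels <- function(candidates, k, smooth_sigma = 2.5) {
  mask <- matrix(FALSE, nrow(candidates), ncol(candidates))
  if (k <= 0) return(mask)
  field <- matrix(stats::rnorm(length(candidates)), nrow(candidates))
  field <- as.matrix(EBImage::gblur(EBImage::Image(field), sigma = smooth_sigma))
  idx <- which(candidates)
  keep <- idx[order(field[idx], decreasing = TRUE)[seq_len(min(k, length(idx)))]]
  mask[keep] <- TRUE
  mask
}

# Concentric elliptical compartment geometry. Cumulative area fractions from
# the inside out: IM 30%, +IS 45%, +OS 60%, +CTX 100% of kidney area; for
# similar concentric ellipses the area fraction inside elliptical radius f
# is f^2, so band edges sit at sqrt of the cumulative fractions.
.kidney_labels <- function(nr, nc, area_fractions = c(CTX = 0.40, OS = 0.15, IS = 0.15, IM = 0.30)) {
  stopifnot(abs(sum(area_fractions) - 1) < 1e-8)
  ci <- (nr + 1) / 2; cj <- (nc + 1) / 2
  a <- 0.92 * nr / 2; b <- 0.85 * nc / 2
  i <- matrix(seq_len(nr), nr, nc)
  j <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  r2 <- ((i - ci) / a)^2 + ((j - cj) / b)^2
  cum_in <- cumsum(rev(area_fractions))  # IM, IM+IS, IM+IS+OS, 1
  lab <- matrix(0L, nr, nc)
  lab[r2 <= 1] <- 1L                          # CTX (outermost)
  lab[r2 <= cum_in[3]] <- 2L                  # OS
  lab[r2 <= cum_in[2]] <- 3L                  # IS
  lab[r2 <= cum_in[1]] <- 4L                  # IM
  lab
}

#' Generate a compartmentalised kidney phantom
#'
#' Builds one 2D longitudinal-section kidney phantom on a regular grid: a
#' label map partitioning the kidney into nested elliptical compartments
#' (CTX outermost, then OS, IS, IM), per-pixel ground-truth maps of baseline
#' signal, T2* and ADC, and a red-cell-congestion (RCC) lesion mask. Each
#' compartment's T2* and ADC are drawn once per kidney from the preset's
#' Normal(mean, SD) (exactly the means when the SDs are zero), emulating
#' kidney-to-kidney biological variation. Inside the RCC mask the T2* is
#' multiplied by `rcc_t2star_factor`, modelling the susceptibility effect of
#' trapped deoxygenated red cells; set the factor to 1 to treat the preset
#' means as compartment-level values that already include congestion.
#'
#' @param matrix_dims integer c(rows, cols); rows span the long axis.
#'   Default 256 x 128.
#' @param fov_mm field of view in mm per axis, default c(100, 50); with the
#'   default matrix this gives the nominal 0.39 mm isotropic pixel.
#' @param preset a [condition_preset()].
#' @param seed integer seed; the phantom is a deterministic function of its
#'   arguments and this seed.
#' @param rcc_t2star_factor multiplicative T2* reduction inside RCC lesions.
#' @param area_fractions kidney-area shares of CTX/OS/IS/IM.
#' @return Object of class `kidney_phantom`: `label_map`, `s0_map`,
#'   `t2star_map` (ms), `adc_map` (10^-3 mm^2/s), `rcc_mask`, `pixel_size`
#'   (mm, per axis), `params` (per-compartment values drawn), `condition`,
#'   `perfusion`, `seed`.
#' @export
make_kidney_phantom <- function(matrix_dims = c(256L, 128L),
                                fov_mm = c(100, 50),
                                preset = condition_preset("CD0h"),
                                seed = 1L,
                                rcc_t2star_factor = 0.35,
                                area_fractions = c(CTX = 0.40, OS = 0.15, IS = 0.15, IM = 0.30)) {
  if (length(matrix_dims) != 2 || any(matrix_dims < 32))
    stop("matrix_dims must be two integers >= 32")
  if (length(fov_mm) != 2 || any(fov_mm <= 0)) stop("fov_mm must be two positive lengths")
  if (rcc_t2star_factor <= 0 || rcc_t2star_factor > 1)
    stop("rcc_t2star_factor must lie in (0, 1]")
  validate_preset(preset)
  nr <- as.integer(matrix_dims[1]); nc <- as.integer(matrix_dims[2])
  lab <- .kidney_labels(nr, nc, area_fractions)
  kidney <- lab > 0L

  with_seed(seed, {
    cmp <- compartment_names()
    t2_draw <- stats::setNames(stats::rnorm(4, preset$t2star, preset$t2star_sd), cmp)
    adc_draw <- stats::setNames(stats::rnorm(4, preset$adc, preset$adc_sd), cmp)
    # biological truth must stay physical: resample rare non-positive draws
    for (k in seq_len(4)) {
      while (t2_draw[k] <= 0) t2_draw[k] <- stats::rnorm(1, preset$t2star[k], preset$t2star_sd[k])
      while (adc_draw[k] < 0) adc_draw[k] <- stats::rnorm(1, preset$adc[k], preset$adc_sd[k])
    }
    t2 <- matrix(NA_real_, nr, nc); adc <- matrix(NA_real_, nr, nc)
    for (k in seq_len(4)) {
      t2[lab == k] <- t2_draw[k]
      adc[lab == k] <- adc_draw[k]
    }
    rcc <- matrix(FALSE, nr, nc)
    for (k in seq_len(4)) {
      sev <- preset$rcc_severity[cmp[k]]
      if (sev > 0) {
        comp <- lab == k
        rcc <- rcc | clustered_pixels(comp, round(sev * sum(comp)))
      }
    }
    t2[rcc] <- t2[rcc] * rcc_t2star_factor
    s0 <- matrix(0, nr, nc); s0[kidney] <- 1000

    structure(list(
      label_map = lab, s0_map = s0, t2star_map = t2, adc_map = adc,
      rcc_mask = rcc, pixel_size = fov_mm / c(nr, nc),
      params = list(t2star = t2_draw, adc = adc_draw),
      condition = preset$condition, perfusion = preset$perfusion,
      rcc_t2star_factor = rcc_t2star_factor, seed = as.integer(seed)
    ), class = "kidney_phantom")
  })
}

#' @export
print.kidney_phantom <- function(x, ...) {
  d <- dim(x$label_map)
  cat(sprintf("Kidney phantom %s/%s: %d x %d px, pixel %.4f x %.4f mm\n",
              x$condition, x$perfusion, d[1], d[2], x$pixel_size[1], x$pixel_size[2]))
  cat(sprintf("  kidney px: %d, RCC px: %d\n", sum(x$label_map > 0), sum(x$rcc_mask)))
  cat("  T2* [ms]:", paste(sprintf("%s=%.1f", names(x$params$t2star), x$params$t2star), collapse = " "), "\n")
  cat("  ADC [1e-3 mm^2/s]:", paste(sprintf("%s=%.3f", names(x$params$adc), x$params$adc), collapse = " "), "\n")
  invisible(x)
}

#' Generate a cohort of phantoms across conditions
#'
#' Draws `n` independent kidneys per condition preset, each with its own
#' per-compartment parameter values sampled from the preset distributions.
#' Deterministic given `seed`.
#'
#' @param design named list of `condition_preset` objects, or a list of
#'   `list(preset =, n =)` pairs; a bare preset list uses `n_per_condition`.
#' @param n_per_condition kidneys per condition when `design` holds bare
#'   presets (the source study used 3).
#' @param seed integer master seed.
#' @param ... passed to [make_kidney_phantom()].
#' @return List of `kidney_phantom` objects, each tagged with its condition.
#' @export
make_cohort <- function(design, n_per_condition = 3L, seed = 1L, ...) {
  if (length(design) == 0) stop("empty cohort design")
  entries <- lapply(design, function(d) {
    if (inherits(d, "condition_preset")) list(preset = d, n = n_per_condition)
    else { validate_preset(d$preset); d }
  })
  if (any(vapply(entries, function(e) e$n < 1, logical(1))))
    stop("each condition needs n >= 1 kidneys")
  total <- sum(vapply(entries, function(e) as.integer(e$n), integer(1)))
  subseeds <- with_seed(seed, sample.int(2147483646L, total))
  out <- list(); s <- 0L
  for (e in entries) {
    for (i in seq_len(e$n)) {
      s <- s + 1L
      out[[s]] <- make_kidney_phantom(preset = e$preset, seed = subseeds[s], ...)
    }
  }
  out
}
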