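#' Renal compartment labels
#'
#' Integer codes used in every label map: 0 = background, 1 = cortex (CTX),
#' 2 = outer stripe of the outer medulla (OS), 3 = inner stripe of the outer
#' medulla (IS), 4 = inner medulla (IM).
#'
#' @return Named integer vector of the four compartment codes.
#' @export
compartment_codes <- function() {
  c(CTX = 1L, OS = 2L, IS = 3L, IM = 4L)
}

#' Compartment names in canonical order
#' @return Character vector `c("CTX", "OS", "IS", "IM")`.
#' @export
compartment_names <- function() names(compartment_codes())

# Published per-compartment summaries (mean, SD, n = 3 kidneys) for grafts
# harvested 0/1/2 h after donor cardiac death, with and without University of
# Wisconsin (UW) solution perfusion, plus the CD0h pre/post 3 h UW-incubation
# pair. T2* in ms; ADC in 1e-3 mm^2/s (numerically equal to 1e-9 m^2/s).
.reference_summaries <- function() {
  cmp <- compartment_names()
  t2 <- list(
    none = list(
      CD0h = list(mean = c(146.7, 133.5, 146.1, 218.1), sd = c(10.8, 3.8, 14.1, 10.3)),
      CD1h = list(mean = c(70.4, 56.8, 42.3, 90.1),     sd = c(1.4, 5.2, 5.8, 4.0)),
      CD2h = list(mean = c(69.9, 58.7, 51.3, 84.8),     sd = c(1.3, 2.1, 0.6, 3.6))
    ),
    uw_perfused = list(
      CD0h = list(mean = c(187.3, 182.9, 177.9, 222.4), sd = c(6.6, 13.1, 16.5, 9.3)),
      CD1h = list(mean = c(140.7, 148.5, 143.0, 168.7), sd = c(3.0, 1.0, 6.6, 12.4)),
      CD2h = list(mean = c(80.2, 77.1, 63.6, 95.9),     sd = c(5.7, 5.0, 2.1, 4.0))
    ),
    uw_incubated = list(
      CD0h = list(mean = c(87.3, 81.4, 87.9, 137.6),    sd = c(7.8, 4.9, 9.0, 6.5))
    )
  )
  adc <- list(
    none = list(
      CD0h = list(mean = c(0.626, 0.793, 0.665, 0.985), sd = c(0.043, 0.066, 0.073, 0.029)),
      CD1h = list(mean = c(0.743, 0.676, 0.773, 0.783), sd = c(0.070, 0.120, 0.067, 0.097)),
      CD2h = list(mean = c(0.667, 0.558, 0.833, 0.840), sd = c(0.054, 0.068, 0.030, 0.120))
    ),
    uw_perfused = list(
      CD0h = list(mean = c(0.568, 0.543, 0.557, 0.983), sd = c(0.060, 0.028, 0.011, 0.013)),
      CD1h = list(mean = c(0.621, 0.486, 0.528, 0.810), sd = c(0.091, 0.068, 0.054, 0.060)),
      CD2h = list(mean = c(0.897, 0.774, 0.671, 0.843), sd = c(0.094, 0.008, 0.053, 0.064))
    ),
    uw_incubated = list(
      CD0h = list(mean = c(0.677, 0.750, 0.517, 0.871), sd = c(0.033, 0.057, 0.013, 0.011))
    )
  )
  name_all <- function(x) lapply(x, function(cond) lapply(cond, function(s) {
    lapply(s, function(v) stats::setNames(v, cmp))
  }))
  list(t2star = name_all(t2), adc = name_all(adc), n = 3L)
}

#' Published compartment-level reference summaries
#'
#' Per-compartment (mean, SD, n = 3) summaries of T2* (ms) and ADC
#' (10^-3 mm^2/s) for kidney grafts harvested 0, 1 or 2 hours after donor
#' cardiac death (CD0h/CD1h/CD2h), under three preservation states:
#' `"none"` (imaged immediately, no perfusion), `"uw_perfused"` (perfused
#' with University of Wisconsin solution before imaging) and
#' `"uw_incubated"` (CD0h only, after 3 h cold UW incubation).
#'
#' @param kind `"t2star"` or `"adc"`.
#' @param perfusion `"none"`, `"uw_perfused"` or `"uw_incubated"`.
#' @return A list keyed by condition (`CD0h`, ...), each with named numeric
#'   vectors `mean` and `sd` over compartments, plus attribute `n`.
#' @export
reference_summary <- function(kind = c("t2star", "adc"),
                              perfusion = c("none", "uw_perfused", "uw_incubated")) {
  kind <- match.arg(kind)
  perfusion <- match.arg(perfusion)
  tabs <- .reference_summaries()
  out <- tabs[[kind]][[perfusion]]
  attr(out, "n") <- tabs$n
  out
}

#' Build a condition preset
#'
#' A preset bundles the per-compartment ground-truth distributions used by
#' the phantom generator for one experimental condition: mean and SD of T2*
#' and ADC for each of CTX/OS/IS/IM, and a red-cell-congestion (RCC)
#' severity per compartment (the fraction of compartment pixels occupied by
#' congestion lesions).
#'
#' @param condition `"CD0h"`, `"CD1h"` or `"CD2h"` (hours between donor
#'   cardiac death and harvest).
#' @param perfusion preservation state; see [reference_summary()].
#' @param t2star,t2star_sd,adc,adc_sd optional named numeric vectors over
#'   compartments overriding the published defaults.
#' @param rcc_severity named numeric vector in \[0, 1\] per compartment;
#'   defaults encode congestion concentrated in the inner stripe for
#'   CD1h/CD2h grafts (partially washed out of CD1h by UW perfusion).
#' @param zero_sd if `TRUE`, set all SDs to zero (every kidney drawn from
#'   this preset carries exactly the mean values).
#' @return An object of class `condition_preset`.
#' @export
condition_preset <- function(condition = c("CD0h", "CD1h", "CD2h"),
                             perfusion = c("none", "uw_perfused", "uw_incubated"),
                             t2star = NULL, t2star_sd = NULL,
                             adc = NULL, adc_sd = NULL,
                             rcc_severity = NULL,
                             zero_sd = FALSE) {
  condition <- match.arg(condition)
  perfusion <- match.arg(perfusion)
  t2_ref <- reference_summary("t2star", perfusion)
  adc_ref <- reference_summary("adc", perfusion)
  if (is.null(t2_ref[[condition]]))
    stop("no published summaries for ", condition, " under perfusion '", perfusion, "'")
  cmp <- compartment_names()
  pick <- function(user, ref) {
    v <- if (is.null(user)) ref else user[cmp]
    if (any(is.na(v))) stop("preset values must name all four compartments")
    stats::setNames(as.numeric(v), cmp)
  }
  sev_default <- .default_rcc_severity(condition, perfusion)
  p <- structure(list(
    condition = condition,
    perfusion = perfusion,
    t2star = pick(t2star, t2_ref[[condition]]$mean),
    t2star_sd = pick(t2star_sd, if (zero_sd) rep(0, 4) else t2_ref[[condition]]$sd),
    adc = pick(adc, adc_ref[[condition]]$mean),
    adc_sd = pick(adc_sd, if (zero_sd) rep(0, 4) else adc_ref[[condition]]$sd),
    rcc_severity = pick(rcc_severity, sev_default)
  ), class = "condition_preset")
  if (zero_sd && is.null(t2star_sd) && is.null(adc_sd)) {
    p$t2star_sd[] <- 0; p$adc_sd[] <- 0
  }
  validate_preset(p)
  p
}

# Default lesion loads: congestion develops in the inner stripe within the
# first hour post-mortem and persists; UW perfusion partially washes it out
# of CD1h but not CD2h grafts. Magnitudes are generator conventions (the
# source figures are not digitised), chosen so the inner stripe dominates.
.default_rcc_severity <- function(condition, perfusion) {
  base <- c(CTX = 0, OS = 0, IS = 0, IM = 0)
  if (condition == "CD0h") return(base)
  base[c("CTX", "OS", "IM")] <- if (condition == "CD1h") 0.02 else 0.04
  base["IS"] <- if (condition == "CD1h") 0.35 else 0.40
  if (perfusion == "uw_perfused" && condition == "CD1h") base["IS"] <- 0.10
  base
}

validate_preset <- function(p) {
  stopifnot(inherits(p, "condition_preset"))
  if (any(p$t2star <= 0) || any(p$adc < 0))
    stop("preset means must be positive (T2*) / non-negative (ADC)")
  if (any(p$t2star_sd < 0) || any(p$adc_sd < 0)) stop("preset SDs must be >= 0")
  if (any(p$rcc_severity < 0 | p$rcc_severity > 1))
    stop("rcc_severity must lie in [0, 1]")
  invisible(p)
}

#' Presets for all conditions of one preservation state
#'
#' @inheritParams condition_preset
#' @param conditions conditions to include.
#' @return Named list of `condition_preset` objects.
#' @export
condition_presets <- function(perfusion = c("none", "uw_perfused"),
                              conditions = c("CD0h", "CD1h", "CD2h"),
                              zero_sd = FALSE) {
  perfusion <- match.arg(perfusion)
  stats::setNames(
    lapply(conditions, condition_preset, perfusion = perfusion, zero_sd = zero_sd),
    conditions
  )
}

#' @export
print.condition_preset <- function(x, ...) {
  cat("Condition preset:", x$condition, "/", x$perfusion, "\n")
  m <- rbind(`T2* [ms]` = x$t2star, `T2* SD` = x$t2star_sd,
             `ADC [1e-3 mm^2/s]` = x$adc, `ADC SD` = x$adc_sd,
             `RCC severity` = x$rcc_severity)
  print(round(m, 3))
  invisible(x)
}

#' Read condition presets from a YAML file
#'
#' One top-level section per condition; fields mirror the arguments of
#' [condition_preset()] with per-compartment values keyed CTX/OS/IS/IM.
#'
#' @param path YAML file path.
#' @return Named list of `condition_preset` objects.
#' @export
read_presets <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(cond) {
    s <- raw[[cond]]
    as_vec <- function(x) if (is.null(x)) NULL else unlist(x)
    condition_preset(
      condition = cond,
      perfusion = if (is.null(s$perfusion)) "none" else s$perfusion,
      t2star = as_vec(s$t2star), t2star_sd = as_vec(s$t2star_sd),
      adc = as_vec(s$adc), adc_sd = as_vec(s$adc_sd),
      rcc_severity = as_vec(s$rcc_severity)
    )
  })
  stats::setNames(out, names(raw))
}

#' Write condition presets to a YAML file
#' @param presets named list of `condition_preset` objects.
#' @param path output file.
#' @export
write_presets <- function(presets, path) {
  ser <- lapply(presets, function(p) list(
    perfusion = p$perfusion,
    t2star = as.list(p$t2star), t2star_sd = as.list(p$t2star_sd),
    adc = as.list(p$adc), adc_sd = as.list(p$adc_sd),
    rcc_severity = as.list(p$rcc_severity)
  ))
  names(ser) <- vapply(presets, function(p) p$condition, character(1))
  yaml::write_yaml(ser, path)
  invisible(path)
}
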