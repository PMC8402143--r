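#' Ultrafiltration binding arithmetic
#'
#' Plasma/matrix protein binding measured by centrifugal ultrafiltration.
#' `nsb_percent()` quantifies non-specific binding of drug to the filtration
#' device from a protein-free buffer control; `free_fraction_percent()`
#' corrects the measured filtrate concentration for that loss and references
#' it to the pre-spin matrix concentration; `recovery_percent()` audits mass
#' balance over the device from the filtrate and retentate concentrations.
#'
#' @param c_before,c_after Buffer-control concentrations before and after the
#'   spin, µg/mL.
#' @param cf Measured filtrate concentration, µg/mL.
#' @param c2 Matrix concentration sampled just before the spin, µg/mL (> 0).
#' @param nsb Non-specific binding, percent (0 to < 100).
#' @param c3 Retentate concentration after the spin, µg/mL.
#' @param filtrate_weight Filtrate mass, g (treated as mL at unit density).
#' @param reservoir_volume Loaded volume remaining in the device, mL
#'   (default 0.4 = 500 µL loaded minus the 100 µL pre-spin aliquot).
#' @return A percentage.
#' @examples
#' nsb <- nsb_percent(5, 4.624)            # 7.52 %
#' free_fraction_percent(0.806 * 3, 3, nsb) # ~87.1 %
#' @export
nsb_percent <- function(c_before, c_after) {
  if (any(c_before <= 0)) stop("`c_before` must be positive")
  (c_before - c_after) / c_before * 100
}

#' @rdname nsb_percent
#' @export
free_fraction_percent <- function(cf, c2, nsb = 0) {
  if (any(c2 <= 0)) stop("`c2` must be positive")
  if (any(nsb < 0) || any(nsb >= 100)) stop("`nsb` must lie in [0, 100)")
  crf <- cf * 100 / (100 - nsb)
  crf / c2 * 100
}

#' @rdname nsb_percent
#' @export
recovery_percent <- function(cf, c3, c2, filtrate_weight,
                             reservoir_volume = 0.4) {
  if (any(c2 <= 0)) stop("`c2` must be positive")
  stopifnot(all(filtrate_weight >= 0), all(reservoir_volume > 0))
  if (any(filtrate_weight > reservoir_volume)) {
    stop("filtrate weight cannot exceed the reservoir volume")
  }
  (cf * filtrate_weight + c3 * (reservoir_volume - filtrate_weight)) /
    (c2 * reservoir_volume) * 100
}

#' Metabolite formation clearance from an S9 time course
#'
#' Fits the initial (linear) formation rate of metabolite per mg of S9
#' protein by least squares on the amount-versus-time points, and divides by
#' the substrate concentration to obtain a formation clearance in
#' µL/min/mg protein (pmol/min/mg divided by µM = pmol/µL gives µL/min/mg).
#'
#' @param times Sampling times, min (at least 2 points; a zero point is
#'   customary).
#' @param amounts Metabolite amounts, pmol/mg protein, same length.
#' @param substrate_conc Substrate concentration, µM (> 0).
#' @param through_origin Force the regression through the origin
#'   (default `FALSE`: ordinary least squares with intercept).
#' @return A tibble with `rate` (pmol/min/mg), `clearance` (µL/min/mg) and
#'   `clipped` (`TRUE` when a negative slope was clipped to zero, with a
#'   warning).
#' @examples
#' formation_clearance(c(0, 15, 30), c(0, 1087.5, 2175), 50)
#' @export
formation_clearance <- function(times, amounts, substrate_conc,
                                through_origin = FALSE) {
  stopifnot(length(times) == length(amounts), length(times) >= 2,
            substrate_conc > 0, all(amounts >= 0))
  fit <- if (through_origin) {
    stats::lm(amounts ~ times + 0)
  } else {
    stats::lm(amounts ~ times)
  }
  rate <- stats::coef(fit)[["times"]]
  clipped <- FALSE
  if (rate < 0) {
    warning("negative formation rate clipped to zero")
    rate <- 0
    clipped <- TRUE
  }
  tibble::tibble(rate = rate, clearance = rate / substrate_conc,
                 clipped = clipped)
}

#' Scale an S9 formation clearance to the whole liver
#'
#' In vitro-in vivo extrapolation of a per-mg-protein clearance:
#' `CLu = cl_per_mg * s9_yield * liver_mass / fu_inc / 1000`, converting
#' µL/min to mL/min and correcting for unbound fraction in the incubation.
#'
#' @param cl_per_mg In vitro formation clearance, µL/min/mg protein.
#' @param s9_yield S9 protein yield, mg/g liver.
#' @param liver_mass Liver mass, g.
#' @param fu_inc Unbound fraction in the incubation (0, 1\].
#' @return Whole-liver unbound formation clearance, mL/min.
#' @examples
#' ivive_scale(1.45, 135, 9, 0.380) # 4.64 mL/min
#' @export
ivive_scale <- function(cl_per_mg, s9_yield, liver_mass, fu_inc) {
  stopifnot(cl_per_mg > 0, s9_yield > 0, liver_mass > 0,
            fu_inc > 0, fu_inc <= 1)
  cl_per_mg * s9_yield * liver_mass / fu_inc / 1000
}

#' Empirical IVIVE scaling factor
#'
#' Ratio of the in vivo unbound intrinsic (formation) clearance to the
#' bottom-up scaled in vitro value; a factor of 1 means the extrapolation is
#' quantitative.
#'
#' @param in_vivo_cl In vivo clearance, mL/min.
#' @param in_vitro_cl Scaled in vitro clearance, mL/min (> 0).
#' @return Fold (unitless).
#' @export
ivive_scaling_factor <- function(in_vivo_cl, in_vitro_cl) {
  if (any(in_vitro_cl <= 0)) stop("`in_vitro_cl` must be positive")
  in_vivo_cl / in_vitro_cl
}
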