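#' Terminal log-linear slope and half-life
#'
#' Estimates the terminal elimination rate constant by log-linear regression
#' on the terminal portion of a concentration-time profile. With
#' `n_terminal = "auto"` the number of terminal points (3 to 6, excluding any
#' trailing zeros) is chosen by best adjusted R-squared, mirroring the common
#' automatic selection of NCA software.
#'
#' @param profile A data frame with columns `time` (min, strictly increasing)
#'   and `conc` (µg/mL, non-negative).
#' @param n_terminal Number of terminal points, or `"auto"`.
#' @return A tibble with `lambda_z` (1/min), `t_half` (min), `n_points` and
#'   `adj_r_squared`.
#' @examples
#' prof <- data.frame(time = c(5, 15, 30, 60, 120), conc = 10 * exp(-0.01 * c(5, 15, 30, 60, 120)))
#' terminal_slope(prof)
#' @export
terminal_slope <- function(profile, n_terminal = "auto") {
  profile <- .check_profile(profile)
  pos <- profile[profile$conc > 0, ]
  if (nrow(pos) < 3) stop("need at least 3 positive concentrations for lambda_z")
  fit_tail <- function(n) {
    tail_df <- utils::tail(pos, n)
    # noise-free inputs give an exactly perfect fit; silence the summary note
    suppressWarnings({
      fit <- stats::lm(log(conc) ~ time, data = tail_df)
      adj_r2 <- summary(fit)$adj.r.squared
    })
    slope <- stats::coef(fit)[["time"]]
    list(lambda_z = -slope, adj_r2 = adj_r2, n = n)
  }
  if (identical(n_terminal, "auto")) {
    ns <- 3:min(6, nrow(pos))
    fits <- lapply(ns, fit_tail)
    fits <- Filter(function(f) f$lambda_z > 0, fits)
    if (!length(fits)) stop("no positive terminal slope found")
    best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "adj_r2"))]]
  } else {
    stopifnot(is.numeric(n_terminal), n_terminal >= 3, n_terminal <= nrow(pos))
    best <- fit_tail(n_terminal)
    if (best$lambda_z <= 0) stop("terminal slope is not negative on the chosen tail")
  }
  tibble::tibble(lambda_z = best$lambda_z, t_half = log(2) / best$lambda_z,
                 n_points = best$n, adj_r_squared = best$adj_r2)
}

.check_profile <- function(profile) {
  stopifnot(all(c("time", "conc") %in% names(profile)))
  profile <- profile[order(profile$time), c("time", "conc")]
  if (any(duplicated(profile$time))) stop("profile times must be strictly increasing")
  if (any(profile$conc < 0)) stop("concentrations must be non-negative")
  profile
}

# linear-up/log-down trapezoid increments for AUC and AUMC
.auc_segments <- function(t, c) {
  dt <- diff(t)
  c1 <- c[-length(c)]; c2 <- c[-1]
  t1 <- t[-length(t)]; t2 <- t[-1]
  logdown <- c2 < c1 & c2 > 0 & c1 > 0
  auc <- ifelse(logdown,
                dt * (c1 - c2) / log(c1 / c2),
                dt * (c1 + c2) / 2)
  aumc <- ifelse(logdown,
                 dt * (t1 * c1 - t2 * c2) / log(c1 / c2) +
                   dt^2 * (c1 - c2) / log(c1 / c2)^2,
                 dt * (t1 * c1 + t2 * c2) / 2)
  list(auc = auc, aumc = aumc)
}

#' AUC, moments, clearance and steady-state volume
#'
#' Computes exposure metrics by the linear-up/log-down trapezoidal rule with
#' a `C_last / lambda_z` extrapolated tail: area under the curve to infinity,
#' the first-moment area, mean residence time, total clearance
#' (`dose / AUCinf`, per kg) and the steady-state distribution volume
#' (`Vss = CL * MRT`).
#'
#' For an IV bolus profile whose first sample is after dosing,
#' `extrapolate_c0 = TRUE` (default) prepends a back-extrapolated time-zero
#' concentration from a log-linear line through the first two positive
#' samples (falling back to the first concentration when the profile does not
#' start by declining) — the standard IV-bolus convention of NCA software.
#'
#' @inheritParams terminal_slope
#' @param lambda_z Terminal rate constant, 1/min (e.g. from
#'   [terminal_slope()]).
#' @param dose Administered dose, µg.
#' @param body_weight Body weight, kg (clearance and Vss are reported per kg).
#' @param extrapolate_c0 Back-extrapolate a time-zero concentration when the
#'   profile lacks one (IV bolus convention).
#' @return A tibble with `auc_last`, `auc_inf` (µg·min/mL), `aumc_inf`,
#'   `mrt` (min), `cl` (mL/min/kg) and `vss` (mL/kg).
#' @export
auc_moments <- function(profile, lambda_z, dose, body_weight,
                        extrapolate_c0 = TRUE) {
  profile <- .check_profile(profile)
  stopifnot(lambda_z > 0, dose >= 0, body_weight > 0)
  if (all(profile$conc == 0)) stop("zero AUC: clearance is undefined")
  if (extrapolate_c0 && profile$time[1] > 0) {
    c1 <- profile$conc[1]; c2 <- profile$conc[2]
    t1 <- profile$time[1]; t2 <- profile$time[2]
    c0 <- if (c1 > c2 && c2 > 0) {
      exp(log(c1) - (log(c2) - log(c1)) / (t2 - t1) * t1)
    } else {
      c1
    }
    profile <- rbind(data.frame(time = 0, conc = c0), profile)
  }
  t <- profile$time; c <- profile$conc
  seg <- .auc_segments(t, c)
  auc_last <- sum(seg$auc)
  aumc_last <- sum(seg$aumc)
  c_last <- c[max(which(c > 0))]
  t_last <- t[max(which(c > 0))]
  auc_inf <- auc_last + c_last / lambda_z
  aumc_inf <- aumc_last + c_last * t_last / lambda_z + c_last / lambda_z^2
  if (auc_inf <= 0) stop("zero AUC: clearance is undefined")
  mrt <- aumc_inf / auc_inf
  cl <- dose / auc_inf / body_weight
  tibble::tibble(auc_last = auc_last, auc_inf = auc_inf, aumc_inf = aumc_inf,
                 mrt = mrt, cl = cl, vss = cl * mrt)
}

#' Partition total clearance into renal and non-renal components
#'
#' Renal clearance is the amount excreted unchanged in urine divided by the
#' total exposure, `CLR = Ae / AUCinf` (per kg); non-renal clearance is the
#' remainder, `CLNR = CL - CLR`.
#'
#' @param dose Administered dose, µg.
#' @param auc_inf Exposure, µg·min/mL (> 0).
#' @param ae_urine Amount excreted in urine, µg (0 to `dose`).
#' @param body_weight Body weight, kg.
#' @return A tibble with `cl`, `cl_r`, `cl_nr` (mL/min/kg).
#' @export
clearance_partition <- function(dose, auc_inf, ae_urine, body_weight) {
  stopifnot(auc_inf > 0, body_weight > 0, ae_urine >= 0)
  if (ae_urine > dose) stop("urinary recovery cannot exceed the dose")
  cl <- dose / auc_inf / body_weight
  cl_r <- ae_urine / auc_inf / body_weight
  tibble::tibble(cl = cl, cl_r = cl_r, cl_nr = cl - cl_r)
}

#' Cumulative urinary recovery
#'
#' Running sum of interval urinary amounts as percent of dose, reported at
#' each interval end.
#'
#' @param urine A data frame with columns `start` and `end` (h, contiguous
#'   non-overlapping intervals) and `amount` (µg, non-negative).
#' @param dose Administered dose, µg.
#' @return A tibble with `end` (h) and `cum_percent`.
#' @export
cumulative_recovery <- function(urine, dose) {
  stopifnot(all(c("start", "end", "amount") %in% names(urine)), dose > 0)
  urine <- urine[order(urine$start), ]
  if (any(urine$amount < 0)) stop("urinary amounts must be non-negative")
  if (any(urine$end <= urine$start)) stop("intervals must have positive width")
  if (nrow(urine) > 1 && any(abs(urine$start[-1] - urine$end[-nrow(urine)]) > 1e-9)) {
    stop("urine collection intervals must be contiguous")
  }
  cum <- cumsum(urine$amount) / dose * 100
  if (cum[length(cum)] > 100 + 1e-9) stop("cumulative recovery exceeds the dose")
  tibble::tibble(end = urine$end, cum_percent = cum)
}

#' Observed tissue-to-plasma ratio
#'
#' Steady-state partition coefficient from paired tissue and plasma
#' concentrations, assuming unit tissue density. Homogenate dilution is
#' undone with `dilution_factor` (e.g. 3 for a two-fold volume of buffer
#' added to one part tissue, 6 for a five-fold volume).
#'
#' @param c_tissue Measured tissue (homogenate) concentration, µg/g.
#' @param c_plasma Plasma concentration, µg/mL (> 0).
#' @param dilution_factor Total-volume/tissue-volume ratio of the homogenate
#'   (default 1 = undiluted).
#' @return Tissue-to-plasma ratio (unitless).
#' @export
kp_ss_observed <- function(c_tissue, c_plasma, dilution_factor = 1) {
  if (any(c_plasma <= 0)) stop("plasma concentration must be positive")
  stopifnot(all(dilution_factor >= 1))
  c_tissue * dilution_factor / c_plasma
}

#' Full non-compartmental analysis of one profile
#'
#' Runs [terminal_slope()], [auc_moments()] and, when urine data are given,
#' [clearance_partition()], returning the standard NCA parameter set for a
#' single animal (or a mean profile): AUCinf, lambda_z, terminal half-life,
#' MRT, Vss, CL, CLR, CLNR, Cmax and Tmax.
#'
#' @inheritParams auc_moments
#' @param ae_urine Total amount excreted in urine, µg, or `NA` to skip the
#'   renal/non-renal split.
#' @param n_terminal Passed to [terminal_slope()].
#' @return A one-row tibble of NCA parameters (clearances in mL/min/kg,
#'   volumes in mL/kg, times in min).
#' @examples
#' t <- c(1, 5, 15, 30, 60, 120, 180, 240, 360, 480)
#' prof <- data.frame(time = t, conc = 12 * exp(-0.012 * t))
#' run_nca(prof, dose = 2976, body_weight = 0.2976)
#' @export
run_nca <- function(profile, dose, body_weight, ae_urine = NA,
                    n_terminal = "auto") {
  profile <- .check_profile(profile)
  ts <- terminal_slope(profile, n_terminal)
  mo <- auc_moments(profile, ts$lambda_z, dose, body_weight)
  imax <- which.max(profile$conc)
  out <- tibble::tibble(
    auc_inf = mo$auc_inf, lambda_z = ts$lambda_z, t_half_beta = ts$t_half,
    mrt = mo$mrt, vss = mo$vss, cl = mo$cl,
    cmax = profile$conc[imax], tmax = profile$time[imax]
  )
  if (!is.na(ae_urine)) {
    part <- clearance_partition(dose, mo$auc_inf, ae_urine, body_weight)
    out$cl_r <- part$cl_r
    out$cl_nr <- part$cl_nr
  } else {
    out$cl_r <- NA_real_
    out$cl_nr <- NA_real_
  }
  out
}

#' Per-animal NCA over a study table
#'
#' Applies [run_nca()] to each animal of a tidy study table and returns one
#' row per animal plus, optionally, the across-animal arithmetic mean and SD
#' (the reporting convention for small-animal PK tables). Mean-of-individual
#' parameters is reported rather than parameters of the mean profile; the two
#' differ because clearance is a reciprocal of exposure.
#'
#' @param profiles A tidy tibble with columns `animal`, `time`, `conc`,
#'   `dose`, `body_weight` (and optionally `ae_urine`, constant per animal).
#' @param summarise If `TRUE`, append `mean` and `sd` rows.
#' @return A tibble of per-animal NCA results.
#' @export
nca_by_animal <- function(profiles, summarise = FALSE) {
  stopifnot(all(c("animal", "time", "conc", "dose", "body_weight") %in% names(profiles)))
  res <- profiles |>
    dplyr::mutate(animal = as.character(.data$animal)) |>
    dplyr::group_by(.data$animal) |>
    dplyr::group_modify(function(df, key) {
      run_nca(df[, c("time", "conc")], dose = df$dose[1],
              body_weight = df$body_weight[1],
              ae_urine = if ("ae_urine" %in% names(df)) df$ae_urine[1] else NA)
    }) |>
    dplyr::ungroup()
  if (summarise) {
    num <- dplyr::select(res, -"animal")
    res <- dplyr::bind_rows(
      res,
      dplyr::mutate(dplyr::summarise(num, dplyr::across(
        dplyr::everything(), mean)), animal = "mean"),
      dplyr::mutate(dplyr::summarise(num, dplyr::across(
        dplyr::everything(), stats::sd)), animal = "sd")
    )
  }
  res
}
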