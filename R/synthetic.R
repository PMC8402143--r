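#' Virtual-rat study design
#'
#' Defaults reproduce the in-vivo study conditions the analysis pipeline
#' expects: 9 animals per arm, an IV bolus of 10 mg/kg of parent-drug salt,
#' 11 nominal sampling times over 480 min, five urine collection intervals
#' over 24 h, and the additive-plus-proportional observation variance model.
#' Between-animal variability is lognormal on clearance-type and
#' partition-type parameters with a 20% coefficient of variation, chosen to
#' approximate the dispersion typical of small-animal PK parameter tables;
#' body weight is normal with the control arm's final mean and SD.
#'
#' @param n_animals Animals per arm.
#' @param bw_mean,bw_sd Body-weight distribution, kg.
#' @param dose_mg_kg IV bolus dose, mg/kg (administered as the salt).
#' @param sampling_times Plasma sampling times, min (the 0-min blank is not
#'   simulated).
#' @param urine_intervals Two-column matrix or data frame of interval start
#'   and end times, h.
#' @param vm A [variance_model()] for plasma concentrations.
#' @param vm_urine A [variance_model()] for interval urine amounts (µg scale).
#' @param bsv_cv Between-animal CV on perturbed parameters.
#' @param seed Integer seed; every generated study is a pure function of the
#'   design including this seed.
#' @return A `study_design` list.
#' @export
study_design <- function(n_animals = 9, bw_mean = 0.2976, bw_sd = 0.0193,
                         dose_mg_kg = 10,
                         sampling_times = c(1, 5, 15, 30, 60, 120, 180, 240, 360, 480),
                         urine_intervals = data.frame(
                           start = c(0, 2, 4, 6, 8), end = c(2, 4, 6, 8, 24)),
                         vm = variance_model(0.01, 0.1),
                         vm_urine = variance_model(1, 0.1),
                         bsv_cv = 0.2, seed = 1L) {
  stopifnot(n_animals >= 1, bw_mean > 0, bw_sd >= 0, dose_mg_kg > 0,
            all(diff(sampling_times) > 0), bsv_cv >= 0)
  structure(
    list(n_animals = n_animals, bw_mean = bw_mean, bw_sd = bw_sd,
         dose_mg_kg = dose_mg_kg, sampling_times = sampling_times,
         urine_intervals = as.data.frame(urine_intervals),
         vm = vm, vm_urine = vm_urine, bsv_cv = bsv_cv,
         seed = as.integer(seed)),
    class = "study_design"
  )
}

# mean-preserving lognormal multiplier with coefficient of variation cv
.lognormal_fold <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

.perturb_bundle <- function(bundle, cv) {
  b <- bundle
  b$kp <- b$kp * .lognormal_fold(length(b$kp), cv)
  b$hepatic$clu_int <- b$hepatic$clu_int * .lognormal_fold(1, cv)
  b$kidney$clu_int_r <- b$kidney$clu_int_r * .lognormal_fold(1, cv)
  b$kidney$cl_rabs <- b$kidney$cl_rabs * .lognormal_fold(1, cv)
  active <- b$kidney$ps_in - b$kidney$ps_pas
  b$kidney$ps_in <- b$kidney$ps_pas + active * .lognormal_fold(1, cv)
  b
}

.add_noise <- function(y, vm) {
  if (is.null(vm)) return(y)
  pmax(0, y + stats::rnorm(length(y), 0, sqrt(obs_variance(y, vm))))
}

#' Generate a virtual bolus plasma/urine study
#'
#' Simulates one study arm animal by animal: body weight drawn from the
#' design's distribution, clearance- and partition-type parameters perturbed
#' lognormally (between-animal variability), the PBPK model solved for the
#' bolus regimen, plasma sampled on the design grid with
#' additive-plus-proportional observation noise (truncated at zero), and
#' urinary amounts integrated over the collection intervals, multiplied by
#' the per-drug urinary calibration factors, and noised on the amount scale.
#' The output is fully reproducible from the design seed.
#'
#' @param design A [study_design()].
#' @param pa,napa `drug_params` bundles for the arm being generated (pass
#'   treatment bundles, e.g. from [apply_treatment()], for a treated arm).
#' @param calibration Named numeric (`pa`, `napa`): observation-scale factors
#'   on urinary amounts.
#' @param noise If `FALSE`, suppress both between-animal variability and
#'   observation noise (deterministic output).
#' @return A list with `profiles` (tibble: `animal`, `drug`, `time`, `conc`,
#'   `dose`, `body_weight`), `urine` (tibble: `animal`, `drug`, `start`,
#'   `end` in h, `amount` µg, `dose`) and `truth` (the design and bundles
#'   used).
#' @export
generate_bolus_study <- function(design, pa, napa,
                                 calibration = c(pa = 1.29, napa = 0.836),
                                 noise = TRUE) {
  stopifnot(inherits(design, "study_design"),
            inherits(pa, "drug_params"), inherits(napa, "drug_params"))
  set.seed(design$seed)
  cv <- if (noise) design$bsv_cv else 0
  interval_min <- design$urine_intervals * 60
  profiles <- list(); urine <- list()
  for (i in seq_len(design$n_animals)) {
    bw <- if (noise && design$bw_sd > 0) {
      min(1, max(0.1, stats::rnorm(1, design$bw_mean, design$bw_sd)))
    } else design$bw_mean
    phys <- rat_physiology(bw)
    pa_i <- .perturb_bundle(pa, cv)
    napa_i <- .perturb_bundle(napa, cv)
    model <- pbpk_model(phys, pa_i, napa_i, rtol = 1e-7, atol = 1e-9)
    dose <- design$dose_mg_kg * bw * 1000
    times <- sort(unique(c(0, design$sampling_times,
                           interval_min$start, interval_min$end)))
    sim <- simulate_pbpk(model, regimen_iv_bolus(dose), times)
    for (drug in c("pa", "napa")) {
      prof <- sim_profile(sim, drug)
      prof <- prof[prof$time %in% design$sampling_times, ]
      conc <- if (noise) .add_noise(prof$conc, design$vm) else prof$conc
      profiles[[length(profiles) + 1L]] <- tibble::tibble(
        animal = i, drug = drug, time = prof$time, conc = conc,
        dose = dose, body_weight = bw
      )
      cum <- sim_urine(sim, drug, calibration = calibration[[drug]])
      amt <- diff(cum$amount[match(c(0, interval_min$end), cum$time)])
      amt <- if (noise) .add_noise(amt, design$vm_urine) else amt
      urine[[length(urine) + 1L]] <- tibble::tibble(
        animal = i, drug = drug,
        start = design$urine_intervals$start, end = design$urine_intervals$end,
        amount = amt, dose = dose
      )
    }
  }
  list(profiles = dplyr::bind_rows(profiles),
       urine = dplyr::bind_rows(urine),
       truth = list(design = design, pa = pa, napa = napa,
                    calibration = calibration))
}

#' Generate a virtual steady-state tissue-distribution study
#'
#' Emulates the loading-dose + constant-infusion design: each animal receives
#' a loading bolus and a constant infusion of the parent drug, plasma is
#' sampled up to the sacrifice time, and the six major tissues are sampled at
#' sacrifice with multiplicative lognormal noise. The noise-free model is
#' checked for attainment of plasma steady state at the sacrifice time.
#'
#' @param design A [study_design()] (only `n_animals`, body weight, noise and
#'   seed fields are used).
#' @param pa,napa `drug_params` bundles for the arm.
#' @param loading_mg_kg Loading dose, mg/kg.
#' @param infusion_mg_kg_h Constant infusion rate, mg/kg/h.
#' @param sample_time Sacrifice time, min.
#' @param plasma_times Plasma sampling times, min.
#' @param tissue_cv Multiplicative CV of the tissue measurement.
#' @param noise As in [generate_bolus_study()].
#' @return A list with `plasma` (tibble: `animal`, `drug`, `time`, `conc`)
#'   and `tissues` (tibble: `animal`, `drug`, `tissue`, `conc`, `c_plasma`,
#'   `kp_ss`).
#' @export
generate_infusion_study <- function(design, pa, napa,
                                    loading_mg_kg = 1.4,
                                    infusion_mg_kg_h = 2.5,
                                    sample_time = 60,
                                    plasma_times = c(1, 5, 15, 30, 45, 60),
                                    tissue_cv = 0.15, noise = TRUE) {
  stopifnot(inherits(design, "study_design"))
  set.seed(design$seed + 1L)
  cv <- if (noise) design$bsv_cv else 0
  tissues <- c("brain", "heart", "kidney", "liver", "lung", "spleen")
  plasma <- list(); tiss <- list()
  for (i in seq_len(design$n_animals)) {
    bw <- if (noise && design$bw_sd > 0) {
      min(1, max(0.1, stats::rnorm(1, design$bw_mean, design$bw_sd)))
    } else design$bw_mean
    phys <- rat_physiology(bw)
    model <- pbpk_model(phys, .perturb_bundle(pa, cv), .perturb_bundle(napa, cv),
                        rtol = 1e-7, atol = 1e-9)
    reg <- regimen_loading_infusion(
      loading = loading_mg_kg * bw * 1000,
      rate = infusion_mg_kg_h * bw * 1000 / 60,
      duration = sample_time
    )
    kp_tbl <- steady_state_kpss(model, reg, sample_time, drug = "pa")
    sim <- simulate_pbpk(model, reg, sort(unique(c(0, plasma_times))))
    for (drug in c("pa", "napa")) {
      prof <- sim_profile(sim, drug)
      prof <- prof[prof$time %in% plasma_times, ]
      conc <- if (noise) .add_noise(prof$conc, design$vm) else prof$conc
      plasma[[length(plasma) + 1L]] <- tibble::tibble(
        animal = i, drug = drug, time = prof$time, conc = conc
      )
    }
    kp_pa <- kp_tbl[kp_tbl$tissue %in% tissues, ]
    mult <- if (noise) .lognormal_fold(nrow(kp_pa), tissue_cv) else 1
    tiss[[length(tiss) + 1L]] <- tibble::tibble(
      animal = i, drug = "pa", tissue = kp_pa$tissue,
      conc = kp_pa$kp_ss * kp_pa$c_plasma * mult,
      c_plasma = kp_pa$c_plasma,
      kp_ss = kp_pa$kp_ss * mult
    )
  }
  list(plasma = dplyr::bind_rows(plasma), tissues = dplyr::bind_rows(tiss))
}
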