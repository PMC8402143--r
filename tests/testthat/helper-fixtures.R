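# Shared fixtures for the test suite. Everything is generated in code.

# the standard plasma sampling grid (min), without the t = 0 blank
sampling_grid <- c(1, 5, 15, 30, 60, 120, 180, 240, 360, 480)

mono_exp_profile <- function(c0 = 10, k = 0.01, times = sampling_grid) {
  data.frame(time = times, conc = c0 * exp(-k * times))
}

# treatment-arm overrides: hepatic block and observed tissue Kp values
trt_overrides <- function() {
  list(
    pa = list(
      hepatic = list(clu_int = 25, f_napa = 0.845, extraction_ratio = 0.529),
      kp = c(liver = 0.649, brain = 0.2861, heart = 1.658,
             lung = 0.9282, spleen = 1.507)
    ),
    napa = list(
      kp = c(liver = 7.25, brain = 0.2458, heart = 2.29,
             lung = 4.191, spleen = 5.186)
    )
  )
}

treated_bundles <- function(r_act = 0.675) {
  sc <- treatment_scalars()
  sc$r_act <- r_act
  ov <- trt_overrides()
  list(pa = apply_treatment(pa_params("control"), sc, ov$pa),
       napa = apply_treatment(napa_params("control"), sc, ov$napa))
}

# flatten a generated bolus study into the observation table fit_ract() takes,
# averaging across animals (naive pooled fitting of mean data)
study_to_observations <- function(study) {
  plasma <- study$profiles |>
    dplyr::group_by(drug, time) |>
    dplyr::summarise(value = mean(conc), .groups = "drop") |>
    dplyr::mutate(kind = "plasma")
  urine <- study$urine |>
    dplyr::group_by(animal, drug) |>
    dplyr::arrange(end, .by_group = TRUE) |>
    dplyr::mutate(cum = cumsum(amount)) |>
    dplyr::group_by(drug, end) |>
    dplyr::summarise(value = mean(cum), .groups = "drop") |>
    dplyr::mutate(kind = "urine_cumulative", time = end * 60) |>
    dplyr::select(-end)
  dplyr::bind_rows(plasma, urine)
}

# model with all elimination pathways switched off (distribution only)
no_elimination_model <- function(body_weight = 0.25, kp_one = FALSE) {
  strip <- function(b) {
    b$hepatic$clu_int <- 0
    b$hepatic$f_napa <- 0
    b$kidney$clu_int_r <- 0
    b$kidney$cl_rabs <- 0
    if (kp_one) {
      b$kp[] <- 1
      # symmetric kidney transport so the cell also equilibrates at unity
      b$kidney$ps_in <- b$kidney$ps_pas
      b$properties$fu_kidney <- b$properties$fup
    }
    b
  }
  ref <- utils::modifyList(rat_physiology_defaults(), list(gfr_per_kg = 1e-9))
  phys <- rat_physiology(body_weight, ref)
  pbpk_model(phys, strip(pa_params()), strip(napa_params()), washout = 0)
}
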