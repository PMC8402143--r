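ctrl <- list(pa = pa_params("control"), napa = napa_params("control"))

test_that("the same seed reproduces a study bit-for-bit", {
  des <- study_design(n_animals = 3, seed = 17)
  s1 <- generate_bolus_study(des, ctrl$pa, ctrl$napa)
  s2 <- generate_bolus_study(des, ctrl$pa, ctrl$napa)
  expect_identical(s1$profiles, s2$profiles)
  expect_identical(s1$urine, s2$urine)
  s3 <- generate_bolus_study(study_design(n_animals = 3, seed = 18),
                             ctrl$pa, ctrl$napa)
  expect_false(identical(s1$profiles$conc, s3$profiles$conc))
})

test_that("with noise off every animal equals the deterministic simulation", {
  des <- study_design(n_animals = 3, seed = 1)
  s <- generate_bolus_study(des, ctrl$pa, ctrl$napa, noise = FALSE)
  by_animal <- split(s$profiles$conc, s$profiles$animal)
  expect_equal(by_animal[[1]], by_animal[[2]])
  expect_equal(by_animal[[1]], by_animal[[3]])
  expect_true(all(s$profiles$body_weight == des$bw_mean))
  # deterministic reference: direct simulation at the design conditions
  phys <- rat_physiology(des$bw_mean)
  m <- pbpk_model(phys, ctrl$pa, ctrl$napa, rtol = 1e-7, atol = 1e-9)
  dose <- des$dose_mg_kg * des$bw_mean * 1000
  sim <- simulate_pbpk(m, regimen_iv_bolus(dose),
                       sort(unique(c(0, des$sampling_times))))
  prof <- sim_profile(sim, "pa")
  expect_equal(by_animal[[1]][s$profiles$drug[s$profiles$animal == 1] == "pa"],
               prof$conc[prof$time > 0], tolerance = 1e-6)
})

test_that("urinary calibration factors act multiplicatively on the observation scale", {
  des <- study_design(n_animals = 1, seed = 2)
  s1 <- generate_bolus_study(des, ctrl$pa, ctrl$napa, noise = FALSE,
                             calibration = c(pa = 1, napa = 1))
  s2 <- generate_bolus_study(des, ctrl$pa, ctrl$napa, noise = FALSE,
                             calibration = c(pa = 1.29, napa = 0.836))
  expect_equal(s2$urine$amount[s2$urine$drug == "pa"],
               1.29 * s1$urine$amount[s1$urine$drug == "pa"])
  expect_equal(s2$urine$amount[s2$urine$drug == "napa"],
               0.836 * s1$urine$amount[s1$urine$drug == "napa"])
})

test_that("NCA of a low-noise control arm recovers the deterministic clearance within 5%", {
  des <- study_design(n_animals = 9, bw_sd = 0.005,
                      vm = variance_model(0.005, 0.02),
                      vm_urine = variance_model(0.5, 0.02),
                      bsv_cv = 0.05, seed = 101)
  s <- generate_bolus_study(des, ctrl$pa, ctrl$napa)
  pa_prof <- s$profiles[s$profiles$drug == "pa", ]
  res <- nca_by_animal(pa_prof)
  # deterministic reference: NCA of the noise-free design
  det <- generate_bolus_study(study_design(n_animals = 1, seed = 1),
                              ctrl$pa, ctrl$napa, noise = FALSE)
  det_prof <- det$profiles[det$profiles$drug == "pa", ]
  cl_det <- run_nca(det_prof[, c("time", "conc")], det_prof$dose[1],
                    det_prof$body_weight[1])$cl
  expect_equal(mean(res$cl), cl_det, tolerance = 0.05)
})

test_that("the infusion study reproduces the model Kp,ss map at zero noise", {
  des <- study_design(n_animals = 2, seed = 9)
  s <- suppressWarnings(
    generate_infusion_study(des, ctrl$pa, ctrl$napa, noise = FALSE)
  )
  phys <- rat_physiology(des$bw_mean)
  m <- pbpk_model(phys, ctrl$pa, ctrl$napa, rtol = 1e-7, atol = 1e-9)
  reg <- regimen_loading_infusion(1.4 * des$bw_mean * 1000,
                                  2.5 * des$bw_mean * 1000 / 60, 60)
  kp_map <- suppressWarnings(steady_state_kpss(m, reg, 60))
  for (t in unique(s$tissues$tissue)) {
    expect_equal(s$tissues$kp_ss[s$tissues$animal == 1 & s$tissues$tissue == t],
                 kp_map$kp_ss[kp_map$tissue == t], tolerance = 1e-8)
  }
  # approach to plateau: late plasma samples lie close together
  pl <- s$plasma[s$plasma$drug == "pa" & s$plasma$time >= 30, ]
  late <- pl$conc[pl$animal == 1]
  expect_lt(max(late) / min(late) - 1, 0.15)
})

test_that("the full loop recovers the generating Ract from noisy virtual rats", {
  # one replicate of the closure property (the replicated study is exercised
  # at acceptance): generate treated-arm data, fit, recover within 15%
  des <- study_design(n_animals = 9, bw_mean = 0.2823, bw_sd = 0.016, seed = 7)
  b <- treated_bundles(0.675)
  study <- generate_bolus_study(des, b$pa, b$napa)
  obs <- study_to_observations(study)
  fit <- fit_ract(obs, rat_physiology(0.2823),
                  regimen_iv_bolus(10 * 0.2823 * 1000),
                  overrides = trt_overrides())
  expect_equal(fit$ract, 0.675, tolerance = 0.15)
})
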