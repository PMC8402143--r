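phys <- rat_physiology(0.2976)
dose <- 10 * 0.2976 * 1000

test_that("mass balance holds to 1e-6 for bolus and infusion regimens", {
  m <- pbpk_model(phys, pa_params(), napa_params())
  for (reg in list(regimen_iv_bolus(dose),
                   regimen_loading_infusion(417, 12.4, 60))) {
    sim <- simulate_pbpk(m, reg, seq(0, 480, by = 5))
    mb <- mass_balance(sim)
    mb <- mb[mb$time > 0, ]
    expect_lt(max(mb$rel_error), 1e-6)
  }
})

test_that("zero dose gives identically zero trajectories", {
  m <- pbpk_model(phys, pa_params(), napa_params())
  sim <- simulate_pbpk(m, regimen_iv_bolus(0), seq(0, 100, 10))
  expect_equal(max(abs(sim$amounts)), 0)
})

test_that("all amounts stay non-negative and cumulative outputs are monotone", {
  m <- pbpk_model(phys, pa_params(), napa_params())
  sim <- simulate_pbpk(m, regimen_iv_bolus(dose), seq(0, 1440, by = 2))
  expect_gt(min(sim$amounts), -1e-8)
  for (col in c("pa_urine", "napa_urine", "pa_hep_elim", "napa_formed")) {
    expect_true(all(diff(sim$amounts[, col]) > -1e-9))
  }
  # urinary recovery bounded by the dose
  expect_lt(max(sim$amounts[, "pa_urine"]) / dose, 1)
})

test_that("with elimination on, tissues empty and eliminated mass approaches the dose", {
  m <- pbpk_model(phys, pa_params(), napa_params())
  sim <- simulate_pbpk(m, regimen_iv_bolus(dose), c(0, 5000))
  last <- nrow(sim$amounts)
  expect_lt(sim$amounts[last, "pa_plasma"], 1e-6 * dose)
  eliminated <- sim$amounts[last, "pa_urine"] + sim$amounts[last, "pa_hep_elim"]
  expect_equal(unname(eliminated), dose, tolerance = 1e-4)
})

test_that("with kidney zeroed, simulated clearance matches the well-stirred closed form", {
  pa0 <- pa_params(); napa0 <- napa_params()
  for (b in c("pa0", "napa0")) {
    x <- get(b)
    x$kidney$clu_int_r <- 0; x$kidney$cl_rabs <- 0
    assign(b, x)
  }
  pa0$hepatic$f_napa <- 0
  ref <- utils::modifyList(rat_physiology_defaults(), list(gfr_per_kg = 1e-9))
  ph <- rat_physiology(0.2976, ref)
  m <- pbpk_model(ph, pa0, napa0, washout = 0)
  # sample the early distribution phase so the AUC sees the mixing spike
  times <- sort(unique(c(seq(0, 5, 0.02), seq(5, 480, 0.5), seq(480, 12000, 10))))
  sim <- simulate_pbpk(m, regimen_iv_bolus(dose), times)
  prof <- sim_profile(sim, "pa")
  prof <- prof[prof$time > 0 & prof$conc > 0, ]
  ts <- terminal_slope(prof, n_terminal = 4)
  mo <- auc_moments(prof, ts$lambda_z, dose, 0.2976)
  cl_expected <- well_stirred_clearance(ph$flows[["liver"]],
                                        pa0$properties$fup,
                                        pa0$hepatic$clu_int) / 0.2976
  expect_equal(mo$cl, cl_expected, tolerance = 0.01)
})

test_that("kidney cell-to-plasma ratio at steady state equals the partition relation", {
  # secretion, reabsorption and filtration off: uptake/efflux balance only
  pa0 <- pa_params(); napa0 <- napa_params()
  for (b in c("pa0", "napa0")) {
    x <- get(b); x$kidney$clu_int_r <- 0; x$kidney$cl_rabs <- 0; assign(b, x)
  }
  ref <- utils::modifyList(rat_physiology_defaults(), list(gfr_per_kg = 1e-9))
  ph <- rat_physiology(0.25, ref)
  m <- pbpk_model(ph, pa0, napa0, washout = 0)
  sim <- simulate_pbpk(m, regimen_loading_infusion(400, 10, 3000),
                       seq(0, 3000, 25))
  i <- nrow(sim$amounts)
  for (drug in c("pa", "napa")) {
    b <- if (drug == "pa") pa0 else napa0
    ratio <- (sim$amounts[i, paste0(drug, "_kid_cell")] /
                ph$kidney_subvolumes[["cell"]]) /
      (sim$amounts[i, paste0(drug, "_plasma")] / ph$volumes[["blood"]])
    expect_equal(
      unname(ratio),
      kidney_kp_model(b$properties$fup, b$kidney$ps_in,
                      b$properties$fu_kidney, b$kidney$ps_pas),
      tolerance = 1e-3
    )
  }
})

test_that("doubling PSin and PSout jointly leaves the cell ratio unchanged", {
  make_ratio <- function(fold) {
    pa0 <- pa_params()
    pa0$kidney$ps_in <- pa0$kidney$ps_in * fold
    pa0$kidney$ps_pas <- pa0$kidney$ps_pas * fold
    pa0$kidney$clu_int_r <- 0; pa0$kidney$cl_rabs <- 0
    ref <- utils::modifyList(rat_physiology_defaults(), list(gfr_per_kg = 1e-9))
    ph <- rat_physiology(0.25, ref)
    m <- pbpk_model(ph, pa0, napa_params(), washout = 0)
    sim <- simulate_pbpk(m, regimen_loading_infusion(400, 10, 3000),
                         seq(0, 3000, 50))
    i <- nrow(sim$amounts)
    (sim$amounts[i, "pa_kid_cell"] / ph$kidney_subvolumes[["cell"]]) /
      (sim$amounts[i, "pa_plasma"] / ph$volumes[["blood"]])
  }
  expect_equal(make_ratio(1), make_ratio(2), tolerance = 1e-3)
})

test_that("with unit Kp and no elimination, plasma approaches dose over total volume", {
  m <- no_elimination_model(0.25, kp_one = TRUE)
  ph <- m$physiology
  sim <- simulate_pbpk(m, regimen_iv_bolus(1000), c(0, 10000))
  # the tubular lumen receives nothing when filtration, secretion and washout
  # are all off, so it is excluded from the equilibration volume
  v_total <- sum(ph$volumes) - ph$kidney_subvolumes[["lumen"]]
  expect_equal(unname(sim$amounts[2, "pa_plasma"] / ph$volumes[["blood"]]),
               1000 / v_total, tolerance = 1e-4)
  # mass is conserved exactly when nothing is eliminated
  mb <- mass_balance(sim)
  expect_lt(max(mb$rel_error[mb$time > 0 & mb$drug == "pa"]), 1e-8)
})

test_that("halving solver tolerances changes the plasma AUC by less than 0.01%", {
  auc_of <- function(rtol, atol) {
    m <- pbpk_model(phys, pa_params(), napa_params(), rtol = rtol, atol = atol)
    sim <- simulate_pbpk(m, regimen_iv_bolus(dose), seq(0, 480, 1))
    prof <- sim_profile(sim, "pa")
    sum(diff(prof$time) * (head(prof$conc, -1) + tail(prof$conc, -1)) / 2)
  }
  expect_equal(auc_of(1e-8, 1e-10), auc_of(5e-9, 5e-11), tolerance = 1e-4)
})

test_that("steady-state Kp extraction returns input Kp for non-eliminating tissues", {
  m <- pbpk_model(phys, pa_params(), napa_params())
  reg <- regimen_loading_infusion(620, 12.4, 12000)
  kp <- suppressWarnings(steady_state_kpss(m, reg, 2000))
  pa <- pa_params()
  for (t in c("brain", "heart", "lung", "adipose", "muscle")) {
    expect_equal(kp$kp_ss[kp$tissue == t], unname(pa$kp[[t]]), tolerance = 0.01)
  }
  expect_error(steady_state_kpss(m, reg, 0), "positive")
  expect_warning(steady_state_kpss(m, reg, 5), "steady state")
})
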