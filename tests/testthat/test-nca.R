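test_that("terminal slope recovers a mono-exponential decay on the study grid", {
  prof <- mono_exp_profile(10, 0.01)
  ts <- terminal_slope(prof)
  expect_equal(ts$lambda_z, 0.01, tolerance = 1e-8)
  expect_equal(ts$t_half, log(2) / 0.01, tolerance = 1e-8)
  # scale invariance
  prof2 <- prof; prof2$conc <- prof2$conc * 37
  expect_equal(terminal_slope(prof2)$lambda_z, ts$lambda_z)
  expect_error(terminal_slope(data.frame(time = 1:2, conc = c(2, 1))), "3 positive")
})

test_that("terminal slope isolates the dominant phase of a biexponential", {
  t <- sampling_grid
  prof <- data.frame(time = t, conc = 5 * exp(-0.1 * t) + 1 * exp(-0.01 * t))
  ts <- terminal_slope(prof, n_terminal = 4)
  expect_equal(ts$lambda_z, 0.01, tolerance = 0.02)
})

test_that("AUC and moments match one-compartment closed forms within 1%", {
  k <- 0.01; v <- 2000; dose <- 3000; bw <- 0.3
  c0 <- dose / v
  prof <- mono_exp_profile(c0, k)
  ts <- terminal_slope(prof)
  mo <- auc_moments(prof, ts$lambda_z, dose, bw)
  expect_equal(mo$auc_inf, c0 / k, tolerance = 0.01)
  expect_equal(mo$mrt, 1 / k, tolerance = 0.01)
  expect_equal(mo$cl, k * v / bw, tolerance = 0.01)
  expect_equal(mo$vss, v / bw, tolerance = 0.02)
  expect_error(auc_moments(data.frame(time = 1:3, conc = c(0, 0, 0)),
                           lambda_z = 0.01, dose = 0, body_weight = 0.3))
})

test_that("trapezoidal AUC agrees with adaptive quadrature on smooth profiles", {
  set.seed(21)
  for (i in 1:10) {
    k1 <- runif(1, 0.02, 0.2); k2 <- runif(1, 0.002, 0.01)
    a <- runif(1, 1, 10); b <- runif(1, 0.1, 1)
    f <- function(t) a * exp(-k1 * t) + b * exp(-k2 * t)
    t <- seq(1, 480, length.out = 150)
    prof <- data.frame(time = t, conc = f(t))
    ts <- terminal_slope(prof, n_terminal = 5)
    mo <- auc_moments(prof, ts$lambda_z, dose = 1, body_weight = 1,
                      extrapolate_c0 = FALSE)
    oracle <- stats::integrate(f, 1, Inf, rel.tol = 1e-10)$value
    expect_equal(mo$auc_last + prof$conc[150] / ts$lambda_z, oracle,
                 tolerance = 0.01)
  }
})

test_that("clearance partition is additive and bounded by the dose", {
  part <- clearance_partition(1000, 100, 0, 0.25)
  expect_equal(part$cl_r, 0)
  expect_equal(part$cl_nr, part$cl)
  part2 <- clearance_partition(1000, 100, 1000, 0.25)
  expect_equal(part2$cl_nr, 0, tolerance = 1e-12)
  expect_error(clearance_partition(1000, 100, 1100, 0.25), "exceed")
  # mono-exponential with known renal fraction: percent in urine = CLR/CL
  k <- 0.01; v <- 2000; dose <- 5000; fr <- 0.3
  prof <- mono_exp_profile(dose / v, k, times = seq(1, 900, 4))
  ts <- terminal_slope(prof)
  mo <- auc_moments(prof, ts$lambda_z, dose, 1)
  part3 <- clearance_partition(dose, mo$auc_inf, fr * dose, 1)
  expect_equal(part3$cl_r / part3$cl, fr, tolerance = 0.01)
})

test_that("cumulative recovery is monotone, bounded, and matches the simulated renal fraction", {
  urine <- data.frame(start = c(0, 2, 4, 6, 8), end = c(2, 4, 6, 8, 24),
                      amount = c(0, 0, 0, 0, 0))
  expect_equal(cumulative_recovery(urine, 100)$cum_percent, rep(0, 5))
  one <- data.frame(start = 0, end = 24, amount = 500)
  expect_equal(cumulative_recovery(one, 500)$cum_percent, 100)
  expect_error(cumulative_recovery(
    data.frame(start = c(0, 3), end = c(2, 5), amount = c(1, 1)), 10),
    "contiguous")
  # control-arm simulation: terminal urinary recovery equals CLR/CL
  phys <- rat_physiology(0.2976)
  m <- pbpk_model(phys, pa_params(), napa_params())
  dose <- 2976
  sim <- simulate_pbpk(m, regimen_iv_bolus(dose),
                       sort(unique(c(seq(0, 480, 2), seq(480, 7000, 20)))))
  prof <- sim_profile(sim, "pa"); prof <- prof[prof$time > 0, ]
  u <- sim_urine(sim, "pa")
  ae_inf <- u$amount[nrow(u)]
  ts <- terminal_slope(prof[prof$conc > 0, ], 4)
  mo <- auc_moments(prof[prof$conc > 0, ], ts$lambda_z, dose, 0.2976)
  part <- clearance_partition(dose, mo$auc_inf, ae_inf, 0.2976)
  expect_equal(ae_inf / dose, part$cl_r / part$cl, tolerance = 0.02)
})

test_that("observed Kp corrects homogenate dilution", {
  expect_equal(kp_ss_observed(3, 3), 1)
  expect_equal(kp_ss_observed(8.484 * 2, 2), 8.484)
  # a 1:2 tissue:buffer homogenate (3x dilution) reproduces the undiluted ratio
  c_t <- 6.2; c_p <- 0.9
  expect_equal(kp_ss_observed(c_t / 3, c_p, dilution_factor = 3),
               kp_ss_observed(c_t, c_p))
  expect_error(kp_ss_observed(1, 0), "positive")
})

test_that("full NCA on a richly sampled simulated bolus recovers the model clearance within 2%", {
  phys <- rat_physiology(0.2976)
  m <- pbpk_model(phys, pa_params(), napa_params())
  dose <- 2976
  # the whole-body model has a small central pool, so the first minutes carry
  # a distribution spike that the sampling must capture
  sim <- simulate_pbpk(m, regimen_iv_bolus(dose),
                       sort(unique(c(seq(0, 5, 0.02), seq(5, 480, 0.5),
                                     seq(480, 9000, 10)))))
  prof <- sim_profile(sim, "pa")
  prof <- prof[prof$time > 0 & prof$conc > 0, ]
  res <- run_nca(prof, dose, 0.2976)
  # reference: dose over a dense trapezoidal AUC of the full decay, plus the
  # short pre-first-sample rectangle
  auc_dense <- sum(diff(prof$time) * (head(prof$conc, -1) + tail(prof$conc, -1)) / 2) +
    prof$conc[1] * prof$time[1] + tail(prof$conc, 1) / res$lambda_z
  expect_equal(res$cl, dose / auc_dense / 0.2976, tolerance = 0.02)
})

test_that("per-animal NCA returns one row per animal plus summary rows", {
  set.seed(5)
  profs <- purrr::map_dfr(1:3, function(i) {
    k <- 0.01 * exp(rnorm(1, 0, 0.1))
    tibble::tibble(animal = i, time = sampling_grid,
                   conc = 10 * exp(-k * sampling_grid),
                   dose = 3000, body_weight = 0.3)
  })
  res <- nca_by_animal(profs, summarise = TRUE)
  expect_equal(nrow(res), 5)
  expect_true(all(c("mean", "sd") %in% res$animal))
  # mean of individual clearances differs from clearance of the mean profile
  mean_prof <- profs |>
    dplyr::group_by(time) |>
    dplyr::summarise(conc = mean(conc))
  cl_pooled <- run_nca(mean_prof, 3000, 0.3)$cl
  cl_mean <- res$cl[res$animal == "mean"]
  expect_false(isTRUE(all.equal(cl_pooled, cl_mean, tolerance = 1e-6)))
})
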