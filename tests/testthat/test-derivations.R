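test_that("retrograde Kp reproduces the reference eliminating-tissue values", {
  expect_equal(signif(retrograde_kp(8.484, 0.253), 3), 11.4)
  expect_equal(signif(retrograde_kp(11.86, 0.195), 3), 14.7)
  expect_equal(signif(retrograde_kp(0.3059, 0.529), 3), 0.649)
  expect_equal(retrograde_kp(3.7, 0), 3.7) # non-eliminating tissue
  expect_error(retrograde_kp(1, 1), "cannot extract")
  expect_error(retrograde_kp(0, 0.5))
})

test_that("retrograde Kp round-trips through forward attenuation", {
  set.seed(11)
  kp <- runif(50, 0.05, 20)
  er <- runif(50, 0, 0.95)
  expect_equal(retrograde_kp(kp, er) * (1 - er), kp, tolerance = 1e-14)
})

test_that("kidney partition model matches the reference transport clearances", {
  # control values agree with the printed retrograde coefficients to ~1%
  expect_equal(kidney_kp_model(0.87, 22.1, 0.223, 7.61), 11.4, tolerance = 0.01)
  expect_equal(signif(kidney_kp_model(0.688, 9.59, 0.0588, 7.61), 3), 14.7)
  # symmetric transport gives unity
  expect_equal(kidney_kp_model(0.5, 3, 0.5, 3), 1)
  expect_error(kidney_kp_model(0.87, -1, 0.223, 7.61), "positive")
  # inversion recovers the uptake clearance
  expect_equal(ps_in_from_kidney_kp(kidney_kp_model(0.87, 22.1, 0.223, 7.61),
                                    0.87, 0.223, 7.61), 22.1)
})

test_that("well-stirred forward and retrograde forms are exact inverses", {
  expect_equal(well_stirred_retrograde(20, 10, 1.0), 20)
  expect_equal(well_stirred_clearance(20, 1.0, 20), 10)
  expect_equal(well_stirred_retrograde(20, 1e-9, 1.0), 0, tolerance = 1e-7)
  set.seed(12)
  for (i in 1:25) {
    q <- runif(1, 5, 50); fu <- runif(1, 0.05, 1); cl <- runif(1, 0.01, 0.95) * q
    expect_equal(well_stirred_clearance(q, fu, well_stirred_retrograde(q, cl, fu)),
                 cl, tolerance = 1e-12)
  }
  # the back-calculated hepatic intrinsic clearance given flow from ER
  expect_equal(signif(well_stirred_retrograde(23.1, 15.76, 0.87), 3), 57.0)
  expect_error(well_stirred_retrograde(10, 12, 0.9), "exceed")
})

test_that("extraction ratio is clearance referenced to flow", {
  expect_equal(extraction_ratio(0, 10), 0)
  expect_equal(extraction_ratio(5, 10), 0.5)
  expect_equal(signif(extraction_ratio(15.76, 23.1), 3), 0.682)
  expect_error(extraction_ratio(10, 10), "exceeds")
})

test_that("active-uptake and MATE-fold scaling reproduce the treated clearances", {
  expect_equal(signif(apply_ract(22.1, 7.61, 0.675), 3), 17.4)
  expect_equal(signif(apply_ract(9.59, 7.61, 0.675), 3), 8.95)
  expect_equal(apply_ract(22.1, 7.61, 1), 22.1) # identity at unit fold
  expect_error(apply_ract(5, 7.61, 0.675), "active component")
  expect_equal(signif(apply_rmate(4.67, 0.312), 3), 1.46)
  expect_equal(signif(apply_rmate(9.16, 0.312), 3), 2.86)
  expect_equal(apply_rmate(4.67, 1), 4.67)
  # linearity in the fold
  r <- seq(0.2, 2, by = 0.2)
  expect_equal(apply_ract(22.1, 7.61, r), (22.1 - 7.61) * r + 7.61)
})

test_that("hepatic uptake scaling by a protein fold gives the expected decrease", {
  expect_equal(signif(scale_hepatic_uptake(0.557, 0.309), 3), 38.5)
  expect_equal(scale_hepatic_uptake(0.3, 1), 0)
  expect_equal(scale_hepatic_uptake(1, 0.5), 50)
})

test_that("expression fold follows comparative-Ct quantification", {
  expect_equal(expression_fold(0), 1)
  expect_equal(expression_fold(-1), 2)
  expect_equal(expression_fold(1.44), 2^(-1.44))
  expect_error(expression_fold(NA_real_))
})

test_that("percent change matches the reported clearance reductions", {
  expect_equal(signif(percent_change(52.95, 41.02), 3), 22.5)
  expect_equal(signif(percent_change(12.67, 8.971), 3), 29.2)
  expect_equal(percent_change(5, 5), 0)
  expect_error(percent_change(0, 1), "non-zero")
})
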