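test_that("transfer functions reproduce their reference evaluations", {
  # maximum potential modern flux
  expect_equal(jdfe_modern(1e9, 1, 1110), 0.153 * 1110, tolerance = 1e-9)
  expect_equal(jdfe_modern(0, 100), 0)
  expect_equal(jdfe_modern(3.31, 100, 1110), 5.62, tolerance = 1e-2)
  expect_error(jdfe_modern(1, 0), "O2")

  expect_equal(delta_modern(0, 100), -1.67)
  expect_equal(delta_modern(1e9, 1), 1.65 - 1.67, tolerance = 1e-6)
  expect_equal(delta_modern(3.31, 100), -1.59, tolerance = 5e-3)

  expect_equal(jdfe_unbioturbated(0, 100), 0)
  expect_equal(jdfe_unbioturbated(1e9, 1, 1110), 0.161 * 1110,
               tolerance = 1e-6)
  expect_equal(jdfe_unbioturbated(3.31, 2, 1110), 178.3, tolerance = 0.1)

  expect_equal(delta_unbioturbated(0, 100), 1.60 - 1.34 - 1.67)
  expect_equal(delta_unbioturbated(1e9, 1), 1.60 - 1.67, tolerance = 1e-6)
  expect_equal(delta_unbioturbated(3.31, 2), -0.07, tolerance = 5e-3)
})

test_that("transfer functions respect their bounds and monotonicity", {
  set.seed(99)
  n <- 1e6
  cox <- 10^runif(n, -2, 1.3)
  o2 <- 10^runif(n, 0, 2.5)
  jm <- jdfe_modern(cox, o2, 1110)
  expect_true(all(jm >= 0 & jm <= 0.153 * 1110))
  ju <- jdfe_unbioturbated(cox, o2, 1110)
  expect_true(all(ju >= 0 & ju <= 0.161 * 1110))
  dm <- delta_modern(cox, o2)
  expect_true(all(dm >= -1.67 & dm <= -0.02 + 1e-12))
  du <- delta_unbioturbated(cox, o2)
  expect_true(all(du >= -1.41 & du <= -0.07 + 1e-12))
  # monotone in the driving ratio
  cox_up <- seq(0.1, 13, length.out = 100)
  expect_true(all(diff(jdfe_modern(cox_up, 50)) > 0))
  expect_true(all(diff(delta_modern(cox_up, 50)) > 0))
  o2_up <- seq(1, 200, length.out = 100)
  expect_true(all(diff(jdfe_modern(5, o2_up)) < 0))
})

test_that("the Rayleigh curve is continuous, monotone and has the right limits", {
  expect_equal(rayleigh_delta(50, d0 = 0.7, alpha_reac = 1), 0.7)
  expect_equal(rayleigh_delta(0), -1.3, tolerance = 1e-6)
  expect_equal(rayleigh_delta(85), -0.90, tolerance = 5e-3)
  j <- seq(0, 169.9, length.out = 400)
  d <- rayleigh_delta(j)
  expect_true(all(diff(d) > 0))
  # continuity through the fr -> 1 series switch
  expect_lt(abs(rayleigh_delta(1e-9) - rayleigh_delta(1e-3)), 1e-4)
  expect_error(rayleigh_delta(170), "j_max")
  expect_error(rayleigh_delta(-1), "j_max")
})

test_that("surface fitting recovers exact coefficients from noiseless data", {
  d <- expand.grid(cox = c(0.4, 1.6, 4.9, 8.3, 13.2),
                   o2 = c(1, 5, 25, 100, 200))
  d$j_feooh <- 1110
  d$response <- jdfe_modern(d$cox, d$o2, d$j_feooh)
  f1 <- fit_surface(d, "flux_modern")
  expect_equal(unname(coef(f1)), 0.153, tolerance = 1e-8)
  expect_equal(f1$r_squared, 1, tolerance = 1e-12)

  d$response <- delta_modern(d$cox, d$o2)
  f2 <- fit_surface(d, "delta_modern")
  expect_equal(unname(coef(f2)), c(1.65, 2.09, -1.67), tolerance = 1e-6)
  expect_equal(f2$r_squared, 1, tolerance = 1e-12)

  d$response <- jdfe_unbioturbated(d$cox, d$o2, d$j_feooh)
  f3 <- fit_surface(d, "flux_unbioturbated")
  expect_equal(unname(coef(f3)), c(0.161, 3.67), tolerance = 1e-6)

  d$response <- delta_unbioturbated(d$cox, d$o2)
  f4 <- fit_surface(d, "delta_unbioturbated")
  expect_equal(unname(coef(f4)), c(1.60, 1.34, 3.67, -1.67),
               tolerance = 1e-6)
  # predict() reproduces the fitted surface
  expect_equal(predict(f4, d), d$response, tolerance = 1e-8)

  d$response <- rep(1, nrow(d))
  expect_error(fit_surface(d, "delta_modern"), "degenerate")
})

test_that("global upscaling aggregates cells exactly and scales with the iron rain", {
  iv <- global_intervals()
  expect_equal(iv$area_1e12_m2, c(27.12, 16.01, 15.84, 302.5))
  expect_equal(iv$cox_mmol_m2_d, c(9.4, 3.0, 1.5, 0.45))

  # single cell: total equals the closed-form product
  one <- data.frame(o2_uM = 120, depth_m = 100, area_m2 = 27.12e12)
  up <- global_upscale(one, "modern")
  expect_equal(up$global$total_Gmol_yr,
               jdfe_modern(9.4, 120) * 27.12e12 * 365.25 / 1e15,
               tolerance = 1e-12)
  # linear in the iron oxide rain; delta unchanged
  up2 <- global_upscale(one, "modern", j_feooh = 2220)
  expect_equal(up2$global$total_Gmol_yr, 2 * up$global$total_Gmol_yr)
  expect_equal(up2$global$mean_delta, up$global$mean_delta)

  # The published functional forms order the two seafloors pointwise:
  # 1 - exp(-3.67 u) >= tanh(u) for all u >= 0, so the unbioturbated
  # form never falls below the modern one at equal forcing (a property
  # of the fitted forms, not of the underlying simulations, whose
  # high-oxygen fluxes order the other way).
  set.seed(2)
  cells <- data.frame(o2_uM = runif(200, 60, 300),
                      depth_m = runif(200, 10, 4000),
                      area_m2 = runif(200, 1e11, 1e12))
  um <- global_upscale(cells, "modern")
  uu <- global_upscale(cells, "unbioturbated")
  expect_gte(uu$global$total_Gmol_yr, um$global$total_Gmol_yr)

  # cells without oxygen are skipped with a reported count
  cells$o2_uM[1:5] <- NA
  expect_message(global_upscale(cells, "modern"), "5 cells")
})
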