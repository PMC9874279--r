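# Steady-state solver, diagnostics and their conservation properties.

test_that("compiled and reference tendencies agree to rounding error", {
  for (v in c("idealized", "site")) {
    cfg <- if (v == "idealized") baseline_config()
           else load_config("monterey_canyon")
    m <- build_model(cfg)
    M <- benthicFe:::initial_state(m)
    set.seed(4)
    M <- M * matrix(runif(length(M), 0.5, 1.5), nrow = nrow(M))
    d_r <- benthicFe:::model_tendency_r(m, M)$dM
    d_c <- benthicFe:::model_tendency(m, M)$dM
    expect_lt(max(abs(d_r - d_c) / pmax(abs(d_r), 1e-10)), 1e-12)
  }
})

test_that("baseline steady state closes its iron and carbon budgets", {
  fit <- baseline_run()
  d <- fit$diagnostics
  expect_lt(fit$residual, 1e-6)
  # column balance of bulk Fe and 56Fe within 1%
  expect_lt(abs(d$fe_balance), 0.01)
  expect_lt(abs(d$fe56_balance), 0.01)
  # flux-burial partition sums to the inputs
  outs <- d$J_DFe + d$B_FeOOH_T + d$B_FeS + d$B_FeS2 + d$B_sorbed
  expect_equal(outs, d$fe_inputs, tolerance = 0.01)
  expect_true(d$pyrite_burial_fraction >= 0 && d$pyrite_burial_fraction <= 1)
  # production - consumption balances efflux plus net sorbed burial
  expect_equal(d$P_DFe - d$C_DFe, d$J_DFe + d$B_sorbed,
               tolerance = 0.01 * max(d$P_DFe, 1))
})

test_that("steady state is independent of the initial condition", {
  fit <- baseline_run()
  m <- fit$model
  M0 <- benthicFe:::initial_state(m)
  set.seed(10)
  M2 <- M0 * matrix(runif(length(M0), 0.6, 1.6), nrow = nrow(M0))
  fit2 <- suppressWarnings(run_steady(baseline_config(), init = M2))
  expect_equal(fit2$diagnostics$J_DFe, fit$diagnostics$J_DFe,
               tolerance = 1e-3)
  expect_equal(fit2$diagnostics$delta_JDFe, fit$diagnostics$delta_JDFe,
               tolerance = 1e-3)
})

test_that("doubling the grid resolution changes the benthic flux by < 2%", {
  fit <- baseline_run()
  fit2 <- cached_run("baseline120", function() baseline_config(n_cells = 120))
  expect_lt(abs(fit2$diagnostics$J_DFe - fit$diagnostics$J_DFe) /
              fit$diagnostics$J_DFe, 0.02)
})

test_that("benthic_flux matches an irrigation quadrature oracle", {
  fit <- baseline_run()
  bf <- benthic_flux(fit, "DFe")
  expect_equal(bf$flux, fit$diagnostics$J_DFe, tolerance = 1e-10)
  expect_error(benthic_flux(fit, "FeS2"), "solid")
  expect_error(benthic_flux(fit, "nonesuch"), "unknown")

  # irrigation part equals the alpha-weighted column integral
  m <- fit$model
  M <- fit$state
  j <- match("DFe", m$state_names)
  irr_oracle <- sum(irrigation_profile(m$transport, fit$grid$cell_centres,
                                       0.2) *
                    fit$grid$porosity_centres * M[, j] * fit$grid$dz)
  fl <- benthicFe:::state_fluxes(m, M)
  diff_top <- -fl$F[1, j]
  expect_equal(bf$flux, flux_yr_to_day(diff_top + irr_oracle),
               tolerance = 1e-6)
})

test_that("with reactions off, a conservative column stays uniform with zero flux", {
  cfg <- baseline_config(n_cells = 40)
  kz <- cfg$kinetics
  for (nm in c("k_nit", "k_mnox", "k_feox", "k_femnox", "k_sox", "k_ch4ox",
               "k_aom", "k_s0ox", "k_fes_pre", "k_fes_dis", "k_pyr_hs",
               "k_pyr_s0", "k_fes_ox", "k_pyr_ox", "k_age"))
    kz[[nm]] <- 0
  kz$poc_k <- c(0, 0, 0)
  cfg$kinetics <- kz
  fit <- suppressWarnings(run_steady(cfg))
  # solutes relax to their bottom-water value everywhere
  for (nm in c("O2", "SO4", "DFe"))
    expect_lt(max(abs(fit$state[, nm] - cfg$bottom_water[[nm]])),
              1e-6 * max(cfg$bottom_water[[nm]], 1e-3))
  expect_lt(abs(benthic_flux(fit, "DFe")$flux), 1e-6)
})

test_that("the HCl-extractable composite mixes its sub-pools exactly", {
  fit <- baseline_run()
  fc <- fehcl_composite(fit)
  expect_true(all(is.finite(fc$FeHCl)))
  # two equal pools at 0 and -1 permil mix to about -0.5
  b <- 1
  h0 <- delta_to_heavy(b, 0)
  h1 <- delta_to_heavy(b, -1)
  expect_equal(delta56(2 * b, h0 + h1), -0.5, tolerance = 1e-3)
  # reporting scale shifts by the igneous offset
  fc2 <- fehcl_composite(fit, scale = "igneous")
  expect_equal(fc2$delta56, fc$delta56 - 0.09, tolerance = 1e-12)
})

test_that("profile tables carry every species and its delta column", {
  fit <- baseline_run()
  pt <- profile_table(fit)
  tab <- fit$model$species
  expect_true(all(tab$name %in% names(pt)))
  expect_true(all(paste0("delta56_", tab$name[tab$iso]) %in% names(pt)))
  expect_equal(nrow(pt), fit$grid$n)
})
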