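# Unit and property tests of the kinetic reaction network, evaluated on
# synthetic states without running the transport solver.

synthetic_state <- function(cfg, n = 10, seed = 3, overrides = list()) {
  tab <- species_table(cfg$variant)
  snames <- c(tab$name, paste0(tab$name[tab$iso], ".56"))
  set.seed(seed)
  st <- lapply(snames, function(nm) runif(n, 0, 2))
  names(st) <- snames
  for (nm in tab$name[tab$iso])
    st[[paste0(nm, ".56")]] <- delta_to_heavy(st[[nm]], runif(n, -2, 2))
  for (nm in names(overrides)) st[[nm]] <- rep_len(overrides[[nm]], n)
  st
}

test_that("mineralization pathways partition total decay exactly", {
  cfg <- fe_config("idealized")
  st <- synthetic_state(cfg, n = 25)
  phi <- rep(0.85, 25)
  paths <- poc_mineralization(st, phi, cfg)
  total <- (1 - phi) * (cfg$kinetics$poc_k[1] * st$POC1 +
                        cfg$kinetics$poc_k[2] * st$POC2 +
                        cfg$kinetics$poc_k[3] * st$POC3)
  expect_equal(rowSums(paths), total, tolerance = 1e-12)
  expect_true(all(paths >= 0))

  # abundant oxygen: aerobic fraction > 0.99 of total decay
  st2 <- synthetic_state(cfg, overrides = list(O2 = 5))
  p2 <- poc_mineralization(st2, rep(0.85, 10), cfg)
  expect_true(all(p2[, "O2"] / rowSums(p2) > 0.99))

  # all external oxidants exhausted: methanogenesis carries everything
  st3 <- synthetic_state(cfg, overrides = list(
    O2 = 0, NO3 = 0, MnO2s = 0, FeHR = 0, FeMR = 0, SO4 = 0))
  p3 <- poc_mineralization(st3, rep(0.85, 10), cfg)
  expect_equal(p3[, "CH4"] / rowSums(p3), rep(1, 10), tolerance = 1e-12)
})

test_that("sulfide-mediated reduction recovers half-lives and class order", {
  k <- sulfide_rate_constants(c(1, 100, 1e5, Inf), hs_ref_mM = 1)
  expect_equal(k[1], log(2))
  expect_equal(k[1] / k[2], 100)
  expect_equal(k[[4]], 0)

  cfg <- fe_config("idealized")
  st <- synthetic_state(cfg, overrides = list(
    FeHR = 1, FeMR = 1, FePR = 1, FeU = 1, HS = 0.5))
  r <- iron_oxide_reduction(st, rep(0.85, 10), cfg)
  sm <- r$sulfide_mediated
  expect_true(all(sm[, "FeHR"] > sm[, "FeMR"]))
  expect_true(all(sm[, "FeMR"] > sm[, "FePR"]))
  # zero sulfide shuts the pathway for every class
  st0 <- synthetic_state(cfg, overrides = list(HS = 0))
  r0 <- iron_oxide_reduction(st0, rep(0.85, 10), cfg)
  expect_equal(max(abs(r0$sulfide_mediated)), 0)
})

test_that("iron-sulfide system respects saturation and the bimolecular law", {
  cfg <- fe_config("idealized")
  K <- cfg$kinetics$K_FeS
  at_sat <- synthetic_state(cfg, overrides = list(DFe = sqrt(K), HS = sqrt(K)))
  r <- sulfide_iron_mineral_rates(at_sat, rep(0.85, 10), cfg)
  # at saturation both half-reactions vanish up to the smoothing width
  expect_lt(max(abs(r$fes_precip)), 1e-2 * cfg$kinetics$k_fes_pre * K)
  # no FeS: no pyrite formation by either pathway
  nofes <- synthetic_state(cfg, overrides = list(FeS = 0))
  r2 <- sulfide_iron_mineral_rates(nofes, rep(0.85, 10), cfg)
  expect_equal(max(abs(r2$pyrite_hs)), 0)
  expect_equal(max(abs(r2$pyrite_s0)), 0)
  # far above saturation doubling the ferrous iron doubles precipitation
  hi <- synthetic_state(cfg, overrides = list(DFe = 0.5, HS = 1))
  hi2 <- synthetic_state(cfg, overrides = list(DFe = 1.0, HS = 1))
  r_hi <- sulfide_iron_mineral_rates(hi, rep(0.85, 10), cfg)
  r_hi2 <- sulfide_iron_mineral_rates(hi2, rep(0.85, 10), cfg)
  expect_equal(r_hi2$fes_precip / r_hi$fes_precip, rep(2, 10),
               tolerance = 2e-3)
  # all oxidative reactions stop without oxygen
  anox <- synthetic_state(cfg, overrides = list(O2 = 0))
  r3 <- sulfide_iron_mineral_rates(anox, rep(0.85, 10), cfg)
  expect_equal(max(abs(r3$fes_ox)), 0)
  expect_equal(max(abs(r3$pyr_ox)), 0)
})

test_that("aging conserves iron and has the analytic e-folding time", {
  cfg <- fe_config("idealized")
  st <- synthetic_state(cfg)
  phi <- rep(0.85, 10)
  expect_equal(aging(st, phi, cfg),
               cfg$kinetics$k_age * pmax(st$FeHR, 0) * (1 - phi))
  st0 <- synthetic_state(cfg, overrides = list(FeHR = 0))
  expect_equal(max(abs(aging(st0, phi, cfg))), 0)
  # closed FeHR pool decays with 1/k_age: integrate dC/dt = -k C
  k <- cfg$kinetics$k_age
  f <- function(t, y, p) list(-k * y)
  out <- deSolve::ode(y = 1, times = c(0, 1 / k), func = f, parms = NULL,
                      rtol = 1e-10, atol = 1e-12)
  expect_equal(unname(out[2, 2]), exp(-1), tolerance = 1e-8)
})

test_that("every reaction conserves iron and sulfur atoms", {
  for (variant in c("idealized", "site")) {
    cfg <- fe_config(variant)
    st <- synthetic_state(cfg, n = 30, seed = 11)
    phi <- runif(30, 0.7, 0.95)
    net <- network_rates(st, phi, cfg)
    td <- net$tend
    scale <- max(vapply(td, function(x) max(abs(x)), 1), 1)
    zero <- function(x) expect_lt(max(abs(x)) / scale, 1e-12)
    fe <- td$DFe + td$FeHR + td$FeMR + td$FeS + td$FeS2
    if (variant == "idealized") fe <- fe + td$FePR + td$FeU
    zero(fe)
    s <- td$SO4 + td$HS + td$S0 + td$FeS + 2 * td$FeS2
    zero(s)
    # paired 56Fe bookkeeping conserves 56Fe identically
    fe56 <- td$DFe.56 + td$FeHR.56 + td$FeMR.56 + td$FeS.56 + td$FeS2.56
    if (variant == "idealized") fe56 <- fe56 + td$FePR.56 + td$FeU.56
    zero(fe56)
  }
})

test_that("zero rate constants silence the network", {
  cfg <- fe_config("idealized")
  kz <- cfg$kinetics
  for (nm in c("k_nit", "k_mnox", "k_feox", "k_femnox", "k_sox", "k_ch4ox",
               "k_aom", "k_s0ox", "k_fes_pre", "k_fes_dis", "k_pyr_hs",
               "k_pyr_s0", "k_fes_ox", "k_pyr_ox", "k_age"))
    kz[[nm]] <- 0
  kz$poc_k <- c(0, 0, 0)
  cfg$kinetics <- kz
  cfg$fe_half_lives <- c(FeHR = Inf, FeMR = Inf, FePR = Inf, FeU = Inf)
  st <- synthetic_state(cfg, n = 15, seed = 5)
  net <- network_rates(st, rep(0.85, 15), cfg)
  expect_equal(max(abs(unlist(net$tend))), 0)
})

test_that("the site network is the idealized network with N and Mn disabled", {
  tab_i <- species_table("idealized")
  tab_s <- species_table("site")
  expect_true(all(tab_s$name %in% tab_i$name))
  expect_false(any(c("NO3", "NH4", "Mn", "MnO2s") %in% tab_s$name))

  # with the N/Mn (and PR/U) pools emptied and identical constants, the
  # idealized tendencies reduce to the site tendencies, species by species
  cfg_s <- fe_config("site")
  cfg_i <- fe_config("idealized",
                     kinetics = cfg_s$kinetics[setdiff(names(cfg_s$kinetics),
                                                       character(0))],
                     fe_half_lives_yr = c(FeHR = 1, FeMR = 10, FePR = Inf,
                                          FeU = Inf))
  st_s <- synthetic_state(cfg_s, n = 12, seed = 9)
  st_i <- synthetic_state(cfg_i, n = 12, seed = 9)
  for (nm in names(st_s)) st_i[[nm]] <- st_s[[nm]]
  for (nm in c("NO3", "NH4", "Mn", "MnO2s", "FePR", "FeU",
               "FePR.56", "FeU.56"))
    st_i[[nm]] <- numeric(12)
  phi <- rep(0.85, 12)
  t_i <- network_rates(st_i, phi, cfg_i)$tend
  t_s <- network_rates(st_s, phi, cfg_s)$tend
  for (nm in names(t_s))
    expect_equal(t_i[[nm]], t_s[[nm]], tolerance = 1e-12, label = nm)
})

test_that("sorption partitioning is exact and invertible", {
  out <- sorption_partition(2, k_ads = 0, phi = 0.9)
  expect_equal(out$adsorbed, 0)
  expect_equal(out$dissolved * 0.9, 2)
  out2 <- sorption_partition(c(0, 1, 7), k_ads = 100, phi = 0.85)
  expect_equal(out2$adsorbed, 100 * out2$dissolved)
  # round trip: phase-weighted sum returns the input inventory
  expect_equal(0.85 * out2$dissolved + 0.15 * out2$adsorbed, c(0, 1, 7),
               tolerance = 1e-12)
  expect_error(sorption_partition(-1, 10, 0.9), ">= 0")
})
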