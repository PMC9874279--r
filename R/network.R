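# Species registry and kinetic reaction network.
#
# One network serves both model variants: the site-specific C-O-Fe-S
# set-up is the idealized C-N-O-Mn-Fe-S network with the nitrogen and
# manganese species disabled and the oxide classes re-interpreted as
# fresh and aged highly reactive iron.
#
# Internal unit convention: solutes in umol cm-3 of pore water (= mM),
# solids in umol cm-3 of solid phase; all rates returned per unit TOTAL
# sediment volume (umol cm-3 bulk yr-1).

#' Species table of a model variant
#'
#' @param variant `"idealized"` or `"site"`.
#' @return data.frame with name, phase, irrigation scaling, whether a
#'   paired 56Fe field exists, and the diffusivity key for solutes.
#' @export
species_table <- function(variant = c("idealized", "site")) {
  variant <- match.arg(variant)
  tab <- data.frame(
    name = c("O2", "NO3", "NH4", "Mn", "SO4", "HS", "CH4", "DFe",
             "POC1", "POC2", "POC3", "MnO2s",
             "FeHR", "FeMR", "FePR", "FeU", "FeS", "FeS2", "S0"),
    phase = c(rep("solute", 8), rep("solid", 11)),
    irr_scaling = c(1, 1, 1, 1, 1, 0.5, 1, 0.2, rep(0, 11)),
    iso = c(rep(FALSE, 7), TRUE, rep(FALSE, 4),
            TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    d0_key = c("O2", "NO3", "NH4", "Mn", "SO4", "HS", "CH4", "DFe",
               rep(NA, 11)),
    stringsAsFactors = FALSE)
  if (variant == "site")
    tab <- tab[!tab$name %in% c("NO3", "NH4", "Mn", "MnO2s", "FePR", "FeU"), ]
  rownames(tab) <- NULL
  tab
}

# full state-column names including the paired 56Fe fields
state_names <- function(tab) {
  c(tab$name, paste0(tab$name[tab$iso], ".56"))
}

# Rate constants of sulfide-mediated oxide reduction from class
# half-lives: k = ln 2 / t_half at the reference sulfide level.
sulfide_rate_constants <- function(half_lives_yr, hs_ref_mM = 1) {
  k <- log(2) / half_lives_yr / hs_ref_mM
  k[!is.finite(half_lives_yr)] <- 0
  k
}

#' Evaluate the full reaction network
#'
#' Computes every volumetric reaction rate from a state and returns the
#' per-species tendencies (per unit total sediment volume) together with
#' the named rate fields used by the diagnostics.
#'
#' @param state named list of concentration fields (one numeric vector
#'   per species, including the `.56` partners).
#' @param phi porosity at the cell centres.
#' @param config an [fe_config()].
#' @return list with `tend` (named list of bulk tendencies) and `rates`
#'   (named list of diagnostic rate fields, including the mineralization
#'   pathway matrix `cox_pathways`).
#' @export
network_rates <- function(state, phi, config) {
  kin <- config$kinetics
  eps <- config$eps
  site <- config$variant == "site"
  sv <- 1 - phi
  n <- length(phi)
  zero <- numeric(n)

  # Raw concentrations enter the bimolecular laws (a slightly negative
  # pool then yields a restoring rate, which keeps the steady-state
  # problem smooth); only the Monod fractions clip at zero.
  g <- function(nm) if (is.null(state[[nm]])) zero else state[[nm]]
  O2 <- g("O2"); NO3 <- g("NO3"); NH4 <- g("NH4"); Mn <- g("Mn")
  SO4 <- g("SO4"); HS <- g("HS"); CH4 <- g("CH4"); DFe <- g("DFe")
  MnO2 <- g("MnO2s"); FeHR <- g("FeHR"); FeMR <- g("FeMR")
  FePR <- g("FePR"); FeS <- g("FeS"); FeS2 <- g("FeS2"); S0 <- g("S0")
  pos <- function(x) pmax(x, 0)
  # smooth positive part used for the mineral saturation switch
  spl <- function(x) 0.5 * (x + sqrt(x * x + 1e-4))

  # --- multi-G mineralization, partitioned over the oxidant cascade ---
  dPOC <- mapply(function(k, nm) k * g(nm), kin$poc_k,
                 c("POC1", "POC2", "POC3"))
  if (is.null(dim(dPOC))) dPOC <- matrix(dPOC, nrow = n)
  Cdec <- sv * rowSums(dPOC)                    # umol C cm-3 bulk yr-1

  # Monod fractions with a C1 regularization at zero: exactly zero for
  # empty pools, quadratic onset over ~K/10, Monod beyond. Keeps the
  # oxidant fronts differentiable without creating phantom pathways.
  mon <- function(x, K) {
    w <- 0.1 * K
    q <- ifelse(x > 0, x * x / (x + w), 0)
    q / (q + K)
  }
  fO2 <- mon(O2, kin$K_O2)
  rem <- 1 - fO2
  if (!site) {
    fNO3 <- mon(NO3, kin$K_NO3) * rem; rem <- rem - fNO3
    fMnO2 <- mon(MnO2, kin$K_MnO2) * rem; rem <- rem - fMnO2
  } else {
    fNO3 <- zero; fMnO2 <- zero
  }
  # DIR draws on the highly reactive oxide pool; in the site variant the
  # aged fraction is part of that pool, discounted by its lower
  # bioavailability
  wa <- kin$dir_aged_weight
  dirpool <- pos(FeHR) + wa * pos(FeMR)
  fFe <- mon(dirpool, kin$K_FeHR) * rem; rem <- rem - fFe
  fSO4 <- mon(SO4, kin$K_SO4) * rem
  fCH4 <- rem - fSO4
  paths <- cbind(O2 = fO2 * Cdec, NO3 = fNO3 * Cdec, MnO2 = fMnO2 * Cdec,
                 FeHR = fFe * Cdec, SO4 = fSO4 * Cdec, CH4 = fCH4 * Cdec)

  R_dir <- 4 * paths[, "FeHR"]                  # Fe released by DIR
  sh_f <- pos(FeHR) / pmax(dirpool, 1e-300)     # fresh share of DIR
  sh_a <- 1 - sh_f
  R_dir_f <- R_dir * sh_f
  R_dir_a <- R_dir * sh_a

  # --- secondary redox reactions ---
  R_nit <- if (site) zero else kin$k_nit * O2 * NH4 * phi
  R_mnox <- if (site) zero else kin$k_mnox * O2 * Mn * phi
  R_feox <- kin$k_feox * O2 * DFe * phi
  # anoxic ferrous iron oxidation by manganese oxide
  R_femnox <- if (site) zero else kin$k_femnox * DFe * MnO2 * sv
  R_sox <- kin$k_sox * O2 * HS * phi
  R_ch4ox <- kin$k_ch4ox * O2 * CH4 * phi
  R_aom <- kin$k_aom * SO4 * CH4 * phi
  R_s0ox <- kin$k_s0ox * S0 * O2 * sv

  # --- sulfide-mediated oxide reduction, one constant per class ---
  ksul <- sulfide_rate_constants(config$fe_half_lives, kin$hs_ref_mM)
  R_sul_HR <- ksul[1] * FeHR * HS * sv
  R_sul_MR <- ksul[2] * FeMR * HS * sv
  R_sul_PR <- if (length(ksul) >= 3) ksul[3] * FePR * HS * sv else zero
  R_sul <- R_sul_HR + R_sul_MR + R_sul_PR

  # --- iron-sulfide system ---
  omega <- DFe * HS / kin$K_FeS
  # bimolecular precipitation, saturation-limited: first-order in each
  # reactant, smoothly zero at and below saturation
  sat <- spl(1 - 1 / pmax(omega, 1e-12))
  R_fespre <- kin$k_fes_pre * DFe * HS * sat * phi
  R_fesdis <- kin$k_fes_dis * FeS * spl(1 - omega) * sv
  R_pyr1 <- kin$k_pyr_hs * FeS * HS * sv
  R_pyr2 <- kin$k_pyr_s0 * FeS * S0 * sv
  R_fesox <- kin$k_fes_ox * FeS * O2 * sv
  R_pyrox <- kin$k_pyr_ox * FeS2 * O2 * sv
  R_age <- kin$k_age * FeHR * sv

  p0 <- kin$p_s0

  tend <- list(
    O2 = -paths[, "O2"] - 2 * R_nit - 0.5 * R_mnox - 0.25 * R_feox -
      (2 * (1 - p0) + 0.5 * p0) * R_sox - 2 * R_ch4ox -
      2 * R_fesox - 3.5 * R_pyrox - 1.5 * R_s0ox,
    SO4 = -0.5 * paths[, "SO4"] + (1 - p0) * R_sox + R_fesox +
      2 * R_pyrox + R_s0ox - R_aom,
    HS = 0.5 * paths[, "SO4"] - R_sox - 0.5 * R_sul - R_fespre +
      R_fesdis - R_pyr1 + R_aom,
    CH4 = 0.5 * paths[, "CH4"] - R_ch4ox - R_aom,
    DFe = R_dir + R_sul + R_fesdis + R_fesox + R_pyrox - R_feox -
      R_femnox - R_fespre,
    POC1 = -sv * dPOC[, 1], POC2 = -sv * dPOC[, 2], POC3 = -sv * dPOC[, 3],
    FeHR = -R_dir_f - R_sul_HR - R_age + R_feox + R_femnox,
    FeMR = R_age - R_dir_a - R_sul_MR,
    FeS = R_fespre - R_fesdis - R_pyr1 - R_pyr2 - R_fesox,
    FeS2 = R_pyr1 + R_pyr2 - R_pyrox,
    S0 = p0 * R_sox + 0.5 * R_sul - R_pyr2 - R_s0ox
  )
  if (!site) {
    tend$NO3 <- -0.8 * paths[, "NO3"] + R_nit
    tend$NH4 <- kin$rNC * Cdec - R_nit
    tend$Mn <- 2 * paths[, "MnO2"] - R_mnox + 0.5 * R_femnox
    tend$MnO2s <- -2 * paths[, "MnO2"] + R_mnox - 0.5 * R_femnox
    tend$FePR <- -R_sul_PR
    tend$FeU <- zero
  }

  # --- paired 56Fe tendencies -----------------------------------------
  cl <- kin$c_lim
  hrf <- function(bulk, heavy, e)
    heavy_rate_fraction(bulk, pmax(state[[heavy]], 0), eps_to_alpha(e), cl)
  f_red_HR <- hrf(FeHR, "FeHR.56", eps$reduction)
  f_red_MR <- hrf(FeMR, "FeMR.56", eps$reduction)
  f_ox <- hrf(DFe, "DFe.56", eps$oxidation)
  f_pre <- hrf(DFe, "DFe.56", eps$fes_precip)
  f_dis <- hrf(FeS, "FeS.56", eps$fes_dissol)
  f_pyr <- hrf(FeS, "FeS.56", eps$pyrite)
  f_fesox <- hrf(FeS, "FeS.56", eps$oxidation)
  f_pyrox <- hrf(FeS2, "FeS2.56", eps$oxidation)
  f_age <- heavy_rate_fraction(FeHR, pmax(state$FeHR.56, 0), 1, cl)

  pyr <- R_pyr1 + R_pyr2
  tend$DFe.56 <- (R_dir_f + R_sul_HR) * f_red_HR +
    (R_dir_a + R_sul_MR) * f_red_MR +
    R_fesdis * f_dis + R_fesox * f_fesox + R_pyrox * f_pyrox -
    (R_feox + R_femnox) * f_ox - R_fespre * f_pre
  tend$FeHR.56 <- -(R_dir_f + R_sul_HR) * f_red_HR - R_age * f_age +
    (R_feox + R_femnox) * f_ox
  tend$FeMR.56 <- R_age * f_age - (R_dir_a + R_sul_MR) * f_red_MR
  tend$FeS.56 <- R_fespre * f_pre - R_fesdis * f_dis - pyr * f_pyr -
    R_fesox * f_fesox
  tend$FeS2.56 <- pyr * f_pyr - R_pyrox * f_pyrox
  if (!site) {
    f_red_PR <- hrf(FePR, "FePR.56", eps$reduction)
    tend$FePR.56 <- -R_sul_PR * f_red_PR
    tend$FeU.56 <- zero
    tend$DFe.56 <- tend$DFe.56 + R_sul_PR * f_red_PR
  }

  list(tend = tend,
       rates = list(cox = Cdec, cox_pathways = paths,
                    p_dfe = R_dir + R_sul + R_fesdis + R_fesox + R_pyrox,
                    c_dfe = R_feox + R_femnox + R_fespre,
                    dir = R_dir, sulfide_reduction = cbind(
                      FeHR = R_sul_HR, FeMR = R_sul_MR, FePR = R_sul_PR),
                    fes_precip = R_fespre, fes_dissol = R_fesdis,
                    pyrite_hs = R_pyr1, pyrite_s0 = R_pyr2,
                    fes_ox = R_fesox, pyr_ox = R_pyrox, fe_ox = R_feox + R_femnox,
                    aging = R_age))
}

#' Organic-matter mineralization pathway rates
#'
#' Partitions total multi-G POC decay over the oxidant cascade (O2,
#' NO3, MnO2, FeOOH-HR, SO4, methanogenesis) by Monod limitation on each
#' oxidant with inhibition by all more favourable ones. The pathway
#' fractions sum to one, so the summed pathway rates equal total decay.
#'
#' @inheritParams network_rates
#' @return matrix of per-pathway C oxidation rates (umol C cm^-3 bulk
#'   yr^-1), one column per pathway.
#' @export
poc_mineralization <- function(state, phi, config) {
  network_rates(state, phi, config)$rates$cox_pathways
}

#' Iron-oxide reduction rates
#'
#' Dissimilatory reduction of the most reactive class (coupled to the
#' POC cascade) and sulfide-mediated reduction of every reactive class,
#' with rate constants derived from the class half-lives toward sulfide.
#' Both pathways release one dissolved ferrous iron per Fe reduced.
#'
#' @inheritParams network_rates
#' @return list with `dissimilatory` (Fe released, umol cm^-3 bulk
#'   yr^-1) and the per-class `sulfide_mediated` matrix.
#' @export
iron_oxide_reduction <- function(state, phi, config) {
  r <- network_rates(state, phi, config)$rates
  list(dissimilatory = r$dir, sulfide_mediated = r$sulfide_reduction)
}

#' Iron-sulfide mineral and oxidative reaction rates
#'
#' FeS precipitates above and dissolves below the `[Fe2+][HS-]`
#' saturation threshold; pyrite forms from FeS by the dissolved-sulfide
#' and elemental-sulfur pathways; DFe, FeS and FeS2 are oxidized by O2.
#'
#' @inheritParams network_rates
#' @return named list of rate fields (umol cm^-3 bulk yr^-1).
#' @export
sulfide_iron_mineral_rates <- function(state, phi, config) {
  r <- network_rates(state, phi, config)$rates
  r[c("fes_precip", "fes_dissol", "pyrite_hs", "pyrite_s0",
      "fes_ox", "pyr_ox", "fe_ox")]
}

#' Oxide aging rate
#'
#' First-order conversion of the most reactive oxide class into the next
#' class (highly reactive to moderately reactive in the idealized
#' variant; fresh to aged highly reactive iron in the site variant).
#' Iron is conserved between the two pools.
#'
#' @inheritParams network_rates
#' @return aging rate field (umol cm^-3 bulk yr^-1).
#' @export
aging <- function(state, phi, config) {
  network_rates(state, phi, config)$rates$aging
}

#' Instantaneous sorption partitioning of ferrous iron
#'
#' Splits a total (bulk-volume) ferrous iron inventory into its
#' dissolved and adsorbed parts under the reversible equilibrium
#' `adsorbed = k_ads * dissolved` (dissolved per pore-water volume,
#' adsorbed per solid volume).
#'
#' @param total_ferrous total inventory (umol cm^-3 of total sediment).
#' @param k_ads dimensionless adsorption constant.
#' @param phi porosity.
#' @return list with `dissolved` (umol cm^-3 pore water) and `adsorbed`
#'   (umol cm^-3 solid).
#' @export
sorption_partition <- function(total_ferrous, k_ads, phi) {
  if (any(total_ferrous < 0))
    stop("total ferrous iron must be >= 0", call. = FALSE)
  if (k_ads < 0) stop("k_ads must be >= 0", call. = FALSE)
  dis <- total_ferrous / (phi + (1 - phi) * k_ads)
  list(dissolved = dis, adsorbed = k_ads * dis)
}
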