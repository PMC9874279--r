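#' Model configuration
#'
#' Builds a fully-validated configuration for a steady-state run. Two
#' variants are supported: the `"idealized"` shelf set-up with a full
#' C-N-O-Mn-Fe-S network and four iron-oxide reactivity classes, and the
#' `"site"` set-up (C-O-Fe-S only) in which the highly reactive oxide
#' pool is split into fresh and aged fractions. The site network is the
#' idealized network with the nitrogen and manganese species disabled;
#' one code path serves both.
#'
#' Units are embedded in the argument names: bottom-water concentrations
#' in mM (= umol cm^-3 of pore water = mol m^-3), solid deposition fluxes
#' in umol m^-2 d^-1 except the POC rain rate in mmol m^-2 d^-1,
#' delta-56Fe in permil on the IRMM-014 scale.
#'
#' @param variant `"idealized"` or `"site"`.
#' @param temperature_C,salinity ambient conditions.
#' @param domain_depth_cm model domain L.
#' @param burial_velocity_cm_kyr burial velocity in compacted sediment.
#' @param phi_surface,phi_deep,phi_attenuation_cm porosity profile.
#' @param db0_cm2_yr,z_mix_cm,alpha0_yr,x_irr_cm bioturbation parameters.
#' @param bottom_water_mM named list of SWI concentrations; recognised
#'   names: O2, NO3, NH4, Mn, SO4, HS, CH4, DFe.
#' @param j_poc_mmol_m2_d POC rain rate.
#' @param j_feooh_umol_m2_d,j_fes_umol_m2_d,j_fes2_umol_m2_d,j_mno2_umol_m2_d
#'   particulate deposition fluxes.
#' @param delta_feooh,delta_fes,delta_fes2 input delta-56Fe per Fe phase.
#' @param eps named overrides of the effective fractionations (permil):
#'   `reduction`, `oxidation`, `sorption`, `fes_precip`, `fes_dissol`,
#'   `pyrite`.
#' @param kinetics named overrides of rate and equilibrium constants
#'   (see [default_kinetics()]).
#' @param fe_half_lives_yr half-life toward sulfide per oxide class.
#' @param fe_partition fraction of the FeOOH flux entering each class;
#'   must sum to 1.
#' @param n_cells,dz_top_cm grid resolution: number of cells and the
#'   target thickness of the top cell (cells grow geometrically; set
#'   `dz_top_cm = NULL` for a uniform grid).
#' @param solver named overrides of solver settings (`t_end`, `rtol`,
#'   `atol_rel`, `steady_tol`, `max_time`).
#' @return an object of class `fe_config`.
#' @export
fe_config <- function(variant = c("idealized", "site"),
                      temperature_C = 10, salinity = 34.2,
                      domain_depth_cm = 150,
                      burial_velocity_cm_kyr = 60,
                      phi_surface = 0.95, phi_deep = 0.82,
                      phi_attenuation_cm = 3.6,
                      db0_cm2_yr = 0, z_mix_cm = 10,
                      alpha0_yr = 0, x_irr_cm = 1.4,
                      bottom_water_mM = list(),
                      j_poc_mmol_m2_d = 10,
                      j_feooh_umol_m2_d = 1110,
                      j_fes_umol_m2_d = 0, j_fes2_umol_m2_d = 0,
                      j_mno2_umol_m2_d = 20,
                      delta_feooh = 0, delta_fes = 0, delta_fes2 = 0,
                      eps = list(), kinetics = list(),
                      fe_half_lives_yr = NULL, fe_partition = NULL,
                      n_cells = 100, dz_top_cm = 0.05,
                      solver = list()) {
  variant <- match.arg(variant)

  bw <- list(O2 = 0.12, NO3 = 0.03, NH4 = 0, Mn = 0, SO4 = 28,
             HS = 0, CH4 = 0, DFe = 0)
  unknown <- setdiff(names(bottom_water_mM), names(bw))
  if (length(unknown))
    stop("unknown bottom-water species: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  bw[names(bottom_water_mM)] <- bottom_water_mM
  if (any(unlist(bw) < 0))
    stop("bottom-water concentrations must be >= 0", call. = FALSE)

  eps0 <- list(reduction = -1.3, oxidation = 0.4, sorption = 0.4,
               fes_precip = 0.5, fes_dissol = -0.5, pyrite = -0.7)
  unknown <- setdiff(names(eps), names(eps0))
  if (length(unknown))
    stop("unknown eps entries: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  eps0[names(eps)] <- eps

  kin <- default_kinetics(variant)
  unknown <- setdiff(names(kinetics), names(kin))
  if (length(unknown))
    stop("unknown kinetics entries: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  kin[names(kinetics)] <- kinetics

  if (is.null(fe_half_lives_yr))
    fe_half_lives_yr <- if (variant == "idealized")
      c(FeHR = 1, FeMR = 100, FePR = 1e5, FeU = Inf)
    else c(FeHR = 1, FeMR = 10, FePR = Inf, FeU = Inf)  # fresh / aged HR
  if (is.null(fe_partition))
    fe_partition <- if (variant == "idealized")
      c(FeHR = 1 / 6, FeMR = 1 / 6, FePR = 1 / 6, FeU = 0.5)
    else c(FeHR = 1, FeMR = 0, FePR = 0, FeU = 0)
  if (abs(sum(fe_partition) - 1) > 1e-10)
    stop("fe_partition must sum to 1", call. = FALSE)
  if (any(c(j_poc_mmol_m2_d, j_feooh_umol_m2_d, j_fes_umol_m2_d,
            j_fes2_umol_m2_d, j_mno2_umol_m2_d) < 0))
    stop("deposition fluxes must be >= 0", call. = FALSE)

  sol <- list(t_end = 1e5, rtol = 1e-5, atol_rel = 1e-6,
              steady_tol = 1e-8, max_time = 1e7, max_wall_s = 90)
  sol[names(solver)] <- solver

  cfg <- list(variant = variant,
              temperature_C = temperature_C, salinity = salinity,
              domain_depth_cm = domain_depth_cm,
              burial_velocity_cm_kyr = burial_velocity_cm_kyr,
              porosity = list(phi_surface = phi_surface, phi_deep = phi_deep,
                              attenuation_cm = phi_attenuation_cm),
              transport = list(db0 = db0_cm2_yr, z_mix = z_mix_cm,
                               alpha0 = alpha0_yr, x_irr = x_irr_cm),
              bottom_water = bw,
              fluxes = list(POC = j_poc_mmol_m2_d,       # mmol m-2 d-1
                            FeOOH = j_feooh_umol_m2_d,   # umol m-2 d-1
                            FeS = j_fes_umol_m2_d,
                            FeS2 = j_fes2_umol_m2_d,
                            MnO2 = j_mno2_umol_m2_d),
              delta_in = list(FeOOH = delta_feooh, FeS = delta_fes,
                              FeS2 = delta_fes2),
              eps = eps0, kinetics = kin,
              fe_half_lives = fe_half_lives_yr,
              fe_partition = fe_partition,
              n_cells = n_cells, dz_top_cm = dz_top_cm,
              solver = sol)
  class(cfg) <- "fe_config"
  cfg
}

#' Default kinetic and equilibrium constants
#'
#' Monod half-saturation constants for the mineralization cascade, rate
#' constants of the secondary redox and mineral reactions, the multi-G
#' organic-matter reactivity split, the sorption constant and the
#' isotope constants. Concentration units are mM for solutes and
#' umol cm^-3 of solid phase for solids; bimolecular constants are per
#' mM (or per umol cm^-3 solid) per year. All values can be overridden
#' through the `kinetics` argument of [fe_config()].
#'
#' @param variant model variant; the site variant carries the same
#'   constants (species not in its network are simply inactive).
#' @return named list of constants.
#' @export
default_kinetics <- function(variant = "idealized") {
  list(
    # Monod half-saturation / inhibition constants
    K_O2 = 0.001, K_NO3 = 0.010, K_MnO2 = 16,
    K_FeHR = if (variant == "site") 4000 else 2500, K_SO4 = 0.9,
    # secondary redox reactions (bimolecular, mM^-1 yr^-1 unless noted)
    k_nit = 1e4, k_mnox = 1e3,
    k_feox = if (variant == "site") 3e4 else 1e6, k_femnox = 30,
    k_sox = 1e5, k_ch4ox = 1e5, k_aom = 10, k_s0ox = 1e3,
    p_s0 = 0.5,                 # fraction of HS oxidation routed to S0
    # iron-sulfide system
    K_FeS = 1e-3,               # [Fe2+][HS-] solubility threshold, mM^2
    k_fes_pre = 100,            # mM^-1 yr^-1, saturation-limited bimolecular
    k_fes_dis = 1,              # yr-1 per undersaturation unit
    k_pyr_hs = 0.3,             # FeS + H2S, mM^-1 yr^-1
    k_pyr_s0 = 1e-3,            # FeS + S0, (umol cm-3 solid)^-1 yr^-1
    k_fes_ox = 1e3, k_pyr_ox = 1,
    # oxide aging, aged-pool bioavailability, sorption
    k_age = if (variant == "site") 1 else 0.5,  # yr^-1
    dir_aged_weight = if (variant == "site") 1 else 0,
    k_ads = 100,                # dimensionless sorption constant
    # sulfide-mediated oxide reduction reference level
    hs_ref_mM = 1,
    # multi-G organic matter: fractions and first-order constants
    poc_fractions = c(0.50, 0.33, 0.17),
    poc_k = c(24, 1.4, 0),      # yr^-1
    rNC = 16 / 106,
    # isotope bookkeeping
    ref_ratio = IRMM014_RATIO, c_lim = C_LIM_DEFAULT
  )
}

#' @export
#' @method print fe_config
print.fe_config <- function(x, ...) {
  cat("benthicFe configuration (", x$variant, " variant)\n", sep = "")
  cat("  domain ", x$domain_depth_cm, " cm, ", x$n_cells, " cells; O2_bw = ",
      x$bottom_water$O2 * 1000, " uM; J_POC = ", x$fluxes$POC,
      " mmol m-2 d-1; J_FeOOH,T = ", x$fluxes$FeOOH, " umol m-2 d-1\n",
      sep = "")
  cat("  bioturbation: Db0 = ", x$transport$db0, " cm2 yr-1, z_L = ",
      x$transport$z_mix, " cm, alpha0 = ", x$transport$alpha0, " yr-1\n",
      sep = "")
  invisible(x)
}

#' Load a configuration from a YAML file
#'
#' Reads a structured-text configuration and passes its keys to
#' [fe_config()]; unknown keys are rejected with the offending name.
#' Fixtures shipped with the package (`"monterey_canyon"`,
#' `"santa_barbara"`, `"baseline"`) can be loaded by name.
#'
#' @param path path to a YAML file, or a fixture name.
#' @param overrides named list merged over the file's values.
#' @return an `fe_config`.
#' @export
load_config <- function(path, overrides = list()) {
  if (!file.exists(path)) {
    pkg <- system.file("extdata", paste0(path, ".yml"), package = "benthicFe")
    if (pkg == "") stop("config file not found: ", path, call. = FALSE)
    path <- pkg
  }
  vals <- yaml::read_yaml(path)
  deep <- c("bottom_water_mM", "eps", "kinetics", "solver")
  for (nm in names(overrides)) {
    if (nm %in% deep && nm %in% names(vals))
      vals[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    else vals[[nm]] <- overrides[[nm]]
  }
  known <- names(formals(fe_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (nm in c("fe_half_lives_yr", "fe_partition"))
    if (!is.null(vals[[nm]])) vals[[nm]] <- unlist(vals[[nm]])
  do.call(fe_config, vals)
}
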