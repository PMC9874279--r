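# Bioturbation scenario experiments and sensitivity grids for the
# idealized shelf set-up.

#' Oxygen scaling of bioturbation intensity
#'
#' Dimensionless factor `f = 0.5 + 0.5 erf(([O2]_BW - a)/b)` with
#' a = 20 uM and b = 12 uM, used to scale the bio-mixing and
#' bio-irrigation coefficients to bottom-water oxygen.
#'
#' @param o2_uM bottom-water oxygen (uM).
#' @param a,b location and width of the ramp (uM).
#' @return f in (0, 1), strictly increasing in oxygen.
#' @export
oxygen_scaling <- function(o2_uM, a = 20, b = 12) {
  if (any(o2_uM < 0)) stop("oxygen must be >= 0", call. = FALSE)
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  0.5 + 0.5 * erf((o2_uM - a) / b)
}

#' Mixing depth from the biodiffusion coefficient
#'
#' `z_L = 1 + 9 (1 - exp(-D_b0 / 3))` cm, saturating from 1 cm (no
#' mixing) to 10 cm at high biodiffusion, and passing through 9.7 cm at
#' the reference D_b0 = 10 cm^2 yr^-1 of the always-bioturbated
#' scenario. `form = "printed"` selects the alternative denominator of
#' 30 cm^2 yr^-1 found in some parameter listings (which does not
#' reproduce the 9.7 cm reference value and is kept only for
#' comparison).
#'
#' @param db0_cm2_yr biodiffusion coefficient (cm^2 yr^-1).
#' @param form `"reference"` (default) or `"printed"`.
#' @return z_L (cm) in `[1, 10]`.
#' @export
mixing_depth <- function(db0_cm2_yr, form = c("reference", "printed")) {
  form <- match.arg(form)
  if (any(db0_cm2_yr < 0)) stop("biodiffusion must be >= 0", call. = FALSE)
  den <- if (form == "reference") 3 else 30
  1 + 9 * (1 - exp(-db0_cm2_yr / den))
}

#' Build a bioturbation scenario configuration
#'
#' The five scenario experiments of the idealized shelf model:
#' * `baseline`: bio-mixing and bio-irrigation scale with bottom-water
#'   oxygen, `D_b0 = 10 f`, `alpha_0 = 290 f`, `f = oxygen_scaling(o2)`;
#' * `unbioturbated`: both set to zero;
#' * `always_bioturbated`: fixed at the maximum
#'   (`D_b0 = 10 cm^2 yr^-1`, `z_L = 9.7 cm`, `alpha_0 = 290 yr^-1`);
#' * `only_biomixing`: mixing at maximum, irrigation zero;
#' * `only_bioirrigation`: irrigation at maximum, mixing zero.
#'
#' All remaining boundary conditions take their idealized baseline
#' values (oxic shelf at 120 uM O2, `J_POC = 10 mmol m^-2 d^-1`,
#' `J_FeOOH,T = 1110 umol m^-2 d^-1` with delta-56Fe 0, 28 mM sulfate).
#'
#' @param name scenario name (see above).
#' @param o2_uM bottom-water oxygen (uM).
#' @param ... overrides forwarded to [fe_config()].
#' @return an `fe_config`.
#' @export
make_scenario <- function(name = c("baseline", "unbioturbated",
                                   "always_bioturbated", "only_biomixing",
                                   "only_bioirrigation"),
                          o2_uM = 120, ...) {
  name <- match.arg(name)
  f <- oxygen_scaling(o2_uM)
  pars <- switch(name,
    baseline = list(db0 = 10 * f, alpha0 = 290 * f),
    unbioturbated = list(db0 = 0, alpha0 = 0),
    always_bioturbated = list(db0 = 10, alpha0 = 290),
    only_biomixing = list(db0 = 10, alpha0 = 0),
    only_bioirrigation = list(db0 = 0, alpha0 = 290))
  zl <- if (name %in% c("always_bioturbated", "only_biomixing")) 9.7
        else mixing_depth(pars$db0)
  dots <- list(...)
  bw <- dots$bottom_water_mM
  if (is.null(bw)) bw <- list()
  bw$O2 <- o2_uM / 1000
  dots$bottom_water_mM <- bw
  do.call(fe_config, c(list(variant = "idealized",
                            db0_cm2_yr = pars$db0, z_mix_cm = zl,
                            alpha0_yr = pars$alpha0, x_irr_cm = 1.4),
                       dots))
}

#' Sensitivity-grid axes
#'
#' The tested levels of the sensitivity experiments: bottom-water
#' oxygen, POC rain, total FeOOH flux and (unbioturbated only) sulfate.
#'
#' @return named list of numeric axes.
#' @export
sensitivity_axes <- function() {
  list(o2_uM = c(1, 2, 5, 10, 15, 25, 50, 100, 120, 200),
       j_poc = c(0.5, 1, 2, 4, 6, 8, 10, 12, 14, 16),
       j_feooh = c(194, 278, 555, 1110, 1914),
       so4_mM = c(0, 0.01, 0.1, 1, 28))
}

#' Enumerate a sensitivity grid
#'
#' Builds the full Cartesian product of scenario configurations for the
#' `modern` seafloor (oxygen-scaled bioturbation; O2 x POC x FeOOH axes)
#' or the `unbioturbated` seafloor (no bioturbation; O2 x POC x SO4 axes
#' at fixed FeOOH flux).
#'
#' @param kind `"modern"` or `"unbioturbated"`.
#' @param o2_uM,j_poc,j_feooh,so4_mM optional axis overrides (defaults
#'   from [sensitivity_axes()]).
#' @param ... forwarded to [make_scenario()] / [fe_config()].
#' @return list with `design` (data.frame of axis values) and `configs`
#'   (list of `fe_config`).
#' @export
enumerate_grid <- function(kind = c("modern", "unbioturbated"),
                           o2_uM = NULL, j_poc = NULL, j_feooh = NULL,
                           so4_mM = NULL, ...) {
  kind <- match.arg(kind)
  ax <- sensitivity_axes()
  if (is.null(o2_uM)) o2_uM <- ax$o2_uM
  if (is.null(j_poc)) j_poc <- ax$j_poc
  if (kind == "modern") {
    if (is.null(j_feooh)) j_feooh <- ax$j_feooh
    design <- expand.grid(o2_uM = o2_uM, j_poc = j_poc, j_feooh = j_feooh,
                          KEEP.OUT.ATTRS = FALSE)
    configs <- lapply(seq_len(nrow(design)), function(i)
      make_scenario("baseline", o2_uM = design$o2_uM[i],
                    j_poc_mmol_m2_d = design$j_poc[i],
                    j_feooh_umol_m2_d = design$j_feooh[i], ...))
  } else {
    if (is.null(j_feooh)) j_feooh <- 1110
    if (is.null(so4_mM)) so4_mM <- ax$so4_mM
    design <- expand.grid(o2_uM = o2_uM, j_poc = j_poc, j_feooh = j_feooh,
                          so4_mM = so4_mM, KEEP.OUT.ATTRS = FALSE)
    configs <- lapply(seq_len(nrow(design)), function(i)
      make_scenario("unbioturbated", o2_uM = design$o2_uM[i],
                    j_poc_mmol_m2_d = design$j_poc[i],
                    j_feooh_umol_m2_d = design$j_feooh[i],
                    bottom_water_mM = list(SO4 = design$so4_mM[i]), ...))
  }
  list(design = design, configs = configs)
}

#' Run a list of configurations to steady state
#'
#' Convenience sweep runner: runs each configuration and collects the
#' flux diagnostics into a data.frame. Consecutive runs warm-start from
#' the previous solution when the grids match.
#'
#' @param configs list of `fe_config` (e.g. from [enumerate_grid()]).
#' @param warm_start reuse the previous steady state as initial guess.
#' @param quiet suppress progress output.
#' @return data.frame of diagnostics, one row per configuration.
#' @export
run_sweep <- function(configs, warm_start = TRUE, quiet = TRUE) {
  prev <- NULL
  rows <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    init <- NULL
    if (warm_start && !is.null(prev)) init <- prev
    fit <- run_steady(configs[[i]], init = init)
    prev <- fit$state
    d <- fit$diagnostics
    rows[[i]] <- data.frame(J_DFe = d$J_DFe, delta_JDFe = d$delta_JDFe,
                            Cox = d$Cox, P_DFe = d$P_DFe, C_DFe = d$C_DFe,
                            B_FeOOH_T = d$B_FeOOH_T, B_FeS2 = d$B_FeS2,
                            pyrite_burial_fraction = d$pyrite_burial_fraction,
                            fe_balance = d$fe_balance,
                            residual = fit$residual)
    if (!quiet) message(sprintf("run %d/%d: J_DFe = %.2f", i,
                                length(configs), d$J_DFe))
  }
  do.call(rbind, rows)
}
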