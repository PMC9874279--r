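#' Porosity profile description
#'
#' Porosity decays exponentially from its value at the sediment-water
#' interface (SWI) to an asymptotic value at depth with an e-folding
#' attenuation depth, the standard description of steady compaction in
#' diagenetic models.
#'
#' @param phi_surface porosity at the SWI (volume fraction, in (0,1)).
#' @param phi_deep asymptotic porosity at depth; must satisfy
#'   `0 < phi_deep <= phi_surface < 1`.
#' @param attenuation_depth e-folding depth of the decay (cm).
#' @return an object of class `porosity_profile`.
#' @export
porosity_profile <- function(phi_surface, phi_deep, attenuation_depth) {
  if (!(phi_deep > 0 && phi_deep <= phi_surface && phi_surface < 1))
    stop("non-physical porosity parameters: need 0 < phi_deep <= phi_surface < 1",
         call. = FALSE)
  if (attenuation_depth <= 0)
    stop("porosity attenuation depth must be positive", call. = FALSE)
  structure(list(phi_surface = phi_surface, phi_deep = phi_deep,
                 attenuation_depth = attenuation_depth),
            class = "porosity_profile")
}

#' Evaluate a porosity profile at depth
#'
#' @param profile a [porosity_profile()].
#' @param z depth below the SWI (cm, positive downward).
#' @return porosity (volume fraction) at `z`.
#' @export
porosity_at <- function(profile, z) {
  profile$phi_deep +
    (profile$phi_surface - profile$phi_deep) * exp(-z / profile$attenuation_depth)
}

#' Build the vertical sediment grid
#'
#' Finite-volume grid over `[0, domain_depth]` with porosity and the
#' steady-compaction advection velocities of solutes and solids. With
#' `stretch = 1` the grid is uniform; with `stretch > 1` cell widths grow
#' geometrically downward, concentrating resolution near the SWI where
#' redox gradients are steepest.
#'
#' Steady compaction fixes the velocity fields from the deep burial
#' velocity `v`: `phi(z) u(z) = phi_deep v` for the pore fluid and
#' `(1 - phi(z)) w(z) = (1 - phi_deep) v` for solids.
#'
#' @param domain_depth total depth of the modelled column L (cm).
#' @param n_cells number of finite-volume cells (>= 10).
#' @param porosity a [porosity_profile()].
#' @param burial_velocity_deep burial velocity in compacted sediment
#'   (cm kyr^-1, as tabulated in the field).
#' @param stretch geometric growth factor of successive cell widths
#'   (1 = uniform).
#' @return an object of class `fe_grid` with cell centres/interfaces,
#'   porosity and velocity fields at both.
#' @export
build_grid <- function(domain_depth, n_cells, porosity,
                       burial_velocity_deep, stretch = 1) {
  if (domain_depth <= 0) stop("domain_depth must be positive", call. = FALSE)
  if (n_cells < 10) stop("n_cells must be at least 10", call. = FALSE)
  if (burial_velocity_deep <= 0)
    stop("burial velocity must be positive", call. = FALSE)
  if (!inherits(porosity, "porosity_profile"))
    stop("porosity must be a porosity_profile", call. = FALSE)

  if (stretch == 1) {
    ifc <- seq(0, domain_depth, length.out = n_cells + 1)
  } else {
    w <- stretch^(0:(n_cells - 1))
    w <- w / sum(w) * domain_depth
    ifc <- c(0, cumsum(w))
    ifc[n_cells + 1] <- domain_depth
  }
  ctr <- 0.5 * (ifc[-1] + ifc[-(n_cells + 1)])
  dz <- diff(ifc)

  v_deep_cm_yr <- burial_velocity_deep / 1000  # cm kyr-1 -> cm yr-1
  phi_c <- porosity_at(porosity, ctr)
  phi_i <- porosity_at(porosity, ifc)

  grid <- structure(list(
    n = n_cells,
    cell_centres = ctr,
    cell_interfaces = ifc,
    dz = dz,
    # centre-to-centre distances bracketing each interior interface,
    # with half-cell distances at the two boundaries
    dzi = c(ctr[1], diff(ctr), domain_depth - ctr[n_cells]),
    porosity_centres = phi_c,
    porosity_interfaces = phi_i,
    solute_velocity = porosity$phi_deep * v_deep_cm_yr / phi_i,
    solid_velocity = (1 - porosity$phi_deep) * v_deep_cm_yr / (1 - phi_i),
    burial_velocity_deep = v_deep_cm_yr,
    porosity = porosity,
    domain_depth = domain_depth
  ), class = "fe_grid")
  grid
}

#' @export
#' @method print fe_grid
print.fe_grid <- function(x, ...) {
  cat("Sediment grid: ", x$n, " cells over ", x$domain_depth, " cm",
      " (dz ", signif(min(x$dz), 3), "-", signif(max(x$dz), 3), " cm)\n",
      sep = "")
  cat("porosity ", x$porosity$phi_surface, " -> ", x$porosity$phi_deep,
      ", burial velocity ", x$burial_velocity_deep * 1000, " cm kyr^-1\n",
      sep = "")
  invisible(x)
}

#' Transport parameters
#'
#' Bundles the bioturbation and molecular-diffusion parameters acting on
#' a sediment column. Bio-mixing is a biodiffusion with coefficient
#' `biodiffusion_coeff` down to `mixing_depth`; bio-irrigation is a
#' non-local solute exchange with surface coefficient `irrigation_coeff`
#' attenuating over `irrigation_attenuation`. Solute-specific multipliers
#' on the irrigation coefficient account for reaction within burrow walls
#' (0.2 for dissolved ferrous iron, 0.5 for free sulfide, 1 otherwise).
#'
#' @param biodiffusion_coeff D_b0 (cm^2 yr^-1).
#' @param mixing_depth z_L (cm).
#' @param irrigation_coeff alpha_0 (yr^-1).
#' @param irrigation_attenuation x_irr (cm).
#' @param mixing_decay_scale e-folding decay (cm) of biodiffusion below
#'   the mixed layer; a smooth taper instead of a hard cutoff.
#' @return an object of class `transport_params`.
#' @export
transport_params <- function(biodiffusion_coeff = 0, mixing_depth = 10,
                             irrigation_coeff = 0, irrigation_attenuation = 3,
                             mixing_decay_scale = 1) {
  vals <- c(biodiffusion_coeff, mixing_depth, irrigation_coeff,
            irrigation_attenuation, mixing_decay_scale)
  if (any(vals < 0)) stop("transport coefficients must be >= 0", call. = FALSE)
  structure(list(biodiffusion_coeff = biodiffusion_coeff,
                 mixing_depth = mixing_depth,
                 irrigation_coeff = irrigation_coeff,
                 irrigation_attenuation = irrigation_attenuation,
                 mixing_decay_scale = mixing_decay_scale),
            class = "transport_params")
}

#' Biodiffusion coefficient profile
#'
#' Constant at `biodiffusion_coeff` within the mixed layer, decaying
#' exponentially below it with `mixing_decay_scale`.
#'
#' @param params a [transport_params()].
#' @param z depths (cm) at which to evaluate.
#' @return D_b(z) (cm^2 yr^-1) at each depth.
#' @export
biodiffusion_profile <- function(params, z) {
  db0 <- params$biodiffusion_coeff
  if (db0 == 0) return(numeric(length(z)) * 0)
  ifelse(z <= params$mixing_depth, db0,
         db0 * exp(-(z - params$mixing_depth) / params$mixing_decay_scale))
}

#' Bio-irrigation exchange profile
#'
#' Non-local exchange coefficient `alpha(z) = s alpha_0 exp(-z / x_irr)`
#' where `s` is the solute-specific scaling.
#'
#' @param params a [transport_params()].
#' @param z depths (cm).
#' @param scaling solute-specific multiplier on `irrigation_coeff`.
#' @return alpha(z) (yr^-1) at each depth.
#' @export
irrigation_profile <- function(params, z, scaling = 1) {
  a0 <- params$irrigation_coeff * scaling
  if (a0 == 0) return(numeric(length(z)) * 0)
  a0 * exp(-z / params$irrigation_attenuation)
}

#' Tortuosity-corrected sediment diffusivity
#'
#' Applies the standard `theta^2 = 1 - 2 ln(phi)` tortuosity correlation.
#'
#' @param d0 free-solution diffusivity (cm^2 yr^-1).
#' @param phi porosity.
#' @return effective sediment diffusivity (cm^2 yr^-1).
#' @export
tortuosity_correct <- function(d0, phi) d0 / (1 - 2 * log(phi))

# Free-solution diffusivities (cm^2 yr^-1) from linear temperature
# correlations (infinite-dilution, approximately corrected to seawater).
# T in degrees C.
molecular_diffusivity <- function(solute, temperature = 10) {
  co <- list(O2  = c(11.70, 0.344),
             NO3 = c(9.50, 0.388),
             NH4 = c(9.50, 0.413),
             SO4 = c(4.88, 0.232),
             HS  = c(10.40, 0.273),
             CH4 = c(9.00, 0.354),
             DFe = c(3.31, 0.150),
             Mn  = c(3.18, 0.155))
  if (!solute %in% names(co)) stop("no diffusivity for solute ", solute,
                                   call. = FALSE)
  m <- co[[solute]]
  (m[1] + m[2] * temperature) * 1e-6 * 3.1557e7  # cm2 s-1 -> cm2 yr-1
}
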