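# Finite-volume transport operators.
#
# Fluxes are evaluated at cell interfaces per unit TOTAL sediment area
# (umol cm-2 yr-1, positive downward); tendencies are returned per unit
# total sediment volume (umol cm-3 bulk yr-1). Dividing by the phase
# capacity (phi for solutes, 1 - phi for solids) recovers the
# per-phase-volume concentration tendency.

# Precompute the interface conductances for one species.
#   phase "solute": molecular diffusion (tortuosity-corrected) +
#     biodiffusion + porewater advection + non-local irrigation;
#     fixed concentration at the SWI, zero diffusive gradient at depth.
#   phase "solid": biodiffusion + burial advection; imposed deposition
#     flux at the SWI, zero diffusive gradient at depth.
make_transport_op <- function(grid, params, phase = c("solute", "solid"),
                              d0 = 0, irrigation_scaling = 1) {
  phase <- match.arg(phase)
  n <- grid$n
  zi <- grid$cell_interfaces
  phii <- grid$porosity_interfaces
  db <- biodiffusion_profile(params, zi)

  if (phase == "solute") {
    dtot <- tortuosity_correct(d0, phii) + db
    vol <- phii                     # area fraction open to transport
    vel <- grid$solute_velocity
    alpha <- irrigation_profile(params, grid$cell_centres, irrigation_scaling)
  } else {
    dtot <- db
    vol <- 1 - phii
    vel <- grid$solid_velocity
    alpha <- numeric(n)
  }

  gd <- vol * dtot / grid$dzi       # diffusive conductance per interface
  ga <- vol * vel                   # advective (upwind) coefficient
  if (phase == "solid") gd[1] <- 0  # solids enter only by deposition

  list(phase = phase, n = n, gd = gd, ga = ga,
       alpha = alpha, phic = grid$porosity_centres,
       dz = grid$dz)
}

# Apply a transport operator to a concentration field.
#   bc_value: bottom-water concentration (solute) or deposition flux in
#     umol cm-2 yr-1 (solid).
# Returns bulk-volume tendency plus the boundary fluxes and the
# irrigation exchange (positive = sediment-to-water), all per total area.
apply_transport <- function(op, conc, bc_value) {
  n <- op$n
  if (length(conc) != n) stop("field/grid size mismatch", call. = FALSE)

  # interface fluxes, positive downward; upwind advection (velocity > 0)
  flux <- numeric(n + 1)
  i <- 2:n
  flux[i] <- op$gd[i] * (conc[i - 1] - conc[i]) + op$ga[i] * conc[i - 1]
  if (op$phase == "solute") {
    flux[1] <- op$gd[1] * (bc_value - conc[1]) + op$ga[1] * bc_value
  } else {
    flux[1] <- bc_value
  }
  flux[n + 1] <- op$ga[n + 1] * conc[n]   # zero-gradient outflow

  tend <- (flux[1:n] - flux[2:(n + 1)]) / op$dz
  irr <- op$phase == "solute" && any(op$alpha > 0)
  if (irr) {
    ex <- op$alpha * op$phic * (conc - bc_value)  # bulk rate, to water
    tend <- tend - ex
    irr_exchange <- sum(ex * op$dz)
  } else {
    irr_exchange <- 0
  }
  list(tendency = tend, flux_top = flux[1], flux_bottom = flux[n + 1],
       irr_exchange = irr_exchange)
}

#' Transport tendency of a concentration field
#'
#' Evaluates the conservative finite-volume transport tendency for a
#' solute (molecular diffusion with tortuosity correction, biodiffusion,
#' porewater advection and non-local bio-irrigation exchange with the
#' bottom water) or a solid (biodiffusive mixing and burial advection).
#' Solutes carry a fixed concentration at the sediment-water interface;
#' solids an imposed deposition flux; both a zero-gradient condition at
#' the bottom of the domain.
#'
#' @param conc concentration field on the grid cells (umol cm^-3 of pore
#'   water for solutes, of solid phase for solids).
#' @param species_phase `"solute"` or `"solid"`.
#' @param grid a [build_grid()] grid.
#' @param params a [transport_params()].
#' @param bottom_water_value fixed SWI concentration (solute) or
#'   deposition flux in umol cm^-2 yr^-1 (solid).
#' @param molecular_diffusivity free-solution diffusivity (cm^2 yr^-1);
#'   solutes only.
#' @param irrigation_scaling solute-specific irrigation multiplier.
#' @return list with `tendency` (umol cm^-3 of phase volume per yr),
#'   boundary fluxes and the depth-integrated irrigation exchange
#'   (umol cm^-2 yr^-1, positive toward the water column).
#' @export
transport_tendency <- function(conc, species_phase, grid, params,
                               bottom_water_value,
                               molecular_diffusivity = 0,
                               irrigation_scaling = 1) {
  op <- make_transport_op(grid, params, species_phase,
                          d0 = molecular_diffusivity,
                          irrigation_scaling = irrigation_scaling)
  out <- apply_transport(op, conc, bottom_water_value)
  cap <- if (species_phase == "solute") grid$porosity_centres
         else 1 - grid$porosity_centres
  out$tendency <- out$tendency / cap
  out
}
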