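# Flux diagnostics and methods for steady-state objects.

#' Flux and rate diagnostics of a steady state
#'
#' Computes the benthic dissolved-iron efflux and its delta-56Fe, the
#' depth-integrated carbon oxidation rate, depth-integrated DFe
#' production and consumption, the burial fluxes of every iron phase
#' with their isotopic signatures, and the column mass balances for bulk
#' Fe and 56Fe. Effluxes toward the water column are positive; fluxes
#' are reported in umol m^-2 d^-1 (Cox in mmol m^-2 d^-1).
#'
#' @param fit an `fe_steady` object from [run_steady()].
#' @return a list of class `fe_diagnostics`.
#' @export
diagnostics <- function(fit) {
  model <- fit$model
  M <- fit$state
  grid <- fit$grid
  n <- grid$n
  dz <- grid$dz
  td <- model_tendency(model, M, with_rates = TRUE)
  F <- td$fluxes$F
  rates <- td$rates
  cfg <- fit$config

  col <- function(nm) match(nm, model$state_names)
  irr_exchange <- function(j)
    sum(model$ALPHA[, j] * (M[, j] - model$bc[j]) * dz)
  efflux <- function(nm) {
    j <- col(nm)
    flux_yr_to_day(-F[1, j] + irr_exchange(j))
  }
  burial <- function(nm) flux_yr_to_day(F[n + 1, col(nm)])

  j_dfe <- efflux("DFe")
  j_dfe56 <- efflux("DFe.56")
  # burial of iron phases at the bottom of the domain
  classes <- intersect(c("FeHR", "FeMR", "FePR", "FeU"), colnames(M))
  b_feooh <- sum(vapply(classes, burial, 1))
  b_feooh56 <- sum(vapply(paste0(classes, ".56"), burial, 1))
  b_fes <- burial("FeS"); b_fes56 <- burial("FeS.56")
  b_fes2 <- burial("FeS2"); b_fes256 <- burial("FeS2.56")
  b_sorb <- flux_yr_to_day(td$fluxes$F_ads[n + 1])
  b_sorb56 <- flux_yr_to_day(td$fluxes$F_ads56[n + 1])
  b_dfe_adv <- flux_yr_to_day(F[n + 1, col("DFe")])
  b_dfe_adv56 <- flux_yr_to_day(F[n + 1, col("DFe.56")])

  integ <- function(v) flux_yr_to_day(sum(v * dz))
  cox <- integ(rates$cox) / 1000                    # mmol m-2 d-1
  p_dfe <- integ(rates$p_dfe)
  c_dfe <- integ(rates$c_dfe)

  j_in <- cfg$fluxes$FeOOH + cfg$fluxes$FeS + cfg$fluxes$FeS2
  out_tot <- j_dfe + b_feooh + b_fes + b_fes2 + b_sorb + b_dfe_adv
  hf <- function(delta) {
    r <- cfg$kinetics$ref_ratio * (1 + delta / 1000)
    r / (1 + r)
  }
  j_in56 <- cfg$fluxes$FeOOH * hf(cfg$delta_in$FeOOH) +
    cfg$fluxes$FeS * hf(cfg$delta_in$FeS) +
    cfg$fluxes$FeS2 * hf(cfg$delta_in$FeS2)
  out56 <- j_dfe56 + b_feooh56 + b_fes56 + b_fes256 + b_sorb56 + b_dfe_adv56

  structure(list(
    J_DFe = j_dfe,
    delta_JDFe = delta56(j_dfe, j_dfe56, cfg$kinetics$ref_ratio),
    Cox = cox, P_DFe = p_dfe, C_DFe = c_dfe,
    B_FeOOH_T = b_feooh,
    delta_B_FeOOH = delta56(b_feooh, b_feooh56, cfg$kinetics$ref_ratio),
    B_FeS = b_fes,
    delta_B_FeS = delta56(b_fes, b_fes56, cfg$kinetics$ref_ratio),
    B_FeS2 = b_fes2,
    delta_B_FeS2 = delta56(b_fes2, b_fes256, cfg$kinetics$ref_ratio),
    B_sorbed = b_sorb + b_dfe_adv,
    pyrite_burial_fraction =
      if (b_fes2 + b_feooh > 0) b_fes2 / (b_fes2 + b_feooh) else NA_real_,
    fe_inputs = j_in, fe_outputs = out_tot,
    fe_balance = if (j_in > 0) (out_tot - j_in) / j_in else 0,
    fe56_balance = if (j_in56 > 0) (out56 - j_in56) / j_in56 else 0
  ), class = "fe_diagnostics")
}

#' @export
#' @method print fe_diagnostics
print.fe_diagnostics <- function(x, ...) {
  cat("Benthic flux diagnostics\n")
  cat(sprintf("  J_DFe        %10.3f umol m-2 d-1   (delta56 %7.2f permil)\n",
              x$J_DFe, x$delta_JDFe))
  cat(sprintf("  Cox          %10.3f mmol m-2 d-1\n", x$Cox))
  cat(sprintf("  P_DFe/C_DFe  %10.3f / %.3f umol m-2 d-1\n",
              x$P_DFe, x$C_DFe))
  cat(sprintf("  burial: FeOOH %8.2f  FeS %8.3f  FeS2 %8.2f  sorbed %8.3f\n",
              x$B_FeOOH_T, x$B_FeS, x$B_FeS2, x$B_sorbed))
  cat(sprintf("  pyrite burial fraction %.3f;  Fe balance %.3g, 56Fe %.3g\n",
              x$pyrite_burial_fraction, x$fe_balance, x$fe56_balance))
  invisible(x)
}

#' Benthic flux of a solute
#'
#' Diffusive flux across the sediment-water interface (porosity- and
#' tortuosity-corrected gradient, plus the advective exchange) plus the
#' depth-integrated bio-irrigation exchange. Positive values are
#' effluxes to the water column. For iron-bearing solutes the
#' delta-56Fe of the flux is reported as well.
#'
#' @param fit an `fe_steady`.
#' @param solute_id species name (default the dissolved ferrous iron).
#' @return list with `flux` (umol m^-2 d^-1) and `delta` (permil, `NA`
#'   for species without isotope tracking).
#' @export
benthic_flux <- function(fit, solute_id = "DFe") {
  tab <- fit$model$species
  if (!solute_id %in% tab$name)
    stop("unknown species: ", solute_id, call. = FALSE)
  if (tab$phase[tab$name == solute_id] != "solute")
    stop(solute_id, " is a solid; benthic fluxes are defined for solutes",
         call. = FALSE)
  model <- fit$model
  M <- fit$state
  n <- fit$grid$n
  fl <- state_fluxes(model, M)
  eff <- function(nm) {
    j <- match(nm, model$state_names)
    flux_yr_to_day(-fl$F[1, j] +
      sum(model$ALPHA[, j] * (M[, j] - model$bc[j]) * fit$grid$dz))
  }
  flux <- eff(solute_id)
  delta <- NA_real_
  iso <- paste0(solute_id, ".56")
  if (iso %in% model$state_names)
    delta <- delta56(flux, eff(iso), fit$config$kinetics$ref_ratio)
  list(flux = flux, delta = delta)
}

#' Depth-integrated rates
#'
#' @param fit an `fe_steady`.
#' @return list with `Cox` (mmol m^-2 d^-1), `P_DFe` and `C_DFe`
#'   (umol m^-2 d^-1).
#' @export
integrated_rates <- function(fit) {
  d <- fit$diagnostics
  list(Cox = d$Cox, P_DFe = d$P_DFe, C_DFe = d$C_DFe)
}

#' HCl-extractable iron composite
#'
#' The operational FeHCl pool: iron oxides (all classes), sorbed ferrous
#' iron and iron monosulfide, with its 56Fe-weighted delta-value. This
#' is the solid-phase quantity that wet-chemical extractions measure and
#' against which the model is calibrated.
#'
#' @param fit an `fe_steady`.
#' @param scale `"irmm"` or `"igneous"` reporting scale.
#' @return data.frame with depth, bulk concentration (umol cm^-3 solid)
#'   and delta-56Fe.
#' @export
fehcl_composite <- function(fit, scale = c("irmm", "igneous")) {
  scale <- match.arg(scale)
  M <- fit$state
  cfg <- fit$config
  phi <- fit$grid$porosity_centres
  classes <- intersect(c("FeHR", "FeMR", "FePR", "FeU"), colnames(M))
  bulk <- rowSums(M[, classes, drop = FALSE]) + M[, "FeS"]
  heavy <- rowSums(M[, paste0(classes, ".56"), drop = FALSE]) + M[, "FeS.56"]
  # sorbed ferrous iron, converted to the solid-phase volume basis
  dfe <- pmax(M[, "DFe"], 0)
  dfe56 <- pmin(pmax(M[, "DFe.56"], 0), dfe)
  kads <- cfg$kinetics$k_ads
  bulk <- bulk + kads * dfe
  heavy <- heavy + sorbed_isotope_pool(dfe, dfe56, kads,
                                       eps_to_alpha(cfg$eps$sorption))
  data.frame(depth_cm = fit$grid$cell_centres,
             FeHCl = bulk,
             delta56 = delta56(bulk, heavy, cfg$kinetics$ref_ratio,
                               scale = scale))
}

#' Profile table of a steady state
#'
#' @param fit an `fe_steady`.
#' @param scale delta reporting scale.
#' @return data.frame with depth, every species concentration and the
#'   delta-56Fe of every isotope-tracked pool.
#' @export
profile_table <- function(fit, scale = c("irmm", "igneous")) {
  scale <- match.arg(scale)
  M <- fit$state
  tab <- fit$model$species
  out <- data.frame(depth_cm = fit$grid$cell_centres)
  for (nm in tab$name) out[[nm]] <- M[, nm]
  for (nm in tab$name[tab$iso])
    out[[paste0("delta56_", nm)]] <-
      delta56(M[, nm], M[, paste0(nm, ".56")],
              fit$config$kinetics$ref_ratio, scale = scale)
  out
}

#' @export
#' @method print fe_steady
print.fe_steady <- function(x, ...) {
  cat("Steady-state iron diagenesis (", x$config$variant, " variant)\n",
      sep = "")
  cat("  grid: ", x$grid$n, " cells over ", x$grid$domain_depth,
      " cm; scaled residual ", format(x$residual, digits = 3), "\n",
      sep = "")
  print(x$diagnostics)
  invisible(x)
}

#' @export
#' @method summary fe_steady
summary.fe_steady <- function(object, ...) {
  d <- object$diagnostics
  structure(list(diagnostics = d, config = object$config,
                 residual = object$residual,
                 opd_cm = oxygen_penetration_depth(object)),
            class = "summary.fe_steady")
}

#' @export
#' @method print summary.fe_steady
print.summary.fe_steady <- function(x, ...) {
  print(x$diagnostics)
  cat(sprintf("  oxygen penetration depth %.2f cm; residual %.3g\n",
              x$opd_cm, x$residual))
  invisible(x)
}

# depth at which O2 falls below 1 umol L-1 (1e-3 mM)
oxygen_penetration_depth <- function(fit, threshold = 1e-3) {
  o2 <- fit$state[, "O2"]
  z <- fit$grid$cell_centres
  below <- which(o2 < threshold)
  if (!length(below)) return(fit$grid$domain_depth)
  z[below[1]]
}

#' @export
residuals.fe_steady <- function(object, ...) {
  model_tendency(object$model, object$state)$dM
}

#' @export
plot.fe_steady <- function(x, species = c("O2", "DFe", "HS", "FeHR", "FeS2"),
                           max_depth = 30, ...) {
  pt <- profile_table(x)
  sel <- pt$depth_cm <= max_depth
  species <- intersect(species, names(pt))
  old <- graphics::par(mfrow = c(1, length(species) + 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (nm in species) {
    graphics::plot(pt[[nm]][sel], pt$depth_cm[sel], type = "l",
                   ylim = rev(range(pt$depth_cm[sel])),
                   xlab = nm, ylab = "depth (cm)", ...)
  }
  graphics::plot(pt$delta56_DFe[sel], pt$depth_cm[sel], type = "l",
                 ylim = rev(range(pt$depth_cm[sel])),
                 xlab = "delta56Fe-DFe (permil)", ylab = "depth (cm)", ...)
  invisible(x)
}
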