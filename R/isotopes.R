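#' Iron isotope systematics
#'
#' The model carries, for every iron-bearing species, the bulk
#' concentration `C` and the heavy-isotope concentration `C56`, under the
#' two-isotope closure `C = 54Fe + 56Fe`. The isotope ratio of a pool is
#' `r = C56 / (C - C56)` and its delta-value is expressed against the
#' IRMM-014 reference ratio.
#'
#' @name iron-isotopes
NULL

#' Reference 56Fe/54Fe ratio of the IRMM-014 standard
#' @export
IRMM014_RATIO <- 15.697861

#' Default fractionation limit (umol cm^-3): reactions drawing on a pool
#' below this bulk concentration induce no isotope fractionation.
#' @export
C_LIM_DEFAULT <- 1e-9

#' delta-56Fe of an isotope pool
#'
#' `delta = (r / r_ref - 1) * 1000` with `r = C56/(C - C56)`.
#' Pools with zero (or fully heavy) bulk concentration return `NA`
#' rather than an infinity, so profile output stays total.
#'
#' @param bulk bulk Fe concentration(s).
#' @param heavy 56Fe concentration(s), same units.
#' @param ref_ratio reference 56Fe/54Fe ratio.
#' @param scale `"irmm"` (default) or `"igneous"`; the igneous-rock scale
#'   subtracts 0.09 permil (the IRMM-014 value on that scale).
#' @return delta-56Fe in permil.
#' @export
delta56 <- function(bulk, heavy, ref_ratio = IRMM014_RATIO,
                    scale = c("irmm", "igneous")) {
  scale <- match.arg(scale)
  light <- bulk - heavy
  d <- ifelse(bulk > 0 & heavy >= 0 & light > 0,
              (heavy / light / ref_ratio - 1) * 1000, NA_real_)
  if (scale == "igneous") d <- d - 0.09
  d
}

#' Heavy-isotope concentration from a delta-value
#'
#' Inverse of [delta56()]: returns the 56Fe concentration of a pool of
#' given bulk concentration and delta-56Fe.
#'
#' @inheritParams delta56
#' @param delta delta-56Fe (permil, IRMM scale).
#' @export
delta_to_heavy <- function(bulk, delta, ref_ratio = IRMM014_RATIO) {
  r <- ref_ratio * (1 + delta / 1000)
  bulk * r / (1 + r)
}

#' Convert an effective fractionation to a fractionation factor
#'
#' `alpha = 1 + eps/1000`.
#'
#' @param eps effective fractionation (permil).
#' @export
eps_to_alpha <- function(eps) 1 + eps / 1000

#' Isotope-specific reaction rate
#'
#' For a reaction consuming a source pool at bulk rate `R`, the paired
#' heavy-isotope rate is `56R = alpha r / (1 + alpha r) R`, where `r` is
#' the source pool's isotope ratio. Below the fractionation limit
#' `c_lim` the reaction proceeds without fractionation,
#' `56R = (C56/C) R`.
#'
#' @param bulk_rate bulk reaction rate(s) (consuming the source pool).
#' @param bulk,heavy source-pool concentrations.
#' @param alpha_eff effective fractionation factor of the reaction.
#' @param c_lim fractionation limit (same units as `bulk`).
#' @return the 56Fe-specific rate, bounded by `[0, bulk_rate]`.
#' @export
isotope_rate <- function(bulk_rate, bulk, heavy, alpha_eff,
                         c_lim = C_LIM_DEFAULT) {
  if (any(bulk_rate > 0 & bulk <= 0))
    stop("bulk rate drawn from an empty pool", call. = FALSE)
  f <- heavy_rate_fraction(bulk, heavy, alpha_eff, c_lim)
  bulk_rate * f
}

# fraction 56R/R for a source pool; vectorized, guards against empty and
# numerically over-full pools (mask arithmetic, no branching)
heavy_rate_fraction <- function(bulk, heavy, alpha_eff, c_lim = C_LIM_DEFAULT) {
  bulk <- pmax(bulk, 0)
  heavy <- pmin(pmax(heavy, 0), bulk)
  tiny <- 1e-300
  f0 <- heavy / pmax(bulk, tiny)               # no-fractionation fraction
  light <- bulk - heavy
  ok <- (bulk >= c_lim) & (light > 0)
  ar <- alpha_eff * heavy / pmax(light, tiny)
  ff <- ar / (1 + ar)
  okn <- as.numeric(ok)
  ff * okn + f0 * (1 - okn)
}

#' Adsorbed 56Fe in sorption equilibrium
#'
#' Instantaneous reversible sorption of ferrous iron,
#' `ads = k_ads * dissolved`, fractionates with factor `alpha_sorption`
#' so that the adsorbed pool's isotope ratio is `alpha * r`. The adsorbed
#' 56Fe concentration follows as
#' `k_ads * alpha (1 + r) / (1 + alpha r) * 56Fe_dissolved`,
#' which reduces to `k_ads * 56Fe_dissolved` for `alpha = 1`.
#'
#' @param bulk,heavy dissolved pool concentrations.
#' @param k_ads dimensionless adsorption constant.
#' @param alpha_sorption fractionation factor of sorption.
#' @return adsorbed 56Fe concentration (per unit solid volume when the
#'   dissolved pool is per unit pore-water volume).
#' @export
sorbed_isotope_pool <- function(bulk, heavy, k_ads, alpha_sorption = 1) {
  k_ads * sorption_k56_factor(bulk, heavy, alpha_sorption) * heavy
}

# multiplier on k_ads for the heavy isotope: alpha (1 + r) / (1 + alpha r)
sorption_k56_factor <- function(bulk, heavy, alpha_sorption) {
  light <- bulk - heavy
  ok <- as.numeric(light > 0 & heavy >= 0)
  r <- ok * heavy / pmax(light, 1e-300)
  f <- alpha_sorption * (1 + r) / (1 + alpha_sorption * r)
  f * ok + (1 - ok)
}
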