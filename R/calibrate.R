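# Calibration of effective isotope fractionation factors against
# measured delta-56Fe profiles (the second stage of the two-stage
# site-calibration procedure: bulk concentrations are fitted first
# through the boundary fluxes and rate constants in the configuration).

# model delta profiles interpolated at observation depths
model_deltas_at <- function(fit, pool, depths) {
  pt <- switch(pool,
    DFe = data.frame(z = fit$grid$cell_centres,
                     d = profile_table(fit)$delta56_DFe),
    FeHCl = {
      fc <- fehcl_composite(fit)
      data.frame(z = fc$depth_cm, d = fc$delta56)
    },
    FeS2 = data.frame(z = fit$grid$cell_centres,
                      d = profile_table(fit)$delta56_FeS2),
    stop("unknown pool: ", pool, call. = FALSE))
  ok <- is.finite(pt$d)
  stats::approx(pt$z[ok], pt$d[ok], xout = depths, rule = 2)$y
}

#' Calibrate an effective fractionation factor
#'
#' Finds the effective fractionation (permil) of one reaction that
#' minimizes the sum of squared residuals between modelled and observed
#' delta-56Fe depth profiles of up to three pools: dissolved iron
#' (`DFe`), HCl-extractable iron (`FeHCl`) and pyrite (`FeS2`). The
#' search is a deterministic coarse grid over the supplied bounds
#' followed by local grid refinement; every candidate requires a steady
#' state, which is warm-started from the previous one.
#'
#' @param observed named list of data.frames (names among `DFe`,
#'   `FeHCl`, `FeS2`), each with columns `depth_cm` and `delta56`.
#' @param config an [fe_config()] whose bulk solution already matches
#'   the site.
#' @param param which effective fractionation to fit (name in the
#'   config's `eps` list, e.g. `"reduction"`).
#' @param bounds numeric length-2 search interval (permil).
#' @param coarse number of coarse grid points.
#' @param refine number of refinement rounds (each shrinks the bracket
#'   around the incumbent by the grid spacing).
#' @return an object of class `fe_calibration`.
#' @export
calibrate_fractionation <- function(observed, config, param = "reduction",
                                    bounds = c(-4, 0), coarse = 7,
                                    refine = 2) {
  if (!length(observed))
    stop("empty observation set", call. = FALSE)
  if (!all(names(observed) %in% c("DFe", "FeHCl", "FeS2")))
    stop("observed pools must be among DFe, FeHCl, FeS2", call. = FALSE)
  if (!param %in% names(config$eps))
    stop("unknown eps parameter: ", param, call. = FALSE)

  warm <- NULL
  evals <- list()
  misfit <- function(eps_val) {
    key <- format(eps_val, digits = 12)
    if (!is.null(evals[[key]])) return(evals[[key]])
    cfg <- config
    cfg$eps[[param]] <- eps_val
    fit <- run_steady(cfg, init = warm)
    warm <<- fit$state
    ss <- 0
    for (pool in names(observed)) {
      ob <- observed[[pool]]
      pred <- model_deltas_at(fit, pool, ob$depth_cm)
      ss <- ss + sum((pred - ob$delta56)^2)
    }
    evals[[key]] <<- ss
    ss
  }

  lo <- min(bounds); hi <- max(bounds)
  grid <- seq(lo, hi, length.out = coarse)
  vals <- vapply(grid, misfit, 1)
  best <- grid[which.min(vals)]
  step <- diff(grid[1:2])
  for (r in seq_len(refine)) {
    g2 <- seq(max(lo, best - step), min(hi, best + step), length.out = coarse)
    v2 <- vapply(g2, misfit, 1)
    if (min(v2) <= min(vals)) {
      best <- g2[which.min(v2)]
      vals <- c(vals, v2)
    }
    step <- diff(g2[1:2])
  }

  cfg <- config
  cfg$eps[[param]] <- best
  fit <- run_steady(cfg, init = warm)
  resid <- lapply(names(observed), function(pool) {
    ob <- observed[[pool]]
    data.frame(pool = pool, depth_cm = ob$depth_cm,
               observed = ob$delta56,
               modelled = model_deltas_at(fit, pool, ob$depth_cm))
  })
  structure(list(param = param, estimate = best,
                 misfit = misfit(best),
                 bounds = c(lo, hi),
                 residuals = do.call(rbind, resid),
                 steady = fit),
            class = "fe_calibration")
}

#' @export
coef.fe_calibration <- function(object, ...) {
  stats::setNames(object$estimate, object$param)
}

#' @export
#' @method print fe_calibration
print.fe_calibration <- function(x, ...) {
  cat("Effective fractionation calibration\n")
  cat(sprintf("  eps_%s = %.3f permil (bounds %.2f .. %.2f), SSR = %.4g\n",
              x$param, x$estimate, x$bounds[1], x$bounds[2], x$misfit))
  invisible(x)
}
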