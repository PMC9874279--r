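# Shared steady-state runs, computed once per test session. Most tests
# only need a handful of configurations; caching them keeps the suite
# fast without weakening any assertion.

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, config_fn, init = NULL) {
  if (is.null(.run_cache[[key]]))
    .run_cache[[key]] <- suppressWarnings(run_steady(config_fn(), init = init))
  .run_cache[[key]]
}

# small idealized baseline used by many tests
baseline_config <- function(n_cells = 60, ...) {
  make_scenario("baseline", o2_uM = 120, n_cells = n_cells, ...)
}

baseline_run <- function() cached_run("baseline60", baseline_config)

scenario_run <- function(name, o2) {
  key <- paste0(name, "@", o2)
  cached_run(key, function()
    make_scenario(name, o2_uM = o2, n_cells = 60,
                  solver = list(max_wall_s = 60)))
}

site_run <- function(site) {
  cached_run(site, function() load_config(site))
}

# reduced sensitivity grids for the transfer-function re-derivation;
# warm-started along the oxygen axis, one shared sweep per kind
grid_axes <- list(o2 = c(2, 10, 25, 100, 200),
                  j_poc = c(16, 12, 8, 4, 2),
                  j_feooh = c(1110, 555))

reduced_grid <- function(kind = c("modern", "unbioturbated")) {
  kind <- match.arg(kind)
  key <- paste0("grid_", kind)
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  ax <- grid_axes
  jfs <- if (kind == "modern") ax$j_feooh else 1110
  rows <- list()
  prev <- NULL
  for (jf in jfs) for (jp in ax$j_poc) for (o2 in ax$o2) {
    cfg <- make_scenario(if (kind == "modern") "baseline" else "unbioturbated",
                         o2_uM = o2, j_poc_mmol_m2_d = jp,
                         j_feooh_umol_m2_d = jf, n_cells = 60,
                         solver = list(max_wall_s = 45))
    fit <- suppressWarnings(run_steady(cfg, init = prev))
    prev <- fit$state
    d <- fit$diagnostics
    rows[[length(rows) + 1]] <- data.frame(
      o2 = o2, j_poc = jp, j_feooh = jf, cox = d$Cox,
      J = d$J_DFe, delta = d$delta_JDFe,
      fe_balance = d$fe_balance, fe56_balance = d$fe56_balance,
      resid = fit$residual)
  }
  .run_cache[[key]] <- do.call(rbind, rows)
  .run_cache[[key]]
}

# random valid isotope pools for property-style checks
random_pools <- function(n, seed = 42) {
  set.seed(seed)
  bulk <- 10^stats::runif(n, -8, 2)
  delta <- stats::runif(n, -3, 3)
  data.frame(bulk = bulk, heavy = delta_to_heavy(bulk, delta), delta = delta)
}
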