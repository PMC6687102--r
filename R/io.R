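# Flat key=value run configuration, sweep orchestration and file output.

#' Default run configuration
#'
#' The default parameter set reproduces the reference interaction and
#' discretization protocol (b = 1, r = 2.325, c = 1, d = 1.2, N = 8;
#' D_C = D_D = 0.1, taxis off; L = 75, dx = 0.375, dt = 0.01; noisy
#' Gaussian initial condition).
#'
#' @return A nested list of class `"epgg_config"` with blocks `game`,
#'   `migration`, `grid`, `initial`, `run` and `thresholds`.
#' @export
default_config <- function() {
  structure(list(
    game = list(b = 1, r = 2.325, c = 1, d = 1.2, N = 8),
    migration = list(D_C = 0.1, D_D = 0.1, A_C = 0, A_D = 0,
                     R_C = 0, R_D = 0),
    grid = list(L = 75, dx = 0.375, dt = 0.01),
    initial = list(kind = "noisy_gaussian", amplitude = 0.2, width = 16,
                   noise_amp = 0.1, eps = 0, mode_m = 1),
    run = list(seed = 1, t_end = 100, cadence = 1,
               snapshot_times = c(0, 50, 100)),
    thresholds = list(extinct_mean = 1e-4, var_threshold = 1e-6,
                      expansion_rate = 5e-3, steepen_threshold = 0.2)
  ), class = "epgg_config")
}

config_num_keys <- function() {
  c("game.b", "game.r", "game.c", "game.d", "game.N",
    "migration.D_C", "migration.D_D", "migration.A_C", "migration.A_D",
    "migration.R_C", "migration.R_D",
    "grid.L", "grid.dx", "grid.dt",
    "initial.amplitude", "initial.width", "initial.noise_amp",
    "initial.eps", "initial.mode_m",
    "run.seed", "run.t_end", "run.cadence",
    "thresholds.extinct_mean", "thresholds.var_threshold",
    "thresholds.expansion_rate", "thresholds.steepen_threshold")
}

#' Read / write a flat key=value configuration
#'
#' The text format is one `block.key = value` pair per line (`#` starts a
#' comment); `run.snapshot_times` is a comma-separated list. Writing then
#' reading reproduces the configuration exactly (numbers are emitted with
#' 17 significant digits).
#'
#' @param path file path.
#' @param config an `"epgg_config"`.
#' @return `read_config` returns an `"epgg_config"`; `write_config`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  cfg <- default_config()
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) < 2) stop("malformed config line: ", ln)
    key <- trimws(parts[1])
    val <- trimws(paste(parts[-1], collapse = "="))
    cfg <- set_config(cfg, key, val)
  }
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  fmt <- function(x) {
    if (is.character(x)) x else paste(format(x, digits = 17), collapse = ",")
  }
  lines <- character(0)
  for (block in names(config)) {
    for (key in names(config[[block]])) {
      lines <- c(lines, sprintf("%s.%s = %s", block, key,
                                fmt(config[[block]][[key]])))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Override one configuration entry
#'
#' @param config an `"epgg_config"`.
#' @param key dotted key, e.g. `"game.r"` or `"migration.R_D"`.
#' @param value new value (strings are parsed for numeric keys).
#' @return The updated configuration.
#' @export
set_config <- function(config, key, value) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2 || is.null(config[[parts[1]]]))
    stop("unknown config key: ", key)
  if (key == "run.snapshot_times") {
    value <- as.numeric(strsplit(as.character(value), ",")[[1]])
  } else if (key %in% config_num_keys()) {
    value <- suppressWarnings(as.numeric(value))
    if (is.na(value)) stop("non-numeric value for key ", key)
  } else if (key != "initial.kind") {
    stop("unknown config key: ", key)
  }
  config[[parts[1]]][[parts[2]]] <- value
  config
}

# materialize parameter objects from a config
config_objects <- function(config) {
  g <- config$game
  m <- config$migration
  gr <- config$grid
  list(game = epgg_game(b = g$b, r = g$r, c = g$c, d = g$d, N = g$N),
       mig = epgg_migration(D_C = m$D_C, D_D = m$D_D, A_C = m$A_C,
                            A_D = m$A_D, R_C = m$R_C, R_D = m$R_D),
       grid = epgg_grid(L = gr$L, dx = gr$dx, dt = gr$dt))
}

#' Run a simulation from a configuration
#'
#' Resolves the configuration into parameter objects, builds the initial
#' state (seeded from `run.seed`) and calls [epgg_simulate()].
#'
#' @param config an `"epgg_config"`.
#' @return An `"epgg_sim"`.
#' @export
run_config <- function(config) {
  obj <- config_objects(config)
  init <- config$initial
  eq <- if (init$kind %in% c("homogeneous", "plane_wave"))
    interior_equilibrium(obj$game) else NULL
  init_args <- list(kind = init$kind, eq = eq, seed = config$run$seed,
                    amplitude = init$amplitude, width = init$width,
                    noise_amp = init$noise_amp, eps = init$eps,
                    mode_m = init$mode_m)
  epgg_simulate(obj$game, obj$mig, obj$grid, init = init_args,
                t_end = config$run$t_end,
                snapshot_times = config$run$snapshot_times,
                cadence = config$run$cadence,
                steepen_threshold = config$thresholds$steepen_threshold,
                quiet = TRUE)
}

#' Write a completed run to a directory
#'
#' Emits `diagnostics.csv`, one `snapshot_t<t>_{u,v}.csv` pair per stored
#' snapshot, and the resolved configuration as `config.txt` sidecar.
#'
#' @param sim an `"epgg_sim"`.
#' @param dir output directory (created if missing).
#' @param config optional `"epgg_config"` echoed alongside the run.
#' @return `dir`, invisibly.
#' @export
write_run <- function(sim, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sim$diagnostics,
                   file.path(dir, "diagnostics.csv"), row.names = FALSE)
  for (nm in names(sim$snapshots)) {
    st <- sim$snapshots[[nm]]
    utils::write.table(st$u, file.path(dir, sprintf("snapshot_t%s_u.csv", nm)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
    utils::write.table(st$v, file.path(dir, sprintf("snapshot_t%s_v.csv", nm)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(config)) write_config(config, file.path(dir, "config.txt"))
  invisible(dir)
}

#' Parameter sweep with analytic criteria and optional simulation
#'
#' Evaluates, on a 1- or 2-axis grid of configuration overrides, (a) the
#' interior equilibrium and its stability together with the Hopf point of
#' the interaction parameters, (b) the spatial criteria (well-posedness,
#' the necessary pattern-formation inequality, the unstable band and
#' dominant mode of the dispersion relation), and optionally (c) a
#' reduced-scale simulation classified by [classify_regime()]. One row
#' per grid point, long format; per-point failures are recorded in the
#' `error` column and never abort the sweep.
#'
#' @param config base `"epgg_config"` (defaults to [default_config()]).
#' @param axis1 list with `name` (dotted config key) and `values`.
#' @param axis2 optional second axis, same form.
#' @param simulate logical: run and classify a simulation per point
#'   (uses the grid and run settings of `config`; seed offset by the
#'   point index for independent noise realizations).
#' @return A data frame, one row per grid point.
#' @examples
#' \donttest{
#' sw <- epgg_sweep(axis1 = list(name = "game.r",
#'                               values = seq(2.3, 2.45, 0.05)))
#' sw[, c("game.r", "eq_stable", "band_exists")]
#' }
#' @export
epgg_sweep <- function(config = default_config(),
                       axis1, axis2 = NULL, simulate = FALSE) {
  stopifnot(is.list(axis1), !is.null(axis1$name))
  vals1 <- axis1$values
  vals2 <- if (is.null(axis2)) NA else axis2$values
  pts <- expand.grid(v1 = vals1, v2 = vals2)
  hopf_cache <- new.env()

  one_row <- function(i) {
    row <- list()
    row[[axis1$name]] <- pts$v1[i]
    if (!is.null(axis2)) row[[axis2$name]] <- pts$v2[i]
    cfg <- set_config(config, axis1$name, pts$v1[i])
    if (!is.null(axis2)) cfg <- set_config(cfg, axis2$name, pts$v2[i])
    err <- NA_character_
    out <- tryCatch({
      obj <- config_objects(cfg)
      key <- paste(cfg$game$b, cfg$game$c, cfg$game$d, cfg$game$N)
      if (is.null(hopf_cache[[key]]))
        hopf_cache[[key]] <- tryCatch(find_hopf(obj$game),
                                      error = function(e) NA_real_)
      r_hopf <- hopf_cache[[key]]
      eq <- interior_equilibrium(obj$game)
      if (is.null(eq)) {
        list(eq_exists = FALSE, u_eq = NA, v_eq = NA, w_eq = NA,
             eq_stable = NA, r_hopf = r_hopf, wellposed = NA, margin = NA,
             eq6 = NA, band_exists = NA, band_lo = NA, band_hi = NA,
             k_star = NA)
      } else {
        wp <- wellposedness_condition(eq, obj$mig)
        nc <- necessary_condition(eq, obj$mig)
        dc <- dispersion_relation(eq, obj$mig)
        has_band <- nrow(dc$band) > 0
        list(eq_exists = TRUE, u_eq = eq$u, v_eq = eq$v, w_eq = eq$w,
             eq_stable = eq$stable, r_hopf = r_hopf,
             wellposed = wp$ok, margin = wp$margin, eq6 = nc$holds,
             band_exists = has_band,
             band_lo = if (has_band) dc$band[1, 1] else NA,
             band_hi = if (has_band) dc$band[nrow(dc$band), 2] else NA,
             k_star = dc$k_star)
      }
    }, error = function(e) {
      err <<- conditionMessage(e)
      list(eq_exists = NA, u_eq = NA, v_eq = NA, w_eq = NA, eq_stable = NA,
           r_hopf = NA, wellposed = NA, margin = NA, eq6 = NA,
           band_exists = NA, band_lo = NA, band_hi = NA, k_star = NA)
    })
    row <- c(row, out)
    if (simulate) {
      sim_out <- tryCatch({
        cfg$run$seed <- cfg$run$seed + i
        sim <- run_config(cfg)
        lab <- classify_regime(
          sim, extinct_mean = cfg$thresholds$extinct_mean,
          var_threshold = cfg$thresholds$var_threshold,
          expansion_rate = cfg$thresholds$expansion_rate)
        eq <- interior_equilibrium(config_objects(cfg)$game)
        rr <- if (is.null(eq)) c(r_p = NA_real_, r_c = NA_real_)
              else population_ratios(sim, eq)
        list(regime = lab$label, r_p = unname(rr["r_p"]),
             r_c = unname(rr["r_c"]))
      }, error = function(e) {
        err <<- paste(stats::na.omit(c(err, conditionMessage(e))),
                      collapse = "; ")
        list(regime = NA_character_, r_p = NA_real_, r_c = NA_real_)
      })
      row <- c(row, sim_out)
    }
    row$error <- err
    as.data.frame(row, stringsAsFactors = FALSE)
  }

  if (nrow(pts) == 0) {
    cols <- c(axis1$name, if (!is.null(axis2)) axis2$name,
              "eq_exists", "u_eq", "v_eq", "w_eq", "eq_stable", "r_hopf",
              "wellposed", "margin", "eq6", "band_exists", "band_lo",
              "band_hi", "k_star",
              if (simulate) c("regime", "r_p", "r_c"), "error")
    out <- as.data.frame(matrix(nrow = 0, ncol = length(cols)))
    names(out) <- cols
    return(out)
  }
  do.call(rbind, lapply(seq_len(nrow(pts)), one_row))
}
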