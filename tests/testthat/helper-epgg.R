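# Shared fixtures and independent oracles.

ref_game <- function(r = 2.325) epgg_game(b = 1, r = r, c = 1, d = 1.2, N = 8)

# memoised equilibria (deterministic, reused across files)
.epgg_cache <- new.env(parent = emptyenv())

ref_eq <- function(r = 2.4) {
  key <- paste0("eq_", r)
  if (is.null(.epgg_cache[[key]]))
    .epgg_cache[[key]] <- interior_equilibrium(ref_game(r))
  .epgg_cache[[key]]
}

# Monte-Carlo group-sampling oracle for the mean payoffs: draw the N-1
# co-player slots from a multinomial over (cooperator, defector, empty);
# a group of S occupied members with n_C cooperators pays r*c*n_C/S to
# each member, cooperators pay c, and a lone cooperator abstains (0).
mc_mean_payoffs <- function(u, v, game, n = 1e5) {
  cnt <- stats::rmultinom(n, game$N - 1, c(u, v, 1 - u - v))
  n_C <- cnt[1, ]
  S <- 1 + cnt[1, ] + cnt[2, ]
  P_D <- game$r * game$c * n_C / S
  P_C <- ifelse(S == 1, 0, game$r * game$c * (n_C + 1) / S - game$c)
  list(f_C = mean(P_C), f_D = mean(P_D),
       se_C = stats::sd(P_C) / sqrt(n),
       se_D = stats::sd(P_D) / sqrt(n))
}

# Measure the exponential growth/decay rate of a single seeded diagonal
# mode against the full nonlinear integrator: initialize along the
# dominant eigenvector of J_I + k^2 J_S, project the u-field onto
# cos(k(x+y)) every 100 steps, and fit the log-amplitude slope.
measure_mode_rate <- function(game, eq, mig, grid, mode_m,
                              t_end, fit_from, eps = 1e-3) {
  k <- 2 * pi * mode_m / grid$L
  M <- eq$J + k^2 * jacobian_spatial(eq, mig)
  es <- eigen(M)
  i <- which.max(Re(es$values))
  vec <- Re(es$vectors[, i])
  vec <- vec / max(abs(vec))
  st <- initial_state("plane_wave", grid, eq = eq, eps = eps,
                      mode_m = mode_m, mode_vec = vec)
  X <- matrix(grid$coords, grid$n, grid$n, byrow = TRUE)
  basis <- cos(k * (X + t(X)))
  ts <- numeric(0); amps <- numeric(0)
  for (s in seq_len(round(t_end / grid$dt))) {
    st <- epgg_step(st, game, mig, grid)
    if (s %% 100 == 0) {
      ts <- c(ts, st$t)
      amps <- c(amps, abs(2 * mean((st$u - mean(st$u)) * basis)))
    }
  }
  keep <- ts >= fit_from
  fit <- stats::lm(log(amps[keep]) ~ ts[keep])
  list(rate = unname(stats::coef(fit)[2]), lambda = Re(es$values[i]))
}

# The reduced-scale smooth-pattern battery: homogeneous-at-Q starts with
# small noise at r = 2.4, D_C = 0.1, D_D = 0.5 and spreading defectors.
# Durations give each run at least seven e-folds of its dominant mode so
# the late-time state is quasi-steady. Built lazily and memoised (shared
# between the diagnostics tests and the acceptance suite).
battery_runs <- function() {
  if (!is.null(.epgg_cache$battery)) return(.epgg_cache$battery)
  game <- ref_game(2.4)
  eq <- ref_eq(2.4)
  grid <- epgg_grid(L = 24, dx = 0.375, dt = 0.01)
  specs <- list(
    list(R_D = 2, t_end = 800, eps = 0.02),
    list(R_D = 4, t_end = 400, eps = 0.01),
    list(R_D = 8, t_end = 400, eps = 0.01))
  runs <- lapply(specs, function(sp) {
    mig <- epgg_migration(D_C = 0.1, D_D = 0.5, R_D = sp$R_D)
    sim <- epgg_simulate(game, mig, grid,
                         init = list(kind = "homogeneous", eq = eq,
                                     eps = sp$eps, seed = 11),
                         t_end = sp$t_end, quiet = TRUE)
    list(R_D = sp$R_D, mig = mig, sim = sim, grid = grid)
  })
  .epgg_cache$battery <- list(game = game, eq = eq, grid = grid, runs = runs)
  .epgg_cache$battery
}
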