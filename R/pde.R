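# Finite-difference operators and the explicit integrator for the
# selection-diffusion-taxis system on the periodic square grid.
#
# Fields are n-by-n matrices indexed [y, x] at node coordinates
# x_i = i*dx. Both the 5-point Laplacian and the flux-form taxis
# divergence telescope over the periodic grid, so migration conserves
# total mass to machine precision; only the reaction term changes it.

# periodic shifts (by one cell)
shift_xp <- function(M) M[, c(2:ncol(M), 1)]
shift_xm <- function(M) M[, c(ncol(M), 1:(ncol(M) - 1))]
shift_yp <- function(M) M[c(2:nrow(M), 1), ]
shift_ym <- function(M) M[c(nrow(M), 1:(nrow(M) - 1)), ]

#' Periodic 5-point Laplacian
#'
#' Standard second-order stencil
#' `(f[x+dx] + f[x-dx] + f[y+dy] + f[y-dy] - 4 f)/dx^2` with periodic
#' wrap. The grid sum of the result is 0 to machine precision.
#'
#' @param f an n-by-n numeric matrix.
#' @param grid an [epgg_grid()] (only `dx` is used).
#' @return Matrix of the same shape.
#' @export
laplacian <- function(f, grid) {
  (shift_xp(f) + shift_xm(f) + shift_yp(f) + shift_ym(f) - 4 * f) / grid$dx^2
}

#' Conservative taxis divergence
#'
#' Flux-form discretization of the directed-migration term
#' \eqn{-K \nabla\cdot(\phi w \nabla\psi)}: the face flux between
#' neighbouring nodes is the arithmetic face mean of `phi*w` times the
#' face gradient of `psi`, and the divergence is the net face-flux sum
#' divided by `dx`. Fluxes telescope over the periodic grid, so the
#' returned field sums to zero (discrete conservation). An upwind variant
#' (donor-cell on the sign of the face gradient of `psi`) is available for
#' steep-gradient regimes.
#'
#' @param phi density of the migrating type (n-by-n matrix).
#' @param psi density whose gradient is followed (same shape).
#' @param w reproductive-opportunity field `1 - u - v` (same shape).
#' @param K taxis rate (non-negative scalar).
#' @param grid an [epgg_grid()].
#' @param scheme `"central"` (arithmetic face mean, second order) or
#'   `"upwind"` (donor cell).
#' @return Matrix of the same shape: the contribution
#'   \eqn{-K \nabla\cdot(\phi w \nabla\psi)} to the time derivative.
#' @export
taxis_divergence <- function(phi, psi, w, K, grid,
                             scheme = c("central", "upwind")) {
  scheme <- match.arg(scheme)
  if (!all(dim(phi) == dim(psi)) || !all(dim(phi) == dim(w)))
    stop("field shapes differ")
  if (K == 0) return(array(0, dim(phi)))
  dx <- grid$dx
  g <- phi * w
  # east/north face gradients of psi
  gx <- (shift_xp(psi) - psi) / dx
  gy <- (shift_yp(psi) - psi) / dx
  if (scheme == "central") {
    gface_x <- 0.5 * (g + shift_xp(g))
    gface_y <- 0.5 * (g + shift_yp(g))
  } else {
    # donor cell: carry phi*w from the side the flux leaves
    gface_x <- ifelse(gx > 0, shift_xp(g), g)
    gface_y <- ifelse(gy > 0, shift_yp(g), g)
  }
  Fx <- gface_x * gx            # flux through east faces
  Fy <- gface_y * gy            # flux through north faces
  div <- (Fx - shift_xm(Fx) + Fy - shift_ym(Fy)) / dx
  -K * div
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}

#' Initial density fields
#'
#' Constructs the spatial state used to start a simulation.
#'
#' Kinds:
#' \describe{
#'   \item{`gaussian`}{`u = v = amplitude * exp(-((x - L/2)^2 +
#'     (y - L/2)^2) / width^2)`, a centred drop of coexisting strategies
#'     (defaults `amplitude = 1/5`, `width = 16`).}
#'   \item{`noisy_gaussian`}{the same profile with independent
#'     multiplicative uniform noise `1 + noise_amp * U(-1, 1)` per node
#'     and per field, seeded.}
#'   \item{`homogeneous`}{constant fields at the interior equilibrium
#'     (`eq` required) plus, for `eps > 0`, seeded additive uniform noise
#'     of amplitude `eps`.}
#'   \item{`plane_wave`}{equilibrium plus a single diagonal mode
#'     `eps * mode_vec * cos(k (x + y))` with `k = 2*pi*mode_m/L`; used to
#'     probe the linear regime against the dispersion relation.}
#'   \item{`custom`}{user-supplied matrices `u`, `v`.}
#' }
#'
#' @param kind one of `"gaussian"`, `"noisy_gaussian"`, `"homogeneous"`,
#'   `"plane_wave"`, `"custom"`.
#' @param grid an [epgg_grid()].
#' @param eq an `"epgg_equilibrium"` (required for `homogeneous` and
#'   `plane_wave`).
#' @param seed integer seed for the noisy kinds; the global RNG state is
#'   left untouched.
#' @param amplitude,width Gaussian peak density and length scale.
#' @param noise_amp multiplicative noise amplitude for `noisy_gaussian`.
#' @param eps perturbation amplitude for `homogeneous` / `plane_wave`.
#' @param mode_m integer number of diagonal wavelengths across the domain
#'   (`plane_wave`).
#' @param mode_vec length-2 weight of the perturbation on (u, v)
#'   (`plane_wave`).
#' @param u,v custom field matrices (`custom`).
#' @return An object of class `"epgg_state"`: list with matrices `u`,
#'   `v` and the time `t = 0`.
#' @examples
#' gr <- epgg_grid(L = 24, dx = 0.375)
#' st <- initial_state("gaussian", gr)
#' max(st$u)  # 0.2 at the centre
#' @export
initial_state <- function(kind, grid, eq = NULL, seed = NULL,
                          amplitude = 0.2, width = 16, noise_amp = 0.1,
                          eps = 0, mode_m = 1, mode_vec = c(1, 1),
                          u = NULL, v = NULL) {
  kind <- match.arg(kind, c("gaussian", "noisy_gaussian", "homogeneous",
                            "plane_wave", "custom"))
  n <- grid$n
  xy <- grid$coords
  X <- matrix(xy, n, n, byrow = TRUE)   # [y, x]
  Y <- matrix(xy, n, n, byrow = FALSE)
  if (kind %in% c("gaussian", "noisy_gaussian")) {
    prof <- amplitude * exp(-((X - grid$L / 2)^2 + (Y - grid$L / 2)^2) /
                              width^2)
    if (kind == "gaussian") {
      u <- prof; v <- prof
    } else {
      fields <- with_seed(seed, {
        list(u = prof * (1 + noise_amp * stats::runif(n * n, -1, 1)),
             v = prof * (1 + noise_amp * stats::runif(n * n, -1, 1)))
      })
      u <- matrix(fields$u, n, n); v <- matrix(fields$v, n, n)
    }
  } else if (kind == "homogeneous") {
    if (is.null(eq)) stop("homogeneous initial state needs an equilibrium")
    u <- matrix(eq$u, n, n); v <- matrix(eq$v, n, n)
    if (eps > 0) {
      pert <- with_seed(seed, {
        list(u = eps * stats::runif(n * n, -1, 1),
             v = eps * stats::runif(n * n, -1, 1))
      })
      u <- u + matrix(pert$u, n, n)
      v <- v + matrix(pert$v, n, n)
    }
  } else if (kind == "plane_wave") {
    if (is.null(eq)) stop("plane_wave initial state needs an equilibrium")
    k <- 2 * pi * mode_m / grid$L
    wave <- cos(k * (X + Y))
    u <- eq$u + eps * mode_vec[1] * wave
    v <- eq$v + eps * mode_vec[2] * wave
  } else {
    if (is.null(u) || is.null(v)) stop("custom initial state needs u and v")
    u <- as.matrix(u); v <- as.matrix(v)
    if (!all(dim(u) == c(n, n)) || !all(dim(v) == c(n, n)))
      stop("custom fields must be n-by-n for this grid")
  }
  if (any(u < 0) || any(v < 0) || any(u + v > 1))
    stop("initial state leaves the simplex")
  structure(list(u = u, v = v, t = 0), class = "epgg_state")
}

#' @export
print.epgg_state <- function(x, ...) {
  cat(sprintf("Spatial state at t = %g: %dx%d grid, mean u = %.4g, mean v = %.4g\n",
              x$t, nrow(x$u), ncol(x$u), mean(x$u), mean(x$v)))
  invisible(x)
}

#' @export
plot.epgg_state <- function(x, which = c("u", "v", "w"), ...) {
  which <- match.arg(which)
  f <- switch(which, u = x$u, v = x$v, w = 1 - x$u - x$v)
  graphics::image(t(f), main = sprintf("%s at t = %g", which, x$t),
                  useRaster = TRUE, asp = 1, ...)
  invisible(x)
}

# one explicit stage: time derivative of (u, v) at the given fields
pde_rhs <- function(u, v, game, mig, grid, taxis_scheme = "central") {
  w <- 1 - u - v
  reac <- ode_rhs(u, v, game)
  du <- reac$du + mig$D_C * laplacian(u, grid)
  dv <- reac$dv + mig$D_D * laplacian(v, grid)
  if (mig$A_C > 0)
    du <- du + taxis_divergence(u, u, w, mig$A_C, grid, taxis_scheme)
  if (mig$R_C > 0)
    du <- du - taxis_divergence(u, v, w, mig$R_C, grid, taxis_scheme)
  if (mig$A_D > 0)
    dv <- dv + taxis_divergence(v, u, w, mig$A_D, grid, taxis_scheme)
  if (mig$R_D > 0)
    dv <- dv - taxis_divergence(v, v, w, mig$R_D, grid, taxis_scheme)
  list(du = du, dv = dv)
}

#' Advance the spatial state by one time step
#'
#' Explicit update combining the ecological reaction (pointwise well-mixed
#' dynamics), diffusion and the four directed-migration terms, followed by
#' projection back onto the simplex: negative densities are clipped to 0
#' and cells with `u + v > 1` are rescaled, with the absolute density
#' change logged as `clipped` (density times cell area).
#'
#' @param state an `"epgg_state"`.
#' @param game an [epgg_game()].
#' @param mig an [epgg_migration()].
#' @param grid an [epgg_grid()].
#' @param scheme `"euler"` (forward Euler, the reference discretization)
#'   or `"heun"` (two-stage, for refinement studies).
#' @param taxis_scheme face averaging for taxis fluxes, `"central"` or
#'   `"upwind"`.
#' @return The updated `"epgg_state"` with attribute `"clipped"` (mass
#'   removed or rescaled by the simplex projection this step).
#' @export
epgg_step <- function(state, game, mig, grid, scheme = c("euler", "heun"),
                      taxis_scheme = "central") {
  scheme <- match.arg(scheme)
  dt <- grid$dt
  u <- state$u; v <- state$v
  r1 <- pde_rhs(u, v, game, mig, grid, taxis_scheme)
  if (scheme == "euler") {
    un <- u + dt * r1$du
    vn <- v + dt * r1$dv
  } else {
    up <- pmin(pmax(u + dt * r1$du, 0), 1)
    vp <- pmin(pmax(v + dt * r1$dv, 0), 1)
    r2 <- pde_rhs(up, vp, game, mig, grid, taxis_scheme)
    un <- u + dt * 0.5 * (r1$du + r2$du)
    vn <- v + dt * 0.5 * (r1$dv + r2$dv)
  }
  if (any(!is.finite(un)) || any(!is.finite(vn))) {
    bad <- which(!is.finite(un) | !is.finite(vn), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "non-finite density at cell (row %d, col %d), t = %g; reduce dt",
      bad[1], bad[2], state$t + dt))
  }
  u2 <- pmax(un, 0)
  v2 <- pmax(vn, 0)
  s <- u2 + v2
  over <- s > 1
  if (any(over)) {
    u2[over] <- u2[over] / s[over]
    v2[over] <- v2[over] / s[over]
  }
  clipped <- sum(abs(u2 - un) + abs(v2 - vn)) * grid$dx^2
  structure(list(u = u2, v = v2, t = state$t + dt),
            class = "epgg_state", clipped = clipped)
}

# radius of the smallest circle centred on the domain centre holding
# `frac` of the total mass; distances capped by the grid geometry
front_radius <- function(u, v, grid, frac = 0.99) {
  n <- grid$n
  xy <- grid$coords
  X <- matrix(xy, n, n, byrow = TRUE)
  Y <- matrix(xy, n, n, byrow = FALSE)
  dist <- sqrt((X - grid$L / 2)^2 + (Y - grid$L / 2)^2)
  m <- u + v
  tot <- sum(m)
  if (tot <= 0) return(0)
  ord <- order(dist)
  csum <- cumsum(m[ord])
  dist[ord][match(TRUE, csum >= frac * tot)]
}

# max |grad u| * dx: dimensionless jump per cell, the steepening monitor
max_grad_jump <- function(u, grid) {
  gx <- (shift_xp(u) - shift_xm(u)) / (2 * grid$dx)
  gy <- (shift_yp(u) - shift_ym(u)) / (2 * grid$dx)
  max(sqrt(gx^2 + gy^2)) * grid$dx
}

#' Simulate the spatial ecological public goods game
#'
#' Time-marches the selection-diffusion-taxis system with [epgg_step()],
#' recording field snapshots at requested times and a diagnostics time
#' series (spatial means, variances, minimum of `w`, clipped mass,
#' steepening monitor, expansion front radius) at a fixed cadence.
#' Deterministic given the initial state (all randomness lives in
#' [initial_state()]).
#'
#' The run is flagged:
#' \itemize{
#'   \item `extinct_exit`: domain-mean `u + v` stayed below
#'     `extinction_mean` for `extinction_steps` consecutive steps
#'     (early exit);
#'   \item `steepening`: the jump monitor `max|grad u| dx` exceeded
#'     `steepen_threshold` at some diagnostic time (solutions may be
#'     discretization-dependent);
#'   \item `clip_flag`: cumulative clipped mass exceeded `clip_warn`
#'     of the mean domain mass.
#' }
#'
#' @param game,mig,grid parameter objects.
#' @param init an `"epgg_state"`, or a list of arguments for
#'   [initial_state()] (e.g. `list(kind = "gaussian")`).
#' @param t_end final time.
#' @param snapshot_times times at which to store full fields (the initial
#'   and final states are always stored).
#' @param cadence diagnostics recording interval (time units).
#' @param scheme,taxis_scheme passed to [epgg_step()].
#' @param extinction_mean,extinction_steps early-exit threshold.
#' @param steepen_threshold jump-per-cell threshold for the steepening
#'   flag.
#' @param clip_warn relative cumulative clipped-mass threshold.
#' @param quiet suppress the CFL warning check.
#' @return An object of class `"epgg_sim"`: list with `snapshots` (named
#'   by time), `diagnostics` (data frame), flags as above, `clip_total`,
#'   and the resolved `config`.
#' @examples
#' \donttest{
#' g <- epgg_game(r = 2.4); m <- epgg_migration(D_C = 0.1, D_D = 0.5, R_D = 2)
#' gr <- epgg_grid(L = 24, dx = 0.375, dt = 0.01)
#' eq <- interior_equilibrium(g)
#' sim <- epgg_simulate(g, m, gr,
#'                      init = list(kind = "homogeneous", eq = eq,
#'                                  eps = 0.01, seed = 1),
#'                      t_end = 50)
#' }
#' @export
epgg_simulate <- function(game, mig, grid, init, t_end,
                          snapshot_times = NULL, cadence = 1,
                          scheme = "euler", taxis_scheme = "central",
                          extinction_mean = 1e-5, extinction_steps = 100,
                          steepen_threshold = 0.2, clip_warn = 1e-3,
                          quiet = FALSE) {
  stopifnot(inherits(game, "epgg_game"), inherits(mig, "epgg_migration"),
            inherits(grid, "epgg_grid"), t_end > 0)
  if (!quiet) check_cfl(grid, mig)
  state <- if (inherits(init, "epgg_state")) init else
    do.call(initial_state, c(init, list(grid = grid)))
  init_meta <- if (inherits(init, "epgg_state")) list(kind = "custom") else init

  n_steps <- ceiling(t_end / grid$dt - 1e-9)
  snap_steps <- unique(sort(c(0, n_steps,
    round(snapshot_times / grid$dt))))
  snap_steps <- snap_steps[snap_steps >= 0 & snap_steps <= n_steps]
  cad_steps <- max(1L, round(cadence / grid$dt))

  snapshots <- list()
  diag_rows <- list()
  clip_total <- 0
  low_count <- 0L
  steepening <- FALSE
  extinct_exit <- FALSE

  record_diag <- function(st, clip) {
    mg <- max_grad_jump(st$u, grid)
    data.frame(t = st$t,
               mean_u = mean(st$u), mean_v = mean(st$v),
               var_u = stats::var(as.vector(st$u)),
               var_v = stats::var(as.vector(st$v)),
               var_uv = stats::var(as.vector(st$u + st$v)),
               min_w = min(1 - st$u - st$v),
               clipped_mass = clip,
               max_grad = mg,
               front_r = front_radius(st$u, st$v, grid))
  }

  if (0 %in% snap_steps) snapshots[[format(state$t)]] <- state
  diag_rows[[1]] <- record_diag(state, 0)

  for (s in seq_len(n_steps)) {
    state <- epgg_step(state, game, mig, grid, scheme, taxis_scheme)
    clip_total <- clip_total + attr(state, "clipped")
    mean_tot <- mean(state$u) + mean(state$v)
    low_count <- if (mean_tot < extinction_mean) low_count + 1L else 0L
    if (s %% cad_steps == 0 || s == n_steps) {
      row <- record_diag(state, clip_total)
      diag_rows[[length(diag_rows) + 1]] <- row
      if (row$max_grad > steepen_threshold) steepening <- TRUE
    }
    if (s %in% snap_steps) snapshots[[format(state$t)]] <- state
    if (low_count >= extinction_steps) {
      extinct_exit <- TRUE
      snapshots[[format(state$t)]] <- state
      break
    }
  }
  diagnostics <- do.call(rbind, diag_rows)
  domain_mass <- mean(diagnostics$mean_u + diagnostics$mean_v) * grid$L^2
  structure(list(
    snapshots = snapshots,
    diagnostics = diagnostics,
    steepening = steepening,
    extinct_exit = extinct_exit,
    clip_total = clip_total,
    clip_flag = domain_mass > 0 && clip_total > clip_warn * domain_mass,
    final = state,
    config = list(game = game, mig = mig, grid = grid, init = init_meta,
                  t_end = t_end, cadence = cadence, scheme = scheme,
                  taxis_scheme = taxis_scheme,
                  version = as.character(utils::packageVersion("epgg")))),
    class = "epgg_sim")
}

#' @export
print.epgg_sim <- function(x, ...) {
  d <- x$diagnostics
  last <- d[nrow(d), ]
  cat(sprintf("Spatial simulation to t = %g (%d snapshots)\n",
              last$t, length(x$snapshots)))
  cat(sprintf("  final: mean u = %.4g, mean v = %.4g, var(u+v) = %.3g\n",
              last$mean_u, last$mean_v, last$var_uv))
  flags <- c(if (x$extinct_exit) "extinct-exit",
             if (x$steepening) "steepening",
             if (x$clip_flag) "clipping")
  if (length(flags)) cat("  flags:", paste(flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.epgg_sim <- function(x, ...) {
  d <- x$diagnostics
  graphics::matplot(d$t, cbind(d$mean_u, d$mean_v), type = "l",
                    lty = 1, col = c(3, 2), xlab = "t",
                    ylab = "mean density", ...)
  graphics::legend("topright", c("cooperators", "defectors"),
                   col = c(3, 2), lty = 1, bty = "n")
  invisible(x)
}
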