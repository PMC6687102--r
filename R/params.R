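#' Public goods interaction parameters
#'
#' Bundles the constants of the ecological public goods game: groups of up
#' to `N` individuals play a public goods game in which each cooperator
#' invests `c` into a common pool that is multiplied by `r` and shared
#' equally among all group members. Payoffs act on the birth rate on top of
#' the baseline `b`; mortality is constant at rate `d`.
#'
#' The regime of primary ecological interest is the harsh environment
#' `d > b`, where the population only persists if the public good is
#' produced; `epgg_game()` flags (but does not enforce) this regime via the
#' `harsh` element.
#'
#' @param b baseline birth rate (per unit time), must be positive.
#' @param r multiplication factor of the common pool (dimensionless),
#'   must exceed 1. For `r < N` the game is a social dilemma.
#' @param c cost of cooperation, in payoff units, positive.
#' @param d death rate (per unit time), positive.
#' @param N maximal interaction group size, integer, at least 2.
#'
#' @return An object of class `"epgg_game"`: a list with elements
#'   `b`, `r`, `c`, `d`, `N` and the logical `harsh` (`d > b`).
#' @examples
#' g <- epgg_game(b = 1, r = 2.325, c = 1, d = 1.2, N = 8)
#' g$harsh  # TRUE: survival hinges on the public good
#' @export
epgg_game <- function(b = 1, r = 2.325, c = 1, d = 1.2, N = 8) {
  stopifnot(is.numeric(b), length(b) == 1L, is.finite(b), b > 0)
  stopifnot(is.numeric(r), length(r) == 1L, is.finite(r), r > 1)
  stopifnot(is.numeric(c), length(c) == 1L, is.finite(c), c > 0)
  stopifnot(is.numeric(d), length(d) == 1L, is.finite(d), d > 0)
  stopifnot(is.numeric(N), length(N) == 1L, is.finite(N),
            N >= 2, N == round(N))
  structure(list(b = b, r = r, c = c, d = d, N = as.integer(N),
                 harsh = d > b),
            class = "epgg_game")
}

#' @export
print.epgg_game <- function(x, ...) {
  cat("Ecological public goods game\n")
  cat(sprintf("  b = %g, r = %g, c = %g, d = %g, N = %d\n",
              x$b, x$r, x$c, x$d, x$N))
  cat(sprintf("  harsh environment (d > b): %s\n", x$harsh))
  invisible(x)
}

#' Migration parameters
#'
#' The six migration rates of the selection-diffusion-taxis system:
#' undirected diffusion `D_C`, `D_D` of cooperators and defectors, and the
#' four modes of directed migration. Taxis terms have the form
#' \eqn{-K \nabla\cdot(\phi w \nabla\psi)}: individuals of type \eqn{\phi}
#' climb the density gradient of type \eqn{\psi} at rate K, modulated by
#' local reproductive opportunities w.
#'
#' @param D_C,D_D diffusion rates of cooperators/defectors (length^2/time).
#' @param A_C cooperator aggregation rate (cooperators seek cooperators).
#' @param A_D defector hunting rate (defectors seek cooperators).
#' @param R_C cooperator flight rate (cooperators avoid defectors).
#' @param R_D defector spreading rate (defectors avoid defectors).
#'
#' @return An object of class `"epgg_migration"` (list of the six rates).
#' @examples
#' epgg_migration(D_C = 0.1, D_D = 0.1, R_D = 8)  # spreading defectors
#' @export
epgg_migration <- function(D_C = 0.1, D_D = 0.1,
                           A_C = 0, A_D = 0, R_C = 0, R_D = 0) {
  rates <- list(D_C = D_C, D_D = D_D, A_C = A_C, A_D = A_D,
                R_C = R_C, R_D = R_D)
  for (nm in names(rates)) {
    val <- rates[[nm]]
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) || val < 0)
      stop(sprintf("migration rate '%s' must be a single finite number >= 0",
                   nm))
  }
  structure(rates, class = "epgg_migration")
}

#' @export
print.epgg_migration <- function(x, ...) {
  cat("Migration rates\n")
  cat(sprintf("  diffusion: D_C = %g, D_D = %g\n", x$D_C, x$D_D))
  cat(sprintf("  taxis:     A_C = %g, A_D = %g, R_C = %g, R_D = %g\n",
              x$A_C, x$A_D, x$R_C, x$R_D))
  invisible(x)
}

#' Periodic square grid and time step
#'
#' Discretization of the periodic L-by-L domain: `n = round(L/dx)` grid
#' nodes per side at coordinates `x_i = i*dx` (i = 0, ..., n-1), with
#' periodic wrap in both axes, and explicit time step `dt`.
#'
#' @param L domain side length.
#' @param dx lattice spacing; `n*dx` must equal `L` to 1e-9 relative.
#' @param dt time step, positive.
#'
#' @return An object of class `"epgg_grid"`: list with `L`, `dx`, `dt`,
#'   `n`, and the coordinate vector `coords`.
#' @examples
#' epgg_grid(L = 24, dx = 0.375, dt = 0.01)
#' @export
epgg_grid <- function(L = 75, dx = 0.375, dt = 0.01) {
  stopifnot(is.numeric(L), L > 0, is.numeric(dx), dx > 0,
            is.numeric(dt), dt > 0)
  n <- round(L / dx)
  if (abs(n * dx - L) > 1e-9 * L)
    stop("L must be an integer multiple of dx (to 1e-9 relative)")
  if (n < 8) stop("grid too coarse: need at least 8 cells per side")
  structure(list(L = L, dx = dx, dt = dt, n = as.integer(n),
                 coords = (seq_len(n) - 1) * dx),
            class = "epgg_grid")
}

#' @export
print.epgg_grid <- function(x, ...) {
  cat(sprintf("Periodic grid: L = %g, dx = %g (n = %d), dt = %g\n",
              x$L, x$dx, x$n, x$dt))
  invisible(x)
}

#' Explicit-step stability guard
#'
#' Checks the forward-Euler time step against the diffusive CFL-type bound
#' `dt <= safety * dx^2 / (4*max(D_C, D_D) + taxis surcharge)`, where the
#' surcharge treats each taxis rate as an effective diffusivity at the
#' maximal density product `phi*w = 1/4`. A violation is a warning, not an
#' error: printed discretizations from reproduction protocols are honoured
#' as given.
#'
#' @param grid an [epgg_grid()].
#' @param mig an [epgg_migration()].
#' @param safety safety factor in (0, 1].
#' @return Invisibly, the maximal stable `dt` under the bound.
#' @export
check_cfl <- function(grid, mig, safety = 0.9) {
  stopifnot(inherits(grid, "epgg_grid"), inherits(mig, "epgg_migration"))
  taxis <- 0.25 * (mig$A_C + mig$A_D + mig$R_C + mig$R_D)
  dt_max <- safety * grid$dx^2 / (4 * (max(mig$D_C, mig$D_D) + taxis))
  if (grid$dt > dt_max)
    warning(sprintf(
      "dt = %g exceeds the explicit stability guard %g for these rates",
      grid$dt, dt_max))
  invisible(dt_max)
}
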