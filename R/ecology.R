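#' Well-mixed eco-evolutionary dynamics
#'
#' Right-hand side of the density dynamics: birth at rate `b + f` throttled
#' by reproductive opportunities `w = 1 - u - v`, death at constant rate
#' `d`:
#' \deqn{\partial_t u = u[w(b + f_C) - d], \quad
#'       \partial_t v = v[w(b + f_D) - d].}
#' Vectorized over `u`, `v` (used pointwise by the spatial integrator).
#'
#' @param u,v cooperator and defector densities.
#' @param game an [epgg_game()].
#' @return List with vectors `du` and `dv`.
#' @export
ode_rhs <- function(u, v, game) {
  f <- mean_payoffs(u, v, game)
  w <- pmax(1 - u - v, 0)
  list(du = u * (w * (game$b + f$f_C) - game$d),
       dv = v * (w * (game$b + f$f_D) - game$d))
}

#' Integrate the well-mixed dynamics
#'
#' Adaptive-step integration (lsoda) of the two-density system from a
#' given initial state.
#'
#' @param game an [epgg_game()].
#' @param u0,v0 initial densities inside the simplex.
#' @param times output times (increasing, starting at the initial time).
#' @return Data frame with columns `time`, `u`, `v`, `w`.
#' @examples
#' g <- epgg_game(r = 2.4)
#' tr <- wellmixed_trajectory(g, 0.07, 0.09, seq(0, 100, 1))
#' tail(tr, 1)
#' @export
wellmixed_trajectory <- function(game, u0, v0, times) {
  check_simplex(u0, v0)
  deriv <- function(t, y, parms) {
    y <- pmin(pmax(y, 0), 1)
    if (y[1] + y[2] > 1) y <- y / (y[1] + y[2])
    rhs <- ode_rhs(y[1], y[2], game)
    list(c(rhs$du, rhs$dv))
  }
  sol <- deSolve::ode(y = c(u = u0, v = v0), times = times, func = deriv,
                      parms = NULL, rtol = 1e-10, atol = 1e-12)
  out <- as.data.frame(sol)
  names(out) <- c("time", "u", "v")
  out$w <- 1 - out$u - out$v
  out
}

#' Interior coexistence equilibrium Q
#'
#' Locates the interior equilibrium of the well-mixed dynamics, at which
#' both growth conditions `w (b + f_C) = d` and `w (b + f_D) = d` hold
#' simultaneously (hence `f_C = f_D`). Because `f_C - f_D` depends on the
#' state only through `w`, the search reduces to a 1-D root problem:
#' find `w_eq` with `f_C = f_D`, then the cooperator fraction
#' `x = u/(u+v)` follows from the growth condition. An equilibrium is
#' interior only if the implied `x` lies in (0, 1).
#'
#' @param game an [epgg_game()].
#' @param tol residual tolerance for the root search.
#' @return An object of class `"epgg_equilibrium"` (elements `u`, `v`,
#'   `w`, `x`, `J` the 2x2 interaction Jacobian, `eigenvalues`, `stable`,
#'   `game`), or `NULL` when no interior equilibrium exists. A root search
#' that brackets a sign change but fails to converge raises an error
#' (distinct from the `NULL` "absent" return).
#' @examples
#' eq <- interior_equilibrium(epgg_game(r = 2.4))
#' eq$stable
#' @export
interior_equilibrium <- function(game, tol = 1e-10) {
  r <- game$r; N <- game$N; b <- game$b; cc <- game$c; d <- game$d
  G <- function(w) payoff_G(w, r, N)
  # scan (0,1) for sign changes of G; w = 1 is always a root (excluded)
  ws <- seq(1e-8, 1 - 1e-8, length.out = 4001)
  gs <- G(ws)
  flips <- which(gs[-1] * gs[-length(gs)] <= 0)
  candidates <- list()
  for (i in flips) {
    root <- tryCatch(
      stats::uniroot(G, c(ws[i], ws[i + 1]), tol = tol)$root,
      error = function(e) stop("equilibrium root search failed to converge: ",
                               conditionMessage(e)))
    # Newton polish to machine precision so the homogeneous state at Q is
    # a fixed point of the discrete step to ~1e-15
    for (it in 1:4) {
      gp <- payoff_G_deriv(root, r, N)
      if (abs(gp) < 1e-14) break
      root <- root - G(root) / gp
    }
    hx <- payoff_h(root, N)
    if (hx <= 0) next
    x <- (d / root - b) / (r * cc * hx)
    if (x > 0 && x < 1) {
      u <- x * (1 - root)
      v <- (1 - x) * (1 - root)
      candidates[[length(candidates) + 1]] <- c(u = u, v = v, w = root, x = x)
    }
  }
  if (!length(candidates)) return(NULL)
  # with several interior roots keep the densest population (largest u+v);
  # in the studied regime exactly one root occurs
  best <- candidates[[which.max(vapply(candidates,
                                       function(q) q["u"] + q["v"], 0))]]
  u <- unname(best["u"]); v <- unname(best["v"])
  rhs <- ode_rhs(u, v, game)
  if (max(abs(rhs$du), abs(rhs$dv)) > 1e3 * tol)
    stop("equilibrium residual exceeds tolerance")
  eq <- structure(list(u = u, v = v, w = unname(best["w"]),
                       x = unname(best["x"]), game = game),
                  class = "epgg_equilibrium")
  eq$J <- jacobian_interactions(eq, game)
  eig <- eigen(eq$J, only.values = TRUE)$values
  eq$eigenvalues <- eig
  eq$stable <- max(Re(eig)) < 0
  eq
}

#' @export
print.epgg_equilibrium <- function(x, ...) {
  cat("Interior coexistence equilibrium Q\n")
  cat(sprintf("  u_eq = %.6f, v_eq = %.6f, w_eq = %.6f\n", x$u, x$v, x$w))
  cat(sprintf("  eigenvalues: %s\n",
              paste(format(x$eigenvalues, digits = 4), collapse = ", ")))
  cat(sprintf("  linearly stable: %s\n", x$stable))
  invisible(x)
}

#' Interaction Jacobian at Q
#'
#' The 2x2 Jacobian of the well-mixed dynamics evaluated at the interior
#' equilibrium, with payoff partial derivatives computed analytically:
#' \deqn{a_{CC} = -u_{eq} d/w_{eq} + u_{eq} w_{eq} \partial_u f_C} and
#' analogously for the other entries.
#'
#' @param eq an `"epgg_equilibrium"` (from [interior_equilibrium()]).
#' @param game an [epgg_game()]; defaults to the one stored in `eq`.
#' @return A 2x2 numeric matrix with rows (cooperator, defector).
#' @export
jacobian_interactions <- function(eq, game = eq$game) {
  stopifnot(inherits(eq, "epgg_equilibrium"))
  u <- eq$u; v <- eq$v; w <- eq$w
  if (w <= 0) stop("interaction Jacobian undefined at w = 0")
  gr <- payoff_gradients(u, v, game)
  d <- game$d
  matrix(c(-u * d / w + u * w * gr$dfC_du, -u * d / w + u * w * gr$dfC_dv,
           -v * d / w + v * w * gr$dfD_du, -v * d / w + v * w * gr$dfD_dv),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("C", "D"), c("u", "v")))
}

#' Locate the Hopf bifurcation in r
#'
#' Bisects on the sign of the maximal real part of the eigenvalues of the
#' interaction Jacobian at Q as the multiplication factor `r` varies. At
#' the Hopf point the complex pair crosses the imaginary axis: below it the
#' well-mixed coexistence equilibrium is unstable (populations are doomed
#' without spatial structure), above it cooperators and defectors coexist.
#'
#' @param game an [epgg_game()]; its `r` is ignored.
#' @param r_lo,r_hi bracket for the bisection. Q must exist with eigenvalue
#'   real parts of opposite sign at the two ends.
#' @param tol bisection tolerance on `r`.
#' @return The critical value `r_Hopf` (numeric scalar).
#' @examples
#' find_hopf(epgg_game(b = 1, c = 1, d = 1.2, N = 8))  # about 2.365
#' @export
find_hopf <- function(game, r_lo = 2.2, r_hi = 2.5, tol = 1e-4) {
  maxre <- function(r) {
    g <- epgg_game(b = game$b, r = r, c = game$c, d = game$d, N = game$N)
    eq <- interior_equilibrium(g)
    if (is.null(eq)) NA_real_ else max(Re(eq$eigenvalues))
  }
  flo <- maxre(r_lo); fhi <- maxre(r_hi)
  if (is.na(flo) || is.na(fhi))
    stop("no interior equilibrium at a bracket endpoint")
  if (sign(flo) == sign(fhi))
    stop("eigenvalue real part does not change sign across [r_lo, r_hi]")
  while (r_hi - r_lo > tol) {
    mid <- (r_lo + r_hi) / 2
    fm <- maxre(mid)
    if (is.na(fm)) stop("interior equilibrium lost inside the bracket")
    if (sign(fm) == sign(flo)) {
      r_lo <- mid; flo <- fm
    } else {
      r_hi <- mid
    }
  }
  (r_lo + r_hi) / 2
}
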