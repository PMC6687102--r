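# Mean payoffs of the ecological public goods game.
#
# Groups hold N slots; besides the focal player each of the N-1 co-player
# slots is independently a cooperator (probability u), a defector (v) or
# empty (w = 1 - u - v). With S occupied members and n_C cooperators among
# them, every member receives r*c*n_C/S from the pool and cooperators pay
# c; a cooperator alone in its group does not play and gets 0.
# Averaging over the multinomial slot distribution yields closed forms in
# x = u/(u+v) and w. All removable singularities (w -> 1, u+v -> 0) are
# evaluated through the explicit geometric sum.

# geometric sum 1 + w + ... + w^(N-1) and its derivative; vectorized in w
geom_sum <- function(w, N) {
  s <- rep(1, length(w))
  p <- rep(1, length(w))
  for (k in seq_len(N - 1)) {
    p <- p * w
    s <- s + p
  }
  s
}

geom_sum_deriv <- function(w, N) {
  s <- rep(0, length(w))
  p <- rep(1, length(w))
  for (k in seq_len(N - 1)) {
    s <- s + k * p
    p <- p * w
  }
  s
}

# h(w) = 1 - (1 - w^N)/(N(1-w)); the defector payoff is r*c*x*h(w)
payoff_h <- function(w, N) 1 - geom_sum(w, N) / N

# G(w) = -(f_C - f_D)/c = 1 + (r-1) w^(N-1) - (r/N)(1-w^N)/(1-w)
payoff_G <- function(w, r, N) 1 + (r - 1) * w^(N - 1) - (r / N) * geom_sum(w, N)

payoff_G_deriv <- function(w, r, N) {
  (r - 1) * (N - 1) * w^(N - 2) - (r / N) * geom_sum_deriv(w, N)
}

check_simplex <- function(u, v, tol = 1e-12) {
  if (any(!is.finite(u)) || any(!is.finite(v)))
    stop("densities must be finite")
  if (any(u < -tol) || any(v < -tol) || any(u + v > 1 + tol))
    stop("state outside the simplex: need u >= 0, v >= 0, u + v <= 1")
}

#' Public goods payoffs for a fixed group composition
#'
#' Payoffs in a full group of `N` players facing `n_C` cooperators among
#' the `N - 1` co-players: defectors receive `n_C * r * c / N`, cooperators
#' the same minus the net cost `(1 - r/N) * c`.
#'
#' @param n_C number of cooperating co-players, integer in `[0, N - 1]`.
#' @param game an [epgg_game()].
#' @return List with numeric elements `P_C` and `P_D`.
#' @examples
#' g <- epgg_game(r = 2.325, N = 8)
#' classic_payoffs(4, g)
#' @export
classic_payoffs <- function(n_C, game) {
  stopifnot(inherits(game, "epgg_game"))
  if (any(n_C != round(n_C)) || any(n_C < 0) || any(n_C > game$N - 1))
    stop("n_C must be an integer in [0, N - 1]")
  P_D <- n_C * game$r * game$c / game$N
  P_C <- P_D - (1 - game$r / game$N) * game$c
  list(P_C = P_C, P_D = P_D)
}

#' Mean payoffs in randomly formed groups
#'
#' Average payoffs `f_C`, `f_D` of a cooperator and a defector when group
#' co-players are drawn independently from the population state: cooperator
#' with probability `u`, defector with `v`, empty slot with `w = 1 - u - v`.
#' Empty slots shrink the effective group, coupling payoffs to population
#' density. Vectorized over `u` and `v`.
#'
#' In the full-population limit `w = 0` the difference `f_C - f_D` reduces
#' to the classic `-c (1 - r/N)`. When `u + v = 0` there are no co-players;
#' both payoffs are evaluated in the limit with the cooperator fraction set
#' to 0 (no producers), giving `f_D = 0`.
#'
#' @param u,v cooperator and defector densities (same length).
#' @param game an [epgg_game()].
#' @return List with numeric vectors `f_C` and `f_D`.
#' @examples
#' g <- epgg_game(r = 2.325, N = 8)
#' mean_payoffs(0.3, 0.2, g)
#' @export
mean_payoffs <- function(u, v, game) {
  stopifnot(inherits(game, "epgg_game"))
  check_simplex(u, v)
  w <- pmax(1 - u - v, 0)
  tot <- u + v
  x <- ifelse(tot > 0, u / pmax(tot, .Machine$double.xmin), 0)
  f_D <- game$r * game$c * x * payoff_h(w, game$N)
  f_C <- f_D - game$c * payoff_G(w, game$r, game$N)
  list(f_C = f_C, f_D = f_D)
}

# Analytic partial derivatives of f_C, f_D with respect to u and v.
# f_D = r c x h(w), x = u/(u+v), w = 1-u-v; f_C = f_D - c G(w).
# Used by the interaction Jacobian; validated against finite differences.
payoff_gradients <- function(u, v, game) {
  check_simplex(u, v)
  tot <- u + v
  if (any(tot <= 0)) stop("payoff gradients need u + v > 0")
  w <- pmax(1 - u - v, 0)
  x <- u / tot
  r <- game$r; cc <- game$c; N <- game$N
  h  <- payoff_h(w, N)
  hp <- -geom_sum_deriv(w, N) / N     # h'(w)
  Gp <- payoff_G_deriv(w, r, N)
  dfD_du <- r * cc * ((v / tot^2) * h - x * hp)   # dw/du = -1
  dfD_dv <- r * cc * ((-u / tot^2) * h - x * hp)
  dfC_du <- dfD_du + cc * Gp
  dfC_dv <- dfD_dv + cc * Gp
  list(dfC_du = dfC_du, dfC_dv = dfC_dv,
       dfD_du = dfD_du, dfD_dv = dfD_dv)
}
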