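#' Spatial (migration) Jacobian at Q
#'
#' Linearizing the migration terms around the homogeneous equilibrium for
#' diagonal plane-wave perturbations of a common mode k gives the spatial
#' Jacobian
#' \deqn{J_S = 2 \begin{pmatrix}
#'   A_C u_{eq} w_{eq} - D_C & -R_C u_{eq} w_{eq} \\
#'   A_D v_{eq} w_{eq} & -R_D v_{eq} w_{eq} - D_D
#' \end{pmatrix},}
#' entering the perturbation dynamics as `J_I + k^2 J_S`.
#'
#' @param eq an `"epgg_equilibrium"`.
#' @param mig an [epgg_migration()].
#' @return A 2x2 numeric matrix.
#' @export
jacobian_spatial <- function(eq, mig) {
  stopifnot(inherits(eq, "epgg_equilibrium"),
            inherits(mig, "epgg_migration"))
  uw <- eq$u * eq$w
  vw <- eq$v * eq$w
  2 * matrix(c(mig$A_C * uw - mig$D_C, -mig$R_C * uw,
               mig$A_D * vw,           -mig$R_D * vw - mig$D_D),
             nrow = 2, byrow = TRUE,
             dimnames = list(c("C", "D"), c("u", "v")))
}

#' Short-wavelength well-posedness
#'
#' For the linearized dynamics to damp arbitrarily fine perturbations
#' (lambda(k) < 0 as k -> infinity) diffusion must dominate cooperator
#' aggregation at the homogeneous equilibrium: `D_C > A_C u_eq w_eq`
#' (equivalently det(J_S) > 0 in the relevant regime). When violated, the
#' continuum model loses meaning at small scales and solutions can steepen
#' into discontinuities.
#'
#' @param eq an `"epgg_equilibrium"`.
#' @param mig an [epgg_migration()].
#' @return List with `ok` (logical, strict inequality) and `margin`
#'   (`D_C - A_C u_eq w_eq`).
#' @export
wellposedness_condition <- function(eq, mig) {
  stopifnot(inherits(eq, "epgg_equilibrium"),
            inherits(mig, "epgg_migration"))
  margin <- mig$D_C - mig$A_C * eq$u * eq$w
  list(ok = margin > 0, margin = margin)
}

#' Dispersion relation lambda(k)
#'
#' Growth rate of a spatial perturbation of mode k under the linearized
#' dynamics: the largest real part of the eigenvalues of `J_I + k^2 J_S`.
#' Modes with `lambda(k) > 0` are unstable and can seed patterns; `k = 0`
#' recovers the purely temporal stability of Q.
#'
#' The default grid spans `[0, k_max]` with `k_max` chosen so that the
#' quadratic large-k decay dominates the k = 0 scale
#' (`k_max^2 |min Re eig J_S| >= 10 |lambda(0)|`), using a union of linear
#' and geometric spacings so both the unstable band and the asymptote are
#' resolved.
#'
#' @param eq an `"epgg_equilibrium"`.
#' @param mig an [epgg_migration()].
#' @param k optional vector of modes (non-negative, sorted); overrides the
#'   automatic grid.
#' @param n_k number of grid points for the automatic grid.
#' @param k_max upper end of the automatic grid (computed if `NULL`).
#' @return An object of class `"epgg_dispersion"`: list with `k`,
#'   `lambda`, `k_star` (dominant mode, `NA` if no instability),
#'   `band` (matrix of unstable k-intervals, 0 rows if none),
#'   `ill_posed` (logical), `J_I`, `J_S`, `eq`, `mig`.
#' @examples
#' eq <- interior_equilibrium(epgg_game(r = 2.4))
#' dc <- dispersion_relation(eq, epgg_migration(D_C = 0.1, D_D = 0.5, R_D = 2))
#' dc$band
#' @export
dispersion_relation <- function(eq, mig, k = NULL, n_k = 400, k_max = NULL) {
  J_I <- eq$J
  J_S <- jacobian_spatial(eq, mig)
  lam0 <- max(Re(eigen(J_I, only.values = TRUE)$values))
  auto_grid <- is.null(k)
  if (is.null(k)) {
    if (is.null(k_max)) {
      decay <- -max(Re(eigen(J_S, only.values = TRUE)$values))
      k_max <- if (decay > 0) sqrt(10 * max(abs(lam0), 1e-8) / decay) else 1
      k_max <- max(k_max, 1)
    }
    n_lin <- ceiling(n_k / 2)
    k <- sort(unique(c(0,
                       seq(0, k_max, length.out = n_lin),
                       k_max * 10^seq(-3, 0, length.out = n_k - n_lin))))
  } else {
    if (is.unsorted(k) || any(k < 0)) stop("k grid must be sorted and >= 0")
  }
  lam_at <- function(kk) {
    max(Re(eigen(J_I + kk^2 * J_S, only.values = TRUE)$values))
  }
  lambda <- vapply(k, lam_at, 0)
  # a well-posed curve must come back below zero: extend the automatic
  # grid until the upper edge is stable (near-marginal aggregation needs
  # a wide range)
  if (auto_grid &&
      max(Re(eigen(J_S, only.values = TRUE)$values)) < 0) {
    tries <- 0
    while (lambda[length(lambda)] > 0 && tries < 8) {
      k_ext <- seq(max(k), 4 * max(k), length.out = 50)[-1]
      k <- c(k, k_ext)
      lambda <- c(lambda, vapply(k_ext, lam_at, 0))
      tries <- tries + 1
    }
  }

  # large-k behaviour: ill-posed when J_S admits a positive eigenvalue
  ill <- max(Re(eigen(J_S, only.values = TRUE)$values)) > 0 &&
    any(abs(J_S) > 0)
  band <- unstable_band(k, lambda, J_I, J_S)
  obj <- structure(list(k = k, lambda = lambda, band = band,
                        ill_posed = ill, J_I = J_I, J_S = J_S,
                        eq = eq, mig = mig),
                   class = "epgg_dispersion")
  obj$k_star <- tryCatch(dominant_mode(obj), error = function(e) NA_real_)
  obj
}

# contiguous sign-change intervals of lambda > 0, edges refined by uniroot
# on the analytic eigenvalue function
unstable_band <- function(k, lambda, J_I, J_S) {
  lam <- function(kk) max(Re(eigen(J_I + kk^2 * J_S,
                                   only.values = TRUE)$values))
  pos <- lambda > 0
  if (!any(pos)) return(matrix(numeric(0), ncol = 2,
                               dimnames = list(NULL, c("lo", "hi"))))
  runs <- rle(pos)
  ends <- cumsum(runs$lengths)
  starts <- c(1, head(ends, -1) + 1)
  out <- NULL
  for (i in which(runs$values)) {
    i0 <- starts[i]; i1 <- ends[i]
    lo <- if (i0 == 1) k[1] else
      stats::uniroot(lam, c(k[i0 - 1], k[i0]), tol = 1e-10)$root
    hi <- if (i1 == length(k)) k[length(k)] else
      stats::uniroot(lam, c(k[i1], k[i1 + 1]), tol = 1e-10)$root
    out <- rbind(out, c(lo = lo, hi = hi))
  }
  out
}

#' @export
print.epgg_dispersion <- function(x, ...) {
  cat("Dispersion relation lambda(k)\n")
  cat(sprintf("  lambda(0) = %.5g, %d modes sampled up to k = %.4g\n",
              x$lambda[1], length(x$k), max(x$k)))
  if (x$ill_posed)
    cat("  ILL-POSED: J_S has a positive eigenvalue (lambda > 0 as k -> Inf)\n")
  if (nrow(x$band)) {
    for (i in seq_len(nrow(x$band)))
      cat(sprintf("  unstable band: k in (%.4g, %.4g)\n",
                  x$band[i, 1], x$band[i, 2]))
    cat(sprintf("  dominant mode k* = %.5g\n", x$k_star))
  } else {
    cat("  no unstable modes\n")
  }
  invisible(x)
}

#' @export
plot.epgg_dispersion <- function(x, ...) {
  graphics::plot(x$k, x$lambda, type = "l", xlab = "k",
                 ylab = expression(lambda(k)), ...)
  graphics::abline(h = 0, lty = 3)
  if (!is.na(x$k_star))
    graphics::abline(v = x$k_star, col = 2, lty = 2)
  invisible(x)
}

#' Necessary condition for pattern formation
#'
#' Evaluates the analytic threshold separating activation through
#' cooperator migration (left side) from inhibition through defector
#' migration (right side):
#' \deqn{-a_{DD}(A_C u_{eq} w_{eq} - D_C) - a_{DC} R_C u_{eq} w_{eq} >
#'       -a_{CD} A_D v_{eq} w_{eq} + a_{CC}(-R_D v_{eq} w_{eq} - D_D).}
#' With Q linearly stable, a spatial instability (unstable k > 0 band)
#' requires this inequality; it is necessary, not sufficient. The entries
#' `a_ij` are taken from the computed interaction Jacobian, with no sign
#' assumptions.
#'
#' @param eq an `"epgg_equilibrium"`.
#' @param mig an [epgg_migration()].
#' @return List with `holds` (logical), `lhs` (activation) and `rhs`
#'   (inhibition).
#' @export
necessary_condition <- function(eq, mig) {
  J <- eq$J
  uw <- eq$u * eq$w
  vw <- eq$v * eq$w
  lhs <- -J[2, 2] * (mig$A_C * uw - mig$D_C) - J[2, 1] * mig$R_C * uw
  rhs <- -J[1, 2] * mig$A_D * vw + J[1, 1] * (-mig$R_D * vw - mig$D_D)
  list(holds = lhs > rhs, lhs = lhs, rhs = rhs)
}

#' Dominant unstable mode k*
#'
#' The argmax of the dispersion relation over unstable modes, refined by
#' quadratic interpolation through the grid maximum and its neighbours.
#' The most unstable mode sets the characteristic length scale of emerging
#' patterns.
#'
#' @param curve an `"epgg_dispersion"` object.
#' @return The dominant mode (numeric scalar), or `NA` when no mode is
#'   unstable. An argmax at the upper grid edge raises an error asking for
#'   a larger k range.
#' @export
dominant_mode <- function(curve) {
  stopifnot(inherits(curve, "epgg_dispersion"))
  pos <- curve$lambda > 0
  if (!any(pos)) return(NA_real_)
  idx <- which(pos)
  i <- idx[which.max(curve$lambda[idx])]
  n <- length(curve$k)
  if (i == n)
    stop("dispersion maximum at the upper grid edge; enlarge k_max")
  if (i == 1) return(curve$k[1])  # maximum at k = 0 (temporal instability)
  # quadratic through (k[i-1], k[i], k[i+1])
  k3 <- curve$k[(i - 1):(i + 1)]
  l3 <- curve$lambda[(i - 1):(i + 1)]
  denom <- (k3[1] - k3[2]) * (k3[1] - k3[3]) * (k3[2] - k3[3])
  a <- (k3[3] * (l3[2] - l3[1]) + k3[2] * (l3[1] - l3[3]) +
          k3[1] * (l3[3] - l3[2])) / denom
  b <- (k3[3]^2 * (l3[1] - l3[2]) + k3[2]^2 * (l3[3] - l3[1]) +
          k3[1]^2 * (l3[2] - l3[3])) / denom
  if (a >= 0) return(curve$k[i])  # degenerate curvature; keep grid argmax
  ks <- -b / (2 * a)
  if (ks < k3[1] || ks > k3[3]) curve$k[i] else ks
}
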