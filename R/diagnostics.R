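#' Population and cooperation ratios
#'
#' Compares a spatial outcome with the well-mixed coexistence equilibrium:
#' \deqn{r_p = (\bar u + \bar v) / (u_{eq} + v_{eq}), \quad
#'       r_c = \frac{\bar u / (\bar u + \bar v)}{u_{eq}/(u_{eq}+v_{eq})}.}
#' `r_p > 1` means the structured population is denser than the
#' unstructured one; `r_c > 1` means cooperators are over-represented.
#'
#' For an `"epgg_sim"` the means are taken over the final 10% of the
#' diagnostics series, damping oscillatory regimes; for an `"epgg_state"`
#' they are plain domain means.
#'
#' @param x an `"epgg_state"` or `"epgg_sim"`.
#' @param eq an `"epgg_equilibrium"`.
#' @return Named numeric vector `c(r_p, r_c)`; `r_c` is `NA` when the
#'   population is extinct.
#' @export
population_ratios <- function(x, eq) {
  stopifnot(inherits(eq, "epgg_equilibrium"))
  if (inherits(x, "epgg_sim")) {
    d <- x$diagnostics
    keep <- d$t >= stats::quantile(d$t, 0.9)
    mu <- mean(d$mean_u[keep]); mv <- mean(d$mean_v[keep])
  } else if (inherits(x, "epgg_state")) {
    mu <- mean(x$u); mv <- mean(x$v)
  } else stop("x must be an epgg_state or epgg_sim")
  tot <- mu + mv
  r_p <- tot / (eq$u + eq$v)
  r_c <- if (tot > 0) (mu / tot) / (eq$u / (eq$u + eq$v)) else NA_real_
  c(r_p = r_p, r_c = r_c)
}

#' Classify the dynamical regime of a completed run
#'
#' Decision tree over the run diagnostics, mirroring the observed regimes
#' of directed migration: `extinct` (population died out), `homogeneous`
#' (uniform coexistence), `smooth_pattern` (heterogeneous but resolved),
#' `discontinuous` (steepening beyond the jump threshold — results are
#' discretization-dependent), and `localized_no_expansion` (a surviving
#' localized population whose front stopped expanding, the strong
#' cooperator-aggregation regime).
#'
#' Order of checks: extinction first (final mean density below
#' `extinct_mean`); then homogeneity (late-time spatial variance of
#' `u + v` below `var_threshold`); then arrested expansion (front radius
#' growth rate below `expansion_rate` while the front has not filled the
#' domain); then the steepening flag; otherwise `smooth_pattern`. All
#' thresholds are recorded in the returned evidence.
#'
#' @param sim an `"epgg_sim"`.
#' @param extinct_mean final mean-density threshold for extinction.
#' @param var_threshold late-time `var(u+v)` below which the run counts
#'   as homogeneous.
#' @param expansion_rate front-radius growth rate (length/time, least
#'   squares over the last half of the run) below which expansion counts
#'   as arrested.
#' @param fill_fraction front radius relative to `L` above which the
#'   domain counts as filled (expansion no longer measurable).
#' @return An object of class `"epgg_regime"`: list with `label` and the
#'   `evidence` used.
#' @export
classify_regime <- function(sim, extinct_mean = 1e-4,
                            var_threshold = 1e-6,
                            expansion_rate = 5e-3,
                            fill_fraction = 0.4) {
  stopifnot(inherits(sim, "epgg_sim"))
  d <- sim$diagnostics
  if (nrow(d) < 3) stop("run too short to classify")
  last <- d[nrow(d), ]
  late <- d[d$t >= stats::quantile(d$t, 0.9), , drop = FALSE]
  late_var <- mean(late$var_uv)
  half <- d[d$t >= stats::quantile(d$t, 0.5), , drop = FALSE]
  growth <- if (nrow(half) >= 2 && stats::sd(half$t) > 0)
    unname(stats::coef(stats::lm(front_r ~ t, data = half))[2]) else 0
  final_mean <- last$mean_u + last$mean_v

  evidence <- list(final_mean = final_mean, late_var = late_var,
                   front_growth = growth, front_r = last$front_r,
                   steepening = sim$steepening,
                   extinct_exit = sim$extinct_exit,
                   thresholds = list(extinct_mean = extinct_mean,
                                     var_threshold = var_threshold,
                                     expansion_rate = expansion_rate,
                                     fill_fraction = fill_fraction))
  label <-
    if (sim$extinct_exit || final_mean < extinct_mean) "extinct"
    else if (late_var < var_threshold) "homogeneous"
    else if (growth < expansion_rate &&
             last$front_r < fill_fraction * sim$config$grid$L)
      "localized_no_expansion"
    else if (sim$steepening) "discontinuous"
    else "smooth_pattern"
  structure(list(label = label, evidence = evidence),
            class = "epgg_regime")
}

#' @export
print.epgg_regime <- function(x, ...) {
  e <- x$evidence
  cat(sprintf("Regime: %s\n", x$label))
  cat(sprintf("  final mean = %.4g, late var(u+v) = %.3g, front growth = %.3g\n",
              e$final_mean, e$late_var, e$front_growth))
  invisible(x)
}

#' Dominant pattern wavelength
#'
#' Measures the characteristic length scale of a spatial pattern from the
#' radially averaged 2-D power spectrum of `u - mean(u)`. The dominant
#' radial frequency `q*` is reported together with its wavelength
#' `2*pi/q*` and both candidate comparisons to the dispersion-relation
#' mode `k*`: the diagonal perturbation ansatz leaves open whether
#' patterns should match `k*` or the physical wavevector magnitude
#' `k* * sqrt(2)`, so both are returned.
#'
#' A peak counts as dominant only if it exceeds `peak_factor` times the
#' median radial power (otherwise the spectrum is considered flat and the
#' result absent).
#'
#' @param state an `"epgg_state"`.
#' @param grid an [epgg_grid()].
#' @param peak_factor flatness criterion for peak detection.
#' @return List with `q_star`, `wavelength`, `k_equiv` (`q*`) and
#'   `k_diag_equiv` (`q*/sqrt(2)`), or `NULL` when no dominant peak
#'   exists (flat or extinct field).
#' @export
pattern_wavelength <- function(state, grid, peak_factor = 5) {
  stopifnot(inherits(state, "epgg_state"), inherits(grid, "epgg_grid"))
  f <- state$u - mean(state$u)
  if (max(abs(f)) < 1e-12) return(NULL)
  n <- grid$n
  P <- Mod(stats::fft(f))^2
  # radial frequency magnitude per FFT bin: q = 2*pi*m/L, m folded
  m <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  if (n %% 2 == 0) m <- c(0:(n / 2 - 1), -(n / 2):-1)
  Qx <- matrix(2 * pi * m / grid$L, n, n, byrow = TRUE)
  Qy <- matrix(2 * pi * m / grid$L, n, n, byrow = FALSE)
  qmag <- sqrt(Qx^2 + Qy^2)
  # annular bins of width one fundamental frequency
  dq <- 2 * pi / grid$L
  bin <- round(qmag / dq)
  keep <- bin > 0 & bin <= n %/% 2
  power <- tapply(P[keep], bin[keep], mean)
  qs <- as.numeric(names(power)) * dq
  if (max(power) < peak_factor * stats::median(power)) return(NULL)
  q_star <- qs[which.max(power)]
  list(q_star = q_star, wavelength = 2 * pi / q_star,
       k_equiv = q_star, k_diag_equiv = q_star / sqrt(2))
}
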