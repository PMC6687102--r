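test_that("spatial Jacobian entries follow the migration linearization", {
  eq <- ref_eq(2.4)
  # no migration, no spatial coupling
  expect_equal(unname(jacobian_spatial(eq, epgg_migration(D_C = 0, D_D = 0))),
               matrix(0, 2, 2))
  # diffusion only: diagonal, factor 2
  J <- jacobian_spatial(eq, epgg_migration(D_C = 0.1, D_D = 0.5))
  expect_equal(unname(J), 2 * diag(c(-0.1, -0.5)))
  # marginal aggregation boundary: s_CC vanishes exactly
  A_C <- 0.1 / (eq$u * eq$w)
  Jm <- jacobian_spatial(eq, epgg_migration(D_C = 0.1, D_D = 0.1, A_C = A_C))
  expect_equal(Jm[1, 1], 0)
})

test_that("well-posedness criterion is diffusion versus aggregation", {
  eq <- ref_eq(2.4)
  expect_true(wellposedness_condition(eq, epgg_migration(D_C = 0.05))$ok)
  # exact boundary is excluded (strict inequality)
  A_C <- 0.1 / (eq$u * eq$w)
  wp <- wellposedness_condition(eq, epgg_migration(D_C = 0.1, A_C = A_C))
  expect_false(wp$ok)
  expect_equal(wp$margin, 0)
  # strong-aggregation reference setting (A_C = 1, D_C = 0.1) at the
  # low-r equilibrium: margin is reported as computed
  eq_low <- ref_eq(2.325)
  wp2 <- wellposedness_condition(eq_low, epgg_migration(D_C = 0.1, A_C = 1))
  expect_equal(wp2$margin, 0.1 - eq_low$u * eq_low$w)
  expect_true(wp2$ok)
})

test_that("dispersion relation limits: temporal mode, flat curve, quadratic decay", {
  eq <- ref_eq(2.4)
  m0 <- epgg_migration(D_C = 0, D_D = 0)
  dc0 <- dispersion_relation(eq, m0, k = seq(0, 2, 0.1))
  expect_equal(dc0$lambda[1], max(Re(eigen(eq$J)$values)), tolerance = 1e-12)
  expect_true(all(abs(dc0$lambda - dc0$lambda[1]) < 1e-12))  # J_S = 0

  m <- epgg_migration(D_C = 0.1, D_D = 0.5, R_D = 2)
  kbig <- 50
  dc <- dispersion_relation(eq, m, k = c(0, kbig))
  JS <- jacobian_spatial(eq, m)
  expect_equal(dc$lambda[2] / kbig^2, max(Re(eigen(JS)$values)),
               tolerance = 1e-3)
})

test_that("unstable band matches a dense brute-force eigenvalue scan", {
  eq <- ref_eq(2.4)
  for (mig in list(epgg_migration(D_C = 0.1, D_D = 0.5),
                   epgg_migration(D_C = 0.1, D_D = 0.5, R_D = 2))) {
    dc <- dispersion_relation(eq, mig)
    JI <- eq$J; JS <- jacobian_spatial(eq, mig)
    kd <- seq(0, 2, length.out = 1e4)
    lam <- vapply(kd, function(k)
      max(Re(eigen(JI + k^2 * JS, only.values = TRUE)$values)), 0)
    if (nrow(dc$band) == 0) {
      expect_true(all(lam <= 0))
    } else {
      pos <- kd[lam > 0]
      expect_equal(unname(dc$band[1, "lo"]), min(pos), tolerance = 1e-3)
      expect_equal(unname(dc$band[nrow(dc$band), "hi"]), max(pos),
                   tolerance = 1e-3)
    }
  }
})

test_that("pure diffusion needs faster defectors for a Turing band", {
  eq <- ref_eq(2.4)
  for (DD in c(0.02, 0.05, 0.1)) {  # D_D <= D_C: no instability
    dc <- dispersion_relation(eq, epgg_migration(D_C = 0.1, D_D = DD))
    expect_equal(nrow(dc$band), 0)
  }
  dc2 <- dispersion_relation(eq, epgg_migration(D_C = 0.1, D_D = 2))
  expect_gt(nrow(dc2$band), 0)
})

test_that("necessary condition: trivial zero case and monotone response to each mode", {
  eq <- ref_eq(2.4)
  nc0 <- necessary_condition(eq, epgg_migration(D_C = 0, D_D = 0))
  expect_false(nc0$holds)
  expect_equal(nc0$lhs, 0); expect_equal(nc0$rhs, 0)

  base <- list(D_C = 0.1, D_D = 0.5, A_C = 0.3, A_D = 0.5, R_C = 0.5,
               R_D = 1)
  margin <- function(args) {
    nc <- necessary_condition(eq, do.call(epgg_migration, args))
    nc$lhs - nc$rhs
  }
  grid_vals <- seq(0, 3, 0.5)
  for (promoter in c("A_C", "R_D")) {
    vals <- sapply(grid_vals, function(v) {
      a <- base; a[[promoter]] <- v; margin(a)
    })
    expect_true(all(diff(vals) > 0))
  }
  for (inhibitor in c("A_D", "R_C")) {
    vals <- sapply(grid_vals, function(v) {
      a <- base; a[[inhibitor]] <- v; margin(a)
    })
    expect_true(all(diff(vals) < 0))
  }
})

test_that("dominant mode: absence, golden-section agreement, edge error", {
  eq <- ref_eq(2.4)
  dc_stable <- dispersion_relation(eq, epgg_migration(D_C = 0.1, D_D = 0.5))
  expect_true(is.na(dc_stable$k_star))

  mig <- epgg_migration(D_C = 0.1, D_D = 0.5, R_D = 2)
  dc <- dispersion_relation(eq, mig)
  JI <- eq$J; JS <- jacobian_spatial(eq, mig)
  opt <- stats::optimize(function(k)
    max(Re(eigen(JI + k^2 * JS, only.values = TRUE)$values)),
    interval = dc$band[1, ], maximum = TRUE, tol = 1e-9)
  expect_equal(dc$k_star, opt$maximum, tolerance = 1e-3)

  # truncated grid puts the argmax on the upper edge
  dc_cut <- dispersion_relation(eq, mig, k = seq(0, 0.5, length.out = 50))
  expect_error(dominant_mode(dc_cut), "edge")
})

test_that("lambda depends on k only through k^2 and varies continuously", {
  eq <- ref_eq(2.4)
  mig <- epgg_migration(D_C = 0.1, D_D = 0.5, R_D = 3)
  ks <- seq(0, 1.5, length.out = 301)
  dc <- dispersion_relation(eq, mig, k = ks)
  JI <- eq$J; JS <- jacobian_spatial(eq, mig)
  lam_k2 <- vapply(ks^2, function(k2)
    max(Re(eigen(JI + k2 * JS, only.values = TRUE)$values)), 0)
  expect_equal(dc$lambda, lam_k2, tolerance = 1e-12)
  expect_lt(max(abs(diff(dc$lambda))), 0.05)  # no jumps on a fine grid
})

test_that("ill-posed aggregation is flagged and the curve grows at large k", {
  eq <- ref_eq(2.4)
  A_C <- 2 * 0.1 / (eq$u * eq$w)  # aggregation twice the diffusion margin
  mig <- epgg_migration(D_C = 0.1, D_D = 0.1, A_C = A_C)
  dc <- dispersion_relation(eq, mig, k = seq(0, 20, 0.5))
  expect_true(dc$ill_posed)
  expect_gt(tail(dc$lambda, 1), 0)
})
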