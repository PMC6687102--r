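test_that("Gaussian initial condition reproduces the reference profile", {
  grid <- epgg_grid(L = 96, dx = 0.375, dt = 0.01)
  st <- initial_state("gaussian", grid)
  ic <- grid$n / 2 + 1           # node at x = L/2
  expect_identical(grid$coords[ic], grid$L / 2)
  expect_equal(st$u[ic, ic], 0.2)            # 1/5 amplitude at the centre
  expect_identical(st$u, st$v)
  expect_lt(st$u[1, 1], 1e-6)                # far tail (corner)
  # printed formula at an off-centre node
  x <- grid$coords[10]; y <- grid$coords[40]
  expect_equal(st$u[40, 10],
               0.2 * exp(-((x - 48)^2 + (y - 48)^2) / 16^2))
})

test_that("seeded initial conditions are reproducible and leave the RNG alone", {
  grid <- epgg_grid(L = 24, dx = 0.375, dt = 0.01)
  a <- initial_state("noisy_gaussian", grid, seed = 5)
  b <- initial_state("noisy_gaussian", grid, seed = 5)
  expect_identical(a$u, b$u)
  expect_identical(a$v, b$v)
  expect_false(identical(a$u, initial_state("noisy_gaussian", grid,
                                            seed = 6)$u))
  set.seed(123); x1 <- runif(1)
  set.seed(123); invisible(initial_state("noisy_gaussian", grid, seed = 5))
  expect_identical(runif(1), x1)
  expect_error(initial_state("vortex", grid))
})

test_that("periodic Laplacian: constant kernel, plane-wave eigenfunction, conservation", {
  grid <- epgg_grid(L = 12, dx = 0.375, dt = 0.01)
  n <- grid$n
  expect_equal(laplacian(matrix(1.7, n, n), grid), matrix(0, n, n))
  # cos(2 pi m x / L) is an eigenfunction of the discrete stencil
  m <- 3
  f <- matrix(cos(2 * pi * m * grid$coords / grid$L), n, n, byrow = TRUE)
  eigval <- -(2 / grid$dx^2) * (1 - cos(2 * pi * m * grid$dx / grid$L))
  expect_equal(laplacian(f, grid), eigval * f, tolerance = 1e-11)
  set.seed(2)
  rf <- matrix(runif(n * n), n, n)
  expect_lt(abs(sum(laplacian(rf, grid))), 1e-12 * sum(abs(rf)) / grid$dx^2)
})

test_that("Laplacian converges at second order to the analytic operator", {
  err <- sapply(c(32, 64), function(n) {
    grid <- epgg_grid(L = 10, dx = 10 / n, dt = 0.01)
    x <- grid$coords
    f <- outer(sin(2 * pi * x / 10), cos(4 * pi * x / 10 + 1), `+`)
    exact <- outer(-(2 * pi / 10)^2 * sin(2 * pi * x / 10),
                   -(4 * pi / 10)^2 * cos(4 * pi * x / 10 + 1), `+`)
    max(abs(laplacian(f, grid) - exact))
  })
  expect_gt(log2(err[1] / err[2]), 1.9)
})

test_that("taxis divergence: null cases, discrete conservation, manufactured solution", {
  grid <- epgg_grid(L = 10, dx = 0.125, dt = 0.01)
  n <- grid$n
  set.seed(3)
  phi <- matrix(runif(n * n, 0.1, 0.4), n, n)
  w <- matrix(runif(n * n, 0.2, 0.6), n, n)
  expect_equal(taxis_divergence(phi, matrix(0.3, n, n), w, 2, grid),
               matrix(0, n, n))                      # constant psi
  psi <- matrix(runif(n * n), n, n)
  expect_equal(taxis_divergence(phi, psi, w, 0, grid), matrix(0, n, n))
  for (scheme in c("central", "upwind")) {
    out <- taxis_divergence(phi, psi, w, 1.5, grid, scheme = scheme)
    expect_lt(abs(sum(out)), 1e-12 * sum(abs(out)))
  }
  expect_error(taxis_divergence(phi[1:10, 1:10], psi, w, 1, grid), "shape")

  # 1-D manufactured solution: observed order >= 1.9 under refinement
  err <- sapply(c(64, 128), function(nn) {
    g <- epgg_grid(L = 10, dx = 10 / nn, dt = 0.01)
    x <- g$coords
    P <- matrix(0.2 + 0.1 * sin(2 * pi * x / 10), nn, nn, byrow = TRUE)
    S <- matrix(0.3 + 0.15 * cos(4 * pi * x / 10), nn, nn, byrow = TRUE)
    W <- matrix(0.5 + 0.2 * sin(2 * pi * x / 10 + 1), nn, nn, byrow = TRUE)
    flux <- function(x) (0.2 + 0.1 * sin(2 * pi * x / 10)) *
      (0.5 + 0.2 * sin(2 * pi * x / 10 + 1)) *
      (-0.15 * 4 * pi / 10 * sin(4 * pi * x / 10))
    h <- 1e-5
    exact <- -(flux(x + h) - flux(x - h)) / (2 * h)
    max(abs(taxis_divergence(P, S, W, 1, g)[1, ] - exact))
  })
  expect_gt(log2(err[1] / err[2]), 1.9)
})

test_that("a homogeneous state at a stable Q is a fixed point of the step", {
  g <- ref_game(2.4)
  eq <- ref_eq(2.4)
  grid <- epgg_grid(L = 12, dx = 0.375, dt = 0.01)
  st <- initial_state("homogeneous", grid, eq = eq)
  st2 <- epgg_step(st, g, epgg_migration(D_C = 0.1, D_D = 0.5), grid)
  expect_lt(max(abs(st2$u - st$u)), 1e-12)
  expect_lt(max(abs(st2$v - st$v)), 1e-12)
  expect_equal(attr(st2, "clipped"), 0)

  zero <- initial_state("custom", grid,
                        u = matrix(0, grid$n, grid$n),
                        v = matrix(0, grid$n, grid$n))
  z2 <- epgg_step(zero, g, epgg_migration(A_C = 1, R_D = 2), grid)
  expect_equal(max(abs(z2$u)), 0)
  expect_equal(max(abs(z2$v)), 0)
})

test_that("a homogeneous non-equilibrium state tracks the well-mixed trajectory", {
  g <- ref_game(2.4)
  grid <- epgg_grid(L = 12, dx = 0.375, dt = 0.01)
  n <- grid$n
  st <- initial_state("custom", grid, u = matrix(0.15, n, n),
                      v = matrix(0.1, n, n))
  mig <- epgg_migration(D_C = 0.1, D_D = 0.5, A_C = 0.5, R_D = 1)
  for (s in 1:100) st <- epgg_step(st, g, mig, grid)
  # stays exactly homogeneous: migration acts only on gradients
  expect_lt(max(st$u) - min(st$u), 1e-13)
  tr <- wellmixed_trajectory(g, 0.15, 0.1, c(0, 1))
  expect_equal(st$u[1, 1], tr$u[2], tolerance = 1e-3)
  expect_equal(st$v[1, 1], tr$v[2], tolerance = 1e-3)
})

test_that("simulations are bit-identical under the same seed", {
  g <- ref_game(2.4)
  grid <- epgg_grid(L = 12, dx = 0.375, dt = 0.01)
  run <- function(seed) epgg_simulate(
    g, epgg_migration(D_C = 0.1, D_D = 0.5, R_D = 2), grid,
    init = list(kind = "noisy_gaussian", seed = seed, width = 4),
    t_end = 5, snapshot_times = c(2, 5), quiet = TRUE)
  a <- run(9); b <- run(9)
  expect_identical(a$final$u, b$final$u)
  expect_identical(a$final$v, b$final$v)
  expect_identical(a$diagnostics, b$diagnostics)
  expect_false(identical(a$final$u, run(10)$final$u))
})

test_that("without directed migration and equal diffusion, noise around a stable Q fades", {
  g <- ref_game(2.4)
  eq <- ref_eq(2.4)
  grid <- epgg_grid(L = 12, dx = 0.375, dt = 0.01)
  sim <- epgg_simulate(g, epgg_migration(D_C = 0.1, D_D = 0.1), grid,
                       init = list(kind = "homogeneous", eq = eq,
                                   eps = 0.005, seed = 21),
                       t_end = 40, quiet = TRUE)
  d <- sim$diagnostics
  expect_lt(tail(d$var_uv, 1), 0.1 * d$var_uv[1])
  expect_equal(tail(d$mean_u, 1), eq$u, tolerance = 0.01)
})

test_that("late-time means are grid-converged in the smooth-pattern regime", {
  g <- ref_game(2.4)
  eq <- ref_eq(2.4)
  mig <- epgg_migration(D_C = 0.1, D_D = 0.5, R_D = 8)
  run <- function(dx, dt) {
    grid <- epgg_grid(L = 12, dx = dx, dt = dt)
    sim <- epgg_simulate(g, mig, grid,
                         init = list(kind = "plane_wave", eq = eq,
                                     eps = 0.02, mode_m = 1),
                         t_end = 200, quiet = TRUE)
    tail(sim$diagnostics, 1)
  }
  coarse <- run(0.375, 0.01)
  fine <- run(0.1875, 0.005)
  expect_gt(coarse$var_uv, 1e-5)  # a pattern actually developed
  expect_lt(abs(fine$mean_u - coarse$mean_u) / coarse$mean_u, 0.02)
  expect_lt(abs(fine$mean_v - coarse$mean_v) / coarse$mean_v, 0.02)
})

test_that("the CFL guard warns on an oversized step", {
  grid <- epgg_grid(L = 12, dx = 0.375, dt = 0.1)
  expect_warning(check_cfl(grid, epgg_migration(D_C = 0.5, D_D = 0.5)),
                 "stability")
  expect_silent(check_cfl(epgg_grid(L = 12, dx = 0.375, dt = 0.01),
                          epgg_migration(D_C = 0.1, D_D = 0.5)))
})
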