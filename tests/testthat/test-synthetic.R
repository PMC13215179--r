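# Forward simulator: permeability maps, Darcy solver, transport, noise.

test_that("permeability maps respect bounds, rescale, and determinism", {
  g <- box_grid(c(16L, 16L, 16L), 0.1)
  for (style in c("smooth", "sharp", "realistic")) {
    K <- make_permeability_map(g, style, k_low = 1e-10, k_high = 1e-6,
                               smoothing_sd_voxels = 3, seed = 11L)
    expect_gte(min(K), 1e-10)
    expect_equal(max(K[g$mask]), 1e-6)           # rescaled exactly to k_high
  }
  # no smoothing: exactly two-valued
  K0 <- make_permeability_map(g, "sharp", 1e-10, 1e-6,
                              smoothing_sd_voxels = 0, seed = 3L)
  expect_setequal(unique(as.numeric(K0)), c(1e-10, 1e-6))
  # determinism
  K1 <- make_permeability_map(g, "realistic", seed = 42L)
  K2 <- make_permeability_map(g, "realistic", seed = 42L)
  expect_identical(K1, K2)
  K3 <- make_permeability_map(g, "realistic", seed = 43L)
  expect_false(identical(K1, K3))
  # oversized kernel
  expect_error(make_permeability_map(g, "smooth", smoothing_sd_voxels = 10),
               "kernel larger")
})

test_that("Darcy solver matches 1D closed forms", {
  g <- box_grid(c(20L, 6L, 6L), 0.1, patch_frac = 1)
  mu <- 6.95e-4
  K <- array(1e-6, dim = g$shape)
  fl <- solve_darcy(g, K, p_inlet = 10, p_outlet = 0, viscosity = mu)
  u_exp <- (1e-6 / mu) * 10 / (20 * 0.1)
  expect_equal(max(abs(fl$velocity[, , , 1][g$mask] - u_exp)), 0,
               tolerance = 1e-10)
  expect_lt(max(abs(fl$velocity[, , , 2][g$mask])), 1e-12)
  expect_lt(fl$flux_divergence, 1e-10)

  # equal pressures: no flow
  fl0 <- solve_darcy(g, K, 5, 5, viscosity = mu)
  expect_lt(max(abs(fl0$velocity[g$mask])), 1e-12)

  # layered slab in series: flux equals dP over summed resistances
  # (independent 1D closed form: q = dP / (L1/K1 + L2/K2), hydraulic K)
  K2 <- array(1e-6, dim = g$shape)
  K2[11:20, , ] <- 1e-8
  fl2 <- solve_darcy(g, K2, 10, 0, viscosity = mu)
  q_oracle <- 10 / (1.0 / (1e-6 / mu) + 1.0 / (1e-8 / mu))
  ux <- fl2$velocity[, 3, 3, 1]
  expect_equal(ux[5], q_oracle, tolerance = 1e-8)
  expect_equal(ux[15], q_oracle, tolerance = 1e-8)

  # misconfiguration
  g2 <- domain_grid(c(8L, 8L, 8L), 0.1)   # no Dirichlet labels
  expect_error(solve_darcy(g2, K[1:8, 1:8, 1:8], 1, 0), "configuration")
})

test_that("advection-diffusion matches heat-kernel and translation oracles", {
  g <- domain_grid(c(25L, 25L, 25L), 0.1)    # closed box
  D <- 2.4e-4
  c0 <- array(0, dim = g$shape); c0[13, 13, 13] <- 1
  u0 <- array(0, dim = c(g$shape, 3L))
  cs <- solve_advection_diffusion(g, u0, D, times = c(2, 5), c0 = c0)
  # mass conserved exactly in the closed box
  expect_equal(sum(cs$values[, , , 1]), 1, tolerance = 1e-9)
  expect_equal(sum(cs$values[, , , 2]), 1, tolerance = 1e-9)
  # per-axis variance of the heat kernel: 2 D t (voxel^2 units: / h^2)
  v <- cs$values[, , , 2]
  idx <- which(v > 0, arr.ind = TRUE)
  w <- v[v > 0] / sum(v[v > 0])
  for (ax in 1:3) {
    mu_ax <- sum(idx[, ax] * w)
    var_ax <- sum((idx[, ax] - mu_ax)^2 * w)
    expect_equal(var_ax, 2 * D * 5 * 60 / 0.1^2, tolerance = 0.02)
  }

  # pure advection: blob translated by u * t, mass conserved, monotone
  cb <- array(0, dim = g$shape); cb[8:12, 11:15, 11:15] <- 1
  uu <- array(0, dim = c(g$shape, 3L)); uu[, , , 1] <- 0.001
  cs2 <- solve_advection_diffusion(g, uu, 0, times = 10, c0 = cb)
  v2 <- cs2$values[, , , 1]
  expect_equal(sum(v2), sum(cb), tolerance = 1e-9)
  cx <- sum(slice.index(v2, 1) * v2) / sum(v2)
  expect_equal(cx, 10 + 0.001 * 600 / 0.1, tolerance = 1e-6)
  expect_gte(min(v2), 0)                      # no new extrema
  expect_lte(max(v2), max(cb) + 1e-12)

  # zero source, zero IC: identically zero
  cs3 <- solve_advection_diffusion(g, uu, D, times = c(1, 2))
  expect_equal(max(abs(cs3$values)), 0)
})

test_that("mass drift per step is tiny after source shut-off", {
  case <- small_case()
  g <- case$grid
  # restart from a post-infusion snapshot with the true Darcy velocity and
  # no source; closed walls, open inlet/outlet. Outflow is the only sink,
  # so mass must decrease monotonically and smoothly.
  c0 <- case$concentration$values[, , , 5]
  cs <- solve_advection_diffusion(g, case$velocity, case$params$D,
                                  times = seq(1, 10, by = 1), c0 = c0)
  mass <- apply(cs$values, 4, sum)
  expect_true(all(diff(mass) <= 1e-9))
  # relative drift bounded by outflow flux scale
  expect_lt(max(abs(diff(mass)) / mass[1]), 1e-2)
})

test_that("observation noise is seeded, unbiased, and scales correctly", {
  g <- domain_grid(c(50L, 50L, 50L), 0.1)
  z <- conc_series(array(0, dim = c(g$shape, 1L)), 10, g)
  nm <- noise_model(base_sd = 0.7, signal_scaling = 0, seed = 21L)
  noisy <- add_observation_noise(z, nm)
  eps <- as.numeric(noisy$values)
  expect_equal(stats::sd(eps), 0.7, tolerance = 0.05)      # LLN, 125k voxels
  expect_lt(abs(mean(eps)) / (0.7 / sqrt(length(eps))), 3) # zero mean (3 SE)
  # determinism
  noisy2 <- add_observation_noise(z, nm)
  expect_identical(noisy$values, noisy2$values)
  # zero-noise identity
  id <- add_observation_noise(z, noise_model(0, 0, 1L))
  expect_identical(id$values, z$values)
  expect_error(noise_model(-1, 0), "base_sd")
})

test_that("generated speed distribution is bimodal over four decades", {
  # the sharp map keeps the permeability contrast (1e4) intact at this
  # grid size; heavy smoothing on a tiny grid merges the populations
  case <- sharp_case()
  pdf <- speed_pdf(case$velocity, case$grid$mask)
  expect_gte(pdf$n_modes, 2L)
  expect_gt(max(pdf$modes) - min(pdf$modes), 2)   # modes decades apart
})

test_that("ground-truth case satisfies Darcy consistency and positivity", {
  case <- small_case()
  expect_true(all(case$concentration$values >= 0))
  # u = -(kappa/mu) grad P at interior voxels
  gP <- grad_field(case$pressure, case$grid$spacing, case$grid$mask)
  inner <- case$grid$mask & !tracerflow:::mask_boundary(case$grid$mask)
  for (ax in 1:3) {
    ud <- -(case$permeability / case$params$viscosity) * gP[, , , ax]
    expect_equal(ud[inner], case$velocity[, , , ax][inner], tolerance = 1e-10)
  }
})
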