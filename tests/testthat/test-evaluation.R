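# Metrics, transport diagnostics, ensemble UQ.

test_that("relative L2 identities", {
  ref <- array(stats::runif(64, 1, 2), dim = c(4, 4, 4))
  expect_equal(relative_l2(ref, ref), 0)
  expect_equal(relative_l2(2 * ref, ref), 100)
  expect_equal(relative_l2(0 * ref, ref), 100)
  # joint-rescaling invariance
  expect_equal(relative_l2(1.3 * ref, 0.9 * ref),
               relative_l2(13 * ref, 9 * ref))
  expect_error(relative_l2(ref, 0 * ref), "zero norm")
})

test_that("angular error identities and scale invariance", {
  up <- rbind(c(1, 0, 0), c(1, 0, 0), c(1, 0, 0), c(1, 0, 0))
  ur <- rbind(c(2, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(1, 1, 0))
  ae <- angular_error(up, ur, speed_floor = 0)
  expect_equal(ae$theta, c(0, 90, 180, 45), tolerance = 1e-10)
  # invariant to positive rescaling of either field
  ae2 <- angular_error(17 * up, 0.01 * ur, speed_floor = 0)
  expect_equal(ae2$theta, ae$theta, tolerance = 1e-10)
  expect_error(angular_error(0 * up, ur, speed_floor = 1), "floor")
})

test_that("W1 distance matches translation identity and brute-force LP", {
  a <- stats::rnorm(500)
  expect_equal(wasserstein_1d(a, a), 0)
  expect_equal(wasserstein_1d(a, a + 2.5), 2.5, tolerance = 1e-12)
  # 3-point sets: exhaustive assignment oracle (equal weights -> best
  # permutation matching)
  brute_w1 <- function(x, y) {
    perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                  c(3, 1, 2), c(3, 2, 1))
    min(vapply(perms, function(p) mean(abs(x - y[p])), numeric(1)))
  }
  set.seed(31)
  for (i in 1:20) {
    x <- stats::rnorm(3); y <- stats::rnorm(3, sd = 2)
    expect_equal(wasserstein_1d(x, y), brute_w1(x, y), tolerance = 1e-12)
  }
  # unequal sizes reduce to the quantile coupling
  expect_equal(wasserstein_1d(c(0, 1), c(0.5, 0.5, 0.5, 0.5)), 0.5,
               tolerance = 0.01)
})

test_that("local Peclet is zero without flow, linear in u, and hand-checked", {
  g <- domain_grid(c(9L, 9L, 9L), 0.1)
  # c = (x in mm)^2 along axis 1, twice (steady): grad = 2x, lap = 2
  xmm <- (slice.index(array(0, g$shape), 1) - 0.5) * 0.1
  v <- array(0, dim = c(g$shape, 2L))
  v[, , , 1] <- xmm^2; v[, , , 2] <- xmm^2
  cs <- conc_series(v, c(1, 2), g)
  D <- 2.4e-4
  u0 <- array(0, dim = c(g$shape, 3L))
  expect_equal(max(local_peclet(u0, cs, D)[g$mask], na.rm = TRUE), 0)
  u1 <- u0; u1[, , , 1] <- 1e-3
  pe1 <- local_peclet(u1, cs, D)
  pe2 <- local_peclet(u1 * 2, cs, D)
  inner <- g$mask & !tracerflow:::mask_boundary(g$mask)
  expect_equal(pe2[inner], 2 * pe1[inner], tolerance = 1e-10)
  # hand value at voxel i=5 (x=0.45): |u * 2x| / |D * 2|
  expect_equal(pe1[5, 5, 5], 1e-3 * 2 * 0.45 / (D * 2), tolerance = 1e-6)
  # both overline placements agree for a time-constant field
  pe3 <- local_peclet(u1, cs, D, average_of_ratios = TRUE)
  expect_equal(pe3[inner], pe1[inner], tolerance = 1e-10)
})

test_that("speed_pdf counts modes of uni- and bimodal populations", {
  s1 <- with_seed_val(41, exp(stats::rnorm(5000, log(1e-4), 0.4)))
  p1 <- speed_pdf(matrix(c(s1, numeric(2 * 5000)), ncol = 3), floor = 0)
  expect_equal(p1$n_modes, 1L)
  # two log-normal populations four decades apart
  s2 <- with_seed_val(42, c(exp(stats::rnorm(4000, log(1e-7), 0.5)),
                            exp(stats::rnorm(4000, log(1e-3), 0.5))))
  p2 <- speed_pdf(matrix(c(s2, numeric(2 * 8000)), ncol = 3), floor = 0)
  expect_equal(p2$n_modes, 2L)
  expect_equal(sort(p2$modes), c(-7, -3), tolerance = 0.35)
  expect_error(speed_pdf(matrix(1e-9, 5, 3), floor = 1), "too few")
})

test_that("ensemble summary arithmetic and degenerate cases", {
  mask <- array(TRUE, dim = c(3, 3, 3))
  s <- array(2e-3, dim = c(3, 3, 3))
  es <- ensemble_uncertainty(list(s, 3 * s), mask)
  expect_equal(es$mean_speed[1, 1, 1], 4e-3)
  expect_equal(es$sd_speed[1, 1, 1], 2e-3)          # population SD
  expect_equal(es$relative[1, 1, 1], 0.5)
  # identical members: zero spread
  es2 <- ensemble_uncertainty(list(s, s, s), mask)
  expect_equal(max(es2$sd_speed), 0)
  expect_equal(es2$frac_below_100, 1)
  expect_error(ensemble_uncertainty(list(s), mask), "at least 2")
  expect_error(ensemble_uncertainty(list(s, array(1, dim = c(2, 2, 2))),
                                    mask), "mismatch")
})
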