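# Characteristic scales, starred/physical conversion, gauge invariance.

make_scale_fixture <- function(p_char = 1000, kmul = 1, D = 2.4e-4) {
  g <- box_grid(c(12L, 12L, 12L), 0.1)
  kp <- array(1e-8, dim = g$shape); kp[5:8, 5:8, 5:8] <- 1e-6
  kp <- kp * kmul
  cs <- conc_series(array(seq(0, 50, length.out = 12^3 * 2),
                          dim = c(g$shape, 2L)), c(5, 10), g)
  con <- material_constants(D = D)
  list(grid = g, scales = compute_scales(g, con, kp, cs, p_char = p_char))
}

test_that("scale definitions satisfy their invariants", {
  fx <- make_scale_fixture()
  sc <- fx$scales
  expect_equal(sc$L_char, 1.2)                      # 12 voxels * 0.1 mm
  expect_equal(sc$U_char, sc$K_char * sc$P_char / sc$L_char)
  expect_equal(sc$t_char, sc$L_char / sc$U_char)
  expect_equal(sc$Pe_g, sc$U_char * sc$L_char / sc$D)
  expect_equal(sc$c_char, 50)
  expect_equal(sc$K_char, 1e-6 / sc$viscosity)
})

test_that("gauge invariance: k * a with P_char / a leaves velocity scales fixed", {
  a <- 37.5
  s1 <- make_scale_fixture()$scales
  s2 <- make_scale_fixture(p_char = 1000 / a, kmul = a)$scales
  expect_equal(s1$U_char, s2$U_char)
  expect_equal(s1$t_char, s2$t_char)
  expect_equal(s1$Pe_g, s2$Pe_g)
  # doubling D halves the global Peclet number
  s3 <- make_scale_fixture(D = 4.8e-4)$scales
  expect_equal(s3$Pe_g, s1$Pe_g / 2)
})

test_that("to_nondim / to_physical are exact inverses with unit tagging", {
  sc <- make_scale_fixture()$scales
  u <- array(stats::rnorm(27, sd = 1e-3), dim = c(3, 3, 3))
  us <- to_nondim(u, sc, "velocity")
  expect_true(attr(us, "starred"))
  back <- to_physical(us, sc)
  expect_equal(as.numeric(back), as.numeric(u), tolerance = 1e-15)
  expect_null(attr(back, "starred"))
  # u = U_char maps to exactly 1
  expect_equal(as.numeric(to_nondim(sc$U_char, sc, "velocity")), 1)
  # type errors
  expect_error(to_nondim(us, sc, "velocity"), "already")
  expect_error(to_physical(u, sc, "velocity"), "not tagged")
  expect_error(to_physical(us, sc, "pressure"), "unit mismatch")
  expect_error(to_nondim(u, sc, "frobnication"), "unknown quantity")
})

test_that("manufactured solution satisfies the starred transport equation", {
  # traveling damped wave: c = sin(k(x - a t)) exp(-k^2 t / Pe) with
  # u = (a, 0, 0) satisfies c_t + u.grad c = (1/Pe) lap c exactly.
  Pe <- 40; a <- 0.7; k <- 2
  fields <- list(
    c = function(tx) sin(k * (tx[, 2] - a * tx[, 1])) *
      exp(-k^2 * tx[, 1] / Pe),
    u = function(x) cbind(rep(a, nrow(x)), 0, 0))
  pts <- cbind(stats::runif(50, 0.1, 1), stats::runif(50, 0, 1),
               stats::runif(50, 0, 1), stats::runif(50, 0, 1))
  r <- residual_AD(fields, pts, Pe_g = Pe, h = 5e-4, h_t = 5e-4)
  expect_lt(max(r), 1e-6)
})
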