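# Neural-field engine and model-state constraints.

test_that("polynomial features follow the per-coordinate power layout", {
  expect_equal(as.numeric(polynomial_features(matrix(0, 1, 3), 5)), rep(0, 15))
  expect_equal(as.numeric(polynomial_features(matrix(1, 1, 2), 5)), rep(1, 10))
  expect_equal(as.numeric(polynomial_features(matrix(0.5, 1, 1), 3)),
               c(0.5, 0.25, 0.125))
})

test_that("backpropagation matches numerical gradients", {
  net <- mlp_init(4, 1, n_layers = 3, n_neurons = 8, degree = 3, seed = 2)
  p <- tracerflow:::net_params(net)
  p <- p + with_seed_val(10, stats::rnorm(length(p), sd = 0.05))
  net <- tracerflow:::net_set_params(net, p)
  X <- with_seed_val(11, matrix(stats::runif(20, -1, 1), 5, 4))
  tgt <- with_seed_val(12, stats::rnorm(5))
  out <- mlp_forward(net, X, cache = TRUE)
  gr <- mlp_backward(net, attr(out, "cache"),
                     matrix(2 * (as.numeric(out) - tgt), ncol = 1))
  gvec <- tracerflow:::grad_flatten(gr)
  lossfn <- function(vec) {
    sum((as.numeric(mlp_forward(tracerflow:::net_set_params(net, vec), X)) -
           tgt)^2)
  }
  eps <- 1e-6
  ii <- with_seed_val(13, sample(length(p), 40))
  gnum <- vapply(ii, function(i) {
    e <- p; e[i] <- e[i] + eps; f1 <- lossfn(e)
    e[i] <- p[i] - eps; (f1 - lossfn(e)) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(gvec[ii] - gnum)), 1e-6 * max(1, max(abs(gnum))))
})

test_that("analytic Jacobian matches central differences below 1e-4", {
  m <- toy_model()
  x <- with_seed_val(3, matrix(stats::runif(60, 0.2, 0.8), 20, 3))
  u_a <- eval_velocity(m, x, method = "analytic")
  u_f <- eval_velocity(m, x, method = "fd", h = 1e-4)
  denom <- max(abs(u_a))
  expect_gt(denom, 0)
  expect_lt(max(abs(u_a - u_f)) / denom, 1e-4)
})

test_that("permeability is hard-bounded with the exact limit values", {
  m <- toy_model(jitter = 0.5)
  x <- with_seed_val(4, matrix(stats::runif(300, -0.2, 1.2), 100, 3))
  K <- eval_permeability(m, x)
  expect_true(all(K > m$K_min & K < m$K_max))
  # saturate the sigmoid via the head bias: K -> K_max / K_min / sqrt mid
  probe <- function(bias) {
    mm <- m
    mm$nets$K$head$g[] <- 0          # zero weights: output = bias
    mm$nets$K$head$b[] <- bias
    eval_permeability(mm, x[1:3, , drop = FALSE])[1]
  }
  expect_equal(probe(-40), m$K_max, tolerance = 1e-12)
  expect_equal(probe(40), m$K_min, tolerance = 1e-9)
  expect_equal(probe(0), sqrt(m$K_min * m$K_max), tolerance = 1e-12)
})

test_that("velocity is Darcy-consistent and steady by construction", {
  m <- toy_model()
  # constant pressure network -> zero velocity
  mc <- m
  mc$nets$P$head$g[] <- 0
  mc$nets$P$head$b[] <- 3.3
  x <- with_seed_val(5, matrix(stats::runif(30, 0.1, 0.9), 10, 3))
  expect_lt(max(abs(eval_velocity(mc, x))), 1e-12)
  # noise output is strictly positive everywhere
  tx <- cbind(30, x)
  expect_true(all(eval_noise(m, tx) > 0))
  # purity: repeated evaluation is identical
  expect_identical(eval_concentration(m, tx), eval_concentration(m, tx))
  expect_true(all(is.finite(eval_concentration(m, tx))))
})

test_that("a pressure net fitted to a linear ramp yields uniform velocity", {
  m <- toy_model(jitter = 0)
  # fit NNP to P* = -x* by least squares (tiny Adam loop)
  np <- length(tracerflow:::net_params(m$nets$P))
  opt <- tracerflow:::adam_init(np)
  X <- with_seed_val(6, matrix(stats::runif(900, 0, 1), 300, 3))
  tgt <- -X[, 1]
  for (it in 1:600) {
    out <- mlp_forward(m$nets$P, m$norm3$fwd(X), cache = TRUE)
    d <- matrix(2 * (as.numeric(out) - tgt) / 300, ncol = 1)
    g <- tracerflow:::grad_flatten(
      mlp_backward(m$nets$P, attr(out, "cache"), d))
    opt <- tracerflow:::adam_step(opt, g, 5e-3)
    m$nets$P <- tracerflow:::net_set_params(
      m$nets$P, tracerflow:::net_params(m$nets$P) + opt$delta)
  }
  xi <- with_seed_val(7, matrix(stats::runif(30, 0.2, 0.8), 10, 3))
  u <- eval_velocity(m, xi)
  K <- eval_permeability(m, xi)
  expect_equal(u[, 1], K, tolerance = 0.05)       # u* = (K*, 0, 0)
  expect_lt(max(abs(u[, 2:3])), 0.05 * max(K))
})

test_that("checkpoints round-trip bit-exactly", {
  m <- toy_model()
  tx <- cbind(30, with_seed_val(8, matrix(stats::runif(30, 0, 1), 10, 3)))
  before <- eval_concentration(m, tx)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(eval_concentration(m2, tx), before)
  expect_identical(tracerflow:::net_params(m2$nets$K),
                   tracerflow:::net_params(m$nets$K))
  unlink(path)
})

test_that("non-finite parameters are rejected by the state check", {
  m <- toy_model()
  m$nets$c$head$b[] <- NaN
  expect_error(tracerflow:::check_finite_state(m), "non-finite")
})
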