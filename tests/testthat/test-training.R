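# Loss arithmetic, residuals, TD-RBA machinery, schedule behavior.

test_that("Gaussian NLL reduces to least squares and prefers sigma = |r|", {
  r <- c(0.3, -0.2, 0.5)
  expect_equal(nll_loss(r, 0 * r, rep(1, 3)), mean(r^2) / 2)
  expect_equal(nll_loss(c(1, 2), c(1, 2), c(1, 1)), 0)
  # residual 1: sigma = 1 gives 0.5; sigma = 2 gives log 2 + 0.125
  expect_equal(nll_loss(1, 0, 1), 0.5)
  expect_equal(nll_loss(1, 0, 2), log(2) + 0.125)
  # scalar calculus: optimum of log(s) + r^2/(2 s^2) is s = |r|
  r0 <- 1.7
  f <- function(s) log(s) + r0^2 / (2 * s^2)
  expect_equal(stats::optimize(f, c(0.01, 10))$minimum, r0, tolerance = 1e-4)
  expect_error(nll_loss(1, 0, 0), "positive")
})

test_that("continuity residual matches hand computations", {
  # constant K, linear P: both terms vanish identically
  f1 <- list(K = function(x) rep(2, nrow(x)),
             P = function(x) 3 - 0.5 * x[, 1])
  pts <- with_seed_val(1, matrix(stats::runif(30, 0.2, 0.8), 10, 3))
  expect_lt(max(residual_CM(f1, pts, h = 1e-3)), 1e-7)  # FD roundoff floor
  # K = exp(x), P = -x: residual = |-exp(x)|
  f2 <- list(K = function(x) exp(x[, 1]), P = function(x) -x[, 1])
  r2 <- residual_CM(f2, pts, h = 5e-4)
  expect_equal(as.numeric(r2), exp(pts[, 1]), tolerance = 1e-5)
  # manufactured divergence-free pair: K constant, P harmonic (x^2 - y^2)
  f3 <- list(K = function(x) rep(1.3, nrow(x)),
             P = function(x) x[, 1]^2 - x[, 2]^2)
  expect_lt(max(residual_CM(f3, pts, h = 1e-3)), 1e-6)
})

test_that("advection-diffusion residual vanishes on steady diffusion", {
  # u = 0 and harmonic steady profile: c = x (lap = 0, c_t = 0)
  f <- list(c = function(tx) tx[, 2], u = function(x) matrix(0, nrow(x), 3))
  pts <- with_seed_val(2, cbind(stats::runif(10, 0, 1),
                                matrix(stats::runif(30, 0.2, 0.8), 10, 3)))
  expect_lt(max(residual_AD(f, pts, Pe_g = 10, h = 1e-3, h_t = 1e-3)), 1e-9)
  # untrained model: finite residuals
  m <- toy_model()
  pts_m <- cbind(stats::runif(5, 28, 32),
                 matrix(stats::runif(15, 0.2, 0.8), 5, 3))
  expect_true(all(is.finite(residual_AD(m, pts_m))))
})

test_that("TD scale implements the max-of-gradient-magnitudes rule", {
  xs <- with_seed_val(3, matrix(stats::runif(600, 0.05, 0.95), 200, 3))
  # c = x: C = max(1, 0, 0, 0) = 1
  f1 <- list(c = function(tx) tx[, 2])
  expect_equal(compute_td_scale(f1, c(0.3, 0.8), xs, Pe_g = 5),
               c(1, 1), tolerance = 1e-6)
  # homogeneity: c = a x -> C = a
  f2 <- list(c = function(tx) 3.7 * tx[, 2])
  expect_equal(compute_td_scale(f2, 0.5, xs, Pe_g = 5), 3.7,
               tolerance = 1e-6)
  # spatially uniform, c_t = beta, no diffusion term -> C = |beta|
  f3 <- list(c = function(tx) -2.2 * tx[, 1])
  expect_equal(compute_td_scale(f3, 0.5, xs, Pe_g = 5), 2.2,
               tolerance = 1e-6)
  # floor kicks in for a constant field
  f4 <- list(c = function(tx) rep(1, nrow(tx)))
  expect_equal(compute_td_scale(f4, 0.5, xs, Pe_g = 5, floor = 1e-8), 1e-8)
  expect_error(compute_td_scale(f1, 0.5, xs[0, , drop = FALSE], Pe_g = 5),
               "empty")
})

test_that("RBA updates decay, converge to eta/(1-gamma), and rank residuals", {
  lam <- c(1, 2, 3)
  expect_equal(update_rba(lam, c(0, 0, 0), gamma = 0.999), 0.999 * lam)
  # constant residuals from zero: geometric series -> eta / (1 - gamma)
  lam2 <- 0
  for (i in 1:3000) lam2 <- update_rba(lam2, 1, gamma = 0.99, eta = 0.01)
  expect_equal(lam2, 0.01 / (1 - 0.99), tolerance = 1e-3)
  # dominant residual gains the most
  lam3 <- update_rba(c(0, 0, 0), c(1, 10, 100), gamma = 0.999, eta = 0.01)
  expect_equal(lam3[3], 0.01)
  expect_true(all(diff(lam3) > 0))
})

test_that("attention resampling respects weights, floor, and seed", {
  pool <- matrix(seq_len(400), ncol = 4)
  lam <- rep(1, 100)
  s1 <- resample_collocation(lam, pool, 50, seed = 5)
  s2 <- resample_collocation(lam, pool, 50, seed = 5)
  expect_identical(s1$idx, s2$idx)
  # uniform weights: draw frequencies uniform within multinomial error
  counts <- integer(100)
  for (k in 1:200) {
    s <- resample_collocation(lam, pool, 50, seed = 1000 + k)
    tb <- tabulate(s$idx, 100)
    counts <- counts + tb
  }
  expect_lt(max(abs(counts / sum(counts) - 0.01)), 0.004)
  # a 100x weighted point is drawn ~100x more often (floor small)
  lam4 <- c(100, rep(1, 99))
  hits <- 0
  for (k in 1:200) {
    s <- resample_collocation(lam4, pool, 10, seed = 2000 + k,
                              floor_frac = 1e-4)
    hits <- hits + sum(s$idx == 1L)
  }
  frac <- hits / 2000
  expect_gt(frac, 0.25)    # multinomial expectation ~ 0.50 per draw
  expect_warning(resample_collocation(lam, pool, 200, seed = 1),
                 "replacement")
})

test_that("sensitivity filter discards uninformative points only", {
  # analytic spreading Gaussian: support grows with time, so the discard
  # fraction decreases as the tracer spreads
  f <- list(c = function(tx) exp(-rowSums((tx[, 2:4] - 0.5)^2) /
                                   (0.005 + 0.05 * tx[, 1])))
  pts <- with_seed_val(6, cbind(stats::runif(4000, 0.05, 1),
                                matrix(stats::runif(12000, 0, 1), 4000, 3)))
  sf <- sensitivity_filter(pts, f, tau_c = 0.01, n_bins = 4L)
  expect_true(all(diff(sf$by_time$discard) < 0))
  expect_gt(sf$discard_fraction, 0)
  # zero-concentration region is discarded
  far <- rowSums((pts[, 2:4] - 0.5)^2) > 0.45
  expect_lt(mean(sf$retained[far]), 0.05)
  # zero thresholds: nothing discarded
  sf0 <- sensitivity_filter(pts, f, tau_c = 0, tau_g = 0)
  expect_true(all(sf0$retained))
})

test_that("grouped loss arithmetic matches hand cases", {
  # single point, lambda = 1, m = 1, q = 2, r = 2 -> 4; q = 1 -> 2
  expect_equal(as.numeric(loss_group(list(list(r = 2, lambda = 1, m = 1,
                                               q = 2)))), 4)
  expect_equal(as.numeric(loss_group(list(list(r = 2, lambda = 1, m = 1,
                                               q = 1)))), 2)
  # stage-2 weight ratio: equal weighted residuals, m = (10, 1e-2)
  l <- loss_group(list(list(r = c(1, 1), lambda = 1, m = 10, q = 2),
                       list(r = c(1, 1), lambda = 1, m = 1e-2, q = 2)))
  tv <- attr(l, "terms")
  expect_equal(tv[1] / tv[2], 1000)
  # TD scaling divides the weights
  l2 <- loss_group(list(list(r = 2, lambda = 1, m = 1, q = 2, C = 2)))
  expect_equal(as.numeric(l2), 1)
  expect_error(loss_group(list(list(r = NaN, m = 1, q = 2, name = "AD"))),
               "AD")
})

test_that("the default schedule encodes the staged weighting table", {
  sch <- default_schedule()
  expect_length(sch, 6L)
  expect_equal(vapply(sch, function(s) s$stage_id, integer(1)), 0:5)
  expect_equal(sch[[1]]$terms$K_prior$m_low, 100)
  expect_equal(sch[[2]]$terms$AD$m, 1e-16)
  for (k in 3:6) {
    expect_equal(sch[[k]]$terms$AD$m, 10)
    expect_equal(sch[[k]]$terms$CM$m, 1e-2)
    expect_true(sch[[k]]$terms$AD$td)
  }
  expect_equal(sch[[6]]$terms$AD$q, 1)
  expect_equal(sch[[6]]$terms$data_c$m, 10)
})

test_that("run_schedule requires priors for the initialization stages", {
  case <- small_case()
  obs <- case$observed
  sc <- compute_scales(case$grid, material_constants(),
                       array(1e-7, dim = case$grid$shape), obs)
  data <- prepare_training_data(obs, sc, case$grid$mask, seed = 1)
  m <- model_state(case$grid, sc, specs = default_network_specs(0.06, 2L))
  expect_error(run_schedule(data, priors = list(), m), "priors")
})

test_that("training data split is a disjoint 50/50 partition", {
  case <- small_case()
  sc <- compute_scales(case$grid, material_constants(),
                       case$permeability, case$observed)
  data <- prepare_training_data(case$observed, sc, case$grid$mask,
                                t_range = c(5, 90), seed = 3)
  n <- nrow(data$train$tx) + nrow(data$val$tx)
  expect_equal(nrow(data$train$tx), floor(n / 2))
  expect_length(intersect(data$train$idx, data$val$idx), 0)
  expect_true(all(data$train$tx[, 1] >= 5 * 60 / sc$t_char - 1e-9))
})
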