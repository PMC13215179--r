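# Preprocessing: SER, smoothing, masks, priors, front tracking.

test_that("compute_ser follows the enhancement formula and masks bad baselines", {
  S0 <- array(2, dim = c(4, 4, 4))
  expect_equal(as.numeric(compute_ser(S0, S0)), rep(0, 64))
  expect_equal(as.numeric(compute_ser(2 * S0, S0)), rep(100, 64))
  expect_equal(compute_ser(array(2.5, dim = c(1, 1, 1)),
                           array(1, dim = c(1, 1, 1)))[1, 1, 1], 150)
  # scale invariance
  St <- array(stats::runif(64, 1, 3), dim = c(4, 4, 4))
  expect_equal(compute_ser(5 * St, 5 * S0), compute_ser(St, S0),
               ignore_attr = TRUE)
  # non-positive baseline voxels are masked, not clipped
  S0b <- S0; S0b[1, 1, 1] <- 0; S0b[2, 2, 2] <- -1
  out <- compute_ser(St, S0b)
  expect_true(is.na(out[1, 1, 1]) && is.na(out[2, 2, 2]))
  expect_equal(attr(out, "n_bad_baseline"), 2L)
  expect_error(compute_ser(St, array(1, dim = c(2, 2, 2))), "shape")
})

test_that("smooth_volume applies the normalized acquisition kernel", {
  v <- array(3.7, dim = c(7, 7, 7))
  expect_equal(smooth_volume(v), v)                       # DC preserved
  imp <- array(0, dim = c(7, 7, 7)); imp[4, 4, 4] <- 1
  sm <- smooth_volume(imp)
  expect_equal(sm[4, 4, 4], (1 / 1.4)^3, tolerance = 1e-12)
  # symmetric kernel leaves a linear ramp unchanged in the interior
  ramp <- array(rep(1:7, times = 49), dim = c(7, 7, 7))
  smr <- smooth_volume(ramp)
  expect_equal(smr[2:6, 4, 4], ramp[2:6, 4, 4], tolerance = 1e-12)
})

test_that("exclusion mask implements the 3x baseline-variation rule", {
  g <- domain_grid(c(3L, 3L, 2L), 0.1)
  nt <- 8L
  v <- array(0, dim = c(3, 3, 2, nt))
  # voxel A: flat at all times -> excluded
  v[1, 1, 1, ] <- 5
  # voxel B: baseline range 1, post range 10 -> retained
  v[2, 1, 1, ] <- c(0, 1, 0, 4, 8, 10, 10, 10)
  # voxel C: zero baseline range, positive change -> retained (threshold 0)
  v[3, 1, 1, ] <- c(2, 2, 2, 2, 2, 2, 2, 5)
  # voxel D: baseline range 1, total range 2 (< 3x) -> excluded
  v[1, 2, 1, ] <- c(0, 1, 0, 1, 2, 2, 2, 2)
  cs <- conc_series(v, 1:nt, g)
  excl <- build_exclusion_mask(cs, baseline_count = 3L)
  expect_true(excl[1, 1, 1])
  expect_false(excl[2, 1, 1])
  expect_false(excl[3, 1, 1])
  expect_true(excl[1, 2, 1])
  expect_error(build_exclusion_mask(cs, baseline_count = 8L), "smaller")
  # anatomical exclusions are OR-ed in
  extra <- array(FALSE, dim = c(3, 3, 2)); extra[2, 1, 1] <- TRUE
  excl2 <- build_exclusion_mask(cs, 3L, extra_exclude = extra)
  expect_true(excl2[2, 1, 1])
})

test_that("effective diffusivity matches the printed tortuosity correction", {
  expect_equal(effective_diffusivity(3.8e-4, 1.6), 1.48e-4, tolerance = 5e-3)
  expect_equal(effective_diffusivity(2.4e-4, 1), 2.4e-4)
  expect_equal(effective_diffusivity(0.5, 2), 0.125)
  expect_error(effective_diffusivity(0.5, 0.5), "tortuosity")
})

test_that("early-arrival permeability prior applies threshold, window, rescale", {
  g <- domain_grid(c(9L, 9L, 9L), 0.1)
  nt <- 6L
  times <- c(4, 10, 16, 30, 60, 90)
  v <- array(0, dim = c(g$shape, nt))
  v[3, 3, 3, times >= 10] <- 200   # reaches 200% at t=10 -> high
  v[7, 7, 7, times >= 30] <- 200   # reaches only at t=30 -> low
  cs <- conc_series(v, times, g)
  k_sharp <- initial_permeability_guess(cs, 150, 16, smoothing_sd_voxels = 0)
  expect_equal(k_sharp[3, 3, 3], 1e-6)
  expect_equal(k_sharp[7, 7, 7], 1e-10)
  k_sm <- initial_permeability_guess(cs, 150, 16, smoothing_sd_voxels = 1)
  expect_equal(max(k_sm), 1e-6)                 # rescaled to k_high exactly
  expect_gte(min(k_sm), 1e-10)
  expect_warning(initial_permeability_guess(cs, 1e4, 16), "all-low")
})

test_that("front tracking recovers a translating front and radial spread", {
  # 1D step-like front moving at constant speed, D = 0
  g <- domain_grid(c(40L, 5L, 5L), 0.1)
  vtrue <- 0.002                                # mm/s
  times <- seq(0, 20, by = 2)                   # minutes
  v <- array(0, dim = c(g$shape, length(times)))
  for (k in seq_along(times)) {
    xf <- 5 + vtrue * times[k] * 60 / 0.1       # front position, voxels
    prof <- 1 / (1 + exp((seq_len(40) - xf) / 1.5))
    v[, , , k] <- array(rep(prof, 25), dim = g$shape)
  }
  cs <- conc_series(v, times, g)
  fp <- front_track_velocity(cs, iso_levels = c(0.3, 0.5, 0.7))
  expect_gt(nrow(fp$vectors), 20)
  sp <- fp$vectors[, 1]
  expect_lt(abs(stats::median(sp) - vtrue) / vtrue, 0.10)
  # vectors point along +x
  expect_gt(mean(fp$vectors[, 1] > 0), 0.95)

  # static field: zero velocity at all tracked voxels
  v2 <- v; for (k in seq_along(times)) v2[, , , k] <- v[, , , 1]
  cs2 <- conc_series(v2, times, g)
  fp2 <- front_track_velocity(cs2, iso_levels = c(0.5))
  expect_lt(max(abs(fp2$vectors)), 1e-12)

  # pure diffusion from a center source: recovered vectors point outward
  g3 <- domain_grid(c(21L, 21L, 21L), 0.1)
  D <- 2.4e-4
  t3 <- c(5, 10, 15, 20)                        # minutes
  v3 <- array(0, dim = c(g3$shape, length(t3)))
  ctr <- 11
  for (k in seq_along(t3)) {
    ts <- t3[k] * 60
    for (i in 1:21) for (j in 1:21) for (l in 1:21) {
      r2 <- sum(((c(i, j, l) - ctr) * 0.1)^2)
      v3[i, j, l, k] <- (4 * pi * D * ts)^(-1.5) * exp(-r2 / (4 * D * ts))
    }
  }
  cs3 <- conc_series(v3, t3, g3)
  # track the outer (spreading) fronts: a level set of a decaying Gaussian
  # moves outward only while the level is below exp(-3/2) of the
  # instantaneous peak, so low iso levels isolate the outward spread
  fp3 <- front_track_velocity(cs3, iso_levels = max(v3) * c(0.005, 0.01, 0.02),
                              min_gradient = 0)
  rad <- (fp3$locations - ctr) * 0.1
  dots <- rowSums(fp3$vectors * rad)
  expect_gt(mean(dots > 0), 0.95)   # the advection-diffusion confound:
  # diffusion masquerades as outward flow; direction is radial regardless
})

test_that("front tracking on simulator output recovers speeds near fronts", {
  # advection-dominated channel flow with weak diffusion
  g <- box_grid(c(24L, 7L, 7L), 0.1, patch_frac = 1)
  K <- array(1e-6, dim = g$shape)
  fl <- solve_darcy(g, K, 2.5, 0)     # ~1.5 um/s: front crosses in ~25 min
  sp_true <- fl$velocity[12, 4, 4, 1]
  src <- g$inlet
  cs <- solve_advection_diffusion(g, fl$velocity, 1e-6, src,
                                  function(t) if (t <= 60) 100 else NA_real_,
                                  times = seq(1, 24, by = 1.5))
  fp <- front_track_velocity(cs)
  err <- abs(fp$vectors[, 1] - sp_true) / sp_true
  expect_lt(stats::median(err), 0.15)
})

test_that("concentration normalization round-trips via c_norm", {
  case <- small_case()
  nn <- normalize_concentration(case$concentration)
  expect_equal(max(nn$values[, , , dim(nn$values)[4]][nn$mask]) <= 100, TRUE)
  back <- nn$values * nn$c_norm / 100
  expect_equal(back, case$concentration$values, tolerance = 1e-12)
})
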