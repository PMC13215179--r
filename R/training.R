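# Staged physics-informed training.
#
# Derivatives of network outputs with respect to (t*, x*) inside the PDE
# residuals are taken with compact central differences in starred
# coordinates (step `h`). The residual at a point is then a fixed linear
# combination of plain network evaluations at stencil points, so parameter
# gradients reduce to standard backpropagation over the stacked stencil
# batch -- no higher-order autodiff needed. The analytic forward-mode
# Jacobian (mlp_jacobian) cross-checks the stencils in the test suite.

#' Gaussian negative log-likelihood loss
#'
#' `mean(log(sigma) + (c_obs - c_pred)^2 / (2 sigma^2))`, the heteroscedastic
#' Gaussian NLL up to an additive constant. With `sigma = 1` it reduces to
#' half the mean squared error.
#'
#' @param c_obs,c_pred observed and predicted values.
#' @param sigma_pred predicted noise SD (> 0).
#' @param weights optional per-point weights (mean is weighted).
#' @export
nll_loss <- function(c_obs, c_pred, sigma_pred, weights = NULL) {
  if (any(sigma_pred <= 0)) stop("sigma_pred must be positive")
  v <- log(sigma_pred) + (c_obs - c_pred)^2 / (2 * sigma_pred^2)
  if (is.null(weights)) mean(v) else sum(weights * v) / length(v)
}

# -- finite-difference field probes -----------------------------------------

as_cfun <- function(object) {
  if (inherits(object, "model_state"))
    function(tx) eval_concentration(object, tx)
  else object$c
}

# c value, time derivative, spatial gradient and Laplacian at tx (n x 4)
fd_probe_c <- function(cfun, tx, h = 2e-3, h_t = 2e-3) {
  n <- nrow(tx)
  stack <- tx
  offs <- list(c(1, h_t), c(1, -h_t))
  for (ax in 2:4) offs <- c(offs, list(c(ax, h), c(ax, -h)))
  for (o in offs) {
    p <- tx; p[, o[1]] <- p[, o[1]] + o[2]
    stack <- rbind(stack, p)
  }
  v <- cfun(stack)
  sl <- function(k) v[((k - 1) * n + 1):(k * n)]
  c0 <- sl(1)
  ct <- (sl(2) - sl(3)) / (2 * h_t)
  gc <- cbind((sl(4) - sl(5)) / (2 * h), (sl(6) - sl(7)) / (2 * h),
              (sl(8) - sl(9)) / (2 * h))
  lap <- (sl(4) + sl(5) + sl(6) + sl(7) + sl(8) + sl(9) - 6 * c0) / h^2
  list(c0 = c0, ct = ct, gc = gc, lap = lap)
}

fd_probe_x <- function(fun, x, h = 2e-3) {
  n <- nrow(x)
  stack <- x
  for (ax in 1:3) for (s in c(h, -h)) {
    p <- x; p[, ax] <- p[, ax] + s
    stack <- rbind(stack, p)
  }
  v <- fun(stack)
  sl <- function(k) v[((k - 1) * n + 1):(k * n)]
  g <- cbind((sl(2) - sl(3)) / (2 * h), (sl(4) - sl(5)) / (2 * h),
             (sl(6) - sl(7)) / (2 * h))
  lap <- (sl(2) + sl(3) + sl(4) + sl(5) + sl(6) + sl(7) - 6 * sl(1)) / h^2
  list(f0 = sl(1), g = g, lap = lap)
}

#' Advection-diffusion residual
#'
#' Nondimensional residual `|c_t + u . grad c - (1/Pe_g) lap c|` of the
#' clean (network) concentration -- the physics is constrained on the
#' denoised signal, never on raw data.
#'
#' @param object a [model_state()], or a list of closures `c(tx) -> c*` and
#'   `u(x) -> n x 3` for oracle tests.
#' @param points n x 4 matrix of `(t*, x*, y*, z*)`.
#' @param Pe_g global Peclet number (taken from the model scales when
#'   `object` is a model).
#' @param h,h_t central-difference steps in starred units.
#' @return vector of absolute residuals; attribute `signed` keeps the sign.
#' @export
residual_AD <- function(object, points, Pe_g = NULL, h = 2e-3, h_t = 2e-3) {
  if (inherits(object, "model_state")) {
    if (is.null(Pe_g)) Pe_g <- object$scales$Pe_g
    ufun <- function(x) eval_velocity(object, x)
  } else ufun <- object$u
  pr <- fd_probe_c(as_cfun(object), points, h, h_t)
  u <- ufun(points[, 2:4, drop = FALSE])
  r <- pr$ct + rowSums(u * pr$gc) - pr$lap / Pe_g
  out <- abs(r)
  attr(out, "signed") <- r
  out
}

#' Continuity (conservation-of-mass) residual
#'
#' `|grad K . grad P + K lap P|`, the divergence of the Darcy flux.
#'
#' @param object a [model_state()] or list of closures `K(x)`, `P(x)`.
#' @param points n x 3 matrix of starred spatial points.
#' @param h central-difference step.
#' @export
residual_CM <- function(object, points, h = 2e-3) {
  if (inherits(object, "model_state")) {
    Kfun <- function(x) eval_permeability(object, x)
    Pfun <- function(x) eval_pressure(object, x)
  } else { Kfun <- object$K; Pfun <- object$P }
  pk <- fd_probe_x(Kfun, points, h)
  pp <- fd_probe_x(Pfun, points, h)
  r <- rowSums(pk$g * pp$g) + pk$f0 * pp$lap
  out <- abs(r)
  attr(out, "signed") <- r
  out
}

#' Time-dependent residual scale C(t)
#'
#' `C(t_i) = max(|c_x|, |c_y|, |c_z|, |c_t - (1/Pe_g) lap c|)` over a
#' spatial sample at each time, evaluated on the clean concentration.
#' Divides the advection-diffusion attention weights so that every phase of
#' the transport -- early sharp fronts and late faint spread -- contributes
#' comparably to the loss.
#'
#' @param object a [model_state()] or list with closure `c`.
#' @param t_star vector of starred times.
#' @param x_star spatial sample (n x 3, starred) covering the mask.
#' @param Pe_g global Peclet number.
#' @param h,h_t central-difference steps.
#' @param floor lower bound (default 1e-8) preventing division blow-up.
#' @return numeric vector, one positive scale per time.
#' @export
compute_td_scale <- function(object, t_star, x_star, Pe_g = NULL,
                             h = 2e-3, h_t = 2e-3, floor = 1e-8) {
  if (nrow(x_star) == 0) stop("empty spatial sample")
  if (inherits(object, "model_state") && is.null(Pe_g))
    Pe_g <- object$scales$Pe_g
  cfun <- as_cfun(object)
  vapply(t_star, function(tt) {
    tx <- cbind(tt, x_star)
    pr <- fd_probe_c(cfun, tx, h, h_t)
    m <- max(abs(pr$gc[, 1]), abs(pr$gc[, 2]), abs(pr$gc[, 3]),
             abs(pr$ct - pr$lap / Pe_g))
    max(m, floor)
  }, numeric(1))
}

#' Residual-based attention weight update
#'
#' Exponentially averaged, max-normalized residuals:
#' `lambda' = gamma * lambda + eta * r / max(r)`. With all-zero residuals
#' the weights decay geometrically; a constant residual drives them to the
#' fixed point `eta / (1 - gamma)`.
#'
#' @param lambda current nonnegative weights.
#' @param residuals nonnegative residual magnitudes (same length).
#' @param gamma decay (default 0.999).
#' @param eta step (default 0.01).
#' @export
update_rba <- function(lambda, residuals, gamma = 0.999, eta = 0.01) {
  stopifnot(length(lambda) == length(residuals), all(residuals >= 0))
  mx <- max(residuals)
  if (mx > 0) gamma * lambda + eta * residuals / mx else gamma * lambda
}

#' Attention-weighted collocation resampling
#'
#' Multinomial draw (with replacement, by cumulative-sum inversion -- O(n)
#' per call, unlike R's weighted sampling without replacement) with
#' probability proportional to `lambda_scaled` plus a uniform floor (a
#' fraction `floor_frac` of the total mass), guaranteeing full support
#' across the spatiotemporal domain.
#'
#' @param lambda_scaled nonnegative weights over the pool.
#' @param pool matrix of pool points (rows).
#' @param batch_size number of draws.
#' @param seed integer seed.
#' @param floor_frac uniform mass fraction (default 0.01).
#' @return list `idx` (row indices) and `points`.
#' @export
resample_collocation <- function(lambda_scaled, pool, batch_size, seed,
                                 floor_frac = 0.01) {
  n <- nrow(pool)
  if (n == 0) stop("empty collocation pool")
  if (batch_size > n)
    warning("batch_size exceeds pool; sampling with replacement")
  tot <- sum(lambda_scaled)
  p <- if (tot > 0) (1 - floor_frac) * lambda_scaled / tot + floor_frac / n
       else rep(1 / n, n)
  cp <- cumsum(p)
  u <- with_seed(seed, stats::runif(batch_size)) * cp[n]
  idx <- findInterval(u, cp) + 1L
  idx[idx > n] <- n
  list(idx = idx, points = pool[idx, , drop = FALSE])
}

#' Sensitivity filter for physics collocation points
#'
#' Discards collocation points where the clean signal carries no usable
#' information for velocity inference: points with `|c| < tau_c` or
#' `|grad c| < tau_g` are dropped from the differential-equation constraint
#' (never from concentration training). Reports the per-time-bin discard
#' fraction.
#'
#' @param points n x 4 starred collocation points.
#' @param model a [model_state()] (or closure list with `c`).
#' @param tau_c clean-signal threshold (starred units; default 1% of
#'   `c_char`, i.e. 0.01).
#' @param tau_g gradient threshold; `NULL` = `tau_g_frac` of the max
#'   sampled gradient magnitude.
#' @param tau_g_frac fractional gradient threshold used when `tau_g` is
#'   `NULL`.
#' @param h,h_t probe steps.
#' @param n_bins time bins for the discard report.
#' @return list `retained` (logical), `discard_fraction` (overall),
#'   `by_time` (data.frame: bin center, discard fraction).
#' @export
sensitivity_filter <- function(points, model, tau_c = 0.01, tau_g = NULL,
                               tau_g_frac = 0.01, h = 2e-3, h_t = 2e-3,
                               n_bins = 8L) {
  stopifnot(tau_c >= 0)
  pr <- fd_probe_c(as_cfun(model), points, h, h_t)
  gmag <- sqrt(rowSums(pr$gc^2))
  if (is.null(tau_g)) tau_g <- tau_g_frac * max(gmag)
  keep <- abs(pr$c0) >= tau_c & gmag >= tau_g
  tt <- points[, 1]
  br <- seq(min(tt), max(tt), length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(tt, br, rightmost.closed = TRUE), 1L), n_bins)
  by_time <- data.frame(
    t_star = (br[-1] + br[-length(br)]) / 2,
    discard = vapply(seq_len(n_bins),
                     function(b) if (any(bin == b)) mean(!keep[bin == b])
                                 else NA_real_, numeric(1)))
  list(retained = keep, discard_fraction = mean(!keep), by_time = by_time)
}

#' Grouped loss arithmetic
#'
#' `L = sum_alpha m_alpha * mean_i[(lambda_i * r_i)^q]` over the supplied
#' subterms; the advection-diffusion subterm's weights are divided by its
#' time scale `C(t_i)` when present.
#'
#' @param subterms list of lists with fields `r` (residual magnitudes),
#'   `lambda` (weights, recycled), `m` (global weight), `q` (norm), and
#'   optional `C` (per-point time scaling divisor).
#' @return scalar loss; attribute `terms` holds per-subterm values.
#' @export
loss_group <- function(subterms) {
  vals <- vapply(subterms, function(s) {
    lam <- rep_len(if (is.null(s$lambda)) 1 else s$lambda, length(s$r))
    if (!is.null(s$C)) lam <- lam / rep_len(s$C, length(s$r))
    if (any(!is.finite(s$r)))
      stop("NaN in residuals of subterm '",
           if (is.null(s$name)) "?" else s$name, "'")
    s$m * mean((lam * s$r)^s$q)
  }, numeric(1))
  out <- sum(vals)
  attr(out, "terms") <- vals
  out
}

# ===========================================================================
# Stage schedule
# ===========================================================================

#' Default six-stage training schedule
#'
#' Stage 0 fits the permeability network to the prior map (separate
#' low/high-permeability subterms, weights 100 and 1). Stage 1 learns the
#' observed concentration and its noise by NLL (weight 100) and refines the
#' pressure network against the front-tracking velocity prior (weight 100),
#' with physics terms present at a negligible 1e-16. Stages 2-3 are two
#' consecutive physics-refinement blocks (advection-diffusion weight 10
#' with TD scaling, continuity 1e-2) updating pressure and permeability.
#' Stage 4 re-introduces the concentration data (weight 100) alongside the
#' physics, and stage 5 repeats it with the q = 1 norm and data weight 10,
#' trading smoothness for robustness.
#'
#' Each stage runs minibatch Adam (with the learning rate decayed tenfold
#' across the stage) and can finish with a full-batch L-BFGS polish on a
#' fixed subsample -- the standard two-phase optimization for
#' physics-informed training, which sharpens the fit well beyond what
#' first-order steps reach in the same time.
#'
#' The default iteration counts and learning rates are the desk-scale
#' recipe used throughout the tests: long data-fitting stages (the
#' denoising NLL stage minimizes what is effectively a log-residual
#' objective and only roughs in the fit; the stage-4 plain data term does
#' the sharpening at full step size), conservative physics stages, and a
#' concentration-only polish in the joint stages.
#'
#' @param iters integer vector of per-stage iteration counts (length 6).
#' @param lr per-stage peak Adam learning rates (length 6).
#' @param polish per-stage L-BFGS iteration caps (length 6; 0 disables).
#' @export
default_schedule <- function(iters = c(1200L, 2500L, 250L, 250L, 3500L, 400L),
                             lr = c(2e-3, 3e-3, 1e-4, 1e-4, 2e-3, 2e-4),
                             polish = c(60L, 60L, 0L, 0L, 100L, 30L)) {
  stopifnot(length(iters) == 6L, length(lr) == 6L, length(polish) == 6L)
  mk <- function(id, terms, trainable)
    list(stage_id = id, iters = iters[id + 1L], lr = lr[id + 1L],
         polish = polish[id + 1L],
         polish_nets = if (id %in% c(4L, 5L)) "c" else trainable,
         # joint stages: the data networks take the full step, the physics
         # networks refine conservatively (the stage lr is tuned for the
         # dominant data term)
         lr_net = if (id %in% c(4L, 5L)) list(P = 1e-4, K = 1e-4)
                  else NULL,
         terms = terms, trainable = trainable)
  list(
    mk(0L, list(K_prior = list(m_low = 100, m_high = 1, q = 2)), "K"),
    mk(1L, list(nll = list(m = 100),
                vel_prior = list(m = 100, q = 2),
                AD = list(m = 1e-16, q = 2, td = FALSE),
                CM = list(m = 1e-16, q = 2)),
       c("c", "sigma", "P")),
    mk(2L, list(AD = list(m = 10, q = 2, td = TRUE),
                CM = list(m = 1e-2, q = 2)), c("P", "K")),
    mk(3L, list(AD = list(m = 10, q = 2, td = TRUE),
                CM = list(m = 1e-2, q = 2)), c("P", "K")),
    mk(4L, list(data_c = list(m = 100, q = 2),
                AD = list(m = 10, q = 2, td = TRUE),
                CM = list(m = 1e-2, q = 2)), c("c", "P", "K")),
    mk(5L, list(data_c = list(m = 10, q = 1),
                AD = list(m = 10, q = 1, td = TRUE),
                CM = list(m = 1e-2, q = 1)), c("c", "P", "K")))
}

#' Training control parameters
#'
#' @param batch_data data-batch size per iteration.
#' @param batch_phys physics-batch size per iteration.
#' @param pool_n collocation-pool size.
#' @param gamma,eta residual-based-attention decay and step.
#' @param floor_frac uniform resampling floor.
#' @param h,h_t finite-difference steps (starred units). `NULL` (default)
#'   resolves to the voxel spacing / scan interval in starred units at the
#'   start of [run_schedule()]: probing network derivatives at the data's
#'   own resolution averages out sub-voxel network wiggle that a much
#'   smaller step would expose, acting as a mild regularizer of the
#'   residuals.
#' @param c_every iterations between C(t) refreshes.
#' @param val_every iterations between validation/history rows.
#' @param val_max validation subsample cap.
#' @param td_sample spatial sample size for C(t).
#' @param tau_c,tau_g_frac sensitivity-filter thresholds (starred `|c|`
#'   floor; gradient threshold as a fraction of the max sampled gradient).
#' @param polish_data,polish_phys fixed-subsample sizes for the per-stage
#'   L-BFGS polish (data-side points and physics collocation points).
#' @param physics_into_c let the transport residual backpropagate into the
#'   concentration network during the joint stages. Off by default at desk
#'   scale: the residual's gradient on `c` is dominated by the
#'   concentration-fit error itself and measurably degrades the fit (the
#'   data term remains the concentration's teacher); the physics terms
#'   always train pressure and permeability.
#' @param ema exponential-moving-average decay for Polyak averaging of the
#'   trainable parameters within each stage (0, the default, disables).
#'   At the end of a stage's Adam phase the averaged parameters replace
#'   the last iterate. Off by default: with the tenfold in-stage
#'   learning-rate decay the late iterates already dominate, and averaging
#'   in earlier ones was measured to worsen the fit.
#' @param max_retries divergence rollbacks allowed per stage.
#' @param verbose print per-stage progress.
#' @export
train_control <- function(batch_data = 1024L, batch_phys = 512L,
                          pool_n = 20000L, gamma = 0.999, eta = 0.01,
                          floor_frac = 0.01, h = NULL, h_t = NULL,
                          c_every = 100L, val_every = 250L, val_max = 20000L,
                          td_sample = 512L, tau_c = 0.01, tau_g_frac = 0.01,
                          polish_data = 24000L, polish_phys = 4000L,
                          physics_into_c = FALSE, ema = 0,
                          max_retries = 3L, verbose = FALSE) {
  as.list(environment())
}

# permeability head chain: K = C1 exp(C2 s(raw)); returns K and dK/draw
k_chain <- function(model, raw) {
  s <- sigmoid(raw)
  K <- model$C1 * exp(model$C2 * s)
  list(K = K, dK = K * model$C2 * s * (1 - s))
}

# ---------------------------------------------------------------------------
# One fused loss+gradient evaluation for the physics terms (AD + CM) on a
# shared collocation batch. Returns losses, residual magnitudes, and
# accumulates flattened gradients into `gacc` (an environment).
physics_step <- function(model, pts, w_AD, w_CM, cfg_AD, cfg_CM,
                         train_c, gacc, ctl,
                         need_grad = max(cfg_AD$m, cfg_CM$m) > 1e-12) {
  n <- nrow(pts)
  h <- ctl$h; h_t <- ctl$h_t
  Pe <- model$scales$Pe_g
  # --- stacked stencils ---
  stack_c <- pts
  offs_c <- list(c(1, h_t), c(1, -h_t), c(2, h), c(2, -h), c(3, h), c(3, -h),
                 c(4, h), c(4, -h))
  for (o in offs_c) { p <- pts; p[, o[1]] <- p[, o[1]] + o[2]; stack_c <- rbind(stack_c, p) }
  x <- pts[, 2:4, drop = FALSE]
  stack_x <- x
  for (ax in 1:3) for (s in c(h, -h)) {
    p <- x; p[, ax] <- p[, ax] + s; stack_x <- rbind(stack_x, p)
  }
  Xc <- model$norm4$fwd(stack_c)
  Xx <- model$norm3$fwd(stack_x)
  oc <- mlp_forward(model$nets$c, Xc, cache = TRUE)
  cache_c <- attr(oc, "cache"); vc <- as.numeric(oc)
  oP <- mlp_forward(model$nets$P, Xx, cache = TRUE)
  cache_P <- attr(oP, "cache"); vP <- as.numeric(oP)
  oK <- mlp_forward(model$nets$K, Xx, cache = TRUE)
  cache_K <- attr(oK, "cache"); rawK <- as.numeric(oK)
  kc <- k_chain(model, rawK)
  slc <- function(v, k) v[((k - 1) * n + 1):(k * n)]
  # concentration derivatives
  c0 <- slc(vc, 1)
  ct <- (slc(vc, 2) - slc(vc, 3)) / (2 * h_t)
  gc <- cbind((slc(vc, 4) - slc(vc, 5)) / (2 * h),
              (slc(vc, 6) - slc(vc, 7)) / (2 * h),
              (slc(vc, 8) - slc(vc, 9)) / (2 * h))
  lapc <- (slc(vc, 4) + slc(vc, 5) + slc(vc, 6) + slc(vc, 7) +
             slc(vc, 8) + slc(vc, 9) - 6 * c0) / h^2
  # P and K derivatives
  P0 <- slc(vP, 1)
  gP <- cbind((slc(vP, 2) - slc(vP, 3)) / (2 * h),
              (slc(vP, 4) - slc(vP, 5)) / (2 * h),
              (slc(vP, 6) - slc(vP, 7)) / (2 * h))
  lapP <- (slc(vP, 2) + slc(vP, 3) + slc(vP, 4) + slc(vP, 5) +
             slc(vP, 6) + slc(vP, 7) - 6 * P0) / h^2
  K0 <- slc(kc$K, 1)
  gK <- cbind((slc(kc$K, 2) - slc(kc$K, 3)) / (2 * h),
              (slc(kc$K, 4) - slc(kc$K, 5)) / (2 * h),
              (slc(kc$K, 6) - slc(kc$K, 7)) / (2 * h))
  u <- -K0 * gP
  rAD <- ct + rowSums(u * gc) - lapc / Pe
  rCM <- rowSums(gK * gP) + K0 * lapP
  if (any(!is.finite(rAD)) || any(!is.finite(rCM)))
    stop("NaN in physics residuals")
  loss_AD <- cfg_AD$m * mean((w_AD * abs(rAD))^cfg_AD$q)
  loss_CM <- cfg_CM$m * mean((w_CM * abs(rCM))^cfg_CM$q)
  if (!need_grad)   # negligible global weights: residuals (for the RBA
    return(list(loss_AD = loss_AD, loss_CM = loss_CM,   # state) only
                rAD = abs(rAD), rCM = abs(rCM)))
  # dL/dR for each residual
  gAD <- cfg_AD$m * cfg_AD$q * (w_AD^cfg_AD$q) *
    abs(rAD)^(cfg_AD$q - 1) * sign(rAD) / n
  gCM <- cfg_CM$m * cfg_CM$q * (w_CM^cfg_CM$q) *
    abs(rCM)^(cfg_CM$q - 1) * sign(rCM) / n
  # --- assemble dOut over the stencil stacks ---
  # concentration stack (only if c is trainable in this stage)
  if (train_c && cfg_AD$m > 0) {
    dc <- numeric(9L * n)
    put <- function(vv, k, val) { vv[((k - 1) * n + 1):(k * n)] <- val; vv }
    dc <- put(dc, 1, gAD * (6 / (Pe * h^2)))
    dc <- put(dc, 2, gAD * (1 / (2 * h_t)))
    dc <- put(dc, 3, gAD * (-1 / (2 * h_t)))
    for (ax in 1:3) {
      base <- 2L + (ax - 1L) * 2L
      dc <- put(dc, base + 2L, gAD * (u[, ax] / (2 * h) - 1 / (Pe * h^2)))
      dc <- put(dc, base + 3L, gAD * (-u[, ax] / (2 * h) - 1 / (Pe * h^2)))
    }
    gr <- mlp_backward(model$nets$c, cache_c, matrix(dc, ncol = 1L))
    gacc$c <- gacc$c + grad_flatten(gr)
  }
  # pressure stack: AD couples through u = -K0 gP; CM through gP and lapP
  dP <- numeric(7L * n)
  putx <- function(vv, k, val) { vv[((k - 1) * n + 1):(k * n)] <- val; vv }
  dR_dgP <- -K0 * gc                       # AD
  dP <- putx(dP, 1, gCM * K0 * (-6 / h^2))
  for (ax in 1:3) {
    co_hi <- gAD * dR_dgP[, ax] / (2 * h) +
      gCM * (gK[, ax] / (2 * h) + K0 / h^2)
    co_lo <- -gAD * dR_dgP[, ax] / (2 * h) +
      gCM * (-gK[, ax] / (2 * h) + K0 / h^2)
    dP <- putx(dP, 2L * ax, co_hi)
    dP <- putx(dP, 2L * ax + 1L, co_lo)
  }
  grP <- mlp_backward(model$nets$P, cache_P, matrix(dP, ncol = 1L))
  gacc$P <- gacc$P + grad_flatten(grP)
  # permeability stack: AD uses K0 (center); CM uses gK (offsets) + K0 lapP
  dK <- numeric(7L * n)
  dR_dK0_AD <- -rowSums(gP * gc)
  dK <- putx(dK, 1, gAD * dR_dK0_AD + gCM * lapP)
  for (ax in 1:3) {
    dK <- putx(dK, 2L * ax, gCM * gP[, ax] / (2 * h))
    dK <- putx(dK, 2L * ax + 1L, -gCM * gP[, ax] / (2 * h))
  }
  dRaw <- dK * kc$dK                        # chain through bounded map
  grK <- mlp_backward(model$nets$K, cache_K, matrix(dRaw, ncol = 1L))
  gacc$K <- gacc$K + grad_flatten(grK)
  list(loss_AD = loss_AD, loss_CM = loss_CM,
       rAD = abs(rAD), rCM = abs(rCM))
}

# NLL data step: trains c and sigma networks
nll_step <- function(model, tx, c_obs, m, lam, gacc) {
  n <- nrow(tx)
  X <- model$norm4$fwd(tx)
  oc <- mlp_forward(model$nets$c, X, cache = TRUE)
  cache_c <- attr(oc, "cache"); cp <- as.numeric(oc)
  os <- mlp_forward(model$nets$sigma, X, cache = TRUE)
  cache_s <- attr(os, "cache"); raw <- as.numeric(os)
  sg <- softplus(raw) + 1e-6
  resid <- c_obs - cp
  loss <- m * sum(lam * (log(sg) + resid^2 / (2 * sg^2))) / n
  dc <- m * lam * (-resid / sg^2) / n
  ds <- m * lam * (1 / sg - resid^2 / sg^3) * softplus_grad(raw) / n
  gr <- mlp_backward(model$nets$c, cache_c, matrix(dc, ncol = 1L))
  gacc$c <- gacc$c + grad_flatten(gr)
  gs <- mlp_backward(model$nets$sigma, cache_s, matrix(ds, ncol = 1L))
  gacc$sigma <- gacc$sigma + grad_flatten(gs)
  list(loss = loss, r = abs(resid))
}

# plain concentration data step (stages 4-5), trains c network
data_c_step <- function(model, tx, c_obs, m, q, lam, gacc) {
  n <- nrow(tx)
  X <- model$norm4$fwd(tx)
  oc <- mlp_forward(model$nets$c, X, cache = TRUE)
  cache_c <- attr(oc, "cache"); cp <- as.numeric(oc)
  r <- cp - c_obs
  loss <- m * mean((lam * abs(r))^q)
  dc <- m * q * lam^q * abs(r)^(q - 1) * sign(r) / n
  gr <- mlp_backward(model$nets$c, cache_c, matrix(dc, ncol = 1L))
  gacc$c <- gacc$c + grad_flatten(gr)
  list(loss = loss, r = abs(r))
}

# stage-0 permeability prior fit (log-space, split by region), trains K
kprior_step <- function(model, x_star, log_tgt, is_high, m_low, m_high,
                        q, lam, gacc) {
  n <- nrow(x_star)
  X <- model$norm3$fwd(x_star)
  oK <- mlp_forward(model$nets$K, X, cache = TRUE)
  cache_K <- attr(oK, "cache"); raw <- as.numeric(oK)
  s <- sigmoid(raw)
  logK <- log(model$C1) + model$C2 * s
  r <- (logK - log_tgt) / abs(model$C2)     # normalized log mismatch
  m_vec <- ifelse(is_high, m_high, m_low)
  loss <- sum(m_vec * (lam * abs(r))^q) / n
  dr <- m_vec * q * lam^q * abs(r)^(q - 1) * sign(r) / n
  draw <- dr * (model$C2 * s * (1 - s)) / abs(model$C2)
  gr <- mlp_backward(model$nets$K, cache_K, matrix(draw, ncol = 1L))
  gacc$K <- gacc$K + grad_flatten(gr)
  list(loss = loss, r = abs(r))
}

# stage-1 velocity prior fit: matches u* = -K gradP to front-tracking
# estimates at prior locations; K is held fixed (only P trains here).
velprior_step <- function(model, x_star, u_tgt, conf, m, q, lam, gacc, ctl) {
  n <- nrow(x_star)
  h <- ctl$h
  stack_x <- x_star
  for (ax in 1:3) for (s in c(h, -h)) {
    p <- x_star; p[, ax] <- p[, ax] + s; stack_x <- rbind(stack_x, p)
  }
  Xx <- model$norm3$fwd(stack_x)
  oP <- mlp_forward(model$nets$P, Xx, cache = TRUE)
  cache_P <- attr(oP, "cache"); vP <- as.numeric(oP)
  slc <- function(v, k) v[((k - 1) * n + 1):(k * n)]
  gP <- cbind((slc(vP, 2) - slc(vP, 3)) / (2 * h),
              (slc(vP, 4) - slc(vP, 5)) / (2 * h),
              (slc(vP, 6) - slc(vP, 7)) / (2 * h))
  K0 <- eval_permeability(model, x_star)
  upred <- -K0 * gP
  e <- upred - u_tgt
  w <- lam * conf
  loss <- m * mean((w * abs(e))^q)   # mean over points and components
  ge <- m * q * (w^q) * abs(e)^(q - 1) * sign(e) / (3 * n)
  dP <- numeric(7L * n)
  for (ax in 1:3) {
    co <- -K0 * ge[, ax] / (2 * h)
    dP[((2L * ax - 1L) * n + 1):((2L * ax) * n)] <- co
    dP[((2L * ax) * n + 1):((2L * ax + 1L) * n)] <- -co
  }
  gr <- mlp_backward(model$nets$P, cache_P, matrix(dP, ncol = 1L))
  gacc$P <- gacc$P + grad_flatten(gr)
  list(loss = loss, r = rowMeans(abs(e)))
}

# ===========================================================================

#' Run the staged training schedule
#'
#' Executes the six stages in order on nondimensionalized data, with
#' residual-based attention weights, TD scaling of the advection-diffusion
#' term, attention-guided resampling, a sensitivity filter on the physics
#' collocation points, and divergence rollback (restore stage-start
#' parameters, halve the step, retry a bounded number of times).
#'
#' @param data list from [prepare_training_data()].
#' @param priors list with `k_prior` (intrinsic permeability array) and
#'   `velocity` (a `velocity_prior`), required for stages 0-1.
#' @param model a [model_state()].
#' @param schedule list of stage configs, see [default_schedule()].
#' @param seed integer seed for all stochastic batching.
#' @param control see [train_control()].
#' @return list `model` (trained), `history` (data.frame), `rba` (final
#'   attention state), `discard` (per-stage sensitivity-filter reports).
#' @export
run_schedule <- function(data, priors, model, schedule = default_schedule(),
                         seed = 1L, control = train_control()) {
  ctl <- control
  if (is.null(ctl$h))
    ctl$h <- model$grid$spacing / model$scales$L_char
  if (is.null(ctl$h_t)) {
    dts <- diff(data$t_star_times)
    ctl$h_t <- if (length(dts)) stats::median(dts) else 1e-2
  }
  needs_prior <- any(vapply(schedule, function(s)
    any(c("K_prior", "vel_prior") %in% names(s$terms)), logical(1)))
  if (needs_prior && (is.null(priors$k_prior) || is.null(priors$velocity)))
    stop("priors (k_prior, velocity) are required for stages 0-1")
  sc <- model$scales
  grid <- model$grid

  # --- stage-0 prior targets -----------------------------------------------
  mask_idx <- which(data$analysis_mask)
  Xall <- voxel_centers(grid, mask_idx) / sc$L_char
  if (!is.null(priors$k_prior)) {
    Kst <- (priors$k_prior[mask_idx] / sc$viscosity) / sc$K_char
    Kst <- pmin(pmax(Kst, model$K_min * (1 + 1e-9)), model$K_max * (1 - 1e-9))
    log_tgt <- log(Kst)
    is_high <- Kst > sqrt(model$K_min * model$K_max)
  }
  # --- velocity prior targets ----------------------------------------------
  if (!is.null(priors$velocity) && nrow(priors$velocity$vectors) > 0) {
    vp <- priors$velocity
    keep <- data$analysis_mask[vp$linear]
    vp_x <- (vp$locations[keep, , drop = FALSE] - 0.5) * grid$spacing / sc$L_char
    vp_u <- vp$vectors[keep, , drop = FALSE] / sc$U_char
    vp_w <- vp$confidence[keep]
    vp_w <- vp_w / mean(vp_w)
  } else { vp_x <- NULL }

  # --- collocation pool ----------------------------------------------------
  pool_n <- min(ctl$pool_n, length(mask_idx) * 50L)
  pool <- with_seed(seed + 11L, {
    vi <- sample(length(mask_idx), pool_n, replace = TRUE)
    jit <- matrix(stats::runif(pool_n * 3L, -0.5, 0.5), ncol = 3L)
    xs <- (arrayInd(mask_idx[vi], grid$shape) - 0.5 + jit) *
      grid$spacing / sc$L_char
    ts <- stats::runif(pool_n, data$t_star_range[1], data$t_star_range[2])
    cbind(ts, xs)
  })
  lam_AD <- rep(1, pool_n)
  lam_CM <- rep(1, pool_n)
  lam_c <- rep(1, nrow(data$train$tx))
  td_bins <- data$t_star_times
  C_of_t <- rep(1, length(td_bins))
  pool_bin <- vapply(pool[, 1], function(tt) which.min(abs(td_bins - tt)),
                     integer(1))
  td_x <- with_seed(seed + 12L,
                    Xall[sample(nrow(Xall), min(ctl$td_sample, nrow(Xall))), ,
                         drop = FALSE])

  history <- list()
  discard_log <- list()
  iter_seed <- seed * 1000L

  val_idx <- with_seed(seed + 13L,
    sample(nrow(data$val$tx), min(ctl$val_max, nrow(data$val$tx))))
  val_tx <- data$val$tx[val_idx, , drop = FALSE]
  val_c <- data$val$c[val_idx]
  validate <- function() {
    pred <- eval_concentration(model, val_tx)
    100 * sqrt(sum((pred - val_c)^2) / sum(val_c^2))
  }

  for (st in schedule) {
    snap <- lapply(model$nets, net_params)
    lr <- st$lr
    attempt <- 0L
    repeat {
      ok <- TRUE
      opt <- lapply(model$nets, function(nn) adam_init(length(net_params(nn))))
      ema_par <- if (ctl$ema > 0)
        lapply(model$nets[st$trainable], net_params) else NULL
      retained <- rep(TRUE, pool_n)
      hasAD <- "AD" %in% names(st$terms)
      if (hasAD && st$terms$AD$m > 1e-12) {
        sf <- sensitivity_filter(pool, model, tau_c = ctl$tau_c,
                                 tau_g_frac = ctl$tau_g_frac,
                                 h = ctl$h, h_t = ctl$h_t)
        retained <- sf$retained
        if (!any(retained)) retained <- rep(TRUE, pool_n)
        discard_log[[paste0("stage", st$stage_id)]] <- sf$by_time
        C_of_t <- compute_td_scale(model, td_bins, td_x,
                                   h = ctl$h, h_t = ctl$h_t)
      }
      res <- tryCatch({
        for (it in seq_len(st$iters)) {
          iter_seed <- iter_seed + 1L
          gacc <- new.env()
          for (nm in names(model$nets))
            assign(nm, numeric(length(net_params(model$nets[[nm]]))),
                   envir = gacc)
          losses <- c()
          # ---- data-side terms ----
          if ("nll" %in% names(st$terms) || "data_c" %in% names(st$terms)) {
            bs <- min(ctl$batch_data, nrow(data$train$tx))
            smp <- resample_collocation(lam_c, data$train$tx, bs,
                                        seed = iter_seed,
                                        floor_frac = ctl$floor_frac)
            tx_b <- smp$points
            c_b <- data$train$c[smp$idx]
            lam_b <- lam_c[smp$idx]
            if ("nll" %in% names(st$terms)) {
              r <- nll_step(model, tx_b, c_b, st$terms$nll$m, lam_b, gacc)
            } else {
              cfg <- st$terms$data_c
              r <- data_c_step(model, tx_b, c_b, cfg$m, cfg$q, lam_b, gacc)
            }
            losses["data"] <- r$loss
            lam_c[smp$idx] <- update_rba(lam_b, r$r, ctl$gamma, ctl$eta)
          }
          if ("K_prior" %in% names(st$terms)) {
            bs <- min(ctl$batch_data, nrow(Xall))
            idx <- with_seed(iter_seed + 1L, sample(nrow(Xall), bs))
            cfg <- st$terms$K_prior
            r <- kprior_step(model, Xall[idx, , drop = FALSE], log_tgt[idx],
                             is_high[idx], cfg$m_low, cfg$m_high, cfg$q,
                             1, gacc)
            losses["K_prior"] <- r$loss
          }
          if ("vel_prior" %in% names(st$terms) && !is.null(vp_x) &&
              nrow(vp_x) > 0) {
            bs <- min(ctl$batch_phys, nrow(vp_x))
            idx <- with_seed(iter_seed + 2L, sample(nrow(vp_x), bs))
            cfg <- st$terms$vel_prior
            r <- velprior_step(model, vp_x[idx, , drop = FALSE],
                               vp_u[idx, , drop = FALSE], vp_w[idx],
                               cfg$m, cfg$q, 1, gacc, ctl)
            losses["vel_prior"] <- r$loss
          }
          # ---- physics terms (skipped entirely while their global
          # weights sit at the negligible 1e-16 placeholder: contributions
          # below double precision cannot move the optimizer) ----
          if ("AD" %in% names(st$terms) &&
              max(st$terms$AD$m, st$terms$CM$m) > 1e-12) {
            cfgA <- st$terms$AD; cfgC <- st$terms$CM
            pool_idx <- which(retained)
            lam_eff <- lam_AD[pool_idx]
            if (isTRUE(cfgA$td)) lam_eff <- lam_eff / C_of_t[pool_bin[pool_idx]]
            bs <- min(ctl$batch_phys, length(pool_idx))
            smp <- resample_collocation(lam_eff, pool[pool_idx, , drop = FALSE],
                                        bs, seed = iter_seed + 3L,
                                        floor_frac = ctl$floor_frac)
            gi <- pool_idx[smp$idx]
            w_AD <- lam_AD[gi]
            if (isTRUE(cfgA$td)) w_AD <- w_AD / C_of_t[pool_bin[gi]]
            w_CM <- lam_CM[gi]
            ps <- physics_step(model, smp$points, w_AD, w_CM, cfgA, cfgC,
                               train_c = "c" %in% st$trainable &&
                                 isTRUE(ctl$physics_into_c), gacc, ctl)
            losses["AD"] <- ps$loss_AD
            losses["CM"] <- ps$loss_CM
            lam_AD[gi] <- update_rba(lam_AD[gi], ps$rAD, ctl$gamma, ctl$eta)
            lam_CM[gi] <- update_rba(lam_CM[gi], ps$rCM, ctl$gamma, ctl$eta)
            if (isTRUE(cfgA$td) && it %% ctl$c_every == 0L)
              C_of_t <- compute_td_scale(model, td_bins, td_x,
                                         h = ctl$h, h_t = ctl$h_t)
          }
          tot <- sum(losses)
          if (!is.finite(tot)) stop("divergence: non-finite loss")
          # ---- optimizer step on trainable networks ----
          decay <- 0.1^((it - 1) / max(st$iters, 1L))       # tenfold decay
          for (nm in st$trainable) {
            g <- get(nm, envir = gacc)
            if (all(g == 0)) next
            base_lr <- if (!is.null(st$lr_net) && !is.null(st$lr_net[[nm]]))
              st$lr_net[[nm]] * (lr / st$lr)  # scale with any retry halving
              else lr
            opt[[nm]] <- adam_step(opt[[nm]], g, base_lr * decay)
            newp <- net_params(model$nets[[nm]]) + opt[[nm]]$delta
            model$nets[[nm]] <- net_set_params(model$nets[[nm]], newp)
            if (!is.null(ema_par))
              ema_par[[nm]] <- ctl$ema * ema_par[[nm]] + (1 - ctl$ema) * newp
          }
          if (it %% ctl$val_every == 0L || it == st$iters) {
            vl <- validate()
            if (!is.finite(vl)) stop("divergence: non-finite validation")
            history[[length(history) + 1L]] <- data.frame(
              stage = st$stage_id, iter = it, loss = tot,
              val_rl2 = vl,
              t(as.matrix(losses)))
            if (ctl$verbose)
              message(sprintf("stage %d it %d loss %.4g val %.2f%%",
                              st$stage_id, it, tot, vl))
          }
        }
        if (!is.null(ema_par) && st$iters > 100L) {
          for (nm in st$trainable)
            model$nets[[nm]] <- net_set_params(model$nets[[nm]], ema_par[[nm]])
          vl <- validate()
          if (!is.finite(vl)) stop("divergence: non-finite validation after EMA")
        }
        # ---- full-batch L-BFGS polish on fixed subsamples ----
        if (!is.null(st$polish) && st$polish > 0L) {
          have_data <- any(c("nll", "data_c") %in% names(st$terms))
          if (have_data) {
            di <- with_seed(seed + 770L + st$stage_id,
                            sample(nrow(data$train$tx),
                                   min(ctl$polish_data, nrow(data$train$tx))))
            ptx <- data$train$tx[di, , drop = FALSE]
            pcc <- data$train$c[di]
            plam <- lam_c[di]
          }
          if ("K_prior" %in% names(st$terms)) {
            ki <- with_seed(seed + 771L,
                            sample(nrow(Xall), min(ctl$polish_data, nrow(Xall))))
          }
          vp_use <- "vel_prior" %in% names(st$terms) && !is.null(vp_x) &&
            nrow(vp_x) > 0
          if (vp_use) {
            vi <- with_seed(seed + 772L,
                            sample(nrow(vp_x), min(ctl$polish_phys, nrow(vp_x))))
          }
          has_phys <- "AD" %in% names(st$terms) && st$terms$AD$m > 1e-12
          if (has_phys) {
            pool_idx <- which(retained)
            lam_eff <- lam_AD[pool_idx]
            if (isTRUE(st$terms$AD$td))
              lam_eff <- lam_eff / C_of_t[pool_bin[pool_idx]]
            smp <- resample_collocation(
              lam_eff, pool[pool_idx, , drop = FALSE],
              min(ctl$polish_phys, length(pool_idx)),
              seed = seed + 773L + st$stage_id, floor_frac = ctl$floor_frac)
            gi <- pool_idx[smp$idx]
            ppts <- pool[gi, , drop = FALSE]
            pw_AD <- lam_AD[gi]
            if (isTRUE(st$terms$AD$td)) pw_AD <- pw_AD / C_of_t[pool_bin[gi]]
            pw_CM <- lam_CM[gi]
          }
          # a stage can restrict its polish to a subset of its trainable
          # networks (e.g. concentration only in the joint stages)
          tr <- if (!is.null(st$polish_nets)) st$polish_nets else st$trainable
          sizes <- vapply(tr, function(nm)
            length(net_params(model$nets[[nm]])), integer(1))
          ends <- cumsum(sizes)
          starts <- c(1L, utils::head(ends, -1L) + 1L)
          getvec <- function()
            unlist(lapply(tr, function(nm) net_params(model$nets[[nm]])))
          setvec <- function(v) {
            for (j in seq_along(tr))
              model$nets[[tr[j]]] <<- net_set_params(model$nets[[tr[j]]],
                                                     v[starts[j]:ends[j]])
          }
          lastg <- NULL
          fn <- function(v) {
            setvec(v)
            gacc <- new.env()
            for (nm in names(model$nets))
              assign(nm, numeric(length(net_params(model$nets[[nm]]))),
                     envir = gacc)
            loss <- 0
            if (have_data) {
              loss <- loss + if ("nll" %in% names(st$terms))
                nll_step(model, ptx, pcc, st$terms$nll$m, plam, gacc)$loss
              else data_c_step(model, ptx, pcc, st$terms$data_c$m,
                               st$terms$data_c$q, plam, gacc)$loss
            }
            if ("K_prior" %in% names(st$terms)) {
              cfg <- st$terms$K_prior
              loss <- loss + kprior_step(model, Xall[ki, , drop = FALSE],
                                         log_tgt[ki], is_high[ki], cfg$m_low,
                                         cfg$m_high, cfg$q, 1, gacc)$loss
            }
            if (vp_use) {
              cfg <- st$terms$vel_prior
              loss <- loss + velprior_step(model, vp_x[vi, , drop = FALSE],
                                           vp_u[vi, , drop = FALSE], vp_w[vi],
                                           cfg$m, cfg$q, 1, gacc, ctl)$loss
            }
            if (has_phys) {
              ps <- physics_step(model, ppts, pw_AD, pw_CM, st$terms$AD,
                                 st$terms$CM,
                                 train_c = "c" %in% tr &&
                                   isTRUE(ctl$physics_into_c), gacc, ctl)
              loss <- loss + ps$loss_AD + ps$loss_CM
            }
            lastg <<- unlist(lapply(tr, function(nm) get(nm, envir = gacc)))
            if (!is.finite(loss)) { lastg[is.na(lastg)] <<- 0; return(1e10) }
            loss
          }
          pres <- stats::optim(getvec(), fn, function(v) lastg,
                               method = "L-BFGS-B",
                               control = list(maxit = st$polish, factr = 1e7))
          setvec(pres$par)
          vl <- validate()
          if (!is.finite(vl)) stop("divergence: non-finite validation after polish")
          history[[length(history) + 1L]] <- data.frame(
            stage = st$stage_id, iter = st$iters + st$polish, loss = pres$value,
            val_rl2 = vl, t(as.matrix(c(polish = pres$value))))
          if (ctl$verbose)
            message(sprintf("stage %d polish(%d) loss %.4g val %.2f%%",
                            st$stage_id, st$polish, pres$value, vl))
        }
        TRUE
      }, error = function(e) e)
      if (isTRUE(res)) break
      # rollback
      attempt <- attempt + 1L
      if (attempt > ctl$max_retries)
        stop("stage ", st$stage_id, " failed after retries: ",
             conditionMessage(res))
      for (nm in names(model$nets))
        model$nets[[nm]] <- net_set_params(model$nets[[nm]], snap[[nm]])
      lr <- lr / 2
      if (ctl$verbose)
        message(sprintf("stage %d rollback (attempt %d): %s",
                        st$stage_id, attempt, conditionMessage(res)))
    }
  }
  hist_df <- do.call(rbind, lapply(history, function(d) {
    for (col in c("data", "K_prior", "vel_prior", "AD", "CM"))
      if (!col %in% names(d)) d[[col]] <- NA_real_
    d[, c("stage", "iter", "loss", "val_rl2", "data", "K_prior",
          "vel_prior", "AD", "CM")]
  }))
  list(model = model, history = hist_df,
       rba = list(lambda_AD = lam_AD, lambda_CM = lam_CM,
                  lambda_c = lam_c, C_of_t = C_of_t, pool = pool),
       discard = discard_log)
}

#' Prepare observation tensors for training
#'
#' Nondimensionalizes the observed series, restricts to the analysis mask
#' and the inference time window, and splits the (voxel, time) observations
#' 50/50 into train and validation sets; validation never touches
#' gradients.
#'
#' @param series observed [conc_series()] (proxy scale).
#' @param scales a [compute_scales()] result.
#' @param analysis_mask logical array of voxels carrying data.
#' @param t_range inference window in minutes (default `c(5, 90)`;
#'   the early injection phase has an unknown source term and is excluded).
#' @param split fraction of observations used for training.
#' @param seed split seed.
#' @export
prepare_training_data <- function(series, scales, analysis_mask = NULL,
                                  t_range = c(5, 90), split = 0.5,
                                  seed = 1L) {
  grid <- series$grid
  if (is.null(analysis_mask)) analysis_mask <- series$mask
  sel_t <- which(series$times >= t_range[1] & series$times <= t_range[2])
  if (length(sel_t) < 2L) stop("time window contains fewer than 2 scans")
  mask_idx <- which(analysis_mask)
  xs <- voxel_centers(grid, mask_idx) / scales$L_char
  nt <- length(sel_t)
  nv <- length(mask_idx)
  tx <- cbind(rep(series$times[sel_t] * 60 / scales$t_char, each = nv),
              xs[rep(seq_len(nv), nt), , drop = FALSE])
  cc <- numeric(nv * nt)
  for (k in seq_len(nt))
    cc[((k - 1) * nv + 1):(k * nv)] <- series$values[, , , sel_t[k]][mask_idx]
  cc <- cc / scales$c_char
  n <- length(cc)
  tr <- with_seed(seed, sample(n, floor(split * n)))
  va <- setdiff(seq_len(n), tr)
  list(train = list(tx = tx[tr, , drop = FALSE], c = cc[tr], idx = tr),
       val = list(tx = tx[va, , drop = FALSE], c = cc[va], idx = va),
       analysis_mask = analysis_mask,
       t_star_range = range(tx[, 1]),
       t_star_times = series$times[sel_t] * 60 / scales$t_char,
       mask_idx = mask_idx, sel_t = sel_t)
}
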