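#' Architecture specification for one subnetwork
#'
#' Defaults mirror the reference architecture: five adaptive-residual tanh
#' layers, fifth-degree polynomial feature expansion, weight normalization.
#' Desk-scale runs typically shrink `n_layers`/`n_neurons`.
#'
#' @param n_layers number of hidden layers (>= 1).
#' @param n_neurons neurons per layer.
#' @param feature_degree polynomial expansion degree.
#' @param cross_terms append pairwise cross-term features (the expansion is
#'   per-coordinate powers by default; cross terms are configurable).
#' @export
network_spec <- function(n_layers = 5L, n_neurons = 64L,
                         feature_degree = 5L, cross_terms = FALSE) {
  stopifnot(n_layers >= 1L, feature_degree >= 1L)
  structure(list(n_layers = n_layers, n_neurons = n_neurons,
                 feature_degree = feature_degree, activation = "tanh",
                 cross_terms = cross_terms,
                 uses_weight_normalization = TRUE,
                 uses_adaptive_residual = TRUE),
            class = "network_spec")
}

#' Reference-size architecture set
#'
#' The full-size configuration (concentration 5x200, noise 5x66, pressure
#' and permeability 5x150). `width_scale` shrinks all widths
#' proportionally for desk-scale runs; `n_layers` overrides the depth.
#'
#' @param width_scale multiplier on the neurons-per-layer counts.
#' @param n_layers number of hidden layers for every subnetwork.
#' @param cross_terms append pairwise cross-term features.
#' @export
default_network_specs <- function(width_scale = 1, n_layers = 5L,
                                  cross_terms = FALSE) {
  w <- function(n) max(8L, as.integer(round(n * width_scale)))
  list(c = network_spec(n_layers, w(200L), cross_terms = cross_terms),
       sigma = network_spec(n_layers, w(66L), cross_terms = cross_terms),
       P = network_spec(n_layers, w(150L), cross_terms = cross_terms),
       K = network_spec(n_layers, w(150L), cross_terms = cross_terms))
}

#' Assemble a model state
#'
#' Four networks approximate nondimensional concentration `c*(t*, x*)`,
#' observation noise `sigma(t*, x*)`, pressure `P*(x*)`, and permeability
#' `K*(x*)`. Two constraints are enforced by construction rather than by
#' loss terms: permeability is bounded via
#' `K* = C1 * exp(C2 * sigmoid(raw))` with `C1 = Kmax*` and
#' `C2 = log(Kmin*) - log(Kmax*)`, and the velocity
#' `u* = -K* grad(P*)` satisfies Darcy's law identically and is steady
#' because `P*` and `K*` take only spatial inputs.
#'
#' @param grid a [domain_grid()].
#' @param scales a [compute_scales()] result.
#' @param k_low,k_high intrinsic permeability bounds (mm^2) defining the
#'   nondimensional permeability band.
#' @param t_range time window of inference in minutes `c(t0, tf)`.
#' @param specs list of [network_spec()]s named `c`, `sigma`, `P`, `K`.
#' @param seed integer seed for parameter initialization.
#' @return object of class `model_state`.
#' @export
model_state <- function(grid, scales, k_low = 1e-10, k_high = 1e-6,
                        t_range = c(5, 90),
                        specs = default_network_specs(width_scale = 0.3,
                                                      n_layers = 3L),
                        seed = 1L) {
  mask <- grid$mask
  ijk <- arrayInd(which(mask), grid$shape)
  lo <- (apply(ijk, 2, min) - 1) * grid$spacing / scales$L_char
  hi <- apply(ijk, 2, max) * grid$spacing / scales$L_char
  t_star <- as.numeric(t_range) * 60 / scales$t_char
  box4 <- rbind(t_star, cbind(lo, hi))
  norm4 <- input_normalizer(box4)
  norm3 <- input_normalizer(box4[2:4, , drop = FALSE])
  Kmax_star <- (k_high / scales$viscosity) / scales$K_char
  Kmin_star <- (k_low / scales$viscosity) / scales$K_char
  stopifnot(Kmin_star < Kmax_star)
  nets <- list(
    c = mlp_init(4L, 1L, specs$c$n_layers, specs$c$n_neurons,
                 specs$c$feature_degree, isTRUE(specs$c$cross_terms),
                 seed = seed),
    sigma = mlp_init(4L, 1L, specs$sigma$n_layers, specs$sigma$n_neurons,
                     specs$sigma$feature_degree,
                     isTRUE(specs$sigma$cross_terms), seed = seed + 1L),
    P = mlp_init(3L, 1L, specs$P$n_layers, specs$P$n_neurons,
                 specs$P$feature_degree, isTRUE(specs$P$cross_terms),
                 seed = seed + 2L),
    K = mlp_init(3L, 1L, specs$K$n_layers, specs$K$n_neurons,
                 specs$K$feature_degree, isTRUE(specs$K$cross_terms),
                 seed = seed + 3L))
  structure(list(nets = nets, norm4 = norm4, norm3 = norm3,
                 K_min = Kmin_star, K_max = Kmax_star,
                 C1 = Kmax_star, C2 = log(Kmin_star) - log(Kmax_star),
                 t_range = t_range, scales = scales, grid = grid,
                 specs = specs, seed = as.integer(seed)),
            class = "model_state")
}

check_finite_state <- function(model) {
  for (nm in names(model$nets))
    if (!all(is.finite(net_params(model$nets[[nm]]))))
      stop("state error: non-finite parameters in network '", nm, "'")
  invisible(TRUE)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Evaluate the clean concentration field
#'
#' @param model a [model_state()].
#' @param tx_star n x 4 matrix of nondimensional `(t*, x*, y*, z*)` points.
#' @return numeric vector of nondimensional concentration `c*`.
#' @export
eval_concentration <- function(model, tx_star) {
  as.numeric(mlp_forward(model$nets$c, model$norm4$fwd(tx_star)))
}

#' Evaluate the learned observation-noise field
#'
#' Positivity is enforced by a softplus map with a `1e-6` floor.
#'
#' @inheritParams eval_concentration
#' @return strictly positive numeric vector (nondimensional units of `c*`).
#' @export
eval_noise <- function(model, tx_star) {
  raw <- as.numeric(mlp_forward(model$nets$sigma, model$norm4$fwd(tx_star)))
  softplus(raw) + 1e-6
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
softplus_grad <- function(x) 1 / (1 + exp(-x))

#' Evaluate the bounded nondimensional permeability
#'
#' `K* = C1 exp(C2 sigmoid(raw))`, guaranteed inside `(K_min, K_max)`.
#'
#' @param model a [model_state()].
#' @param x_star n x 3 matrix of nondimensional spatial points.
#' @export
eval_permeability <- function(model, x_star) {
  raw <- as.numeric(mlp_forward(model$nets$K, model$norm3$fwd(x_star)))
  model$C1 * exp(model$C2 * sigmoid(raw))
}

#' Evaluate the nondimensional pressure
#'
#' @inheritParams eval_permeability
#' @export
eval_pressure <- function(model, x_star) {
  as.numeric(mlp_forward(model$nets$P, model$norm3$fwd(x_star)))
}

#' Evaluate the nondimensional velocity
#'
#' `u* = -K* grad(P*)`, with the pressure gradient from the analytic
#' forward-mode Jacobian (`method = "analytic"`) or central finite
#' differences in starred coordinates (`method = "fd"`). Steady by
#' construction.
#'
#' @inheritParams eval_permeability
#' @param method `"analytic"` or `"fd"`.
#' @param h finite-difference step (starred units) for `method = "fd"`.
#' @return n x 3 matrix of `u*` components.
#' @export
eval_velocity <- function(model, x_star, method = c("analytic", "fd"),
                          h = 1e-3) {
  method <- match.arg(method)
  K <- eval_permeability(model, x_star)
  gP <- if (method == "analytic") {
    J <- mlp_jacobian(model$nets$P, model$norm3$fwd(x_star))
    sweep(matrix(J$jac[, 1L, ], ncol = 3L), 2L, model$norm3$dnorm_dstar, "*")
  } else {
    g <- matrix(0, nrow(x_star), 3L)
    for (ax in 1:3) {
      xp <- x_star; xp[, ax] <- xp[, ax] + h
      xn <- x_star; xn[, ax] <- xn[, ax] - h
      g[, ax] <- (eval_pressure(model, xp) - eval_pressure(model, xn)) / (2 * h)
    }
    g
  }
  if (is.null(dim(gP))) gP <- matrix(gP, ncol = 3L)
  -K * gP
}

#' Evaluate fields on the grid
#'
#' Convenience: evaluates concentration (at given times), velocity,
#' pressure and permeability at all mask voxel centers and returns them as
#' arrays in physical units.
#'
#' @param model a [model_state()].
#' @param times evaluation times in minutes (for the concentration).
#' @param what character subset of `c("concentration","velocity","pressure",
#'   "permeability")`.
#' @export
predict_fields <- function(model, times = NULL,
                           what = c("velocity", "permeability", "pressure")) {
  grid <- model$grid
  sc <- model$scales
  mask_idx <- which(grid$mask)
  Xs <- voxel_centers(grid, mask_idx) / sc$L_char
  out <- list()
  if ("velocity" %in% what) {
    u <- eval_velocity(model, Xs) * sc$U_char
    arr <- array(NA_real_, dim = c(grid$shape, 3L))
    for (ax in 1:3) {
      tmp <- array(NA_real_, dim = grid$shape)
      tmp[mask_idx] <- u[, ax]
      arr[, , , ax] <- tmp
    }
    out$velocity <- arr
  }
  if ("permeability" %in% what) {
    kk <- eval_permeability(model, Xs) * sc$K_char * sc$viscosity
    arr <- array(NA_real_, dim = grid$shape)
    arr[mask_idx] <- kk
    out$permeability <- arr   # intrinsic, mm^2
  }
  if ("pressure" %in% what) {
    pp <- eval_pressure(model, Xs) * sc$P_char
    arr <- array(NA_real_, dim = grid$shape)
    arr[mask_idx] <- pp
    out$pressure <- arr
  }
  if ("concentration" %in% what) {
    stopifnot(!is.null(times))
    vals <- array(NA_real_, dim = c(grid$shape, length(times)))
    for (k in seq_along(times)) {
      tx <- cbind(times[k] * 60 / sc$t_char, Xs)
      tmp <- array(NA_real_, dim = grid$shape)
      tmp[mask_idx] <- eval_concentration(model, tx) * sc$c_char
      vals[, , , k] <- tmp
    }
    out$concentration <- vals
  }
  out
}

#' Save / load a model checkpoint
#'
#' RDS containers are used (no R HDF5 binding is available in the target
#' environment); doubles round-trip bit-exactly.
#'
#' @param model a [model_state()].
#' @param path file path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
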