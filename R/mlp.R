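# Neural-field engine.
#
# No autodiff framework is available in this environment, so the network
# machinery is self-contained: dense tanh layers with weight normalization
# (direction/magnitude reparameterization W_j = g_j * V_j / ||V_j||),
# adaptive residual connections (a per-layer learnable gate alpha on the
# skip path, initialized at 0 so the stack starts identity-dominant),
# a polynomial feature expansion of the normalized inputs, hand-derived
# backpropagation for parameter gradients, and analytic forward-mode
# Jacobians for derivatives with respect to the inputs.

#' Polynomial feature expansion
#'
#' Per-coordinate powers `1..degree`, no cross terms, applied to inputs
#' already normalized to (-1, 1). Column order: all coordinates at power 1,
#' then power 2, and so on.
#'
#' @param x numeric matrix (n x d) of normalized coordinates (a vector is
#'   treated as one row).
#' @param degree highest power (>= 1); default 5.
#' @param cross append pairwise products `x_i x_j` (i < j); off by default.
#' @export
polynomial_features <- function(x, degree = 5L, cross = FALSE) {
  stopifnot(degree >= 1L)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  out <- do.call(cbind, lapply(seq_len(degree), function(p) x^p))
  if (cross && ncol(x) > 1L) {
    d <- ncol(x)
    pr <- utils::combn(d, 2L)
    out <- cbind(out, x[, pr[1, ], drop = FALSE] * x[, pr[2, ], drop = FALSE])
  }
  out
}

# d(features)/d(x_k): returns n x nfeat matrix for one input dim k
polyfeat_jac <- function(x, degree, k, cross = FALSE) {
  n <- nrow(x); d <- ncol(x)
  npair <- if (cross && d > 1L) ncol(utils::combn(d, 2L)) else 0L
  J <- matrix(0, n, d * degree + npair)
  for (p in seq_len(degree))
    J[, (p - 1L) * d + k] <- p * x[, k]^(p - 1L)
  if (npair > 0L) {
    pr <- utils::combn(d, 2L)
    for (q in seq_len(npair)) {
      i <- pr[1, q]; j <- pr[2, q]
      if (i == k) J[, d * degree + q] <- x[, j]
      else if (j == k) J[, d * degree + q] <- x[, i]
    }
  }
  J
}

colnorms <- function(V) sqrt(colSums(V * V))

wn_weight <- function(layer) {
  sweep(layer$V, 2L, layer$g / pmax(colnorms(layer$V), 1e-12), "*")
}

# gradient of loss wrt (V, g) given gradient wrt the effective weight W
wn_backward <- function(layer, dW) {
  nr <- pmax(colnorms(layer$V), 1e-12)
  vdW <- colSums(layer$V * dW)
  dg <- vdW / nr
  dV <- sweep(dW, 2L, layer$g / nr, "*") -
    sweep(layer$V, 2L, layer$g * vdW / nr^3, "*")
  list(dV = dV, dg = dg)
}

#' Initialize a tanh multilayer perceptron
#'
#' @param d_in input dimension (before feature expansion).
#' @param d_out output dimension.
#' @param n_layers number of hidden (adaptive residual) layers.
#' @param n_neurons neurons per hidden layer.
#' @param degree polynomial feature degree.
#' @param cross include pairwise cross-term features.
#' @param seed integer seed for fan-in-scaled Gaussian initialization.
#' @return an object of class `mlp`.
#' @export
mlp_init <- function(d_in, d_out = 1L, n_layers = 5L, n_neurons = 64L,
                     degree = 5L, cross = FALSE, seed = 1L) {
  stopifnot(n_layers >= 1L, n_neurons >= 1L)
  nf <- d_in * degree + if (cross && d_in > 1L) choose(d_in, 2L) else 0L
  with_seed(seed, {
    mk <- function(p, q) {
      V <- matrix(stats::rnorm(p * q, sd = sqrt(1 / p)), p, q)
      list(V = V, g = colnorms(V), b = numeric(q))
    }
    layers <- vector("list", n_layers)
    layers[[1]] <- mk(nf, n_neurons)
    if (n_layers > 1L)
      for (l in 2:n_layers) layers[[l]] <- mk(n_neurons, n_neurons)
    structure(list(layers = layers,
                   alpha = if (n_layers > 1L) numeric(n_layers - 1L)
                           else numeric(0),
                   head = mk(n_neurons, d_out),
                   d_in = d_in, d_out = d_out, degree = degree,
                   cross = cross,
                   n_layers = n_layers, n_neurons = n_neurons),
              class = "mlp")
  })
}

#' Evaluate an MLP on a batch
#'
#' @param net an [mlp_init()] network.
#' @param X n x d_in matrix of normalized inputs.
#' @param cache keep intermediate activations for [mlp_backward()].
#' @return matrix n x d_out, with attribute `cache` when requested.
#' @export
mlp_forward <- function(net, X, cache = FALSE) {
  if (is.null(dim(X))) X <- matrix(X, ncol = net$d_in)
  A0 <- polynomial_features(X, net$degree, isTRUE(net$cross))
  L <- net$n_layers
  n <- nrow(A0)
  addb <- function(Z, b) Z + rep(b, each = n)   # faster than sweep here
  W1 <- wn_weight(net$layers[[1]])
  H <- vector("list", L)
  A <- vector("list", L)
  H[[1]] <- tanh(addb(A0 %*% W1, net$layers[[1]]$b))
  A[[1]] <- H[[1]]
  if (L > 1L) for (l in 2:L) {
    Wl <- wn_weight(net$layers[[l]])
    H[[l]] <- tanh(addb(A[[l - 1]] %*% Wl, net$layers[[l]]$b))
    A[[l]] <- A[[l - 1]] + net$alpha[l - 1] * H[[l]]
  }
  Wh <- wn_weight(net$head)
  out <- addb(A[[L]] %*% Wh, net$head$b)
  if (cache) attr(out, "cache") <- list(A0 = A0, H = H, A = A, X = X)
  out
}

#' Backpropagate parameter gradients through an MLP
#'
#' @param net the network.
#' @param cache the `cache` attribute from `mlp_forward(..., cache = TRUE)`.
#' @param dOut n x d_out matrix of loss gradients at the outputs.
#' @return list mirroring the parameter structure (`layers`, `alpha`,
#'   `head`) holding gradients.
#' @export
mlp_backward <- function(net, cache, dOut) {
  L <- net$n_layers
  A <- cache$A; H <- cache$H; A0 <- cache$A0
  Alast <- A[[L]]
  Wh <- wn_weight(net$head)
  dWh <- t(Alast) %*% dOut
  dbh <- colSums(dOut)
  gh <- wn_backward(net$head, dWh)
  dA <- dOut %*% t(Wh)
  glayers <- vector("list", L)
  dalpha <- if (L > 1L) numeric(L - 1L) else numeric(0)
  if (L > 1L) for (l in L:2) {
    dalpha[l - 1] <- sum(dA * H[[l]])
    dZ <- (net$alpha[l - 1] * dA) * (1 - H[[l]]^2)
    Wl <- wn_weight(net$layers[[l]])
    dWl <- t(A[[l - 1]]) %*% dZ
    gl <- wn_backward(net$layers[[l]], dWl)
    glayers[[l]] <- list(V = gl$dV, g = gl$dg, b = colSums(dZ))
    dA <- dA + dZ %*% t(Wl)
  }
  dZ1 <- dA * (1 - H[[1]]^2)
  W1 <- wn_weight(net$layers[[1]])
  dW1 <- t(A0) %*% dZ1
  g1 <- wn_backward(net$layers[[1]], dW1)
  glayers[[1]] <- list(V = g1$dV, g = g1$dg, b = colSums(dZ1))
  list(layers = glayers, alpha = dalpha,
       head = list(V = gh$dV, g = gh$dg, b = dbh))
}

#' Analytic forward-mode Jacobian of an MLP with respect to its inputs
#'
#' Propagates exact first derivatives through the feature expansion and
#' every layer; used to evaluate velocity `u* = -K* grad P*` and to
#' cross-check the finite-difference stencils used during training.
#'
#' @param net the network.
#' @param X n x d_in matrix of normalized inputs.
#' @return list `out` (n x d_out) and `jac` (array n x d_out x d_in),
#'   derivatives with respect to the *normalized* inputs.
#' @export
mlp_jacobian <- function(net, X) {
  if (is.null(dim(X))) X <- matrix(X, ncol = net$d_in)
  n <- nrow(X); L <- net$n_layers
  out <- mlp_forward(net, X, cache = TRUE)
  cache <- attr(out, "cache")
  attr(out, "cache") <- NULL
  Ws <- lapply(net$layers, wn_weight)
  Wh <- wn_weight(net$head)
  jac <- array(0, dim = c(n, net$d_out, net$d_in))
  for (k in seq_len(net$d_in)) {
    Jl <- polyfeat_jac(X, net$degree, k, isTRUE(net$cross)) %*% Ws[[1]]
    Jl <- Jl * (1 - cache$H[[1]]^2)
    if (L > 1L) for (l in 2:L) {
      JZ <- Jl %*% Ws[[l]]
      Jl <- Jl + net$alpha[l - 1] * (JZ * (1 - cache$H[[l]]^2))
    }
    jac[, , k] <- Jl %*% Wh
  }
  list(out = out, jac = jac)
}

# ---- parameter flattening and Adam ----------------------------------------

net_params <- function(net) {
  as.numeric(unlist(list(net$layers, net$alpha, net$head),
                    use.names = FALSE))
}

# direct-slicing inverse of net_params (same traversal order)
net_set_params <- function(net, vec) {
  pos <- 0L
  take <- function(n) {
    out <- vec[(pos + 1L):(pos + n)]
    pos <<- pos + n
    out
  }
  for (l in seq_len(net$n_layers)) {
    net$layers[[l]]$V[] <- take(length(net$layers[[l]]$V))
    net$layers[[l]]$g[] <- take(length(net$layers[[l]]$g))
    net$layers[[l]]$b[] <- take(length(net$layers[[l]]$b))
  }
  if (net$n_layers > 1L) net$alpha[] <- take(length(net$alpha))
  net$head$V[] <- take(length(net$head$V))
  net$head$g[] <- take(length(net$head$g))
  net$head$b[] <- take(length(net$head$b))
  stopifnot(pos == length(vec))
  net
}

grad_flatten <- function(g)
  as.numeric(unlist(list(g$layers, g$alpha, g$head), use.names = FALSE))

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(state, grad, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  state$delta <- -lr * mhat / (sqrt(vhat) + eps)
  state
}
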