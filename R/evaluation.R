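#' Relative L2 error (percent)
#'
#' `100 * sqrt(sum((pred - ref)^2) / sum(ref^2))` over the mask, the
#' standard field-reconstruction error normalized by the reference norm.
#'
#' @param pred,ref numeric fields of equal shape (arrays or vectors).
#' @param mask optional logical selector.
#' @export
relative_l2 <- function(pred, ref, mask = NULL) {
  if (!is.null(mask)) { pred <- pred[mask]; ref <- ref[mask] }
  keep <- is.finite(pred) & is.finite(ref)
  pred <- pred[keep]; ref <- ref[keep]
  den <- sum(ref^2)
  if (den == 0) stop("reference field has zero norm; relative L2 undefined")
  100 * sqrt(sum((pred - ref)^2) / den)
}

#' Angular error between vector fields (degrees)
#'
#' Pointwise `arccos` of the cosine similarity (clamped to the unit range),
#' independent of magnitudes. Voxels where either speed is below
#' `speed_floor` are skipped and counted; by default the floor is
#' `1e-3 * median` reference speed, since direction is meaningless in
#' near-stagnant voxels.
#'
#' @param u_pred,u_ref n x 3 matrices (or 4D arrays with a `mask`).
#' @param mask logical array when inputs are 4D arrays.
#' @param speed_floor minimum speed; `NULL` for the default rule.
#' @return list `theta` (per-voxel degrees), `mean` (arithmetic mean),
#'   `n_skipped`.
#' @export
angular_error <- function(u_pred, u_ref, mask = NULL, speed_floor = NULL) {
  if (length(dim(u_pred)) == 4L) {
    stopifnot(!is.null(mask))
    u_pred <- field_to_mat(u_pred, mask)
    u_ref <- field_to_mat(u_ref, mask)
  }
  sp <- sqrt(rowSums(u_pred^2))
  sr <- sqrt(rowSums(u_ref^2))
  if (is.null(speed_floor))
    speed_floor <- 1e-3 * stats::median(sr[is.finite(sr)])
  ok <- is.finite(sp) & is.finite(sr) & sp >= speed_floor & sr >= speed_floor
  if (!any(ok)) stop("no voxels pass the speed floor")
  cosv <- rowSums(u_pred[ok, , drop = FALSE] * u_ref[ok, , drop = FALSE]) /
    (sp[ok] * sr[ok])
  th <- acos(pmin(pmax(cosv, -1), 1)) * 180 / pi
  list(theta = th, mean = mean(th), n_skipped = sum(!ok))
}

field_to_mat <- function(u, mask) {
  cbind(u[, , , 1][mask], u[, , , 2][mask], u[, , , 3][mask])
}

#' 1-Wasserstein distance between empirical distributions
#'
#' Sorted-sample (quantile-coupling) formulation of the earth mover's
#' distance on the line; unequal sample sizes are handled by evaluating
#' both empirical quantile functions on a common uniform grid.
#'
#' @param a,b numeric samples.
#' @param n_quad quadrature points when lengths differ.
#' @export
wasserstein_1d <- function(a, b, n_quad = 1000L) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) == 0 || length(b) == 0) stop("empty samples")
  if (length(a) == length(b)) return(mean(abs(sort(a) - sort(b))))
  p <- (seq_len(n_quad) - 0.5) / n_quad
  qa <- stats::quantile(a, p, type = 1, names = FALSE)
  qb <- stats::quantile(b, p, type = 1, names = FALSE)
  mean(abs(qa - qb))
}

#' Local Peclet number field
#'
#' Ratio of time-averaged advective to diffusive transport magnitudes,
#' `Pe = mean_t|u . grad c| / mean_t|D lap c|` per voxel (the default
#' "ratio of averages" reading; `average_of_ratios = TRUE` averages the
#' per-time ratio instead). The denominator is floored at `1e-3` times its
#' median positive value to avoid division by vanishing Laplacians.
#'
#' @param u 4D velocity array (mm/s).
#' @param series a [conc_series()].
#' @param D diffusivity (mm^2/s).
#' @param mask optional logical array.
#' @param average_of_ratios alternative overline placement.
#' @return 3D array of local Peclet numbers (`NA` outside mask).
#' @export
local_peclet <- function(u, series, D, mask = NULL,
                         average_of_ratios = FALSE) {
  if (is.null(mask)) mask <- series$mask
  h <- series$grid$spacing
  nt <- length(series$times)
  shape <- series$grid$shape
  num <- array(0, dim = shape)
  den <- array(0, dim = shape)
  rat <- array(0, dim = shape)
  uu <- u; uu[is.na(uu)] <- 0
  for (k in seq_len(nt)) {
    ck <- series$values[, , , k]
    g <- grad_field(ck, h, mask)
    adv <- abs(uu[, , , 1] * g[, , , 1] + uu[, , , 2] * g[, , , 2] +
                 uu[, , , 3] * g[, , , 3])
    dif <- abs(D * laplacian_field(ck, h, mask))
    num <- num + adv
    den <- den + dif
    if (average_of_ratios) {
      med <- stats::median(dif[mask & dif > 0])
      rat <- rat + adv / pmax(dif, 1e-3 * med)
    }
  }
  out <- if (average_of_ratios) rat / nt else {
    medden <- stats::median(den[mask & den > 0]) / nt
    (num / nt) / pmax(den / nt, 1e-3 * medden)
  }
  out[!mask] <- NA_real_
  out
}

#' Speed distribution and modality report
#'
#' Kernel density of `log10` speed over the mask with a local-maxima count;
#' used to check the bimodal (parenchyma vs open-conduit) structure of the
#' inferred velocity magnitude.
#'
#' @param u 4D velocity array or n x 3 matrix.
#' @param mask logical array (for the 4D case).
#' @param floor speeds below this are dropped (default: 1e-6 of max).
#' @param bw density bandwidth passed to [stats::density()].
#' @param min_prominence modes are maxima exceeding neighboring minima by
#'   this fraction of the peak density.
#' @return list `density`, `modes` (log10-speed locations), `n_modes`.
#' @export
speed_pdf <- function(u, mask = NULL, floor = NULL, bw = "nrd0",
                      min_prominence = 0.05) {
  sp <- if (length(dim(u)) == 4L) {
    stopifnot(!is.null(mask))
    sqrt(u[, , , 1][mask]^2 + u[, , , 2][mask]^2 + u[, , , 3][mask]^2)
  } else sqrt(rowSums(u^2))
  sp <- sp[is.finite(sp)]
  if (is.null(floor)) floor <- 1e-6 * max(sp)
  sp <- sp[sp > floor]
  if (length(sp) < 10L) stop("too few positive speeds after flooring")
  d <- stats::density(log10(sp), bw = bw)
  y <- d$y
  n <- length(y)
  mx <- which(diff(sign(diff(y))) == -2) + 1L   # interior local maxima
  thr <- min_prominence * max(y)
  keep <- logical(length(mx))
  for (j in seq_along(mx)) {
    i <- mx[j]
    # valley depth toward the nearest taller density on each side
    valley_l <- if (j > 1) min(y[mx[j - 1]:i]) else min(y[1:i])
    valley_r <- if (j < length(mx)) min(y[i:mx[j + 1]]) else min(y[i:n])
    prominence <- y[i] - max(min(valley_l, valley_r), 0)
    keep[j] <- y[i] >= thr && prominence >= thr
  }
  modes <- d$x[mx[keep]]
  if (length(modes) > 1) modes <- modes[c(TRUE, diff(modes) > 2 * d$bw)]
  list(density = d, modes = modes, n_modes = length(modes))
}

#' Ensemble summary and epistemic uncertainty
#'
#' Voxelwise mean speed, speed SD and relative uncertainty
#' `sigma_|u| / mean|u|` across ensemble members trained from different
#' initial permeability guesses, plus the fraction of the domain with
#' relative uncertainty below 100%.
#'
#' @param speeds list (>= 2) of 3D speed arrays or of 4D velocity arrays
#'   on identical grids.
#' @param mask logical array.
#' @return object of class `ensemble_summary`.
#' @export
ensemble_uncertainty <- function(speeds, mask) {
  if (length(speeds) < 2L) stop("need at least 2 ensemble members")
  as_speed <- function(u) {
    if (length(dim(u)) == 4L)
      sqrt(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2)
    else u
  }
  sp <- lapply(speeds, as_speed)
  d0 <- dim(sp[[1]])
  for (s in sp) if (!identical(dim(s), d0)) stop("mismatched grids")
  arr <- simplify2array(sp)
  mu <- apply(arr, 1:3, mean)
  # population SD across members (an m-member ensemble is the whole
  # population of fits, not a sample from one)
  sdv <- sqrt(apply(arr, 1:3, function(v) mean((v - mean(v))^2)))
  rel <- sdv / pmax(mu, .Machine$double.eps)
  mu[!mask] <- NA_real_; sdv[!mask] <- NA_real_; rel[!mask] <- NA_real_
  structure(list(mean_speed = mu, sd_speed = sdv, relative = rel,
                 n_members = length(speeds),
                 frac_below_100 = mean(rel[mask] < 1, na.rm = TRUE)),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("<ensemble_summary: %d members, %.1f%% of domain below 100%% relative uncertainty>\n",
              x$n_members, 100 * x$frac_below_100))
  invisible(x)
}

#' Field-metric report for a prediction against ground truth
#'
#' @param u_pred,u_ref 4D velocity arrays (mm/s).
#' @param mask logical array.
#' @param err_threshold pointwise relative-magnitude error threshold for
#'   the coverage statistic (default 0.25).
#' @return list: `speed_rl2` (%), `mean_angular` (deg), `wasserstein`
#'   (per-component W1), `coverage_below` (fraction of voxels with
#'   pointwise relative speed error below the threshold).
#' @export
field_metrics <- function(u_pred, u_ref, mask, err_threshold = 0.25) {
  sp <- sqrt(u_pred[, , , 1]^2 + u_pred[, , , 2]^2 + u_pred[, , , 3]^2)
  sr <- sqrt(u_ref[, , , 1]^2 + u_ref[, , , 2]^2 + u_ref[, , , 3]^2)
  rl2 <- relative_l2(sp, sr, mask)
  ang <- angular_error(u_pred, u_ref, mask)
  wd <- vapply(1:3, function(ax)
    wasserstein_1d(u_pred[, , , ax][mask], u_ref[, , , ax][mask]), numeric(1))
  ptrel <- abs(sp - sr) / pmax(sr, .Machine$double.eps)
  cov <- mean(ptrel[mask] < err_threshold, na.rm = TRUE)
  list(speed_rl2 = rl2, mean_angular = ang$mean, wasserstein = wd,
       coverage_below = cov)
}
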