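#' Material constants of the fluid and tissue
#'
#' Defaults are water at 37 C for density and viscosity, the gadobutrol
#' diffusion coefficient used throughout the domain, the free diffusion
#' coefficient of a comparable gadolinium chelate, and the repeatedly
#' measured extracellular-space tortuosity.
#'
#' @param density kg/m^3.
#' @param viscosity Pa s.
#' @param D working diffusivity, mm^2/s.
#' @param D_free free diffusivity, mm^2/s.
#' @param tortuosity dimensionless, >= 1.
#' @export
material_constants <- function(density = 993, viscosity = 6.95e-4,
                               D = 2.4e-4, D_free = 3.8e-4,
                               tortuosity = 1.6) {
  stopifnot(density > 0, viscosity > 0, D > 0, D_free > 0, tortuosity >= 1)
  structure(list(density = density, viscosity = viscosity, D = D,
                 D_free = D_free, tortuosity = tortuosity),
            class = "material_constants")
}

#' Effective diffusivity in a porous medium
#'
#' `D_eff = D_free / lambda^2`, the tortuosity correction for diffusion in
#' the extracellular space.
#'
#' @param D_free free diffusivity (mm^2/s).
#' @param tortuosity dimensionless tortuosity lambda (>= 1).
#' @export
effective_diffusivity <- function(D_free, tortuosity) {
  stopifnot(tortuosity >= 1, D_free > 0)
  D_free / tortuosity^2
}

#' Signal enhancement ratio
#'
#' `SER = (S_t - S_0) / S_0 * 100`, the percentage enhancement of the
#' T1-weighted signal over baseline, used as a linear proxy for tracer
#' concentration. Voxels with non-positive baseline are artifacts; they are
#' masked out (`NA`) rather than clipped, and their count is reported via
#' attribute `n_bad_baseline`.
#'
#' @param S_t signal volume (3D array).
#' @param S_0 baseline signal volume, same shape.
#' @export
compute_ser <- function(S_t, S_0) {
  if (!identical(dim(S_t), dim(S_0))) stop("input error: shape mismatch")
  bad <- !is.finite(S_0) | S_0 <= 0
  out <- (S_t - S_0) / S_0 * 100
  out[bad] <- NA_real_
  attr(out, "n_bad_baseline") <- sum(bad)
  out
}

#' Smooth a volume with the standard acquisition kernel
#'
#' Separable 3x3x3 convolution with per-axis weights `[0.2, 1, 0.2]`
#' (normalized by 1.4), the kernel applied to the imaging series to damp
#' registration artifacts. Near mask/array boundaries the kernel is
#' renormalized over its in-mask support, so constants are preserved.
#'
#' @param v 3D array.
#' @param mask optional logical array restricting support.
#' @export
smooth_volume <- function(v, mask = NULL) {
  stopifnot(length(dim(v)) == 3L)
  w <- c(0.2, 1, 0.2) / 1.4
  num <- v
  den <- array(1, dim = dim(v))
  if (!is.null(mask)) {
    num[!mask] <- 0
    den[!mask] <- 0
  }
  conv_axis <- function(x, axis) {
    w[2] * x + w[1] * shift_arr_zero(x, axis, +1L) +
      w[3] * shift_arr_zero(x, axis, -1L)
  }
  for (ax in 1:3) {
    num <- conv_axis(num, ax)
    den <- conv_axis(den, ax)
  }
  out <- num / pmax(den, .Machine$double.eps)
  if (!is.null(mask)) out[!mask] <- v[!mask]
  out
}

# shift with zero fill (helper for smooth_volume edge renormalization)
shift_arr_zero <- function(a, axis, step) {
  d <- dim(a); n <- d[axis]
  out <- array(0, dim = d)
  if (step > 0) { dst <- (1 + step):n; src <- 1:(n - step) }
  else { dst <- 1:(n + step); src <- (1 - step):n }
  if (axis == 1L) out[dst, , ] <- a[src, , ]
  else if (axis == 2L) out[, dst, ] <- a[, src, ]
  else out[, , dst] <- a[, , src]
  out
}

#' Exclusion mask from temporal signal variation
#'
#' Excludes voxels the tracer never reached: those whose signal range over
#' the whole series is less than three times the range over the baseline
#' scans. Caller-supplied anatomical exclusions (infusion site, ventricles,
#' outside-brain) are OR-ed in; no inference is attempted there.
#'
#' @param series a [conc_series()] of SER (or signal) volumes.
#' @param baseline_count number of leading baseline scans (>= 2).
#' @param factor threshold multiplier (default 3).
#' @param extra_exclude optional logical array of anatomical exclusions.
#' @return logical array, `TRUE` = excluded. Attribute `analysis_mask`
#'   holds `series$mask & !excluded`.
#' @export
build_exclusion_mask <- function(series, baseline_count = 3L, factor = 3,
                                 extra_exclude = NULL) {
  nt <- length(series$times)
  if (baseline_count < 2L) stop("baseline_count must be >= 2")
  if (baseline_count >= nt)
    stop("input error: baseline_count must be smaller than the number of scans")
  v <- series$values
  rng_all <- apply(v, 1:3, function(x) diff(range(x)))
  rng_base <- apply(v[, , , seq_len(baseline_count), drop = FALSE], 1:3,
                    function(x) diff(range(x)))
  excl <- rng_all < factor * rng_base
  # zero baseline range: threshold 0, any positive change retains the voxel
  excl[rng_base == 0 & rng_all > 0] <- FALSE
  excl[rng_base == 0 & rng_all == 0] <- TRUE   # flat signal: never reached
  if (!is.null(extra_exclude)) excl <- excl | extra_exclude
  excl[!series$mask] <- TRUE
  attr(excl, "analysis_mask") <- series$mask & !excl
  excl
}

#' Normalize a series to the 0-100 concentration-proxy scale
#'
#' Divides by the global maximum over the analysis mask and multiplies by
#' 100; the normalization constant is kept in `c_norm` metadata so values
#' can be round-tripped.
#'
#' @param series a [conc_series()].
#' @export
normalize_concentration <- function(series) {
  m <- 0
  for (k in seq_along(series$times))
    m <- max(m, max(series$values[, , , k][series$mask]))
  if (m <= 0) stop("series has no positive signal inside the mask")
  out <- conc_series(series$values / m * 100, series$times, series$grid,
                     series$mask)
  out$c_norm <- m
  out
}

#' Early-arrival initial permeability guess
#'
#' Voxels the tracer reaches quickly (proxy concentration exceeding
#' `ser_threshold` at or before `arrival_time`) are assigned `k_high` (the
#' effective permeability of an open 6-um conduit); all others `k_low`.
#' The binary map is Gaussian-smoothed (SD 1 voxel for a "sharp" prior,
#' 3 voxels for a "smooth" one) and rescaled so its maximum returns to
#' `k_high`, exactly as the synthetic generator treats its maps.
#'
#' @param series a [conc_series()] on the SER (percent) scale.
#' @param ser_threshold arrival threshold in percent (default 150).
#' @param arrival_time arrival window in minutes (default 16).
#' @param k_high,k_low permeability bounds (mm^2).
#' @param smoothing_sd_voxels Gaussian SD in voxels (1 = sharp, 3 = smooth).
#' @return 3D intrinsic-permeability array (mm^2).
#' @export
initial_permeability_guess <- function(series, ser_threshold = 150,
                                       arrival_time = 16,
                                       k_high = 1e-6, k_low = 1e-10,
                                       smoothing_sd_voxels = 3) {
  stopifnot(ser_threshold > 0, arrival_time > 0)
  if (max(series$times) < arrival_time)
    stop("series does not cover the arrival window")
  sel_t <- which(series$times <= arrival_time)
  reached <- array(FALSE, dim = series$grid$shape)
  for (k in sel_t)
    reached <- reached | (series$values[, , , k] >= ser_threshold)
  reached <- reached & series$mask
  if (!any(reached))
    warning("no voxel passes the arrival threshold; returning an all-low map")
  kmap <- array(k_low, dim = series$grid$shape)
  kmap[reached] <- k_high
  if (smoothing_sd_voxels > 0 && any(reached)) {
    kmap <- gauss_smooth3d(kmap, smoothing_sd_voxels)
    kmap <- kmap * (k_high / max(kmap[series$mask]))
  }
  kmap
}

#' Sparse velocity prior from front tracking
#'
#' Tracks iso-concentration fronts through time: at voxels lying on an
#' iso-surface (the level passes within half a voxel along the local
#' gradient) with gradient magnitude at least `min_gradient`, the normal
#' front speed is `v_n = -(dc/dt) / |grad c|` and the vector estimate
#' `v_n * grad(c)/|grad c|`. Diffusion is neglected, so estimates are
#' biased where diffusion dominates transport. Estimates from all levels
#' and all time pairs are pooled per voxel under the steady-flow assumption
#' using gradient-magnitude confidence weights.
#'
#' @param series a [conc_series()].
#' @param iso_levels concentration levels to track; default: 5 levels
#'   between the 30% and 90% quantiles of positive in-mask values.
#' @param min_gradient minimum `|grad c|` (concentration units per mm);
#'   default 5% of the maximum observed gradient magnitude.
#' @param mask optional analysis mask.
#' @param diffusivity if supplied (mm^2/s), the diffusive part of the
#'   front motion is subtracted: `v_n = -(c_t - D lap c)/|grad c|`, which
#'   estimates the advective normal speed exactly under the transport
#'   equation. `NULL` gives the classical uncorrected tracker, which
#'   reports diffusive spreading as outward flow.
#' @return object of class `velocity_prior`: `locations` (n x 3 voxel
#'   indices), `vectors` (n x 3, mm/s), `confidence` (n), `linear` (voxel
#'   linear indices).
#' @export
front_track_velocity <- function(series, iso_levels = NULL,
                                 min_gradient = NULL, mask = NULL,
                                 diffusivity = NULL) {
  nt <- length(series$times)
  if (nt < 2L) stop("need at least two time points")
  if (is.null(mask)) mask <- series$mask
  grid <- series$grid
  h <- grid$spacing
  if (is.null(iso_levels)) {
    pos <- numeric(0)
    for (k in seq_len(nt)) {
      v <- series$values[, , , k][mask]
      pos <- c(pos, v[v > 0])
    }
    if (length(pos) == 0) stop("series has no positive values to track")
    iso_levels <- as.numeric(stats::quantile(pos, c(0.3, 0.45, 0.6, 0.75, 0.9)))
  }
  npx <- prod(grid$shape)
  acc_v <- matrix(0, npx, 3)
  acc_w <- numeric(npx)
  gmax <- 0
  snaps <- vector("list", nt)
  grads <- vector("list", nt)
  for (k in seq_len(nt)) {
    snaps[[k]] <- series$values[, , , k]
    grads[[k]] <- grad_field(snaps[[k]], h, mask)
    gm <- sqrt(grads[[k]][, , , 1]^2 + grads[[k]][, , , 2]^2 +
                 grads[[k]][, , , 3]^2)
    gmax <- max(gmax, max(gm[mask], na.rm = TRUE))
    grads[[k]] <- list(g = grads[[k]], gm = gm)
  }
  if (is.null(min_gradient)) min_gradient <- 0.05 * gmax
  ks <- if (nt >= 3L) 2:(nt - 1) else 1L
  for (k in ks) {
    if (nt >= 3L) {
      dt_s <- (series$times[k + 1] - series$times[k - 1]) * 60
      ct <- (snaps[[k + 1]] - snaps[[k - 1]]) / dt_s
    } else {
      dt_s <- (series$times[2] - series$times[1]) * 60
      ct <- (snaps[[2]] - snaps[[1]]) / dt_s
    }
    if (!is.null(diffusivity))
      ct <- ct - diffusivity * laplacian_field(snaps[[k]], h, mask)
    gm <- grads[[k]]$gm
    for (lev in iso_levels) {
      on_front <- mask & is.finite(gm) & gm >= min_gradient &
        abs(snaps[[k]] - lev) <= 0.5 * gm * h
      if (!any(on_front)) next
      sel <- which(on_front)
      vn <- -ct[sel] / gm[sel]
      for (ax in 1:3) {
        acc_v[sel, ax] <- acc_v[sel, ax] +
          gm[sel] * vn * grads[[k]]$g[, , , ax][sel] / gm[sel]
      }
      acc_w[sel] <- acc_w[sel] + gm[sel]
    }
  }
  keep <- which(acc_w > 0)
  if (length(keep) == 0) {
    warning("all gradients below threshold; empty velocity prior")
    return(structure(list(locations = matrix(0L, 0, 3),
                          vectors = matrix(0, 0, 3), confidence = numeric(0),
                          linear = integer(0), grid = grid),
                     class = "velocity_prior"))
  }
  vec <- acc_v[keep, , drop = FALSE] / acc_w[keep]
  structure(list(locations = arrayInd(keep, grid$shape),
                 vectors = vec, confidence = acc_w[keep],
                 linear = keep, grid = grid),
            class = "velocity_prior")
}

#' @export
print.velocity_prior <- function(x, ...) {
  cat(sprintf("<velocity_prior: %d voxels, median speed %.3g mm/s>\n",
              nrow(x$vectors),
              if (nrow(x$vectors)) stats::median(sqrt(rowSums(x$vectors^2)))
              else NA_real_))
  invisible(x)
}
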