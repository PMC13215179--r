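#' Spatial domain grid for voxelized fields
#'
#' A `domain_grid` describes the voxel lattice every field in the package
#' lives on: the array shape, the isotropic voxel spacing in mm, a logical
#' interior mask, and inlet/outlet boundary labels used by the Darcy solver.
#' Voxel centers sit at `(index - 0.5) * spacing` (0-based faces), with the
#' x, y, z axes corresponding to array dimensions 1, 2, 3.
#'
#' @param shape integer vector of length 3, voxels per axis.
#' @param spacing voxel edge length in mm (isotropic, > 0).
#' @param mask logical array of dimension `shape` marking the interior
#'   domain; default all `TRUE`.
#' @param inlet,outlet logical arrays of dimension `shape` (or `NULL`)
#'   tagging boundary voxels that carry Dirichlet pressure values. They must
#'   be disjoint, inside the mask, and on the mask boundary.
#' @return an object of class `domain_grid`.
#' @export
domain_grid <- function(shape, spacing, mask = NULL, inlet = NULL,
                        outlet = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 2L))
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("`spacing` must be a single positive number (mm per voxel)")
  if (is.null(mask)) mask <- array(TRUE, dim = shape)
  mask <- array(as.logical(mask), dim = shape)
  if (!any(mask)) stop("domain error: mask is empty")
  z <- array(FALSE, dim = shape)
  if (is.null(inlet)) inlet <- z
  if (is.null(outlet)) outlet <- z
  inlet <- array(as.logical(inlet), dim = shape)
  outlet <- array(as.logical(outlet), dim = shape)
  if (any(inlet & outlet)) stop("inlet and outlet voxel sets must be disjoint")
  if (any((inlet | outlet) & !mask))
    stop("inlet/outlet voxels must lie inside the mask")
  bnd <- mask_boundary(mask)
  if (any((inlet | outlet) & !bnd))
    stop("inlet/outlet voxels must lie on the mask boundary")
  structure(list(shape = shape, spacing = spacing, mask = mask,
                 inlet = inlet, outlet = outlet),
            class = "domain_grid")
}

#' @export
print.domain_grid <- function(x, ...) {
  cat(sprintf("<domain_grid %dx%dx%d, %.4g mm/voxel, %d mask voxels, %d inlet, %d outlet>\n",
              x$shape[1], x$shape[2], x$shape[3], x$spacing,
              sum(x$mask), sum(x$inlet), sum(x$outlet)))
  invisible(x)
}

#' Full-box grid with inlet/outlet patches on opposite x faces
#'
#' Convenience constructor used by the synthetic cases: a box-shaped mask
#' whose `x = 1` face carries a centered inlet patch and whose `x = nx` face
#' a centered outlet patch.
#'
#' @param shape integer triple.
#' @param spacing mm per voxel.
#' @param patch_frac fraction of each face edge covered by the patch.
#' @export
box_grid <- function(shape, spacing = 0.1, patch_frac = 0.5) {
  shape <- as.integer(shape)
  z <- array(FALSE, dim = shape)
  idx <- function(n) {
    w <- max(1L, round(n * patch_frac))
    lo <- max(1L, floor((n - w) / 2) + 1L)
    lo:min(n, lo + w - 1L)
  }
  inlet <- z; inlet[1L, idx(shape[2]), idx(shape[3])] <- TRUE
  outlet <- z; outlet[shape[1], idx(shape[2]), idx(shape[3])] <- TRUE
  domain_grid(shape, spacing, inlet = inlet, outlet = outlet)
}

# Voxels of `mask` touching the outside (array edge or an unmasked neighbor).
mask_boundary <- function(mask) {
  d <- dim(mask)
  pad <- array(FALSE, dim = d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  inner <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  mask & !inner
}

# Shift an array by one voxel along `axis`. `step = -1` returns the value
# at index + 1 and vice versa. `fill = "edge"` replicates the edge slab;
# any other value (NA, FALSE, 0) is placed beyond the array boundary.
shift_arr <- function(a, axis, step, fill = "edge") {
  d <- dim(a)
  n <- d[axis]
  src <- seq_len(n) - step
  if (identical(fill, "edge")) {
    src <- pmin(pmax(src, 1L), n)
    return(switch(axis, a[src, , , drop = FALSE], a[, src, , drop = FALSE],
                  a[, , src, drop = FALSE]))
  }
  ok <- src >= 1L & src <= n
  src2 <- pmin(pmax(src, 1L), n)
  out <- switch(axis, a[src2, , , drop = FALSE], a[, src2, , drop = FALSE],
                a[, , src2, drop = FALSE])
  if (any(!ok)) {
    if (axis == 1L) out[!ok, , ] <- fill
    else if (axis == 2L) out[, !ok, ] <- fill
    else out[, , !ok] <- fill
  }
  out
}

#' Central-difference gradient of a 3D scalar field
#'
#' One-sided differences are used at array edges and at mask boundaries
#' (values outside the mask never enter the stencil).
#'
#' @param f 3D numeric array.
#' @param spacing voxel spacing (same units as the desired denominator).
#' @param mask optional logical array; outside voxels are excluded from
#'   stencils and get `NA` gradients.
#' @return 4D array `dim = c(dim(f), 3)` of d f / d x_k.
#' @export
grad_field <- function(f, spacing, mask = NULL) {
  d <- dim(f)
  if (is.null(mask)) mask <- array(TRUE, dim = d)
  g <- array(NA_real_, dim = c(d, 3L))
  fm <- f; fm[!mask] <- NA_real_
  for (ax in 1:3) {
    fp <- shift_arr(fm, ax, -1L, fill = NA)   # value at index + 1
    fn <- shift_arr(fm, ax, +1L, fill = NA)   # value at index - 1
    okp <- !is.na(fp); okn <- !is.na(fn)
    # central where both neighbors valid, one-sided otherwise
    num <- ifelse(okp & okn, (fp - fn) / (2 * spacing),
                  ifelse(okp, (fp - fm) / spacing,
                         ifelse(okn, (fm - fn) / spacing, 0)))
    num[!mask] <- NA_real_
    g[, , , ax] <- num
  }
  g
}

#' Discrete Laplacian of a 3D scalar field
#'
#' Standard 7-point stencil with homogeneous Neumann closure at mask/array
#' boundaries (missing neighbors are mirrored).
#'
#' @inheritParams grad_field
#' @export
laplacian_field <- function(f, spacing, mask = NULL) {
  d <- dim(f)
  if (is.null(mask)) mask <- array(TRUE, dim = d)
  fm <- f; fm[!mask] <- NA_real_
  out <- array(0, dim = d)
  for (ax in 1:3) {
    fp <- shift_arr(fm, ax, -1L, fill = NA)
    fn <- shift_arr(fm, ax, +1L, fill = NA)
    fp[is.na(fp)] <- fm[is.na(fp)]  # mirror: no flux through boundary
    fn[is.na(fn)] <- fm[is.na(fn)]
    out <- out + (fp - 2 * fm + fn) / spacing^2
  }
  out[!mask] <- NA_real_
  out
}

# Evaluate a function with a temporary, isolated RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# World coordinates (mm) of all voxel centers, n x 3 matrix.
voxel_centers <- function(grid, which = NULL) {
  d <- grid$shape
  if (is.null(which)) which <- seq_len(prod(d))
  ijk <- arrayInd(which, d)
  (ijk - 0.5) * grid$spacing
}
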