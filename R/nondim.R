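#' Characteristic scales for nondimensionalization
#'
#' The governing equations are solved in nondimensional (starred) form:
#' physical quantities span many orders of magnitude (permeability alone
#' covers four decades) and raw-scale optimization loses small terms to
#' floating-point error. Scales are defined by:
#' `L_char` = largest mask extent; `K_char` = max hydraulic permeability of
#' the prior (`max(kappa)/mu`); `c_char` = max concentration;
#' `U_char = K_char * P_char / L_char`; `t_char = L_char / U_char`;
#' `Pe_g = U_char * L_char / D` (the global Peclet number).
#'
#' `P_char` is a free gauge: scaling the permeability prior by `a` while
#' dividing `P_char` by `a` leaves every starred equation, the inferred
#' velocity, and `Pe_g` unchanged, so absolute pressure/permeability are
#' identifiable only up to this factor. The default 1000 Pa is the order of
#' magnitude of intracranial pressure differences.
#'
#' @param grid a [domain_grid()].
#' @param constants a [material_constants()].
#' @param k_prior intrinsic permeability prior (mm^2).
#' @param c_series a [conc_series()] (for `c_char`).
#' @param p_char characteristic pressure (Pa).
#' @return object of class `nondim_scales` with fields `L_char` (mm),
#'   `t_char` (s), `c_char`, `U_char` (mm/s), `K_char` (mm^2 Pa^-1 s^-1),
#'   `P_char` (Pa), `Pe_g`.
#' @export
compute_scales <- function(grid, constants, k_prior, c_series,
                           p_char = 1000) {
  stopifnot(p_char > 0)
  mask <- grid$mask
  if (!any(mask)) stop("domain error: zero-extent mask")
  ijk <- arrayInd(which(mask), grid$shape)
  ext <- apply(ijk, 2, function(v) diff(range(v)) + 1L) * grid$spacing
  L_char <- max(ext)
  K_char <- max(k_prior[mask]) / constants$viscosity
  c_char <- c_series$c_char
  U_char <- K_char * p_char / L_char
  t_char <- L_char / U_char
  Pe_g <- U_char * L_char / constants$D
  structure(list(L_char = L_char, t_char = t_char, c_char = c_char,
                 U_char = U_char, K_char = K_char, P_char = p_char,
                 Pe_g = Pe_g, D = constants$D,
                 viscosity = constants$viscosity),
            class = "nondim_scales")
}

#' @export
print.nondim_scales <- function(x, ...) {
  cat(sprintf(paste0("<nondim_scales L=%.3g mm, t=%.3g s, c=%.3g, ",
                     "U=%.3g mm/s, K=%.3g mm^2/(Pa s), P=%.3g Pa, Pe_g=%.3g>\n"),
              x$L_char, x$t_char, x$c_char, x$U_char, x$K_char, x$P_char,
              x$Pe_g))
  invisible(x)
}

scale_for <- function(scales, quantity) {
  switch(quantity,
         length = scales$L_char,
         time = scales$t_char,          # seconds
         concentration = scales$c_char,
         velocity = scales$U_char,
         permeability = scales$K_char,  # hydraulic
         pressure = scales$P_char,
         stop("type error: unknown quantity '", quantity, "'"))
}

#' Convert a field to nondimensional (starred) form
#'
#' `to_nondim` divides by the characteristic scale of `quantity` and tags
#' the result; [to_physical()] is its exact inverse. Converting a field
#' that is already starred (or already physical) is a type error.
#'
#' @param x numeric field (any shape).
#' @param scales a [compute_scales()] result.
#' @param quantity one of `"length"`, `"time"`, `"concentration"`,
#'   `"velocity"`, `"permeability"` (hydraulic), `"pressure"`.
#' @export
to_nondim <- function(x, scales, quantity) {
  if (isTRUE(attr(x, "starred"))) stop("type error: field is already nondimensional")
  out <- x / scale_for(scales, quantity)
  attr(out, "starred") <- TRUE
  attr(out, "quantity") <- quantity
  out
}

#' @rdname to_nondim
#' @export
to_physical <- function(x, scales, quantity = NULL) {
  if (!isTRUE(attr(x, "starred")))
    stop("type error: field is not tagged nondimensional")
  if (is.null(quantity)) quantity <- attr(x, "quantity")
  if (!is.null(attr(x, "quantity")) && !identical(quantity, attr(x, "quantity")))
    stop("type error: unit mismatch (field tagged '", attr(x, "quantity"), "')")
  out <- x * scale_for(scales, quantity)
  attr(out, "starred") <- NULL
  attr(out, "quantity") <- NULL
  out
}

# Affine map of starred spatial/temporal coordinates into (-1, 1) per axis,
# the input normalization required by tanh networks. `box` rows are
# (lo, hi) in starred units for t*, x*, y*, z*.
input_normalizer <- function(box) {
  ctr <- rowMeans(box)
  hw <- (box[, 2] - box[, 1]) / 2
  hw[hw == 0] <- 1
  list(center = ctr, halfwidth = hw,
       fwd = function(X) sweep(sweep(X, 2, ctr, "-"), 2, hw, "/"),
       # derivative of normalized coords w.r.t. starred coords
       dnorm_dstar = 1 / hw)
}
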