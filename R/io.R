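# File carriers.
#
# Volumes travel as single-file NIfTI-1 (.nii). No R NIfTI package is
# available in the target environment, so a minimal reader/writer for the
# fixed 348-byte NIfTI-1 header is implemented here (float64 data,
# little-endian, mm/sec units, diagonal sform); the test suite cross-checks
# round trips against Python nibabel as an independent oracle. Structured
# bundles (ground-truth cases, checkpoints) use RDS in place of HDF5, for
# which no R binding is preinstalled either.

#' Write a 3D/4D volume as NIfTI-1
#'
#' @param x 3D or 4D numeric array.
#' @param path output `.nii` path.
#' @param spacing isotropic voxel spacing in mm.
#' @param dt time step between 4th-dimension frames, in seconds (4D only).
#' @export
write_volume <- function(x, path, spacing, dt = 0) {
  nd <- length(dim(x))
  stopifnot(nd %in% c(3L, 4L), spacing > 0)
  d <- dim(x)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v, size) writeBin(as.integer(v), con, size = size,
                                   endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4L,
                             endian = "little")
  wc <- function(s, n) {
    r <- charToRaw(s)
    writeBin(c(r, raw(n - length(r))), con)
  }
  wi(348L, 4)                               # sizeof_hdr
  writeBin(raw(10 + 18 + 4 + 2 + 1), con)   # data_type..regular
  writeBin(as.raw(0L), con)                 # dim_info
  dimv <- c(nd, d, rep(1L, 7 - length(d)))
  wi(dimv, 2)                               # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2)                 # intent_p1..3, intent_code
  wi(64L, 2); wi(64L, 2); wi(0L, 2)         # datatype float64, bitpix, slice_start
  wf(c(1, rep(spacing, 3), dt, 0, 0, 0))    # pixdim[8]
  wf(352); wf(1); wf(0)                     # vox_offset, scl_slope, scl_inter
  wi(0L, 2); writeBin(as.raw(0L), con)      # slice_end, slice_code
  writeBin(as.raw(10L), con)                # xyzt_units: mm | sec
  wf(c(0, 0, 0, 0)); wi(c(0L, 0L), 4)       # cal_max..glmin
  wc("tracerflow", 80); wc("", 24)          # descrip, aux_file
  wi(0L, 2); wi(1L, 2)                      # qform_code 0, sform_code 1
  wf(c(0, 0, 0)); wf(c(0, 0, 0))            # quatern, qoffset
  wf(c(spacing, 0, 0, 0))                   # srow_x
  wf(c(0, spacing, 0, 0))                   # srow_y
  wf(c(0, 0, spacing, 0))                   # srow_z
  wc("", 16)                                # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  writeBin(raw(4), con)                     # extension flag
  writeBin(as.numeric(x), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Supports the subset written by [write_volume()] plus float32/int16
#' payloads with scaling. Anisotropic voxel spacing is rejected: the
#' framework assumes isotropic voxels throughout.
#'
#' @param path `.nii` file path.
#' @return numeric array with attributes `spacing` (mm) and `dt` (sec).
#' @export
read_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348L)
  if (length(hdr) < 348L) stop("descriptive error: truncated NIfTI header")
  ri <- function(off, size, n = 1L)
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = "little")
  rf <- function(off, n = 1L)
    readBin(hdr[(off + 1):(off + 4 * n)], "numeric", n = n, size = 4L,
            endian = "little")
  if (ri(0, 4) != 348L) stop("descriptive error: not a NIfTI-1 file (bad sizeof_hdr)")
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("descriptive error: bad NIfTI magic")
  dims <- ri(40, 2, 8)
  nd <- dims[1]
  if (!nd %in% c(3L, 4L)) stop("only 3D/4D volumes supported (got dim ", nd, ")")
  d <- dims[2:(1 + nd)]
  pix <- rf(76, 8)
  sp <- pix[2:4]
  if (max(sp) - min(sp) > 1e-5 * max(sp))
    stop("anisotropic voxel spacing (", paste(signif(sp, 5), collapse = "x"),
         ") is not supported: isotropic voxels are assumed")
  datatype <- ri(70, 2)
  vox_offset <- rf(108)
  slope <- rf(112); inter <- rf(116)
  if (slope == 0) slope <- 1
  seek(con, where = vox_offset, origin = "start")
  n <- prod(d)
  vals <- switch(as.character(datatype),
                 "64" = readBin(con, "numeric", n = n, size = 8L,
                                endian = "little"),
                 "16" = readBin(con, "numeric", n = n, size = 4L,
                                endian = "little"),
                 "4" = readBin(con, "integer", n = n, size = 2L,
                               endian = "little"),
                 stop("unsupported NIfTI datatype code ", datatype))
  if (length(vals) != n) stop("descriptive error: truncated NIfTI data")
  out <- array(vals * slope + inter, dim = d)
  attr(out, "spacing") <- sp[1]
  attr(out, "dt") <- pix[5]
  out
}

#' Save / load a ground-truth case bundle
#'
#' Writes each field as NIfTI (concentration series as 4D with time on the
#' 4th axis), a `meta.json` sidecar with units, spacing, times, seed and
#' case parameters, and an RDS container with the full object.
#'
#' @param case a `ground_truth_case` from [make_case()].
#' @param dir output directory (created).
#' @export
save_case <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- case$grid$spacing
  tt <- case$concentration$times
  dt <- if (length(tt) > 1) (tt[2] - tt[1]) * 60 else 0
  write_volume(case$concentration$values, file.path(dir, "concentration.nii"),
               sp, dt)
  write_volume(case$observed$values, file.path(dir, "observed.nii"), sp, dt)
  write_volume(zero_na(case$pressure), file.path(dir, "pressure.nii"), sp)
  write_volume(zero_na(case$permeability), file.path(dir, "permeability.nii"), sp)
  for (ax in 1:3)
    write_volume(zero_na(case$velocity[, , , ax]),
                 file.path(dir, paste0("velocity_", c("x", "y", "z")[ax], ".nii")),
                 sp)
  meta <- list(units = list(spacing = "mm", time = "min", velocity = "mm/s",
                            pressure = "Pa", permeability = "mm^2",
                            concentration = "proxy 0-100"),
               spacing = sp, times = tt, seed = case$seed,
               style = case$style, params = case$params,
               shape = case$grid$shape)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  saveRDS(case, file.path(dir, "case.rds"))
  invisible(dir)
}

zero_na <- function(x) { x[is.na(x)] <- 0; x }

#' @rdname save_case
#' @param dir directory written by `save_case`.
#' @export
load_case <- function(dir) readRDS(file.path(dir, "case.rds"))

# Deterministic rolling hash of a serialized R object (for run manifests;
# no external digest package needed).
config_hash <- function(x) {
  r <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in r) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

write_manifest <- function(dir, config, seed, outputs, failed_at = NULL) {
  m <- list(config_hash = config_hash(config), seed = seed,
            created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
            outputs = outputs, failed_at = failed_at,
            package_version = as.character(utils::packageVersion("tracerflow")))
  m <- Filter(Negate(is.null), m)
  jsonlite::write_json(m, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
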