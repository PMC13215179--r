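#' Preprocess an observed series into priors and an analysis mask
#'
#' For synthetic cases the observations are already on the 0-100
#' concentration-proxy scale, so the signal-to-SER step is skipped; each
#' volume is smoothed with the acquisition kernel before front tracking to
#' damp noise. The infusion-site voxels (the Dirichlet source patch) are
#' excluded from inference, as is everything outside the mask.
#'
#' The early-arrival threshold is 60 on the 0-100 proxy scale: the
#' reference rule of 150% raw signal enhancement, mapped through the
#' normalization of the series maximum (peak enhancement around 250%).
#'
#' @param observed a [conc_series()] of observations.
#' @param grid the [domain_grid()].
#' @param prior_style `"smooth"` (3-voxel SD) or `"sharp"` (1-voxel SD)
#'   permeability prior.
#' @param prior_scale multiplier applied to the permeability prior (the
#'   gauge factor probed by ensemble uncertainty analysis).
#' @param k_low,k_high prior permeability bounds (mm^2) before scaling.
#' @param arrival_threshold proxy-scale arrival threshold.
#' @param arrival_min arrival window (minutes).
#' @param diffusivity tracer diffusivity (mm^2/s) used to subtract the
#'   diffusive component from front-tracking speeds.
#' @return list `analysis_mask`, `k_prior`, `velocity` (a
#'   `velocity_prior`), `smoothed` (the smoothed series).
#' @export
preprocess_observations <- function(observed, grid,
                                    prior_style = c("smooth", "sharp"),
                                    prior_scale = 1,
                                    k_low = 1e-10, k_high = 1e-6,
                                    arrival_threshold = 60,
                                    arrival_min = 16,
                                    diffusivity = 2.4e-4) {
  prior_style <- match.arg(prior_style)
  analysis_mask <- grid$mask & !grid$inlet
  sm_vals <- observed$values
  for (k in seq_along(observed$times))
    sm_vals[, , , k] <- smooth_volume(observed$values[, , , k], grid$mask)
  smoothed <- conc_series(sm_vals, observed$times, grid, observed$mask,
                          c_char = observed$c_char)
  sd_vox <- if (prior_style == "smooth") 3 else 1
  k_prior <- initial_permeability_guess(
    smoothed, ser_threshold = arrival_threshold, arrival_time = arrival_min,
    k_high = k_high, k_low = k_low, smoothing_sd_voxels = sd_vox)
  k_prior <- k_prior * prior_scale
  vel <- front_track_velocity(smoothed, mask = analysis_mask,
                              diffusivity = diffusivity)
  list(analysis_mask = analysis_mask, k_prior = k_prior, velocity = vel,
       smoothed = smoothed, prior_style = prior_style,
       prior_scale = prior_scale)
}

#' Infer velocity, pressure and permeability from an observed series
#'
#' The end-to-end inference wrapper: preprocessing, nondimensionalization,
#' model assembly and the staged training schedule. Network sizes and
#' iteration counts default to desk-scale values; pass
#' `specs = default_network_specs()` and a larger schedule for full-size
#' runs.
#'
#' @param observed a [conc_series()] of observations (proxy scale).
#' @param grid the [domain_grid()].
#' @param seed master seed for initialization and batching.
#' @param prior_style,prior_scale see [preprocess_observations()].
#' @param constants a [material_constants()].
#' @param p_char characteristic pressure (Pa), or `NULL` (default) to set
#'   the gauge from data: `P_char = U_est * L_char / K_char` with `U_est`
#'   the 90th percentile of front-tracking speeds, so that starred
#'   velocities are order one and the transport and continuity losses are
#'   balanced as intended. Absolute pressure/permeability are only defined
#'   up to this gauge in any case.
#' @param t_range inference window (minutes).
#' @param specs network architecture set.
#' @param schedule stage schedule.
#' @param control training control.
#' @return list `model`, `fit` (run_schedule output), `prep`, `data`,
#'   `scales`.
#' @export
infer_case <- function(observed, grid, seed = 1L,
                       prior_style = "smooth", prior_scale = 1,
                       constants = material_constants(),
                       p_char = NULL, t_range = c(5, 90),
                       specs = default_network_specs(width_scale = 0.5,
                                                     n_layers = 3L),
                       schedule = default_schedule(),
                       control = train_control(batch_phys = 128L,
                                               polish_phys = 1000L,
                                               tau_g_frac = 0.05)) {
  prep <- preprocess_observations(observed, grid, prior_style, prior_scale,
                                  diffusivity = constants$D)
  if (is.null(p_char)) {
    sp <- sqrt(rowSums(prep$velocity$vectors^2))
    u_est <- if (length(sp) > 10) stats::quantile(sp, 0.9, names = FALSE)
             else NA_real_
    p_char <- if (is.finite(u_est) && u_est > 0) {
      sc0 <- compute_scales(grid, constants, prep$k_prior, observed,
                            p_char = 1)
      u_est * sc0$L_char / sc0$K_char
    } else 1000
  }
  scales <- compute_scales(grid, constants, prep$k_prior, observed,
                           p_char = p_char)
  t_range <- c(max(t_range[1], min(observed$times)),
               min(t_range[2], max(observed$times)))
  # training consumes the kernel-smoothed series, exactly as the imaging
  # pipeline does before computing the concentration proxy
  data <- prepare_training_data(prep$smoothed, scales, prep$analysis_mask,
                                t_range = t_range, seed = seed + 100L)
  model <- model_state(grid, scales,
                       k_low = min(prep$k_prior[grid$mask]),
                       k_high = max(prep$k_prior[grid$mask]),
                       t_range = t_range, specs = specs, seed = seed)
  fit <- run_schedule(data, prep, model, schedule = schedule,
                      seed = seed + 200L, control = control)
  list(model = fit$model, fit = fit, prep = prep, data = data,
       scales = scales)
}

#' Evaluate an inference against a ground-truth case
#'
#' @param result an [infer_case()] result.
#' @param case the matching `ground_truth_case`.
#' @return list: `conc_rl2_val` (relative L2 of the clean reconstruction
#'   against the noiseless truth on held-out observations, %),
#'   `velocity` ([field_metrics()]), plus the predicted fields.
#' @details The concentration reference is the noiseless simulated field
#'   passed through the same acquisition smoothing kernel the training
#'   data received: the clean counterpart of the fitted observable.
#' @export
evaluate_inference <- function(result, case) {
  model <- result$model
  sc <- result$scales
  data <- result$data
  grid <- case$grid
  # held-out clean-truth comparison
  nv <- length(data$mask_idx)
  truth <- numeric(nv * length(data$sel_t))
  for (k in seq_along(data$sel_t))
    truth[((k - 1) * nv + 1):(k * nv)] <-
      smooth_volume(case$concentration$values[, , , data$sel_t[k]],
                    grid$mask)[data$mask_idx]
  val_truth <- truth[data$val$idx] / sc$c_char
  pred <- eval_concentration(model, data$val$tx)
  conc_rl2 <- relative_l2(pred, val_truth)
  fields <- predict_fields(model, what = c("velocity", "permeability",
                                           "pressure"))
  amask <- result$prep$analysis_mask
  vel <- field_metrics(fields$velocity, case$velocity, amask)
  list(conc_rl2_val = conc_rl2, velocity = vel, fields = fields,
       analysis_mask = amask)
}

#' Run the full pipeline on a synthetic case
#'
#' simulate (or load) -> preprocess -> train -> evaluate, writing fields,
#' metrics and a provenance manifest to `out_dir`. Any stage failure
#' preserves partial artifacts and records the failure point in the
#' manifest.
#'
#' @param out_dir output directory.
#' @param style synthetic case style.
#' @param shape grid shape.
#' @param seed master seed.
#' @param case optional pre-built `ground_truth_case` (skips simulation).
#' @param ... passed to [infer_case()].
#' @return list with `case`, `result`, `metrics` (invisibly).
#' @export
run_pipeline <- function(out_dir, style = "smooth", shape = c(20L, 20L, 20L),
                         seed = 1L, case = NULL, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(style = style, shape = shape, seed = seed, dots = list(...))
  outputs <- character(0)
  stage <- "simulate"
  res <- tryCatch({
    if (is.null(case)) case <- make_case(style, shape = shape, seed = seed)
    save_case(case, file.path(out_dir, "case"))
    outputs <- c(outputs, "case")
    stage <- "infer"
    result <- infer_case(case$observed, case$grid, seed = seed, ...)
    save_model(result$model, file.path(out_dir, "model.rds"))
    outputs <- c(outputs, "model.rds")
    stage <- "evaluate"
    metrics <- evaluate_inference(result, case)
    sp <- case$grid$spacing
    for (ax in 1:3)
      write_volume(zero_na(metrics$fields$velocity[, , , ax]),
                   file.path(out_dir, paste0("velocity_",
                                             c("x", "y", "z")[ax], ".nii")), sp)
    write_volume(zero_na(metrics$fields$permeability),
                 file.path(out_dir, "permeability.nii"), sp)
    write_volume(zero_na(metrics$fields$pressure),
                 file.path(out_dir, "pressure.nii"), sp)
    jsonlite::write_json(
      list(conc_rl2_val = metrics$conc_rl2_val,
           speed_rl2 = metrics$velocity$speed_rl2,
           mean_angular = metrics$velocity$mean_angular,
           coverage_below_25 = metrics$velocity$coverage_below,
           wasserstein = metrics$velocity$wasserstein),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, "metrics.json")
    write_manifest(out_dir, cfg, seed, outputs)
    list(case = case, result = result, metrics = metrics)
  }, error = function(e) {
    write_manifest(out_dir, cfg, seed, outputs, failed_at = stage)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e))
  })
  invisible(res)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `pipeline`, `evaluate`. Invoked by the
#' `inst/cli/tracerflow.R` script; exposed as a function so it can be
#' driven programmatically.
#'
#' @param args character vector of command-line arguments.
#' @export
tracerflow_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0)
    stop("usage: tracerflow <simulate|pipeline|evaluate> [options]")
  cmd <- args[1]
  opts <- parse_cli_opts(args[-1])
  get_opt <- function(name, default = NULL, as = identity) {
    if (!is.null(opts[[name]])) as(opts[[name]]) else default
  }
  seed <- get_opt("seed", 1L, as.integer)
  out <- get_opt("out", "tracerflow_out")
  switch(cmd,
    simulate = {
      shape <- get_opt("shape", "24,24,24")
      shape <- as.integer(strsplit(shape, ",")[[1]])
      case <- make_case(get_opt("style", "smooth"), shape = shape,
                        k_low = get_opt("k-low", 1e-10, as.numeric),
                        k_high = get_opt("k-high", 1e-6, as.numeric),
                        dp = get_opt("dp", NULL, as.numeric), seed = seed)
      save_case(case, out)
      message("case written to ", out)
    },
    pipeline = {
      shape <- as.integer(strsplit(get_opt("shape", "20,20,20"), ",")[[1]])
      run_pipeline(out, style = get_opt("style", "smooth"), shape = shape,
                   seed = seed)
      message("pipeline outputs in ", out)
    },
    evaluate = {
      case <- load_case(get_opt("truth", stop("--truth required")))
      model <- load_model(get_opt("model", stop("--model required")))
      fields <- predict_fields(model)
      m <- field_metrics(fields$velocity, case$velocity,
                         case$grid$mask & !case$grid$inlet)
      jsonlite::write_json(m, file.path(out, "metrics.json"),
                           auto_unbox = TRUE, digits = NA)
      message("metrics in ", file.path(out, "metrics.json"))
    },
    stop("unknown subcommand: ", cmd))
  invisible(NULL)
}

parse_cli_opts <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i < length(args) && !startsWith(args[i + 1L], "--")) {
        out[[key]] <- args[i + 1L]; i <- i + 2L
      } else { out[[key]] <- TRUE; i <- i + 1L }
    } else i <- i + 1L
  }
  out
}
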