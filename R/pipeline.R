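#' Run configuration for the simulate-correct-reconstruct pipeline
#'
#' Validates and normalizes a nested configuration list.  Field names
#' carry their units (`_mm`, `_px`, `_deg`); the single `seed` drives
#' every random stage through deterministically derived sub-seeds, so two
#' runs of the same configuration are identical.
#'
#' @param config A nested list with components `geometry`, `phantom`,
#'   `blocker`, `scatter`, `detection`, `correction`, `recon`,
#'   `evaluation`, and a mandatory integer `seed`.  See
#'   [make_fixture()] for complete examples.
#' @return The validated configuration, classed `run_config`.
#' @export
run_config <- function(config) {
  need <- c("seed", "geometry", "phantom", "blocker", "scatter",
            "detection", "correction", "recon", "evaluation")
  miss <- setdiff(need, names(config))
  if (length(miss) > 0)
    stop("config is missing: ", paste(miss, collapse = ", "))
  if (!is.numeric(config$seed) || length(config$seed) != 1)
    stop("config$seed must be a single integer")
  config$seed <- as.integer(config$seed)
  if (!config$detection$method %in% c("adaptive", "twopoint", "truth"))
    stop("detection$method must be adaptive, twopoint or truth")
  if (!config$correction$method %in% c("mvsc", "svsc", "none", "truth"))
    stop("correction$method must be mvsc, svsc, none or truth")
  if (is.null(config$version)) config$version <- 1L
  structure(config, class = "run_config")
}

#' Serialize / parse a run configuration
#'
#' JSON round-trip: `read_run_config(write_run_config(cfg, f))` restores
#' the configuration exactly (up to numeric formatting).
#'
#' @param config A `run_config`.
#' @param path JSON file path.
#' @return The path (write) or the parsed `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  # primitive list comes back as a data frame; restore list-of-lists
  if (is.data.frame(cfg$phantom$primitives))
    cfg$phantom$primitives <- lapply(
      seq_len(nrow(cfg$phantom$primitives)), function(i)
        lapply(cfg$phantom$primitives[i, ], function(x)
          if (is.list(x)) x[[1]] else x))
  if (is.data.frame(cfg$evaluation$rois))
    cfg$evaluation$rois <- lapply(
      seq_len(nrow(cfg$evaluation$rois)), function(i)
        lapply(cfg$evaluation$rois[i, ], function(x)
          if (is.list(x)) x[[1]] else x))
  run_config(cfg)
}

# Deterministic stage sub-seed from the master seed (kept below 2^31).
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + stage * 104729) %% 2147483629)
}

config_geometry <- function(config) {
  g <- config$geometry
  scan_geometry(g$sad_mm, g$sdd_mm, g$n_views, g$angles_deg, g$det_rows,
                g$det_cols, g$pixel_pitch_mm)
}

config_phantom <- function(config) {
  ph <- config$phantom
  prims <- lapply(ph$primitives, function(p)
    phantom_primitive(p$shape, unlist(p$center_mm), unlist(p$semi_axes_mm),
                      p$mu_per_mm))
  make_phantom(phantom_spec(prims), dims = unlist(ph$dims),
               voxel_size = ph$voxel_size_mm,
               supersample = if (is.null(ph$supersample)) 1L else
                 ph$supersample)
}

config_trajectory <- function(config, geom) {
  b <- config$blocker
  blocker_trajectory(b$strip_width_mm, b$strip_gap_mm, geom$n_views,
                     amplitude = b$amplitude_mm, period = b$period_views,
                     phase = if (is.null(b$phase_mm)) 0 else b$phase_mm,
                     penumbra_margin = b$penumbra_margin_px,
                     cover = if (is.null(b$cover_mm)) c(-Inf, Inf) else
                       unlist(b$cover_mm))
}

config_rois <- function(config) {
  lapply(config$evaluation$rois, function(r)
    roi_spec(r$label, r$shape, unlist(r$center_mm), r$radius_mm,
             unlist(r$half_size_mm)))
}

#' Execute the full moving-blocker pipeline
#'
#' Runs simulate, detect, correct, reconstruct and evaluate in order,
#' returning every stage's output (and writing artifacts when
#' `output_dir` is given).  A stage failure aborts with the stage name.
#' Re-running the same configuration reproduces the report exactly.
#'
#' @param config A [run_config()] (or plain list passed through it).
#' @param stack Optional pre-simulated `projection_stack` (reuses one
#'   acquisition across several correction methods).
#' @param output_dir Directory for artifacts (`NULL` = keep in memory
#'   only).
#' @param verbose Print stage progress.
#'
#' @return A list of class `pipeline_result`: `config`, `stack`,
#'   `truth_vol`, `edges`, `masks_used`, `scatter_est`, `corrected`,
#'   `recon`, `report` (an `eval_report`), `log` (stage timings).
#' @export
run_pipeline <- function(config, stack = NULL, output_dir = NULL,
                         verbose = FALSE) {
  config <- run_config(unclass(config))
  log <- list()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
    log[[stage]] <<- proc.time()[["elapsed"]] - t0
    if (verbose) message(sprintf("[%s] %.1fs", stage, log[[stage]]))
    res
  }

  geom <- config_geometry(config)
  vol_truth <- tick("phantom", config_phantom(config))
  traj <- config_trajectory(config, geom)

  if (is.null(stack)) {
    s <- config$scatter
    stack <- tick("simulate", acquire(
      vol_truth, geom, traj, i0 = s$i0, spr = s$spr,
      blur_sigma = s$blur_sigma_mm,
      apply_poisson = isTRUE(s$apply_poisson),
      noise_seed = derive_seed(config$seed, 1L)))
  }

  det <- config$detection
  detect_result <- tick("detect", switch(
    det$method,
    truth = list(edges = NULL, masks = stack$masks),
    adaptive = {
      e <- detect_edges_adaptive(
        stack, n_adjacent = det$n_adjacent, alpha = det$alpha)
      list(edges = e, masks = edges_to_masks(e, geom,
                                             traj$penumbra_margin))
    },
    twopoint = {
      perturb <- if (!is.null(det$perturb_views) &&
                     length(det$perturb_views) > 0)
        list(views = unlist(det$perturb_views),
             delta_rows = det$perturb_delta_rows)
      e <- detect_edges_two_point(
        stack, unlist(det$probe_cols), det$threshold, perturb = perturb)
      list(edges = e, masks = edges_to_masks(e, geom,
                                             traj$penumbra_margin))
    }))
  edges <- detect_result$edges
  masks_used <- detect_result$masks

  corr <- config$correction
  scatter_est <- tick("correct", switch(
    corr$method,
    none = rep(list(matrix(0, geom$det_rows, geom$det_cols)),
               geom$n_views),
    truth = stack$ground_truth$scatter,
    svsc = lapply(seq_len(geom$n_views), function(v)
      estimate_scatter_svsc(stack, masks_used, v,
                            lateral_smooth = corr$lateral_smooth)),
    mvsc = lapply(seq_len(geom$n_views), function(v)
      estimate_scatter_mvsc(stack, masks_used, v,
                            n_adjacent = corr$n_adjacent,
                            lateral_smooth = corr$lateral_smooth,
                            max_span_deg = corr$max_span_deg))))
  corrected <- correct_and_log(stack, scatter_est, masks_used)

  rc <- config$recon
  recon <- tick("reconstruct", reconstruct(
    corrected, geom, dims = unlist(rc$dims),
    voxel_size = rc$voxel_size_mm, lambda = rc$lambda,
    n_iterations = rc$n_iterations, tv_steps = rc$tv_steps,
    tv_step_scale = rc$tv_step_scale, verbose = verbose))

  rois <- config_rois(config)
  report <- tick("evaluate", {
    recon_truth_grid <- resample_like(vol_truth, recon$vol)
    compare_methods(recon_truth_grid,
                    setNames(list(recon$vol), corr$method), rois,
                    mu_water = config$evaluation$mu_water_per_mm)
  })

  out <- structure(list(config = config, stack = stack,
                        truth_vol = vol_truth, edges = edges,
                        masks_used = masks_used,
                        scatter_est = scatter_est, corrected = corrected,
                        recon = recon, report = report, log = log),
                   class = "pipeline_result")
  if (!is.null(output_dir)) write_pipeline_artifacts(out, output_dir)
  out
}

# Nearest-neighbour resample of a volume onto the grid of `like` (used when
# the reconstruction grid differs from the phantom grid).
resample_like <- function(vol, like) {
  if (all(dim(vol$values) == dim(like$values)) &&
      vol$voxel_size == like$voxel_size &&
      all(vol$origin == like$origin)) return(vol)
  idx <- function(axis) {
    centers <- voxel_centers(like, axis)
    i <- round((centers - vol$origin[axis]) / vol$voxel_size + 0.5)
    pmin(pmax(i, 1L), dim(vol$values)[axis])
  }
  out <- like
  out$values <- vol$values[idx(1), idx(2), idx(3)]
  out
}

write_pipeline_artifacts <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(res$config, file.path(dir, "config.json"))
  write_projection_stack(res$stack, file.path(dir, "projections"))
  if (!is.null(res$edges))
    write_edges_json(res$edges, file.path(dir, "edges.json"))
  tiff::writeTIFF(lapply(res$scatter_est, function(m)
    m / max(1, max(unlist(res$scatter_est)))),
    file.path(dir, "scatter_estimate.tif"), bits.per.sample = 32L)
  write_volume_mha(res$recon$vol, file.path(dir, "recon_mu.mha"))
  hu <- res$recon$vol
  hu$values <- to_hu(res$recon$vol, res$config$evaluation$mu_water_per_mm)
  write_volume_mha(hu, file.path(dir, "recon_hu.mha"))
  write.csv(res$recon$trace, file.path(dir, "iterations.csv"),
            row.names = FALSE)
  write.csv(res$report, file.path(dir, "report.csv"), row.names = FALSE)
  jsonlite::write_json(res$log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline run: detection=%s, correction=%s, seed=%d\n",
              x$config$detection$method, x$config$correction$method,
              x$config$seed))
  print(x$report)
  invisible(x)
}

#' Canned end-to-end study configurations
#'
#' Three desk-scale acquisitions sharing one geometry (60 views over 360
#' degrees, 96 x 96 detector at 2 mm, 64^3 volume at 2 mm voxels, equal
#' projected strip width and gap of 16 mm, SPR 1, Poisson noise at
#' i0 = 1e5):
#'
#' * `"clean"` -- a water cylinder with a central air insert, blocker
#'   covering the whole detector: both correction methods should agree
#'   and CT numbers should be accurate (air near -1000 HU).
#' * `"boundary"` -- the blocker board ends partway up the detector, so
#'   the upper end of the object shadow has no scatter samples in a
#'   single view: single-view estimation must extrapolate across the
#'   falling scatter transition and fails there, while adjacent views
#'   reach closer to the end and repair it.
#' * `"robustness"` -- a wide, low-contrast cylinder with a simulated
#'   two-point mis-detection (+3 rows at the second probe point) in every
#'   tenth view, with probe points close together so the error is
#'   amplified toward distant columns; the envelope-based detection is
#'   unaffected.
#'
#' The blocker motion (triangular, 64 mm amplitude, 10-view period) is
#' fast enough that a five-view window shifts the band pattern across
#' most of a strip period, the regime in which joint estimation
#' multiplies the axial sampling rate several-fold.
#'
#' @param name `"clean"`, `"boundary"` or `"robustness"`.
#' @param seed Master seed for the run.
#' @return A [run_config()].
#' @export
make_fixture <- function(name = c("clean", "boundary", "robustness"),
                         seed = 1L) {
  name <- match.arg(name)
  base <- list(
    version = 1L,
    seed = as.integer(seed),
    fixture = name,
    geometry = list(sad_mm = 1000, sdd_mm = 1500, n_views = 60L,
                    angles_deg = NULL, det_rows = 96L, det_cols = 96L,
                    pixel_pitch_mm = 2.0),
    phantom = list(dims = c(64L, 64L, 64L), voxel_size_mm = 2.0,
                   supersample = 2L, primitives = NULL),
    blocker = list(strip_width_mm = 16, strip_gap_mm = 16,
                   amplitude_mm = 64, period_views = 10L, phase_mm = 0,
                   penumbra_margin_px = 2L,
                   cover_mm = c(-Inf, Inf)),
    scatter = list(spr = 1.0, blur_sigma_mm = 40, i0 = 1e5,
                   apply_poisson = TRUE),
    detection = list(method = "adaptive", n_adjacent = 5L, alpha = 0.5),
    correction = list(method = "mvsc", n_adjacent = 5L,
                      max_span_deg = 30, lateral_smooth = 11L),
    recon = list(dims = c(64L, 64L, 64L), voxel_size_mm = 2.0,
                 lambda = 0.5, n_iterations = 30L, tv_steps = 10L,
                 tv_step_scale = 0.2),
    evaluation = list(mu_water_per_mm = 0.02, rois = NULL))

  water <- function(r, hz, center = c(0, 0, 0))
    list(shape = "cylinder", center_mm = center,
         semi_axes_mm = c(r, r, hz), mu_per_mm = 0.02)

  if (name == "clean") {
    base$phantom$primitives <- list(
      water(40, 55),
      list(shape = "cylinder", center_mm = c(0, 0, 0),
           semi_axes_mm = c(15, 15, 45), mu_per_mm = 0))
    base$evaluation$rois <- list(
      list(label = "air", shape = "cylinder", center_mm = c(0, 0, 0),
           radius_mm = 8, half_size_mm = c(8, 8, 15)),
      list(label = "water", shape = "cylinder", center_mm = c(26, 0, 0),
           radius_mm = 7, half_size_mm = c(7, 7, 15)),
      list(label = "water2", shape = "cylinder", center_mm = c(-26, 0, 0),
           radius_mm = 7, half_size_mm = c(7, 7, 15)))
  } else if (name == "boundary") {
    base$phantom$primitives <- list(water(40, 55))
    base$blocker$cover_mm <- c(-200, 70)
    base$evaluation$rois <- list(
      list(label = "water_end", shape = "cylinder",
           center_mm = c(0, 0, 40), radius_mm = 20,
           half_size_mm = c(20, 20, 12)),
      list(label = "water_mid", shape = "cylinder",
           center_mm = c(0, 0, 0), radius_mm = 20,
           half_size_mm = c(20, 20, 12)))
  } else {
    base$phantom$primitives <- list(water(55, 55))
    base$detection <- list(method = "twopoint", n_adjacent = 5L,
                           alpha = 0.5, probe_cols = c(86L, 94L),
                           threshold = 0.45e5,
                           perturb_views = as.list(seq(10L, 60L, by = 10L)),
                           perturb_delta_rows = 3L)
    base$evaluation$rois <- list(
      list(label = "water_mid", shape = "cylinder",
           center_mm = c(0, 0, 0), radius_mm = 25,
           half_size_mm = c(25, 25, 15)))
  }
  run_config(base)
}
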