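#' Simulate a moving-blocker CBCT acquisition
#'
#' Ray-traces the primary fluence `i0 * exp(-line integrals)`, adds a
#' simulated low-frequency scatter field, applies the blocker (blocked
#' pixels receive the scatter signal only, unblocked pixels the total
#' signal), and optionally Poisson noise.  Ground-truth primary and
#' scatter fields and the masks are retained on the returned stack so
#' every downstream stage can be tested against them.
#'
#' @param vol An [attenuation_volume()].
#' @param geom A [scan_geometry()].
#' @param traj A [blocker_trajectory()], or `NULL` for a blocker-free scan.
#' @param i0 Open-field fluence, counts per pixel.
#' @param spr Scatter-to-primary ratio (see [simulate_scatter()]).
#' @param blur_sigma Scatter low-pass width at the detector, mm.
#' @param apply_poisson Apply Poisson counting noise to the detected
#'   intensity.
#' @param noise_seed Integer seed for the noise; mandatory when
#'   `apply_poisson` is `TRUE` so that acquisitions are reproducible.
#'
#' @return An object of class `projection_stack`: per-view `intensities`,
#'   plus `i0`, `geometry`, `masks` (a `mask_set`, `NULL` without blocker)
#'   and `ground_truth` (`$primary`, `$scatter` per view).
#' @export
acquire <- function(vol, geom, traj, i0 = 1e5, spr = 1.0, blur_sigma = 40,
                    apply_poisson = FALSE, noise_seed = NULL) {
  stopifnot(inherits(vol, "attenuation_volume"),
            inherits(geom, "scan_geometry"))
  if (apply_poisson && is.null(noise_seed))
    stop("noise_seed is required when apply_poisson = TRUE")
  fp <- forward_project(vol, geom, drop = FALSE)
  primary <- lapply(fp, function(p) i0 * exp(-p))
  scatter <- simulate_scatter(primary, i0, spr, blur_sigma,
                              geom$pixel_pitch)
  masks <- if (is.null(traj)) NULL else build_masks(traj, geom)
  intensities <- vector("list", geom$n_views)
  for (v in seq_len(geom$n_views)) {
    tot <- primary[[v]] + scatter[[v]]
    if (!is.null(masks)) tot[masks$blocked[[v]]] <- scatter[[v]][masks$blocked[[v]]]
    intensities[[v]] <- tot
  }
  if (apply_poisson) {
    set.seed(as.integer(noise_seed))
    intensities <- lapply(intensities, function(m) {
      matrix(rpois(length(m), m), nrow(m), ncol(m))
    })
  }
  structure(list(intensities = intensities, i0 = i0, geometry = geom,
                 trajectory = traj, masks = masks,
                 ground_truth = list(primary = primary, scatter = scatter),
                 noise_seed = noise_seed,
                 apply_poisson = apply_poisson),
            class = "projection_stack")
}

#' @export
print.projection_stack <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("projection stack: %d views of %d x %d pixels, i0 = %g\n",
              g$n_views, g$det_rows, g$det_cols, x$i0))
  cat(sprintf("  blocker: %s, Poisson noise: %s\n",
              if (is.null(x$trajectory)) "none" else "moving strips",
              if (isTRUE(x$apply_poisson)) "on" else "off"))
  invisible(x)
}
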