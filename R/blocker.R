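#' Moving-blocker trajectory
#'
#' Layout and motion of the lead-strip blocker, specified in
#' detector-plane millimetres (the physical strip sizes projected onto the
#' detector; see [blocker_projected()] to convert).  Strips run laterally
#' (perpendicular to the rotation axis) and the whole pattern translates
#' axially between views with a triangular back-and-forth motion.
#'
#' The strip pattern is periodic with period `strip_width_det +
#' strip_gap_det`; at offset 0 a strip starts at axial coordinate 0.  An
#' optional finite board extent `cover` (axial interval, mm, moving with
#' the pattern) models a blocker that does not span the whole detector,
#' which is what creates end regions without scatter samples.
#'
#' @param strip_width_det Strip width projected to the detector plane, mm.
#' @param strip_gap_det Unblocked gap ("pitch") between strips, projected,
#'   mm.
#' @param n_views Number of views the trajectory covers.
#' @param amplitude Peak axial offset of the triangular motion, mm.
#'   Default: one full strip period.
#' @param period Period of the triangular motion, in views.
#' @param phase Axial shift of the whole pattern at offset 0, mm.
#' @param penumbra_margin Pixels trimmed from each axial side of a blocked
#'   band when building the eroded (scatter-sampling) mask.
#' @param cover Length-2 axial interval (mm, in pattern coordinates) within
#'   which strips exist; `c(-Inf, Inf)` covers everything.
#'
#' @return An object of class `blocker_trajectory` with the per-view
#'   offsets in `$offset_per_view`.
#' @export
blocker_trajectory <- function(strip_width_det, strip_gap_det, n_views,
                               amplitude = strip_width_det + strip_gap_det,
                               period = 40, phase = 0,
                               penumbra_margin = 2,
                               cover = c(-Inf, Inf)) {
  if (strip_width_det <= 0 || strip_gap_det <= 0)
    stop("strip width and gap must be positive")
  if (amplitude < 0 || period <= 0) stop("bad motion parameters")
  i <- seq_len(n_views) - 1
  frac <- (i %% period) / period
  tri <- ifelse(frac < 0.5, 2 * frac, 2 * (1 - frac))
  offsets <- amplitude * tri
  structure(list(strip_width_det = as.numeric(strip_width_det),
                 strip_gap_det = as.numeric(strip_gap_det),
                 n_views = as.integer(n_views),
                 motion = list(amplitude = as.numeric(amplitude),
                               period = as.numeric(period)),
                 phase = as.numeric(phase),
                 offset_per_view = offsets,
                 penumbra_margin = as.integer(penumbra_margin),
                 cover = cover),
            class = "blocker_trajectory")
}

#' Convert physical blocker dimensions to detector-plane ones
#'
#' A strip of physical width `w` at source-to-blocker distance `sbd`
#' projects to `w * sdd / sbd` on the detector.
#'
#' @param w Physical size at the blocker plane, mm.
#' @param sbd Source-to-blocker distance, mm.
#' @param geom A [scan_geometry()] (supplies `sdd`).
#' @return Projected size at the detector, mm.
#' @export
blocker_projected <- function(w, sbd, geom) {
  if (sbd <= 0 || sbd >= geom$sdd) stop("need 0 < sbd < sdd")
  w * geom$sdd / sbd
}

#' Per-view blocked/unblocked detector masks
#'
#' For each view, detector rows whose axial pixel-center coordinate falls
#' inside a strip interval (half-open `[start, start + width)`) are blocked
#' across all columns.  The eroded variant shrinks every blocked band by
#' `penumbra_margin` pixels on both axial sides and is the mask scatter
#' samples are drawn from.
#'
#' @param traj A [blocker_trajectory()].
#' @param geom A [scan_geometry()]; the strip period must be smaller than
#'   the detector's axial extent.
#'
#' @return An object of class `mask_set`: lists `blocked` and `eroded` of
#'   logical `det_rows x det_cols` matrices (TRUE = blocked).
#' @export
build_masks <- function(traj, geom) {
  stopifnot(inherits(traj, "blocker_trajectory"),
            inherits(geom, "scan_geometry"))
  period <- traj$strip_width_det + traj$strip_gap_det
  if (period >= geom$det_rows * geom$pixel_pitch)
    stop("strip period must be smaller than the detector axial extent")
  if (traj$n_views < geom$n_views)
    stop("trajectory covers fewer views than the geometry")
  z <- det_axial_coords(geom)
  blocked <- eroded <- vector("list", geom$n_views)
  for (v in seq_len(geom$n_views)) {
    off <- traj$offset_per_view[v] + traj$phase
    zp <- z - off  # pattern coordinates
    b <- (zp %% period) < traj$strip_width_det
    b <- b & zp >= traj$cover[1] & zp < traj$cover[2]
    e <- erode_runs(b, traj$penumbra_margin)
    blocked[[v]] <- matrix(b, geom$det_rows, geom$det_cols)
    eroded[[v]] <- matrix(e, geom$det_rows, geom$det_cols)
  }
  structure(list(blocked = blocked, eroded = eroded),
            class = "mask_set")
}

# Shrink every run of TRUE in a logical vector by m elements at each end.
erode_runs <- function(b, m) {
  if (m <= 0L || !any(b)) return(b)
  r <- rle(b)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- rep(FALSE, length(b))
  for (k in which(r$values)) {
    s <- starts[k] + m
    e <- ends[k] - m
    if (s <= e) out[s:e] <- TRUE
  }
  out
}

#' @export
print.mask_set <- function(x, ...) {
  nb <- vapply(x$blocked, mean, numeric(1))
  cat(sprintf("mask set: %d views, blocked fraction %.3f-%.3f\n",
              length(x$blocked), min(nb), max(nb)))
  invisible(x)
}
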