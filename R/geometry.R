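#' Circular cone-beam scan geometry
#'
#' Describes the acquisition frame every other object references: a point
#' source and a flat-panel detector rotating on a circle about the z axis
#' (the axial direction, along detector rows).
#'
#' @param sad Source-to-axis distance, mm.
#' @param sdd Source-to-detector distance, mm. Must exceed `sad`.
#' @param n_views Number of projection views.
#' @param angles Gantry angles in degrees, ascending over `[0, 360)`. Default
#'   is `n_views` equally spaced angles starting at 0.
#' @param det_rows,det_cols Detector grid size. Rows run along the rotation
#'   axis (the blocker motion direction), columns laterally.
#' @param pixel_pitch Detector pixel size, mm (isotropic).
#'
#' @return An object of class `scan_geometry`.
#' @examples
#' g <- scan_geometry(n_views = 8, det_rows = 32, det_cols = 32,
#'                    pixel_pitch = 2)
#' @export
scan_geometry <- function(sad = 1000, sdd = 1500, n_views = 670,
                          angles = NULL, det_rows = 512, det_cols = 512,
                          pixel_pitch = 0.8) {
  if (!(sdd > sad && sad > 0))
    stop("need sdd > sad > 0")
  if (is.null(angles))
    angles <- seq(0, 360, length.out = n_views + 1)[seq_len(n_views)]
  if (length(angles) != n_views)
    stop("n_views must equal length(angles)")
  if (is.unsorted(angles, strictly = TRUE) || any(angles < 0) ||
      any(angles >= 360))
    stop("angles must be strictly ascending within [0, 360)")
  if (det_rows <= 0 || det_cols <= 0 || pixel_pitch <= 0)
    stop("det_rows, det_cols and pixel_pitch must be positive")
  structure(list(sad = as.numeric(sad), sdd = as.numeric(sdd),
                 n_views = as.integer(n_views),
                 angles = as.numeric(angles),
                 det_rows = as.integer(det_rows),
                 det_cols = as.integer(det_cols),
                 pixel_pitch = as.numeric(pixel_pitch)),
            class = "scan_geometry")
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat("CBCT scan geometry\n")
  cat(sprintf("  SAD %g mm, SDD %g mm (magnification %.3f)\n",
              x$sad, x$sdd, x$sdd / x$sad))
  cat(sprintf("  %d views over [%g, %g] deg\n", x$n_views,
              min(x$angles), max(x$angles)))
  cat(sprintf("  detector %d x %d pixels at %g mm\n",
              x$det_rows, x$det_cols, x$pixel_pitch))
  invisible(x)
}

#' Detector coordinates
#'
#' Axial (row) and lateral (column) physical coordinates of detector pixel
#' centers, in mm, with 0 at the detector center (the piercing point).
#'
#' @param geom A [scan_geometry()].
#' @return Numeric vector of pixel-center coordinates.
#' @export
det_axial_coords <- function(geom) {
  (seq_len(geom$det_rows) - (geom$det_rows + 1) / 2) * geom$pixel_pitch
}

#' @rdname det_axial_coords
#' @export
det_lateral_coords <- function(geom) {
  (seq_len(geom$det_cols) - (geom$det_cols + 1) / 2) * geom$pixel_pitch
}

# Source position and detector pixel-center world coordinates for one view.
# Source at angle theta sits at sad*(cos, sin, 0); the detector center at
# -(sdd-sad)*(cos, sin, 0); u = lateral unit vector, v = axial (z).
view_frame <- function(geom, view) {
  th <- geom$angles[view] * pi / 180
  ca <- cos(th); sa <- sin(th)
  src <- c(geom$sad * ca, geom$sad * sa, 0)
  cen <- c(-(geom$sdd - geom$sad) * ca, -(geom$sdd - geom$sad) * sa, 0)
  u <- c(-sa, ca, 0)
  ax <- det_axial_coords(geom)     # rows
  lat <- det_lateral_coords(geom)  # cols
  px <- outer(rep(cen[1], geom$det_rows), lat * u[1], "+")
  py <- outer(rep(cen[2], geom$det_rows), lat * u[2], "+")
  pz <- matrix(ax, geom$det_rows, geom$det_cols)
  list(src = src, px = px, py = py, pz = pz)
}
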