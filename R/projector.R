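#' Forward projection by Siddon ray tracing
#'
#' Line integrals of the attenuation volume along the rays from the source
#' to every detector pixel center, computed with exact voxel intersection
#' lengths (Siddon/Amanatides-Woo traversal).  The same ray tracer backs
#' the ART reconstruction, so projector and system matrix agree by
#' construction.
#'
#' @param vol An [attenuation_volume()].
#' @param geom A [scan_geometry()].
#' @param views Integer view indices; defaults to all views.
#' @param drop If `TRUE` and a single view is requested, return its matrix
#'   instead of a one-element list.
#'
#' @return A list of `det_rows x det_cols` matrices of line integrals
#'   (dimensionless), one per view, or a single matrix if `drop = TRUE`.
#' @export
forward_project <- function(vol, geom, views = seq_len(geom$n_views),
                            drop = TRUE) {
  stopifnot(inherits(vol, "attenuation_volume"),
            inherits(geom, "scan_geometry"))
  d <- dim(vol$values)
  ext <- vol$origin + d * vol$voxel_size
  if (any(abs(c(vol$origin[1:2], ext[1:2])) >= geom$sad))
    stop("source lies inside the volume support")
  out <- vector("list", length(views))
  for (k in seq_along(views)) {
    fr <- view_frame(geom, views[k])
    out[[k]] <- cpp_project_view(as.numeric(vol$values), d,
                                 vol$voxel_size, vol$origin, fr$src,
                                 fr$px, fr$py, fr$pz)
  }
  names(out) <- as.character(views)
  if (drop && length(out) == 1L) out[[1]] else out
}

#' Intersection lengths of a single projection ray
#'
#' The nonzero row of the ART system matrix for one detector pixel: voxel
#' indices and exact intersection lengths (mm) of the ray from the source
#' to the pixel center.
#'
#' @inheritParams forward_project
#' @param view View index.
#' @param row,col Detector pixel (1-based).
#'
#' @return A list with `index` (1-based linear indices into the volume
#'   array) and `length` (mm).
#' @export
system_matrix_row <- function(vol, geom, view, row, col) {
  stopifnot(inherits(vol, "attenuation_volume"),
            inherits(geom, "scan_geometry"),
            row >= 1, row <= geom$det_rows,
            col >= 1, col <= geom$det_cols)
  fr <- view_frame(geom, view)
  cpp_trace_ray(fr$src, c(fr$px[row, col], fr$py[row, col], fr$pz[row, col]),
                dim(vol$values), vol$voxel_size, vol$origin)
}

#' Trace an arbitrary ray through a voxel grid
#'
#' Low-level access to the shared ray tracer: voxel indices and
#' intersection lengths for the segment from `src` to `dst` clipped to the
#' grid bounding box.  Mostly useful for testing projector properties.
#'
#' @param vol An [attenuation_volume()].
#' @param src,dst Length-3 world coordinates, mm.
#' @return A list with `index` and `length` as in [system_matrix_row()].
#' @export
trace_ray <- function(vol, src, dst) {
  cpp_trace_ray(as.numeric(src), as.numeric(dst), dim(vol$values),
                vol$voxel_size, vol$origin)
}
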