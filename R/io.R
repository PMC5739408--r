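#' Write / read a projection stack as multi-page TIFF plus JSON sidecar
#'
#' Intensities go to `<path>.tif` (one 32-bit float page per view,
#' normalized by nothing -- raw fluence), ground truth (when present) to
#' `<path>.primary.tif` / `<path>.scatter.tif`, blocked masks to
#' `<path>.mask.tif` (8-bit), and the geometry, blocker trajectory, `i0`
#' and seed to `<path>.json`.
#'
#' @param stack A `projection_stack`.
#' @param path Output path without extension.
#' @return `path`, invisibly.
#' @export
write_projection_stack <- function(stack, path) {
  g <- stack$geometry
  scale <- max(unlist(lapply(stack$intensities, max)), 1)
  tiff::writeTIFF(lapply(stack$intensities, function(m) m / scale),
                  paste0(path, ".tif"), bits.per.sample = 32L)
  if (!is.null(stack$ground_truth)) {
    tiff::writeTIFF(lapply(stack$ground_truth$primary, function(m) m / scale),
                    paste0(path, ".primary.tif"), bits.per.sample = 32L)
    tiff::writeTIFF(lapply(stack$ground_truth$scatter, function(m) m / scale),
                    paste0(path, ".scatter.tif"), bits.per.sample = 32L)
  }
  if (!is.null(stack$masks))
    tiff::writeTIFF(lapply(stack$masks$blocked, function(m) m * 1),
                    paste0(path, ".mask.tif"), bits.per.sample = 8L)
  meta <- list(
    format_version = 1L,
    intensity_scale = scale,
    i0 = stack$i0,
    noise_seed = stack$noise_seed,
    apply_poisson = isTRUE(stack$apply_poisson),
    geometry = unclass(g),
    trajectory = if (is.null(stack$trajectory)) NULL else
      unclass(stack$trajectory))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_projection_stack
#' @export
read_projection_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  g <- meta$geometry
  geom <- scan_geometry(g$sad, g$sdd, g$n_views, g$angles, g$det_rows,
                        g$det_cols, g$pixel_pitch)
  pages <- tiff::readTIFF(paste0(path, ".tif"), all = TRUE)
  ints <- lapply(pages, function(m) m * meta$intensity_scale)
  traj <- NULL
  if (!is.null(meta$trajectory)) {
    t <- meta$trajectory
    traj <- blocker_trajectory(t$strip_width_det, t$strip_gap_det,
                               t$n_views, t$motion$amplitude,
                               t$motion$period, t$phase,
                               t$penumbra_margin,
                               if (is.null(t$cover)) c(-Inf, Inf) else t$cover)
  }
  gt <- NULL
  if (file.exists(paste0(path, ".scatter.tif"))) {
    gt <- list(
      primary = lapply(tiff::readTIFF(paste0(path, ".primary.tif"),
                                      all = TRUE),
                       function(m) m * meta$intensity_scale),
      scatter = lapply(tiff::readTIFF(paste0(path, ".scatter.tif"),
                                      all = TRUE),
                       function(m) m * meta$intensity_scale))
  }
  structure(list(intensities = ints, i0 = meta$i0, geometry = geom,
                 trajectory = traj,
                 masks = if (is.null(traj)) NULL else
                   build_masks(traj, geom),
                 ground_truth = gt, noise_seed = meta$noise_seed,
                 apply_poisson = meta$apply_poisson),
            class = "projection_stack")
}

#' Write / read an attenuation volume as MetaImage (.mha)
#'
#' Minimal MetaImage support: an ASCII header followed by the raw voxel
#' buffer (MET_FLOAT or MET_DOUBLE, local byte order), which is the
#' interchange format volumetric CT tools expect.  No installed package
#' writes MetaImage, so the few header fields needed are emitted directly.
#'
#' @param vol An [attenuation_volume()].
#' @param path Output file (`.mha`).
#' @param element_type `"float"` or `"double"`.
#' @return `path`, invisibly.
#' @export
write_volume_mha <- function(vol, path, element_type = c("float", "double")) {
  element_type <- match.arg(element_type)
  d <- dim(vol$values)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    sprintf("BinaryDataByteOrderMSB = %s",
            if (.Platform$endian == "big") "True" else "False"),
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    sprintf("ElementSpacing = %g %g %g", vol$voxel_size, vol$voxel_size,
            vol$voxel_size),
    sprintf("Offset = %g %g %g", vol$origin[1] + vol$voxel_size / 2,
            vol$origin[2] + vol$voxel_size / 2,
            vol$origin[3] + vol$voxel_size / 2),
    sprintf("ElementType = %s",
            if (element_type == "float") "MET_FLOAT" else "MET_DOUBLE"),
    "ElementDataFile = LOCAL")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  writeBin(as.numeric(vol$values), con,
           size = if (element_type == "float") 4L else 8L)
  invisible(path)
}

#' @rdname write_volume_mha
#' @export
read_volume_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, n = 1)
    hdr <- c(hdr, line)
    if (grepl("^ElementDataFile", line)) break
  }
  field <- function(key) {
    ln <- hdr[grepl(paste0("^", key, " *="), hdr)]
    trimws(sub(".*=", "", ln[1]))
  }
  d <- as.integer(strsplit(field("DimSize"), " +")[[1]])
  sp <- as.numeric(strsplit(field("ElementSpacing"), " +")[[1]])
  off <- as.numeric(strsplit(field("Offset"), " +")[[1]])
  sz <- if (field("ElementType") == "MET_FLOAT") 4L else 8L
  vals <- readBin(con, numeric(), n = prod(d), size = sz)
  attenuation_volume(array(pmax(vals, 0), d), sp[1], off - sp[1] / 2)
}

#' Serialize an edge model to JSON
#'
#' Per view, a list of `{slope, intercept, kind}` records, `kind` being
#' `"start"` or `"end"`.
#'
#' @param edges An `edge_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_edges_json <- function(edges, path) {
  ser <- lapply(edges$bands, function(bands)
    unlist(lapply(bands, function(b) list(
      list(slope = b$start[["slope"]], intercept = b$start[["intercept"]],
           kind = "start"),
      list(slope = b$end[["slope"]], intercept = b$end[["intercept"]],
           kind = "end"))), recursive = FALSE))
  jsonlite::write_json(list(method = edges$method, views = ser), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
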