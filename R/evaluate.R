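#' Convert linear attenuation to Hounsfield units
#'
#' `HU = 1000 * (mu - mu_water) / mu_water`: water maps to 0 HU, air
#' (mu = 0) to -1000 HU.  The transform is affine and exactly invertible
#' via [from_hu()].
#'
#' @param vol An [attenuation_volume()] or numeric array of mu, mm^-1.
#' @param mu_water Linear attenuation of water at the beam quality,
#'   mm^-1; must be positive.
#' @return Numeric array of CT numbers (HU) with the same dimensions.
#' @export
to_hu <- function(vol, mu_water = 0.02) {
  if (mu_water <= 0) stop("mu_water must be positive")
  a <- if (inherits(vol, "attenuation_volume")) vol$values else vol
  1000 * (a - mu_water) / mu_water
}

#' @param hu Numeric array of CT numbers.
#' @rdname to_hu
#' @export
from_hu <- function(hu, mu_water = 0.02) {
  if (mu_water <= 0) stop("mu_water must be positive")
  mu_water * (1 + hu / 1000)
}

#' Region of interest in volume coordinates
#'
#' A labelled cylinder or box in world mm coordinates, resolved to voxel
#' membership by voxel-center inclusion.
#'
#' @param label Short ROI name.
#' @param shape `"cylinder"` (axis parallel to z) or `"box"`.
#' @param center Length-3 center, mm.
#' @param radius Cylinder radius, mm (cylinder only).
#' @param half_size Length-3 half-extents, mm (`half_size[3]` is the
#'   half-height of a cylinder).
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(label, shape = c("cylinder", "box"), center,
                     radius = NULL, half_size = NULL) {
  shape <- match.arg(shape)
  if (shape == "cylinder" && (is.null(radius) || radius <= 0))
    stop("cylinder ROI needs a positive radius")
  if (is.null(half_size)) stop("half_size is required")
  structure(list(label = label, shape = shape, center = as.numeric(center),
                 radius = radius, half_size = as.numeric(half_size)),
            class = "roi_spec")
}

# Logical membership array for an ROI on a volume grid.
roi_mask <- function(vol, roi) {
  x <- voxel_centers(vol, 1) - roi$center[1]
  y <- voxel_centers(vol, 2) - roi$center[2]
  z <- voxel_centers(vol, 3) - roi$center[3]
  inz <- abs(z) <= roi$half_size[3]
  if (roi$shape == "cylinder") {
    inxy <- outer(x^2, y^2, "+") <= roi$radius^2
  } else {
    inxy <- outer(abs(x) <= roi$half_size[1], abs(y) <= roi$half_size[2],
                  "&")
  }
  m <- outer(inxy, inz, "&")
  if (!any(m)) stop(sprintf("ROI '%s' contains no voxels", roi$label))
  m
}

#' ROI mean and standard deviation
#'
#' Sample mean and population standard deviation (divide by N) of the
#' voxel values inside the ROI.
#'
#' @param vol_hu An [attenuation_volume()] (values typically in HU; the
#'   voxel grid is needed to resolve the ROI).
#' @param roi A [roi_spec()].
#' @return Named numeric vector `c(mean, std, n)`.
#' @export
roi_stats <- function(vol_hu, roi) {
  stopifnot(inherits(vol_hu, "attenuation_volume"))
  v <- vol_hu$values[roi_mask(vol_hu, roi)]
  c(mean = mean(v), std = sqrt(mean((v - mean(v))^2)), n = length(v))
}

#' ROI root-mean-square error between two aligned volumes
#'
#' `sqrt(sum_i (a_i - b_i)^2 / N)` over the ROI voxels; symmetric in its
#' two volume arguments.
#'
#' @param vol_hu,ref_hu Two [attenuation_volume()]s on the same grid
#'   (values typically in HU).
#' @param roi A [roi_spec()].
#' @return Scalar RMSE (>= 0).
#' @export
roi_rmse <- function(vol_hu, ref_hu, roi) {
  stopifnot(inherits(vol_hu, "attenuation_volume"),
            inherits(ref_hu, "attenuation_volume"))
  if (!all(dim(vol_hu$values) == dim(ref_hu$values)))
    stop("volumes must share a grid")
  m <- roi_mask(vol_hu, roi)
  sqrt(mean((vol_hu$values[m] - ref_hu$values[m])^2))
}

#' Tabulate ROI statistics for several reconstructions against a reference
#'
#' For each ROI and each labelled reconstruction, reports the mean and
#' population STD of the CT numbers plus the RMSE against the reference
#' volume (the ground-truth phantom here, standing in for the benchmark
#' modality).  Columns follow the conventional Mean, STD, RMSE layout.
#'
#' @param truth_vol Reference [attenuation_volume()] of mu (mm^-1).
#' @param recon_vols Named list of reconstructed [attenuation_volume()]s
#'   of mu on the same grid.
#' @param rois List of [roi_spec()]s.
#' @param mu_water Water attenuation for the HU conversion.
#' @return An `eval_report` data frame with columns `roi`, `method`,
#'   `mean`, `std`, `rmse` (all HU).
#' @export
compare_methods <- function(truth_vol, recon_vols, rois,
                            mu_water = 0.02) {
  stopifnot(inherits(truth_vol, "attenuation_volume"))
  if (is.null(names(recon_vols)) || any(names(recon_vols) == ""))
    stop("recon_vols must be a named list")
  truth_hu <- truth_vol
  truth_hu$values <- to_hu(truth_vol, mu_water)
  rows <- list()
  for (roi in rois) {
    ts <- roi_stats(truth_hu, roi)
    rows[[length(rows) + 1L]] <- data.frame(
      roi = roi$label, method = "reference", mean = ts[["mean"]],
      std = ts[["std"]], rmse = 0)
    for (nm in names(recon_vols)) {
      rv <- recon_vols[[nm]]
      rv_hu <- rv
      rv_hu$values <- to_hu(rv, mu_water)
      st <- roi_stats(rv_hu, roi)
      rows[[length(rows) + 1L]] <- data.frame(
        roi = roi$label, method = nm, mean = st[["mean"]],
        std = st[["std"]], rmse = roi_rmse(rv_hu, truth_hu, roi))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("eval_report", "data.frame")
  out
}
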