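#' Attenuation volume
#'
#' A 3-D grid of linear attenuation coefficients mu (mm^-1) on cubic voxels.
#' The z axis of the array is parallel to the rotation axis.
#'
#' @param values 3-D numeric array, indexed (x, y, z); all values >= 0.
#' @param voxel_size Voxel edge length, mm.
#' @param origin Length-3 world position (mm) of the corner of voxel
#'   `[1, 1, 1]` relative to the rotation axis. Default centers the grid on
#'   the isocenter.
#'
#' @return An object of class `attenuation_volume`.
#' @export
attenuation_volume <- function(values, voxel_size,
                               origin = -dim(values) * voxel_size / 2) {
  if (length(dim(values)) != 3L) stop("values must be a 3-D array")
  if (any(values < 0)) stop("attenuation values must be >= 0")
  if (voxel_size <= 0) stop("voxel_size must be positive")
  structure(list(values = values, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "attenuation_volume")
}

#' @export
print.attenuation_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("attenuation volume %d x %d x %d at %g mm voxels\n",
              d[1], d[2], d[3], x$voxel_size))
  cat(sprintf("  mu range [%g, %g] mm^-1\n", min(x$values), max(x$values)))
  invisible(x)
}

# World coordinates of voxel centers along one axis.
voxel_centers <- function(vol, axis) {
  n <- dim(vol$values)[axis]
  vol$origin[axis] + (seq_len(n) - 0.5) * vol$voxel_size
}

#' Geometric phantom specification
#'
#' A list of solid primitives painted into a volume in order: later
#' primitives overwrite earlier ones, so holes are carved by painting a
#' low-mu shape on top of its surroundings.
#'
#' @param ... Primitives created with [phantom_primitive()].
#' @return An object of class `phantom_spec`.
#' @seealso [make_phantom()]
#' @export
phantom_spec <- function(...) {
  prims <- list(...)
  if (length(prims) == 1L && is.list(prims[[1]]) &&
      !inherits(prims[[1]], "phantom_primitive"))
    prims <- prims[[1]]
  if (!all(vapply(prims, inherits, logical(1), "phantom_primitive")))
    stop("all elements must be phantom_primitive objects")
  structure(prims, class = "phantom_spec")
}

#' @param shape `"ellipsoid"` or `"cylinder"` (axis parallel to z; semi-axis
#'   3 is the half-height).
#' @param center Length-3 center, mm.
#' @param semi_axes Length-3 positive semi-axes, mm.
#' @param mu Linear attenuation coefficient, mm^-1.
#' @rdname phantom_spec
#' @export
phantom_primitive <- function(shape = c("ellipsoid", "cylinder"),
                              center, semi_axes, mu) {
  shape <- match.arg(shape)
  if (length(center) != 3L || length(semi_axes) != 3L)
    stop("center and semi_axes must have length 3")
  if (any(semi_axes <= 0)) stop("semi_axes must be positive")
  if (mu < 0) stop("mu must be >= 0")
  structure(list(shape = shape, center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes), mu = mu),
            class = "phantom_primitive")
}

#' Rasterize a phantom specification into an attenuation volume
#'
#' Voxels are assigned by center-point inclusion: a voxel takes a
#' primitive's mu iff its center lies inside the primitive; later
#' primitives overwrite earlier ones.  With `supersample > 1` each voxel is
#' instead averaged over `supersample^3` sub-points, giving partial-volume
#' (anti-aliased) boundaries -- useful when projector accuracy at object
#' edges matters more than a crisp binary phantom.
#'
#' @param spec A [phantom_spec()]; must be non-empty.
#' @param dims Length-3 grid size (voxels).
#' @param voxel_size Voxel edge length, mm.
#' @param origin Grid origin as in [attenuation_volume()].
#' @param supersample Sub-samples per axis per voxel (integer >= 1).
#'
#' @return An [attenuation_volume()].
#' @examples
#' spec <- phantom_spec(
#'   phantom_primitive("cylinder", c(0, 0, 0), c(50, 50, 60), 0.02))
#' vol <- make_phantom(spec, dims = c(32, 32, 32), voxel_size = 4)
#' @export
make_phantom <- function(spec, dims, voxel_size,
                         origin = -dims * voxel_size / 2,
                         supersample = 1L) {
  if (!inherits(spec, "phantom_spec")) stop("spec must be a phantom_spec")
  if (length(spec) == 0L) stop("empty phantom spec")
  dims <- as.integer(dims)
  vol <- array(0, dims)
  if (supersample < 1L) stop("supersample must be >= 1")
  sub <- (seq_len(supersample) - 0.5) / supersample  # in [0,1)
  xs <- origin[1] + (seq_len(dims[1]) - 1) * voxel_size
  ys <- origin[2] + (seq_len(dims[2]) - 1) * voxel_size
  zs <- origin[3] + (seq_len(dims[3]) - 1) * voxel_size
  for (ox in sub) for (oy in sub) for (oz in sub) {
    x <- xs + ox * voxel_size
    y <- ys + oy * voxel_size
    z <- zs + oz * voxel_size
    pass <- array(0, dims)
    for (pr in spec) {
      dx <- (x - pr$center[1]) / pr$semi_axes[1]
      dy <- (y - pr$center[2]) / pr$semi_axes[2]
      dz <- (z - pr$center[3]) / pr$semi_axes[3]
      r2 <- outer(dx^2, dy^2, "+")
      if (pr$shape == "ellipsoid") {
        inside <- outer(r2, dz^2, "+") <= 1
      } else {
        inside <- outer(r2 <= 1, abs(dz) <= 1, "&")
      }
      pass[inside] <- pr$mu
    }
    vol <- vol + pass
  }
  vol <- vol / supersample^3
  attenuation_volume(vol, voxel_size, origin)
}
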