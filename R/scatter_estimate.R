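#' Contiguous neighbourhood of views for joint scatter estimation
#'
#' The views contributing to the multi-view fit for one target view: a
#' contiguous window of `n_adjacent` views containing the target (shifted
#' inward at the ends of the scan).  The gantry angle spanned by the
#' window must stay below `max_span_deg`, since the joint fit assumes the
#' scatter field is essentially unchanged across the members.
#'
#' @param geom A [scan_geometry()].
#' @param view Target view index.
#' @param n_adjacent Window size (odd counts keep the target centred).
#' @param max_span_deg Largest admissible angular span, degrees.
#' @return Integer vector of member view indices.
#' @export
neighbor_views <- function(geom, view, n_adjacent, max_span_deg = 3) {
  nbr <- neighbor_window(view, n_adjacent, geom$n_views)
  span <- diff(range(geom$angles[nbr]))
  if (span > max_span_deg)
    stop(sprintf(
      "neighbourhood spans %.2f deg, above the %.2f deg limit: scatter can no longer be assumed constant across the member views",
      span, max_span_deg))
  nbr
}

# Shared SVSC/MVSC engine: per lateral column, fit the spline to the
# eroded-blocked samples of the member views and evaluate it on every
# detector row; columns whose member sample rows coincide share one
# factorization (multi-RHS solve).  A lateral moving average smooths the
# per-column fits.
estimate_scatter_views <- function(stack, masks, views, K = NULL,
                                   lateral_smooth = 11, ridge = 1e-8) {
  g <- stack$geometry
  zax <- det_axial_coords(g)
  rows_per_col <- lapply(seq_len(g$det_cols), function(cc)
    lapply(views, function(j) which(masks$eroded[[j]][, cc])))
  for (cc in seq_len(g$det_cols))
    for (k in seq_along(views))
      if (length(rows_per_col[[cc]][[k]]) == 0L)
        stop(sprintf("view %d has no eroded blocked pixels at column %d",
                     views[k], cc))
  keys <- vapply(rows_per_col, function(rl)
    paste(vapply(rl, paste, character(1), collapse = ","), collapse = ";"),
    character(1))
  out <- matrix(NA_real_, g$det_rows, g$det_cols)
  for (key in unique(keys)) {
    cols <- which(keys == key)
    rl <- rows_per_col[[cols[1]]]
    z <- unlist(lapply(rl, function(r) zax[r]))
    Y <- do.call(rbind, lapply(seq_along(views), function(k)
      stack$intensities[[views[k]]][rl[[k]], cols, drop = FALSE]))
    Kc <- if (is.null(K)) default_K(stack, range(z)) else K
    fit <- spline_lsq(z, Y, Kc, ridge)
    out[, cols] <- spline_eval(fit, zax)
  }
  lateral_running_mean(out, lateral_smooth)
}

# K default: one basis function per strip period across the sampled range,
# plus 4 for the cubic end conditions.
default_K <- function(stack, rng) {
  traj <- stack$trajectory
  period <- if (is.null(traj)) {
    diff(rng) / 4
  } else {
    traj$strip_width_det + traj$strip_gap_det
  }
  max(4L, as.integer(round(diff(rng) / period)) + 4L)
}

lateral_running_mean <- function(m, w) {
  if (w <= 1) return(m)
  t(apply(m, 1, running_mean, w = w))
}

#' Single-view scatter estimation (SVSC)
#'
#' Estimates the full-detector scatter field of one view from that view's
#' own blocked-region samples alone: per lateral column, a cubic B-spline
#' least-squares fit across the eroded blocked rows, evaluated on every
#' row (clamped beyond the outermost sample), then smoothed laterally by
#' an 11-column moving average.
#'
#' @param stack A `projection_stack`.
#' @param masks A `mask_set` (detected or ground truth).
#' @param view View index.
#' @param K Basis-function count; default one per strip period plus 4.
#' @param lateral_smooth Width (columns) of the lateral moving average.
#'
#' @return A `det_rows x det_cols` matrix: the estimated scatter field.
#' @export
estimate_scatter_svsc <- function(stack, masks, view, K = NULL,
                                  lateral_smooth = 11) {
  estimate_scatter_views(stack, masks, views = view, K = K,
                         lateral_smooth = lateral_smooth)
}

#' Multi-view scatter estimation (MVSC)
#'
#' As [estimate_scatter_svsc()], but the spline is fitted jointly to the
#' blocked-region samples of `n_adjacent` views centred on the target
#' view.  The blocker sits at different axial offsets in the member views,
#' so the joint sample set covers the axial range several times more
#' densely -- which is what repairs the single-view failure modes at
#' object boundaries and at the un-sampled end of the detector.  With
#' `n_adjacent = 1` the method collapses to SVSC exactly.
#'
#' @inheritParams estimate_scatter_svsc
#' @param n_adjacent Number of contributing views (odd keeps the window
#'   centred).
#' @param max_span_deg Largest angular span the window may cover (see
#'   [neighbor_views()]).
#'
#' @return A `det_rows x det_cols` matrix: the estimated scatter field.
#' @export
estimate_scatter_mvsc <- function(stack, masks, view, n_adjacent = 5,
                                  K = NULL, lateral_smooth = 11,
                                  max_span_deg = 3) {
  nbr <- neighbor_views(stack$geometry, view, n_adjacent, max_span_deg)
  estimate_scatter_views(stack, masks, views = nbr, K = K,
                         lateral_smooth = lateral_smooth)
}

#' Scatter-correct and log-transform a projection stack
#'
#' Subtracts the estimated scatter from the total signal on unblocked
#' pixels and log-transforms the corrected primary into line integrals:
#' `p = -log(max(total - scatter, floor) / i0)` with
#' `floor = 1e-6 * i0`.  Blocked pixels carry no primary information and
#' are masked out.
#'
#' @param stack A `projection_stack`.
#' @param scatter Per-view list of estimated scatter matrices (a single
#'   matrix is recycled to every view).
#' @param masks A `mask_set`, or `NULL` to use the stack's own masks (no
#'   masking if the stack has none).
#' @param floor_frac Clamp floor as a fraction of `i0`.
#'
#' @return An object of class `corrected_projection`: per-view `p_tilde`
#'   matrices (`NA` on blocked pixels), logical `valid` masks, and the
#'   per-view count of clamped pixels.  A diagnostic warning is raised
#'   when the estimated scatter exceeds the measured total on more than
#'   half the unblocked pixels of a view.
#' @export
correct_and_log <- function(stack, scatter, masks = NULL,
                            floor_frac = 1e-6) {
  g <- stack$geometry
  if (is.matrix(scatter)) scatter <- rep(list(scatter), g$n_views)
  if (length(scatter) != g$n_views)
    stop("scatter must provide one field per view")
  if (is.null(masks)) masks <- stack$masks
  floor_val <- floor_frac * stack$i0
  p_tilde <- valid <- vector("list", g$n_views)
  clamped <- integer(g$n_views)
  for (v in seq_len(g$n_views)) {
    unblocked <- if (is.null(masks)) {
      matrix(TRUE, g$det_rows, g$det_cols)
    } else {
      !masks$blocked[[v]]
    }
    prim <- stack$intensities[[v]] - scatter[[v]]
    nclamp <- sum(prim[unblocked] < floor_val)
    if (nclamp > 0.5 * sum(unblocked))
      warning(sprintf(
        "view %d: estimated scatter exceeds the total on %d of %d unblocked pixels",
        v, nclamp, sum(unblocked)))
    p <- -log(pmax(prim, floor_val) / stack$i0)
    p[!unblocked] <- NA_real_
    p_tilde[[v]] <- p
    valid[[v]] <- unblocked
    clamped[v] <- nclamp
  }
  structure(list(p_tilde = p_tilde, valid = valid, clamped = clamped,
                 geometry = g, i0 = stack$i0),
            class = "corrected_projection")
}

#' @export
print.corrected_projection <- function(x, ...) {
  cat(sprintf(
    "corrected projections: %d views, %.1f%% pixels usable, %d clamped\n",
    x$geometry$n_views,
    100 * mean(vapply(x$valid, mean, numeric(1))), sum(x$clamped)))
  invisible(x)
}
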