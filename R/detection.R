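#' Axial intensity profile of one view
#'
#' Intensity along the detector rows (the axial, blocker-motion direction)
#' at one lateral position, taken as the median over a small lateral band
#' of columns to suppress noise.
#'
#' @param stack A `projection_stack`.
#' @param view View index.
#' @param col Center column of the lateral band.
#' @param width Band width in columns (odd; 1 = single column).
#' @return Numeric vector of length `det_rows`.
#' @export
axial_profile <- function(stack, view, col = NULL, width = 5) {
  g <- stack$geometry
  if (is.null(col)) col <- (g$det_cols + 1) %/% 2
  half <- (width - 1) %/% 2
  cols <- max(1, col - half):min(g$det_cols, col + half)
  m <- stack$intensities[[view]][, cols, drop = FALSE]
  apply(m, 1, median)
}

#' Blocker-edge detection by the two-point method
#'
#' The classical approach: at two probe columns, blocked bands are found as
#' runs of the axial profile below a fixed intensity threshold; each band
#' edge is then the straight line through its two detected points, extended
#' across the whole detector.  Accurate when both probe points are reliable
#' and far apart, but a small error at one point tilts the line and the
#' error grows linearly toward distant columns -- the failure mode that
#' motivates the multi-view detection path.
#'
#' @param stack A `projection_stack`.
#' @param probe_cols Two lateral column indices.
#' @param threshold Intensity threshold separating blocked from unblocked.
#' @param views Views to process (default all).
#' @param perturb Optional simulated mis-detection: a list
#'   `list(views =, delta_rows =)` shifting the detected edge rows at the
#'   second probe column by `delta_rows` in the given views.
#'
#' @return An object of class `edge_model`: per view, a list of bands,
#'   each with `start` and `end` edges `c(slope, intercept)` so that the
#'   edge row at column `c` is `intercept + slope * c`.  Band rows are
#'   `start <= r < end`.
#' @export
detect_edges_two_point <- function(stack, probe_cols, threshold,
                                   views = seq_len(stack$geometry$n_views),
                                   perturb = NULL) {
  g <- stack$geometry
  if (length(probe_cols) != 2L || any(probe_cols < 1) ||
      any(probe_cols > g$det_cols))
    stop("probe_cols must be two columns within the detector")
  c1 <- probe_cols[1]; c2 <- probe_cols[2]
  if (c1 == c2) stop("probe columns must differ")
  per_view <- vector("list", length(views))
  for (k in seq_along(views)) {
    v <- views[k]
    p1 <- stack$intensities[[v]][, c1]
    p2 <- stack$intensities[[v]][, c2]
    b1 <- profile_bands(p1 < threshold)
    b2 <- profile_bands(p2 < threshold)
    if (nrow(b1) != nrow(b2))
      stop(sprintf(
        "two-point detection failure at view %d: %d vs %d bands at the probe columns",
        v, nrow(b1), nrow(b2)))
    if (!is.null(perturb) && v %in% perturb$views)
      b2 <- b2 + perturb$delta_rows
    bands <- vector("list", nrow(b1))
    for (i in seq_len(nrow(b1))) {
      bands[[i]] <- list(
        start = line_through(c1, b1[i, 1], c2, b2[i, 1]),
        end   = line_through(c1, b1[i, 2], c2, b2[i, 2]))
    }
    per_view[[k]] <- bands
  }
  structure(list(bands = setNames(per_view, views), views = views,
                 method = "two-point"),
            class = "edge_model")
}

# Runs of TRUE as a matrix with columns (start row, end row + 1).
profile_bands <- function(b) {
  r <- rle(b)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  w <- which(r$values)
  cbind(start = starts[w], end = ends[w] + 1, deparse.level = 0)
}

line_through <- function(x1, y1, x2, y2) {
  slope <- unname((y2 - y1) / (x2 - x1))
  c(slope = slope, intercept = unname(y1 - slope * x1))
}

#' Minimum envelope of adjacent-view profiles
#'
#' Pointwise minimum of axial profiles from adjacent views.  Because the
#' blocker moves between views while the scatter field barely changes,
#' every axial position is blocked in at least one nearby view once the
#' band positions of the contributing views tile the strip period, so the
#' envelope approximates the scatter profile without any edge detection.
#' Iterating the pairwise minimum over the profiles (in any order) equals
#' the direct pointwise minimum.
#'
#' @param profiles A list of equal-length numeric vectors (>= 2), or a
#'   matrix with one profile per column.
#' @return Numeric vector: the pointwise minimum.
#' @export
min_envelope <- function(profiles) {
  if (is.matrix(profiles)) profiles <- asplit(profiles, 2)
  if (length(profiles) < 2L) stop("need at least two profiles")
  n <- lengths(profiles)
  if (any(n != n[1])) stop("profiles must have equal length")
  do.call(pmin, lapply(profiles, as.numeric))
}

#' Blocker-edge detection by adaptive thresholding of the scatter envelope
#'
#' Uses the multi-view minimum envelope as a scatter proxy `S(z)` and the
#' view's own profile running maximum over one strip period as the total
#' level `U(z)`, then thresholds the profile at
#' `t(z) = S(z) + alpha * (U(z) - S(z))`.  Rows below `t` form the blocked
#' bands; each band boundary is refined per column within a +/- 3 row
#' window and a least-squares line is fitted per edge.
#'
#' @param envelope Minimum envelope (from [min_envelope()]) of profiles
#'   centred on this view.
#' @param stack A `projection_stack`.
#' @param view View index the envelope is centred on.
#' @param alpha Fraction of the scatter-to-total gap placed above the
#'   scatter level, in (0, 1).
#' @param period_px Strip period in detector rows; defaults to the stack's
#'   blocker trajectory.
#' @param col,width Lateral band used for the profiles (see
#'   [axial_profile()]).
#' @param refine_cols Fit the per-edge line to per-column refined
#'   boundaries (set `FALSE` to keep the zero-slope run boundaries).
#' @param min_band_px Discard below-threshold runs narrower than this
#'   (default: half the strip width), which suppresses spurious
#'   single-pixel bands where scatter and total levels meet.
#'
#' @return An `edge_model` for the single view.
#' @export
adaptive_threshold_edges <- function(envelope, stack, view, alpha = 0.5,
                                     period_px = NULL, col = NULL,
                                     width = 5, refine_cols = TRUE,
                                     min_band_px = NULL) {
  g <- stack$geometry
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (is.null(period_px)) {
    traj <- stack$trajectory
    if (is.null(traj)) stop("period_px required when the stack has no trajectory")
    period_px <- ceiling((traj$strip_width_det + traj$strip_gap_det) /
                           g$pixel_pitch)
  }
  prof <- axial_profile(stack, view, col, width)
  if (length(envelope) != length(prof))
    stop("envelope length must equal det_rows")
  S <- running_mean(envelope, max(3L, as.integer(period_px) %/% 2))
  # local total (unblocked) level: grayscale closing with a one-period
  # window fills the blocked valleys to the surrounding plateau without
  # displacing sharp object-shadow edges the way a bare running max would
  U <- running_min(running_max(prof, as.integer(period_px) + 1L),
                   as.integer(period_px) + 1L)
  U <- pmax(U, prof)
  S <- pmin(S, U)  # smoothing overshoot near sharp steps must not exceed U
  gap <- U - S
  if (max(gap) <= 0.02 * max(U))
    stop("degenerate profile: no blocker contrast (U ~ S everywhere)")
  thr <- S + alpha * gap
  below <- prof < thr
  bands_rc <- profile_bands(below)
  if (is.null(min_band_px)) {
    traj <- stack$trajectory
    min_band_px <- if (is.null(traj)) 2L else
      max(2L, as.integer(traj$strip_width_det / g$pixel_pitch / 2))
  }
  if (nrow(bands_rc) > 0L) {
    wide <- bands_rc[, 2] - bands_rc[, 1] >= min_band_px
    # bands clipped by the detector border are kept regardless of width
    clipped <- bands_rc[, 1] == 1L | bands_rc[, 2] == g$det_rows + 1L
    bands_rc <- bands_rc[wide | clipped, , drop = FALSE]
  }
  if (nrow(bands_rc) == 0L)
    stop("no blocked bands found")
  img <- stack$intensities[[view]]
  bands <- vector("list", nrow(bands_rc))
  cols <- seq_len(g$det_cols)
  for (i in seq_len(nrow(bands_rc))) {
    if (refine_cols) {
      s_rows <- vapply(cols, function(cc)
        refine_boundary(img[, cc], thr, bands_rc[i, 1], "start"), numeric(1))
      e_rows <- vapply(cols, function(cc)
        refine_boundary(img[, cc], thr, bands_rc[i, 2], "end"), numeric(1))
      bands[[i]] <- list(start = ls_line(cols, s_rows),
                         end = ls_line(cols, e_rows))
    } else {
      bands[[i]] <- list(
        start = c(slope = 0, intercept = unname(bands_rc[i, 1])),
        end = c(slope = 0, intercept = unname(bands_rc[i, 2])))
    }
  }
  structure(list(bands = setNames(list(bands), view), views = view,
                 method = "adaptive"),
            class = "edge_model")
}

# First row >= r0-3 within +/-3 of r0 satisfying the crossing condition.
refine_boundary <- function(prof, thr, r0, kind) {
  n <- length(prof)
  win <- max(1, r0 - 3):min(n, r0 + 3)
  hit <- if (kind == "start") prof[win] < thr[win] else prof[win] >= thr[win]
  w <- which(hit)
  if (length(w) == 0L) return(r0)
  win[w[1]]
}

ls_line <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  vx <- sum((x - mx)^2)
  slope <- if (vx > 0) sum((x - mx) * (y - my)) / vx else 0
  c(slope = slope, intercept = my - slope * mx)
}

running_mean <- function(x, w) {
  w <- max(1L, as.integer(w))
  k <- rep(1 / w, w)
  n <- length(x)
  pad <- (w - 1L) %/% 2L
  xp <- c(rep(x[1], pad), x, rep(x[n], w - 1L - pad))
  as.numeric(stats::filter(xp, k, sides = 1))[w:(n + w - 1L)]
}

running_max <- function(x, w) {
  n <- length(x)
  half <- (w - 1L) %/% 2L
  vapply(seq_len(n), function(i)
    max(x[max(1, i - half):min(n, i + half)]), numeric(1))
}

running_min <- function(x, w) -running_max(-x, w)

#' Multi-view adaptive edge detection across a whole stack
#'
#' Convenience driver: for every view, builds the minimum envelope from the
#' axial profiles of the `n_adjacent` surrounding views and runs
#' [adaptive_threshold_edges()].
#'
#' @param stack A `projection_stack`.
#' @param n_adjacent Number of contributing views (window is clipped and
#'   shifted at the ends of the scan so it stays contiguous).
#' @param alpha,col,width,refine_cols Passed on to
#'   [adaptive_threshold_edges()].
#' @return An `edge_model` covering all views.
#' @export
detect_edges_adaptive <- function(stack, n_adjacent = 5, alpha = 0.5,
                                  col = NULL, width = 5,
                                  refine_cols = TRUE) {
  g <- stack$geometry
  all_bands <- vector("list", g$n_views)
  for (v in seq_len(g$n_views)) {
    nbr <- neighbor_window(v, n_adjacent, g$n_views)
    profs <- lapply(nbr, function(j) axial_profile(stack, j, col, width))
    env <- if (length(profs) >= 2) min_envelope(profs) else profs[[1]]
    em <- adaptive_threshold_edges(env, stack, v, alpha, col = col,
                                   width = width, refine_cols = refine_cols)
    all_bands[[v]] <- em$bands[[1]]
  }
  structure(list(bands = setNames(all_bands, seq_len(g$n_views)),
                 views = seq_len(g$n_views), method = "adaptive"),
            class = "edge_model")
}

# Contiguous window of n views containing v, clipped to [1, n_views].
neighbor_window <- function(v, n, n_views) {
  n <- min(n, n_views)
  half <- (n - 1L) %/% 2L
  lo <- v - half
  hi <- lo + n - 1L
  if (lo < 1L) { lo <- 1L; hi <- n }
  if (hi > n_views) { hi <- n_views; lo <- n_views - n + 1L }
  lo:hi
}

#' Evaluate an edge model at a column
#'
#' @param edges An `edge_model`.
#' @param view View index.
#' @param col Column at which to evaluate the edge lines.
#' @return Matrix with one row per band and columns `start`, `end` (row
#'   coordinates).
#' @export
edge_rows <- function(edges, view, col) {
  bands <- edges$bands[[as.character(view)]]
  if (is.null(bands)) stop(sprintf("view %d not present in edge model", view))
  t(vapply(bands, function(b)
    c(start = b$start[["intercept"]] + b$start[["slope"]] * col,
      end = b$end[["intercept"]] + b$end[["slope"]] * col),
    numeric(2)))
}

#' Convert an edge model into blocked/eroded masks
#'
#' @param edges An `edge_model` covering the views of `geom`.
#' @param geom A [scan_geometry()].
#' @param penumbra_margin Pixels trimmed from each side of every band in
#'   the eroded mask.
#' @return A `mask_set`.
#' @export
edges_to_masks <- function(edges, geom, penumbra_margin = 2) {
  blocked <- eroded <- vector("list", geom$n_views)
  for (v in seq_len(geom$n_views)) {
    bands <- edges$bands[[as.character(v)]]
    if (is.null(bands)) stop(sprintf("edge model lacks view %d", v))
    b <- matrix(FALSE, geom$det_rows, geom$det_cols)
    for (cc in seq_len(geom$det_cols)) {
      for (bd in bands) {
        s <- bd$start[["intercept"]] + bd$start[["slope"]] * cc
        e <- bd$end[["intercept"]] + bd$end[["slope"]] * cc
        rr <- max(1, ceiling(s)):min(geom$det_rows, ceiling(e) - 1)
        if (length(rr) > 0 && rr[1] <= rr[length(rr)]) b[rr, cc] <- TRUE
      }
    }
    e <- apply(b, 2, erode_runs, m = penumbra_margin)
    blocked[[v]] <- b
    eroded[[v]] <- matrix(e, geom$det_rows, geom$det_cols)
  }
  structure(list(blocked = blocked, eroded = eroded), class = "mask_set")
}
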