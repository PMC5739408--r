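#' Total variation of an attenuation volume
#'
#' `f(mu) = sum sqrt(dx^2 + dy^2 + dz^2 + delta)` over all voxels with a
#' full set of backward neighbours, where `dx, dy, dz` are the backward
#' finite differences.  The smoothing constant `delta` keeps the gradient
#' defined on flat regions, at the cost of `f` evaluating to
#' `sqrt(delta) * n_terms` rather than exactly zero on a constant volume.
#'
#' @param vol An [attenuation_volume()] (at least 2 voxels per dimension),
#'   or a plain 3-D array.
#' @param delta Smoothing constant inside the square root.
#' @return Scalar TV value (>= 0).
#' @export
tv_value <- function(vol, delta = 1e-8) {
  a <- if (inherits(vol, "attenuation_volume")) vol$values else vol
  if (any(dim(a) < 2)) stop("volume must be at least 2 voxels per dimension")
  cpp_tv_value(as.numeric(a), dim(a), delta)
}

# Analytic gradient of tv_value with respect to every voxel.
tv_gradient <- function(vol, delta = 1e-8) {
  a <- if (inherits(vol, "attenuation_volume")) vol$values else vol
  array(cpp_tv_grad(as.numeric(a), dim(a), delta), dim(a))
}

#' One ART pass over the usable rays
#'
#' Sequential Kaczmarz updates
#' `mu <- mu + lambda * a_j * (p_j - <a_j, mu>) / ||a_j||^2` for every
#' unblocked, finite ray `j`, with the intersection lengths `a_j` computed
#' on demand by the same Siddon tracer as [forward_project()].  Views are
#' visited in a bit-reversed order (spreading angular coverage through the
#' pass); rays run in column-major detector order within a view.  Rays
#' whose path misses the grid are skipped and counted.
#'
#' @param vol Current volume estimate (an [attenuation_volume()]).
#' @param proj A `corrected_projection` (its validity mask selects the
#'   rays used).
#' @param geom A [scan_geometry()].
#' @param lambda Relaxation factor in (0, 1].
#' @param nonneg Clamp the volume at zero after the pass.
#'
#' @return A list: `vol` (updated volume), `update_norm` (L2 norm of the
#'   accumulated per-ray updates), `residual_rms` (RMS of `p - A mu` over
#'   the rays, before each one's update), `n_used`, `n_skipped`.
#' @export
art_pass <- function(vol, proj, geom, lambda = 0.5, nonneg = TRUE) {
  stopifnot(inherits(vol, "attenuation_volume"),
            inherits(proj, "corrected_projection"))
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  d <- dim(vol$values)
  v <- as.numeric(vol$values)  # private copy: C++ updates it in place
  sq_update <- sq_resid <- 0
  n_used <- n_skipped <- 0L
  for (view in bit_reversed_order(geom$n_views)) {
    use <- proj$valid[[view]] & is.finite(proj$p_tilde[[view]])
    if (!any(use)) next
    p <- proj$p_tilde[[view]]
    p[!use] <- 0
    fr <- view_frame(geom, view)
    st <- cpp_art_view(v, d, vol$voxel_size, vol$origin, fr$src,
                       fr$px, fr$py, fr$pz, p, use, lambda)
    sq_update <- sq_update + st[1]
    sq_resid <- sq_resid + st[2]
    n_used <- n_used + as.integer(st[3])
    n_skipped <- n_skipped + as.integer(st[4])
  }
  if (nonneg) v[v < 0] <- 0
  out <- vol
  out$values <- array(v, d)
  list(vol = out, update_norm = sqrt(sq_update),
       residual_rms = if (n_used > 0) sqrt(sq_resid / n_used) else 0,
       n_used = n_used, n_skipped = n_skipped)
}

# Permutation of 1..n in bit-reversed order (multilevel view schedule).
bit_reversed_order <- function(n) {
  bits <- ceiling(log2(max(n, 2)))
  idx <- 0:(2^bits - 1)
  rev_bits <- vapply(idx, function(i) {
    r <- 0L
    for (b in seq_len(bits)) {
      r <- bitwOr(bitwShiftL(r, 1L), bitwAnd(i, 1L))
      i <- bitwShiftR(i, 1L)
    }
    r
  }, integer(1))
  (rev_bits[rev_bits < n]) + 1L
}

#' Steepest-descent TV minimization steps
#'
#' `tv_steps` steps of `mu <- mu - s * grad f / ||grad f||`, with the step
#' size tied to the preceding ART pass (`s = tv_step_scale *
#' ref_update_norm`, adaptive-steepest-descent style).  Each step is
#' backtracked (halving `s`, up to 10 times) until `f` does not increase,
#' so the TV value is non-increasing across the call; a zero gradient is a
#' no-op.
#'
#' @param vol An [attenuation_volume()].
#' @param ref_update_norm Norm of the preceding ART pass's update.
#' @param tv_steps Number of descent steps.
#' @param tv_step_scale Step size as a fraction of `ref_update_norm`.
#' @param delta TV smoothing constant.
#' @return The updated [attenuation_volume()].
#' @export
tv_descent <- function(vol, ref_update_norm, tv_steps = 10,
                       tv_step_scale = 0.2, delta = 1e-8) {
  if (tv_steps <= 0 || ref_update_norm <= 0) return(vol)
  a <- vol$values
  d <- dim(a)
  s <- tv_step_scale * ref_update_norm
  f <- cpp_tv_value(as.numeric(a), d, delta)
  for (k in seq_len(tv_steps)) {
    g <- cpp_tv_grad(as.numeric(a), d, delta)
    gn <- sqrt(sum(g^2))
    if (gn == 0) break
    step <- s
    ok <- FALSE
    for (try in 1:10) {
      cand <- as.numeric(a) - step * g / gn
      fc <- cpp_tv_value(cand, d, delta)
      if (fc <= f) {
        a <- array(cand, d)
        f <- fc
        ok <- TRUE
        break
      }
      step <- step / 2
    }
    if (!ok) break
  }
  out <- vol
  out$values <- a
  out
}

#' TV-constrained ART reconstruction
#'
#' Reconstructs the attenuation volume from scatter-corrected, partially
#' masked projections by alternating a relaxed ART pass over the usable
#' (unblocked) rays with steepest-descent steps on the total variation,
#' under a non-negativity constraint.  The blocked rays simply drop out of
#' the data-fidelity term; the TV prior supplies the missing information,
#' in the manner of compressed-sensing few-view CT.  Iteration stops after
#' `n_iterations` passes, or earlier once the data residual falls below
#' `epsilon` or plateaus (relative change below `plateau_tol`); a residual
#' rising over three consecutive passes aborts with the residual trace in
#' the error.
#'
#' @param proj A `corrected_projection`.
#' @param geom A [scan_geometry()].
#' @param dims Length-3 reconstruction grid size (voxels).
#' @param voxel_size Voxel edge length, mm.
#' @param origin Grid origin (mm); default centres the grid on the
#'   isocenter.
#' @param lambda ART relaxation factor in (0, 1].
#' @param n_iterations Number of ART passes.
#' @param tv_steps,tv_step_scale TV descent schedule per pass (see
#'   [tv_descent()]).
#' @param epsilon Optional data-fidelity stop: halt once the RMS residual
#'   (line-integral units) drops below it.
#' @param plateau_tol Relative residual change below which iteration
#'   stops.
#' @param nonneg Enforce `mu >= 0` after every pass.
#' @param verbose Print per-iteration residual and TV.
#'
#' @return An object of class `cbct_recon`: `vol` (the reconstructed
#'   [attenuation_volume()]), `trace` (per-iteration data frame with
#'   `residual_rms`, `tv`, `update_norm`) and the settings used.
#' @export
reconstruct <- function(proj, geom, dims, voxel_size,
                        origin = -dims * voxel_size / 2,
                        lambda = 0.5, n_iterations = 30,
                        tv_steps = 10, tv_step_scale = 0.2,
                        epsilon = NULL, plateau_tol = 1e-4,
                        nonneg = TRUE, verbose = FALSE) {
  stopifnot(inherits(proj, "corrected_projection"),
            inherits(geom, "scan_geometry"))
  vol <- attenuation_volume(array(0, dims), voxel_size, origin)
  trace <- data.frame(iteration = integer(), residual_rms = numeric(),
                      tv = numeric(), update_norm = numeric())
  if (n_iterations <= 0)
    return(structure(list(vol = vol, trace = trace,
                          settings = list(lambda = lambda,
                                          n_iterations = n_iterations)),
                     class = "cbct_recon"))
  rising <- 0L
  prev <- Inf
  for (it in seq_len(n_iterations)) {
    st <- art_pass(vol, proj, geom, lambda, nonneg)
    vol <- st$vol
    if (tv_steps > 0) {
      vol <- tv_descent(vol, st$update_norm, tv_steps, tv_step_scale)
      if (nonneg) vol$values[vol$values < 0] <- 0  # descent can undercut 0
    }
    res <- st$residual_rms
    trace <- rbind(trace, data.frame(iteration = it, residual_rms = res,
                                     tv = tv_value(vol),
                                     update_norm = st$update_norm))
    if (verbose)
      message(sprintf("  pass %2d: residual %.5g, TV %.5g", it, res,
                      trace$tv[it]))
    if (res > prev) rising <- rising + 1L else rising <- 0L
    if (rising >= 3L)
      stop(paste0("residual diverging for 3 consecutive passes: ",
                  paste(signif(utils::tail(trace$residual_rms, 5), 5),
                        collapse = ", ")))
    if (!is.null(epsilon) && res <= epsilon) break
    if (is.finite(prev) && abs(prev - res) < plateau_tol * prev) break
    prev <- res
  }
  structure(list(vol = vol, trace = trace,
                 settings = list(lambda = lambda,
                                 n_iterations = n_iterations,
                                 tv_steps = tv_steps,
                                 tv_step_scale = tv_step_scale,
                                 epsilon = epsilon,
                                 plateau_tol = plateau_tol)),
            class = "cbct_recon")
}

#' @export
print.cbct_recon <- function(x, ...) {
  d <- dim(x$vol$values)
  cat(sprintf("TV-ART reconstruction: %d x %d x %d at %g mm voxels\n",
              d[1], d[2], d[3], x$vol$voxel_size))
  if (nrow(x$trace) > 0)
    cat(sprintf("  %d passes, final residual RMS %.5g, TV %.5g\n",
                nrow(x$trace), utils::tail(x$trace$residual_rms, 1),
                utils::tail(x$trace$tv, 1)))
  invisible(x)
}

#' @param x A `cbct_recon`.
#' @param slice Axial slice index (default: central).
#' @param ... Passed to [graphics::image()].
#' @rdname reconstruct
#' @export
plot.cbct_recon <- function(x, slice = NULL, ...) {
  d <- dim(x$vol$values)
  if (is.null(slice)) slice <- (d[3] + 1) %/% 2
  image(x$vol$values[, , slice], asp = 1, useRaster = TRUE,
        main = sprintf("mu, slice z = %d", slice), ...)
  invisible(x)
}
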