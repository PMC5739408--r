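#' Collect scatter samples from blocked regions of adjacent views
#'
#' Gathers, at one lateral column, the detected intensities of every
#' eroded-blocked pixel of each contributing view.  Because the blocker
#' translates axially between views, the member views sample the scatter
#' profile at different axial positions; the union of their samples is what
#' lifts the multi-view fit over the single-view one.  Duplicated axial
#' positions (views with identical offsets) are retained, which weights
#' them by repetition in the least-squares fit.
#'
#' @param stack A `projection_stack`.
#' @param masks A `mask_set` (detected or ground truth).
#' @param views Contributing view indices (the neighbourhood, including the
#'   view being corrected).
#' @param col Lateral column index.
#'
#' @return An object of class `scatter_samples`: a data frame with columns
#'   `z` (axial position, mm), `value` (intensity), `view`, `row`.
#' @export
collect_samples <- function(stack, masks, views, col) {
  g <- stack$geometry
  zax <- det_axial_coords(g)
  parts <- lapply(views, function(j) {
    rows <- which(masks$eroded[[j]][, col])
    if (length(rows) == 0L)
      stop(sprintf("view %d has no eroded blocked pixels at column %d",
                   j, col))
    data.frame(z = zax[rows], value = stack$intensities[[j]][rows, col],
               view = j, row = rows)
  })
  out <- do.call(rbind, parts)
  class(out) <- c("scatter_samples", "data.frame")
  attr(out, "col") <- col
  out
}

# Shared least-squares machinery: cubic B-spline basis on uniform knots
# spanning the sample range, fitted by the normal equations (the objective
# is linear in the weights, so the direct solve is the converged Newton
# step).  A small ridge is added only when the Cholesky factorization
# fails, so well-posed fits are the exact least-squares solution.  Y may
# have several columns (several lateral positions sharing the same sample
# rows).
spline_lsq <- function(z, Y, K, ridge = 1e-8) {
  Y <- as.matrix(Y)
  K <- as.integer(K)
  if (K < 4) stop("K must be >= 4")
  if (length(z) < K)
    stop(sprintf("need at least K = %d samples, got %d", K, length(z)))
  rng <- range(z)
  if (diff(rng) <= 0) stop("samples must span a nonzero axial range")
  h <- diff(rng) / (K - 3)
  knots <- rng[1] + h * (-3:K)
  B <- splines::splineDesign(knots, z, ord = 4)
  covered <- colSums(abs(B)) > 0
  if (!all(covered)) {
    k0 <- which(!covered)[1]
    stop(sprintf(
      "rank-deficient design: basis function %d (knot span [%.2f, %.2f] mm) has no samples",
      k0, knots[k0], knots[k0 + 4]))
  }
  M <- crossprod(B)
  R <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(R)) {
    diag(M) <- diag(M) + ridge
    R <- chol(M)
  }
  A <- backsolve(R, forwardsolve(t(R), crossprod(B, Y)))
  list(coef = A, knots = knots, range = rng, K = K, basis = B)
}

# Evaluate the fitted spline(s) at z, clamping beyond the sampled range to
# the end value (constant extrapolation).
spline_eval <- function(fit, z) {
  zc <- pmin(pmax(z, fit$range[1]), fit$range[2])
  Be <- splines::splineDesign(fit$knots, zc, ord = 4)
  Be %*% fit$coef
}

#' Fit a cubic B-spline scatter model to blocked-region samples
#'
#' Finds the basis weights `a` minimizing
#' `sum_j sum_n (S_j(z_jn) - sum_k a_k W_k(z_jn))^2` over all samples of
#' the contributing views, where `W_k` are cubic B-splines on uniform
#' knots spanning the sampled axial range.  The evaluated model
#' `S(z) = sum_k a_k W_k(z)` is the estimated scatter profile; beyond the
#' outermost sample it is clamped to the end value.
#'
#' @param samples A [collect_samples()] result, or any data frame with
#'   columns `z` and `value`.
#' @param K Number of basis functions (>= 4); the sample count must be at
#'   least `K`.
#' @param ridge Ridge added to the normal-equations diagonal only when
#'   the plain Cholesky solve fails (near-singular designs).
#'
#' @return An object of class `scatter_spline` with `coef`, `print`,
#'   `predict`, `fitted` and `residuals` methods.
#' @examples
#' s <- data.frame(z = seq(-40, 40, by = 2), value = 5 + 0 * seq(-40, 40, by = 2))
#' f <- fit_spline(s, K = 8)
#' predict(f, c(-60, 0, 60))  # constant 5 everywhere (partition of unity)
#' @export
fit_spline <- function(samples, K, ridge = 1e-8) {
  fit <- spline_lsq(samples$z, samples$value, K, ridge)
  structure(list(coef = drop(fit$coef), knots = fit$knots,
                 range = fit$range, K = fit$K, samples = samples),
            class = "scatter_spline")
}

#' @export
coef.scatter_spline <- function(object, ...) object$coef

#' @param object,newdata A fitted `scatter_spline` and axial positions
#'   (mm) at which to evaluate it; defaults to the sample positions.
#' @rdname fit_spline
#' @export
predict.scatter_spline <- function(object, newdata = NULL, ...) {
  z <- if (is.null(newdata)) object$samples$z else as.numeric(newdata)
  drop(spline_eval(list(coef = object$coef, knots = object$knots,
                        range = object$range), z))
}

#' @export
fitted.scatter_spline <- function(object, ...) predict(object)

#' @export
residuals.scatter_spline <- function(object, ...)
  object$samples$value - fitted(object)

#' @export
print.scatter_spline <- function(x, ...) {
  cat(sprintf(
    "cubic B-spline scatter fit: K = %d basis functions on [%.1f, %.1f] mm\n",
    x$K, x$range[1], x$range[2]))
  cat(sprintf("  %d samples, RMS residual %.4g\n", nrow(x$samples),
              sqrt(mean(residuals(x)^2))))
  invisible(x)
}
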