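#' Simulate a low-frequency scatter field
#'
#' Generates per-view scatter as a scatter-to-primary-ratio (SPR) scaled
#' Gaussian low-pass of the primary fluence deficit `i0 - primary`.  The
#' deficit is large where the object attenuates strongly, so the blurred
#' deficit mimics the real behaviour of detected scatter: a smooth field
#' that peaks behind the object and decays slowly past its boundary.  Each
#' view is normalized so that `mean(scatter) / mean(primary) == spr` over
#' the object shadow (pixels whose deficit exceeds 1% of `i0`); views with
#' no shadow get zero scatter.  Because the primary rotates slowly with the
#' gantry, the resulting scatter also varies slowly from view to view.
#'
#' @param primary List of per-view primary fluence matrices (>= 0).
#' @param i0 Open-field fluence (scalar).
#' @param spr Scatter-to-primary ratio over the object shadow; must be
#'   >= 0.
#' @param blur_sigma Gaussian low-pass width at the detector, mm.
#' @param pixel_pitch Detector pixel size, mm.
#'
#' @return List of per-view scatter matrices.
#' @export
simulate_scatter <- function(primary, i0, spr = 1.0, blur_sigma = 40,
                             pixel_pitch = 0.8) {
  if (is.matrix(primary)) primary <- list(primary)
  if (spr < 0) stop("spr must be >= 0")
  if (blur_sigma <= 0) stop("blur_sigma must be positive")
  lapply(primary, function(pm) {
    if (any(pm < 0)) stop("primary must be >= 0")
    if (spr == 0) return(matrix(0, nrow(pm), ncol(pm)))
    deficit <- i0 - pm
    sc <- gauss_blur2d(deficit, blur_sigma / pixel_pitch)
    shadow <- deficit > 0.01 * i0
    if (!any(shadow)) return(matrix(0, nrow(pm), ncol(pm)))
    target <- spr * mean(pm[shadow])
    have <- mean(sc[shadow])
    if (have <= 0) return(matrix(0, nrow(pm), ncol(pm)))
    sc * (target / have)
  })
}

#' Separable Gaussian blur of a matrix
#'
#' Truncated-Gaussian convolution (radius 3 sigma) applied along rows then
#' columns, with the kernel renormalized at the borders so that a constant
#' input is preserved exactly.
#'
#' @param m Numeric matrix.
#' @param sigma_px Gaussian sigma in pixels; values below ~0.3 px return
#'   `m` unchanged.
#' @return Blurred matrix of the same size.
#' @export
gauss_blur2d <- function(m, sigma_px) {
  if (sigma_px < 0.3) return(m)
  blur_operator(nrow(m), sigma_px) %*% m %*%
    t(blur_operator(ncol(m), sigma_px))
}

# n x n row-stochastic blur operator: truncated Gaussian kernel, each row
# renormalized to sum 1 (mass-preserving replicate-like boundary rule).
blur_operator <- function(n, sigma_px) {
  r <- ceiling(3 * sigma_px)
  k <- exp(-((-r:r)^2) / (2 * sigma_px^2))
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1 & j <= n
    B[i, j[ok]] <- k[ok]
  }
  B / rowSums(B)
}
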