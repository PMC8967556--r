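# Discrete total variation: forward-difference gradient with Neumann
# (replicate) boundary, its exact negative adjoint (divergence), the isotropic
# TV functional, and the per-pixel dual-ball projection used by PDHG.
#
# With this stencil the operator norm satisfies ||D||^2 <= 8, the classical
# bound underlying the PDHG step-size choice tau * theta * 8 < 1.

#' Discrete image gradient
#'
#' Forward differences with Neumann boundary:
#' `px[i,j] = u[i,j+1] - u[i,j]` (0 at the last column) and
#' `py[i,j] = u[i+1,j] - u[i,j]` (0 at the last row).
#'
#' @param u complex H x W matrix, H, W >= 2.
#' @return list with complex matrices `px`, `py` (a dual-domain field).
#' @export
img_grad <- function(u) {
  u <- check_image(u)
  h <- nrow(u); w <- ncol(u)
  px <- matrix(0i, h, w); py <- matrix(0i, h, w)
  px[, -w] <- u[, -1, drop = FALSE] - u[, -w, drop = FALSE]
  py[-h, ] <- u[-1, , drop = FALSE] - u[-h, , drop = FALSE]
  list(px = px, py = py)
}

#' Discrete divergence (negative adjoint of the gradient)
#'
#' Backward-difference divergence chosen so that
#' `<img_grad(u), p> = <u, -img_div(p)>` holds exactly (up to rounding) for
#' every image/field pair, the adjoint relation PDHG convergence rests on.
#'
#' @param p list with complex H x W matrices `px`, `py`.
#' @return complex H x W matrix.
#' @export
img_div <- function(p) {
  px <- as.matrix(p$px); py <- as.matrix(p$py)
  h <- nrow(px); w <- ncol(px)
  dx <- px
  dx[, 2:w] <- px[, 2:w, drop = FALSE] - px[, 1:(w - 1), drop = FALSE]
  dx[, w] <- -px[, w - 1, drop = FALSE]
  dy <- py
  dy[2:h, ] <- py[2:h, , drop = FALSE] - py[1:(h - 1), , drop = FALSE]
  dy[h, ] <- -py[h - 1, , drop = FALSE]
  dx + dy
}

#' Isotropic total-variation seminorm
#'
#' Sum over pixels of the Euclidean norm of the discrete gradient,
#' `sum_i sqrt(|px_i|^2 + |py_i|^2)`; the complex modulus couples the real and
#' imaginary parts so the functional stays convex on complex images.
#'
#' @param u complex H x W matrix.
#' @return nonnegative real scalar; 0 iff `u` is constant.
#' @export
tv_norm <- function(u) {
  p <- img_grad(u)
  sum(sqrt(abs(p$px)^2 + abs(p$py)^2))
}

#' Projection onto the TV dual unit ball
#'
#' Per-pixel radial projection `p_i / max(||p_i||_2, 1)` where
#' `||p_i||_2 = sqrt(|px_i|^2 + |py_i|^2)`; idempotent and nonexpansive.
#'
#' @param p list with complex matrices `px`, `py`.
#' @return projected field of the same shape.
#' @export
project_dual <- function(p) {
  nrm <- sqrt(abs(p$px)^2 + abs(p$py)^2)
  scale <- 1 / pmax(nrm, 1)
  list(px = p$px * scale, py = p$py * scale)
}
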