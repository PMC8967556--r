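# Primal-dual hybrid gradient solver for the weighted TV-denoising subproblem
#
#   min_v  TV(v) + sum_x w(x) |v(x) - t(x)|^2
#
# via the saddle form  min_v max_{||p_i|| <= 1} <p, Dv> + sum_x w |v - t|^2.
# The iteration alternates the dual ascent-and-project step with the exact
# proximal primal step; both have closed forms. The weight may be a scalar or
# a per-pixel field (the coil-splitting ADMM needs the field form when
# sensitivity maps are unnormalized; pixels with w = 0 see no fidelity pull).

#' PDHG step-size and stopping parameters
#'
#' @param tau positive dual step size.
#' @param theta positive primal step size. The defaults `tau = theta =
#'   1/sqrt(8)` satisfy the stability bound `tau * theta * ||D||^2 < 1`
#'   (with `||D||^2 <= 8` for the forward-difference stencil); choices
#'   violating the bound trigger a warning but still run.
#' @param max_iters maximum iterations.
#' @param tol relative-change stopping tolerance on the primal iterate.
#' @return list of class `"pdhg_params"`.
#' @export
pdhg_params <- function(tau = 1 / sqrt(8), theta = 1 / sqrt(8),
                        max_iters = 200L, tol = 1e-8) {
  if (!is.numeric(tau) || tau <= 0 || !is.numeric(theta) || theta <= 0)
    stop_contract("tau and theta must be positive")
  if (max_iters < 1L)
    stop_contract("max_iters must be >= 1")
  if (!is.numeric(tol) || tol <= 0)
    stop_contract("tol must be positive")
  if (tau * theta * 8 >= 1)
    warning(sprintf("tau*theta*8 = %.3g >= 1 violates the PDHG stability bound; proceeding anyway",
                    tau * theta * 8), call. = FALSE)
  structure(list(tau = tau, theta = theta,
                 max_iters = as.integer(max_iters), tol = tol),
            class = "pdhg_params")
}

# Internal workhorse: weight w is a scalar or H x W matrix >= 0; v0/p0 allow
# warm starts across ADMM outer iterations. Returns v and the final dual p.
pdhg_weighted_denoise <- function(target, w, params, v0 = NULL, p0 = NULL) {
  target <- as.matrix(target) + 0i
  if (length(w) == 1L) w <- matrix(w, nrow(target), ncol(target))
  v <- if (is.null(v0)) target else as.matrix(v0) + 0i
  p <- if (is.null(p0)) list(px = matrix(0i, nrow(v), ncol(v)),
                             py = matrix(0i, nrow(v), ncol(v))) else p0
  tau <- params$tau; theta <- params$theta
  denom <- 1 + 2 * theta * w
  for (it in seq_len(params$max_iters)) {
    g <- img_grad(v)
    p <- project_dual(list(px = p$px + tau * g$px, py = p$py + tau * g$py))
    # D^T p = -div(p); exact minimizer of <D^T p, v> + w|v-t|^2 + |v-v_k|^2/(2 theta)
    v_new <- (v + theta * img_div(p) + 2 * theta * w * target) / denom
    rel <- sqrt(sum(abs(v_new - v)^2)) / max(sqrt(sum(abs(v)^2)), 1e-12)
    v <- v_new
    if (rel < params$tol) break
  }
  list(v = v, p = p, iterations = it)
}

#' TV denoising by primal-dual hybrid gradient
#'
#' Solves `min_v TV(v) + weight * ||v - u_ref||_2^2` by alternating the dual
#' update `p <- Pi_X(p + tau * D v)` (projection onto the per-pixel unit
#' ball) with the closed-form proximal primal update combining `v`, `u_ref`
#' and `div(p)`. This is the inner solver for the image subproblem of both
#' reconstruction schemes.
#'
#' @param u_ref complex H x W matrix to stay close to.
#' @param weight positive fidelity weight (scalar, or per-pixel matrix with
#'   nonnegative entries for the weighted form).
#' @param params a [pdhg_params()] object.
#' @return denoised complex H x W matrix.
#' @export
pdhg_tv_denoise <- function(u_ref, weight, params = pdhg_params()) {
  u_ref <- check_image(u_ref, "u_ref")
  if (length(weight) == 1L) {
    if (!is.numeric(weight) || weight <= 0)
      stop_contract("weight must be positive")
  } else {
    weight <- as.matrix(weight)
    if (!identical(dim(weight), dim(u_ref)) || any(weight < 0))
      stop_contract("weight field must be a nonnegative H x W matrix")
  }
  pdhg_weighted_denoise(u_ref, weight, params)$v
}
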