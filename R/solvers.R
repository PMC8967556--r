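# The two alternating-direction reconstruction schemes.
#
# Coil-splitting ADMM: split X_j = S_j u so the per-coil data subproblem
# becomes diagonal in k-space (M^T M + alpha I is diagonal for a binary mask)
# and the image subproblem is a weighted TV denoise solved inexactly by
# warm-started PDHG.
#
# Penalty splitting: introduce v = u with a quadratic penalty; alternate a TV
# denoise in v with a linearized (majorized) data step in u whose local
# curvature delta_k = ||A(u^k - u^{k-1})||^2 / ||u^k - u^{k-1}||^2 estimates
# ||A||^2 along the current trajectory.

#' Outer-loop parameters for the alternating-direction solvers
#'
#' @param outer_iters maximum outer iterations.
#' @param tol relative-change stopping tolerance
#'   `||u_{k+1} - u_k|| / max(||u_k||, 1e-12)`.
#' @param inner a [pdhg_params()] object for the TV subproblem. The default
#'   budget of 20 warm-started inner iterations solves the image subproblem
#'   inexactly, which suffices because the outer loop refines the target.
#' @return list of class `"admm_params"`.
#' @export
admm_params <- function(outer_iters = 100L, tol = 1e-6,
                        inner = pdhg_params(max_iters = 20L)) {
  if (outer_iters < 1L) stop_contract("outer_iters must be >= 1")
  if (!is.numeric(tol) || tol <= 0) stop_contract("tol must be positive")
  stopifnot(inherits(inner, "pdhg_params"))
  structure(list(outer_iters = as.integer(outer_iters), tol = tol,
                 inner = inner),
            class = "admm_params")
}

#' TV-SENSE objective
#'
#' The reconstruction objective `TV(u) + lambda * sum_j ||M F S_j u - f_j||^2`
#' that both solvers minimize.
#'
#' @param u complex H x W matrix.
#' @param problem a [recon_problem()] (supplies `lambda`, data, maps, mask).
#' @return nonnegative real scalar.
#' @export
recon_objective <- function(u, problem) {
  tv_norm(u) + problem$lambda * data_fidelity(u, problem)
}

#' Per-coil data subproblem of the coil-splitting scheme
#'
#' Exact minimizer of `||M F X - f_j||^2 + alpha ||X - x_rhs||^2`, computed in
#' closed form through the Fourier-diagonal factorization
#' `F^T M^T M F + alpha I = F^T (M + alpha I) F` (M binary, so `M^T M = M`
#' elementwise):
#' `X = F^{-1}[ (M f_j + alpha F(x_rhs)) / (M + alpha) ]`.
#'
#' @param x_rhs complex H x W matrix the solution is pulled towards
#'   (`S_j u - b_j` in the ADMM cycle).
#' @param f_j complex H x W k-space data for this coil (zeros off-mask).
#' @param mask [sampling_mask()].
#' @param alpha positive penalty weight.
#' @return complex H x W matrix.
#' @export
solve_coil_subproblem <- function(x_rhs, f_j, mask, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop_contract("alpha must be a positive scalar")
  # unlike an acquisition mask, an all-zero mask is legal here: with no data
  # the subproblem reduces to the penalty term and X = x_rhs
  m <- as.matrix(unclass(mask))
  if (!all(m %in% c(0, 1)))
    stop_contract("mask entries must be exactly 0 or 1")
  x_rhs <- check_image(x_rhs, "x_rhs")
  ift2c((m * f_j + alpha * ft2c(x_rhs)) / (m + alpha))
}

check_iterate <- function(u, scheme, k) {
  if (!all(is.finite(Re(u))) || !all(is.finite(Im(u))))
    stop_contract("%s diverged: non-finite iterate at outer iteration %d (check step sizes / weights)",
                  scheme, k)
}

recon_result <- function(image, objective, residual, iterations, converged,
                         solver, problem) {
  structure(list(image = image,
                 objective_history = objective,
                 primal_residuals = residual,
                 iterations = iterations,
                 converged = converged,
                 solver = solver,
                 problem = problem),
            class = "recon_result")
}

#' Coil-splitting ADMM reconstruction
#'
#' Minimizes `TV(u) + lambda * sum_j ||M F X_j - f_j||^2` subject to
#' `X_j = S_j u` by scaled ADMM. Each outer cycle performs
#' (i) the exact per-coil solve [solve_coil_subproblem()] with
#' `x_rhs = S_j u - b_j`, (ii) the image update minimizing
#' `TV(u) + alpha * sum_j ||X_j - S_j u + b_j||^2` — a TV denoise with
#' per-pixel weight `alpha * sum_j |S_j|^2` and target
#' `sum_j conj(S_j)(X_j + b_j) / sum_j |S_j|^2` on the sensitivity support —
#' by warm-started PDHG, and (iii) the multiplier update
#' `b_j <- b_j + X_j - S_j u`. Starts from the zero-filled reconstruction and
#' stops on `outer_iters` or relative image change below `tol`.
#'
#' @param problem a [recon_problem()].
#' @param params an [admm_params()] object.
#' @param verbose logical; log one line per outer iteration.
#' @return object of class `"recon_result"`: final image, per-iteration
#'   objective and aggregated primal residual `sqrt(sum_j ||X_j - S_j u||^2)`,
#'   iteration count and convergence flag.
#' @export
admm_reconstruct <- function(problem, params = admm_params(), verbose = FALSE) {
  stopifnot(inherits(problem, "recon_problem"))
  if (attr(problem$mask, "sampled_count") < 1L)
    stop_contract("empty sampling mask: no k-space data to reconstruct from")
  sens <- problem$sens; mask <- problem$mask
  alpha <- problem$alpha
  K <- n_coils(sens)
  ssq <- apply(abs(unclass(sens))^2, c(1, 2), sum)
  supp <- attr(sens, "support")
  u <- zero_filled_recon(problem)
  X <- array(0i, dim(problem$data))
  for (j in seq_len(K)) X[, , j] <- sens[, , j] * u
  b <- array(0i, dim(X))
  obj <- numeric(0); res <- numeric(0)
  converged <- FALSE
  p_warm <- NULL
  for (k in seq_len(params$outer_iters)) {
    # X_j-update minimizes lambda ||M F X - f_j||^2 + alpha ||X - x_rhs||^2,
    # i.e. the unit-fidelity subproblem at penalty alpha / lambda.
    for (j in seq_len(K))
      X[, , j] <- solve_coil_subproblem(sens[, , j] * u - b[, , j],
                                        problem$data[, , j], mask,
                                        alpha / problem$lambda)
    target <- matrix(0i, nrow(u), ncol(u))
    for (j in seq_len(K))
      target <- target + Conj(sens[, , j]) * (X[, , j] + b[, , j])
    target[supp] <- target[supp] / ssq[supp]
    target[!supp] <- 0
    w <- alpha * ssq
    w[!supp] <- 0
    fit <- pdhg_weighted_denoise(target, w, params$inner, v0 = u, p0 = p_warm)
    u_new <- fit$v; p_warm <- fit$p
    check_iterate(u_new, "ADMM", k)
    r2 <- 0
    for (j in seq_len(K)) {
      b[, , j] <- b[, , j] + X[, , j] - sens[, , j] * u_new
      r2 <- r2 + sum(abs(X[, , j] - sens[, , j] * u_new)^2)
    }
    obj <- c(obj, recon_objective(u_new, problem))
    res <- c(res, sqrt(r2))
    rel <- sqrt(sum(abs(u_new - u)^2)) / max(sqrt(sum(abs(u)^2)), 1e-12)
    u <- u_new
    if (verbose)
      message(sprintf("admm iter %3d  objective %.6e  residual %.3e  rel_change %.3e",
                      k, obj[k], res[k], rel))
    if (rel < params$tol) { converged <- TRUE; break }
  }
  recon_result(u, obj, res, length(obj), converged, "admm", problem)
}

#' Penalty-splitting reconstruction with a linearized data step
#'
#' Relaxes `v = u` by a quadratic penalty and alternates (i) the TV denoise
#' `v <- argmin TV(v) + alpha ||v - u||^2` via [pdhg_tv_denoise()] with
#' (ii) a linearized proximal data step: the fidelity `lambda ||A u - f||^2`
#' is majorized around `u^k` using the local curvature estimate
#' `delta_k = ||A(u^k - u^{k-1})||^2 / ||u^k - u^{k-1}||^2` (`delta_0 = 1`;
#' retained when consecutive iterates coincide), giving the pixelwise
#' closed form
#' `u <- (lambda delta_k u^k + alpha v - lambda A^H r^k) / (lambda delta_k + alpha)`
#' with `r^k = A u^k - f`. Same initialization, stopping rule and history
#' contract as [admm_reconstruct()]; the scheme is inexact, trading the
#' per-coil exact solves for one gradient of the data term per cycle.
#'
#' A quadratic penalty enforces `v = u` exactly only as the penalty weight
#' grows without bound, so the solver applies the standard continuation
#' schedule: the weight in cycle k is
#' `min(alpha * alpha_growth^(k-1), alpha * alpha_cap)`, and convergence is
#' declared only once the cap is reached. With `alpha_growth = 1` the
#' fixed-weight iteration of the plain penalty formulation is recovered.
#'
#' @inheritParams admm_reconstruct
#' @param alpha_growth per-cycle multiplicative growth of the penalty weight
#'   (>= 1; default 1.1).
#' @param alpha_cap cap on the growth, as a multiple of `alpha` (default
#'   1000).
#' @return object of class `"recon_result"`; `primal_residuals` records the
#'   splitting gap `||v - u||` per outer iteration.
#' @export
penalty_split_reconstruct <- function(problem, params = admm_params(),
                                      alpha_growth = 1.1, alpha_cap = 1000,
                                      verbose = FALSE) {
  if (alpha_growth < 1 || alpha_cap < 1)
    stop_contract("alpha_growth and alpha_cap must be >= 1")
  stopifnot(inherits(problem, "recon_problem"))
  if (attr(problem$mask, "sampled_count") < 1L)
    stop_contract("empty sampling mask: no k-space data to reconstruct from")
  sens <- problem$sens; mask <- problem$mask
  lam <- problem$lambda; alpha <- problem$alpha
  u <- zero_filled_recon(problem)
  u_prev <- NULL
  delta <- 1
  obj <- numeric(0); res <- numeric(0)
  converged <- FALSE
  p_warm <- NULL
  for (k in seq_len(params$outer_iters)) {
    al <- min(alpha * alpha_growth^(k - 1), alpha * alpha_cap)
    fit <- pdhg_weighted_denoise(u, al, params$inner, v0 = u, p0 = p_warm)
    v <- fit$v; p_warm <- fit$p
    if (!is.null(u_prev)) {
      du <- u - u_prev
      nd2 <- sum(abs(du)^2)
      if (nd2 > 0) {
        Adu <- apply_forward(du, sens, mask)
        delta <- sum(abs(unclass(Adu))^2) / nd2
        delta <- max(delta, 1e-8)
      }
    }
    resid <- unclass(apply_forward(u, sens, mask)) - unclass(problem$data)
    g <- apply_adjoint(resid, sens, mask)
    u_new <- (lam * delta * u + al * v - lam * g) / (lam * delta + al)
    check_iterate(u_new, "penalty splitting", k)
    obj <- c(obj, recon_objective(u_new, problem))
    res <- c(res, sqrt(sum(abs(v - u_new)^2)))
    rel <- sqrt(sum(abs(u_new - u)^2)) / max(sqrt(sum(abs(u)^2)), 1e-12)
    u_prev <- u
    u <- u_new
    if (verbose)
      message(sprintf("penalty iter %3d  objective %.6e  gap %.3e  rel_change %.3e  delta %.3g  alpha %.3g",
                      k, obj[k], res[k], rel, delta, al))
    if (rel < params$tol && (alpha_growth == 1 || al >= alpha * alpha_cap)) {
      converged <- TRUE
      break
    }
  }
  recon_result(u, obj, res, length(obj), converged, "penalty", problem)
}

#' @export
print.recon_result <- function(x, ...) {
  cat(sprintf("TV-SENSE reconstruction (%s solver)\n", x$solver))
  cat(sprintf("  %d x %d image, %d outer iterations, %s\n",
              nrow(x$image), ncol(x$image), x$iterations,
              if (x$converged) "converged" else "iteration limit reached"))
  if (x$iterations > 0)
    cat(sprintf("  final objective %.6e, final primal residual %.3e\n",
                x$objective_history[x$iterations],
                x$primal_residuals[x$iterations]))
  invisible(x)
}

#' Export a solver iteration history as a data frame
#'
#' @param result a `"recon_result"`.
#' @return data.frame with columns `iteration`, `objective`,
#'   `primal_residual`, ready for `write.csv`.
#' @export
iteration_history <- function(result) {
  stopifnot(inherits(result, "recon_result"))
  data.frame(iteration = seq_len(result$iterations),
             objective = result$objective_history,
             primal_residual = result$primal_residuals)
}
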