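# Coil-splitting ADMM and penalty-splitting solvers.

test_that("the objective composes TV and data-fidelity terms", {
  sp <- small_problem(seed = 3, H = 8, W = 8, K = 2, sigma = 0)
  pr <- sp$problem
  zero_pr <- recon_problem(array(0i, dim(unclass(pr$data))), pr$sens, pr$mask,
                           lambda = pr$lambda)
  expect_equal(recon_objective(matrix(0i, 8, 8), zero_pr), 0)
  # constant image with consistent full-sampling data: both terms vanish
  const <- matrix(0.5 + 0i, 8, 8)
  s1 <- coil_sens(array(1 + 0i, c(8, 8, 1)))
  mfull <- sampling_mask(matrix(1, 8, 8))
  dfull <- apply_forward(const, s1, mfull)
  pr_const <- recon_problem(dfull, s1, mfull, lambda = 5)
  expect_lt(recon_objective(const, pr_const), 1e-20)
  set.seed(9)
  u <- rand_cimage(8, 8)
  expect_equal(recon_objective(u, pr),
               tv_norm(u) + pr$lambda * data_fidelity(u, pr),
               tolerance = 1e-14)
})

test_that("coil subproblem: no-data and large-penalty limits", {
  set.seed(19)
  x_rhs <- rand_cimage(4, 4)
  f <- matrix(0i, 4, 4)
  none <- matrix(0, 4, 4)
  expect_lt(max(Mod(solve_coil_subproblem(x_rhs, f, none, 2) - x_rhs)), 1e-13)
  mask <- make_mask(4, 4, acceleration = 2, pattern = "random-points",
                    center_fraction = 0, seed = 5)
  f <- unclass(rand_kspace(mask, 1))[, , 1]
  big <- solve_coil_subproblem(x_rhs, f, mask, 1e8)
  expect_lt(sqrt(sum(Mod(big - x_rhs)^2)) / sqrt(sum(Mod(x_rhs)^2)), 1e-6)
  expect_error(solve_coil_subproblem(x_rhs, f, mask, 0), "positive")
})

test_that("coil subproblem matches the dense normal-equations oracle", {
  set.seed(29)
  for (trial in 1:4) {
    mask <- make_mask(4, 4, acceleration = 2, pattern = "random-points",
                      center_fraction = 0, seed = trial)
    x_rhs <- rand_cimage(4, 4)
    f <- unclass(rand_kspace(mask, 1))[, , 1]
    alpha <- c(0.1, 1, 5, 40)[trial]
    F2 <- oracle_dft2(4, 4)
    Mdiag <- diag(as.vector(unclass(mask)))
    lhs <- Conj(t(F2)) %*% Mdiag %*% F2 + alpha * diag(16)
    rhs <- Conj(t(F2)) %*% Mdiag %*% as.vector(f) + alpha * as.vector(x_rhs)
    expected <- matrix(solve(lhs, rhs), 4, 4)
    got <- solve_coil_subproblem(x_rhs, f, mask, alpha)
    expect_lt(max(Mod(got - expected)), 1e-10)
  }
})

test_that("ADMM attains the exact-recovery limit and kills zero data", {
  truth <- make_phantom(16, 16, seed = 5)
  s1 <- coil_sens(array(1 + 0i, c(16, 16, 1)))
  mfull <- sampling_mask(matrix(1, 16, 16))
  d <- simulate_acquisition(truth, s1, mfull, noise_sigma = 0, seed = 1)
  pr <- recon_problem(d, s1, mfull, lambda = 1e3, alpha = 1)
  fit <- admm_reconstruct(pr, admm_params(outer_iters = 100))
  expect_lt(sqrt(sum(Mod(fit$image - truth)^2) / sum(truth^2)), 1e-3)
  # zero data: TV and fidelity are both minimized by the zero image
  mask <- make_mask(16, 16, acceleration = 2, seed = 2)
  pr0 <- recon_problem(array(0i, c(16, 16, 1)), s1, mask)
  fit0 <- admm_reconstruct(pr0, admm_params(outer_iters = 20))
  expect_lt(max(Mod(fit0$image)), 1e-12)
})

test_that("ADMM matches the convex oracle on a small seeded problem", {
  sp <- small_problem(seed = 104, H = 8, W = 8, K = 2, accel = 2, lambda = 10)
  pr <- sp$problem
  A <- oracle_forward_matrix(pr$sens, pr$mask)
  D <- oracle_diff_matrices(8, 8)
  orc <- oracle_tv_solve(A, as.vector(unclass(pr$data)), D, pr$lambda,
                         u0 = as.vector(zero_filled_recon(pr)),
                         eps_stages = c(1e-3, 1e-6), maxit = 2000L)
  fit <- admm_reconstruct(pr, admm_params(outer_iters = 250, tol = 1e-10,
                                          inner = pdhg_params(max_iters = 40)))
  expect_lt(tail(fit$objective_history, 1) / orc$objective, 1 + 1e-3)
})

test_that("solver histories satisfy their length/convergence contracts", {
  sp <- small_problem(seed = 23, H = 8, W = 8, K = 2)
  for (fn in list(admm_reconstruct, penalty_split_reconstruct)) {
    fit <- fn(sp$problem, admm_params(outer_iters = 30, tol = 1e-12))
    expect_length(fit$objective_history, fit$iterations)
    expect_length(fit$primal_residuals, fit$iterations)
    expect_false(fit$converged)  # tol far below what 30 iterations reach
    expect_true(all(is.finite(fit$objective_history)))
  }
  expect_error(admm_reconstruct(sp$problem, admm_params(outer_iters = 0)),
               "outer_iters")
})

test_that("penalty splitting: zero data, consistency limit, cross-solver gap", {
  s1 <- coil_sens(array(1 + 0i, c(16, 16, 1)))
  mask <- make_mask(16, 16, acceleration = 2, seed = 2)
  pr0 <- recon_problem(array(0i, c(16, 16, 1)), s1, mask)
  fit0 <- penalty_split_reconstruct(pr0, admm_params(outer_iters = 20))
  expect_lt(max(Mod(fit0$image)), 1e-12)

  truth <- make_phantom(16, 16, seed = 5)
  mfull <- sampling_mask(matrix(1, 16, 16))
  d <- simulate_acquisition(truth, s1, mfull, noise_sigma = 0, seed = 1)
  pr <- recon_problem(d, s1, mfull, lambda = 1e3, alpha = 1)
  fit <- penalty_split_reconstruct(pr, admm_params(outer_iters = 200))
  expect_lt(sqrt(sum(Mod(fit$image - truth)^2) / sum(truth^2)), 1e-2)

  sp <- small_problem(seed = 31, H = 8, W = 8, K = 2, lambda = 10)
  fa <- admm_reconstruct(sp$problem, admm_params(outer_iters = 150))
  fp <- penalty_split_reconstruct(sp$problem, admm_params(outer_iters = 200))
  oa <- tail(fa$objective_history, 1); op <- tail(fp$objective_history, 1)
  expect_lt(abs(op - oa) / oa, 0.05)
})

test_that("identical seeds and parameters reproduce bit-identical results", {
  sp1 <- small_problem(seed = 37, H = 8, W = 8, K = 2)
  sp2 <- small_problem(seed = 37, H = 8, W = 8, K = 2)
  expect_identical(sp1$truth, sp2$truth)
  expect_identical(unclass(sp1$problem$data), unclass(sp2$problem$data))
  f1 <- admm_reconstruct(sp1$problem, admm_params(outer_iters = 25))
  f2 <- admm_reconstruct(sp2$problem, admm_params(outer_iters = 25))
  expect_identical(f1$image, f2$image)
  expect_identical(f1$objective_history, f2$objective_history)
})

test_that("reconstruction error does not increase with sampling fraction", {
  # mean over 10 matched seeds at 25% / 50% / 100% sampling
  errs <- matrix(NA_real_, 10, 3)
  for (s in 1:10) {
    truth <- make_phantom(16, 16, n_ellipses = 3, lesion_count = 1,
                          seed = 400 + s)
    sens <- make_sensitivities(4, 16, 16, normalized = TRUE)
    for (fi in 1:3) {
      accel <- c(4, 2, 1)[fi]
      mask <- make_mask(16, 16, acceleration = accel,
                        pattern = "random-points", center_fraction = 0.1,
                        seed = 500 + s)
      d <- simulate_acquisition(truth, sens, mask, noise_sigma = 0.01,
                                seed = 600 + s)
      pr <- recon_problem(d, sens, mask, lambda = 100, alpha = 1)
      fit <- admm_reconstruct(pr, admm_params(outer_iters = 40))
      errs[s, fi] <- sqrt(sum(Mod(fit$image - truth)^2) / sum(truth^2))
    }
  }
  m <- colMeans(errs)
  expect_lte(m[2], m[1] * (1 + 1e-9))
  expect_lte(m[3], m[2] * (1 + 1e-9))
})

test_that("the ADMM primal residual decays by an order of magnitude", {
  acq <- demo_problem(seed = 20220323L)
  fit <- admm_reconstruct(acq$problem, admm_params(outer_iters = 100))
  expect_gte(fit$primal_residuals[1] / fit$primal_residuals[fit$iterations], 10)
})

test_that("an empty acquisition is refused with an explicit error", {
  sens <- make_sensitivities(1, 4, 4)
  expect_error(recon_problem(array(0i, c(4, 4, 1)), sens,
                             matrix(0, 4, 4)), "at least one")
})
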