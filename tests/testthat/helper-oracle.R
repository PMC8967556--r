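# Independent oracles, built from explicit matrices and double loops only —
# no calls into the package's operator code.

# Centered orthonormal 1-D DFT matrix: frequency and position indices are
# taken relative to the center bin floor(N/2)+1.
oracle_dft1 <- function(N) {
  F1 <- matrix(0i, N, N)
  for (k in seq_len(N))
    for (n in seq_len(N))
      F1[k, n] <- exp(-2i * pi * (k - 1 - floor(N / 2)) * (n - 1 - floor(N / 2)) / N) /
        sqrt(N)
  F1
}

# 2-D centered DFT on column-major vec(u): vec(F_H U F_W^T) = (F_W x F_H) vec(U)
oracle_dft2 <- function(H, W) kronecker(oracle_dft1(W), oracle_dft1(H))

# Stacked acquisition matrix A = [M F S_1; ...; M F S_K], (K*H*W) x (H*W)
oracle_forward_matrix <- function(sens, mask) {
  H <- nrow(mask); W <- ncol(mask); K <- dim(unclass(sens))[3]
  F2 <- oracle_dft2(H, W)
  mvec <- as.vector(unclass(mask))
  rows <- vector("list", K)
  for (j in seq_len(K))
    rows[[j]] <- (mvec * F2) * rep(as.vector(unclass(sens)[, , j]),
                                   each = H * W)
  do.call(rbind, rows)
}

# Forward-difference matrices Dx, Dy ((H*W) x (H*W)) for column-major vec(u),
# Neumann boundary (zero last difference), built index by index.
oracle_diff_matrices <- function(H, W) {
  N <- H * W
  idx <- function(i, j) (j - 1L) * H + i
  Dx <- matrix(0, N, N); Dy <- matrix(0, N, N)
  for (i in seq_len(H))
    for (j in seq_len(W)) {
      if (j < W) {
        Dx[idx(i, j), idx(i, j + 1L)] <- 1
        Dx[idx(i, j), idx(i, j)] <- -1
      }
      if (i < H) {
        Dy[idx(i, j), idx(i + 1L, j)] <- 1
        Dy[idx(i, j), idx(i, j)] <- -1
      }
    }
  list(Dx = Dx, Dy = Dy)
}

# Exact TV-SENSE objective from the explicit matrices.
oracle_objective <- function(uvec, A, fvec, D, lam) {
  gx <- D$Dx %*% uvec; gy <- D$Dy %*% uvec
  sum(sqrt(Mod(gx)^2 + Mod(gy)^2)) + lam * sum(Mod(A %*% uvec - fvec)^2)
}

# Generic convex solver for min_u sum_p |(Du)_p| + lam ||A u - f||^2 over
# complex u: smooth the TV kink (sqrt(. + eps^2)), minimize with L-BFGS-B
# over stacked (Re, Im) coordinates with the analytic gradient, and anneal
# eps. Returns the minimizer and its exact (unsmoothed) objective.
oracle_tv_solve <- function(A, fvec, D, lam, u0 = NULL,
                            eps_stages = c(1e-3, 1e-6, 1e-9),
                            maxit = 3000L) {
  N <- ncol(A)
  AH <- Conj(t(A)); DxH <- t(D$Dx); DyH <- t(D$Dy)
  par <- if (is.null(u0)) numeric(2 * N) else c(Re(u0), Im(u0))
  for (eps in eps_stages) {
    fn <- function(x) {
      u <- complex(real = x[1:N], imaginary = x[(N + 1):(2 * N)])
      gx <- D$Dx %*% u; gy <- D$Dy %*% u
      r <- A %*% u - fvec
      sum(sqrt(Mod(gx)^2 + Mod(gy)^2 + eps^2)) + lam * sum(Mod(r)^2)
    }
    gr <- function(x) {
      u <- complex(real = x[1:N], imaginary = x[(N + 1):(2 * N)])
      gx <- D$Dx %*% u; gy <- D$Dy %*% u
      rt <- sqrt(Mod(gx)^2 + Mod(gy)^2 + eps^2)
      G <- DxH %*% (gx / rt) + DyH %*% (gy / rt) +
        2 * lam * (AH %*% (A %*% u - fvec))
      c(Re(G), Im(G))
    }
    fit <- stats::optim(par, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = maxit, factr = 10))
    par <- fit$par
  }
  u <- complex(real = par[1:N], imaginary = par[(N + 1):(2 * N)])
  list(u = u, objective = oracle_objective(u, A, fvec, D, lam))
}

# Windowed SSIM by an explicit double loop over every fully-contained
# 11 x 11 window, Gaussian-weighted moments, mean pooling.
oracle_ssim_gaussian <- function(f, g, k1 = 0.01, k2 = 0.03, L) {
  s <- 11L; r <- 5L; sig <- 1.5
  w <- matrix(0, s, s)
  for (a in seq_len(s))
    for (b in seq_len(s))
      w[a, b] <- exp(-((a - 6)^2 + (b - 6)^2) / (2 * sig^2))
  w <- w / sum(w)
  C1 <- (k1 * L)^2; C2 <- (k2 * L)^2
  vals <- c()
  for (i in seq_len(nrow(f) - s + 1L))
    for (j in seq_len(ncol(f) - s + 1L)) {
      wf <- f[i:(i + s - 1L), j:(j + s - 1L)]
      wg <- g[i:(i + s - 1L), j:(j + s - 1L)]
      mx <- sum(w * wf); my <- sum(w * wg)
      vx <- sum(w * wf^2) - mx^2; vy <- sum(w * wg^2) - my^2
      cxy <- sum(w * wf * wg) - mx * my
      vals <- c(vals, ((2 * mx * my + C1) * (2 * cxy + C2)) /
                  ((mx^2 + my^2 + C1) * (vx + vy + C2)))
    }
  mean(vals)
}

# Seeded random complex matrix / coil stack.
rand_cimage <- function(H, W) {
  matrix(complex(real = rnorm(H * W), imaginary = rnorm(H * W)), H, W)
}
rand_kspace <- function(mask, K) {
  H <- nrow(mask); W <- ncol(mask)
  arr <- array(complex(real = rnorm(H * W * K), imaginary = rnorm(H * W * K)),
               c(H, W, K))
  arr * array(rep(unclass(mask), K), c(H, W, K))
}

# Small seeded reconstruction problem for solver tests.
small_problem <- function(seed, H = 8L, W = 8L, K = 2L, accel = 2,
                          lambda = 10, alpha = 1, sigma = 0.02) {
  truth <- make_phantom(H, W, n_ellipses = 2L, lesion_count = 0L, seed = seed)
  sens <- make_sensitivities(K, H, W, normalized = TRUE)
  mask <- make_mask(H, W, acceleration = accel, pattern = "random-points",
                    center_fraction = 0, seed = seed + 1L)
  data <- simulate_acquisition(truth, sens, mask, noise_sigma = sigma,
                               seed = seed + 2L)
  list(truth = truth,
       problem = recon_problem(data, sens, mask, lambda = lambda, alpha = alpha))
}
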