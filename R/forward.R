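# Multi-coil SENSE acquisition operator A = [M F S_1; ...; M F S_K], its
# adjoint, the zero-filled baseline and the data-fidelity functional.

check_problem_shapes <- function(u, sens, mask) {
  u <- check_image(u)
  if (!inherits(sens, "coil_sens")) sens <- coil_sens(sens)
  if (!inherits(mask, "sampling_mask")) mask <- sampling_mask(mask)
  if (!identical(dim(u), dim(mask)) || !identical(dim(u), dim(sens)[1:2]))
    stop_contract("image (%d x %d), mask (%d x %d) and sensitivities (%d x %d) must share one grid",
                  nrow(u), ncol(u), nrow(mask), ncol(mask),
                  dim(sens)[1], dim(sens)[2])
  list(u = u, sens = sens, mask = mask)
}

#' Multi-coil acquisition operator
#'
#' Applies the SENSE forward model: for each coil j the image is modulated by
#' the sensitivity map, transformed with the centered orthonormal 2-D DFT
#' [ft2c()], and restricted to the sampled k-space locations
#' (`M * F(S_j * u)`). Unsampled locations are exact zeros.
#'
#' @param u complex H x W image matrix.
#' @param sens [coil_sens()] maps.
#' @param mask [sampling_mask()].
#' @return a [coil_data()] H x W x K array.
#' @seealso [apply_adjoint()] for the exact adjoint.
#' @export
apply_forward <- function(u, sens, mask) {
  z <- check_problem_shapes(u, sens, mask)
  K <- n_coils(z$sens)
  out <- array(0i, c(dim(z$u), K))
  for (j in seq_len(K))
    out[, , j] <- unclass(z$mask) * ft2c(z$sens[, , j] * z$u)
  coil_data(out, z$mask)
}

#' Adjoint of the acquisition operator
#'
#' Computes `sum_j conj(S_j) * F^{-1}(M * f_j)`, the exact adjoint of
#' [apply_forward()] under the standard complex inner product (the centered
#' orthonormal DFT is unitary, so its inverse is its adjoint).
#'
#' @param f [coil_data()] (or H x W x K complex array) of k-space values.
#' @param sens [coil_sens()] maps.
#' @param mask [sampling_mask()].
#' @return complex H x W image matrix.
#' @export
apply_adjoint <- function(f, sens, mask) {
  if (!inherits(sens, "coil_sens")) sens <- coil_sens(sens)
  if (!inherits(mask, "sampling_mask")) mask <- sampling_mask(mask)
  f <- unclass(f) + 0i
  if (length(dim(f)) != 3L || !identical(dim(f)[1:2], dim(mask)) ||
      dim(f)[3L] != n_coils(sens))
    stop_contract("k-space array must be H x W x K matching mask and sensitivities")
  u <- matrix(0i, nrow(mask), ncol(mask))
  for (j in seq_len(n_coils(sens)))
    u <- u + Conj(sens[, , j]) * ift2c(unclass(mask) * f[, , j])
  u
}

#' Zero-filled reconstruction baseline
#'
#' The adjoint of the acquisition operator applied to the measured data:
#' the standard no-regularization baseline, and the default initial iterate
#' of both iterative solvers.
#'
#' @param problem a [recon_problem()].
#' @return complex H x W image matrix.
#' @export
zero_filled_recon <- function(problem) {
  stopifnot(inherits(problem, "recon_problem"))
  apply_adjoint(problem$data, problem$sens, problem$mask)
}

#' Data-fidelity functional
#'
#' `sum_j || M F(S_j u) - f_j ||_2^2`, the squared residual of the acquisition
#' model summed over coils.
#'
#' @param u complex H x W image matrix.
#' @param problem a [recon_problem()].
#' @return nonnegative real scalar.
#' @export
data_fidelity <- function(u, problem) {
  stopifnot(inherits(problem, "recon_problem"))
  pred <- apply_forward(u, problem$sens, problem$mask)
  sum(abs(unclass(pred) - unclass(problem$data))^2)
}
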