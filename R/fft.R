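# Centered, orthonormal 2-D DFT helpers.
#
# Convention: the DC component sits at matrix position (floor(H/2)+1,
# floor(W/2)+1), and the transform is unitary, so the inverse equals the
# conjugate transpose and adjoint code can mirror forward code.  All k-space
# arrays in the package live on this centered grid.

fftshift_mat <- function(m) {
  h <- nrow(m); w <- ncol(m)
  m[c((ceiling(h / 2) + 1):h, 1:ceiling(h / 2)),
    c((ceiling(w / 2) + 1):w, 1:ceiling(w / 2)), drop = FALSE]
}

ifftshift_mat <- function(m) {
  h <- nrow(m); w <- ncol(m)
  m[c((floor(h / 2) + 1):h, 1:floor(h / 2)),
    c((floor(w / 2) + 1):w, 1:floor(w / 2)), drop = FALSE]
}

#' Centered orthonormal 2-D discrete Fourier transform
#'
#' Unitary 2-D DFT with the zero-frequency component at the grid center
#' (row `floor(H/2)+1`, column `floor(W/2)+1`). Because the transform is
#' unitary, [ift2c()] is both its inverse and its adjoint.
#'
#' @param x complex (or numeric) matrix.
#' @return complex matrix of the same dimension.
#' @export
ft2c <- function(x) {
  fftshift_mat(stats::fft(ifftshift_mat(as.matrix(x)))) / sqrt(length(x))
}

#' @rdname ft2c
#' @export
ift2c <- function(x) {
  fftshift_mat(stats::fft(ifftshift_mat(as.matrix(x)), inverse = TRUE)) /
    sqrt(length(x))
}
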