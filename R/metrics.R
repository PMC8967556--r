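# Reference image-quality metrics: MSE, PSNR (dB) and SSIM.
#
# Metrics are defined on real-valued (magnitude) images; complex
# reconstructions are reduced with Mod() before evaluation, matching how MRI
# reconstructions are displayed and scored.

check_pair <- function(f, g) {
  f <- as.matrix(f); g <- as.matrix(g)
  if (is.complex(f)) f <- Mod(f)
  if (is.complex(g)) g <- Mod(g)
  if (!identical(dim(f), dim(g)))
    stop_contract("images must share one shape (got %d x %d vs %d x %d)",
                  nrow(f), ncol(f), nrow(g), ncol(g))
  list(f = f, g = g)
}

#' Mean squared error
#'
#' `(1/(H*W)) * sum_{i,j} (f(i,j) - g(i,j))^2` between a reconstruction and
#' the ground truth.
#'
#' @param f,g real H x W matrices (complex inputs are reduced to magnitude).
#' @return nonnegative real scalar.
#' @export
mse <- function(f, g) {
  z <- check_pair(f, g)
  mean((z$f - z$g)^2)
}

#' Peak signal-to-noise ratio in dB
#'
#' `10 * log10(peak^2 / MSE)` with `peak = 2^n_bits - 1` for integer-typed
#' dynamic ranges. For floating-point images pass the dynamic range `peak`
#' directly (the default, `peak = max(g) - min(g)` of the reference image,
#' is used when both arguments are omitted). Identical images yield `Inf`.
#'
#' @param f,g real H x W matrices (complex inputs are reduced to magnitude).
#' @param n_bits bit depth defining the maximum possible pixel value
#'   `2^n_bits - 1`; the conventional choice for 8-bit display images is 8.
#' @param peak positive dynamic range, overriding `n_bits`.
#' @return real scalar in dB (`Inf` when `MSE = 0`); higher is better.
#' @export
psnr <- function(f, g, n_bits = NULL, peak = NULL) {
  z <- check_pair(f, g)
  if (is.null(peak)) {
    if (!is.null(n_bits)) {
      if (n_bits < 1) stop_contract("n_bits must be >= 1")
      peak <- 2^n_bits - 1
    } else {
      peak <- max(z$g) - min(z$g)
    }
  }
  if (!is.numeric(peak) || peak <= 0)
    stop_contract("dynamic range must be positive")
  err <- mean((z$f - z$g)^2)
  if (err == 0) return(Inf)
  10 * log10(peak^2 / err)
}

gaussian_kernel <- function(size = 11L, sigma = 1.5) {
  r <- (size - 1) / 2
  x <- seq(-r, r)
  k1 <- exp(-x^2 / (2 * sigma^2))
  k <- outer(k1, k1)
  k / sum(k)
}

# Weighted local moments over every fully-contained size x size window,
# vectorized as a sum of shifted submatrices.
local_filter <- function(x, kernel) {
  s <- nrow(kernel)
  h <- nrow(x) - s + 1L; w <- ncol(x) - s + 1L
  out <- matrix(0, h, w)
  for (a in seq_len(s))
    for (b in seq_len(s))
      out <- out + kernel[a, b] * x[a:(a + h - 1L), b:(b + w - 1L), drop = FALSE]
  out
}

#' Structural similarity index
#'
#' `SSIM = ((2 mu_x mu_y + C1)(2 sigma_xy + C2)) /
#' ((mu_x^2 + mu_y^2 + C1)(sigma_x^2 + sigma_y^2 + C2))` with
#' `C1 = (k1 L)^2`, `C2 = (k2 L)^2`, combining luminance, contrast and
#' structure comparisons. Two pooling modes:
#' \describe{
#'   \item{`"global"`}{one set of moments over the whole image — the
#'     formula-exact reference form.}
#'   \item{`"gaussian"`}{moments under an 11 x 11 Gaussian window
#'     (sigma 1.5) centered at every fully-contained position, mean-pooled —
#'     the universal windowed convention.}
#' }
#'
#' @param f,g real H x W matrices (complex inputs are reduced to magnitude).
#' @param window `"gaussian"` (default) or `"global"`.
#' @param k1,k2 stability constants (defaults 0.01, 0.03).
#' @param dynamic_range positive `L`; defaults to `max(g) - min(g)` of the
#'   reference for floating-point images.
#' @return real scalar in `[-1, 1]`; 1 iff the images are identical.
#' @export
ssim <- function(f, g, window = c("gaussian", "global"),
                 k1 = 0.01, k2 = 0.03, dynamic_range = NULL) {
  window <- match.arg(window)
  z <- check_pair(f, g)
  L <- if (is.null(dynamic_range)) max(z$g) - min(z$g) else dynamic_range
  if (!is.numeric(L) || L <= 0) {
    if (isTRUE(all.equal(z$f, z$g))) return(1)
    stop_contract("dynamic range must be positive")
  }
  C1 <- (k1 * L)^2; C2 <- (k2 * L)^2
  if (window == "global") {
    mx <- mean(z$f); my <- mean(z$g)
    vx <- mean((z$f - mx)^2); vy <- mean((z$g - my)^2)
    cxy <- mean((z$f - mx) * (z$g - my))
    return(((2 * mx * my + C1) * (2 * cxy + C2)) /
             ((mx^2 + my^2 + C1) * (vx + vy + C2)))
  }
  if (nrow(z$f) < 11L || ncol(z$f) < 11L)
    stop_contract("gaussian-window SSIM needs images at least 11 x 11; use window = \"global\"")
  ker <- gaussian_kernel()
  mx <- local_filter(z$f, ker); my <- local_filter(z$g, ker)
  mxx <- local_filter(z$f^2, ker); myy <- local_filter(z$g^2, ker)
  mxy <- local_filter(z$f * z$g, ker)
  vx <- mxx - mx^2; vy <- myy - my^2; cxy <- mxy - mx * my
  smap <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
  mean(smap)
}

#' Quality report against a ground-truth image
#'
#' @param recon reconstruction (complex allowed; magnitude is scored).
#' @param truth ground-truth image.
#' @param window SSIM pooling mode, see [ssim()].
#' @return object of class `"quality_report"`: list with `mse`, `psnr_db`
#'   (Inf when `mse` is 0) and `ssim`.
#' @export
quality_report <- function(recon, truth, window = "gaussian") {
  structure(list(mse = mse(recon, truth),
                 psnr_db = psnr(recon, truth),
                 ssim = ssim(recon, truth, window = window)),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("mse: %.6g\n", x$mse))
  cat(sprintf("psnr_db: %s\n", if (is.infinite(x$psnr_db)) "Inf" else sprintf("%.4f", x$psnr_db)))
  cat(sprintf("ssim: %.6f\n", x$ssim))
  invisible(x)
}
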