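# Domain containers for a parallel-MRI reconstruction problem.
#
# All are lightweight validated S3 wrappers around base matrices/arrays:
#   sampling_mask   - binary H x W k-space indicator (centered grid)
#   coil_sens       - H x W x K complex sensitivity maps
#   coil_data       - H x W x K complex k-space samples (zeros where unsampled)
#   recon_problem   - mask + sens + data + regularization weights

stop_contract <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_image <- function(u, what = "image") {
  u <- as.matrix(u)
  if (nrow(u) < 2L || ncol(u) < 2L)
    stop_contract("%s must be at least 2 x 2 (got %d x %d)", what, nrow(u), ncol(u))
  if (!all(is.finite(Re(u))) || !all(is.finite(Im(u))))
    stop_contract("%s contains non-finite entries", what)
  u
}

#' Binary k-space sampling mask
#'
#' Wraps an H x W 0/1 indicator of acquired k-space locations on the centered
#' frequency grid (DC at `floor(H/2)+1`, `floor(W/2)+1`).
#'
#' @param indicator numeric/logical H x W matrix with entries exactly 0 or 1.
#' @return object of class `"sampling_mask"`: the 0/1 matrix with attributes
#'   `sampled_count` and `acceleration` (= H*W / sampled_count).
#' @export
sampling_mask <- function(indicator) {
  m <- as.matrix(indicator)
  storage.mode(m) <- "double"
  if (!all(m %in% c(0, 1)))
    stop_contract("sampling mask entries must be exactly 0 or 1")
  n <- sum(m)
  if (n < 1)
    stop_contract("sampling mask must contain at least one sampled location")
  structure(m, sampled_count = as.integer(n),
            acceleration = length(m) / n,
            class = c("sampling_mask", class(m)))
}

#' Coil sensitivity maps
#'
#' @param maps complex H x W x K array (or a list of K complex matrices) of
#'   sensitivity maps, one per receiver coil.
#' @param normalized logical; assert the sum-of-squares normalization
#'   `sum_j |S_j|^2 = 1` (tolerance 1e-10) at supported pixels.
#' @return object of class `"coil_sens"`: complex H x W x K array with
#'   attributes `normalized` and `support` (logical matrix of pixels where
#'   `sum_j |S_j|^2 > 1e-8`; reconstructions outside it are unreliable).
#' @export
coil_sens <- function(maps, normalized = FALSE) {
  if (is.list(maps)) {
    dims <- dim(as.matrix(maps[[1]]))
    maps <- array(unlist(lapply(maps, as.matrix)), c(dims, length(maps)))
  }
  if (length(dim(maps)) != 3L)
    stop_contract("sensitivity maps must be an H x W x K array")
  maps <- maps + 0i
  ssq <- apply(abs(maps)^2, c(1, 2), sum)
  support <- ssq > 1e-8
  if (!any(support))
    stop_contract("sensitivity maps have empty support (sum_j |S_j|^2 <= 1e-8 everywhere)")
  if (normalized && max(abs(ssq[support] - 1)) > 1e-10)
    stop_contract("maps declared normalized but max |sum_j |S_j|^2 - 1| = %.3g on support",
                  max(abs(ssq[support] - 1)))
  structure(maps, normalized = normalized, support = support,
            class = "coil_sens")
}

n_coils <- function(sens) dim(sens)[3L]

#' Multi-coil k-space data
#'
#' @param samples complex H x W x K array (or list of K matrices) of measured
#'   k-space values on the centered grid; positions not covered by `mask`
#'   must be exact zeros.
#' @param mask a [sampling_mask()] the data were acquired with.
#' @return object of class `"coil_data"`: the complex array.
#' @export
coil_data <- function(samples, mask) {
  if (is.list(samples)) {
    dims <- dim(as.matrix(samples[[1]]))
    samples <- array(unlist(lapply(samples, as.matrix)), c(dims, length(samples)))
  }
  if (length(dim(samples)) != 3L)
    stop_contract("coil data must be an H x W x K array")
  samples <- samples + 0i
  mask <- sampling_mask(unclass(mask))
  if (!identical(dim(samples)[1:2], dim(mask)))
    stop_contract("coil data grid (%d x %d) does not match mask grid (%d x %d)",
                  dim(samples)[1], dim(samples)[2], nrow(mask), ncol(mask))
  off <- which(mask == 0)
  for (j in seq_len(dim(samples)[3L]))
    if (any(samples[, , j][off] != 0))
      stop_contract("coil %d has nonzero values at unsampled k-space locations", j)
  structure(samples, class = "coil_data")
}

#' Assemble a reconstruction problem
#'
#' Bundles the acquisition (mask, sensitivities, k-space data) with the model
#' weights of the TV-regularized SENSE objective
#' `TV(u) + lambda * sum_j || M F S_j u - f_j ||^2`.
#'
#' @param data [coil_data()] measurements.
#' @param sens [coil_sens()] maps sharing the grid and coil count.
#' @param mask [sampling_mask()].
#' @param lambda positive data-fidelity weight.
#' @param alpha positive penalty / augmented-Lagrangian weight.
#' @return object of class `"recon_problem"` (a list).
#' @export
recon_problem <- function(data, sens, mask, lambda = 100, alpha = 1) {
  if (!inherits(mask, "sampling_mask")) mask <- sampling_mask(mask)
  if (!inherits(sens, "coil_sens")) sens <- coil_sens(sens)
  if (!inherits(data, "coil_data")) data <- coil_data(data, mask)
  if (!identical(dim(sens)[1:2], dim(mask)))
    stop_contract("sensitivity grid does not match mask grid")
  if (dim(data)[3L] != n_coils(sens))
    stop_contract("coil count mismatch: %d data channels vs %d maps",
                  dim(data)[3L], n_coils(sens))
  if (!identical(dim(data)[1:2], dim(mask)))
    stop_contract("data grid does not match mask grid")
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stop_contract("lambda must be a positive scalar")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop_contract("alpha must be a positive scalar")
  structure(list(data = data, sens = sens, mask = mask,
                 lambda = lambda, alpha = alpha),
            class = "recon_problem")
}

#' @export
print.recon_problem <- function(x, ...) {
  d <- dim(x$sens)
  cat(sprintf("TV-SENSE reconstruction problem: %d x %d grid, %d coils\n",
              d[1], d[2], d[3]))
  cat(sprintf("  sampled: %d / %d k-space locations (acceleration %.2fx)\n",
              attr(x$mask, "sampled_count"), length(x$mask),
              attr(x$mask, "acceleration")))
  cat(sprintf("  lambda = %g, alpha = %g\n", x$lambda, x$alpha))
  invisible(x)
}
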