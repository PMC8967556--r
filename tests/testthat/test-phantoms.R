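# Synthetic phantom, coil maps, undersampling masks, noisy acquisition.

test_that("phantom composition: empty, single-ellipse area, determinism", {
  expect_equal(make_phantom(16, 16, n_ellipses = 0, lesion_count = 0, seed = 1),
               matrix(0, 16, 16))
  # one centered full-intensity ellipse: binary image, area near analytic
  ph <- make_phantom(64, 64, n_ellipses = 1, lesion_count = 0,
                     background_levels = 1, seed = 1)
  expect_true(all(ph %in% c(0, 1)))
  a_pix <- 0.9 * 32; b_pix <- 0.9 * 32
  analytic <- pi * a_pix * b_pix
  perimeter <- 2 * pi * sqrt((a_pix^2 + b_pix^2) / 2)
  expect_lt(abs(sum(ph) - analytic), 2 * perimeter)
  expect_identical(make_phantom(32, 32, seed = 7), make_phantom(32, 32, seed = 7))
  expect_false(identical(make_phantom(32, 32, seed = 7),
                         make_phantom(32, 32, seed = 8)))
  ph2 <- make_phantom(32, 32, seed = 3)
  expect_true(all(ph2 >= 0 & ph2 <= 1))
})

test_that("lesions sit inside the body at the declared contrast", {
  base <- make_phantom(64, 64, n_ellipses = 1, lesion_count = 0,
                       background_levels = 0.5, seed = 9)
  les <- make_phantom(64, 64, n_ellipses = 1, lesion_count = 2,
                      lesion_contrast = 0.3, background_levels = 0.5, seed = 9)
  changed <- which(les != base)
  expect_gt(length(changed), 0)
  expect_true(all(base[changed] > 0))            # inside the body
  expect_true(all(abs(les[changed] - base[changed] - 0.3) < 1e-12))
})

test_that("sensitivity maps: normalization, single-coil limit, smoothness", {
  s1 <- make_sensitivities(1, 16, 16, normalized = TRUE)
  expect_lt(max(abs(Mod(unclass(s1)[, , 1]) - 1)), 1e-12)
  s8 <- make_sensitivities(8, 32, 32, normalized = TRUE)
  ssq <- apply(abs(unclass(s8))^2, c(1, 2), sum)
  expect_lt(max(abs(ssq - 1)), 1e-10)
  expect_true(attr(s8, "normalized"))
  # unnormalized maps vary slowly: max finite difference < 10 / min(H, W)
  su <- make_sensitivities(8, 32, 32, normalized = FALSE)
  for (j in 1:8) {
    g <- img_grad(unclass(su)[, , j])
    expect_lt(max(sqrt(Mod(g$px)^2 + Mod(g$py)^2)), 10 / 32)
  }
  expect_error(make_sensitivities(0, 8, 8), ">= 1")
})

test_that("masks: full sampling, uniform lines, variable density, errors", {
  m1 <- make_mask(16, 16, acceleration = 1, pattern = "uniform-lines",
                  center_fraction = 0, seed = 1)
  expect_equal(sum(m1), 256)
  m2 <- make_mask(64, 48, acceleration = 2, pattern = "uniform-lines",
                  center_fraction = 0, seed = 1)
  expect_equal(attr(m2, "sampled_count"), 32L * 48L)  # exactly 32 rows
  rows2 <- which(rowSums(unclass(m2)) > 0)
  expect_true(all(rowSums(unclass(m2))[rows2] == 48))  # whole rows
  expect_true((floor(64 / 2) + 1) %in% rows2)          # DC row included
  m3 <- make_mask(64, 64, acceleration = 4, pattern = "variable-density-lines",
                  center_fraction = 0.08, seed = 12)
  expect_lt(abs(attr(m3, "acceleration") - 4) / 4, 0.1)
  dc <- floor(64 / 2) + 1
  expect_true(all(unclass(m3)[(dc - 2):(dc + 2), ] == 1))  # center block present
  expect_identical(unclass(make_mask(64, 64, 4, seed = 12)),
                   unclass(make_mask(64, 64, 4, seed = 12)))
  expect_error(make_mask(64, 64, acceleration = 32,
                         pattern = "variable-density-lines",
                         center_fraction = 0.5, seed = 1), "center_fraction")
})

test_that("acquisition simulation: exact at zero noise, calibrated otherwise", {
  truth <- make_phantom(32, 32, seed = 2)
  sens <- make_sensitivities(2, 32, 32)
  mask <- make_mask(32, 32, acceleration = 2, seed = 3)
  clean <- simulate_acquisition(truth, sens, mask, noise_sigma = 0, seed = 1)
  expect_identical(unclass(clean),
                   unclass(apply_forward(truth + 0i, sens, mask)))
  # full-sampling single-coil round trip recovers the phantom
  s1 <- coil_sens(array(1 + 0i, c(32, 32, 1)))
  mfull <- sampling_mask(matrix(1, 32, 32))
  d <- simulate_acquisition(truth, s1, mfull, noise_sigma = 0, seed = 1)
  expect_lt(max(Mod(ift2c(unclass(d)[, , 1]) - truth)), 1e-12)
  # per-component noise moments within 5% at >= 10000 masked samples
  mbig <- sampling_mask(matrix(1, 128, 128))
  sbig <- coil_sens(array(1 + 0i, c(128, 128, 1)))
  tru <- matrix(0, 128, 128)
  noisy <- simulate_acquisition(tru, sbig, mbig, noise_sigma = 0.05, seed = 8)
  dev <- unclass(noisy)[, , 1]
  expect_lt(abs(stats::sd(Re(dev)) - 0.05) / 0.05, 0.05)
  expect_lt(abs(stats::sd(Im(dev)) - 0.05) / 0.05, 0.05)
  # noise only touches sampled locations
  m4 <- make_mask(32, 32, acceleration = 4, seed = 5)
  n4 <- simulate_acquisition(truth, sens, m4, noise_sigma = 0.1, seed = 9)
  off <- which(unclass(m4) == 0)
  for (j in 1:2) expect_true(all(unclass(n4)[, , j][off] == 0))
  expect_error(simulate_acquisition(truth, sens, m4, noise_sigma = -1),
               "nonnegative")
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- rnorm(3)
  set.seed(123)
  invisible(make_phantom(16, 16, seed = 42))
  invisible(make_mask(16, 16, acceleration = 2, seed = 42))
  after <- rnorm(3)
  expect_identical(before, after)
})

test_that("the demo fixture retains ground truth next to the acquisition", {
  acq <- demo_problem(seed = 77)
  expect_equal(dim(acq$truth), c(64L, 64L))
  expect_s3_class(acq$problem, "recon_problem")
  expect_equal(dim(unclass(acq$problem$data))[3], 8L)
  rep <- quality_report(acq$truth, acq$truth, window = "global")
  expect_equal(rep$ssim, 1)
  expect_identical(demo_problem(seed = 77)$truth, acq$truth)
})
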