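make_random_image <- function(shape, seed = 1) {
  set.seed(seed)
  array(complex(real = rnorm(prod(shape)), imaginary = rnorm(prod(shape))),
        dim = shape)
}

test_that("encoding reduces to the centred FFT for one uniform coil", {
  shape <- c(16L, 16L, 8L)
  img <- make_random_image(shape)
  sens <- make_sensitivities(shape, 1)
  kd <- encode(img, sens, caipi_pattern(shape[2], shape[3]), voxel = 7)
  # independent centred unitary FFT via base R
  ift <- function(n) c((n %/% 2 + 1):n, 1:(n %/% 2))   # ifftshift indices
  ft <- function(n) c((n - n %/% 2 + 1):n, 1:(n - n %/% 2))
  ref <- img[ift(shape[1]), ift(shape[2]), ift(shape[3])]
  ref <- fft(ref) / sqrt(prod(shape))
  ref <- ref[ft(shape[1]), ft(shape[2]), ft(shape[3])]
  expect_equal(as.vector(kd$data), as.vector(ref), tolerance = 1e-10)
  expect_true(all(encode(img * 0, sens, caipi_pattern(shape[2], shape[3]),
                         voxel = 7)$data == 0))
})

test_that("Cartesian, wave and NUFFT operators pass the adjoint test", {
  shape <- c(16L, 16L, 8L)
  sens <- make_sensitivities(shape, 4, seed = 3)
  x <- make_random_image(shape, 11)
  samplings <- list(
    caipi = caipi_pattern(shape[2], shape[3], 2, 2, 1),
    wave = wave_sampling(caipi_pattern(shape[2], shape[3]),
                         kz_mod = 5 * sin(seq(0, 6 * pi,
                                              length.out = shape[1]))),
    traj = {
      set.seed(4)
      n <- 400
      structure(list(time = seq_len(n) * 1e-3,
                     kx = runif(n, -7.5, 7.5) / (shape[1] * 7e-3),
                     ky = runif(n, -7.5, 7.5) / (shape[2] * 7e-3),
                     kz = runif(n, -3.5, 3.5) / (shape[3] * 7e-3),
                     raster = 1), class = "k_trajectory")
    })
  for (s in samplings) {
    Ax <- encode(x, sens, s, voxel = 7)
    set.seed(5)
    y <- matrix(complex(real = rnorm(length(Ax$data)),
                        imaginary = rnorm(length(Ax$data))),
                nrow(Ax$data))
    Ay <- Ax; Ay$data <- y
    aty <- adjoint_recon(Ay, sens)
    lhs <- sum(Conj(Ax$data) * y)
    rhs <- sum(Conj(x) * aty)
    expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-6)
  }
})

test_that("encoding a shifted image applies the analytic phase ramp", {
  shape <- c(16L, 16L, 8L)
  img <- make_random_image(shape, 2)
  sens <- make_sensitivities(shape, 1)
  full <- caipi_pattern(shape[2], shape[3])
  k0 <- encode(img, sens, full, voxel = 7)
  shifted <- img[c(shape[1], 1:(shape[1] - 1)), , ]   # +1 voxel along x
  k1 <- encode(shifted, sens, full, voxel = 7)
  kx <- rep(centered_idx <- seq_len(shape[1]) - (shape[1] %/% 2) - 1,
            times = sum(full$mask))
  ramp <- exp(-2i * pi * kx / shape[1])
  expect_equal(as.vector(k1$data), as.vector(k0$data) * ramp,
               tolerance = 1e-6)
})

test_that("CG-SENSE equals the inverse FFT on fully sampled single-coil data", {
  shape <- c(16L, 16L, 8L)
  img <- make_random_image(shape, 6)
  sens <- make_sensitivities(shape, 1)
  kd <- encode(img, sens, caipi_pattern(shape[2], shape[3]), voxel = 7)
  rec <- cg_sense(kd, sens, n_iter = 5)
  expect_lt(nrmse_arr(rec$image, img), 1e-6)
  expect_lte(rec$iterations, 2L)
})

test_that("CAIPI and wave phantom data reconstruct accurately; residuals fall", {
  ph <- make_brain_phantom(small_shape, small_voxel, seed = 1)
  sens <- make_sensitivities(small_shape, 8, seed = 2)
  b1 <- make_b1_map(small_shape, 0.3, TRUE, seed = 3)
  pat <- caipi_pattern(small_shape[2], small_shape[3], 2, 2, 1)
  kd <- simulate_acquisition(ph, conventional_protocol(), pat, sens,
                             b1 = b1, noise_sd = 0)
  rec <- suppressWarnings(cg_sense(kd, sens, n_iter = 30))
  expect_lt(nrmse_arr(Mod(rec$image), kd$truth), 0.05)
  expect_true(all(diff(rec$residuals) <= 1e-10))
  ro <- make_quiet_readout(small_shape[1], small_shape[1] * small_voxel * 1e-3)
  ws <- wave_sampling(caipi_pattern(small_shape[2], small_shape[3]),
                      ro$kz_mod)
  kw <- simulate_acquisition(ph, quiet_protocol(), ws, sens, b1 = b1,
                             noise_sd = 0)
  rw <- suppressWarnings(cg_sense(kw, sens, n_iter = 30))
  expect_lt(nrmse_arr(Mod(rw$image), kw$truth), 0.05)
  expect_true(all(diff(rw$residuals) <= 1e-10))
})

test_that("the CAIPI shift lowers reconstructed noise at equal density", {
  ph <- make_brain_phantom(small_shape, small_voxel, seed = 1)
  sens <- make_sensitivities(small_shape, 8, seed = 2)
  noise_of <- function(shift) {
    pat <- caipi_pattern(small_shape[2], small_shape[3], 2, 2, shift)
    k0 <- simulate_acquisition(ph, conventional_protocol(), pat, sens,
                               noise_sd = 0)
    k1 <- simulate_acquisition(ph, conventional_protocol(), pat, sens,
                               noise_sd = 0.02, seed = 9)
    r0 <- suppressWarnings(cg_sense(k0, sens, n_iter = 20))$image
    r1 <- suppressWarnings(cg_sense(k1, sens, n_iter = 20))$image
    stats::sd(Mod(r1 - r0)[ph$labels > 0])
  }
  expect_lt(noise_of(1), noise_of(0))
})

test_that("trajectory mismatch degrades and correcting it recovers", {
  shape <- c(16L, 16L, 16L)
  voxel <- 12
  ph <- make_brain_phantom(shape, voxel, seed = 2)
  sens <- make_sensitivities(shape, 2, seed = 3)
  # nominal: a Cartesian raster scan expressed as a trajectory
  grid_k <- function(n, fov) (seq_len(n) - (n %/% 2) - 1) / fov
  pts <- expand.grid(kx = grid_k(shape[1], shape[1] * voxel * 1e-3),
                     ky = grid_k(shape[2], shape[2] * voxel * 1e-3),
                     kz = grid_k(shape[3], shape[3] * voxel * 1e-3))
  nominal <- structure(list(time = seq_len(nrow(pts)) * 1e-3, kx = pts$kx,
                            ky = pts$ky, kz = pts$kz, raster = 1),
                       class = "k_trajectory")
  perturbed <- nominal
  dk <- 0.25 / (shape[1] * voxel * 1e-3)
  # one-sided perturbation keeps the path inside the Nyquist box
  perturbed$kx <- perturbed$kx +
    dk * (0.5 + 0.5 * sin(seq(0, 20, length.out = nrow(pts))))
  kd <- simulate_acquisition(ph, conventional_protocol(), perturbed, sens,
                             noise_sd = 0)
  rec_wrong <- suppressWarnings({
    kd_wrong <- kd; kd_wrong$sampling <- nominal
    cg_sense(kd_wrong, sens, n_iter = 6)
  })
  rec_right <- suppressWarnings(cg_sense(kd, sens, n_iter = 6))
  err_wrong <- nrmse_arr(Mod(rec_wrong$image), kd$truth)
  err_right <- nrmse_arr(Mod(rec_right$image), kd$truth)
  expect_gt(err_wrong, 2 * err_right)
  expect_lt(err_right, 0.05)
})

test_that("malformed trajectory files are rejected with line numbers", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# raster_us=2.5", "# kind=trajectory",
               "0.0025 1 0 0", "0.005 2 0", "0.0075 3 0 0"), path)
  expect_error(load_measured_trajectory(path), "line 4")
  writeLines(c("# raster_us=2.5", "0.005 1 0 0", "0.0025 2 0 0"), path)
  expect_error(load_measured_trajectory(path), "non-monotone")
  writeLines(c("0.0025 1 0 0"), path)
  expect_error(load_measured_trajectory(path), "raster_us")
})

test_that("trajectories beyond the grid Nyquist extent are rejected", {
  shape <- c(16L, 16L, 8L)
  sens <- make_sensitivities(shape, 1)
  img <- make_random_image(shape)
  bad <- structure(list(time = c(1, 2), kx = c(0, 200), ky = c(0, 0),
                        kz = c(0, 0), raster = 1), class = "k_trajectory")
  expect_error(encode(img, sens, bad, voxel = 7), "Nyquist")
})

test_that("NIfTI export writes a readable volume", {
  vol <- array(runif(16 * 16 * 8), dim = c(16, 16, 8))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume_nifti(vol, path, voxel = 3.5)
  back <- RNifti::readNifti(path)
  expect_equal(array(as.numeric(back), dim(vol)), vol, tolerance = 1e-6)
})
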