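test_that("phantom generation is deterministic and partitions the grid", {
  a <- make_brain_phantom(small_shape, small_voxel, seed = 7)
  b <- make_brain_phantom(small_shape, small_voxel, seed = 7)
  expect_identical(a$labels, b$labels)
  c_ <- make_brain_phantom(small_shape, small_voxel, seed = 8)
  expect_false(identical(a$labels, c_$labels))
  counts <- table(factor(a$labels, levels = 0:3))
  expect_identical(as.integer(sum(counts)), as.integer(prod(small_shape)))
  expect_true(all(counts[c("1", "2", "3")] > 0))
  expect_error(make_brain_phantom(c(8, 8, 8)), class = "quietmr_invalid")
})

test_that("default phantom hits the configured volume fractions", {
  ph <- make_brain_phantom()   # 64 x 64 x 32
  target <- c(GM = 0.40, WM = 0.37, CSF = 0.23)
  for (nm in names(target)) {
    expect_lt(abs(ph$volume_fractions[[nm]] - target[[nm]]) / target[[nm]],
              0.20)
  }
})

test_that("sensitivity maps satisfy the SENSE normalisation", {
  sens <- make_sensitivities(small_shape, 8, seed = 2)
  rss <- sqrt(apply(Mod(sens$maps)^2, 1:3, sum))
  expect_true(all(rss > 0.9 & rss < 1.1))
  uni <- make_sensitivities(small_shape, 1)
  expect_true(all(uni$maps == 1 + 0i))
  expect_error(make_sensitivities(small_shape, 0), class = "quietmr_invalid")
})

test_that("B1 map is smooth, positive, mean one, with the temporal dip", {
  flat <- make_b1_map(small_shape, 0)
  expect_true(all(flat$values == 1))
  b1 <- make_b1_map(small_shape, 0.3, temporal_dip = TRUE, seed = 4)
  expect_true(all(b1$values > 0))
  expect_equal(mean(b1$values), 1, tolerance = 0.02)
  # bounded voxel-to-voxel change along every axis (smoothness)
  nx <- dim(b1$values)[1]; ny <- dim(b1$values)[2]; nz <- dim(b1$values)[3]
  expect_lt(max(abs(b1$values[-1, , ] - b1$values[-nx, , ])), 0.05)
  expect_lt(max(abs(b1$values[, -1, ] - b1$values[, -ny, ])), 0.05)
  expect_lt(max(abs(b1$values[, , -1] - b1$values[, , -nz])), 0.05)
  # left-temporal octant mean below the right-temporal octant mean
  nx <- small_shape[1]
  left <- b1$values[1:(nx / 2), , 1:(small_shape[3] / 2)]
  right <- b1$values[(nx / 2 + 1):nx, , 1:(small_shape[3] / 2)]
  expect_lt(mean(left), mean(right))
  expect_error(make_b1_map(small_shape, 1.5), class = "quietmr_invalid")
})

test_that("noiseless full-Cartesian acquisition inverts by the adjoint", {
  ph <- make_brain_phantom(small_shape, small_voxel, seed = 1)
  sens <- make_sensitivities(small_shape, 4, seed = 2)
  full <- caipi_pattern(small_shape[2], small_shape[3])
  kd <- simulate_acquisition(ph, conventional_protocol(), full, sens,
                             noise_sd = 0)
  rec <- Mod(adjoint_recon(kd, sens))
  expect_lt(nrmse_arr(rec, kd$truth), 1e-3)
  # zero proton density gives identically zero samples
  void <- lapply(default_tissues(), function(t) {
    tissue_params(t$name, t$t1, t$t2, pd = 0)
  })
  ph0 <- make_brain_phantom(small_shape, small_voxel, seed = 1,
                            tissue_map = void)
  kd0 <- simulate_acquisition(ph0, conventional_protocol(), full, sens,
                              noise_sd = 0)
  expect_true(all(Mod(kd0$data) == 0))
})

test_that("per-tissue image means reproduce the EPG prediction", {
  ph <- make_brain_phantom(small_shape, small_voxel, seed = 1)
  sens <- make_sensitivities(small_shape, 4, seed = 2)
  full <- caipi_pattern(small_shape[2], small_shape[3])
  p <- conventional_protocol()
  kd <- simulate_acquisition(ph, p, full, sens, noise_sd = 0)
  rec <- Mod(adjoint_recon(kd, sens))
  gm_mean <- mean(rec[ph$labels == 1L])
  wm_mean <- mean(rec[ph$labels == 2L])
  want <- simulate_mprage(p, default_tissues()$GM)$central /
    simulate_mprage(p, default_tissues()$WM)$central
  expect_equal(gm_mean / wm_mean, want, tolerance = 1e-3)
})

test_that("noise depends only on its seed and decorrelates across seeds", {
  ph <- make_brain_phantom(small_shape, small_voxel, seed = 1)
  sens <- make_sensitivities(small_shape, 4, seed = 2)
  full <- caipi_pattern(small_shape[2], small_shape[3])
  p <- conventional_protocol()
  k0 <- simulate_acquisition(ph, p, full, sens, noise_sd = 0)
  k1 <- simulate_acquisition(ph, p, full, sens, noise_sd = 0.01, seed = 5)
  k1b <- simulate_acquisition(ph, p, full, sens, noise_sd = 0.01, seed = 5)
  k2 <- simulate_acquisition(ph, p, full, sens, noise_sd = 0.01, seed = 6)
  expect_identical(k1$data, k1b$data)
  n1 <- as.vector(Re(k1$data - k0$data))
  n2 <- as.vector(Re(k2$data - k0$data))
  expect_gt(stats::sd(n1), 0)
  expect_lt(abs(stats::cor(n1, n2)), 0.05)
})

test_that("inversion preparation suppresses CSF", {
  tis <- default_tissues()
  # conventional protocol sits in the nulling regime at the k-space centre
  conv <- simulate_mprage(conventional_protocol(), tis$CSF)$central /
    simulate_mprage(conventional_protocol(), tis$WM)$central
  expect_lt(conv, 0.20)
  # the quiet variant's longer TR weakens the null but CSF stays well below
  # its proton-density-weighted level relative to WM (pd ratio 1.43)
  quiet <- simulate_mprage(quiet_protocol(), tis$CSF)$central /
    simulate_mprage(quiet_protocol(), tis$WM)$central
  expect_lt(quiet, 0.5)
})
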