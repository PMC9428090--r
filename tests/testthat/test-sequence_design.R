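test_that("trapezoid area matches the request and respects limits", {
  lim <- whole_body_limits("conventional")
  expect_length(make_trapezoid(0, lim)$samples, 0)
  for (area in c(0.5, 5, 40, -12)) {
    wf <- make_trapezoid(area, lim, raster = 4)
    # trapezoidal-integration oracle
    expect_equal(sum(wf$samples) * wf$raster * 1e-3, area,
                 tolerance = 1e-9)
    expect_lte(max(abs(wf$samples)), lim$max_amplitude * (1 + 1e-9))
    expect_lte(waveform_peak_slew(wf), lim$max_slew * (1 + 1e-9))
  }
})

test_that("doubling the slew limit never lengthens a trapezoid", {
  for (area in c(1, 10, 60)) {
    slow <- make_trapezoid(area, whole_body_limits(max_slew = 100))
    fast <- make_trapezoid(area, whole_body_limits(max_slew = 200))
    expect_lte(length(fast$samples), length(slow$samples))
  }
})

test_that("silent gradient is a feasible sinusoid with the analytic slew", {
  spec <- silent_gradient_spec()
  expect_equal(silent_peak_slew(spec), 2 * pi * 20e3 * 28.6e-3,
               tolerance = 1e-12)
  wf <- make_silent_gradient(spec, duration = 1)
  expect_equal(max(abs(wf$samples)), 28.6, tolerance = 1e-6)
  # finite-difference slew approaches 2*pi*f*A (within discretisation)
  expect_equal(waveform_peak_slew(wf), 2 * pi * 20e3 * 28.6e-3,
               tolerance = 0.02)
  # zero amplitude degenerates to silence
  z <- make_silent_gradient(silent_gradient_spec(amplitude = 0), 0.5)
  expect_true(all(z$samples == 0))
  # an infeasible drive (slew ceiling) is rejected at construction
  expect_error(silent_gradient_spec(amplitude = 45),
               class = "quietmr_infeasible")
  expect_error(silent_gradient_spec(frequency = 40, amplitude = 28.6),
               class = "quietmr_infeasible")
})

test_that("full-amplitude 20 kHz drive stays inside the coil slew ceiling", {
  spec <- silent_gradient_spec(amplitude = 40)
  expect_lt(silent_peak_slew(spec), 5200)
  expect_equal(silent_peak_slew(spec), 5026.548, tolerance = 1e-4)
})

test_that("k-space trajectory integration matches closed forms", {
  # constant 10 mT/m for 1 ms -> kx = 425.77 1/m
  wf <- gradient_waveform(rep(10, 400), raster = 2.5, axis = "x")
  traj <- k_trajectory(wf)
  expect_equal(tail(traj$kx, 1), 42.577e6 * 0.010 * 0.001, tolerance = 1e-6)
  expect_true(all(traj$ky == 0) && all(traj$kz == 0))
  # zero gradient -> k identically 0
  z <- k_trajectory(gradient_waveform(numeric(100), 2.5, "y"))
  expect_true(all(z$ky == 0))
  # 20 kHz sinusoid: kz oscillates with amplitude gamma_bar*A/(2*pi*f)
  spec <- silent_gradient_spec()
  sg <- make_silent_gradient(spec, duration = 1)
  tz <- k_trajectory(sg)
  k_amp <- 42.577e6 * 28.6e-3 / (2 * pi * 20e3)
  expect_equal(max(tz$kz), 2 * k_amp, tolerance = 1e-2)
  expect_equal(mean(range(tz$kz)), k_amp, tolerance = 1e-2)
})

test_that("differentiating the trajectory recovers the waveform", {
  wf <- make_trapezoid(20, whole_body_limits("quiet"), raster = 2.5)
  traj <- k_trajectory(wf)
  g_back <- diff(c(0, traj$kx)) / (traj$raster * 1e-6) / 42.577e6 * 1e3
  expect_equal(g_back, wf$samples, tolerance = 1e-6)
})

test_that("quiet readout degenerates, zig-zags and respects reduced limits", {
  n_x <- 64L; fov_x <- 0.224
  # amplitude 0 reduces to a conventional Cartesian readout
  ro0 <- make_quiet_readout(n_x, fov_x,
                            spec = silent_gradient_spec(amplitude = 0))
  expect_null(ro0$gz)
  expect_true(all(ro0$kz_mod == 0))
  ro <- make_quiet_readout(n_x, fov_x)
  # kz modulation is centred and spans the analytic excursion
  k_amp <- 42.577e6 * 28.6e-3 / (2 * pi * 20e3)
  expect_lte(max(abs(ro$kz_mod)), k_amp + 1e-9)
  expect_gt(max(ro$kz_mod), 0.95 * k_amp)
  expect_lt(min(ro$kz_mod), -0.95 * k_amp)
  # distinct kz bands = 2*floor(excursion/dkz) + 1 for the phantom grid
  dkz <- 1 / (32 * 3.5e-3)
  bands <- length(unique(round(ro$kz_mod / dkz)))
  expect_identical(bands, as.integer(2 * floor(k_amp / dkz) + 1))
  # kx advances monotonically over the flat top while kz sweeps
  traj <- k_trajectory(ro)
  flat <- ro$flat_start:ro$flat_end
  expect_true(all(diff(traj$kx[flat]) > 0))
  expect_gt(length(unique(sign(diff(traj$kz[flat])))), 1)
  # whole-body component obeys the reduced (quiet) limits
  expect_lte(waveform_peak_slew(ro$gx), 100 * (1 + 1e-9))
  # quiet whole-body readout has strictly lower peak slew than conventional
  conv <- make_quiet_readout(n_x, fov_x, whole_body_limits("conventional"),
                             spec = NULL)
  expect_lt(waveform_peak_slew(ro$gx), waveform_peak_slew(conv$gx))
  # infeasibly short flat top errors with the minimum feasible value named
  expect_error(make_quiet_readout(256, 0.01, flat_ms = 0.05, spec = NULL),
               class = "quietmr_infeasible")
})

test_that("CAIPI patterns tile the lattice as enumerated", {
  full <- caipi_pattern(8, 8)
  expect_true(all(full$mask))
  p <- caipi_pattern(8, 8, Ry = 2, Rz = 2, shift = 1)
  expect_identical(sum(p$mask), 16L)
  # enumeration: sampled ky columns 1,3,5,7 with kz offsets cycling 0,1
  want <- matrix(FALSE, 8, 8)
  for (j in seq(1, 8, by = 2))
    want[j, seq(1 + (((j - 1) / 2) %% 2), 8, by = 2)] <- TRUE
  expect_identical(p$mask, want)
  expect_identical(sum(caipi_pattern(7, 9, 2, 2, 1)$mask) -
                     ceiling(7 / 2) * ceiling(9 / 2) <= 4, TRUE)
  expect_warning(caipi_pattern(8, 8, 2, 2, shift = 2), "modulo")
})

test_that("sequence duration reproduces the printed acquisition times", {
  expect_identical(sequence_duration(conventional_protocol(), 0), 0)
  # 48 shots at 3 s -> 144 s (2:24)
  expect_equal(sequence_duration(conventional_protocol(), 48), 144)
  # 55 shots -> 165 s, within one shot interval of the printed 2:44 (164 s)
  expect_lte(abs(sequence_duration(quiet_protocol(), 55) - 164), 3)
})

test_that("trajectory text round trip is lossless", {
  ro <- make_quiet_readout(32, 0.2)
  traj <- k_trajectory(ro)
  path <- withr::local_tempfile(fileext = ".txt")
  write_trajectory(traj, path)
  back <- load_measured_trajectory(path)
  expect_equal(back$kx, traj$kx, tolerance = 1e-9)
  expect_equal(back$kz, traj$kz, tolerance = 1e-9)
  expect_equal(back$raster, traj$raster)
})
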