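test_that("RF operator reproduces the textbook limits", {
  s <- epg_state(K = 4)
  inv <- epg_rf(s, 180, 0)
  expect_equal(Re(inv$z[1]), -1, tolerance = 1e-12)
  expect_equal(max(Mod(inv$f_plus)), 0, tolerance = 1e-12)
  exc <- epg_rf(s, 90, 90)
  expect_equal(Mod(exc$f_plus[1]), 1, tolerance = 1e-12)
  expect_equal(Mod(exc$z[1]), 0, tolerance = 1e-12)
  # zero flip is the identity
  id <- epg_rf(random_epg_state(seed = 3), 0, 45)
  expect_equal(id, random_epg_state(seed = 3))
})

test_that("RF operator matches the dense per-order rotation oracle", {
  s <- random_epg_state(K = 6, seed = 11)
  got <- epg_rf(s, 37, 13)
  want <- epg_rf_oracle(s, 37, 13)
  expect_equal(got$f_plus, want$f_plus, tolerance = 1e-12)
  expect_equal(got$f_minus, want$f_minus, tolerance = 1e-12)
  expect_equal(got$z, want$z, tolerance = 1e-12)
  expect_error(epg_rf(s, NaN, 0), class = "quietmr_invalid")
})

test_that("relaxation/shift behaves as closed forms demand", {
  t <- tissue_params("x", t1 = 800, t2 = 60, pd = 0.9)
  s <- random_epg_state(seed = 5)
  expect_equal(epg_relax_shift(s, 0, t, 0L), s)   # identity at dt = 0
  # pure T1 recovery of z[0] toward pd
  s0 <- epg_state(K = 4, pd = 0.9)
  s0$z[1] <- 0.2 + 0i
  rec <- epg_relax_shift(s0, 123, t, 0L)
  expect_equal(Re(rec$z[1]), 0.9 - (0.9 - 0.2) * exp(-123 / 800),
               tolerance = 1e-12)
  # structural shift: new F+(k+1) equals old F+(k)
  sh <- epg_relax_shift(s, 0, t, 1L)
  expect_equal(sh$f_plus[-1], s$f_plus[seq_len(s$K)])
  expect_error(epg_relax_shift(s, -1, t), class = "quietmr_invalid")
})

test_that("simulated signal is bounded by proton density and pd = 0 is dark", {
  p <- quiet_protocol()
  for (tis in default_tissues()) {
    e <- simulate_mprage(p, tis, n_shots = 4)$echoes
    expect_true(all(e >= 0 & e <= tis$pd + 1e-12))
  }
  dark <- tissue_params("void", 1000, 50, pd = 0)
  expect_equal(simulate_mprage(p, dark)$echoes,
               rep(0, p$n_echoes_per_shot))
})

test_that("without inversion the train converges to the Ernst closed form", {
  set.seed(202)
  for (i in 1:20) {
    t1 <- runif(1, 600, 1600)
    t2 <- runif(1, 30, 100)
    tr <- runif(1, 8, 30)
    te <- 0.3 * tr
    flip <- runif(1, 5, 40)
    pd <- runif(1, 0.5, 1.2)
    n_echo <- 4000L
    p <- mprage_protocol(te, tr, ti = 1, shot_interval = tr * n_echo + 2,
                         flip = flip, inv_efficiency = NA,
                         n_echoes_per_shot = n_echo,
                         ti_convention = "first_excitation")
    sim <- simulate_mprage(p, tissue_params("t", t1, t2, pd), n_shots = 2)
    expect_lt(rel_err(tail(sim$echoes, 1),
                      ernst_oracle(pd, t1, t2, flip, tr, te)), 1e-6)
  }
})

test_that("steady state is reached across shots", {
  p <- quiet_protocol()
  gm <- default_tissues()$GM
  a <- simulate_mprage(p, gm, n_shots = 8)
  b <- simulate_mprage(p, gm, n_shots = 9)
  expect_lt(max(abs(a$echoes - b$echoes)) / max(a$echoes), 1e-6)
})

test_that("signals rise with flip angle below the Ernst angle", {
  tr <- 15
  for (tis in default_tissues(c("GM", "WM"))) {
    ernst_deg <- acos(exp(-tr / tis$t1)) * 180 / pi
    flips <- seq(1, ernst_deg, length.out = 6)
    p0 <- mprage_protocol(te = 4, tr = tr, ti = 1,
                          shot_interval = tr * 200 + 2, flip = 10,
                          inv_efficiency = NA, n_echoes_per_shot = 200L,
                          ti_convention = "first_excitation")
    sig <- vapply(flips, function(f) {
      p0$flip <- f
      tail(simulate_mprage(p0, tis, n_shots = 2)$echoes, 1)
    }, numeric(1))
    expect_true(all(diff(sig) > 0))
  }
})

test_that("B1 scaling hook is equivalent to scaling the flip angle", {
  gm <- default_tissues()$GM
  p <- quiet_protocol()
  for (b in c(0.7, 1.15)) {
    direct <- simulate_mprage(quiet_protocol(flip = p$flip * b), gm)
    hooked <- simulate_mprage(p, gm, b1 = b)
    expect_equal(hooked$echoes, direct$echoes, tolerance = 1e-12)
  }
})

test_that("flip matching returns the reference flip for identical protocols", {
  tis <- default_tissues()
  conv <- conventional_protocol()
  res <- optimize_flip(conv, conv, tissues = tis,
                       flip_grid = seq(1, 90, by = 0.5))
  expect_identical(res$flip, 7)
})

test_that("flip matching is stable under grid refinement and rejects bad input", {
  tis <- default_tissues()
  quiet <- quiet_protocol()
  ref <- protocol_contrast(conventional_protocol(), tis)
  coarse <- optimize_flip(quiet, ref, tis, flip_grid = seq(1, 90, by = 2))
  fine <- optimize_flip(quiet, ref, tis, flip_grid = seq(1, 90, by = 1))
  expect_lte(abs(coarse$flip - fine$flip), 2)
  expect_error(optimize_flip(quiet, ref, tis, flip_grid = numeric(0)),
               class = "quietmr_invalid")
  expect_error(optimize_flip(quiet, ref, tis, flip_grid = c(10, 95)),
               class = "quietmr_invalid")
})

test_that("protocol validation enforces the timing invariants", {
  expect_error(mprage_protocol(te = 5, tr = 4, ti = 900, shot_interval = 3000,
                               flip = 10), class = "quietmr_invalid")
  expect_error(mprage_protocol(te = 2, tr = 4, ti = 3500,
                               shot_interval = 3000, flip = 10),
               class = "quietmr_invalid")
  expect_error(quiet_protocol(flip = 120), class = "quietmr_invalid")
  # train must fit inside the shot interval
  expect_error(mprage_protocol(te = 2, tr = 20, ti = 1000,
                               shot_interval = 3000, flip = 10,
                               n_echoes_per_shot = 150L),
               class = "quietmr_invalid")
  expect_error(tissue_params("x", t1 = 50, t2 = 80, pd = 1),
               class = "quietmr_invalid")
})

test_that("protocol YAML round trip preserves all fields", {
  path <- withr::local_tempfile(fileext = ".yaml")
  p <- quiet_protocol()
  write_protocol(p, path)
  expect_equal(read_protocol(path), p)
  fx <- system.file("extdata", "protocol_quiet.yaml", package = "quietmr")
  q <- read_protocol(fx)
  expect_equal(q$te, 8.9)
  expect_equal(q$flip, 13)
})
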