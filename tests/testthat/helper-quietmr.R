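# Shared fixtures and independent oracles for the test suite.

# Small grid used by most reconstruction tests (full size is exercised in
# the acceptance tests).
small_shape <- c(32L, 32L, 16L)
small_voxel <- 7

random_epg_state <- function(K = 6L, seed = 1L) {
  set.seed(seed)
  s <- epg_state(K = K)
  s$f_plus <- complex(real = rnorm(K + 1), imaginary = rnorm(K + 1))
  s$f_minus <- complex(real = rnorm(K + 1), imaginary = rnorm(K + 1))
  s$z <- complex(real = rnorm(K + 1), imaginary = rnorm(K + 1))
  s
}

# Independent dense EPG rotation oracle: build the 3x3 mixing matrix
# explicitly and apply it per configuration order.
epg_rf_oracle <- function(state, flip, phase) {
  a <- flip * pi / 180
  p <- phase * pi / 180
  T <- matrix(c(
    cos(a / 2)^2,                exp(2i * p) * sin(a / 2)^2,  -1i * exp(1i * p) * sin(a),
    exp(-2i * p) * sin(a / 2)^2, cos(a / 2)^2,                1i * exp(-1i * p) * sin(a),
    -0.5i * exp(-1i * p) * sin(a), 0.5i * exp(1i * p) * sin(a), cos(a)),
    nrow = 3, byrow = TRUE)
  out <- state
  for (k in seq_len(state$K + 1L)) {
    v <- T %*% c(state$f_plus[k], state$f_minus[k], state$z[k])
    out$f_plus[k] <- v[1]; out$f_minus[k] <- v[2]; out$z[k] <- v[3]
  }
  out
}

# Spoiled gradient-echo steady state, written out independently of the
# package's ernst_signal().
ernst_oracle <- function(pd, t1, t2, flip, tr, te) {
  a <- flip * pi / 180
  e1 <- exp(-tr / t1)
  pd * sin(a) * (1 - e1) / (1 - e1 * cos(a)) * exp(-te / t2)
}

# Brute-force Wilcoxon signed-rank oracle: enumerate sign assignments via
# expand.grid (a different code path from the implementation's bit matrix).
wilcoxon_oracle <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  if (!length(d)) return(1)
  r <- rank(abs(d))
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  w_obs <- sum(r[d > 0])
  mu <- sum(r) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# IEC 61672 A-weighting magnitude, written out independently.
a_weight_oracle <- function(f) {
  ra <- function(f) {
    12194^2 * f^4 / ((f^2 + 20.6^2) *
                       sqrt((f^2 + 107.7^2) * (f^2 + 737.9^2)) *
                       (f^2 + 12194^2))
  }
  20 * log10(ra(f)) - 20 * log10(ra(1000))
}

sine_tone <- function(freq, fs = 48000, dur = 1, rms = 1, phase = 0) {
  t <- seq_len(round(fs * dur)) / fs
  pressure_series(rms * sqrt(2) * sin(2 * pi * freq * t + phase), fs)
}

rel_err <- function(x, ref) abs(x - ref) / abs(ref)

nrmse_arr <- function(x, ref) sqrt(sum(Mod(x - ref)^2) / sum(Mod(ref)^2))
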