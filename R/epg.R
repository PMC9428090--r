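#' Extended phase graph configuration state
#'
#' The EPG formalism tracks magnetisation as complex configuration-order
#' amplitudes: `f_plus[k+1]` holds the transverse state F+(k),
#' `f_minus[k+1]` holds F-(k) (stored as the conjugate-pair partner of
#' F+(-k), the usual convention), and `z[k+1]` holds the longitudinal state
#' Z(k), for dephasing orders k = 0..K.
#'
#' At thermal equilibrium all transverse orders vanish and `z[1] = pd`.
#'
#' @param K Maximum tracked dephasing order (integer >= 1).
#' @param pd Equilibrium longitudinal magnetisation (proton density).
#' @return An object of class `epg_state` with fields `f_plus`, `f_minus`,
#'   `z` (complex vectors of length `K + 1`), `K` and `pd`.
#' @examples
#' s <- epg_state(K = 4)
#' s <- epg_rf(s, flip = 90, phase = 90)
#' Mod(s$f_plus[1])  # full excitation
#' @export
epg_state <- function(K = 16L, pd = 1) {
  K <- as.integer(K)
  if (K < 1L) stop_invalid("K must be >= 1")
  z <- complex(K + 1L)
  z[1L] <- pd
  structure(list(f_plus = complex(K + 1L), f_minus = complex(K + 1L),
                 z = z, K = K, pd = pd),
            class = "epg_state")
}

#' @export
print.epg_state <- function(x, ...) {
  cat(sprintf("<epg state> K = %d, |F+(0)| = %.4g, Z(0) = %.4g%+.4gi\n",
              x$K, Mod(x$f_plus[1]), Re(x$z[1]), Im(x$z[1])))
  invisible(x)
}

#' Apply an RF pulse to an EPG state
#'
#' Mixes every configuration order by the standard EPG rotation matrix for a
#' pulse of the given flip angle and phase. The order count is unchanged.
#'
#' @param state An `epg_state`.
#' @param flip Flip angle, degrees, in `[0, 180]`.
#' @param phase Pulse phase, degrees.
#' @return The rotated `epg_state`.
#' @export
epg_rf <- function(state, flip, phase = 0) {
  stopifnot(inherits(state, "epg_state"))
  check_scalar(flip, "flip"); check_scalar(phase, "phase")
  if (flip < 0 || flip > 180) stop_invalid("flip must lie in [0, 180] degrees")
  a <- flip * pi / 180
  p <- phase * pi / 180
  ca2 <- cos(a / 2)^2
  sa2 <- sin(a / 2)^2
  sa <- sin(a)
  ep <- exp(1i * p)
  # 3x3 mixing of (F+(k), F-(k), Z(k)) per order (Hennig / Weigel convention)
  T11 <- ca2;                T12 <- ep^2 * sa2;        T13 <- -1i * ep * sa
  T21 <- Conj(ep)^2 * sa2;   T22 <- ca2;               T23 <- 1i * Conj(ep) * sa
  T31 <- -0.5i * Conj(ep) * sa; T32 <- 0.5i * ep * sa; T33 <- cos(a)
  fp <- state$f_plus; fm <- state$f_minus; z <- state$z
  state$f_plus  <- T11 * fp + T12 * fm + T13 * z
  state$f_minus <- T21 * fp + T22 * fm + T23 * z
  state$z       <- T31 * fp + T32 * fm + T33 * z
  state
}

#' Relaxation, recovery and gradient dephasing of an EPG state
#'
#' Decays all transverse orders by `exp(-dt/t2)` and longitudinal orders by
#' `exp(-dt/t1)` with T1 recovery of the order-0 longitudinal state toward
#' the tissue proton density, then shifts the transverse configuration
#' orders by `shift` gradient-dephasing increments.
#'
#' @param state An `epg_state`.
#' @param dt Evolution interval, ms, non-negative.
#' @param tissue A [tissue_params()] object.
#' @param shift Integer dephasing increment (positive shifts F+ orders up).
#' @return The evolved `epg_state`.
#' @export
epg_relax_shift <- function(state, dt, tissue, shift = 0L) {
  stopifnot(inherits(state, "epg_state"), inherits(tissue, "tissue_params"))
  check_scalar(dt, "dt")
  if (dt < 0) stop_invalid("dt must be non-negative")
  shift <- as.integer(shift)
  if (dt > 0) {
    e2 <- exp(-dt / tissue$t2)
    e1 <- exp(-dt / tissue$t1)
    state$f_plus <- state$f_plus * e2
    state$f_minus <- state$f_minus * e2
    state$z <- state$z * e1
    state$z[1L] <- state$z[1L] + tissue$pd * (1 - e1)
  }
  if (shift != 0L) {
    K <- state$K
    for (s in seq_len(abs(shift))) {
      if (shift > 0L) {
        fp <- state$f_plus; fm <- state$f_minus
        state$f_plus <- c(Conj(fm[2L]), fp[seq_len(K)])
        state$f_minus <- c(fm[-1L], 0)
      } else {
        fp <- state$f_plus; fm <- state$f_minus
        state$f_minus <- c(Conj(fp[2L]), fm[seq_len(K)])
        state$f_plus <- c(fp[-1L], 0)
      }
    }
  }
  state
}

#' Ideal spoiling: discard all transverse configuration orders
#'
#' @param state An `epg_state`.
#' @return The spoiled state (longitudinal orders untouched).
#' @export
epg_spoil <- function(state) {
  stopifnot(inherits(state, "epg_state"))
  state$f_plus[] <- 0
  state$f_minus[] <- 0
  state
}

# Inversion preparation: multiplies every longitudinal order by the
# efficiency scalar (-1 = perfect adiabatic inversion). NA means the pulse
# is not played at all.
apply_inversion <- function(state, efficiency) {
  if (is.na(efficiency)) return(state)
  state$z <- state$z * efficiency
  state
}

#' Simulate the MPRAGE echo train for one tissue
#'
#' Runs the EPG recursion through `n_shots` inversion shots of the protocol
#' and returns the echo-signal magnitudes of the last shot, by which point a
#' periodic steady state has normally been reached. Ideal RF and gradient
#' spoiling is assumed between excitations (transverse states are discarded
#' at the end of each TR), which is the regime a spoiled MPRAGE readout is
#' designed for; the echo signal is `|F+(0)|` at time TE after each
#' excitation.
#'
#' @param protocol An [mprage_protocol()].
#' @param tissue A [tissue_params()].
#' @param n_shots Number of shots to simulate (integer >= 1). The default 6
#'   is ample for the built-in protocols; convergence can be checked by
#'   comparing `echoes` across `n_shots`.
#' @param b1 Relative transmit (B1) scale; the excitation flip angle is
#'   multiplied by `b1`. The inversion is modelled as B1-robust (adiabatic)
#'   and is not scaled.
#' @param K Maximum tracked EPG order; defaults to
#'   `min(n_echoes_per_shot + 2, 8)` — under ideal spoiling only the lowest
#'   orders are ever populated, so a small cap loses nothing.
#' @return A list with `echoes` (magnitudes per echo of the last shot),
#'   `mean` (their mean, the scalar used for contrast matching), `central`
#'   (the central echo — the k-space-centre signal that sets image contrast
#'   under linear phase-encode ordering), and `z_end` (the longitudinal
#'   state at the end of the last shot).
#' @examples
#' gm <- default_tissues()$GM
#' simulate_mprage(quiet_protocol(), gm)$mean
#' @export
simulate_mprage <- function(protocol, tissue, n_shots = 6L, b1 = 1,
                            K = NULL) {
  stopifnot(inherits(protocol, "mprage_protocol"),
            inherits(tissue, "tissue_params"))
  n_shots <- as.integer(n_shots)
  if (n_shots < 1L) stop_invalid("n_shots must be >= 1")
  check_scalar(b1, "b1")
  n_echo <- protocol$n_echoes_per_shot
  if (is.null(K)) K <- min(n_echo + 2L, 8L)
  st <- epg_state(K = K, pd = tissue$pd)
  flip_eff <- protocol$flip * b1
  if (flip_eff > 180) flip_eff <- 180
  e2_te <- exp(-protocol$te / tissue$t2)
  echoes <- numeric(n_echo)
  ti_first <- ti_first_excitation(protocol)
  train_time <- protocol$tr * n_echo
  tail_time <- protocol$shot_interval - ti_first - train_time
  for (shot in seq_len(n_shots)) {
    st <- apply_inversion(st, protocol$inv_efficiency)
    st <- epg_relax_shift(st, ti_first, tissue, shift = 0L)
    for (e in seq_len(n_echo)) {
      st <- epg_rf(st, flip_eff, phase = 0)
      echoes[e] <- Mod(st$f_plus[1L]) * e2_te
      st <- epg_relax_shift(st, protocol$tr, tissue, shift = 1L)
      st <- epg_spoil(st)
    }
    st <- epg_relax_shift(st, tail_time, tissue, shift = 0L)
  }
  list(echoes = echoes, mean = mean(echoes),
       central = echoes[n_echo %/% 2L + 1L], z_end = st$z[1L])
}

#' Steady-state spoiled gradient-echo (Ernst) signal
#'
#' Closed form `pd * sin(a) * (1 - E1) / (1 - E1 cos(a)) * exp(-te/t2)` with
#' `E1 = exp(-tr/t1)`; the limit the MPRAGE train converges to when no
#' inversion preparation is played.
#'
#' @param tissue A [tissue_params()].
#' @param flip Flip angle, degrees.
#' @param tr Repetition time, ms.
#' @param te Echo time, ms.
#' @return Signal magnitude.
#' @export
ernst_signal <- function(tissue, flip, tr, te) {
  a <- flip * pi / 180
  e1 <- exp(-tr / tissue$t1)
  tissue$pd * sin(a) * (1 - e1) / (1 - e1 * cos(a)) * exp(-te / tissue$t2)
}

#' Grey-white matter contrast of a protocol
#'
#' The scalar contrast used for flip-angle matching: by default the absolute
#' difference of the mean-over-train GM and WM signals; a ratio and a CNR-like
#' normalised difference are available behind `mode`.
#'
#' @param protocol An [mprage_protocol()].
#' @param tissues Named list containing `GM` and `WM` [tissue_params()].
#' @param mode `"difference"` (default), `"ratio"` or `"normalized"`
#'   (difference over sum).
#' @param n_shots Shots simulated to reach steady state.
#' @return Scalar contrast.
#' @export
protocol_contrast <- function(protocol, tissues = default_tissues(),
                              mode = c("difference", "ratio", "normalized"),
                              n_shots = 6L) {
  mode <- match.arg(mode)
  s_gm <- simulate_mprage(protocol, tissues$GM, n_shots = n_shots)$mean
  s_wm <- simulate_mprage(protocol, tissues$WM, n_shots = n_shots)$mean
  switch(mode,
         difference = abs(s_wm - s_gm),
         ratio = if (s_gm > 0) s_wm / s_gm else Inf,
         normalized = abs(s_wm - s_gm) / (s_wm + s_gm))
}

#' Match the quiet sequence's flip angle to a reference contrast
#'
#' Sweeps the quiet protocol's excitation flip angle over a grid and returns
#' the grid value whose simulated grey-white matter contrast is closest to
#' the reference (normally the conventional protocol's contrast on the same
#' tissues). Ties are broken toward the smaller flip angle.
#'
#' @param quiet An [mprage_protocol()] whose flip angle is to be chosen.
#' @param reference_contrast Target contrast scalar, or an
#'   [mprage_protocol()] from which it is computed with the same `mode` and
#'   tissues.
#' @param tissues Named list with `GM` and `WM` entries.
#' @param flip_grid Candidate flip angles, degrees, within (0, 90].
#' @param mode Contrast definition, see [protocol_contrast()].
#' @param n_shots Shots per simulation.
#' @return A list with `flip` (chosen angle), `contrast` (its contrast),
#'   `reference` (the target), and `grid` (a data.frame of all candidates).
#' @examples
#' \donttest{
#' optimize_flip(quiet_protocol(), conventional_protocol(),
#'               flip_grid = seq(4, 30, by = 1))$flip
#' }
#' @export
optimize_flip <- function(quiet, reference_contrast,
                          tissues = default_tissues(),
                          flip_grid = seq(1, 90, by = 0.5),
                          mode = "difference", n_shots = 6L) {
  stopifnot(inherits(quiet, "mprage_protocol"))
  if (length(flip_grid) == 0L) stop_invalid("flip_grid is empty")
  if (any(flip_grid <= 0 | flip_grid > 90))
    stop_invalid("flip_grid must lie in (0, 90]")
  if (inherits(reference_contrast, "mprage_protocol"))
    reference_contrast <- protocol_contrast(reference_contrast, tissues,
                                            mode = mode, n_shots = n_shots)
  check_scalar(reference_contrast, "reference_contrast")
  flip_grid <- sort(flip_grid)
  contrasts <- vapply(flip_grid, function(f) {
    p <- quiet; p$flip <- f
    protocol_contrast(p, tissues, mode = mode, n_shots = n_shots)
  }, numeric(1))
  err <- abs(contrasts - reference_contrast)
  best <- which(err == min(err))[1L]  # sorted grid: first index = smaller flip
  list(flip = flip_grid[best], contrast = contrasts[best],
       reference = reference_contrast,
       grid = data.frame(flip = flip_grid, contrast = contrasts,
                         abs_error = err))
}
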