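# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

# Normalised [-1, 1] coordinate arrays for a grid.
coord_arrays <- function(shape) {
  u <- lapply(shape, function(n) 2 * (seq_len(n) - (n + 1) / 2) / n)
  list(x = array(rep(u[[1]], times = shape[2] * shape[3]), dim = shape),
       y = array(rep(rep(u[[2]], each = shape[1]), times = shape[3]),
                 dim = shape),
       z = array(rep(u[[3]], each = shape[1] * shape[2]), dim = shape))
}

#' Synthetic three-compartment brain phantom
#'
#' A nested-ellipsoid head: a CSF rim inside the scalp surface, a grey
#' matter shell, a white matter core, and two CSF ventricles. The geometry
#' is deterministic for a given seed (the seed perturbs the ellipsoid axes
#' and ventricle positions by a few percent, standing in for anatomical
#' variability across subjects).
#'
#' @param shape Grid dimensions, integer length-3, each >= 16.
#' @param voxel Isotropic voxel size, mm. The default desk-scale grid of
#'   64 x 64 x 32 voxels at 3.5 mm covers a 224 x 224 x 112 mm head-sized
#'   field of view.
#' @param seed Integer seed.
#' @param tissue_map Label-to-parameter map, default [default_tissues()].
#' @return An object of class `brain_phantom`: integer `labels` array
#'   (0 background, 1 GM, 2 WM, 3 CSF), `voxel`, `shape`, `tissue_map`, and
#'   `volume_fractions` (per-class fraction of in-head voxels).
#' @examples
#' ph <- make_brain_phantom(c(32, 32, 16), voxel = 7)
#' table(ph$labels)
#' @export
make_brain_phantom <- function(shape = c(64, 64, 32), voxel = 3.5,
                               seed = 1L, tissue_map = default_tissues()) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 16L))
    stop_invalid("shape must be three dimensions, each >= 16")
  if (voxel <= 0) stop_invalid("voxel size must be positive")
  co <- with_seed(seed, {
    jit <- function() 1 + stats::runif(3, -0.03, 0.03)
    list(head = c(0.82, 0.92, 0.86) * jit(),
         gm = c(0.74, 0.84, 0.78) * jit(),
         wm = c(0.58, 0.68, 0.60) * jit(),
         vent_dx = stats::runif(1, 0.16, 0.22),
         vent_c = c(stats::runif(1, -0.02, 0.02),
                    stats::runif(1, 0.02, 0.10),
                    stats::runif(1, -0.05, 0.05)))
  })
  u <- coord_arrays(shape)
  inside <- function(ax, cx = c(0, 0, 0)) {
    ((u$x - cx[1]) / ax[1])^2 + ((u$y - cx[2]) / ax[2])^2 +
      ((u$z - cx[3]) / ax[3])^2 < 1
  }
  labels <- array(0L, dim = shape)
  labels[inside(co$head)] <- 3L                     # CSF rim
  labels[inside(co$gm)] <- 1L                       # GM shell
  labels[inside(co$wm)] <- 2L                       # WM core
  vent_ax <- c(0.10, 0.26, 0.14)
  labels[inside(vent_ax, co$vent_c + c(-co$vent_dx, 0, 0))] <- 3L
  labels[inside(vent_ax, co$vent_c + c(co$vent_dx, 0, 0))] <- 3L
  n_head <- sum(labels > 0L)
  fr <- c(GM = sum(labels == 1L), WM = sum(labels == 2L),
          CSF = sum(labels == 3L)) / n_head
  structure(list(labels = labels, voxel = voxel, shape = shape,
                 tissue_map = tissue_map, volume_fractions = fr,
                 seed = seed),
            class = "brain_phantom")
}

#' @export
print.brain_phantom <- function(x, ...) {
  cat(sprintf("<brain phantom> %s @ %g mm, fractions GM %.2f WM %.2f CSF %.2f\n",
              paste(x$shape, collapse = "x"), x$voxel,
              x$volume_fractions["GM"], x$volume_fractions["WM"],
              x$volume_fractions["CSF"]))
  invisible(x)
}

#' Smooth complex coil sensitivity maps
#'
#' Coil magnitudes are Gaussian lobes centred just outside the field of view
#' on a ring (mimicking a receive array around the head), each with a mild
#' linear phase; the maps are normalised to unit root-sum-of-squares
#' everywhere, which is the normalisation iterative SENSE assumes. With a
#' single coil the map is identically one.
#'
#' @param shape Grid dimensions.
#' @param n_coils Number of receive channels, >= 1 (default 8, a desk-scale
#'   stand-in for a 32-channel array).
#' @param seed Integer seed (jitters lobe positions/widths).
#' @return An object of class `sensitivity_maps`: complex array
#'   `shape x n_coils` and `n_coils`.
#' @export
make_sensitivities <- function(shape = c(64, 64, 32), n_coils = 8L,
                               seed = 1L) {
  shape <- as.integer(shape); n_coils <- as.integer(n_coils)
  if (n_coils < 1L) stop_invalid("n_coils must be >= 1")
  maps <- array(0i, dim = c(shape, n_coils))
  if (n_coils == 1L) {
    maps[] <- 1 + 0i
  } else {
    u <- coord_arrays(shape)
    pars <- with_seed(seed, {
      ang <- 2 * pi * (seq_len(n_coils) - 1) / n_coils +
        stats::runif(n_coils, -0.1, 0.1)
      list(ang = ang,
           # loops on two rings above/below the axial midplane
           zc = rep(c(-0.35, 0.35), length.out = n_coils) +
             stats::runif(n_coils, -0.05, 0.05),
           width = 0.6 * stats::runif(n_coils, 0.95, 1.05),
           ph0 = stats::runif(n_coils, 0, 2 * pi))
    })
    idx <- function(c_) (1:prod(shape)) + (c_ - 1L) * prod(shape)
    for (c_ in seq_len(n_coils)) {
      cx <- 1.2 * cos(pars$ang[c_]); cy <- 1.2 * sin(pars$ang[c_])
      d2 <- (u$x - cx)^2 + (u$y - cy)^2 + 0.8 * (u$z - pars$zc[c_])^2
      mag <- exp(-d2 / (2 * pars$width[c_]^2))
      phase <- pars$ph0[c_] + 1.5 * (u$x * cos(pars$ang[c_]) +
                                     u$y * sin(pars$ang[c_])) +
        0.8 * u$z * pars$zc[c_]
      maps[idx(c_)] <- mag * exp(1i * phase)
    }
    rss <- sqrt(apply(Mod(maps)^2, 1:3, sum))
    for (c_ in seq_len(n_coils))
      maps[idx(c_)] <- maps[idx(c_)] / rss
  }
  structure(list(maps = maps, n_coils = n_coils, shape = shape),
            class = "sensitivity_maps")
}

#' Smooth relative transmit (B1) field map
#'
#' Models 7 T transmit inhomogeneity as a smooth centre-bright field with
#' mean one over the grid; `inhomogeneity` in `[0, 1]` scales the spatial
#' variation (0 gives a uniform field). The optional `temporal_dip`
#' subtracts a localised Gaussian in the left temporal region, emulating the
#' left-right transmit asymmetry seen at 7 T.
#'
#' @param shape Grid dimensions.
#' @param inhomogeneity Variation strength, in `[0, 1]`.
#' @param temporal_dip Add the left-temporal dip?
#' @param seed Integer seed (jitters the field centre).
#' @return An object of class `b1_map` with a positive `values` array of
#'   mean approximately one.
#' @export
make_b1_map <- function(shape = c(64, 64, 32), inhomogeneity = 0.3,
                        temporal_dip = TRUE, seed = 1L) {
  shape <- as.integer(shape)
  if (inhomogeneity < 0 || inhomogeneity > 1)
    stop_invalid("inhomogeneity must lie in [0, 1]")
  vals <- array(1, dim = shape)
  if (inhomogeneity > 0) {
    u <- coord_arrays(shape)
    ctr <- with_seed(seed, stats::runif(3, -0.05, 0.05))
    r2 <- (u$x - ctr[1])^2 + (u$y - ctr[2])^2 + (u$z - ctr[3])^2
    bump <- exp(-r2 / (2 * 0.55^2))
    if (temporal_dip) {
      # "left" = negative x; temporal = lateral, slightly inferior
      d2 <- ((u$x + 0.55) / 0.30)^2 + (u$y / 0.45)^2 + ((u$z + 0.25) / 0.40)^2
      bump <- bump - 0.6 * exp(-d2 / 2)
    }
    vals <- 1 + inhomogeneity * (bump - mean(bump))
    vals[vals < 0.05] <- 0.05
  }
  structure(list(values = vals, shape = shape,
                 inhomogeneity = inhomogeneity,
                 temporal_dip = temporal_dip),
            class = "b1_map")
}

#' Per-voxel steady-state signal image of a phantom under a protocol
#'
#' Evaluates the EPG steady-state k-space-centre (central-echo) signal for
#' each tissue over the range of B1 scales present in the map (interpolating
#' a 33-point B1 grid) and paints it onto the phantom labels. The central
#' echo is what sets image contrast under linear phase-encode ordering.
#'
#' @param phantom A [make_brain_phantom()] object.
#' @param protocol An [mprage_protocol()].
#' @param b1 A [make_b1_map()] object or `NULL` for a uniform field.
#' @param n_shots Shots per EPG simulation.
#' @return Numeric array of signal magnitudes on the phantom grid.
#' @export
signal_image <- function(phantom, protocol, b1 = NULL, n_shots = 6L) {
  stopifnot(inherits(phantom, "brain_phantom"))
  img <- array(0, dim = phantom$shape)
  b1v <- if (is.null(b1)) array(1, dim = phantom$shape) else b1$values
  lab_codes <- c(GM = 1L, WM = 2L, CSF = 3L)
  for (nm in names(lab_codes)) {
    sel <- phantom$labels == lab_codes[[nm]]
    if (!any(sel)) next
    tissue <- phantom$tissue_map[[nm]]
    b_here <- b1v[sel]
    rng <- range(b_here)
    if (diff(rng) < 1e-9) {
      img[sel] <- simulate_mprage(protocol, tissue, n_shots = n_shots,
                                  b1 = rng[1])$central
    } else {
      grid <- seq(rng[1], rng[2], length.out = 33)
      sig <- vapply(grid, function(b)
        simulate_mprage(protocol, tissue, n_shots = n_shots, b1 = b)$central,
        numeric(1))
      img[sel] <- stats::approx(grid, sig, xout = b_here)$y
    }
  }
  img
}

#' Simulate a multi-coil k-space acquisition of the phantom
#'
#' Builds the per-voxel signal image (EPG contrast with B1-scaled flip
#' angles), encodes it through the coil sensitivities onto the requested
#' sampling (full/CAIPI Cartesian, wave, or an arbitrary trajectory), and
#' adds complex circular Gaussian noise whose standard deviation is
#' `noise_sd` times the magnitude of the DC sample.
#'
#' @param phantom A [make_brain_phantom()] object.
#' @param protocol An [mprage_protocol()].
#' @param sampling A [caipi_pattern()], [wave_sampling()], or
#'   `k_trajectory`.
#' @param sens A [make_sensitivities()] object.
#' @param b1 A [make_b1_map()] object or `NULL`.
#' @param noise_sd Noise level relative to the DC k-space magnitude.
#' @param seed Integer seed for the noise realisation.
#' @param n_shots Shots per EPG simulation.
#' @return An object of class `kspace_data`: complex `data` matrix
#'   (samples x coils), the `sampling` object, grid `shape`, `voxel` (mm),
#'   and `truth` (the noiseless signal image).
#' @export
simulate_acquisition <- function(phantom, protocol, sampling, sens,
                                 b1 = NULL, noise_sd = 0, seed = 1L,
                                 n_shots = 6L) {
  stopifnot(inherits(phantom, "brain_phantom"),
            inherits(sens, "sensitivity_maps"))
  if (!identical(as.integer(sens$shape), phantom$shape))
    stop_invalid("sensitivity grid does not match the phantom grid")
  truth <- signal_image(phantom, protocol, b1 = b1, n_shots = n_shots)
  y <- encode(truth + 0i, sens, sampling, shape = phantom$shape,
              voxel = phantom$voxel)
  if (noise_sd > 0) {
    dc <- dc_magnitude(y, sampling, phantom$shape)
    sd_abs <- noise_sd * dc
    y$data <- y$data + with_seed(seed, {
      n <- length(y$data)
      (stats::rnorm(n, sd = sd_abs) + 1i * stats::rnorm(n, sd = sd_abs)) /
        sqrt(2)
    })
  }
  y$truth <- truth
  y
}
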