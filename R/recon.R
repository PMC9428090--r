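# ---- centered unitary FFT helpers -----------------------------------------

# Circular shift of an array along one dimension.
circshift_dim <- function(arr, dim, by) {
  n <- dim(arr)[dim]
  by <- ((by %% n) + n) %% n
  if (by == 0) return(arr)
  idx <- c((n - by + 1):n, 1:(n - by))
  eval_idx <- rep(list(quote(expr = )), length(dim(arr)))
  eval_idx[[dim]] <- idx
  do.call(`[`, c(list(arr), eval_idx, list(drop = FALSE)))
}

fftshift_dim <- function(arr, dim) circshift_dim(arr, dim, dim(arr)[dim] %/% 2)
ifftshift_dim <- function(arr, dim) {
  circshift_dim(arr, dim, -(dim(arr)[dim] %/% 2))
}

# Unitary FFT along one dimension of an n-d array.
fft_dim <- function(arr, dim, inverse = FALSE) {
  d <- dim(arr)
  perm <- c(dim, setdiff(seq_along(d), dim))
  a <- aperm(arr, perm)
  dm <- dim(a)
  dim(a) <- c(dm[1L], prod(dm[-1L]))
  a <- stats::mvfft(a, inverse = inverse)
  a <- a / sqrt(dm[1L])
  dim(a) <- dm
  aperm(a, order(perm))
}

# Centered unitary FFT along the given dimensions (DC at floor(n/2)+1).
cfft <- function(arr, dims = seq_along(dim(arr)), inverse = FALSE) {
  for (d in dims) {
    arr <- ifftshift_dim(arr, d)
    arr <- fft_dim(arr, d, inverse = inverse)
    arr <- fftshift_dim(arr, d)
  }
  arr
}

# ---- sampling descriptors --------------------------------------------------

#' Wave sampling: CAIPI phase-encode lattice plus per-kx kz modulation
#'
#' Describes the quiet readout's sampling: a Cartesian (possibly CAIPI
#' undersampled) phase-encode lattice in (ky, kz), with the silent
#' z-gradient sweeping kz by `kz_mod[kx]` (1/m) during each readout sample.
#' With `kz_mod = 0` this reduces to plain Cartesian/CAIPI sampling.
#'
#' @param pattern A [caipi_pattern()] over the (ky, kz) grid.
#' @param kz_mod Numeric vector, one kz offset (1/m) per kx sample, centred
#'   on zero; typically the `kz_mod` element of [make_quiet_readout()].
#' @return An object of class `wave_sampling`.
#' @export
wave_sampling <- function(pattern, kz_mod) {
  stopifnot(inherits(pattern, "caipi_pattern"))
  if (!all(is.finite(kz_mod))) stop_invalid("kz_mod must be finite")
  structure(list(pattern = pattern, kz_mod = as.numeric(kz_mod)),
            class = "wave_sampling")
}

# Number of k-space sample locations implied by a sampling descriptor.
sampling_n_points <- function(sampling, shape) {
  if (inherits(sampling, "caipi_pattern")) {
    shape[1L] * sum(sampling$mask)
  } else if (inherits(sampling, "wave_sampling")) {
    shape[1L] * sum(sampling$pattern$mask)
  } else if (inherits(sampling, "k_trajectory")) {
    length(sampling$time)
  } else stop_invalid("unsupported sampling descriptor")
}

# Peak k-space magnitude across coils, used to express relative noise.
dc_magnitude <- function(y, sampling, shape) max(Mod(y$data))

# ---- Cartesian / wave encoding --------------------------------------------

# Wave phase array P[kx, y, z] = exp(-2 pi i kz_mod[kx] z_m), constant in y.
wave_phase <- function(shape, voxel, kz_mod) {
  z_m <- centered_offsets(shape[3L]) * voxel * 1e-3
  P <- exp(-2i * pi * outer(kz_mod, z_m))            # (kx, z)
  aperm(array(P, dim = c(shape[1L], shape[3L], shape[2L])), c(1L, 3L, 2L))
}

cartesian_forward <- function(img, sens, mask, shape, Pw = NULL) {
  sel <- which(mask)                                  # over (ky, kz)
  n_samp <- shape[1L] * length(sel)
  out <- matrix(0i, n_samp, sens$n_coils)
  np <- prod(shape)
  for (c_ in seq_len(sens$n_coils)) {
    sc <- array(sens$maps[(1:np) + (c_ - 1L) * np], dim = shape)
    a <- cfft(sc * img, dims = 1L)
    if (!is.null(Pw)) a <- a * Pw
    a <- cfft(a, dims = c(2L, 3L))
    dim(a) <- c(shape[1L], shape[2L] * shape[3L])
    out[, c_] <- as.vector(a[, sel])
  }
  out
}

cartesian_adjoint <- function(data, sens, mask, shape, Pw = NULL) {
  sel <- which(mask)
  np <- prod(shape)
  img <- array(0i, dim = shape)
  for (c_ in seq_len(sens$n_coils)) {
    a <- matrix(0i, shape[1L], shape[2L] * shape[3L])
    a[, sel] <- data[, c_]
    dim(a) <- shape
    a <- cfft(a, dims = c(2L, 3L), inverse = TRUE)
    if (!is.null(Pw)) a <- a * Conj(Pw)
    a <- cfft(a, dims = 1L, inverse = TRUE)
    sc <- array(sens$maps[(1:np) + (c_ - 1L) * np], dim = shape)
    img <- img + Conj(sc) * a
  }
  img
}

# ---- gridding NUFFT for arbitrary trajectories ----------------------------

kb_beta <- function(width, os) pi * sqrt(width^2 / os^2 * (os - 0.5)^2 - 0.8)

kb_kernel <- function(u, width, beta) {
  t <- 1 - (2 * u / width)^2
  out <- numeric(length(u))
  ok <- t > 0
  out[ok] <- besselI(beta * sqrt(t[ok]), 0) / besselI(beta, 0)
  out
}

# Image-domain deapodisation weights along one (original-grid) dimension.
kb_deapod <- function(n, n_os, width, beta) {
  x <- centered_offsets(n) / n_os
  arg2 <- beta^2 - (pi * width * x)^2
  val <- ifelse(arg2 > 0,
                sinh(sqrt(pmax(arg2, 0))) / sqrt(pmax(arg2, 1e-300)),
                sin(sqrt(pmax(-arg2, 1e-300))) / sqrt(pmax(-arg2, 1e-300)))
  val / max(val)
}

# Build the sparse interpolation matrix G (n_samples x prod(shape_os)) for
# k-space points given in grid units of the oversampled grid (centred).
nufft_plan <- function(traj_nu, shape, voxel, os = 2, width = 4) {
  nd <- length(shape)
  shape_os <- as.integer(round(shape * os))
  fov <- shape * voxel * 1e-3                       # m
  # cycles across the original FOV per dimension
  nu <- mapply(function(k, f) k * f, traj_nu, fov, SIMPLIFY = FALSE)
  for (d in seq_len(nd))
    if (any(abs(nu[[d]]) > shape[d] / 2 + 1e-9))
      stop_invalid("trajectory exceeds the grid Nyquist extent on axis ", d)
  pos <- lapply(seq_len(nd), function(d)
    nu[[d]] * os + shape_os[d] %/% 2 + 1)           # 1-based fractional index
  n_pts <- length(pos[[1L]])
  half <- width / 2
  offs <- seq.int(-ceiling(half) + 1L, ceiling(half))
  beta <- kb_beta(width, os)
  grids <- expand.grid(rep(list(offs), nd))
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  base <- lapply(pos, floor)
  stride <- cumprod(c(1L, shape_os[-nd]))
  for (r in seq_len(nrow(grids))) {
    w <- rep(1, n_pts)
    lin <- rep(1L, n_pts)
    ok <- rep(TRUE, n_pts)
    for (d in seq_len(nd)) {
      idx <- base[[d]] + grids[r, d]
      w <- w * kb_kernel(idx - pos[[d]], width, beta)
      # wrap around the oversampled grid (periodic FFT convention)
      idxw <- ((idx - 1L) %% shape_os[d]) + 1L
      lin <- lin + (idxw - 1L) * stride[d]
      ok <- ok & abs(idx - pos[[d]]) <= half
    }
    keep <- ok & w > 0
    ii <- c(ii, which(keep)); jj <- c(jj, lin[keep]); vv <- c(vv, w[keep])
  }
  G <- Matrix::sparseMatrix(i = ii, j = jj, x = vv,
                            dims = c(n_pts, prod(shape_os)))
  deapod <- Reduce(function(a, d) {
    outer(a, kb_deapod(shape[d], shape_os[d], width, beta))
  }, seq_len(nd)[-1L], init = kb_deapod(shape[1L], shape_os[1L], width, beta))
  dim(deapod) <- shape
  list(G = G, shape = shape, shape_os = shape_os, deapod = deapod,
       os = os, width = width)
}

# Embed an array centred into the oversampled grid / crop back.
pad_center <- function(arr, shape_os) {
  shape <- dim(arr)
  out <- array(0i, dim = shape_os)
  idx <- lapply(seq_along(shape), function(d) {
    start <- shape_os[d] %/% 2 - shape[d] %/% 2
    start + seq_len(shape[d])
  })
  do.call(`[<-`, c(list(out), idx, list(value = arr)))
}

crop_center <- function(arr, shape) {
  shape_os <- dim(arr)
  idx <- lapply(seq_along(shape), function(d) {
    start <- shape_os[d] %/% 2 - shape[d] %/% 2
    start + seq_len(shape[d])
  })
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}

# The interpolation matrix is real; complex vectors are multiplied
# part-wise (the Matrix package does not handle complex vectors).
sp_mult <- function(G, v) {
  as.vector(G %*% Re(v)) + 1i * as.vector(G %*% Im(v))
}
sp_mult_t <- function(G, v) {
  as.vector(Matrix::crossprod(G, Re(v))) +
    1i * as.vector(Matrix::crossprod(G, Im(v)))
}

nufft_forward <- function(img, sens, plan) {
  np <- prod(plan$shape)
  out <- matrix(0i, nrow(plan$G), sens$n_coils)
  for (c_ in seq_len(sens$n_coils)) {
    sc <- array(sens$maps[(1:np) + (c_ - 1L) * np], dim = plan$shape)
    a <- pad_center((sc * img) / plan$deapod, plan$shape_os)
    a <- cfft(a)
    out[, c_] <- sp_mult(plan$G, as.vector(a))
  }
  out
}

nufft_adjoint <- function(data, sens, plan) {
  np <- prod(plan$shape)
  img <- array(0i, dim = plan$shape)
  for (c_ in seq_len(sens$n_coils)) {
    a <- sp_mult_t(plan$G, data[, c_])
    dim(a) <- plan$shape_os
    a <- cfft(a, inverse = TRUE)
    a <- crop_center(a, plan$shape) / plan$deapod
    sc <- array(sens$maps[(1:np) + (c_ - 1L) * np], dim = plan$shape)
    img <- img + Conj(sc) * a
  }
  img
}

# Convert a k_trajectory into per-dimension coordinate lists matching the
# grid dimensionality (unused trailing axes must be ~0).
traj_coords <- function(traj, nd) {
  co <- list(traj$kx, traj$ky, traj$kz)
  co[seq_len(nd)]
}

# ---- the public encoding operator -----------------------------------------

#' Forward SENSE encoding
#'
#' Samples the Fourier transform of `sens_c * image` at the locations of the
#' sampling descriptor, per coil: a centred unitary FFT with mask extraction
#' for Cartesian/CAIPI patterns, the hybrid-space wave operator for
#' [wave_sampling()], and a Kaiser-Bessel gridding NUFFT (oversampling 2,
#' kernel width 4) for arbitrary `k_trajectory` objects. The operator is
#' linear and its adjoint is exact (same interpolator transposed).
#'
#' @param image Complex (or numeric) array on the grid.
#' @param sens A [make_sensitivities()] object.
#' @param sampling A [caipi_pattern()], [wave_sampling()] or `k_trajectory`.
#' @param shape Grid dimensions; defaults to `dim(image)`.
#' @param voxel Voxel size, mm.
#' @return An object of class `kspace_data` with complex `data`
#'   (samples x coils), `sampling`, `shape`, `voxel`.
#' @export
encode <- function(image, sens, sampling, shape = dim(image), voxel = 3.5) {
  stopifnot(inherits(sens, "sensitivity_maps"))
  shape <- as.integer(shape)
  if (!identical(as.integer(dim(image)), shape))
    stop_invalid("image dimensions do not match the stated grid shape")
  if (!identical(as.integer(sens$shape), shape))
    stop_invalid("sensitivity dimensions do not match the grid shape")
  img <- image + 0i
  if (inherits(sampling, "caipi_pattern")) {
    check_pattern_shape(sampling, shape)
    data <- cartesian_forward(img, sens, sampling$mask, shape)
  } else if (inherits(sampling, "wave_sampling")) {
    check_pattern_shape(sampling$pattern, shape)
    if (length(sampling$kz_mod) != shape[1L])
      stop_invalid("kz_mod must have one entry per kx sample")
    Pw <- wave_phase(shape, voxel, sampling$kz_mod)
    data <- cartesian_forward(img, sens, sampling$pattern$mask, shape, Pw)
  } else if (inherits(sampling, "k_trajectory")) {
    plan <- nufft_plan(traj_coords(sampling, length(shape)), shape, voxel)
    data <- nufft_forward(img, sens, plan)
  } else stop_invalid("unsupported sampling descriptor")
  structure(list(data = data, sampling = sampling, shape = shape,
                 voxel = voxel),
            class = "kspace_data")
}

check_pattern_shape <- function(pattern, shape) {
  if (pattern$n_ky != shape[2L] || pattern$n_kz != shape[3L])
    stop_invalid("sampling pattern grid (", pattern$n_ky, "x", pattern$n_kz,
                 ") does not match the image phase-encode grid (",
                 shape[2L], "x", shape[3L], ")")
}

#' @export
print.kspace_data <- function(x, ...) {
  cat(sprintf("<k-space data> %d samples x %d coils on a %s grid\n",
              nrow(x$data), ncol(x$data), paste(x$shape, collapse = "x")))
  invisible(x)
}

# Adjoint of encode() for a kspace_data object.
encode_adjoint <- function(kdata, sens) {
  shape <- kdata$shape
  s <- kdata$sampling
  if (inherits(s, "caipi_pattern")) {
    cartesian_adjoint(kdata$data, sens, s$mask, shape)
  } else if (inherits(s, "wave_sampling")) {
    Pw <- wave_phase(shape, kdata$voxel, s$kz_mod)
    cartesian_adjoint(kdata$data, sens, s$pattern$mask, shape, Pw)
  } else if (inherits(s, "k_trajectory")) {
    plan <- nufft_plan(traj_coords(s, length(shape)), shape, kdata$voxel)
    nufft_adjoint(kdata$data, sens, plan)
  } else stop_invalid("unsupported sampling descriptor")
}

#' Single-pass adjoint (zero-filled) reconstruction
#'
#' @param kdata A `kspace_data` object.
#' @param sens A [make_sensitivities()] object.
#' @return Complex image array.
#' @export
adjoint_recon <- function(kdata, sens) encode_adjoint(kdata, sens)

# ---- CG-SENSE --------------------------------------------------------------

#' Iterative (conjugate-gradient) SENSE reconstruction
#'
#' Solves the encoding normal equations `(A* A + lambda I) x = A* y` by
#' conjugate gradients, where `A` is the forward operator of [encode()] for
#' the acquisition's sampling. Unregularised by default; the data residual
#' `||A x_k - y|| / ||y||` is recorded each iteration and is monotonically
#' non-increasing.
#'
#' @param kdata A `kspace_data` object (from [simulate_acquisition()] or
#'   [encode()]).
#' @param sens The [make_sensitivities()] used for the acquisition.
#' @param n_iter Maximum CG iterations.
#' @param tol Relative data-residual stopping tolerance.
#' @param lambda Optional Tikhonov regularisation weight.
#' @return A list with `image` (complex array), `residuals` (relative data
#'   residual per iteration), `iterations`, and `converged`.
#' @export
cg_sense <- function(kdata, sens, n_iter = 30L, tol = 1e-6, lambda = 0) {
  stopifnot(inherits(kdata, "kspace_data"),
            inherits(sens, "sensitivity_maps"))
  n_iter <- as.integer(n_iter)
  if (n_iter < 1L) stop_invalid("n_iter must be >= 1")
  shape <- kdata$shape
  s <- kdata$sampling
  plan <- NULL; Pw <- NULL; mask <- NULL
  if (inherits(s, "caipi_pattern")) {
    mask <- s$mask
  } else if (inherits(s, "wave_sampling")) {
    mask <- s$pattern$mask
    Pw <- wave_phase(shape, kdata$voxel, s$kz_mod)
  } else if (inherits(s, "k_trajectory")) {
    plan <- nufft_plan(traj_coords(s, length(shape)), shape, kdata$voxel)
  } else stop_invalid("unsupported sampling descriptor")
  fwd <- function(x) {
    if (is.null(plan)) cartesian_forward(x, sens, mask, shape, Pw)
    else nufft_forward(x, sens, plan)
  }
  adj <- function(d) {
    if (is.null(plan)) cartesian_adjoint(d, sens, mask, shape, Pw)
    else nufft_adjoint(d, sens, plan)
  }
  y <- kdata$data
  y_norm <- sqrt(sum(Mod(y)^2))
  if (y_norm == 0) {
    return(list(image = array(0i, dim = shape), residuals = numeric(0),
                iterations = 0L, converged = TRUE))
  }
  normal <- function(x) {
    out <- adj(fwd(x))
    if (lambda > 0) out <- out + lambda * x
    out
  }
  cdot <- function(a, b) sum(Conj(a) * b)
  x <- array(0i, dim = shape)
  b <- adj(y)
  r <- b
  p <- r
  rs0 <- Re(cdot(r, r))
  rs_old <- rs0
  residuals <- numeric(0)
  converged <- rs0 == 0
  iterations <- 0L
  while (!converged && iterations < n_iter) {
    Ap <- normal(p)
    den <- Re(cdot(p, Ap))
    if (den <= 0) { converged <- TRUE; break }  # p in the null space: done
    alpha <- rs_old / den
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- Re(cdot(r, r))
    residuals <- c(residuals, sqrt(sum(Mod(fwd(x) - y)^2)) / y_norm)
    iterations <- iterations + 1L
    # stop on the relative normal-equation residual: the data residual
    # bottoms out at the noise floor and is not a usable criterion
    if (sqrt(rs_new / rs0) < tol) { converged <- TRUE; break }
    p <- r + (rs_new / rs_old) * p
    rs_old <- rs_new
  }
  if (!converged)
    warning("cg_sense: tolerance not reached in ", n_iter, " iterations",
            call. = FALSE)
  list(image = x, residuals = residuals, iterations = iterations,
       converged = converged)
}

# ---- measured-trajectory input --------------------------------------------

#' Load a measured (field-camera style) k-space trajectory
#'
#' Reads the plain-text trajectory dialect written by [write_trajectory()]:
#' comment headers including `# raster_us=...`, then columns
#' `t_ms kx ky kz` (1/m). Trajectories read this way are used
#' interchangeably with computed ones.
#'
#' @param path File path.
#' @return A `k_trajectory`.
#' @export
load_measured_trajectory <- function(path) {
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  hdr <- lines[hdr_idx]
  raster_line <- grep("raster_us=", hdr, value = TRUE)
  if (!length(raster_line))
    stop_invalid("trajectory file lacks a '# raster_us=' header (line 1)")
  raster <- suppressWarnings(
    as.numeric(sub(".*raster_us=([0-9.eE+-]+).*", "\\1", raster_line[1L])))
  if (!is.finite(raster) || raster <= 0)
    stop_invalid("invalid raster_us header value")
  body_idx <- setdiff(which(nzchar(lines)), hdr_idx)
  if (!length(body_idx)) stop_invalid("trajectory file has no data rows")
  rows <- strsplit(trimws(lines[body_idx]), "[[:space:]]+")
  bad <- which(lengths(rows) != 4L)
  if (length(bad))
    stop_invalid("malformed trajectory row at line ", body_idx[bad[1L]],
                 ": expected 4 columns (t_ms kx ky kz)")
  m <- matrix(suppressWarnings(as.numeric(unlist(rows))), ncol = 4L,
              byrow = TRUE)
  nonnum <- which(rowSums(!is.finite(m)) > 0)
  if (length(nonnum))
    stop_invalid("non-numeric trajectory value at line ", body_idx[nonnum[1L]])
  if (any(diff(m[, 1L]) <= 0)) {
    first <- which(diff(m[, 1L]) <= 0)[1L] + 1L
    stop_invalid("non-monotone time at line ", body_idx[first])
  }
  structure(list(time = m[, 1L], kx = m[, 2L], ky = m[, 3L], kz = m[, 4L],
                 raster = raster),
            class = "k_trajectory")
}

#' Export a volume as NIfTI
#'
#' Thin wrapper writing a (magnitude) image array with its voxel size into a
#' NIfTI-1 file.
#'
#' @param volume Numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel Isotropic voxel size, mm.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(volume, path, voxel = 3.5) {
  img <- RNifti::asNifti(volume, pixdim = rep(voxel, length(dim(volume))))
  RNifti::writeNifti(img, path)
  invisible(path)
}
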