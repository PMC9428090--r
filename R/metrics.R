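#' Tissue signal samples for SNR/CNR computation
#'
#' Collects the grey-matter and white-matter signal magnitudes of an image
#' (the "foreground" for SNR is their union), either from explicit vectors
#' or from an image plus a ground-truth label array.
#'
#' @param gm,wm Numeric vectors of per-voxel signal magnitudes.
#' @return An object of class `tissue_samples`.
#' @export
tissue_samples <- function(gm, wm) {
  gm <- as.numeric(gm); wm <- as.numeric(wm)
  if (!all(is.finite(gm)) || !all(is.finite(wm)))
    stop_invalid("tissue samples must be finite")
  structure(list(gm = gm, wm = wm, foreground = c(gm, wm)),
            class = "tissue_samples")
}

#' @rdname tissue_samples
#' @param image Numeric array of signal magnitudes.
#' @param labels Integer label array of the same shape (1 = GM, 2 = WM, as
#'   produced by [make_brain_phantom()]).
#' @export
tissue_samples_from_labels <- function(image, labels) {
  if (!identical(dim(image), dim(labels)))
    stop_invalid("image and labels must have identical dimensions")
  tissue_samples(gm = image[labels == 1L], wm = image[labels == 2L])
}

#' Signal-to-noise ratio of the foreground tissue
#'
#' `SNR = (mu / sigma) * sqrt(n / (n - 1))` over the grey+white foreground,
#' with `sigma` the sample (n-1 denominator) standard deviation.
#'
#' @param samples A [tissue_samples()] object.
#' @return Dimensionless SNR.
#' @examples
#' snr(tissue_samples(gm = 1, wm = 3))  # exactly 2
#' @export
snr <- function(samples) {
  stopifnot(inherits(samples, "tissue_samples"))
  x <- samples$foreground
  n <- length(x)
  if (n < 2L) stop_invalid("SNR needs at least two foreground voxels")
  s <- stats::sd(x)
  if (s == 0) stop_invalid("degenerate input: zero foreground variance")
  mean(x) / s * sqrt(n / (n - 1))
}

#' Grey-white matter contrast-to-noise ratio
#'
#' `CNR = |mu_wm - mu_gm| / sqrt(sigma_wm^2 + sigma_gm^2)` with sample
#' standard deviations.
#'
#' @param samples A [tissue_samples()] object.
#' @return Dimensionless CNR.
#' @examples
#' cnr(tissue_samples(gm = c(0, 2), wm = c(2, 4)))  # 2 / 2 = 1
#' @export
cnr <- function(samples) {
  stopifnot(inherits(samples, "tissue_samples"))
  if (!length(samples$gm) || !length(samples$wm))
    stop_invalid("both tissue classes must be non-empty")
  s_gm <- if (length(samples$gm) > 1L) stats::sd(samples$gm) else 0
  s_wm <- if (length(samples$wm) > 1L) stats::sd(samples$wm) else 0
  denom <- sqrt(s_wm^2 + s_gm^2)
  if (denom == 0) stop_invalid("degenerate input: both class variances zero")
  abs(mean(samples$wm) - mean(samples$gm)) / denom
}

#' Per-class normalised signal histograms
#'
#' Histograms of the grey- and white-matter signal magnitudes on shared bin
#' edges, each normalised to unit mass, plus their overlap coefficient (the
#' shared area under the two densities).
#'
#' @param samples A [tissue_samples()] object.
#' @param bins Number of bins, >= 2.
#' @return A list with `breaks`, `mids`, `gm`, `wm` (per-class bin masses
#'   summing to one) and `overlap` in `[0, 1]`.
#' @export
signal_histogram <- function(samples, bins = 50L) {
  stopifnot(inherits(samples, "tissue_samples"))
  bins <- as.integer(bins)
  if (bins < 2L) stop_invalid("bins must be >= 2")
  all_v <- samples$foreground
  if (!length(all_v)) {
    warning("empty tissue classes: empty histogram", call. = FALSE)
    return(list(breaks = numeric(0), mids = numeric(0),
                gm = numeric(0), wm = numeric(0), overlap = NA_real_))
  }
  rng <- range(all_v)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  count <- function(v) {
    if (!length(v)) {
      warning("empty tissue class in histogram", call. = FALSE)
      return(numeric(bins))
    }
    h <- graphics::hist(v, breaks = breaks, plot = FALSE)
    h$counts / length(v)
  }
  gm_d <- count(samples$gm)
  wm_d <- count(samples$wm)
  list(breaks = breaks, mids = (breaks[-1L] + breaks[-(bins + 1L)]) / 2,
       gm = gm_d, wm = wm_d, overlap = sum(pmin(gm_d, wm_d)))
}

#' Full image-quality report for one reconstructed volume
#'
#' @param image Numeric (magnitude) array.
#' @param labels Ground-truth label array (from the phantom).
#' @param bins Histogram bins.
#' @return A list with `snr`, `cnr`, `histogram`, and the per-class means
#'   and standard deviations.
#' @export
image_metrics <- function(image, labels, bins = 50L) {
  ts <- tissue_samples_from_labels(image, labels)
  list(snr = snr(ts), cnr = cnr(ts), histogram = signal_histogram(ts, bins),
       gm_mean = mean(ts$gm), gm_sd = stats::sd(ts$gm),
       wm_mean = mean(ts$wm), wm_sd = stats::sd(ts$wm),
       n_foreground = length(ts$foreground))
}
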