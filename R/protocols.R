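#' Tissue relaxation parameters
#'
#' Bundles the longitudinal (T1) and transverse (T2) relaxation times and the
#' proton density of one tissue class, as used by the EPG simulator and the
#' digital phantom.
#'
#' @param name Tissue label, one of `"GM"`, `"WM"`, `"CSF"` (other labels are
#'   allowed for ad-hoc tissues).
#' @param t1 Longitudinal relaxation time, ms. Must be positive.
#' @param t2 Effective transverse relaxation time governing echo decay, ms.
#'   Must be positive and not exceed `t1`. For the spoiled gradient echoes
#'   of an MPRAGE readout the operative constant is T2* (susceptibility
#'   included), which at 7 T is much shorter than spin-echo T2.
#' @param pd Proton density, arbitrary units, non-negative.
#' @return An object of class `tissue_params`.
#' @examples
#' tissue_params("WM", t1 = 1200, t2 = 46, pd = 0.7)
#' @export
tissue_params <- function(name, t1, t2, pd = 1) {
  check_scalar(t1, "t1"); check_scalar(t2, "t2"); check_scalar(pd, "pd")
  if (t1 <= 0 || t2 <= 0) stop_invalid("t1 and t2 must be positive")
  if (t2 > t1) stop_invalid("t2 must not exceed t1")
  if (pd < 0) stop_invalid("pd must be non-negative")
  structure(list(name = as.character(name), t1 = t1, t2 = t2, pd = pd),
            class = "tissue_params")
}

#' @export
print.tissue_params <- function(x, ...) {
  cat(sprintf("<tissue %s> T1 = %g ms, T2 = %g ms, PD = %g\n",
              x$name, x$t1, x$t2, x$pd))
  invisible(x)
}

#' Default brain tissue parameters at 7 T
#'
#' Literature-typical 7 T values for grey matter, white matter and CSF:
#' T1 2000/1200/4300 ms. The transverse constants are T2* values
#' (GM 33 ms, WM 27 ms), not spin-echo T2: the MPRAGE readout is a spoiled
#' gradient echo, so its echo amplitude decays with T2*, and at 7 T the
#' difference is large enough to change which flip angle matches the
#' grey-white contrast between a short-TE and a long-TE variant. These are
#' the defaults used by flip-angle matching and the phantom; every value can
#' be overridden by constructing [tissue_params()] directly.
#'
#' @param which Optional character vector selecting a subset of
#'   `c("GM", "WM", "CSF")`.
#' @return A named list of [tissue_params()] objects.
#' @export
default_tissues <- function(which = c("GM", "WM", "CSF")) {
  all <- list(
    GM  = tissue_params("GM",  t1 = 2000, t2 = 33,   pd = 0.8),
    WM  = tissue_params("WM",  t1 = 1200, t2 = 27,   pd = 0.7),
    CSF = tissue_params("CSF", t1 = 4300, t2 = 1000, pd = 1.0)
  )
  missing <- setdiff(which, names(all))
  if (length(missing)) stop_invalid("unknown tissue(s): ",
                                    paste(missing, collapse = ", "))
  all[which]
}

#' MPRAGE protocol parameters
#'
#' Timing and contrast parameters of one inversion-prepared rapid
#' gradient-echo variant. One "shot" is: inversion pulse, inversion delay
#' `ti`, a train of `n_echoes_per_shot` spoiled gradient echoes spaced `tr`
#' apart (each read out `te` after its excitation), then free recovery until
#' the next inversion `shot_interval` after the previous one.
#'
#' @param te Echo time, ms.
#' @param tr Repetition time between excitations in the train, ms.
#' @param ti Inversion time, ms. By the scanner convention
#'   (`ti_convention = "train_centre"`, the default) this is the time from
#'   the inversion pulse to the *central* echo of the train — the echo that
#'   acquires the k-space centre under linear ordering and therefore sets
#'   the image contrast (and the CSF null). With
#'   `ti_convention = "first_excitation"` it is the delay to the first
#'   excitation instead.
#' @param shot_interval Time between successive inversions, ms.
#' @param flip Excitation flip angle, degrees, in (0, 90].
#' @param inv_efficiency Inversion efficiency in `[-1, 1]`. The inversion
#'   pulse multiplies all longitudinal states by this factor: -1 is a perfect
#'   inversion, values in (-1, 0] model imperfect/absent preparation
#'   (0 saturates; use `NA` to skip the pulse entirely, i.e. run the train
#'   without magnetisation preparation).
#' @param n_echoes_per_shot Number of echoes per shot, integer >= 1.
#' @param name Optional label (e.g. `"quiet"`, `"conventional"`).
#' @return An object of class `mprage_protocol`.
#' @examples
#' quiet_protocol()
#' conventional_protocol()
#' @export
mprage_protocol <- function(te, tr, ti, shot_interval, flip,
                            inv_efficiency = -1, n_echoes_per_shot = 1L,
                            ti_convention = c("train_centre",
                                              "first_excitation"),
                            name = "protocol") {
  ti_convention <- match.arg(ti_convention)
  for (v in c("te", "tr", "ti", "shot_interval", "flip"))
    check_scalar(get(v), v)
  n_echoes_per_shot <- as.integer(n_echoes_per_shot)
  if (!(te > 0 && te < tr)) stop_invalid("need 0 < te < tr")
  if (!(ti > 0 && ti < shot_interval)) stop_invalid("need 0 < ti < shot_interval")
  if (!(flip > 0 && flip <= 90)) stop_invalid("need 0 < flip <= 90 degrees")
  if (n_echoes_per_shot < 1L) stop_invalid("n_echoes_per_shot must be >= 1")
  if (!is.na(inv_efficiency) && abs(inv_efficiency) > 1)
    stop_invalid("inv_efficiency must lie in [-1, 1] (or NA for no pulse)")
  p <- structure(list(te = te, tr = tr, ti = ti,
                      shot_interval = shot_interval,
                      flip = flip, inv_efficiency = inv_efficiency,
                      n_echoes_per_shot = n_echoes_per_shot,
                      ti_convention = ti_convention, name = name),
                 class = "mprage_protocol")
  if (ti_first_excitation(p) <= 0)
    stop_invalid("ti is too short: the train centre precedes the first ",
                 "excitation (ti - tr * floor(n/2) must be positive)")
  if (ti_first_excitation(p) + tr * n_echoes_per_shot > shot_interval)
    stop_invalid("echo train does not fit inside the shot interval")
  p
}

#' @rdname mprage_protocol
#' @details `ti_first_excitation()` returns the delay (ms) from the
#'   inversion pulse to the first excitation implied by the protocol's TI
#'   convention.
#' @param protocol An `mprage_protocol`.
#' @export
ti_first_excitation <- function(protocol) {
  if (protocol$ti_convention == "first_excitation") return(protocol$ti)
  centre <- protocol$n_echoes_per_shot %/% 2L    # 0-based central echo index
  protocol$ti - protocol$tr * centre
}

#' @export
print.mprage_protocol <- function(x, ...) {
  cat(sprintf(paste0("<mprage protocol '%s'>\n",
                     "  TE %g ms | TR %g ms | TI %g ms | shot %g ms\n",
                     "  flip %g deg | inv. efficiency %s | %d echoes/shot\n"),
              x$name, x$te, x$tr, x$ti, x$shot_interval, x$flip,
              ifelse(is.na(x$inv_efficiency), "none", x$inv_efficiency),
              x$n_echoes_per_shot))
  invisible(x)
}

#' Built-in quiet and conventional protocol variants
#'
#' The two protocol variants compared throughout the package: the quiet
#' sequence (TE 8.9 ms, TR 17.6 ms, flip 13 deg) and the conventional
#' sequence (TE 1.9 ms, TR 4.2 ms, flip 7 deg), both with a 3,000 ms shot
#' interval and 1,000 ms inversion time. The echo train lengths default to
#' the longest trains that fit the shot interval at full-scale matrix sizes
#' (107 and 307 echoes respectively) and are freely overridable.
#'
#' @param ... Overrides passed to [mprage_protocol()] (e.g. `flip`,
#'   `n_echoes_per_shot`).
#' @return An `mprage_protocol`.
#' @export
quiet_protocol <- function(...) {
  args <- utils::modifyList(
    list(te = 8.9, tr = 17.6, ti = 1000, shot_interval = 3000, flip = 13,
         inv_efficiency = -1, n_echoes_per_shot = 107L, name = "quiet"),
    list(...))
  do.call(mprage_protocol, args)
}

#' @rdname quiet_protocol
#' @export
conventional_protocol <- function(...) {
  args <- utils::modifyList(
    list(te = 1.9, tr = 4.2, ti = 1000, shot_interval = 3000, flip = 7,
         inv_efficiency = -1, n_echoes_per_shot = 307L,
         name = "conventional"),
    list(...))
  do.call(mprage_protocol, args)
}

#' Read or write a protocol as a YAML key/value file
#'
#' The file mirrors the protocol-table field names: `te_ms`, `tr_ms`,
#' `ti_ms`, `shot_interval_ms`, `flip_deg`, `inv_efficiency`,
#' `n_echoes_per_shot`, `name`.
#'
#' @param path File path.
#' @param protocol An `mprage_protocol`.
#' @return `read_protocol()` returns an `mprage_protocol`;
#'   `write_protocol()` returns `path` invisibly.
#' @export
read_protocol <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("te_ms", "tr_ms", "ti_ms", "shot_interval_ms", "flip_deg")
  miss <- setdiff(need, names(y))
  if (length(miss)) stop_invalid("protocol file missing field(s): ",
                                 paste(miss, collapse = ", "))
  mprage_protocol(te = y$te_ms, tr = y$tr_ms, ti = y$ti_ms,
                  shot_interval = y$shot_interval_ms, flip = y$flip_deg,
                  inv_efficiency = if (is.null(y$inv_efficiency)) -1
                                   else y$inv_efficiency,
                  n_echoes_per_shot = if (is.null(y$n_echoes_per_shot)) 1L
                                      else y$n_echoes_per_shot,
                  ti_convention = if (is.null(y$ti_convention))
                                    "train_centre" else y$ti_convention,
                  name = if (is.null(y$name)) "protocol" else y$name)
}

#' @rdname read_protocol
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "mprage_protocol"))
  yaml::write_yaml(list(
    name = protocol$name, te_ms = protocol$te, tr_ms = protocol$tr,
    ti_ms = protocol$ti, shot_interval_ms = protocol$shot_interval,
    flip_deg = protocol$flip, inv_efficiency = protocol$inv_efficiency,
    n_echoes_per_shot = protocol$n_echoes_per_shot,
    ti_convention = protocol$ti_convention), path)
  invisible(path)
}
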