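#' Experiment configuration for the quiet-vs-conventional comparison
#'
#' Collects every knob of the end-to-end experiment with documented
#' defaults: the desk-scale grid, the two protocol variants, silent-coil
#' and whole-body gradient specifications, phantom/noise/coil settings and
#' explicit seeds.
#'
#' @param shape Grid dimensions.
#' @param voxel Voxel size, mm.
#' @param quiet,conventional The two [mprage_protocol()] variants.
#' @param silent_spec [silent_gradient_spec()] for the quiet readout.
#' @param quiet_limits,conventional_limits [whole_body_limits()] per mode.
#' @param n_coils Receive channels.
#' @param noise_sd Relative k-space noise (fraction of the DC magnitude).
#' @param b1_inhomogeneity Transmit field variation in `[0, 1]`.
#' @param b1_temporal_dip Include the left-temporal transmit dip?
#' @param conventional_accel `c(Ry, Rz, shift)` CAIPI factors for the
#'   conventional acquisition (the quiet acquisition is fully sampled, its
#'   extra encoding coming from the silent gradient).
#' @param n_iter CG iterations.
#' @param flat_ms Quiet readout flat-top duration, ms.
#' @param acoustic_model A [transfer_model()].
#' @param acoustic_repeats TR blocks tiled for sound prediction.
#' @param seeds Named integer seeds (`phantom`, `sens`, `b1`, `noise`).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(shape = c(64, 64, 32), voxel = 3.5,
                              quiet = quiet_protocol(),
                              conventional = conventional_protocol(),
                              silent_spec = silent_gradient_spec(),
                              quiet_limits = whole_body_limits("quiet"),
                              conventional_limits =
                                whole_body_limits("conventional"),
                              n_coils = 8L, noise_sd = 2e-4,
                              b1_inhomogeneity = 0.3,
                              b1_temporal_dip = TRUE,
                              conventional_accel = c(2L, 1L, 0L),
                              n_iter = 15L, flat_ms = NULL,
                              acoustic_model = transfer_model(),
                              acoustic_repeats = 25L,
                              seeds = list(phantom = 101L, sens = 202L,
                                           b1 = 303L, noise = 404L)) {
  cfg <- structure(list(shape = as.integer(shape), voxel = voxel,
                        quiet = quiet, conventional = conventional,
                        silent_spec = silent_spec,
                        quiet_limits = quiet_limits,
                        conventional_limits = conventional_limits,
                        n_coils = as.integer(n_coils), noise_sd = noise_sd,
                        b1_inhomogeneity = b1_inhomogeneity,
                        b1_temporal_dip = b1_temporal_dip,
                        conventional_accel = as.integer(conventional_accel),
                        n_iter = as.integer(n_iter), flat_ms = flat_ms,
                        acoustic_model = acoustic_model,
                        acoustic_repeats = as.integer(acoustic_repeats),
                        seeds = lapply(seeds, as.integer)),
                   class = "experiment_config")
  stopifnot(inherits(quiet, "mprage_protocol"),
            inherits(conventional, "mprage_protocol"),
            inherits(silent_spec, "silent_gradient_spec"))
  if (!all(c("phantom", "sens", "b1", "noise") %in% names(cfg$seeds)))
    stop_invalid("seeds must name phantom, sens, b1 and noise")
  cfg
}

run_stage <- function(report, name, expr, verbose) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(list(ok = TRUE, value = force(expr)),
                  error = function(e) list(ok = FALSE, error = conditionMessage(e)))
  dt <- proc.time()[["elapsed"]] - t0
  report$stages[[name]] <- list(ok = res$ok, seconds = round(dt, 3),
                                error = if (!res$ok) res$error)
  if (verbose)
    message(sprintf("[%s] %s (%.1f s)", name,
                    if (res$ok) "ok" else paste("FAILED:", res$error), dt))
  report$last_ok <- res$ok
  report$last_value <- if (res$ok) res$value
  report
}

#' Run the full quiet-vs-conventional comparison experiment
#'
#' Executes the whole pipeline for both protocol variants: readout waveform
#' construction and acoustic prediction, phantom/sensitivity/B1 generation,
#' k-space simulation, CG-SENSE reconstruction, and image metrics; then
#' assembles a structured report of per-protocol results and differences.
#' Deterministic for fixed seeds; any stage failure is recorded in the
#' report while upstream results are preserved.
#'
#' @param config An [experiment_config()].
#' @param verbose Print stage progress?
#' @return A list of class `comparison_report`.
#' @export
run_comparison <- function(config = experiment_config(), verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  report <- list(config_hash = config_hash(
                   config[setdiff(names(config), "acoustic_model")]),
                 seeds = config$seeds,
                 package_version = as.character(utils::packageVersion("quietmr")),
                 stages = list(), protocols = list(), acoustics = list(),
                 metrics = list(), differences = list())
  shape <- config$shape

  # --- waveforms + acoustics ---------------------------------------------
  fov_x <- shape[1L] * config$voxel * 1e-3
  report <- run_stage(report, "waveforms_quiet", {
    make_quiet_readout(shape[1L], fov_x, config$quiet_limits,
                       config$silent_spec, flat_ms = config$flat_ms)
  }, verbose)
  ro_quiet <- report$last_value
  report <- run_stage(report, "waveforms_conventional", {
    make_quiet_readout(shape[1L], fov_x, config$conventional_limits,
                       spec = NULL, flat_ms = 1.0)
  }, verbose)
  ro_conv <- report$last_value
  for (nm in c("quiet", "conventional")) {
    ro <- if (nm == "quiet") ro_quiet else ro_conv
    proto <- config[[nm]]
    if (is.null(ro)) next
    report <- run_stage(report, paste0("acoustics_", nm), {
      # tile the readout over its TR before filtering
      n_tr <- round(proto$tr * 1000 / ro$raster)
      wfs <- Filter(Negate(is.null), list(ro$gx, ro$gz))
      wfs <- lapply(wfs, function(w) {
        gradient_waveform(c(w$samples,
                            numeric(max(0L, n_tr - length(w$samples)))),
                          w$raster, w$axis)
      })
      p <- predict_pressure(wfs, config$acoustic_model,
                            repeats = config$acoustic_repeats)
      m <- spl_meter(p, "fast")
      list(peak_dba = m$peak, duration_s = length(p$samples) / p$fs)
    }, verbose)
    if (report$last_ok) report$acoustics[[nm]] <- report$last_value
  }

  # --- phantom + maps ------------------------------------------------------
  report <- run_stage(report, "phantom", {
    make_brain_phantom(shape, config$voxel, seed = config$seeds$phantom)
  }, verbose)
  phantom <- report$last_value
  report <- run_stage(report, "sensitivities", {
    make_sensitivities(shape, config$n_coils, seed = config$seeds$sens)
  }, verbose)
  sens <- report$last_value
  report <- run_stage(report, "b1_map", {
    make_b1_map(shape, config$b1_inhomogeneity, config$b1_temporal_dip,
                seed = config$seeds$b1)
  }, verbose)
  b1 <- report$last_value

  # --- acquisition + reconstruction per protocol ---------------------------
  if (!is.null(phantom) && !is.null(sens)) {
    for (nm in c("quiet", "conventional")) {
      proto <- config[[nm]]
      sampling <- if (nm == "quiet" && !is.null(ro_quiet)) {
        wave_sampling(caipi_pattern(shape[2L], shape[3L]), ro_quiet$kz_mod)
      } else {
        acc <- config$conventional_accel
        if (nm == "quiet") caipi_pattern(shape[2L], shape[3L])
        else caipi_pattern(shape[2L], shape[3L], acc[1L], acc[2L], acc[3L])
      }
      report <- run_stage(report, paste0("acquire_", nm), {
        simulate_acquisition(phantom, proto, sampling, sens, b1 = b1,
                             noise_sd = config$noise_sd,
                             seed = config$seeds$noise)
      }, verbose)
      kdata <- if (report$last_ok) report$last_value
      report <- run_stage(report, paste0("recon_", nm), {
        if (is.null(kdata)) stop("no k-space data")
        rec <- cg_sense(kdata, sens, n_iter = config$n_iter)
        list(image = Mod(rec$image), residuals = rec$residuals,
             truth = kdata$truth)
      }, verbose)
      if (report$last_ok) {
        rec <- report$last_value
        met <- image_metrics(rec$image, phantom$labels)
        met$nrmse_vs_truth <- nrmse(rec$image, rec$truth)
        report$metrics[[nm]] <- met
        report$protocols[[nm]] <- list(
          te = proto$te, tr = proto$tr, ti = proto$ti,
          shot_interval = proto$shot_interval, flip = proto$flip,
          n_echoes_per_shot = proto$n_echoes_per_shot)
      }
    }
  }

  # --- differences ---------------------------------------------------------
  m <- report$metrics
  if (!is.null(m$quiet) && !is.null(m$conventional)) {
    report$differences <- list(
      snr_quiet_minus_conventional = m$quiet$snr - m$conventional$snr,
      cnr_quiet_minus_conventional = m$quiet$cnr - m$conventional$cnr,
      overlap_quiet_minus_conventional =
        m$quiet$histogram$overlap - m$conventional$histogram$overlap)
  }
  a <- report$acoustics
  if (!is.null(a$quiet) && !is.null(a$conventional)) {
    report$differences$peak_dba_quiet_minus_conventional <-
      a$quiet$peak_dba - a$conventional$peak_dba
  }
  report$last_value <- NULL
  report$last_ok <- NULL
  class(report) <- "comparison_report"
  report
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison report>\n")
  for (nm in names(x$metrics))
    cat(sprintf("  %-13s SNR %6.2f  CNR %5.2f  overlap %.3f\n", nm,
                x$metrics[[nm]]$snr, x$metrics[[nm]]$cnr,
                x$metrics[[nm]]$histogram$overlap))
  for (nm in names(x$acoustics))
    cat(sprintf("  %-13s predicted peak %6.1f dB(A)\n", nm,
                x$acoustics[[nm]]$peak_dba))
  invisible(x)
}

# Strip non-serialisable members (images) for the JSON report.
report_for_json <- function(report) {
  out <- unclass(report)
  for (nm in names(out$metrics)) {
    h <- out$metrics[[nm]]$histogram
    out$metrics[[nm]]$histogram <-
      list(overlap = h$overlap, bins = length(h$mids))
  }
  out
}

#' Write a comparison report to disk
#'
#' Produces a machine-readable JSON file and/or a human-readable markdown
#' summary (with the protocol parameter table, metrics, acoustic
#' predictions and provenance: seeds, config hash, package version).
#'
#' @param report A `comparison_report`.
#' @param dir Output directory (created if needed).
#' @param format `"json"`, `"markdown"` or both.
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(report, dir, format = c("json", "markdown")) {
  stopifnot(inherits(report, "comparison_report"))
  format <- match.arg(format, several.ok = TRUE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0)
  if ("json" %in% format) {
    path <- file.path(dir, "report.json")
    jsonlite::write_json(report_for_json(report), path, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
    written <- c(written, path)
  }
  if ("markdown" %in% format) {
    path <- file.path(dir, "report.md")
    lines <- c("# Quiet vs conventional MPRAGE comparison", "",
               sprintf("- config hash: `%s`", report$config_hash),
               sprintf("- package version: %s", report$package_version),
               sprintf("- seeds: %s",
                       paste(names(report$seeds), unlist(report$seeds),
                             sep = "=", collapse = ", ")), "")
    if (length(report$protocols)) {
      nms <- names(report$protocols)
      lines <- c(lines, "## Protocols", "",
                 paste0("| parameter | ", paste(nms, collapse = " | "),
                        " |"),
                 paste0("|---", strrep("|---", length(nms)), "|"))
      for (f in c("te", "tr", "ti", "shot_interval", "flip",
                  "n_echoes_per_shot")) {
        vals <- vapply(nms, function(nm)
          format(report$protocols[[nm]][[f]]), character(1))
        lines <- c(lines, paste0("| ", f, " | ",
                                 paste(vals, collapse = " | "), " |"))
      }
      lines <- c(lines, "")
    }
    if (length(report$metrics)) {
      nms <- names(report$metrics)
      fm <- function(v) sprintf("%.4g", v)
      lines <- c(lines, "## Image metrics", "",
                 paste0("| metric | ", paste(nms, collapse = " | "), " |"),
                 paste0("|---", strrep("|---", length(nms)), "|"))
      for (f in c("snr", "cnr")) {
        vals <- vapply(nms, function(nm) fm(report$metrics[[nm]][[f]]),
                       character(1))
        lines <- c(lines, paste0("| ", toupper(f), " | ",
                                 paste(vals, collapse = " | "), " |"))
      }
      ov <- vapply(nms, function(nm)
        fm(report$metrics[[nm]]$histogram$overlap), character(1))
      lines <- c(lines, paste0("| histogram overlap | ",
                               paste(ov, collapse = " | "), " |"), "")
    }
    if (length(report$acoustics)) {
      lines <- c(lines, "## Predicted sound level", "",
                 vapply(names(report$acoustics), function(nm)
                   sprintf("- %s: %.1f dB(A)", nm,
                           report$acoustics[[nm]]$peak_dba), character(1)),
                 "")
    }
    failed <- Filter(function(s) !s$ok, report$stages)
    if (length(failed)) {
      lines <- c(lines, "## Failed stages", "",
                 vapply(names(failed), function(nm)
                   sprintf("- %s: %s", nm, failed[[nm]]$error),
                   character(1)), "")
    }
    writeLines(lines, path)
    written <- c(written, path)
  }
  invisible(written)
}
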