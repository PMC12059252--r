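# File formats and workflow entry points: calibration CSV + metadata JSON,
# plan JSON, FID CSV, and the run_* functions behind the command-line
# interface. Every run can emit a provenance record (inputs, parameters,
# package version, seed) for reproducibility.

.cal_columns <- c("rg", "signal_integral", "noise_rms", "fid_max",
                  "n_averages")

#' Read / write calibration tables and curves
#'
#' The calibration CSV has columns `rg, signal_integral, noise_rms,
#' fid_max, n_averages` (UTF-8, '.' decimal, header required). Curve
#' metadata travels in a JSON sidecar: nucleus, field_T, alpha_ref_deg,
#' p_ref, c_ref_M, rg_units. Stored gains are always linear; dB input is
#' converted on read via the declared `rg_units`.
#'
#' @param path CSV file of calibration points.
#' @param required Columns that must be present (schema check).
#' @return `read_calibration_table`: a data frame of points.
#' @export
read_calibration_table <- function(path, required = c("rg", "signal_integral",
                                                      "noise_rms")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(tab))
  if (length(miss)) {
    stop("calibration CSV is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  tab
}

#' @rdname read_calibration_table
#' @param curve A [build_calibration()] curve.
#' @param csv_path,meta_path Output paths for the points CSV and metadata
#'   JSON (`meta_path` defaults to the CSV path with a `.json` extension).
#' @return `write_calibration`: the paths, invisibly.
#' @export
write_calibration <- function(curve, csv_path,
                              meta_path = sub("\\.csv$", ".json", csv_path)) {
  stopifnot(inherits(curve, "calibration_curve"))
  pts <- curve$points[, intersect(.cal_columns, names(curve$points))]
  # stored channels are per-scan; write the as-measured values so that
  # re-reading (which normalizes again) reconstructs the identical curve
  pts$signal_integral <- pts$signal_integral * pts$n_averages
  pts$fid_max <- pts$fid_max * pts$n_averages
  utils::write.csv(pts, csv_path, row.names = FALSE)
  meta <- list(
    nucleus = list(name = curve$nucleus$name,
                   gamma_MHz_per_T = curve$nucleus$gamma_MHz_per_T,
                   spins_per_molecule = curve$nucleus$spins_per_molecule),
    field_T = curve$field, alpha_ref_deg = curve$alpha_ref,
    p_ref = curve$p_ref, c_ref_M = curve$c_ref,
    rg_units = "linear", original_rg_units = curve$rg_units,
    disc_threshold = curve$disc_threshold
  )
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv_path, meta = meta_path))
}

#' @rdname read_calibration_table
#' @return `read_calibration`: the reconstructed `calibration_curve`.
#' @export
read_calibration <- function(csv_path,
                             meta_path = sub("\\.csv$", ".json", csv_path)) {
  pts <- read_calibration_table(csv_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  nuc <- nucleus(meta$nucleus$name,
                 gamma_MHz_per_T = meta$nucleus$gamma_MHz_per_T,
                 spins_per_molecule = meta$nucleus$spins_per_molecule)
  units <- if (identical(meta$rg_units, "dB")) "dB" else "linear"
  thr <- if (is.null(meta$disc_threshold)) 0.1 else meta$disc_threshold
  build_calibration(pts, nuc, field = meta$field_T,
                    alpha_ref = meta$alpha_ref_deg, p_ref = meta$p_ref,
                    c_ref = meta$c_ref_M, rg_units = units,
                    disc_threshold = thr)
}

#' Read / write an acquisition plan as JSON
#'
#' @param plan A `plan_result` from [optimize_acquisition()].
#' @param path Output JSON path.
#' @param maps Include the full (RG, alpha) map arrays (default `FALSE`;
#'   they can be large).
#' @return The path (write) or a list mirroring the plan fields (read).
#' @export
write_plan <- function(plan, path, maps = FALSE) {
  stopifnot(inherits(plan, "plan_result"))
  out <- list(rg_opt = plan$rg_opt, alpha_opt_deg = plan$alpha_opt,
              snr_pred = plan$snr_pred, fid_max_pred = plan$fid_max_pred,
              clip_margin = plan$clip_margin, s_m = plan$s_m)
  if (maps) {
    out$maps <- list(rg = plan$maps$rg, alpha_deg = plan$maps$alpha,
                     snr = plan$maps$snr, fid_max = plan$maps$fid_max,
                     allowed = plan$maps$allowed)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Read / write an FID as CSV
#'
#' Columns `time, real, imag` (seconds, a.u.); acquisition metadata
#' (`dwell`, `rg`, `alpha`, `clipped`) goes to a JSON sidecar.
#'
#' @param fid A [fid_record()].
#' @param csv_path,meta_path Paths; `meta_path` defaults to the CSV path
#'   with a `.json` extension.
#' @return Paths (write) or the reconstructed `fid_record` (read).
#' @export
write_fid <- function(fid, csv_path,
                      meta_path = sub("\\.csv$", ".json", csv_path)) {
  stopifnot(inherits(fid, "fid_record"))
  n <- length(fid$samples)
  utils::write.csv(
    data.frame(time = (seq_len(n) - 1) * fid$dwell,
               real = Re(fid$samples), imag = Im(fid$samples)),
    csv_path, row.names = FALSE)
  jsonlite::write_json(
    list(dwell = fid$dwell, rg = fid$rg, alpha = fid$alpha,
         clipped = fid$clipped, meta = fid$meta),
    meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv_path, meta = meta_path))
}

#' @rdname write_fid
#' @export
read_fid <- function(csv_path,
                     meta_path = sub("\\.csv$", ".json", csv_path)) {
  tab <- utils::read.csv(csv_path)
  miss <- setdiff(c("time", "real", "imag"), names(tab))
  if (length(miss)) {
    stop("FID CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list(dwell = if (nrow(tab) > 1) tab$time[2] - tab$time[1] else
      stop("cannot infer dwell", call. = FALSE),
      rg = NA_real_, alpha = NA_real_, clipped = FALSE, meta = list())
  }
  fid_record(complex(real = tab$real, imaginary = tab$imag),
             dwell = meta$dwell, rg = meta$rg, alpha = meta$alpha,
             clipped = isTRUE(meta$clipped),
             meta = if (is.null(meta$meta)) list() else meta$meta)
}

# Machine-readable provenance for a workflow run.
.provenance <- function(command, params, seed = NULL) {
  list(command = command,
       package = "rgplan",
       version = as.character(utils::packageVersion("rgplan")),
       seed = seed,
       parameters = params)
}

#' Calibration workflow: CSV in, curve files out
#'
#' Reads an RG-sweep CSV, builds the calibration curve, and writes the
#' curve CSV plus metadata JSON and a provenance record. Slope fits,
#' per-point SNR and detected discontinuities are reported in the returned
#' summary.
#'
#' @param input Path to a calibration CSV (see
#'   [read_calibration_table()]).
#' @param out_prefix Output path prefix; writes `<prefix>.csv`,
#'   `<prefix>.json` and `<prefix>_provenance.json`.
#' @param nucleus_name,field,alpha_ref,p_ref,c_ref,rg_units,disc_threshold
#'   Curve metadata; see [build_calibration()]. Concentration in M.
#' @return The `calibration_curve`, invisibly; prints a summary.
#' @export
run_calibrate <- function(input, out_prefix, nucleus_name, field, alpha_ref,
                          p_ref, c_ref, rg_units = "linear",
                          disc_threshold = 0.1) {
  pts <- read_calibration_table(input)
  curve <- build_calibration(pts, nucleus(nucleus_name), field = field,
                             alpha_ref = alpha_ref, p_ref = p_ref,
                             c_ref = c_ref, rg_units = rg_units,
                             disc_threshold = disc_threshold)
  write_calibration(curve, paste0(out_prefix, ".csv"),
                    paste0(out_prefix, ".json"))
  jsonlite::write_json(
    .provenance("calibrate",
                list(input = input, nucleus = nucleus_name, field_T = field,
                     alpha_ref_deg = alpha_ref, p_ref = p_ref,
                     c_ref_M = c_ref, rg_units = rg_units,
                     disc_threshold = disc_threshold)),
    paste0(out_prefix, "_provenance.json"), auto_unbox = TRUE, digits = NA)
  print(curve)
  invisible(curve)
}

#' Planning workflow: curve + sample + receiver in, plan JSON out
#'
#' @param calibration Path prefix or CSV path of a stored calibration (as
#'   written by [run_calibrate()]), or a `calibration_curve` object.
#' @param out Output plan JSON path.
#' @param nucleus_name Nucleus label (used with thermal polarization).
#' @param conc_mM Spin concentration in mM (the conventional CLI unit;
#'   stored as M internally).
#' @param polarization Polarization fraction, or the string
#'   `"thermal:<T_K>"` to compute the Boltzmann value at the curve's field.
#' @param alpha_max Maximum flip angle, degrees.
#' @param rrt ADC ceiling, a.u.
#' @param safety_factor Fraction of `rrt` used as the overflow limit.
#' @param rg_list Optional discrete settable gains.
#' @param maps Include full maps in the JSON output.
#' @return The `plan_result`, invisibly; prints a summary.
#' @export
run_plan <- function(calibration, out, nucleus_name, conc_mM, polarization,
                     alpha_max = 90, rrt, safety_factor = 1, rg_list = NULL,
                     maps = FALSE) {
  curve <- if (inherits(calibration, "calibration_curve")) {
    calibration
  } else {
    csv <- if (grepl("\\.csv$", calibration)) calibration
           else paste0(calibration, ".csv")
    read_calibration(csv)
  }
  nuc <- if (missing(nucleus_name)) curve$nucleus else nucleus(nucleus_name)
  pol <- if (is.character(polarization)) {
    if (!grepl("^thermal:", polarization)) {
      stop("polarization must be a fraction or 'thermal:<T_K>'", call. = FALSE)
    }
    temp <- as.numeric(sub("^thermal:", "", polarization))
    thermal_polarization(nuc, curve$field, temp)
  } else {
    polarization
  }
  sample <- sample_spec(nuc, concentration = conc_mM / 1000,
                        polarization = pol)
  receiver <- receiver_model(rg_min = min(curve$points$rg),
                             rg_max = max(curve$points$rg), rrt = rrt,
                             safety_factor = safety_factor,
                             allowed_rg = rg_list)
  plan <- optimize_acquisition(curve, sample, receiver,
                               constraint_spec(alpha_max = alpha_max))
  write_plan(plan, out, maps = maps)
  jsonlite::write_json(
    .provenance("plan",
                list(conc_mM = conc_mM, polarization = pol,
                     alpha_max_deg = alpha_max, rrt = rrt,
                     safety_factor = safety_factor)),
    sub("\\.json$", "_provenance.json", out), auto_unbox = TRUE, digits = NA)
  print(plan)
  invisible(plan)
}
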