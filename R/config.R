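# Run configuration: a versioned YAML schema tying the model stages into
# the three standard studies (acoustic baseline, transducer drive, rod
# study) plus the electrical report. Unknown keys are rejected so typos in
# physical parameters fail loudly. Convenience keys with _mm / _um / _gpa
# suffixes are converted to SI base units at load; all internal computation
# is SI.

CONFIG_SCHEMA_VERSION <- 1L

config_defaults <- function() {
  list(
    schema_version = CONFIG_SCHEMA_VERSION,
    stack = list(n_layers = 50L, layer_thickness_um = 40,
                 width_mm = 2, depth_mm = 2, refinement = c(1L, 1L, 1L)),
    rod = list(diameter_mm = 0.5, length_mm = 2.0, youngs_modulus_gpa = 116,
               density = 4500, n_elements = 6L),
    surrogate = list(cochlear_damping = 0.2, cv = 0),
    damping = list(alpha = 0, beta = 1e-4),
    drive = list(type = "voltage", v_rms = 10.5, spl_db = 100,
                 spl_ref = 100,
                 f_min_hz = 160, f_max_hz = 8000, n_freq = 40L),
    power = list(frequency_hz = 1000, v_rms = 1,
                 eps33_rel = 635, capacitance_nf = NULL),
    outputs = list(stem = "run"),
    seed = 1L
  )
}

# overlay user values on defaults, rejecting unknown keys with a field path
merge_config <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    here <- if (path == "") nm else paste0(path, ".", nm)
    if (!nm %in% names(defaults))
      stop("unknown configuration key: ", here, call. = FALSE)
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      if (!is.list(user[[nm]]))
        stop("configuration key ", here, " must be a mapping", call. = FALSE)
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]], here)
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Read and validate a run configuration
#'
#' Loads a YAML run configuration, overlays it on the documented defaults,
#' rejects unknown keys (reporting the offending field path), converts the
#' unit-suffixed convenience keys to SI and validates ranges.
#'
#' @param path YAML file path, or NULL for the pure defaults
#' @return object of class `run_config` with resolved SI values:
#'   `stack_spec`, `rod_spec`, `surrogate`, `drive`, `power`, `outputs`,
#'   `seed`
#' @export
read_run_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (!is.null(user$schema_version) &&
      user$schema_version != CONFIG_SCHEMA_VERSION)
    stop("unsupported schema_version: ", user$schema_version)
  cfg <- merge_config(config_defaults(), user)

  drive_type <- match.arg(cfg$drive$type, c("voltage", "spl"))
  if (cfg$drive$f_min_hz < 1 || cfg$drive$f_max_hz > 20000 ||
      cfg$drive$f_min_hz >= cfg$drive$f_max_hz)
    stop("frequency grid must lie within [1, 20000] Hz (drive.f_min_hz / ",
         "drive.f_max_hz)")
  if (drive_type == "voltage" && cfg$drive$v_rms <= 0)
    stop("zero drive: drive.v_rms must be positive for a voltage run")

  spec <- stack_spec(cfg$stack$n_layers,
                     cfg$stack$layer_thickness_um * 1e-6,
                     cfg$stack$width_mm * 1e-3,
                     cfg$stack$depth_mm * 1e-3,
                     cfg$stack$refinement)
  rod <- rod_spec(cfg$rod$diameter_mm * 1e-3, cfg$rod$length_mm * 1e-3,
                  cfg$rod$youngs_modulus_gpa * 1e9, cfg$rod$density,
                  cfg$rod$n_elements)
  surrogate <- surrogate_config(alpha = cfg$damping$alpha,
                                beta = cfg$damping$beta,
                                cochlear_damping = cfg$surrogate$cochlear_damping,
                                cv = cfg$surrogate$cv,
                                seed = cfg$seed)

  structure(
    list(stack_spec = spec, rod_spec = rod, surrogate = surrogate,
         damping = cfg$damping,
         drive = c(cfg$drive[setdiff(names(cfg$drive), "type")],
                   list(type = drive_type)),
         power = cfg$power, outputs = cfg$outputs,
         seed = as.integer(cfg$seed), raw = cfg),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration (schema", x$raw$schema_version, ")\n")
  print(x$stack_spec)
  print(x$rod_spec)
  cat(sprintf("  drive: %s (%.3g V RMS / %.3g dB SPL), %d frequencies %g-%g Hz\n",
              x$drive$type, x$drive$v_rms, x$drive$spl_db, x$drive$n_freq,
              x$drive$f_min_hz, x$drive$f_max_hz))
  invisible(x)
}

config_grid <- function(config)
  default_frequency_grid(config$drive$n_freq, config$drive$f_min_hz,
                         config$drive$f_max_hz)

config_network <- function(config) {
  net <- build_default_network(config$surrogate)
  if (config$surrogate$cv > 0)
    net <- randomize_network(net, config$surrogate$cv, config$seed)
  net
}

write_run_log <- function(config, out_dir, stem, lines) {
  log_path <- file.path(out_dir, paste0(stem, ".log"))
  writeLines(c("resolved configuration:",
               utils::capture.output(utils::str(config$raw)), lines),
             log_path)
  log_path
}

#' Run the acoustic-baseline study
#'
#' Drives the middle-ear surrogate acoustically at `drive.spl_db` and
#' writes the stapes displacement spectrum and the stapes velocity
#' transfer function to `<stem>_acoustic.csv`, plus a run log with every
#' resolved parameter.
#'
#' @param config a `run_config` (drive type must be "spl")
#' @param out_dir output directory
#' @return invisibly, the data.frame written
#' @export
run_acoustic <- function(config, out_dir = ".") {
  stopifnot(inherits(config, "run_config"))
  if (config$drive$type != "spl")
    stop("run_acoustic requires drive.type = 'spl'")
  freq <- config_grid(config)
  net <- config_network(config)
  spec <- acoustic_drive(net, config$drive$spl_db, freq)
  p_rms <- attr(spec, "p_rms")
  out <- data.frame(
    frequency_hz = freq,
    re = Re(spec$displacement), im = Im(spec$displacement),
    magnitude_m = Mod(spec$displacement),
    phase_deg = Arg(spec$displacement) * 180 / pi,
    stf_ms_per_pa = stf(spec$displacement, freq, p_rms)
  )
  stem <- config$outputs$stem
  utils::write.csv(out, file.path(out_dir, paste0(stem, "_acoustic.csv")),
                   row.names = FALSE)
  write_run_log(config, out_dir, paste0(stem, "_acoustic"),
                sprintf("p_rms = %.6g Pa (%.6g dB SPL)", p_rms,
                        config$drive$spl_db))
  invisible(out)
}

#' Run the transducer-drive study
#'
#' Runs the acoustic baseline at `drive.spl_ref`, then the coupled
#' transducer sweep at `drive.v_rms`, and writes the stapes spectrum with
#' the equivalent sound pressure level to `<stem>_transducer.csv`.
#'
#' @param config a `run_config` (drive type must be "voltage")
#' @param out_dir output directory
#' @return invisibly, the data.frame written
#' @export
run_transducer <- function(config, out_dir = ".") {
  stopifnot(inherits(config, "run_config"))
  if (config$drive$type != "voltage")
    stop("run_transducer requires drive.type = 'voltage'")
  freq <- config_grid(config)
  net <- config_network(config)
  sys <- assemble_stack(mesh_stack(config$stack_spec), pzt4(),
                        beta = config$damping$beta)
  model <- couple(sys, build_rod(config$rod_spec), net, with_rod = TRUE)
  d_tr <- transducer_drive(model, config$drive$v_rms, freq)$displacement
  d_ac <- acoustic_drive(net, config$drive$spl_ref, freq)$displacement
  out <- data.frame(
    frequency_hz = freq,
    re = Re(d_tr), im = Im(d_tr), magnitude_m = Mod(d_tr),
    phase_deg = Arg(d_tr) * 180 / pi,
    d_ac_m = Mod(d_ac),
    peq_db = equivalent_spl(d_tr, d_ac, config$drive$spl_ref)
  )
  stem <- config$outputs$stem
  utils::write.csv(out, file.path(out_dir, paste0(stem, "_transducer.csv")),
                   row.names = FALSE)
  write_run_log(config, out_dir, paste0(stem, "_transducer"),
                sprintf("v_rms = %.6g V, spl_ref = %.6g dB SPL",
                        config$drive$v_rms, config$drive$spl_ref))
  invisible(out)
}

#' Run the coupling-rod stiffness study
#'
#' @param config a `run_config`
#' @param rod_moduli named vector of rod Young's moduli, N/m^2
#' @param out_dir output directory
#' @return invisibly, the `rod_study` result
#' @export
run_rod_study <- function(config, rod_moduli = c(titanium = 116e9,
                                                 ceramic = 510e9),
                          out_dir = ".") {
  stopifnot(inherits(config, "run_config"))
  freq <- config_grid(config)
  st <- rod_stiffness_study(rod_moduli, config$drive$v_rms, freq,
                            stack = config$stack_spec,
                            network = config_network(config),
                            rod_template = config$rod_spec,
                            beta = config$damping$beta)
  stem <- config$outputs$stem
  utils::write.csv(st$spectra,
                   file.path(out_dir, paste0(stem, "_rod_study.csv")),
                   row.names = FALSE)
  utils::write.csv(st$summary,
                   file.path(out_dir, paste0(stem, "_rod_summary.csv")),
                   row.names = FALSE)
  write_run_log(config, out_dir, paste0(stem, "_rod_study"),
                sprintf("variants: %s",
                        paste(sprintf("%s=%.4g GPa", st$summary$variant,
                                      st$summary$rod_E_gpa), collapse = ", ")))
  invisible(st)
}

#' Run the layer-number study
#'
#' @param config a `run_config`
#' @param layer_counts integer vector of layer counts
#' @param out_dir output directory
#' @return invisibly, the `layer_study` data.frame
#' @export
run_layer_study <- function(config, layer_counts = c(10, 25, 50),
                            out_dir = ".") {
  stopifnot(inherits(config, "run_config"))
  freq <- config_grid(config)
  spec <- config$stack_spec
  st <- layer_number_study(layer_counts, config$drive$v_rms,
                           config$drive$spl_ref, freq,
                           network = config_network(config),
                           rod = config$rod_spec,
                           total_thickness = spec$n_layers * spec$layer_thickness,
                           width = spec$width, depth = spec$depth,
                           refinement = spec$refinement,
                           beta = config$damping$beta)
  stem <- config$outputs$stem
  utils::write.csv(st, file.path(out_dir, paste0(stem, "_layer_study.csv")),
                   row.names = FALSE)
  write_run_log(config, out_dir, paste0(stem, "_layer_study"),
                sprintf("layer counts: %s", paste(layer_counts, collapse = ", ")))
  invisible(st)
}

#' Run the electrical report
#'
#' Reports the geometric capacitance (layer formula with the configured
#' permittivity), the model-based clamped and free capacitances, and the
#' drive current and both power conventions at the configured frequency and
#' voltage. A user-supplied `power.capacitance_nf` overrides the geometric
#' value for the current/power figures.
#'
#' @param config a `run_config`
#' @param out_dir output directory
#' @return invisibly, a one-row data.frame report
#' @export
run_power <- function(config, out_dir = ".") {
  stopifnot(inherits(config, "run_config"))
  spec <- config$stack_spec
  area <- spec$width * spec$depth
  c_geom <- stack_capacitance(spec$n_layers, config$power$eps33_rel,
                              area, spec$layer_thickness)
  sys <- assemble_stack(mesh_stack(spec), pzt4(), beta = config$damping$beta)
  c_model <- model_capacitance(sys)
  c_used <- if (!is.null(config$power$capacitance_nf))
    config$power$capacitance_nf * 1e-9 else c_geom
  ep <- current_and_power(c_used, config$power$frequency_hz,
                          config$power$v_rms)
  out <- data.frame(
    capacitance_geometric_nf = c_geom * 1e9,
    capacitance_clamped_nf = c_model$clamped * 1e9,
    capacitance_free_nf = c_model$free * 1e9,
    capacitance_used_nf = c_used * 1e9,
    frequency_hz = config$power$frequency_hz,
    v_rms = config$power$v_rms,
    irms_ma = ep$i_rms_a * 1e3,
    p_half_mw = ep$p_half_w * 1e3,
    p_apparent_mw = ep$p_apparent_w * 1e3
  )
  stem <- config$outputs$stem
  utils::write.csv(out, file.path(out_dir, paste0(stem, "_power.csv")),
                   row.names = FALSE)
  write_run_log(config, out_dir, paste0(stem, "_power"),
                sprintf("I_rms = %.4g mA at %.4g Hz, %.4g V RMS",
                        out$irms_ma, out$frequency_hz, out$v_rms))
  invisible(out)
}
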