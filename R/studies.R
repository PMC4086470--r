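# Design studies: layer-count of the piezostack and stiffness of the
# coupling rod, both evaluated on the coupled transducer/middle-ear model.

#' Layer-number design study
#'
#' Rebuilds the stack for each layer count at fixed total thickness (layer
#' thickness = total / n), drives the coupled model at `v_rms`, and
#' compares against the acoustic baseline at `spl_ref` via the equivalent
#' sound pressure level. Because the stack envelope is fixed, only the
#' electrical layering changes: free stroke (n * d33 * V) and hence output
#' grows with n.
#'
#' @param layer_counts integer vector of layer counts
#' @param v_rms drive voltage, V RMS
#' @param spl_ref acoustic reference level, dB SPL
#' @param frequencies frequency grid, Hz
#' @param mat piezoceramic constitutive set
#' @param network middle-ear surrogate
#' @param rod rod specification ([rod_spec]); the study drives through the rod
#' @param total_thickness,width,depth stack envelope, m
#' @param refinement mesh refinement per layer
#' @param beta stiffness-proportional damping, s
#' @return data.frame of class `layer_study`: `n_layers`, `frequency_hz`,
#'   `d_tr_m`, `d_ac_m`, `peq_db`
#' @export
layer_number_study <- function(layer_counts, v_rms = 10.5, spl_ref = 100,
                               frequencies = default_frequency_grid(),
                               mat = pzt4(),
                               network = build_default_network(),
                               rod = rod_spec(),
                               total_thickness = 2e-3, width = 2e-3,
                               depth = 2e-3, refinement = c(1, 1, 1),
                               beta = 1e-4) {
  stopifnot(length(layer_counts) >= 1, all(layer_counts >= 1))
  d_ac <- Mod(acoustic_drive(network, spl_ref, frequencies)$displacement)
  rows <- lapply(as.integer(layer_counts), function(n) {
    spec <- stack_spec(n, total_thickness / n, width, depth, refinement)
    sys <- assemble_stack(mesh_stack(spec), mat, beta = beta)
    model <- couple(sys, build_rod(rod), network, with_rod = TRUE)
    d_tr <- Mod(transducer_drive(model, v_rms, frequencies)$displacement)
    data.frame(n_layers = n, frequency_hz = frequencies,
               d_tr_m = d_tr, d_ac_m = d_ac,
               peq_db = equivalent_spl(d_tr, d_ac, spl_ref))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("layer_study", "data.frame")
  out
}

#' Coupling-rod stiffness study
#'
#' Computes the transducer-driven stapes spectrum with a rigid tip-incus
#' junction (`d_tr`) once, then with the coupling rod for each Young's
#' modulus variant (`d_tr_rod`), and reports the insertion penalty
#' spectrum and the per-variant maximum drop with its frequency.
#'
#' @param rod_moduli vector of rod Young's moduli, N/m^2 (e.g.
#'   `c(titanium = 116e9, ceramic = 510e9)`)
#' @param v_rms drive voltage, V RMS
#' @param frequencies frequency grid, Hz
#' @param stack a [stack_spec]
#' @param mat piezoceramic constitutive set
#' @param network middle-ear surrogate
#' @param rod_template a [rod_spec] supplying geometry, density and element
#'   count; only the modulus is varied
#' @param beta stiffness-proportional damping, s
#' @return list of class `rod_study`: `spectra` (data.frame `variant`,
#'   `rod_E_gpa`, `frequency_hz`, `d_tr_m`, `d_tr_rod_m`, `delta_h_db`) and
#'   `summary` (`variant`, `rod_E_gpa`, `max_drop_db` >= 0,
#'   `at_frequency_hz`)
#' @export
rod_stiffness_study <- function(rod_moduli = c(titanium = 116e9,
                                               ceramic = 510e9),
                                v_rms = 10.5,
                                frequencies = default_frequency_grid(),
                                stack = stack_spec(),
                                mat = pzt4(),
                                network = build_default_network(),
                                rod_template = rod_spec(),
                                beta = 1e-4) {
  stopifnot(length(rod_moduli) >= 1)
  if (is.null(names(rod_moduli)))
    names(rod_moduli) <- sprintf("E_%.4gGPa", rod_moduli / 1e9)
  sys <- assemble_stack(mesh_stack(stack), mat, beta = beta)
  direct <- couple(sys, NULL, network, with_rod = FALSE)
  d_tr <- Mod(transducer_drive(direct, v_rms, frequencies)$displacement)

  spectra <- lapply(names(rod_moduli), function(nm) {
    rs <- rod_spec(diameter = rod_template$diameter,
                   length = rod_template$length,
                   youngs_modulus = rod_moduli[[nm]],
                   density = rod_template$density,
                   n_elements = rod_template$n_elements)
    model <- couple(sys, build_rod(rs), network, with_rod = TRUE)
    d_tr_rod <- Mod(transducer_drive(model, v_rms, frequencies)$displacement)
    data.frame(variant = nm, rod_E_gpa = rod_moduli[[nm]] / 1e9,
               frequency_hz = frequencies,
               d_tr_m = d_tr, d_tr_rod_m = d_tr_rod,
               delta_h_db = rod_effect_db(d_tr_rod, d_tr))
  })
  spectra <- do.call(rbind, spectra)

  summary <- do.call(rbind, lapply(split(spectra, spectra$variant), function(d) {
    k <- which.min(d$delta_h_db)   # largest drop = most negative penalty
    data.frame(variant = d$variant[1], rod_E_gpa = d$rod_E_gpa[1],
               max_drop_db = -d$delta_h_db[k],
               at_frequency_hz = d$frequency_hz[k])
  }))
  rownames(summary) <- NULL
  structure(list(spectra = spectra, summary = summary), class = "rod_study")
}

#' @export
print.rod_study <- function(x, ...) {
  cat("Coupling-rod stiffness study\n")
  print(x$summary)
  invisible(x)
}
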