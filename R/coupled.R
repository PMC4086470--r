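# Coupling the piezostack FEM model to the middle-ear surrogate.
#
# The stack base is anchored to the mastoid (fully fixed); the stack tip
# plane moves as a rigid platen in the axial direction and drives the incus
# body either directly (rigid junction; the "d_tr" case that ignores the
# rod's structure) or through a flexible coupling rod modeled as a chain of
# axial bar elements (the "d_tr_rod" case). Junctions are rigid ties,
# matching an epoxy-bonded attachment.

#' Specify a coupling rod
#'
#' @param diameter rod diameter, m (default 0.5 mm)
#' @param length rod length, m (default 2.0 mm)
#' @param youngs_modulus Young's modulus, N/m^2 (116 GPa titanium;
#'   510 GPa ceramic)
#' @param density density, kg/m^3
#' @param n_elements number of bar elements along the rod (default 6)
#' @return object of class `rod_spec`
#' @export
rod_spec <- function(diameter = 0.5e-3, length = 2.0e-3,
                     youngs_modulus = 116e9, density = 4500,
                     n_elements = 6L) {
  stopifnot(diameter > 0, length > 0, youngs_modulus > 0, density > 0,
            n_elements >= 1)
  structure(
    list(diameter = diameter, length = length,
         youngs_modulus = youngs_modulus, density = density,
         n_elements = as.integer(n_elements),
         area = pi * diameter^2 / 4),
    class = "rod_spec"
  )
}

#' @export
print.rod_spec <- function(x, ...) {
  cat(sprintf(
    "Coupling rod: %.3g mm dia x %.3g mm, E = %.4g GPa, %d elements (k = %.4g N/m)\n",
    x$diameter * 1e3, x$length * 1e3, x$youngs_modulus / 1e9, x$n_elements,
    x$youngs_modulus * x$area / x$length))
  invisible(x)
}

#' Build the rod element chain
#'
#' Assembles `n_elements` axial bar elements (stiffness E A / L_e each,
#' consistent mass) into a 1-D sub-chain aligned with the stack axis.
#'
#' @param spec a [rod_spec]
#' @return list with dense `K`, `M` ((n+1) x (n+1)), `n_nodes`, `spec`;
#'   `k_total` is the series stiffness E A / L
#' @export
build_rod <- function(spec) {
  stopifnot(inherits(spec, "rod_spec"))
  ne <- spec$n_elements
  nn <- ne + 1L
  Le <- spec$length / ne
  ke <- spec$youngs_modulus * spec$area / Le
  me <- spec$density * spec$area * Le
  K <- matrix(0, nn, nn)
  M <- matrix(0, nn, nn)
  for (e in seq_len(ne)) {
    id <- c(e, e + 1L)
    K[id, id] <- K[id, id] + ke * matrix(c(1, -1, -1, 1), 2)
    M[id, id] <- M[id, id] + me / 6 * matrix(c(2, 1, 1, 2), 2)
  }
  list(K = K, M = M, n_nodes = nn, spec = spec,
       k_total = spec$youngs_modulus * spec$area / spec$length)
}

#' Couple the piezostack, the rod and the middle-ear network
#'
#' Builds the combined sparse system over stack DOFs + rod DOFs + network
#' DOFs. With `with_rod = TRUE` the rod chain is inserted between the stack
#' tip platen and the incus attachment port; with `with_rod = FALSE` the tip
#' is tied rigidly to the incus port and the rod is omitted (identical
#' topology, zero-length junction). The stack base is mechanically grounded
#' (mastoid).
#'
#' @param stack_system an `assembled_system` from [assemble_stack]
#' @param rod a rod chain from [build_rod] (ignored when `with_rod = FALSE`)
#' @param network a `middle_ear_network`
#' @param with_rod logical
#' @return object of class `coupled_model`
#' @export
couple <- function(stack_system, rod, network, with_rod = TRUE) {
  stopifnot(inherits(stack_system, "assembled_system"),
            inherits(network, "middle_ear_network"))
  if (with_rod && !is.list(rod)) stop("with_rod = TRUE requires a rod chain")
  ns <- stack_system$ndof
  beta <- stack_system$beta
  nnet <- length(network$masses)

  if (with_rod) {
    nr <- rod$n_nodes
    K <- Matrix::bdiag(stack_system$K, rod$K, network$K)
    M <- Matrix::bdiag(stack_system$M, rod$M, network$M)
    C <- Matrix::bdiag(stack_system$C, beta * rod$K, network$C)
  } else {
    nr <- 0L
    K <- Matrix::bdiag(stack_system$K, network$K)
    M <- Matrix::bdiag(stack_system$M, network$M)
    C <- Matrix::bdiag(stack_system$C, network$C)
  }
  ndof <- ns + nr + nnet
  net_off <- ns + nr

  mesh <- stack_system$mesh
  nodes <- mesh$nodes
  tol <- 1e-12 + 1e-9 * max(nodes)
  tip_nodes <- which(abs(nodes[, 3] - max(nodes[, 3])) < tol)
  tip_uz <- mech_dofs(tip_nodes, 3)
  incus_dof <- net_off + network$attach_port

  if (with_rod) {
    junction_groups <- list(c(tip_uz, ns + 1L),
                            c(ns + nr, incus_dof))
  } else {
    junction_groups <- list(c(tip_uz, incus_dof))
  }

  electrode_sets <- lapply(mesh$electrode_sets,
                           function(s) pot_dofs(stack_system$n_nodes, s))

  structure(
    list(system = list(K = K, M = M, C = C, ndof = ndof),
         stack_system = stack_system,
         rod = if (with_rod) rod else NULL,
         network = network, with_rod = with_rod,
         junction_groups = junction_groups,
         electrode_sets = electrode_sets,
         electrode_polarity = mesh$electrode_polarity,
         fixed_dofs = stack_supports(mesh, "base_fixed"),
         probes = list(stapes = net_off + network$probe_port,
                       incus = incus_dof,
                       eardrum = net_off + network$drive_port)),
    class = "coupled_model"
  )
}

#' @export
print.coupled_model <- function(x, ...) {
  cat(sprintf(
    "Coupled transducer/middle-ear model: %d DOFs, %s\n", x$system$ndof,
    if (x$with_rod)
      sprintf("rod E = %.4g GPa (%d elements)",
              x$rod$spec$youngs_modulus / 1e9, x$rod$spec$n_elements)
    else "rigid tip-incus junction (no rod)"))
  invisible(x)
}

# constrain a coupled model for a given terminal voltage
constrain_coupled <- function(model, v_rms) {
  if (v_rms > 10.5)
    warning(sprintf("drive %.3g V RMS exceeds the 10.5 V RMS safety limit",
                    v_rms))
  first <- vapply(model$electrode_sets, `[`, integer(1), 1)
  vals <- ifelse(model$electrode_polarity == "driven", v_rms, 0)
  constrain_system(
    model$system,
    groups = c(model$electrode_sets, model$junction_groups),
    prescribed = list(idx = c(first, model$fixed_dofs),
                      val = c(vals, rep(0, length(model$fixed_dofs))))
  )
}

#' Transducer-driven stapes displacement spectrum
#'
#' Runs the harmonic sweep of the coupled model under a terminal voltage
#' (RMS phasor) and returns the complex stapes displacement per frequency:
#' `d_tr_rod` when the model includes the coupling rod, `d_tr` when the tip
#' is tied rigidly to the incus.
#'
#' @param model a `coupled_model`
#' @param v_rms terminal voltage, V RMS (warning above 10.5)
#' @param frequencies frequency grid, Hz
#' @return data.frame of class `ear_spectrum` with `frequency_hz`,
#'   `displacement` (complex, m RMS); attribute `v_rms`
#' @export
transducer_drive <- function(model, v_rms,
                             frequencies = default_frequency_grid()) {
  stopifnot(inherits(model, "coupled_model"), v_rms > 0)
  cs <- constrain_coupled(model, v_rms)
  sw <- solve_harmonic(cs, frequencies, probes = model$probes["stapes"],
                       keep_full = FALSE)
  out <- data.frame(frequency_hz = frequencies,
                    displacement = sw$probes[, "stapes"])
  attr(out, "v_rms") <- v_rms
  class(out) <- c("ear_spectrum", "data.frame")
  out
}
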