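# Constraint handling and static/harmonic solution of second-order coupled
# systems  M x'' + C x' + K x = F.
#
# Constraints are imposed by master-slave reduction: each tie group
# (equipotential electrode set, rigid junction) collapses to one master DOF
# through a Boolean transformation T (full x reduced), and prescribed DOFs
# (supports, terminal potentials) are eliminated by partitioning the reduced
# system into free and prescribed sets. Reactions (forces, electrode
# charges) are recovered from the prescribed rows.

# Boolean reduction matrix for tie groups; `groups` is a list of disjoint
# full-DOF index vectors, each collapsing to the group's first member.
make_reduction <- function(ndof, groups = list()) {
  map <- seq_len(ndof)
  for (g in groups) {
    g <- as.integer(g)
    if (length(g) < 2) next
    map[g] <- g[1]
  }
  # compress to consecutive reduced indices
  masters <- sort(unique(map))
  red <- match(map, masters)
  T <- Matrix::sparseMatrix(i = seq_len(ndof), j = red, x = 1,
                            dims = c(ndof, length(masters)))
  list(T = T, red_of_full = red, n_red = length(masters))
}

#' Constrain a coupled second-order system
#'
#' Applies tie groups (all DOFs in a group move/float together) and
#' prescribed DOF values (zero for supports, a terminal voltage for driven
#' electrodes) to an assembled system, producing a reduced operator ready
#' for static or harmonic solution.
#'
#' @param system an `assembled_system` (or any list with sparse `K`, `M`,
#'   `C` and `ndof`)
#' @param groups list of full-DOF index vectors to tie together
#' @param prescribed named list with `idx` (full DOF indices) and `val`
#'   (values); DOFs of a tie group may be prescribed via any member
#' @return object of class `constrained_system`
#' @export
constrain_system <- function(system, groups = list(),
                             prescribed = list(idx = integer(), val = numeric())) {
  ndof <- system$ndof
  stopifnot(length(prescribed$idx) == length(prescribed$val))
  if (length(groups) > 1) {
    all_g <- unlist(groups)
    if (anyDuplicated(all_g))
      stop("tie groups overlap: a DOF may belong to at most one group")
  }
  red <- make_reduction(ndof, groups)
  T <- red$T
  Kr <- Matrix::forceSymmetric(Matrix::crossprod(T, system$K %*% T))
  Mr <- Matrix::crossprod(T, system$M %*% T)
  Cr <- Matrix::crossprod(T, system$C %*% T)

  p_idx <- red$red_of_full[prescribed$idx]
  # a prescribed tie group maps several full DOFs to one reduced DOF;
  # collapse duplicates, demanding consistent values
  if (anyDuplicated(p_idx)) {
    sp <- split(prescribed$val, p_idx)
    if (any(vapply(sp, function(v) diff(range(v)) > 0, logical(1))))
      stop("conflicting prescribed values within one tie group")
    p_val <- vapply(sp, `[`, numeric(1), 1)
    p_idx <- as.integer(names(sp))
  } else {
    p_val <- prescribed$val
  }
  free <- setdiff(seq_len(red$n_red), p_idx)

  structure(
    list(K = Kr, M = Mr, C = Cr, T = T, red_of_full = red$red_of_full,
         n_red = red$n_red, free = free, p_idx = p_idx, p_val = p_val,
         parent = system),
    class = "constrained_system"
  )
}

#' @export
print.constrained_system <- function(x, ...) {
  cat(sprintf("Constrained system: %d reduced DOFs (%d free, %d prescribed)\n",
              x$n_red, length(x$free), length(x$p_idx)))
  invisible(x)
}

#' Apply electrode constraints to a piezostack system
#'
#' Ties every electrode interface node set to a single master potential DOF
#' (internal electrodes are equipotential) and prescribes the alternating
#' terminal potentials: driven interfaces at `v_rms`, grounded interfaces at
#' zero. Mechanical supports can be added via `fixed_dofs` (see
#' [stack_supports]). Voltages above the 10.5 V RMS transducer safety limit
#' trigger a warning, not an error.
#'
#' @param system an `assembled_system` from [assemble_stack]
#' @param v_rms terminal voltage, V RMS
#' @param fixed_dofs full mechanical DOF indices to pin to zero
#' @return a `constrained_system`; electrode master bookkeeping is attached
#'   for charge recovery
#' @export
apply_electrodes <- function(system, v_rms, fixed_dofs = integer()) {
  stopifnot(inherits(system, "assembled_system"))
  mesh <- system$mesh
  if (v_rms > 10.5)
    warning(sprintf("drive %.3g V RMS exceeds the 10.5 V RMS safety limit",
                    v_rms))
  sets <- lapply(mesh$electrode_sets, function(s) pot_dofs(system$n_nodes, s))
  if (anyDuplicated(unlist(sets)))
    stop("electrode sets overlap")
  first <- vapply(sets, `[`, integer(1), 1)
  vals <- ifelse(mesh$electrode_polarity == "driven", v_rms, 0)
  cs <- constrain_system(
    system, groups = sets,
    prescribed = list(idx = c(first, as.integer(fixed_dofs)),
                      val = c(vals, rep(0, length(fixed_dofs))))
  )
  cs$electrode_masters <- cs$red_of_full[first]
  cs$electrode_polarity <- mesh$electrode_polarity
  cs$v_rms <- v_rms
  cs
}

# expand reduced solution to the full DOF vector
expand_solution <- function(cs, x_red) as.vector(cs$T %*% x_red)

#' Solve the static coupled problem
#'
#' Solves \eqn{K x = F} on the free partition with the prescribed values
#' substituted, and recovers reactions on the prescribed partition
#' (mechanical reactions at supports; nodal charges at electrode masters).
#'
#' @param cs a `constrained_system`; must restrain all mechanical rigid-body
#'   modes (e.g. via [stack_supports])
#' @param F optional full-DOF load vector
#' @return list with `x` (full DOF solution), `x_red`, `reactions`
#'   (named by reduced prescribed index)
#' @export
solve_static <- function(cs, F = NULL) {
  stopifnot(inherits(cs, "constrained_system"))
  Fr <- reduce_load(cs, F)
  f <- cs$free; p <- cs$p_idx
  rhs <- Fr[f]
  if (length(p)) rhs <- rhs - as.vector(cs$K[f, p, drop = FALSE] %*% cs$p_val)
  singular_msg <- paste0(
    "constrained static system is singular; unrestrained rigid-body ",
    "or floating modes remain (add supports or electrode constraints)")
  if (length(f) == 0L) {
    xf <- numeric(0)
  } else {
    # explicit LU with a pivot check: a floating-point factorisation of a
    # singular operator often "succeeds" with a tiny residual, silently
    # fixing the arbitrary rigid-mode amplitude, so the near-zero pivot is
    # the only reliable witness. The mechanical and dielectric blocks
    # differ by ~18 decades, so equilibrate symmetrically by the diagonal
    # before judging pivots.
    Kff <- methods::as(methods::as(cs$K[f, f, drop = FALSE], "generalMatrix"),
                       "CsparseMatrix")
    d <- abs(Matrix::diag(Kff))
    s <- 1 / sqrt(ifelse(d > 0, d, 1))
    S <- Matrix::Diagonal(x = s)
    Ks <- S %*% Kff %*% S
    fac <- tryCatch(Matrix::lu(Ks), error = function(e) stop(singular_msg))
    du <- abs(Matrix::diag(fac@U))
    if (!all(is.finite(du)) || min(du) < 1e-12 * max(du))
      stop(singular_msg)
    xf <- s * as.vector(Matrix::solve(fac, s * rhs))
    if (!all(is.finite(xf))) stop(singular_msg)
  }
  x_red <- numeric(cs$n_red)
  x_red[f] <- xf
  x_red[p] <- cs$p_val
  reactions <- as.vector(cs$K[p, , drop = FALSE] %*% x_red) - Fr[p]
  names(reactions) <- as.character(p)
  list(x = expand_solution(cs, x_red), x_red = x_red, reactions = reactions)
}

reduce_load <- function(cs, F) {
  if (is.null(F)) return(numeric(cs$n_red))
  as.vector(Matrix::crossprod(cs$T, F))
}

#' Solve the harmonic coupled problem over a frequency grid
#'
#' For each frequency solves the complex system
#' \eqn{(-\omega^2 M + i\omega C + K) x = F} with the prescribed DOFs held
#' at their (real phasor) values, via the equivalent real block form
#' \eqn{[[A, -B], [B, A]]} with \eqn{A = K - \omega^2 M}, \eqn{B = \omega C}.
#' Drive and response are interpreted as RMS phasor amplitudes.
#'
#' @param cs a `constrained_system`
#' @param frequencies vector of frequencies, Hz
#' @param F optional full-DOF complex load vector
#' @param probes optional named list of full DOF indices at which to record
#'   the complex response
#' @param keep_full if TRUE, store the full complex solution per frequency
#' @return object of class `harmonic_sweep`: `frequencies`, `probes`
#'   (complex matrix, one column per probe), optionally `X` (full solutions,
#'   ndof x nf), `reactions` (complex, prescribed rows x nf)
#' @export
solve_harmonic <- function(cs, frequencies, F = NULL, probes = NULL,
                           keep_full = is.null(probes)) {
  stopifnot(inherits(cs, "constrained_system"), all(frequencies > 0))
  f <- cs$free; p <- cs$p_idx
  nf <- length(frequencies)
  Fr <- reduce_load(cs, if (is.null(F)) NULL else Re(F))
  Fi <- reduce_load(cs, if (is.null(F) || is.double(F)) NULL else Im(F))

  Kff <- cs$K[f, f, drop = FALSE]; Mff <- cs$M[f, f, drop = FALSE]
  Cff <- cs$C[f, f, drop = FALSE]
  Kfp <- cs$K[f, p, drop = FALSE]; Mfp <- cs$M[f, p, drop = FALSE]
  Cfp <- cs$C[f, p, drop = FALSE]

  nfree <- length(f)
  X <- if (keep_full) matrix(0i, length(cs$red_of_full), nf) else NULL
  probe_mat <- if (!is.null(probes))
    matrix(0i, nf, length(probes), dimnames = list(NULL, names(probes)))
  reactions <- matrix(0i, length(p), nf)

  for (k in seq_len(nf)) {
    w <- 2 * pi * frequencies[k]
    A <- Kff - w^2 * Mff
    B <- w * Cff
    rhs_r <- Fr[f] - as.vector((Kfp - w^2 * Mfp) %*% cs$p_val)
    rhs_i <- Fi[f] - as.vector((w * Cfp) %*% cs$p_val)
    Aug <- rbind(cbind(A, -B), cbind(B, A))
    sol <- tryCatch(
      as.vector(Matrix::solve(Aug, c(rhs_r, rhs_i))),
      error = function(e)
        stop("harmonic system is singular at ", frequencies[k],
             " Hz; an undamped resonance was hit (use beta > 0)")
    )
    xr_re <- numeric(cs$n_red); xr_im <- numeric(cs$n_red)
    xr_re[f] <- sol[seq_len(nfree)]
    xr_im[f] <- sol[nfree + seq_len(nfree)]
    xr_re[p] <- cs$p_val
    x_red <- complex(real = xr_re, imaginary = xr_im)
    if (keep_full)
      X[, k] <- complex(real = as.vector(cs$T %*% xr_re),
                        imaginary = as.vector(cs$T %*% xr_im))
    if (!is.null(probes))
      probe_mat[k, ] <- x_red[cs$red_of_full[unlist(probes)]]
    # complex reaction r = (K - w^2 M + i w C) x - F on prescribed rows,
    # multiplied real part by real part (sparse ops are real-only)
    Dp <- (cs$K[p, , drop = FALSE] - w^2 * cs$M[p, , drop = FALSE])
    Cp <- cs$C[p, , drop = FALSE]
    reactions[, k] <- complex(
      real = as.vector(Dp %*% xr_re) - w * as.vector(Cp %*% xr_im) - Fr[p],
      imaginary = as.vector(Dp %*% xr_im) + w * as.vector(Cp %*% xr_re) - Fi[p])
  }
  structure(
    list(frequencies = frequencies, probes = probe_mat, X = X,
         reactions = reactions, p_idx = p),
    class = "harmonic_sweep"
  )
}

#' @export
print.harmonic_sweep <- function(x, ...) {
  cat(sprintf("Harmonic sweep: %d frequencies, %.4g - %.4g Hz\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies)))
  if (!is.null(x$probes))
    cat("  probes:", paste(colnames(x$probes), collapse = ", "), "\n")
  invisible(x)
}

# total free charge delivered through the driven terminal of a solved
# static problem (sign such that a positive capacitor charge is positive)
driven_charge <- function(cs, sol) {
  driven <- cs$electrode_masters[cs$electrode_polarity == "driven"]
  rows <- match(driven, cs$p_idx)
  -sum(sol$reactions[rows])
}

#' Terminal capacitance of an assembled piezostack
#'
#' Computes the capacitance seen at the stack terminals from static solves
#' at unit voltage, in two mechanical states: with every mechanical DOF
#' clamped (constant-strain, i.e. \eqn{\varepsilon^S}, capacitance) and with
#' the stack mechanically free on a statically determinate support
#' (effective constant-stress, \eqn{\varepsilon^T}-like, capacitance). The
#' free value exceeds the clamped one whenever the piezoelectric coupling is
#' non-zero.
#'
#' @param system an `assembled_system`
#' @param v test voltage (cancels out; default 1 V)
#' @return list with `clamped` and `free` capacitances, F
#' @export
model_capacitance <- function(system, v = 1) {
  stopifnot(inherits(system, "assembled_system"))
  all_mech <- seq_len(3L * system$n_nodes)
  cs_cl <- apply_electrodes(system, v_rms = v, fixed_dofs = all_mech)
  q_cl <- driven_charge(cs_cl, solve_static(cs_cl))
  cs_fr <- apply_electrodes(system, v_rms = v,
                            fixed_dofs = stack_supports(system$mesh, "tripod"))
  q_fr <- driven_charge(cs_fr, solve_static(cs_fr))
  list(clamped = q_cl / v, free = q_fr / v)
}
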