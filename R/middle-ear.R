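# Lumped-parameter surrogate of the human middle ear.
#
# A four-mass piston chain (eardrum - malleus - incus - stapes) stands in
# for a subject-specific middle ear finite element model: the ossicular
# geometry of any individual temporal bone is not publishable, but every
# downstream metric (stapes transfer function, equivalent SPL, coupling-rod
# penalty) only needs the port dynamics at the eardrum, the incus body and
# the stapes footplate. Stiffnesses come from the literature moduli of the
# connecting tissues via k = E * A_c / L with documented assumed connector
# areas and lengths; masses from tissue densities times assumed body
# volumes. The cochlear load is a single damper on the stapes DOF.

#' Configuration of the middle-ear surrogate network
#'
#' All geometric assumptions of the surrogate are collected here, never
#' hard-coded. Defaults give body masses close to the literature ossicle
#' masses (malleus ~25 mg, incus ~28 mg, stapes ~3 mg) and place the
#' undamped primary resonance of the chain in the typical middle-ear range
#' (500--1500 Hz).
#'
#' @param connector_area_m2 named vector of connector cross-sections, m^2:
#'   `tympanic_annulus`, `drum_malleus`, `incudomalleolar`,
#'   `incudostapedial`, `stapedial_annulus`
#' @param connector_length_m named vector of connector lengths, m (same names)
#' @param body_volume_m3 named vector of body volumes, m^3: `eardrum`,
#'   `malleus`, `incus`, `stapes`
#' @param eardrum_area effective eardrum piston area converting pressure to
#'   force, m^2
#' @param alpha,beta Rayleigh damping coefficients (1/s, s)
#' @param cochlear_damping cochlear load damper on the stapes DOF, N s/m
#' @param cv coefficient of variation for [randomize_network] perturbations
#' @param seed integer seed for perturbations
#' @return object of class `surrogate_config`
#' @export
surrogate_config <- function(
    connector_area_m2 = c(tympanic_annulus = 0.60e-6,
                          drum_malleus = 0.12e-6,
                          incudomalleolar = 0.30e-6,
                          incudostapedial = 0.30e-6,
                          stapedial_annulus = 0.80e-6),
    connector_length_m = c(tympanic_annulus = 0.20e-3,
                           drum_malleus = 1.00e-3,
                           incudomalleolar = 0.50e-3,
                           incudostapedial = 0.60e-3,
                           stapedial_annulus = 0.20e-3),
    body_volume_m3 = c(eardrum = 5.0e-9, malleus = 9.8e-9,
                       incus = 11.9e-9, stapes = 1.4e-9),
    eardrum_area = 3.2e-5,
    alpha = 0, beta = 1e-4,
    cochlear_damping = 0.2,
    cv = 0, seed = 1L) {
  conn <- c("tympanic_annulus", "drum_malleus", "incudomalleolar",
            "incudostapedial", "stapedial_annulus")
  bodies <- c("eardrum", "malleus", "incus", "stapes")
  stopifnot(setequal(names(connector_area_m2), conn),
            setequal(names(connector_length_m), conn),
            setequal(names(body_volume_m3), bodies))
  if (any(connector_area_m2 <= 0) || any(connector_length_m <= 0) ||
      any(body_volume_m3 <= 0) || eardrum_area <= 0)
    stop("all geometric values must be positive")
  if (alpha < 0 || beta < 0 || cochlear_damping < 0)
    stop("damping values must be non-negative")
  if (cv < 0) stop("cv must be non-negative")
  structure(
    list(connector_area_m2 = connector_area_m2[conn],
         connector_length_m = connector_length_m[conn],
         body_volume_m3 = body_volume_m3[bodies],
         eardrum_area = eardrum_area, alpha = alpha, beta = beta,
         cochlear_damping = cochlear_damping, cv = cv,
         seed = as.integer(seed)),
    class = "surrogate_config"
  )
}

# moduli (N/m^2) and densities (kg/m^3) used by the default chain
SURROGATE_MODULI <- c(tympanic_annulus = 4.00e5,   # tympanic annulus ligament
                      drum_malleus = 1.00e7,       # pars tensa
                      incudomalleolar = 1.41e10,   # incudomalleolar joint
                      incudostapedial = 4.00e6,    # incudostapedial joint
                      stapedial_annulus = 4.10e5)  # stapedial annulus ligament
SURROGATE_DENSITIES <- c(eardrum = 1.20e3, malleus = 2.55e3,
                         incus = 2.36e3, stapes = 2.20e3)

#' Build the default middle-ear surrogate network
#'
#' Assembles the 4-DOF piston chain eardrum-malleus-incus-stapes. Springs:
#' eardrum grounded through the tympanic annulus ligament, stapes grounded
#' through the stapedial annulus ligament, serial couplings through the
#' pars tensa attachment, the incudomalleolar joint and the incudostapedial
#' joint, each with k = E * A_c / L. Damping is C = alpha*M + beta*K plus
#' the cochlear load damper on the stapes DOF.
#'
#' @param config a [surrogate_config]
#' @return object of class `middle_ear_network` with `dof_names`, `M`, `K`,
#'   `C` (4 x 4 dense), `springs` (construction table), `masses`,
#'   `eardrum_area`, port indices `drive_port`, `attach_port`, `probe_port`
#' @export
build_default_network <- function(config = surrogate_config()) {
  stopifnot(inherits(config, "surrogate_config"))
  A <- config$connector_area_m2
  L <- config$connector_length_m
  k <- SURROGATE_MODULI * A[names(SURROGATE_MODULI)] / L[names(SURROGATE_MODULI)]
  masses <- SURROGATE_DENSITIES *
    config$body_volume_m3[names(SURROGATE_DENSITIES)]

  springs <- data.frame(
    name = names(k),
    i = c(1L, 1L, 2L, 3L, 4L),
    j = c(0L, 2L, 3L, 4L, 0L),   # 0 = ground
    k = as.numeric(k)
  )
  if (!any(springs$j == 0L))
    stop("network has no grounding spring; stiffness matrix would be singular")
  build_network(dof_names = c("eardrum", "malleus", "incus", "stapes"),
                masses = as.numeric(masses), springs = springs,
                config = config)
}

# assemble a middle_ear_network from masses + spring table + config
build_network <- function(dof_names, masses, springs, config) {
  n <- length(dof_names)
  K <- matrix(0, n, n, dimnames = list(dof_names, dof_names))
  for (r in seq_len(nrow(springs))) {
    i <- springs$i[r]; j <- springs$j[r]; kk <- springs$k[r]
    K[i, i] <- K[i, i] + kk
    if (j > 0L) {
      K[j, j] <- K[j, j] + kk
      K[i, j] <- K[i, j] - kk
      K[j, i] <- K[j, i] - kk
    }
  }
  M <- diag(masses, n)
  dimnames(M) <- dimnames(K)
  C_struct <- config$alpha * M + config$beta * K
  C_cochlea <- matrix(0, n, n, dimnames = dimnames(K))
  C_cochlea[n, n] <- config$cochlear_damping
  structure(
    list(dof_names = dof_names, M = M, K = K, C = C_struct + C_cochlea,
         C_structural = C_struct, C_cochlea = C_cochlea,
         masses = masses, springs = springs,
         eardrum_area = config$eardrum_area,
         drive_port = 1L, attach_port = 3L, probe_port = length(dof_names),
         config = config),
    class = "middle_ear_network"
  )
}

#' @export
print.middle_ear_network <- function(x, ...) {
  cat("Middle-ear surrogate network:", paste(x$dof_names, collapse = " - "), "\n")
  cat(sprintf("  masses (mg): %s\n",
              paste(sprintf("%.3g", x$masses * 1e6), collapse = ", ")))
  cat(sprintf("  springs (N/m): %s\n",
              paste(sprintf("%s=%.3g", x$springs$name, x$springs$k),
                    collapse = ", ")))
  fn <- natural_frequencies(x)
  cat(sprintf("  undamped natural frequencies (Hz): %s\n",
              paste(sprintf("%.0f", fn), collapse = ", ")))
  invisible(x)
}

#' Undamped natural frequencies of a network, Hz
#'
#' Generalized symmetric eigenvalue solve of (K, M) through the
#' mass-normalised form.
#'
#' @param network a `middle_ear_network`
#' @return sorted vector of natural frequencies, Hz
#' @export
natural_frequencies <- function(network) {
  s <- 1 / sqrt(diag(network$M))
  A <- outer(s, s) * network$K
  ev <- eigen((A + t(A)) / 2, symmetric = TRUE, only.values = TRUE)$values
  sort(sqrt(pmax(ev, 0)) / (2 * pi))
}

#' Is a damped network passive?
#'
#' Checks that all eigenvalues of the first-order state matrix have
#' non-positive real parts (within a numerical tolerance), i.e. free
#' vibrations decay.
#'
#' @param network a `middle_ear_network`
#' @param tol tolerance on the real part, 1/s
#' @return logical
#' @export
is_passive <- function(network, tol = 1e-6) {
  n <- length(network$masses)
  Minv <- diag(1 / network$masses, n)
  A <- rbind(cbind(matrix(0, n, n), diag(1, n)),
             cbind(-Minv %*% network$K, -Minv %*% network$C))
  all(Re(eigen(A, only.values = TRUE)$values) <= tol)
}

#' Convert sound pressure level to RMS pressure
#'
#' @param spl_db sound pressure level, dB SPL re 20 uPa
#' @return RMS pressure, Pa
#' @examples
#' spl_to_pressure(100)  # 2 Pa
#' @export
spl_to_pressure <- function(spl_db) 20e-6 * 10^(spl_db / 20)

#' Default harmonic-analysis frequency grid
#'
#' 40 log-spaced points over 160--8000 Hz, the band conventionally used for
#' middle-ear transfer-function evaluation.
#'
#' @param n number of points
#' @param f_min,f_max band edges, Hz
#' @return vector of frequencies, Hz
#' @export
default_frequency_grid <- function(n = 40, f_min = 160, f_max = 8000)
  exp(seq(log(f_min), log(f_max), length.out = n))

# harmonic solve of a small dense network: returns complex displacement at
# every DOF (n x nf) for a force phasor vector F (length n)
network_harmonic <- function(network, F, frequencies) {
  n <- length(network$masses)
  out <- matrix(0i, n, length(frequencies))
  for (k in seq_along(frequencies)) {
    w <- 2 * pi * frequencies[k]
    D <- -w^2 * network$M + 1i * w * network$C + network$K
    out[, k] <- solve(D, F)
  }
  out
}

#' Acoustic drive of the middle-ear network
#'
#' Applies a uniform RMS pressure of the given SPL to the eardrum port
#' (force = pressure x effective eardrum area) and returns the complex
#' stapes displacement spectrum.
#'
#' @param network a `middle_ear_network`
#' @param spl_db drive level, dB SPL
#' @param frequencies frequency grid, Hz
#' @return data.frame of class `ear_spectrum` with columns `frequency_hz`,
#'   `displacement` (complex, m RMS); attributes `p_rms` (Pa) and `spl_db`
#' @export
acoustic_drive <- function(network, spl_db, frequencies = default_frequency_grid()) {
  stopifnot(inherits(network, "middle_ear_network"),
            is.finite(spl_db), all(frequencies > 0))
  p_rms <- spl_to_pressure(spl_db)
  F <- numeric(length(network$masses))
  F[network$drive_port] <- p_rms * network$eardrum_area
  U <- network_harmonic(network, F, frequencies)
  out <- data.frame(frequency_hz = frequencies,
                    displacement = U[network$probe_port, ])
  attr(out, "p_rms") <- p_rms
  attr(out, "spl_db") <- spl_db
  class(out) <- c("ear_spectrum", "data.frame")
  out
}

#' Randomly perturb a middle-ear network
#'
#' Multiplies every spring stiffness and every mass by independent
#' lognormal factors of unit mean and the given coefficient of variation,
#' emulating inter-individual ("temporal bone to temporal bone")
#' variability. Deterministic under a fixed seed; the perturbed network is
#' rebuilt from its construction table, so passivity is preserved by
#' construction.
#'
#' @param network a `middle_ear_network`
#' @param cv coefficient of variation (cv = 0 returns the network unchanged)
#' @param seed integer seed
#' @return a perturbed `middle_ear_network`
#' @export
randomize_network <- function(network, cv = network$config$cv,
                              seed = network$config$seed) {
  stopifnot(inherits(network, "middle_ear_network"), cv >= 0)
  if (cv == 0) return(network)
  sdlog <- sqrt(log(1 + cv^2))
  mulog <- -sdlog^2 / 2   # unit-mean lognormal
  n_draw <- nrow(network$springs) + length(network$masses)
  factors <- withr::with_seed(seed,
    stats::rlnorm(n_draw, meanlog = mulog, sdlog = sdlog))
  springs <- network$springs
  springs$k <- springs$k * factors[seq_len(nrow(springs))]
  masses <- network$masses * factors[nrow(springs) + seq_along(network$masses)]
  build_network(network$dof_names, masses, springs, network$config)
}
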