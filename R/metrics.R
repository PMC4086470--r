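# Evaluation metrics: stapes velocity transfer function, coupling-rod
# insertion penalty, equivalent sound pressure level, and the electrical
# capacitance / current / power estimates of the stack actuator.

#' Stapes velocity transfer function
#'
#' STF(f) = v / P_TM with v = 2*pi*f*D: footplate velocity magnitude per
#' unit sound pressure at the tympanic membrane, (m/s)/Pa.
#'
#' @param displacement displacement magnitude spectrum D(f), m RMS (complex
#'   input is reduced by `Mod`)
#' @param frequencies frequency grid, Hz
#' @param p_tm drive pressure at the tympanic membrane, Pa RMS
#' @return STF spectrum, (m/s)/Pa
#' @examples
#' stf(1e-9, 1000, 2)   # 3.1416e-6
#' @export
stf <- function(displacement, frequencies, p_tm) {
  if (!is.numeric(p_tm) || p_tm <= 0) stop("p_tm must be a positive pressure")
  2 * pi * frequencies * Mod(displacement) / p_tm
}

#' Coupling-rod insertion penalty, dB
#'
#' The change in transducer-excited stapes displacement caused by the
#' flexible coupling rod, relative to a rigid tip-incus junction. The
#' default is the decibel convention 20*log10(d_tr_rod / d_tr) in which the
#' reported drops are expressed; `convention = "literal"` gives the bare
#' log10 ratio without the factor 20.
#'
#' @param d_tr_rod displacement spectrum with the rod, m (magnitudes taken)
#' @param d_tr displacement spectrum with a rigid junction, m
#' @param convention "db" (20*log10) or "literal" (log10)
#' @return penalty spectrum; negative values are drops
#' @export
rod_effect_db <- function(d_tr_rod, d_tr, convention = c("db", "literal")) {
  convention <- match.arg(convention)
  d_tr <- Mod(d_tr); d_tr_rod <- Mod(d_tr_rod)
  if (any(d_tr <= 0)) stop("reference spectrum d_tr must be positive")
  r <- log10(d_tr_rod / d_tr)
  if (convention == "db") 20 * r else r
}

#' Equivalent sound pressure level, dB SPL
#'
#' The acoustic level at the eardrum that would produce the same stapes
#' displacement as the transducer drive:
#' Peq(f) = spl_ref + 20*log10(d_tr / d_ac), where d_ac is the stapes
#' displacement under acoustic stimulation at `spl_ref` dB SPL.
#'
#' @param d_tr transducer-driven stapes displacement spectrum, m
#' @param d_ac acoustically driven stapes displacement spectrum at
#'   `spl_ref`, m
#' @param spl_ref acoustic reference level, dB SPL (default 100)
#' @return Peq spectrum, dB SPL
#' @export
equivalent_spl <- function(d_tr, d_ac, spl_ref = 100) {
  d_tr <- Mod(d_tr); d_ac <- Mod(d_ac)
  if (any(d_ac <= 0)) stop("acoustic baseline d_ac must be positive")
  spl_ref + 20 * log10(d_tr / d_ac)
}

#' Stack capacitance from layer geometry
#'
#' Low-frequency terminal capacitance of an n-layer stack with electrically
#' parallel layers: C = n * eps0 * eps33 * A / t, with t the single-layer
#' thickness. The relative permittivity is an explicit input: with the
#' clamped value eps33^S the result is the constant-strain capacitance; the
#' free (constant-stress) capacitance requires eps33^T, which is larger by
#' the piezoelectric coupling contribution.
#'
#' @param n number of layers
#' @param eps33_rel relative permittivity (dimensionless)
#' @param area electrode surface area, m^2
#' @param thickness single layer thickness, m
#' @return capacitance, F
#' @examples
#' stack_capacitance(50, 635, 4e-6, 4e-5)   # 2.81e-8 F
#' @export
stack_capacitance <- function(n, eps33_rel, area, thickness) {
  stopifnot(n > 0, eps33_rel > 0, area > 0, thickness > 0)
  n * EPS0 * eps33_rel * area / thickness
}

#' Drive current and power of a capacitive actuator
#'
#' For a sinusoidal drive V_rms at frequency f into capacitance C:
#' I_rms = 2*pi*f*C*V_rms. Two power figures are returned, corresponding to
#' the two printed conventions for a reactive load: `p_half_w` =
#' I_rms*V_rms/2 and `p_apparent_w` = I_rms*V_rms. They differ by a factor
#' of two and are labelled rather than conflated.
#'
#' @param c_farads capacitance, F
#' @param f frequency, Hz
#' @param v_rms drive voltage, V RMS
#' @return list with `i_rms_a`, `p_half_w`, `p_apparent_w`
#' @examples
#' current_and_power(71e-9, 1000, 1)$i_rms_a   # 4.46e-4 A
#' @export
current_and_power <- function(c_farads, f, v_rms) {
  stopifnot(c_farads >= 0, all(f >= 0), v_rms >= 0)
  i_rms <- 2 * pi * f * c_farads * v_rms
  list(i_rms_a = i_rms,
       p_half_w = i_rms * v_rms / 2,
       p_apparent_w = i_rms * v_rms)
}
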