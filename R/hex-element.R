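# 8-node trilinear hexahedral element with coupled electromechanical fields.
#
# Each node carries three mechanical DOFs (u, v, w) and one electric
# potential DOF. Element matrices are integrated with 2 x 2 x 2 Gauss
# quadrature. Constitutive relation (stress-charge form, E = -grad phi):
#   T = cE S - e' E,   D = e S + epsS E
# which yields the element blocks
#   Kuu = int Bu' cE Bu dV      (24 x 24)
#   Kup = int Bu' e'  Bp dV     (24 x 8)
#   Kpp = -int Bp' epsS Bp dV   (8 x 8, negative definite)
# The dielectric block carries a negative sign so that the assembled
# block operator [[Kuu, Kup], [Kup', Kpp]] is symmetric as a whole; the
# coupled system is symmetric indefinite and is solved accordingly.

# Corner order: (-,-,-),(+,-,-),(+,+,-),(-,+,-),(-,-,+),(+,-,+),(+,+,+),(-,+,+)
HEX_XI <- matrix(c(
  -1, -1, -1,
   1, -1, -1,
   1,  1, -1,
  -1,  1, -1,
  -1, -1,  1,
   1, -1,  1,
   1,  1,  1,
  -1,  1,  1
), ncol = 3, byrow = TRUE)

# shape function derivatives wrt (xi, eta, zeta) at a quadrature point; 8 x 3
hex_dN <- function(xi, eta, zeta) {
  t(vapply(seq_len(8), function(a) {
    s <- HEX_XI[a, ]
    0.125 * c(
      s[1] * (1 + s[2] * eta) * (1 + s[3] * zeta),
      (1 + s[1] * xi) * s[2] * (1 + s[3] * zeta),
      (1 + s[1] * xi) * (1 + s[2] * eta) * s[3]
    )
  }, numeric(3)))
}

hex_N <- function(xi, eta, zeta) {
  vapply(seq_len(8), function(a) {
    s <- HEX_XI[a, ]
    0.125 * (1 + s[1] * xi) * (1 + s[2] * eta) * (1 + s[3] * zeta)
  }, numeric(1))
}

GAUSS2 <- 1 / sqrt(3)
HEX_QP <- as.matrix(expand.grid(xi = c(-GAUSS2, GAUSS2),
                                eta = c(-GAUSS2, GAUSS2),
                                zeta = c(-GAUSS2, GAUSS2)))

#' Element matrices for a coupled piezoelectric hexahedron
#'
#' Integrates the mechanical stiffness, piezoelectric coupling, dielectric
#' and consistent mass matrices of one 8-node hexahedral element over its
#' volume with 2 x 2 x 2 Gauss quadrature. The element's poling sign flips
#' the sign of the coupling block, which is how alternately poled layers of
#' a stack actuator are represented.
#'
#' @param coords 8 x 3 matrix of node coordinates (m), package corner order
#' @param mat a [piezo_constitutive] object
#' @param poling_sign +1 or -1; multiplies the piezoelectric coupling
#' @return list with `Kuu` (24 x 24), `Kup` (24 x 8), `Kpp` (8 x 8,
#'   negative semidefinite as stored), `Muu` (24 x 24), `volume`
#' @export
element_matrices <- function(coords, mat, poling_sign = 1) {
  stopifnot(is.matrix(coords), nrow(coords) == 8, ncol(coords) == 3)
  stopifnot(inherits(mat, "piezo_constitutive"))
  stopifnot(poling_sign %in% c(-1, 1))

  e_eff <- poling_sign * mat$e
  Kuu <- matrix(0, 24, 24)
  Kup <- matrix(0, 24, 8)
  Kpp <- matrix(0, 8, 8)
  Muu <- matrix(0, 24, 24)
  vol <- 0

  for (q in seq_len(nrow(HEX_QP))) {
    p <- HEX_QP[q, ]
    dN <- hex_dN(p[1], p[2], p[3])          # 8 x 3, d/d(xi)
    J <- t(dN) %*% coords                   # 3 x 3
    detJ <- det(J)
    if (detJ <= 0)
      stop("non-positive Jacobian: degenerate element geometry")
    dNx <- dN %*% t(solve(J))               # 8 x 3, d/d(x)

    Bu <- matrix(0, 6, 24)
    Bp <- matrix(0, 3, 8)
    for (a in seq_len(8)) {
      ca <- 3 * (a - 1)
      gx <- dNx[a, 1]; gy <- dNx[a, 2]; gz <- dNx[a, 3]
      Bu[1, ca + 1] <- gx
      Bu[2, ca + 2] <- gy
      Bu[3, ca + 3] <- gz
      Bu[4, ca + 2] <- gz; Bu[4, ca + 3] <- gy   # gamma_23
      Bu[5, ca + 1] <- gz; Bu[5, ca + 3] <- gx   # gamma_13
      Bu[6, ca + 1] <- gy; Bu[6, ca + 2] <- gx   # gamma_12
      Bp[, a] <- c(gx, gy, gz)
    }

    N <- hex_N(p[1], p[2], p[3])
    Nu <- matrix(0, 3, 24)
    Nu[1, seq(1, 24, 3)] <- N
    Nu[2, seq(2, 24, 3)] <- N
    Nu[3, seq(3, 24, 3)] <- N

    w <- detJ  # unit Gauss weights at 2-point rule
    Kuu <- Kuu + w * crossprod(Bu, mat$cE %*% Bu)
    Kup <- Kup + w * crossprod(Bu, t(e_eff) %*% Bp)
    Kpp <- Kpp - w * crossprod(Bp, mat$epsS %*% Bp)
    Muu <- Muu + w * mat$rho * crossprod(Nu)
    vol <- vol + w
  }

  list(Kuu = Kuu, Kup = Kup, Kpp = Kpp, Muu = Muu, volume = vol)
}
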