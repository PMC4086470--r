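# Constitutive operators: PZT-4 piezoceramic and isotropic elastic components.
#
# Voigt ordering used throughout the package: (11, 22, 33, 23, 13, 12),
# engineering shear strains. The piezoelectric stress matrix e (3 x 6) and the
# clamped permittivity matrix eps^S (3 x 3) follow the same convention, with
# the poling direction along the local 3-axis.

#' Vacuum permittivity (F/m)
#'
#' CODATA value of the electric constant, used to convert relative
#' permittivities to absolute ones.
#' @export
EPS0 <- 8.8541878128e-12

#' Build a transversely isotropic piezoelectric constitutive set
#'
#' Constructs the elastic stiffness matrix at constant electric field
#' \eqn{c^E} (Pa), the piezoelectric stress matrix \eqn{e} (C/m^2) and the
#' clamped (constant-strain) permittivity matrix \eqn{\varepsilon^S} (F/m)
#' for a poled ceramic such as PZT-4. Stiffness inputs are in GPa as
#' conventionally tabulated; they are stored in SI Pa. Relative
#' permittivities are multiplied by the vacuum permittivity [EPS0].
#'
#' The transversely isotropic pattern is enforced: \eqn{c_{22}=c_{11}},
#' \eqn{c_{23}=c_{13}}, \eqn{c_{55}=c_{44}}. The tabulated \eqn{c_{66}} is
#' checked against \eqn{(c_{11}-c_{12})/2}.
#'
#' @param c11,c12,c13,c33,c44,c66 elastic stiffness constants, GPa
#' @param e15,e31,e33 piezoelectric stress constants, C/m^2
#' @param eps11_rel,eps33_rel relative clamped permittivities (dimensionless)
#' @param rho mass density, kg/m^3
#' @return an object of class `piezo_constitutive` with elements `cE` (6 x 6,
#'   Pa), `e` (3 x 6, C/m^2), `epsS` (3 x 3, F/m), `rho`, `poling_axis`
#' @examples
#' mat <- pzt4()
#' mat$cE[1, 1]   # 139 GPa in Pa
#' @export
build_piezo_constitutive <- function(c11, c12, c13, c33, c44, c66,
                                     e15, e31, e33,
                                     eps11_rel, eps33_rel, rho) {
  stiff <- c(c11 = c11, c12 = c12, c13 = c13, c33 = c33, c44 = c44, c66 = c66)
  if (any(!is.finite(stiff)) || any(stiff <= 0))
    stop("all stiffness constants must be positive and finite")
  if (eps11_rel <= 0 || eps33_rel <= 0)
    stop("relative permittivities must be positive")
  if (rho <= 0) stop("density must be positive")

  cE <- matrix(0, 6, 6)
  cE[1, 1] <- cE[2, 2] <- c11
  cE[1, 2] <- cE[2, 1] <- c12
  cE[1, 3] <- cE[3, 1] <- cE[2, 3] <- cE[3, 2] <- c13
  cE[3, 3] <- c33
  cE[4, 4] <- cE[5, 5] <- c44
  cE[6, 6] <- c66
  cE <- cE * 1e9  # GPa -> Pa

  ev <- eigen(cE, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    stop("elastic stiffness matrix is not positive definite; ",
         "check the transcribed constants")

  e <- matrix(0, 3, 6)
  e[1, 5] <- e15
  e[2, 4] <- e15
  e[3, 1] <- e[3, 2] <- e31
  e[3, 3] <- e33

  epsS <- diag(c(eps11_rel, eps11_rel, eps33_rel)) * EPS0

  structure(
    list(cE = cE, e = e, epsS = epsS, rho = rho, poling_axis = "3"),
    class = "piezo_constitutive"
  )
}

#' PZT-4 constitutive set
#'
#' The standard published constants for PZT-4 ceramic: stiffness 139, 77.8,
#' 74.3, 115, 25.6, 30.6 GPa; piezoelectric stress constants 12.7, -5.2,
#' 15.1 C/m^2; relative clamped permittivities 370 and 635; density
#' 7500 kg/m^3 (handbook value; configurable).
#'
#' @param rho density, kg/m^3
#' @return a `piezo_constitutive` object
#' @export
pzt4 <- function(rho = 7500) {
  build_piezo_constitutive(
    c11 = 139, c12 = 77.8, c13 = 74.3, c33 = 115, c44 = 25.6, c66 = 30.6,
    e15 = 12.7, e31 = -5.2, e33 = 15.1,
    eps11_rel = 370, eps33_rel = 635, rho = rho
  )
}

#' @export
print.piezo_constitutive <- function(x, ...) {
  cat("Piezoelectric constitutive set (poling axis", x$poling_axis, ")\n")
  cat(sprintf("  c11^E = %.4g GPa, c33^E = %.4g GPa\n",
              x$cE[1, 1] / 1e9, x$cE[3, 3] / 1e9))
  cat(sprintf("  e33 = %.4g C/m^2, e31 = %.4g C/m^2, e15 = %.4g C/m^2\n",
              x$e[3, 3], x$e[3, 1], x$e[1, 5]))
  cat(sprintf("  eps33^S = %.4g eps0, rho = %.4g kg/m^3\n",
              x$epsS[3, 3] / EPS0, x$rho))
  invisible(x)
}

#' Derive piezoelectric strain constants d = e s^E
#'
#' Computes the strain (charge) constant matrix \eqn{d = e \cdot s^E} (C/N),
#' where \eqn{s^E = (c^E)^{-1}} is the elastic compliance at constant field.
#' `d[3, 3]` is the familiar d33 governing free stroke of a stack actuator.
#' Used as an independent oracle for actuator-level checks; the finite
#' element path never calls it.
#'
#' @param mat a `piezo_constitutive` object
#' @return 3 x 6 matrix of strain constants, C/N
#' @export
derive_strain_constants <- function(mat) {
  stopifnot(inherits(mat, "piezo_constitutive"))
  sE <- tryCatch(solve(mat$cE),
                 error = function(e) stop("stiffness matrix is singular"))
  mat$e %*% sE
}

#' Build an isotropic elastic material and its Voigt stiffness operator
#'
#' Standard isotropic Hooke operator in the package Voigt convention
#' (11, 22, 33, 23, 13, 12), with Rayleigh damping coefficients carried
#' alongside.
#'
#' @param E Young's modulus, N/m^2
#' @param nu Poisson ratio
#' @param rho density, kg/m^3
#' @param alpha mass-proportional damping, 1/s
#' @param beta stiffness-proportional damping, s
#' @return an object of class `elastic_material` with the 6 x 6 operator `C`
#' @export
build_isotropic_elastic <- function(E, nu = 0.3, rho, alpha = 0, beta = 1e-4) {
  if (E <= 0) stop("Young's modulus must be positive")
  if (nu < 0 || nu >= 0.5) stop("Poisson ratio must satisfy 0 <= nu < 0.5")
  if (rho <= 0) stop("density must be positive")
  if (alpha < 0 || beta < 0) stop("damping coefficients must be non-negative")

  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  C <- matrix(0, 6, 6)
  C[1:3, 1:3] <- lam
  diag(C)[1:3] <- lam + 2 * mu
  diag(C)[4:6] <- mu

  structure(
    list(E = E, nu = nu, rho = rho, alpha = alpha, beta = beta, C = C),
    class = "elastic_material"
  )
}

#' @export
print.elastic_material <- function(x, ...) {
  cat(sprintf(
    "Isotropic elastic material: E = %.4g N/m^2, nu = %.3g, rho = %.4g kg/m^3\n",
    x$E, x$nu, x$rho))
  invisible(x)
}

#' Load the middle-ear material property tables
#'
#' Reads the fixture tables of ossicle/eardrum/joint material properties and
#' ligament/tendon boundary properties shipped with the package (columns
#' `name`, `youngs_modulus_pa`, `density_kg_m3`). Values are the literature
#' constants conventionally used for human middle ear finite element models.
#'
#' @param path path to a CSV file; by default both shipped tables are read
#'   and concatenated
#' @return a data.frame with columns `name`, `youngs_modulus_pa`,
#'   `density_kg_m3`, `group`
#' @export
load_material_fixtures <- function(path = NULL) {
  if (is.null(path)) {
    files <- c(
      ear_components = system.file("extdata", "ear_components.csv",
                                   package = "ossidrive"),
      ligaments = system.file("extdata", "ligaments.csv",
                              package = "ossidrive")
    )
    if (any(files == ""))
      stop("shipped material fixtures not found; is the package installed?")
    tabs <- lapply(names(files), function(nm) {
      d <- read_material_table(files[[nm]])
      d$group <- nm
      d
    })
    return(do.call(rbind, tabs))
  }
  read_material_table(path)
}

read_material_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  wanted <- c("name", "youngs_modulus_pa", "density_kg_m3")
  if (!setequal(names(d), wanted))
    stop("material table schema mismatch: expected columns {",
         paste(wanted, collapse = ", "), "}, got {",
         paste(names(d), collapse = ", "), "}")
  d <- d[, wanted]
  if (any(d$youngs_modulus_pa <= 0) || any(d$density_kg_m3 <= 0))
    stop("material table contains non-positive modulus or density")
  d
}
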