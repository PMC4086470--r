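# Multilayer piezostack: structured hexahedral meshing and global assembly.
#
# The stack is a rectangular prism of n thin ceramic layers poled
# alternately along the stack axis (z). Internal electrodes at every layer
# interface are wired to two terminals in alternation, so the layers act
# mechanically in series and electrically in parallel: stroke scales with
# layer count at fixed voltage, capacitance is the sum of the layer
# capacitances.

#' Specify a multilayer piezostack
#'
#' @param n_layers number of ceramic layers
#' @param layer_thickness layer thickness, m
#' @param width,depth cross-section dimensions, m
#' @param refinement integer vector (a, b, c): element subdivisions along
#'   width, depth, and through each layer's thickness
#' @return object of class `stack_spec`
#' @examples
#' # 2 x 2 x 2 mm transducer, 50 layers of 40 um
#' stack_spec(50, 0.04e-3, 2e-3, 2e-3)
#' @export
stack_spec <- function(n_layers = 50, layer_thickness = 0.04e-3,
                       width = 2e-3, depth = 2e-3,
                       refinement = c(1, 1, 1)) {
  stopifnot(n_layers >= 1, layer_thickness > 0, width > 0, depth > 0)
  refinement <- as.integer(refinement)
  if (length(refinement) != 3 || any(refinement < 1))
    stop("refinement must be three positive integers (a, b, c)")
  structure(
    list(n_layers = as.integer(n_layers), layer_thickness = layer_thickness,
         width = width, depth = depth, refinement = refinement),
    class = "stack_spec"
  )
}

#' @export
print.stack_spec <- function(x, ...) {
  cat(sprintf(
    "Piezostack: %d layers x %.3g um, %.3g x %.3g mm cross-section (total %.3g mm)\n",
    x$n_layers, x$layer_thickness * 1e6, x$width * 1e3, x$depth * 1e3,
    x$n_layers * x$layer_thickness * 1e3))
  cat(sprintf("  refinement %d x %d x %d per layer\n",
              x$refinement[1], x$refinement[2], x$refinement[3]))
  invisible(x)
}

#' Mesh a multilayer piezostack
#'
#' Builds a structured grid of 8-node hexahedra over the stack volume.
#' Every element belongs to exactly one ceramic layer; the poling sign
#' alternates between adjacent layers and the electrode node sets at the
#' layer interfaces alternate between the ground and driven terminals, so
#' that all layers expand together under a single terminal voltage.
#'
#' @param spec a [stack_spec]
#' @return object of class `stack_mesh` with `nodes` (N x 3, m), `elements`
#'   (E x 8 node indices), `element_layer`, `poling_sign`, `electrode_sets`
#'   (list of node-index vectors, interfaces base to tip), and
#'   `electrode_polarity` ("ground"/"driven" per interface)
#' @export
mesh_stack <- function(spec) {
  stopifnot(inherits(spec, "stack_spec"))
  a <- spec$refinement[1]; b <- spec$refinement[2]; cc <- spec$refinement[3]
  n <- spec$n_layers
  nz <- n * cc

  xs <- seq(0, spec$width, length.out = a + 1)
  ys <- seq(0, spec$depth, length.out = b + 1)
  zs <- seq(0, n * spec$layer_thickness, length.out = nz + 1)

  # node id for grid position (ix, iy, iz), 0-based grid indices
  nid <- function(ix, iy, iz) ix + 1L + (a + 1L) * iy + (a + 1L) * (b + 1L) * iz

  grid <- expand.grid(ix = 0:a, iy = 0:b, iz = 0:nz)
  nodes <- cbind(xs[grid$ix + 1], ys[grid$iy + 1], zs[grid$iz + 1])

  el <- expand.grid(ix = 0:(a - 1), iy = 0:(b - 1), iz = 0:(nz - 1))
  elements <- t(mapply(function(ix, iy, iz) {
    c(nid(ix,     iy,     iz),     nid(ix + 1, iy,     iz),
      nid(ix + 1, iy + 1, iz),     nid(ix,     iy + 1, iz),
      nid(ix,     iy,     iz + 1), nid(ix + 1, iy,     iz + 1),
      nid(ix + 1, iy + 1, iz + 1), nid(ix,     iy + 1, iz + 1))
  }, el$ix, el$iy, el$iz))
  element_layer <- el$iz %/% cc + 1L
  # odd layers sit between a grounded interface below and a driven one
  # above; their field points down (-z), so they are poled -1 to expand
  # under positive terminal voltage, and even layers +1
  poling_sign <- ifelse(element_layer %% 2L == 1L, -1L, 1L)

  electrode_sets <- lapply(0:n, function(k) {
    iz <- k * cc
    as.integer(nid(rep(0:a, times = b + 1), rep(0:b, each = a + 1), iz))
  })
  electrode_polarity <- ifelse(seq(0, n) %% 2 == 0, "ground", "driven")

  structure(
    list(spec = spec, nodes = nodes, elements = elements,
         element_layer = element_layer, poling_sign = poling_sign,
         electrode_sets = electrode_sets,
         electrode_polarity = electrode_polarity),
    class = "stack_mesh"
  )
}

#' @export
print.stack_mesh <- function(x, ...) {
  cat(sprintf("Piezostack mesh: %d nodes, %d hex elements, %d electrode interfaces\n",
              nrow(x$nodes), nrow(x$elements), length(x$electrode_sets)))
  invisible(x)
}

# DOF layout: mechanical DOFs of node i are 3(i-1)+1..3(i-1)+3; potential
# DOF of node i is 3*N + i.
mech_dofs <- function(nodes, comp = 1:3) {
  as.vector(t(outer(3L * (as.integer(nodes) - 1L), as.integer(comp), `+`)))
}
pot_dofs <- function(n_nodes, nodes) 3L * n_nodes + as.integer(nodes)

#' Assemble the coupled global system of a piezostack mesh
#'
#' Forms the sparse global blocks \eqn{K_{uu}}, \eqn{K_{u\phi}},
#' \eqn{K_{\phi\phi}}, \eqn{M_{uu}} and the stiffness-proportional damping
#' \eqn{C_{uu} = \beta K_{uu}}, arranged as one symmetric operator over the
#' mechanical-then-potential DOF vector. The dielectric block is stored with
#' a negative sign so the full block matrix is symmetric (and indefinite).
#' Because the mesh is a uniform structured grid, the element matrices are
#' computed once and replicated, with the coupling sign flipped per layer.
#'
#' @param mesh a [stack_mesh]
#' @param mat a [piezo_constitutive]
#' @param beta stiffness-proportional damping coefficient, s
#' @return object of class `assembled_system`: sparse `K`, `M`, `C`
#'   (ndof x ndof), `n_nodes`, `ndof`, `mesh`, `beta`
#' @export
assemble_stack <- function(mesh, mat, beta = 1e-4) {
  stopifnot(inherits(mesh, "stack_mesh"), inherits(mat, "piezo_constitutive"))
  stopifnot(beta >= 0)
  nn <- nrow(mesh$nodes)
  ndof <- 4L * nn

  # all elements share one geometry in a uniform structured grid
  em <- element_matrices(mesh$nodes[mesh$elements[1, ], ], mat, poling_sign = 1)

  ne <- nrow(mesh$elements)
  iK <- jK <- integer(0); xK <- numeric(0)
  iM <- jM <- integer(0); xM <- numeric(0)
  iC <- jC <- integer(0); xC <- numeric(0)

  idx24 <- rep(seq_len(24), times = 24)
  jdx24 <- rep(seq_len(24), each = 24)
  idx24x8 <- rep(seq_len(24), times = 8)
  jdx24x8 <- rep(seq_len(8), each = 24)
  idx8 <- rep(seq_len(8), times = 8)
  jdx8 <- rep(seq_len(8), each = 8)

  Ku <- as.vector(em$Kuu); Mu <- as.vector(em$Muu)
  Kp <- as.vector(em$Kpp); Kc <- as.vector(em$Kup)

  iKl <- jKl <- vector("list", ne); xKl <- vector("list", ne)
  iMl <- jMl <- vector("list", ne); xMl <- vector("list", ne)
  for (e in seq_len(ne)) {
    en <- mesh$elements[e, ]
    md <- mech_dofs(en)                 # 24 global mech dofs
    pd <- pot_dofs(nn, en)              # 8 global potential dofs
    s <- mesh$poling_sign[e]
    iKl[[e]] <- c(md[idx24], md[idx24x8], pd[jdx24x8], pd[idx8])
    jKl[[e]] <- c(md[jdx24], pd[jdx24x8], md[idx24x8], pd[jdx8])
    xKl[[e]] <- c(Ku, s * Kc, s * Kc, Kp)
    iMl[[e]] <- md[idx24]
    jMl[[e]] <- md[jdx24]
    xMl[[e]] <- Mu
  }
  K <- Matrix::sparseMatrix(i = unlist(iKl), j = unlist(jKl), x = unlist(xKl),
                            dims = c(ndof, ndof))
  M <- Matrix::sparseMatrix(i = unlist(iMl), j = unlist(jMl), x = unlist(xMl),
                            dims = c(ndof, ndof))
  # damping applies to the mechanical block only: beta * Kuu
  C <- Matrix::sparseMatrix(i = unlist(iMl), j = unlist(jMl),
                            x = beta * rep(Ku, ne), dims = c(ndof, ndof))

  structure(
    list(K = K, M = M, C = C, n_nodes = nn, ndof = ndof,
         mesh = mesh, material = mat, beta = beta),
    class = "assembled_system"
  )
}

#' @export
print.assembled_system <- function(x, ...) {
  cat(sprintf("Assembled piezostack system: %d nodes, %d DOFs (%d mech + %d potential)\n",
              x$n_nodes, x$ndof, 3L * x$n_nodes, x$n_nodes))
  invisible(x)
}

#' Mechanical support sets for a stack mesh
#'
#' Returns global DOF indices to fix for the standard load cases:
#' \describe{
#'   \item{tripod}{statically determinate 3-2-1 support on the base plane;
#'     removes the six rigid-body modes without restraining deformation
#'     (free-stroke case)}
#'   \item{base_fixed}{all mechanical DOFs on the base plane (mastoid
#'     anchoring)}
#'   \item{blocked}{base and tip planes axially blocked and all four lateral
#'     faces roller-constrained in their normal direction (blocked-force
#'     case, uniform-field condition)}
#' }
#'
#' @param mesh a [stack_mesh]
#' @param type one of "tripod", "base_fixed", "blocked"
#' @return integer vector of global DOF indices
#' @export
stack_supports <- function(mesh, type = c("tripod", "base_fixed", "blocked")) {
  type <- match.arg(type)
  nodes <- mesh$nodes
  tol <- 1e-12 + 1e-9 * max(nodes)
  on_plane <- function(col, val) which(abs(nodes[, col] - val) < tol)
  base <- on_plane(3, 0)
  tip <- on_plane(3, max(nodes[, 3]))

  if (type == "base_fixed") return(mech_dofs(base))
  if (type == "tripod") {
    near <- function(x, y) {
      d <- (nodes[base, 1] - x)^2 + (nodes[base, 2] - y)^2
      base[which.min(d)]
    }
    nA <- near(0, 0)
    nB <- near(max(nodes[, 1]), 0)
    nC <- near(0, max(nodes[, 2]))
    return(c(mech_dofs(nA, 1:3), mech_dofs(nB, 2:3), mech_dofs(nC, 3)))
  }
  # blocked: uz on base and tip, normal rollers on the four lateral faces
  fixed <- c(mech_dofs(base, 3), mech_dofs(tip, 3),
             mech_dofs(on_plane(1, 0), 1),
             mech_dofs(on_plane(1, max(nodes[, 1])), 1),
             mech_dofs(on_plane(2, 0), 2),
             mech_dofs(on_plane(2, max(nodes[, 2])), 2))
  unique(fixed)
}
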