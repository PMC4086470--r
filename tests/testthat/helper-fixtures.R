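# Shared fixtures: small stacks, a single-DOF oscillator routed through the
# same constrained-system machinery as the FEM models, and mesh probes.

small_stack <- function(n = 3, layer_t = 0.5e-3, refinement = c(1, 1, 1),
                        mat = pzt4(), beta = 1e-4) {
  mesh <- mesh_stack(stack_spec(n, layer_t, 2e-3, 2e-3, refinement))
  assemble_stack(mesh, mat, beta = beta)
}

# purely elastic anisotropic material: PZT-4 stiffness with zero coupling
pzt4_uncoupled <- function() {
  build_piezo_constitutive(139, 77.8, 74.3, 115, 25.6, 30.6,
                           e15 = 0, e31 = 0, e33 = 0,
                           eps11_rel = 370, eps33_rel = 635, rho = 7500)
}

# single-DOF oscillator m x'' + c x' + k x = F as a sparse 'system'
sdof_system <- function(m, k, beta) {
  list(K = Matrix::sparseMatrix(i = 1, j = 1, x = k, dims = c(1, 1)),
       M = Matrix::sparseMatrix(i = 1, j = 1, x = m, dims = c(1, 1)),
       C = Matrix::sparseMatrix(i = 1, j = 1, x = beta * k, dims = c(1, 1)),
       ndof = 1L)
}

tip_nodes <- function(mesh)
  which(abs(mesh$nodes[, 3] - max(mesh$nodes[, 3])) < 1e-12)
base_nodes <- function(mesh) which(mesh$nodes[, 3] < 1e-12)

node_uz <- function(mesh, x) x[seq(3, 3 * nrow(mesh$nodes), 3)]

# mean tip-minus-base axial elongation of a solved stack
stack_elongation <- function(mesh, x) {
  uz <- node_uz(mesh, x)
  mean(uz[tip_nodes(mesh)]) - mean(uz[base_nodes(mesh)])
}

# summed axial support reaction over the tip plane of a blocked stack
tip_reaction <- function(sys, cs, sol) {
  dofs <- ossidrive:::mech_dofs(tip_nodes(sys$mesh), 3)
  rows <- match(cs$red_of_full[dofs], cs$p_idx)
  sum(sol$reactions[rows])
}

# transversely isotropic closed form for d33, the independent oracle for
# the strain-constant derivation (GPa inputs, C/m^2, result C/N)
d33_closed_form <- function(c11 = 139, c12 = 77.8, c13 = 74.3, c33 = 115,
                            e31 = -5.2, e33 = 15.1) {
  (e33 * (c11 + c12) - 2 * e31 * c13) /
    ((c11 + c12) * c33 - 2 * c13^2) / 1e9
}
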