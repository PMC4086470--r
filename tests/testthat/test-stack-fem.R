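test_that("structured stack meshes have the expected counts and geometry", {
  # the designed device: 50 layers of 40 um, 2 x 2 mm cross-section
  mesh50 <- mesh_stack(stack_spec(50, 0.04e-3, 2e-3, 2e-3))
  expect_length(mesh50$electrode_sets, 51)
  expect_equal(max(mesh50$nodes[, 3]), 2e-3)
  expect_equal(nrow(mesh50$nodes), 2 * 2 * 51)

  # single layer: a parallel-plate capacitor geometry
  mesh1 <- mesh_stack(stack_spec(1, 2e-3, 2e-3, 2e-3))
  expect_length(mesh1$electrode_sets, 2)

  # structured-grid node count (a+1)(b+1)(n c + 1)
  m <- mesh_stack(stack_spec(4, 0.5e-3, 2e-3, 2e-3, refinement = c(2, 3, 2)))
  expect_equal(nrow(m$nodes), 3 * 4 * (4 * 2 + 1))
  expect_equal(nrow(m$elements), 2 * 3 * 2 * 4)

  # poling alternates between adjacent layers
  s <- tapply(m$poling_sign, m$element_layer, unique)
  expect_equal(as.vector(s), c(-1, 1, -1, 1))
  # each element has one layer; interface sets are coplanar
  for (k in seq_along(m$electrode_sets)) {
    z <- m$nodes[m$electrode_sets[[k]], 3]
    expect_lt(diff(range(z)), 1e-15)
  }
  expect_error(stack_spec(4, 0.5e-3, refinement = c(0, 1, 1)), "refinement")
})

test_that("element matrices satisfy symmetry, nullspace and mass conservation", {
  mesh <- mesh_stack(stack_spec(1, 0.4e-3, 2e-3, 2e-3))
  coords <- mesh$nodes[mesh$elements[1, ], ]
  em <- element_matrices(coords, pzt4())

  expect_true(isSymmetric(em$Kuu, tol = 1e-9))
  expect_true(isSymmetric(em$Kpp, tol = 1e-9))
  # rigid translations in the stiffness nullspace
  for (comp in 1:3) {
    v <- rep(0, 24); v[seq(comp, 24, 3)] <- 1
    expect_lt(max(abs(em$Kuu %*% v)), 1e-3 * max(abs(em$Kuu)))
  }
  # consistent mass preserves total mass rho * V per direction
  vol <- 2e-3 * 2e-3 * 0.4e-3
  for (comp in 1:3) {
    v <- rep(0, 24); v[seq(comp, 24, 3)] <- 1
    expect_equal(sum(v %*% em$Muu %*% v), 7500 * vol, tolerance = 1e-10)
  }
  expect_equal(em$volume, vol, tolerance = 1e-12)

  # inverted geometry (negative Jacobian) rejected
  bad <- coords[c(5:8, 1:4), ]
  expect_error(element_matrices(bad, pzt4()), "Jacobian")
})

test_that("single uncoupled element reproduces the parallel-plate capacitance", {
  sys <- small_stack(n = 1, layer_t = 0.4e-3, mat = pzt4_uncoupled())
  cm <- model_capacitance(sys)
  c_plate <- 635 * EPS0 * (2e-3 * 2e-3) / 0.4e-3
  expect_equal(cm$clamped, c_plate, tolerance = 1e-10)
  # with zero coupling the free capacitance equals the clamped one
  expect_equal(cm$free, cm$clamped, tolerance = 1e-10)
})

test_that("assembly yields a symmetric block system with C = beta K on the mechanical block", {
  sys <- small_stack(n = 3, beta = 1e-4)
  expect_true(Matrix::isSymmetric(sys$K))
  expect_true(Matrix::isSymmetric(sys$M))
  mech <- seq_len(3 * sys$n_nodes)
  expect_equal(as.matrix(sys$C[mech, mech]),
               1e-4 * as.matrix(sys$K[mech, mech]), tolerance = 1e-12)
  # no damping or mass on the potential block
  pot <- 3 * sys$n_nodes + seq_len(sys$n_nodes)
  expect_equal(Matrix::norm(sys$C[pot, pot], "F"), 0)
  expect_equal(Matrix::norm(sys$M[pot, pot], "F"), 0)

  sys0 <- small_stack(n = 3, beta = 0)
  expect_equal(Matrix::norm(sys0$C, "F"), 0)
})

test_that("two stacked elastic elements behave as springs in series", {
  # uncoupled ceramic, lateral rollers: pure uniaxial strain, so each
  # element layer is a spring c33 A / t and the chain is their series
  sys <- small_stack(n = 2, layer_t = 0.5e-3, mat = pzt4_uncoupled())
  mesh <- sys$mesh
  supports <- setdiff(stack_supports(mesh, "blocked"),
                      ossidrive:::mech_dofs(tip_nodes(mesh), 3))
  cs <- apply_electrodes(sys, 0, fixed_dofs = supports)
  F_tip <- 1e-3
  F <- numeric(sys$ndof)
  tip_dofs <- ossidrive:::mech_dofs(tip_nodes(mesh), 3)
  F[tip_dofs] <- F_tip / length(tip_dofs)
  sol <- solve_static(cs, F = F)
  k_series <- 115e9 * (2e-3 * 2e-3) / 1e-3   # c33 A / (2 t)
  uz <- node_uz(mesh, sol$x)
  expect_equal(mean(uz[tip_nodes(mesh)]), F_tip / k_series,
               tolerance = 1e-9)
  # mid-plane carries half the tip displacement: the series pattern
  mid <- which(abs(mesh$nodes[, 3] - 0.5e-3) < 1e-12)
  expect_equal(mean(uz[mid]), 0.5 * F_tip / k_series, tolerance = 1e-9)
})

test_that("electrode constraints enforce equipotential interfaces and the safety warning", {
  sys <- small_stack(n = 2, refinement = c(2, 2, 2))
  cs <- apply_electrodes(sys, 5)
  cs <- apply_electrodes(sys, 5,
                         fixed_dofs = stack_supports(sys$mesh, "tripod"))
  sol <- solve_static(cs)
  phi <- sol$x[3 * sys$n_nodes + seq_len(sys$n_nodes)]
  for (k in seq_along(sys$mesh$electrode_sets)) {
    v <- phi[sys$mesh$electrode_sets[[k]]]
    expect_lt(diff(range(v)), 1e-12)
    expect_equal(unique(round(v, 9)),
                 if (sys$mesh$electrode_polarity[k] == "driven") 5 else 0)
  }
  expect_warning(apply_electrodes(sys, 10.6), "safety")
  # 10.5 V is the boundary case: no warning
  expect_no_warning(apply_electrodes(sys, 10.5))

  # zero drive gives the zero solution
  cs0 <- apply_electrodes(sys, 0,
                          fixed_dofs = stack_supports(sys$mesh, "tripod"))
  expect_equal(max(abs(solve_static(cs0)$x)), 0)
})

test_that("static FEM matches the free-stroke and blocked-force closed forms", {
  mat <- pzt4()
  d33 <- derive_strain_constants(mat)[3, 3]
  for (n in c(2, 3)) {
    sys <- small_stack(n = n, layer_t = 0.4e-3, refinement = c(2, 2, 2))
    mesh <- sys$mesh
    V <- 4
    cs <- apply_electrodes(sys, V, fixed_dofs = stack_supports(mesh, "tripod"))
    sol <- solve_static(cs)
    expect_equal(stack_elongation(mesh, sol$x), n * d33 * V,
                 tolerance = 0.01)

    csb <- apply_electrodes(sys, V, fixed_dofs = stack_supports(mesh, "blocked"))
    solb <- solve_static(csb)
    f_expected <- (2e-3 * 2e-3) * mat$e[3, 3] * V / 0.4e-3
    expect_equal(abs(tip_reaction(sys, csb, solb)), f_expected,
                 tolerance = 0.01)
  }
})

test_that("static response is linear in the drive voltage", {
  sys <- small_stack(n = 2)
  fx <- stack_supports(sys$mesh, "tripod")
  x1 <- solve_static(apply_electrodes(sys, 1, fixed_dofs = fx))$x
  x2 <- solve_static(apply_electrodes(sys, 2, fixed_dofs = fx))$x
  expect_equal(x2, 2 * x1, tolerance = 1e-12)
})

test_that("an unconstrained static system is reported as singular", {
  sys <- small_stack(n = 2)
  cs <- apply_electrodes(sys, 1)   # no mechanical supports
  expect_error(solve_static(cs), "rigid-body")
})

test_that("harmonic solution approaches the static one at vanishing frequency", {
  sys <- small_stack(n = 2)
  fx <- stack_supports(sys$mesh, "base_fixed")
  cs <- apply_electrodes(sys, 3, fixed_dofs = fx)
  xs <- solve_static(cs)$x
  sw <- solve_harmonic(cs, 0.01)
  expect_equal(Re(sw$X[, 1]), xs, tolerance = 1e-6)
  expect_lt(max(Mod(sw$X[, 1] - xs)) / max(abs(xs)), 1e-6)
})

test_that("harmonic magnitudes scale linearly with voltage", {
  sys <- small_stack(n = 2)
  fx <- stack_supports(sys$mesh, "base_fixed")
  f <- c(500, 2000, 8000)
  s1 <- solve_harmonic(apply_electrodes(sys, 1, fixed_dofs = fx), f)
  s3 <- solve_harmonic(apply_electrodes(sys, 3, fixed_dofs = fx), f)
  expect_equal(s3$X, 3 * s1$X, tolerance = 1e-10)
})

test_that("harmonic solve satisfies the complex residual at every frequency", {
  sys <- small_stack(n = 2, refinement = c(2, 2, 1))
  fx <- stack_supports(sys$mesh, "base_fixed")
  cs <- apply_electrodes(sys, 2, fixed_dofs = fx)
  freqs <- c(160, 1000, 8000)
  sw <- solve_harmonic(cs, freqs)
  for (k in seq_along(freqs)) {
    w <- 2 * pi * freqs[k]
    # recover the reduced vector (all members of a tie share one value)
    cnt <- Matrix::colSums(cs$T)
    xr <- complex(
      real = as.vector(Matrix::crossprod(cs$T, Re(sw$X[, k]))) / cnt,
      imaginary = as.vector(Matrix::crossprod(cs$T, Im(sw$X[, k]))) / cnt)
    A <- cs$K[cs$free, ] - w^2 * cs$M[cs$free, ]
    B <- w * cs$C[cs$free, ]
    r <- complex(
      real = as.vector(A %*% Re(xr)) - as.vector(B %*% Im(xr)),
      imaginary = as.vector(A %*% Im(xr)) + as.vector(B %*% Re(xr)))
    scale <- max(Mod(complex(real = as.vector(cs$K %*% Re(xr)),
                             imaginary = as.vector(cs$K %*% Im(xr)))))
    expect_lt(max(Mod(r)) / scale, 1e-8)
  }
})

test_that("undamped resonance of an oscillator raises an informative error", {
  m <- 1e-3; k <- 1e3
  sys <- sdof_system(m, k, beta = 0)
  cs <- constrain_system(sys)
  fn <- sqrt(k / m) / (2 * pi)
  expect_error(solve_harmonic(cs, fn, F = 1), "undamped resonance")
})

test_that("clamped capacitance converges to the layer formula under refinement", {
  errs <- vapply(list(c(1, 1, 1), c(2, 2, 1), c(3, 3, 1)), function(r) {
    sys <- small_stack(n = 2, layer_t = 0.4e-3, refinement = r)
    cm <- model_capacitance(sys)
    abs(cm$clamped / stack_capacitance(2, 635, 4e-6, 0.4e-3) - 1)
  }, numeric(1))
  expect_true(all(errs < 1e-6))
  expect_true(all(diff(errs) <= 1e-12))  # non-increasing with refinement
})

test_that("capacitance scales with area and coupling raises the free value", {
  sys_a <- small_stack(n = 2)
  mesh_b <- mesh_stack(stack_spec(2, 0.5e-3, 4e-3, 2e-3))
  sys_b <- assemble_stack(mesh_b, pzt4())
  ca <- model_capacitance(sys_a)
  cb <- model_capacitance(sys_b)
  expect_equal(cb$clamped, 2 * ca$clamped, tolerance = 1e-9)
  expect_equal(cb$free, 2 * ca$free, tolerance = 1e-6)
  expect_gt(ca$free, ca$clamped)
})

test_that("terminal electrical power is non-negative across a sweep (passivity)", {
  sys <- small_stack(n = 3)
  cs <- apply_electrodes(sys, 2, fixed_dofs = stack_supports(sys$mesh, "base_fixed"))
  freqs <- default_frequency_grid(10)
  sw <- solve_harmonic(cs, freqs)
  driven <- cs$electrode_masters[cs$electrode_polarity == "driven"]
  rows <- match(driven, cs$p_idx)
  for (k in seq_along(freqs)) {
    q <- -sum(sw$reactions[rows, k])     # terminal charge phasor
    w <- 2 * pi * freqs[k]
    p_active <- Re(2 * Conj(1i * w * q))  # V = 2 volts, real
    expect_gte(p_active, -1e-10)
  }
})
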