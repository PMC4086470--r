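# Coupled transducer / rod / middle-ear model. Unit tests run on reduced
# stacks (few layers, coarse frequency grids); the full design-study sizes
# live in the acceptance tests.

test_that("rod chain reproduces the series-spring identity", {
  spec <- rod_spec()   # 0.5 mm dia x 2.0 mm, titanium, 6 elements
  rod <- build_rod(spec)
  k_hand <- 116e9 * pi * (0.25e-3)^2 / 2.0e-3   # = 1.1388271e7 N/m
  expect_equal(rod$k_total, k_hand, tolerance = 1e-12)
  expect_equal(rod$k_total, 1.1388273e7, tolerance = 1e-6)

  # static tip stiffness independent of discretisation: condense the chain
  # to its tip DOF with the base clamped
  tip_stiffness <- function(rod) {
    n <- rod$n_nodes
    Kff <- rod$K[-1, -1, drop = FALSE]
    u <- solve(Kff, c(rep(0, n - 2), 1))   # unit tip force
    1 / u[n - 1]
  }
  expect_equal(tip_stiffness(build_rod(rod_spec(n_elements = 1))),
               tip_stiffness(build_rod(rod_spec(n_elements = 6))),
               tolerance = 1e-9)
  # consistent mass preserves rho A L
  expect_equal(sum(rod$M), 4500 * pi * (0.25e-3)^2 * 2e-3, tolerance = 1e-12)
})

test_that("coupling bookkeeping: DOF counts, junction ties, symmetry", {
  sys <- small_stack(n = 2)
  net <- build_default_network()
  direct <- couple(sys, NULL, net, with_rod = FALSE)
  expect_equal(direct$system$ndof, sys$ndof + 4)
  withrod <- couple(sys, build_rod(rod_spec()), net, with_rod = TRUE)
  expect_equal(withrod$system$ndof, sys$ndof + 7 + 4)
  expect_true(Matrix::isSymmetric(withrod$system$K))
  expect_error(couple(sys, NULL, net, with_rod = TRUE), "rod")
})

test_that("zero drive produces zero response everywhere", {
  sys <- small_stack(n = 2)
  model <- couple(sys, build_rod(rod_spec()), build_default_network(),
                  with_rod = TRUE)
  cs <- ossidrive:::constrain_coupled(model, 0)
  sw <- solve_harmonic(cs, c(500, 2000))
  expect_equal(max(Mod(sw$X)), 0)
})

test_that("transducer-driven spectrum is linear in voltage and finite", {
  sys <- small_stack(n = 4, layer_t = 0.25e-3)
  model <- couple(sys, build_rod(rod_spec()), build_default_network(),
                  with_rod = TRUE)
  freq <- default_frequency_grid(8)
  d1 <- transducer_drive(model, 1, freq)
  d4 <- transducer_drive(model, 4, freq)
  expect_true(all(is.finite(Mod(d1$displacement))))
  expect_true(all(Mod(d1$displacement) > 0))
  expect_equal(Mod(d4$displacement), 4 * Mod(d1$displacement),
               tolerance = 1e-10)
})

test_that("a very stiff rod converges to the rigid junction", {
  sys <- small_stack(n = 3)
  net <- build_default_network()
  freq <- default_frequency_grid(10)
  direct <- couple(sys, NULL, net, with_rod = FALSE)
  stiff <- couple(sys, build_rod(rod_spec(youngs_modulus = 1e15)), net,
                  with_rod = TRUE)
  d0 <- Mod(transducer_drive(direct, 5, freq)$displacement)
  d1 <- Mod(transducer_drive(stiff, 5, freq)$displacement)
  expect_lt(max(abs(20 * log10(d1 / d0))), 0.1)
})

test_that("stapes output strictly increases with layer count at fixed envelope", {
  freq <- c(200, 1000, 6000)
  st <- layer_number_study(c(4, 8), v_rms = 5, frequencies = freq,
                           total_thickness = 2e-3)
  d4 <- st$d_tr_m[st$n_layers == 4]
  d8 <- st$d_tr_m[st$n_layers == 8]
  expect_true(all(d8 > d4))
  # doubling n doubles the quasi-static stroke: +6 dB below resonance
  expect_equal(20 * log10(d8[1] / d4[1]), 6.0206, tolerance = 0.5 / 6)
  # Peq increases in n at every frequency
  expect_true(all(st$peq_db[st$n_layers == 8] > st$peq_db[st$n_layers == 4]))
  expect_equal(nrow(st), 2 * length(freq))
})

test_that("rod penalty ordering: compliant rods cost more, identical spectra cost nothing", {
  freq <- default_frequency_grid(10)
  st <- rod_stiffness_study(c(titanium = 116e9, ceramic = 510e9),
                            v_rms = 5, frequencies = freq,
                            stack = stack_spec(4, 0.5e-3))
  s <- st$summary
  expect_gte(s$max_drop_db[s$variant == "titanium"],
             s$max_drop_db[s$variant == "ceramic"])
  expect_gte(min(s$max_drop_db), 0)   # insertion always costs somewhere

  rigid <- rod_stiffness_study(c(rigid = 1e15), v_rms = 5,
                               frequencies = freq,
                               stack = stack_spec(4, 0.5e-3))
  expect_lt(max(abs(rigid$spectra$delta_h_db)), 0.5)
})

test_that("coupled model with zero voltage is stable (passive free decay)", {
  sys <- small_stack(n = 2)
  model <- couple(sys, build_rod(rod_spec()), build_default_network(),
                  with_rod = TRUE)
  cs <- ossidrive:::constrain_coupled(model, 0)
  f <- cs$free
  K <- as.matrix(cs$K[f, f]); M <- as.matrix(cs$M[f, f])
  C <- as.matrix(cs$C[f, f])
  # mechanical sub-block only: drop potential DOFs (no mass), i.e. rows
  # with non-zero mass
  mech <- which(diag(M) > 0)
  Kc <- if (length(mech) < nrow(K))
    K[mech, mech] - K[mech, -mech] %*% solve(K[-mech, -mech], K[-mech, mech])
  else K
  Minv <- solve(M[mech, mech])
  A <- rbind(cbind(0 * Kc, diag(nrow(Kc))),
             cbind(-Minv %*% Kc, -Minv %*% C[mech, mech]))
  expect_true(all(Re(eigen(A, only.values = TRUE)$values) <= 1e-6))
})
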