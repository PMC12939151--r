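test_that("Numerov kinetic matrix differentiates a sine mode analytically", {
  n <- 2000
  g <- spatial_grid(0, 1, n)
  K <- numerov_kinetic(g)
  # exact eigenmode of the discrete Dirichlet problem: walls one spacing
  # outside the grid, box length L_eff
  L_eff <- 1 + 2 * g$dx
  v <- sin(pi * (g$x + g$dx) / L_eff)
  expect_lt(max(abs(K %*% v - (pi^2 / (2 * L_eff^2)) * v)) /
              (pi^2 / (2 * L_eff^2)), 1e-8)
  expect_identical(K, t(K))  # symmetrized exactly
  # second difference of a constant vanishes in the interior (B^-1 spreads
  # the boundary rows inward with geometric decay, so stand clear of them)
  Kc <- as.vector(K %*% rep(1, n))
  expect_lt(max(abs(Kc[16:(n - 15)])) * g$dx^2, 1e-9)
})

test_that("Hamiltonian assembly is linear in alpha and exactly symmetric", {
  s <- asym_spec()
  g <- grid_for_spec(s, 64)
  K <- numerov_kinetic(g)
  pot <- potential_on_grid(s, g)
  H0 <- assemble_hamiltonian(K, pot, 0)
  expect_equal(H0$matrix, diag(pot$values))      # alpha = 0: pure potential
  H1 <- assemble_hamiltonian(K, pot, 1.7)
  expect_equal(diag(H1$matrix), 1.7 * diag(K) + pot$values)
  H2 <- assemble_hamiltonian(K, pot, 3.4)
  expect_equal(H2$matrix - diag(pot$values),
               2 * (H1$matrix - diag(pot$values)))
  expect_identical(H1$matrix, t(H1$matrix))
  expect_error(assemble_hamiltonian(K[1:10, 1:10], pot, 1), "dimension")
  expect_error(assemble_hamiltonian(K, pot, -1), "nonnegative")
})

test_that("box spectrum approaches the particle-in-a-box ladder", {
  s <- box_spec()
  g <- grid_for_spec(s, 500)
  H <- assemble_hamiltonian(numerov_kinetic(g), potential_on_grid(s, g), 1)
  eig <- bound_eigensystem(H)
  # E_k ~ 0.077 k^2 on this box, so exactly k = 1..3 fit below Eb = 1
  expect_identical(eig$n_states, 3L)
  exact <- box_energies(g, 1, 1:3)
  expect_lt(max(abs(eig$energies[1:3] - exact) / exact), 1e-4)
  # retained energies ascending, all below the cutoff, states orthonormal
  expect_true(all(diff(eig$energies) > 0))
  expect_true(all(eig$energies < eig$Eb_cutoff))
  Gram <- crossprod(eig$states)
  expect_lt(max(abs(Gram - diag(eig$n_states))), 1e-8)
  expect_equal(eig$delta, max(diff(eig$energies)))
})

test_that("eigenvalue convergence to the box ladder is high order", {
  err_at <- function(n) {
    g <- grid_for_spec(box_spec(), n)
    H <- assemble_hamiltonian(numerov_kinetic(g), potential_on_grid(box_spec(), g), 1)
    e1 <- bound_eigensystem(H)$energies[1]
    abs(e1 - box_energies(g, 1, 1)) / box_energies(g, 1, 1)
  }
  # fourth-order scheme: halving dx should cut the error by >> 2^2
  expect_gt(err_at(100) / err_at(200), 4)
})

test_that("cutoff below the ground energy yields an empty spectrum", {
  s <- box_spec()
  g <- grid_for_spec(s, 200)
  H <- assemble_hamiltonian(numerov_kinetic(g), potential_on_grid(s, g), 1)
  eig <- bound_eigensystem(H, Eb = 1e-6)
  expect_equal(eig$n_states, 0L)
  expect_equal(eig$delta, 0)
  expect_length(eig$energies, 0)
})

test_that("deep single well matches the finite-well transcendental oracle", {
  # m_gap = 0 and equal depths merge the two wells into one of width 2w;
  # distant hard walls (large e at the barrier energy) emulate the infinite
  # domain of the textbook solution
  alpha <- 0.05
  s <- well_spec(Eb = 1, EwL = 0, EwR = 0, Em = 0, w = 1.5, e = 5,
                 m_gap = 0, E_edge = 1)
  g <- grid_for_spec(s, 800)
  H <- assemble_hamiltonian(numerov_kinetic(g), potential_on_grid(s, g), alpha)
  eig <- bound_eigensystem(H)
  oracle <- finite_well_bound_energies(V0 = 1, a = 3, alpha = alpha)
  expect_equal(eig$n_states, length(oracle))
  # sharp potential edges fall between grid points, so the effective well
  # width carries an O(dx) offset and energies converge linearly (~0.4%
  # here), unlike the fourth-order smooth-box case
  expect_lt(max(abs(eig$energies - oracle) / oracle), 0.01)

  # ground-state probability mass inside the well matches the analytic value
  sets <- well_index_sets(s, g)
  ground <- quantum_state(eig$states[, 1], g)
  mass <- mie(ground, c(sets$left, sets$right))
  expect_gt(mass, 0.9)
  expect_lt(abs(mass - finite_well_ground_mass_inside(1, 3, alpha)), 0.02)
})

test_that("eigenvectors of symmetric landscapes have definite parity", {
  s <- sym_spec()
  g <- grid_for_spec(s, 129)
  H <- assemble_hamiltonian(numerov_kinetic(g), potential_on_grid(s, g), 0.02)
  eig <- bound_eigensystem(H)
  expect_gt(eig$n_states, 2)
  for (j in seq_len(eig$n_states)) {
    v <- eig$states[, j]
    expect_lt(min(max(abs(v - rev(v))), max(abs(v + rev(v)))), 1e-6)
  }
})

test_that("uniform start is neutral and normalized", {
  g4 <- spatial_grid(0, 1, 4)
  psi <- uniform_initial_state(g4)
  expect_equal(psi$amplitudes, rep(0.5 + 0i, 4))
  for (n in c(5, 33, 256))
    expect_equal(sum(Mod(uniform_initial_state(spatial_grid(0, 1, n))$amplitudes)^2), 1)
  s <- sym_spec()
  g <- grid_for_spec(s, 100)
  sets <- well_index_sets(s, g)
  psi0 <- uniform_initial_state(g)
  expect_equal(mie(psi0, sets$left), mie(psi0, sets$right))
})

test_that("propagation is the identity at t = 0 and composes over time", {
  s <- asym_spec()
  g <- grid_for_spec(s, 96)
  H <- assemble_hamiltonian(numerov_kinetic(g), potential_on_grid(s, g), 5)
  he <- hamiltonian_eigen(H)
  psi0 <- uniform_initial_state(g)
  expect_lt(max(Mod(propagate(he, psi0, 0)$amplitudes - psi0$amplitudes)), 1e-12)
  # group property
  ab <- propagate(he, propagate(he, psi0, 0.21), 0.34)
  once <- propagate(he, psi0, 0.55)
  expect_lt(max(Mod(ab$amplitudes - once$amplitudes)), 1e-8)
  # an eigenstate only acquires a global phase
  eig <- bound_eigensystem(H)
  if (eig$n_states > 0) {
    st <- quantum_state(eig$states[, 1], g)
    ev <- propagate(he, st, 2.5)
    expect_equal(Mod(sum(Conj(st$amplitudes) * ev$amplitudes)), 1,
                 tolerance = 1e-10)
  }
  expect_error(propagate(he, psi0, Inf), "finite")
  expect_error(propagate(he, psi0, -1), "nonnegative")
})

test_that("evolution preserves the norm across landscapes and scales", {
  for (spec in random_well_spec(8, seed = 2024)) {
    g <- grid_for_spec(spec, 64)
    pot <- potential_on_grid(spec, g)
    K <- numerov_kinetic(g)
    psi0 <- uniform_initial_state(g)
    for (alpha in c(0.1, 10)) {
      he <- hamiltonian_eigen(assemble_hamiltonian(K, pot, alpha))
      for (t in c(0.3, 7)) {
        psi <- propagate(he, psi0, t)
        expect_lt(abs(sum(Mod(psi$amplitudes)^2) - 1), 1e-10)
      }
    }
  }
})

test_that("eigensystem export writes readable delimited files", {
  s <- asym_spec()
  g <- grid_for_spec(s, 64)
  eig <- bound_eigensystem(
    assemble_hamiltonian(numerov_kinetic(g), potential_on_grid(s, g), 0.02))
  prefix <- file.path(withr::local_tempdir(), "eig")
  files <- export_eigensystem(eig, prefix)
  expect_true(all(file.exists(files)))
  en <- utils::read.csv(files[1])
  st <- utils::read.csv(files[2])
  expect_equal(en$energy, eig$energies)
  expect_equal(dim(st), c(64L, eig$n_states))
})
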