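# Perturbed Matrix Method engine

test_that("Coulomb site potentials follow the atomic-unit convention", {
  bohr_in_ang <- 1 / 1.8897259886
  v <- site_potentials(matrix(c(bohr_in_ang, 0, 0), 1, 3), 1, matrix(0, 1, 3))
  expect_equal(v, 1.0, tolerance = 1e-12)

  # two opposite charges symmetric about the site cancel
  v0 <- site_potentials(rbind(c(2, 0, 0), c(-2, 0, 0)), c(0.7, -0.7),
                        matrix(0, 1, 3))
  expect_equal(v0, 0, tolerance = 1e-14)

  # brute-force double loop agrees to 1e-12
  set.seed(51)
  qxyz <- 6 + matrix(rnorm(60), 20, 3)
  q <- rnorm(20)
  sites <- matrix(rnorm(9), 3, 3)
  v <- site_potentials(qxyz, q, sites)
  brute <- sapply(1:3, function(a) {
    acc <- 0
    for (s in 1:20) {
      acc <- acc + q[s] / (sqrt(sum((sites[a, ] - qxyz[s, ])^2)) * 1.8897259886)
    }
    acc
  })
  expect_equal(v, brute, tolerance = 1e-12)

  expect_error(site_potentials(matrix(0.01, 1, 3), 1, matrix(0, 1, 3)),
               "singularity|within 0.1")
})

test_that("zero perturbation reproduces the reference spectrum exactly", {
  ref <- gen_qm_reference(n_states = 11, n_atoms = 6, seed = 52)
  H <- build_perturbed_hamiltonian(ref, ref$ref_potentials)
  expect_equal(H, diag(ref$energies), tolerance = 1e-15, ignore_attr = TRUE)
  r <- diagonalize_pmm(H, ref)
  expect_equal(r$excitation_energies, ref$energies - ref$energies[1],
               tolerance = 1e-12)
})

test_that("a 2-state system matches the closed-form 2x2 eigenvalues", {
  # closed form: E_pm = mean(diag) +/- sqrt(delta^2 + c^2)
  e <- c(0, 0.10)
  qarr <- array(0, dim = c(2, 2, 2))
  qarr[1, 1, ] <- c(0.3, -0.3)
  qarr[2, 2, ] <- c(-0.2, 0.2)
  od <- c(0.15, -0.15)
  qarr[1, 2, ] <- od; qarr[2, 1, ] <- od
  ref <- qm_reference(e, qarr, rbind(c(0, 0, 0), c(1, 0, 0)), c(0, 0))
  dV <- c(0.02, -0.01)
  H <- build_perturbed_hamiltonian(ref, dV)
  diag_terms <- e + c(sum(qarr[1, 1, ] * dV), sum(qarr[2, 2, ] * dV))
  c_od <- sum(od * dV)
  mean_d <- mean(diag_terms)
  delta <- (diag_terms[2] - diag_terms[1]) / 2
  closed <- c(mean_d - sqrt(delta^2 + c_od^2), mean_d + sqrt(delta^2 + c_od^2))
  r <- diagonalize_pmm(H, ref)
  expect_equal(r$eigenvalues, closed, tolerance = 1e-14)

  # scaling dV scales the off-diagonal coupling linearly
  H2 <- build_perturbed_hamiltonian(ref, 3 * dV)
  expect_equal(H2[1, 2], 3 * H[1, 2], tolerance = 1e-14)
})

test_that("Weyl bound and trace conservation hold over seeded references", {
  for (s in 1:1000) {
    set.seed(600 + s)
    ref <- gen_qm_reference(n_states = 6, n_atoms = 5, coupling_scale = 0.1,
                            seed = 600 + s)
    dV <- rnorm(5, 0, 0.02)
    H <- build_perturbed_hamiltonian(ref, dV)
    r <- diagonalize_pmm(H, ref)
    dH_norm <- max(abs(eigen(H - diag(ref$energies), symmetric = TRUE,
                             only.values = TRUE)$values))
    expect_true(all(abs(r$eigenvalues - ref$energies) <= dH_norm + 1e-12))
    expect_equal(sum(r$eigenvalues), sum(diag(H)),
                 tolerance = 1e-10 * max(1, abs(sum(diag(H)))))
  }
})

test_that("oscillator strengths are non-negative and vanish without coupling", {
  ref <- gen_qm_reference(n_states = 8, n_atoms = 4, coupling_scale = 0,
                          seed = 53)
  # coupling_scale = 0 decouples the solute: any solvent configuration
  # returns the reference energies
  V <- rnorm(4, 0, 0.1)
  r <- diagonalize_pmm(build_perturbed_hamiltonian(ref, V), ref)
  expect_equal(r$excitation_energies, ref$energies - ref$energies[1],
               tolerance = 1e-12)
  expect_true(all(r$oscillator_strengths >= 0))
})

test_that("QM reference files round-trip all blocks", {
  ref <- gen_qm_reference(n_states = 5, n_atoms = 3, seed = 54,
                          ref_potentials = c(0.01, -0.02, 0.005))
  path <- withr::local_tempfile(fileext = ".dat")
  write_qm_reference(ref, path)
  back <- read_qm_reference(path)
  expect_equal(back$energies, ref$energies, tolerance = 1e-10)
  expect_equal(back$transition_charges, ref$transition_charges,
               tolerance = 1e-10)
  expect_equal(back$transition_dipoles, ref$transition_dipoles,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(back$ref_potentials, ref$ref_potentials, tolerance = 1e-10)
})

test_that("constructor enforces symmetry and charge sum rules", {
  qarr <- array(0, dim = c(2, 2, 2))
  qarr[1, 2, ] <- c(0.1, 0)  # asymmetric
  expect_error(qm_reference(c(0, 0.1), qarr, matrix(0, 2, 3), c(0, 0)),
               "symmetric")
  qarr[2, 1, ] <- qarr[1, 2, ]
  qarr[1, 1, ] <- c(0.5, 0.1)  # sums to 0.6, not the stated total of 0
  expect_error(qm_reference(c(0, 0.1), qarr, matrix(0, 2, 3), c(0, 0)),
               "total charge")
})

test_that("pmm_trajectory converts excitations to the printed units", {
  spec <- regime_spec(list(list(hb_count = 1, r_mean = 1.8, r_sd = 0.05,
                                theta_sd = 3, dwell = 1)),
                      n_frames = 4, n_solvent = 3, seed = 55)
  g <- gen_trajectory(spec)
  a <- g$trajectory$topology$atoms
  solute_sites <- which(a$role == "solute")
  ref <- gen_qm_reference(n_states = 4, n_atoms = length(solute_sites),
                          coupling_scale = 0.02, seed = 56)
  res <- pmm_trajectory(g$trajectory, ref, solute_sites,
                        which(a$role == "solvent"))
  expect_equal(nrow(res), 4 * 3)
  expect_equal(res$wavenumber_cm1,
               res$excitation_hartree * 219474.6313632, tolerance = 1e-9)
  expect_equal(res$lambda_nm, 1e7 / res$wavenumber_cm1, tolerance = 1e-9)
  expect_true(all(res$excitation_hartree > 0))
})
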