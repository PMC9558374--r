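#' Perturbed Matrix Method engine
#'
#' The electronic problem is solved once at a reference solvent
#' configuration, giving eigenstate energies E_i, atomic transition
#' charges q_a^(ij) and transition dipoles. For every other solvent
#' configuration the perturbed Hamiltonian is built in that basis,
#' \deqn{\tilde H_{ij} = E_i \delta_{ij} + \sum_a q_a^{ij}
#'   (V_a - V_a^{ref})}
#' where V_a is the solvent electrostatic potential at solute atom a,
#' and diagonalized to obtain perturbed excitation energies and rotated
#' transition dipoles. Everything is in atomic units internally.
#'
#' @name pmm
NULL

#' Construct a QM reference set
#'
#' @param energies state energies, hartree, ascending (default 11 states:
#'   ground + 10 excited)
#' @param transition_charges numeric array [n_states, n_states, n_atoms]
#'   of atomic transition charges (e), symmetric in the state indices;
#'   each diagonal block must sum over atoms to the total molecular charge
#' @param transition_dipoles matrix [n_states, 3] of ground-to-state
#'   transition dipoles (a.u.); row 1 is the permanent ground dipole or 0
#' @param ref_potentials reference electrostatic potential at each solute
#'   atom, hartree/e
#' @param total_charge total molecular charge, e (default 0)
#' @return object of class \code{"qm_reference"}
#' @export
qm_reference <- function(energies, transition_charges, transition_dipoles,
                         ref_potentials, total_charge = 0) {
  ns <- length(energies)
  if (ns < 2) stop("qm_reference: need >= 2 states")
  if (is.unsorted(energies)) stop("qm_reference: energies must be ascending")
  d <- dim(transition_charges)
  if (length(d) != 3 || d[1] != ns || d[2] != ns) {
    stop("qm_reference: transition_charges must be [n_states, n_states, n_atoms]")
  }
  na <- d[3]
  if (length(ref_potentials) != na) {
    stop("qm_reference: ref_potentials length must equal atom count")
  }
  for (i in seq_len(ns)) {
    for (j in seq_len(i)) {
      if (max(abs(transition_charges[i, j, ] - transition_charges[j, i, ])) > 1e-9) {
        stop("qm_reference: transition charges not symmetric in (i, j)")
      }
    }
    if (abs(sum(transition_charges[i, i, ]) - total_charge) > 1e-6) {
      stop("qm_reference: diagonal charges of state ", i,
           " do not sum to the total charge")
    }
  }
  transition_dipoles <- as.matrix(transition_dipoles)
  if (nrow(transition_dipoles) != ns || ncol(transition_dipoles) != 3) {
    stop("qm_reference: transition_dipoles must be [n_states, 3]")
  }
  structure(list(n_states = ns, n_atoms = na, energies = energies,
                 transition_charges = transition_charges,
                 transition_dipoles = transition_dipoles,
                 ref_potentials = ref_potentials,
                 total_charge = total_charge),
            class = "qm_reference")
}

#' @export
print.qm_reference <- function(x, ...) {
  cat(sprintf("qm_reference: %d states, %d atoms, first excitation %.4f hartree\n",
              x$n_states, x$n_atoms, x$energies[2] - x$energies[1]))
  invisible(x)
}

#' Electrostatic potential of point charges at solute sites
#'
#' V(r_a) = sum_s q_s / |r_a - r_s| in atomic units; distances are
#' converted from angstrom to bohr at this single site. Charge sites
#' closer than 0.1 angstrom to a solute site raise a singularity error.
#'
#' @param charge_xyz n x 3 charge-site coordinates, angstrom
#' @param charges charges, elementary charges
#' @param site_xyz m x 3 solute-site coordinates, angstrom
#' @return potential at each solute site, hartree per elementary charge
#' @export
site_potentials <- function(charge_xyz, charges, site_xyz) {
  charge_xyz <- as.matrix(charge_xyz)
  site_xyz <- as.matrix(site_xyz)
  if (nrow(charge_xyz) == 0) return(rep(0, nrow(site_xyz)))
  V <- numeric(nrow(site_xyz))
  for (a in seq_len(nrow(site_xyz))) {
    d <- sqrt(colSums((t(charge_xyz) - site_xyz[a, ])^2))
    if (any(d <= 0.1)) {
      stop(sprintf("site_potentials: charge site %d within 0.1 A of solute site %d",
                   which(d <= 0.1)[1], a))
    }
    V[a] <- sum(charges / (d * ANG_TO_BOHR))
  }
  V
}

#' Build the perturbed Hamiltonian
#'
#' @param ref \code{qm_reference}
#' @param current_potentials potential at each solute atom for the
#'   current solvent configuration, hartree/e
#' @return symmetric n_states x n_states matrix, hartree
#' @export
build_perturbed_hamiltonian <- function(ref, current_potentials) {
  if (length(current_potentials) != ref$n_atoms) {
    stop("build_perturbed_hamiltonian: potential vector length mismatch")
  }
  dV <- current_potentials - ref$ref_potentials
  ns <- ref$n_states
  # contract the charge array with dV over atoms
  qmat <- matrix(ref$transition_charges, ns * ns, ref$n_atoms) %*% dV
  H <- matrix(qmat, ns, ns) + diag(ref$energies, ns)
  (H + t(H)) / 2
}

#' Diagonalize a perturbed Hamiltonian
#'
#' Eigenvalues are sorted ascending; excitation energies are E_k - E_0.
#' Perturbed ground-to-state transition dipoles are obtained by rotating
#' the reference dipole matrix with the eigenvectors; dipole blocks not
#' supplied (between excited states) are treated as zero, which affects
#' intensities, not positions. Oscillator strengths are
#' f_k = (2/3) dE_k |mu_k|^2 in atomic units.
#'
#' @param H symmetric Hamiltonian, hartree
#' @param ref \code{qm_reference}
#' @return list with \code{eigenvalues}, \code{eigenvectors} (columns),
#'   \code{excitation_energies} (hartree), \code{rotated_dipoles}
#'   ([n_states, 3], a.u.), \code{oscillator_strengths}
#' @export
diagonalize_pmm <- function(H, ref) {
  if (max(abs(H - t(H))) > 1e-9) stop("diagonalize_pmm: Hamiltonian not symmetric")
  ns <- nrow(H)
  eig <- eigen(H, symmetric = TRUE)
  ord <- order(eig$values)
  vals <- eig$values[ord]
  vecs <- eig$vectors[, ord, drop = FALSE]
  # reference dipole matrix: ground row/column from supplied dipoles,
  # excited-excited blocks zero unless provided
  excit <- vals - vals[1]
  rotated <- matrix(0, ns, 3)
  for (x in 1:3) {
    M <- matrix(0, ns, ns)
    M[1, ] <- ref$transition_dipoles[, x]
    M[, 1] <- ref$transition_dipoles[, x]
    M[1, 1] <- ref$transition_dipoles[1, x]
    rotated[, x] <- as.numeric(t(vecs[, 1]) %*% M %*% vecs)
  }
  f <- (2 / 3) * excit * rowSums(rotated^2)
  f[1] <- 0
  list(eigenvalues = vals, eigenvectors = vecs,
       excitation_energies = excit, rotated_dipoles = rotated,
       oscillator_strengths = f)
}

#' Run the PMM over trajectory frames
#'
#' For each frame, computes the solvent potential at the solute atoms,
#' builds and diagonalizes the perturbed Hamiltonian, and records the
#' perturbed excitation energies and oscillator strengths.
#'
#' @param traj trajectory
#' @param ref \code{qm_reference} (atom count = number of solute sites)
#' @param solute_sites indices of the solute atoms the reference
#'   potentials refer to
#' @param charge_sites indices of the perturbing charge sites (solvent
#'   atoms and virtual sites); their charges are read from the topology
#' @param frame_indices frames to process (default all)
#' @return data frame with columns \code{frame}, \code{state},
#'   \code{excitation_hartree}, \code{wavenumber_cm1}, \code{lambda_nm},
#'   \code{oscillator_strength}
#' @export
pmm_trajectory <- function(traj, ref, solute_sites, charge_sites,
                           frame_indices = seq_len(n_frames(traj))) {
  q <- traj$topology$atoms$charge[charge_sites]
  rows <- lapply(frame_indices, function(fi) {
    xyz <- traj$frames[[fi]]$xyz
    V <- site_potentials(xyz[charge_sites, , drop = FALSE], q,
                         xyz[solute_sites, , drop = FALSE])
    res <- diagonalize_pmm(build_perturbed_hamiltonian(ref, V), ref)
    st <- seq_len(ref$n_states - 1)
    data.frame(frame = fi, state = st,
               excitation_hartree = res$excitation_energies[st + 1],
               wavenumber_cm1 = res$excitation_energies[st + 1] * HARTREE_TO_WAVENUMBER,
               lambda_nm = hartree_to_nm(res$excitation_energies[st + 1]),
               oscillator_strength = res$oscillator_strengths[st + 1])
  })
  do.call(rbind, rows)
}

#' Read and write QM reference files
#'
#' Structured plain-text format: a header with \code{n_states},
#' \code{n_atoms}, \code{total_charge}, then blocks \code{ENERGIES}
#' (one hartree value per state), \code{TRANSITION_CHARGES} (lines
#' \code{i j a q}, 1-based upper triangle sufficient),
#' \code{DIPOLES} (lines \code{j x y z}) and \code{REF_POTENTIALS}
#' (one value per atom).
#'
#' @param path file path
#' @return \code{read_qm_reference}: a \code{qm_reference}
#' @export
read_qm_reference <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- function(key) {
    m <- grep(paste0("^", key, "\\s"), lines, value = TRUE)
    if (length(m) == 0) stop("read_qm_reference: missing header key ", key)
    as.numeric(strsplit(m[1], "\\s+")[[1]][2])
  }
  ns <- as.integer(kv("n_states"))
  na <- as.integer(kv("n_atoms"))
  qtot <- tryCatch(kv("total_charge"), error = function(e) 0)
  block <- function(name) {
    i0 <- which(lines == name)
    if (length(i0) == 0) stop("read_qm_reference: missing block ", name)
    ends <- which(lines == "END")
    i1 <- min(ends[ends > i0]) - 1
    lines[seq.int(i0 + 1, i1)]
  }
  energies <- as.numeric(block("ENERGIES"))
  if (length(energies) != ns) stop("read_qm_reference: energy count mismatch")
  qarr <- array(0, dim = c(ns, ns, na))
  for (ln in block("TRANSITION_CHARGES")) {
    v <- as.numeric(strsplit(ln, "\\s+")[[1]])
    qarr[v[1], v[2], v[3]] <- v[4]
    qarr[v[2], v[1], v[3]] <- v[4]
  }
  dip <- matrix(0, ns, 3)
  for (ln in block("DIPOLES")) {
    v <- as.numeric(strsplit(ln, "\\s+")[[1]])
    dip[v[1], ] <- v[2:4]
  }
  vref <- as.numeric(block("REF_POTENTIALS"))
  qm_reference(energies, qarr, dip, vref, total_charge = qtot)
}

#' @rdname read_qm_reference
#' @param ref \code{qm_reference} to write
#' @export
write_qm_reference <- function(ref, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("n_states %d", ref$n_states)
  w("n_atoms %d", ref$n_atoms)
  w("total_charge %.6f", ref$total_charge)
  writeLines("ENERGIES", con)
  w("%.12f", ref$energies)
  writeLines(c("END", "TRANSITION_CHARGES"), con)
  for (i in seq_len(ref$n_states)) {
    for (j in i:ref$n_states) {
      for (a in seq_len(ref$n_atoms)) {
        qv <- ref$transition_charges[i, j, a]
        if (qv != 0) w("%d %d %d %.12f", i, j, a, qv)
      }
    }
  }
  writeLines(c("END", "DIPOLES"), con)
  for (j in seq_len(ref$n_states)) {
    w("%d %.12f %.12f %.12f", j, ref$transition_dipoles[j, 1],
      ref$transition_dipoles[j, 2], ref$transition_dipoles[j, 3])
  }
  writeLines(c("END", "REF_POTENTIALS"), con)
  w("%.12f", ref$ref_potentials)
  writeLines("END", con)
  invisible(path)
}
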