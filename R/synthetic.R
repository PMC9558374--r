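#' Synthetic fixtures with known ground truth
#'
#' Geometry-only generators emulating the study conditions: a rigid
#' nitroxide-like solute at the origin, solvent molecules placed either
#' as hydrogen-bond donors at sampled (R, theta) geometries near the
#' acceptor sites or uniformly as bulk, with the active hydrogen-bond
#' regime planted per frame. Companion generators produce randomly
#' packed solvent unit cells and physically consistent QM reference
#' sets. Every generator is a pure function of its seed.
#'
#' @name synthetic_fixtures
NULL

# rotation matrix taking unit vector a to unit vector b
rotation_align <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (c_ < -1 + 1e-12) return(diag(c(-1, -1, 1)))  # antiparallel: flip
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

random_rotation <- function() {
  # uniform via QR of a Gaussian matrix
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

#' Rigid solute and solvent molecule templates
#'
#' \code{solute_template} builds a minimal nitroxide-like rigid solute:
#' two carbons flanking the nitrogen, the N-O group along +z, and two
#' lone-pair virtual sites generated from the N-O geometry. Charges sum
#' to zero. \code{water_template} is a 3-site water-like molecule and
#' \code{methanol_template} a 6-site methanol-like molecule, both rigid
#' with zero net charge.
#'
#' @param lp_distance,lp_half_angle lone-pair geometry passed to
#'   \code{\link{lone_pair_sites}}
#' @return list with \code{element}, \code{name}, \code{xyz},
#'   \code{charge}, \code{role}, and named site indices in \code{sites}
#' @export
solute_template <- function(lp_distance = 0.3, lp_half_angle = 55) {
  nN <- c(0, 0, 0)
  oO <- c(0, 0, 1.28)
  c1 <- c(1.22, 0, -0.55)
  c2 <- c(-1.22, 0, -0.55)
  lp <- lone_pair_sites(nN, oO, c1, c2, distance = lp_distance,
                        half_angle = lp_half_angle)
  list(element = c("C", "N", "C", "O", "X", "X"),
       name = c("C1", "N", "C2", "O", "LP1", "LP2"),
       xyz = rbind(c1, nN, c2, oO, lp),
       charge = c(0.083, 0.134, 0.083, -0.10, -0.10, -0.10),
       role = c(rep("solute", 4), rep("virtual_site", 2)),
       vdw_radius = c(bondi_radius(c("C", "N", "C", "O")), 0, 0),
       sites = list(N = 2L, O = 4L, LP1 = 5L, LP2 = 6L))
}

#' @rdname solute_template
#' @export
water_template <- function() {
  ang <- 104.52 / 2 * pi / 180
  r <- 0.9572
  list(element = c("O", "H", "H"),
       name = c("Ow", "Hw1", "Hw2"),
       xyz = rbind(c(0, 0, 0),
                   c(r * sin(ang), 0, r * cos(ang)),
                   c(-r * sin(ang), 0, r * cos(ang))),
       charge = c(-0.84, 0.42, 0.42),
       donor_h = c(2L, 3L), acceptor = 1L)
}

#' @rdname solute_template
#' @export
methanol_template <- function() {
  # O at origin, hydroxyl H along +z, methyl group below
  list(element = c("O", "H", "C", "H", "H", "H"),
       name = c("Om", "Hm", "Cm", "Hc1", "Hc2", "Hc3"),
       xyz = rbind(c(0, 0, 0),
                   c(0, 0, 0.96),
                   c(1.36, 0, -0.48),
                   c(1.96, 0.89, -0.32),
                   c(1.96, -0.89, -0.32),
                   c(1.30, -0.07, -1.57)),
       charge = c(-0.65, 0.42, 0.10, 0.04, 0.04, 0.05),
       donor_h = 2L, acceptor = 1L)
}

#' Specification of planted hydrogen-bond regimes
#'
#' @param regimes list of per-regime lists with \code{hb_count} (0, 1 or
#'   2 planted donors), \code{r_mean}, \code{r_sd} (donor H to acceptor
#'   distance distribution, angstrom), \code{theta_sd} (angular jitter,
#'   degrees), \code{dwell} (fraction of frames)
#' @param n_frames total frames
#' @param n_solvent solvent molecules per frame (constant topology)
#' @param sphere_radius placement sphere radius for bulk molecules, angstrom
#' @param dt frame spacing, ps
#' @param seed RNG seed
#' @return list of class \code{"regime_spec"}
#' @export
regime_spec <- function(regimes, n_frames = 100, n_solvent = 6,
                        sphere_radius = 8, dt = 1, seed = 1L) {
  if (length(regimes) < 1) stop("regime_spec: need >= 1 regime")
  dw <- vapply(regimes, `[[`, numeric(1), "dwell")
  if (abs(sum(dw) - 1) > 1e-6) stop("regime_spec: dwell fractions must sum to 1")
  hb <- vapply(regimes, `[[`, numeric(1), "hb_count")
  if (any(!hb %in% 0:2)) stop("regime_spec: hb_count must be 0, 1 or 2")
  if (max(hb) > n_solvent) stop("regime_spec: n_solvent below planted donor count")
  structure(list(regimes = regimes, n_frames = n_frames,
                 n_solvent = n_solvent, sphere_radius = sphere_radius,
                 dt = dt, seed = seed),
            class = "regime_spec")
}

place_donor <- function(acc_pos, direction, solvent, r_mean, r_sd, theta_sd) {
  R <- -1
  while (R < 1.2) R <- stats::rnorm(1, r_mean, r_sd)  # truncate unphysical
  u <- direction / sqrt(sum(direction^2))
  h_pos <- acc_pos + R * u
  # tilt the heavy-atom direction away from the outward axis
  eta <- stats::rnorm(1, 0, theta_sd) * pi / 180
  perp <- random_unit_vector()
  perp <- perp - sum(perp * u) * u
  perp <- perp / sqrt(sum(perp^2))
  u_tilt <- cos(eta) * u + sin(eta) * perp
  # rigid placement: map the template donor bond onto (h_pos - o_pos)
  h_idx <- solvent$donor_h[1]
  o_idx <- solvent$acceptor
  bond <- solvent$xyz[h_idx, ] - solvent$xyz[o_idx, ]
  o_pos <- h_pos + sqrt(sum(bond^2)) * u_tilt
  Rm <- rotation_align(bond, h_pos - o_pos)
  spin <- {  # random spin about the bond axis
    ax <- (h_pos - o_pos) / sqrt(sum((h_pos - o_pos)^2))
    th <- stats::runif(1, 0, 2 * pi)
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                3, 3, byrow = TRUE)
    diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  }
  sweep(sweep(solvent$xyz, 2, solvent$xyz[o_idx, ], "-") %*% t(spin %*% Rm),
        2, o_pos, "+")
}

place_bulk <- function(existing_centers, solute_xyz, sphere_radius, solvent,
                       min_dist = 2.8, keepout = 4.5) {
  for (attempt in seq_len(1000)) {
    p <- random_unit_vector() * sphere_radius * stats::runif(1)^(1 / 3)
    if (min(sqrt(rowSums(sweep(solute_xyz, 2, p, "-")^2))) < keepout) next
    if (length(existing_centers) > 0) {
      ec <- do.call(rbind, existing_centers)
      if (min(sqrt(rowSums(sweep(ec, 2, p, "-")^2))) < min_dist) next
    }
    rot <- random_rotation()
    return(sweep(solvent$xyz %*% t(rot), 2, p, "+"))
  }
  stop("place_bulk: infeasible placement after 1000 attempts")
}

#' Generate a trajectory with planted hydrogen-bond regimes
#'
#' The rigid solute sits at the origin. Frames are assigned to regimes
#' in contiguous blocks of the requested dwell fractions; in each frame
#' the planted donors are placed at sampled (R, theta) geometries along
#' the lone-pair directions and the remaining solvent molecules
#' uniformly in the placement sphere, away from the acceptor.
#'
#' @param spec a \code{\link{regime_spec}}
#' @param solute solute template (default \code{\link{solute_template}()})
#' @param solvent solvent template (default \code{\link{water_template}()})
#' @return list with \code{trajectory} and \code{labels} (planted regime
#'   id per frame)
#' @export
gen_trajectory <- function(spec, solute = solute_template(),
                           solvent = water_template()) {
  set.seed(spec$seed)
  nreg <- length(spec$regimes)
  dw <- vapply(spec$regimes, `[[`, numeric(1), "dwell")
  counts <- allocate_frames_counts(dw, spec$n_frames)
  labels <- rep(seq_len(nreg), counts)

  ns_atoms <- nrow(solvent$xyz)
  atoms <- data.frame(
    name = c(solute$name, rep(solvent$name, spec$n_solvent)),
    element = c(solute$element, rep(solvent$element, spec$n_solvent)),
    molecule_id = c(rep(1L, nrow(solute$xyz)),
                    rep(seq_len(spec$n_solvent) + 1L, each = ns_atoms)),
    role = c(solute$role, rep("solvent", ns_atoms * spec$n_solvent)),
    charge = c(solute$charge, rep(solvent$charge, spec$n_solvent)),
    vdw_radius = c(solute$vdw_radius,
                   rep(bondi_radius(solvent$element), spec$n_solvent)),
    stringsAsFactors = FALSE)
  top <- topology(atoms)

  acc_pos <- solute$xyz[solute$sites$O, ]
  lp_dirs <- rbind(solute$xyz[solute$sites$LP1, ] - acc_pos,
                   solute$xyz[solute$sites$LP2, ] - acc_pos)

  frames <- vector("list", spec$n_frames)
  for (fi in seq_len(spec$n_frames)) {
    rg <- spec$regimes[[labels[fi]]]
    placed <- vector("list", spec$n_solvent)
    centers <- list()
    if (rg$hb_count > 0) {
      for (b in seq_len(rg$hb_count)) {
        placed[[b]] <- place_donor(acc_pos, lp_dirs[b, ], solvent,
                                   rg$r_mean, rg$r_sd, rg$theta_sd)
        centers[[length(centers) + 1]] <- placed[[b]][solvent$acceptor, ,
                                                      drop = FALSE]
      }
    }
    if (spec$n_solvent > rg$hb_count) {
      for (b in seq.int(rg$hb_count + 1, spec$n_solvent)) {
        placed[[b]] <- place_bulk(centers, solute$xyz, spec$sphere_radius,
                                  solvent)
        centers[[length(centers) + 1]] <- placed[[b]][solvent$acceptor, ,
                                                      drop = FALSE]
      }
    }
    frames[[fi]] <- frame(do.call(rbind, c(list(solute$xyz), placed)),
                          time = (fi - 1) * spec$dt)
  }
  list(trajectory = trajectory(top, frames), labels = labels)
}

# integer frame counts for dwell fractions (largest remainder)
allocate_frames_counts <- function(fractions, total) {
  quota <- fractions * total
  alloc <- floor(quota)
  left <- total - sum(alloc)
  if (left > 0) {
    ord <- order(-(quota - alloc), seq_along(quota))
    alloc[ord[seq_len(left)]] <- alloc[ord[seq_len(left)]] + 1
  }
  as.integer(alloc)
}

#' Generate a physically consistent random QM reference set
#'
#' Ascending state energies with a first excitation near 0.1 hartree
#' (a visible band), symmetric atomic transition charges whose diagonal
#' blocks sum to the total molecular charge (off-diagonal blocks sum to
#' zero and scale with \code{coupling_scale}), and random transition
#' dipoles. Bit-reproducible given the seed.
#'
#' @param n_states number of states (default 11: ground + 10 excited)
#' @param n_atoms number of solute atoms
#' @param coupling_scale magnitude of the transition charges, e
#'   (0 decouples the solute from the solvent entirely)
#' @param total_charge total molecular charge, e
#' @param ref_potentials reference potentials (default zero vector)
#' @param seed RNG seed
#' @return a \code{\link{qm_reference}}
#' @export
gen_qm_reference <- function(n_states = 11, n_atoms = 6,
                             coupling_scale = 0.05, total_charge = 0,
                             ref_potentials = NULL, seed = 1L) {
  if (n_states < 2) stop("gen_qm_reference: need >= 2 states")
  set.seed(seed)
  gaps <- c(0.098, abs(stats::rnorm(n_states - 2, 0.03, 0.01)) + 0.005)
  energies <- cumsum(c(0, gaps))
  qarr <- array(0, dim = c(n_states, n_states, n_atoms))
  for (i in seq_len(n_states)) {
    for (j in i:n_states) {
      q <- coupling_scale * stats::rnorm(n_atoms)
      if (i == j) {
        q <- q - mean(q) + total_charge / n_atoms
      } else {
        q <- q - mean(q)  # off-diagonal blocks carry no monopole
      }
      qarr[i, j, ] <- q
      qarr[j, i, ] <- q
    }
  }
  dip <- rbind(rep(0, 3),
               matrix(stats::rnorm(3 * (n_states - 1), 0, 0.4),
                      n_states - 1, 3))
  if (is.null(ref_potentials)) ref_potentials <- rep(0, n_atoms)
  qm_reference(energies, qarr, dip, ref_potentials,
               total_charge = total_charge)
}

#' Generate a randomly packed solvent unit cell
#'
#' Places \code{round(rho_N * V)} copies of the molecule template at
#' random positions and orientations in a cubic cell, rejecting
#' placements whose acceptor-site centers come closer than
#' \code{packing_cutoff}.
#'
#' @param solvent solvent molecule template
#' @param density mass density, g/cm^3
#' @param cell_edge cubic cell edge, angstrom
#' @param packing_cutoff minimum center-center distance, angstrom
#' @param seed RNG seed
#' @return a \code{\link{unit_cell}}
#' @export
gen_solvent_cell <- function(solvent, density, cell_edge,
                             packing_cutoff = 2.4, seed = 1L) {
  if (density < 0) stop("gen_solvent_cell: density must be >= 0")
  set.seed(seed)
  molmass <- sum(atomic_mass(solvent$element))
  rho_n <- density / molmass * 0.6022140857  # molecules per A^3
  n_mol <- round(rho_n * cell_edge^3)
  centers <- matrix(0, 0, 3)
  xyz <- NULL; elem <- character(0); mol_id <- integer(0)
  for (m in seq_len(n_mol)) {
    ok <- FALSE
    for (attempt in seq_len(5000)) {
      p <- stats::runif(3, 0, cell_edge)
      if (nrow(centers) > 0 &&
          min(sqrt(rowSums(sweep(centers, 2, p, "-")^2))) < packing_cutoff) next
      ok <- TRUE
      break
    }
    if (!ok) stop("gen_solvent_cell: packing failure at molecule ", m)
    centers <- rbind(centers, p)
    placed <- sweep(solvent$xyz %*% t(random_rotation()), 2, p, "+")
    xyz <- rbind(xyz, placed)
    elem <- c(elem, solvent$element)
    mol_id <- c(mol_id, rep(m, nrow(placed)))
  }
  if (n_mol == 0) {
    xyz <- matrix(0, 0, 3)
  }
  unit_cell(c(0, 0, 0), diag(3) * cell_edge, elem, xyz, mol_id)
}
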