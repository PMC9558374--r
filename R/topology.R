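#' Atom tables, topologies, frames and trajectories
#'
#' A topology is a data frame of per-atom metadata: \code{name},
#' \code{element}, \code{molecule_id} (grouping atoms into rigid
#' molecules), \code{role} (one of \code{"solute"}, \code{"solvent"},
#' \code{"virtual_site"}), \code{charge} (elementary charges) and
#' \code{vdw_radius} (angstrom). Virtual sites (lone pairs) carry charge
#' but zero van der Waals radius; every physical atom must have a
#' positive radius.
#'
#' @param atoms data frame with the columns listed above
#' @return object of class \code{"topology"}
#' @export
topology <- function(atoms) {
  required <- c("name", "element", "molecule_id", "role", "charge", "vdw_radius")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop("topology: missing columns: ", paste(missing_cols, collapse = ", "))
  }
  bad_role <- setdiff(unique(atoms$role), c("solute", "solvent", "virtual_site"))
  if (length(bad_role) > 0) {
    stop("topology: unknown role(s): ", paste(bad_role, collapse = ", "))
  }
  if (!all(is.finite(atoms$charge))) stop("topology: non-finite charge")
  physical <- atoms$role != "virtual_site"
  if (any(!is.finite(atoms$vdw_radius[physical]) | atoms$vdw_radius[physical] <= 0)) {
    stop("topology: every physical atom needs a positive vdW radius")
  }
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  structure(list(atoms = atoms), class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("topology: %d atoms, %d molecules (%d solute, %d solvent, %d virtual sites)\n",
              nrow(a), length(unique(a$molecule_id)),
              sum(a$role == "solute"), sum(a$role == "solvent"),
              sum(a$role == "virtual_site")))
  invisible(x)
}

#' Number of atoms in a topology
#' @param top topology
#' @return integer atom count
#' @export
n_atoms <- function(top) nrow(top$atoms)

#' Bondi van der Waals radii (angstrom)
#'
#' Default radius set used by the sphere builder when a topology does not
#' override them.
#'
#' @param elements character vector of element symbols
#' @return numeric radii in angstrom
#' @export
bondi_radius <- function(elements) {
  tab <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80,
           S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98, He = 1.40, Ne = 1.54,
           Ar = 1.88, Si = 2.10, B = 1.92)
  r <- unname(tab[elements])
  if (any(is.na(r))) {
    stop("bondi_radius: no radius for element(s): ",
         paste(unique(elements[is.na(r)]), collapse = ", "))
  }
  r
}

# standard atomic masses, used only to convert mass density to number density
atomic_mass <- function(elements) {
  tab <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
           P = 30.974, S = 32.06, Cl = 35.45)
  m <- unname(tab[elements])
  if (any(is.na(m))) {
    stop("atomic_mass: no mass for element(s): ",
         paste(unique(elements[is.na(m)]), collapse = ", "))
  }
  m
}

#' Construct a single time-stamped frame
#'
#' @param xyz numeric matrix, one row per atom, columns x, y, z (angstrom)
#' @param time time stamp in ps
#' @return object of class \code{"frame"}
#' @export
frame <- function(xyz, time = 0) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3) stop("frame: coordinates must be an n x 3 matrix")
  if (!all(is.finite(xyz))) stop("frame: non-finite coordinates")
  structure(list(time = time, xyz = xyz), class = "frame")
}

#' Construct a trajectory from a topology and a list of frames
#'
#' Frame times must be strictly increasing and every frame must have as
#' many coordinate rows as the topology has atoms.
#'
#' @param top topology
#' @param frames list of \code{frame} objects
#' @return object of class \code{"trajectory"}
#' @export
trajectory <- function(top, frames) {
  na <- n_atoms(top)
  for (i in seq_along(frames)) {
    if (nrow(frames[[i]]$xyz) != na) {
      stop(sprintf("trajectory: frame %d has %d atoms, topology has %d",
                   i, nrow(frames[[i]]$xyz), na))
    }
  }
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("trajectory: frame times must be strictly increasing")
  }
  structure(list(topology = top, frames = frames, times = times),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d atoms", length(x$frames), n_atoms(x$topology)))
  if (length(x$times) > 1) {
    cat(sprintf(", t = %g..%g ps", x$times[1], x$times[length(x$times)]))
  }
  cat("\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj trajectory
#' @return integer frame count
#' @export
n_frames <- function(traj) length(traj$frames)

#' Generate lone-pair virtual-site positions from the N-O geometry
#'
#' Places two massless sites near the nitroxide oxygen, representing its
#' lone pairs: each at \code{distance} from O, in the plane containing
#' the N-O axis and perpendicular to the C-N-C framework (the plane
#' bisecting the C-N-C angle), symmetric about the N-O axis at
#' \code{half_angle}.
#'
#' @param n_pos,o_pos positions of the nitroxide N and O (angstrom)
#' @param c1_pos,c2_pos positions of the two carbons flanking N
#' @param distance O-to-site distance, angstrom (default 0.3)
#' @param half_angle half-angle from the N-O axis, degrees (default 55)
#' @return 2 x 3 matrix of site positions
#' @export
lone_pair_sites <- function(n_pos, o_pos, c1_pos, c2_pos,
                            distance = 0.3, half_angle = 55) {
  u <- o_pos - n_pos
  u <- u / sqrt(sum(u^2))           # N->O axis
  w <- c2_pos - c1_pos              # C..C direction, spans the CNC plane
  p <- c(u[2] * w[3] - u[3] * w[2], # u x w: in the bisecting plane,
         u[3] * w[1] - u[1] * w[3], #        orthogonal to the axis
         u[1] * w[2] - u[2] * w[1])
  pn <- sqrt(sum(p^2))
  if (pn < 1e-10) stop("lone_pair_sites: degenerate C-N-C geometry")
  p <- p / pn
  a <- half_angle * pi / 180
  d1 <- cos(a) * u + sin(a) * p
  d2 <- cos(a) * u - sin(a) * p
  rbind(o_pos + distance * d1, o_pos + distance * d2)
}
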