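#' Spherical solvation-box construction
#'
#' A non-periodic simulation sphere is built in three stages: the solvent
#' unit cell is replicated along its (generally non-orthogonal) axes
#' until the replica block covers the sphere of radius \code{r_max}
#' around the solute; whole solvent molecules whose centroids fall
#' outside the sphere are erased; and solvent molecules with any atom
#' closer to any solute atom than the scaled sum of their van der Waals
#' radii are removed. Molecules are always kept or dropped whole.
#'
#' @name sphere_builder
NULL

# a "molecule list" is a list of list(element, xyz, vdw_radius) entries

cell_molecules <- function(cell) {
  ids <- unique(cell$molecule_id)
  lapply(ids, function(id) {
    sel <- cell$molecule_id == id
    list(element = cell$element[sel],
         xyz = cell$xyz[sel, , drop = FALSE],
         vdw_radius = bondi_radius(cell$element[sel]))
  })
}

#' Replicate a solvent unit cell to cover a sphere
#'
#' The replica range along each axis is computed from the sphere's
#' circumscribing box in fractional coordinates, with one extra replica
#' of margin per axis, which guarantees geometric coverage for any
#' non-degenerate (including sheared) cell.
#'
#' @param cell \code{unit_cell}
#' @param center sphere center (angstrom)
#' @param r_max sphere radius (angstrom)
#' @return molecule list covering the sphere
#' @export
replicate_cell <- function(cell, center, r_max) {
  if (abs(det(cell$lattice)) < 1e-8) stop("replicate_cell: degenerate cell")
  if (r_max < 0) stop("replicate_cell: r_max must be >= 0")
  # corners of the axis-aligned box circumscribing the sphere
  signs <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  corners <- sweep(signs * r_max, 2, center, "+")
  # fractional coordinates relative to the cell origin
  frac <- t(solve(t(cell$lattice), t(sweep(corners, 2, cell$origin, "-"))))
  lo <- floor(apply(frac, 2, min)) - 1
  hi <- ceiling(apply(frac, 2, max)) + 1
  base <- cell_molecules(cell)
  shifts <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
  out <- vector("list", nrow(shifts) * length(base))
  n <- 0L
  for (s in seq_len(nrow(shifts))) {
    disp <- cell$origin + as.numeric(shifts[s, ] %*% cell$lattice)
    for (m in base) {
      n <- n + 1L
      out[[n]] <- list(element = m$element,
                       xyz = sweep(m$xyz, 2, disp, "+"),
                       vdw_radius = m$vdw_radius)
    }
  }
  attr(out, "shift_range") <- list(lo = lo, hi = hi)
  out
}

molecule_centroids <- function(molecules) {
  t(vapply(molecules, function(m) colMeans(m$xyz), numeric(3)))
}

#' Keep molecules whose centroid lies within a sphere
#'
#' The centroid is the unweighted mean of atomic positions; the boundary
#' is inclusive (centroid exactly at \code{r_max} is kept).
#'
#' @param molecules molecule list
#' @param center sphere center (angstrom)
#' @param r_max sphere radius (angstrom)
#' @return filtered molecule list (possibly empty)
#' @export
carve_sphere <- function(molecules, center, r_max) {
  if (length(molecules) == 0) return(molecules)
  cen <- molecule_centroids(molecules)
  d2 <- rowSums(sweep(cen, 2, center, "-")^2)
  molecules[d2 <= r_max^2]
}

#' Remove solvent molecules overlapping the solute
#'
#' A solvent molecule is removed when ANY of its atoms lies strictly
#' closer to ANY solute atom than \code{overlap_scale} times the sum of
#' the two van der Waals radii; a pair exactly at the threshold
#' survives. The test is per atom, not per centroid.
#'
#' @param solute_xyz solute coordinates (n x 3, angstrom)
#' @param solute_radii solute per-atom vdW radii (angstrom)
#' @param molecules solvent molecule list
#' @param overlap_scale multiplier on the vdW-sum threshold (default 1)
#' @return filtered molecule list
#' @export
prune_overlaps <- function(solute_xyz, solute_radii, molecules, overlap_scale = 1) {
  if (overlap_scale <= 0) stop("prune_overlaps: overlap_scale must be > 0")
  solute_xyz <- as.matrix(solute_xyz)
  if (nrow(solute_xyz) == 0 || length(molecules) == 0) return(molecules)
  if (length(solute_radii) != nrow(solute_xyz) || any(!is.finite(solute_radii))) {
    stop("prune_overlaps: solute atoms need vdW radii")
  }
  keep <- vapply(molecules, function(m) {
    if (any(!is.finite(m$vdw_radius))) stop("prune_overlaps: solvent atom lacks vdW radius")
    for (a in seq_len(nrow(m$xyz))) {
      d <- sqrt(colSums((t(solute_xyz) - m$xyz[a, ])^2))
      if (any(d < overlap_scale * (solute_radii + m$vdw_radius[a]))) return(FALSE)
    }
    TRUE
  }, logical(1))
  molecules[keep]
}

#' Build a solvation sphere around a centered solute
#'
#' Composition of \code{\link{replicate_cell}},
#' \code{\link{carve_sphere}} and \code{\link{prune_overlaps}}: the
#' solute centroid is translated to the origin, the cell is replicated
#' to cover the sphere, molecules are carved by centroid and pruned by
#' per-atom vdW overlap. The result merges solute (first) and solvent
#' with fresh molecule ids, and reports the solvent count and the
#' implied number density.
#'
#' @param cell solvent \code{unit_cell}
#' @param solute list with \code{element}, \code{xyz} and optionally
#'   \code{vdw_radius} (Bondi by element when absent) and \code{charge}
#' @param r_max sphere radius, angstrom
#' @param overlap_scale vdW threshold multiplier (default 1)
#' @return list with \code{topology}, \code{frame}, \code{n_solvent}
#'   (molecule count) and \code{density} (molecules per A^3)
#' @export
build_solvation_sphere <- function(cell, solute, r_max, overlap_scale = 1) {
  if (r_max < 0) stop("build_solvation_sphere: r_max must be >= 0")
  sol_xyz <- sweep(as.matrix(solute$xyz), 2, colMeans(as.matrix(solute$xyz)), "-")
  sol_role <- if (!is.null(solute$role)) solute$role else rep("solute", nrow(sol_xyz))
  sol_r <- if (!is.null(solute$vdw_radius)) solute$vdw_radius else bondi_radius(solute$element)
  sol_q <- if (!is.null(solute$charge)) solute$charge else rep(0, nrow(sol_xyz))

  physical <- sol_role != "virtual_site"  # lone pairs have no vdW volume
  molecules <- if (r_max > 0) {
    prune_overlaps(sol_xyz[physical, , drop = FALSE], sol_r[physical],
                   carve_sphere(replicate_cell(cell, c(0, 0, 0), r_max),
                                c(0, 0, 0), r_max),
                   overlap_scale)
  } else list()

  elem <- c(solute$element, unlist(lapply(molecules, `[[`, "element")))
  xyz <- do.call(rbind, c(list(sol_xyz), lapply(molecules, `[[`, "xyz")))
  mol_id <- c(rep(1L, nrow(sol_xyz)),
              rep(seq_along(molecules) + 1L,
                  vapply(molecules, function(m) nrow(m$xyz), integer(1))))
  role <- c(sol_role, rep("solvent", length(elem) - nrow(sol_xyz)))
  vdw <- c(sol_r, unlist(lapply(molecules, `[[`, "vdw_radius")))
  charge <- c(sol_q, rep(0, length(elem) - nrow(sol_xyz)))
  top <- topology(data.frame(name = elem, element = elem, molecule_id = mol_id,
                             role = role, charge = charge, vdw_radius = vdw,
                             stringsAsFactors = FALSE))
  list(topology = top, frame = frame(xyz),
       n_solvent = length(molecules),
       density = if (r_max > 0) length(molecules) / (4 / 3 * pi * r_max^3) else NA_real_)
}
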