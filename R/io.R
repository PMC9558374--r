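#' Extended-XYZ trajectory and structure I/O
#'
#' The trajectory format is multi-frame extended-XYZ: for each frame an
#' atom-count line, a comment line that may carry \code{time=<ps>} and a
#' \code{Lattice="ax ay az bx by bz cx cy cz"} field, then one
#' \code{element x y z [molecule_id] [charge]} line per atom. Units are
#' angstrom and ps throughout.
#'
#' @param path file path
#' @param top topology matching the per-frame atom count
#' @return \code{read_trajectory}: a \code{trajectory}
#' @export
read_trajectory <- function(path, top) {
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0))]
  frames <- list()
  i <- 1L
  fidx <- 0L
  na_top <- n_atoms(top)
  while (i <= length(lines)) {
    fidx <- fidx + 1L
    na <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(na) || na < 0) {
      stop(sprintf("read_trajectory: malformed header at frame %d (line %d)", fidx, i))
    }
    if (i + 1L + na > length(lines) + 1L && na > 0) {
      stop(sprintf("read_trajectory: truncated frame %d", fidx))
    }
    comment <- if (i + 1L <= length(lines)) lines[i + 1L] else ""
    if (na != na_top) {
      stop(sprintf("read_trajectory: frame %d has %d atoms, topology has %d",
                   fidx, na, na_top))
    }
    body <- lines[seq.int(i + 2L, length.out = na)]
    xyz <- parse_xyz_body(body, fidx)$xyz
    t <- parse_comment_time(comment)
    if (is.na(t)) t <- fidx - 1
    frames[[fidx]] <- frame(xyz, time = t)
    i <- i + 2L + na
  }
  if (fidx == 0L) stop("read_trajectory: empty file")
  trajectory(top, frames)
}

parse_xyz_body <- function(body, fidx = 1L) {
  parts <- strsplit(trimws(body), "[[:space:]]+")
  nfld <- lengths(parts)
  if (any(nfld < 4)) {
    stop(sprintf("read_trajectory: malformed atom line in frame %d", fidx))
  }
  elem <- vapply(parts, `[[`, character(1), 1L)
  num <- function(k) vapply(parts, function(p) as.numeric(p[[k]]), numeric(1))
  xyz <- cbind(num(2L), num(3L), num(4L))
  if (!all(is.finite(xyz))) {
    stop(sprintf("read_trajectory: non-numeric coordinates in frame %d", fidx))
  }
  mol <- if (all(nfld >= 5)) suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 5L))) else NULL
  chg <- if (all(nfld >= 6)) num(6L) else NULL
  list(element = elem, xyz = xyz, molecule_id = mol, charge = chg)
}

parse_comment_time <- function(comment) {
  m <- regmatches(comment, regexpr("time=([-+0-9.eE]+)", comment))
  if (length(m) == 0 || !nzchar(m)) return(NA_real_)
  as.numeric(sub("time=", "", m))
}

parse_comment_lattice <- function(comment) {
  m <- regmatches(comment, regexpr('Lattice="[^"]*"', comment))
  if (length(m) == 0 || !nzchar(m)) return(NULL)
  v <- as.numeric(strsplit(trimws(gsub('Lattice="|"', "", m)), "[[:space:]]+")[[1]])
  if (length(v) != 9 || !all(is.finite(v))) stop("malformed Lattice field")
  matrix(v, nrow = 3, byrow = TRUE)  # rows = lattice vectors
}

#' @rdname read_trajectory
#' @param traj trajectory to write
#' @param digits decimals used for coordinates (default 6)
#' @return \code{write_trajectory}: invisibly, the path
#' @export
write_trajectory <- function(traj, path, digits = 6) {
  con <- file(path, "w")
  on.exit(close(con))
  elem <- traj$topology$atoms$element
  for (f in traj$frames) {
    writeLines(as.character(nrow(f$xyz)), con)
    writeLines(sprintf("time=%.6f", f$time), con)
    writeLines(sprintf(paste0("%s %.", digits, "f %.", digits, "f %.", digits, "f"),
                       elem, f$xyz[, 1], f$xyz[, 2], f$xyz[, 3]), con)
  }
  invisible(path)
}

#' Read a single-structure XYZ file
#'
#' @param path file path
#' @return list with \code{element}, \code{xyz} (n x 3, angstrom) and,
#'   when present in the file, \code{molecule_id} and \code{charge}
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  na <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(na)) stop("read_xyz: malformed atom-count line")
  parse_xyz_body(lines[seq.int(3L, length.out = na)])
}

#' Read a solvent unit cell from extended-XYZ
#'
#' The comment line must carry a \code{Lattice="..."} field (row-major
#' lattice vectors, angstrom) and may carry \code{origin="ox oy oz"};
#' the optional 5th column groups atoms into molecules.
#'
#' @param path file path
#' @return object of class \code{"unit_cell"}: \code{origin},
#'   \code{lattice} (3 x 3, rows are cell vectors), \code{element},
#'   \code{xyz}, \code{molecule_id}
#' @export
read_unit_cell <- function(path) {
  lines <- readLines(path)
  na <- suppressWarnings(as.integer(trimws(lines[1])))
  lattice <- parse_comment_lattice(lines[2])
  if (is.null(lattice)) stop("read_unit_cell: missing Lattice field")
  m <- regmatches(lines[2], regexpr('origin="[^"]*"', lines[2]))
  origin <- if (length(m) > 0 && nzchar(m)) {
    as.numeric(strsplit(trimws(gsub('origin="|"', "", m)), "[[:space:]]+")[[1]])
  } else c(0, 0, 0)
  body <- parse_xyz_body(lines[seq.int(3L, length.out = na)])
  mol <- body$molecule_id
  if (is.null(mol)) mol <- seq_len(na)  # each atom its own molecule
  unit_cell(origin, lattice, body$element, body$xyz, mol)
}

#' Construct a solvent unit cell
#'
#' @param origin origin vector (angstrom)
#' @param lattice 3 x 3 matrix, rows are the three cell vectors
#' @param element element symbols
#' @param xyz n x 3 coordinates (angstrom)
#' @param molecule_id integer molecule grouping
#' @return object of class \code{"unit_cell"}
#' @export
unit_cell <- function(origin, lattice, element, xyz, molecule_id) {
  lattice <- as.matrix(lattice)
  if (abs(det(lattice)) < 1e-8) stop("unit_cell: degenerate lattice (zero volume)")
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != length(element) || nrow(xyz) != length(molecule_id)) {
    stop("unit_cell: atom fields disagree in length")
  }
  structure(list(origin = as.numeric(origin), lattice = lattice,
                 element = element, xyz = xyz,
                 molecule_id = as.integer(molecule_id)),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit_cell: %d atoms, %d molecules, volume %.2f A^3\n",
              nrow(x$xyz), length(unique(x$molecule_id)), abs(det(x$lattice))))
  invisible(x)
}

#' Write a unit cell as extended-XYZ with Lattice and origin fields
#' @param cell unit cell
#' @param path file path
#' @export
write_unit_cell <- function(cell, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(nrow(cell$xyz)), con)
  lat <- paste(sprintf("%.6f", t(cell$lattice)), collapse = " ")
  org <- paste(sprintf("%.6f", cell$origin), collapse = " ")
  writeLines(sprintf('Lattice="%s" origin="%s"', lat, org), con)
  writeLines(sprintf("%s %.6f %.6f %.6f %d", cell$element,
                     cell$xyz[, 1], cell$xyz[, 2], cell$xyz[, 3],
                     cell$molecule_id), con)
  invisible(path)
}

#' Write point charges as "x y z q" lines
#'
#' Export format for external QM/MM embedding: one line per site, fixed
#' six-decimal precision, coordinates in angstrom and charges in
#' elementary charges. No header; an empty input produces an empty file.
#'
#' @param xyz n x 3 site coordinates (angstrom)
#' @param charges n charges (elementary charges)
#' @param path file path
#' @export
write_point_charges <- function(xyz, charges, path) {
  xyz <- as.matrix(xyz)
  if (length(charges) != nrow(xyz)) stop("write_point_charges: length mismatch")
  if (length(charges) > 0 && (!all(is.finite(xyz)) || !all(is.finite(charges)))) {
    stop("write_point_charges: non-finite coordinate or charge")
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (length(charges) > 0) {
    writeLines(sprintf("%.6f %.6f %.6f %.6f",
                       xyz[, 1], xyz[, 2], xyz[, 3], charges), con)
  }
  invisible(path)
}

#' @rdname write_point_charges
#' @return \code{read_point_charges}: list with \code{xyz} and \code{charges}
#' @export
read_point_charges <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(list(xyz = matrix(0, 0, 3), charges = numeric(0)))
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "[[:space:]]+"), as.numeric))
  list(xyz = m[, 1:3, drop = FALSE], charges = m[, 4])
}

#' Read a topology from a YAML file
#'
#' Expects a top-level \code{atoms:} list whose entries provide
#' \code{name}, \code{element}, \code{molecule_id}, \code{role},
#' \code{charge} and optionally \code{vdw_radius} (Bondi default by
#' element when omitted; virtual sites get zero).
#'
#' @param path YAML file path
#' @return a \code{topology}
#' @export
read_topology_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$atoms)) stop("read_topology_yaml: no 'atoms' block")
  rows <- lapply(y$atoms, function(a) {
    r <- a$vdw_radius
    if (is.null(r)) {
      r <- if (identical(a$role, "virtual_site")) 0 else bondi_radius(a$element)
    }
    data.frame(name = a$name, element = a$element,
               molecule_id = as.integer(a$molecule_id), role = a$role,
               charge = as.numeric(a$charge), vdw_radius = as.numeric(r),
               stringsAsFactors = FALSE)
  })
  topology(do.call(rbind, rows))
}

#' @rdname read_topology_yaml
#' @param top topology to write
#' @export
write_topology_yaml <- function(top, path) {
  atoms <- lapply(seq_len(n_atoms(top)), function(i) {
    a <- top$atoms[i, ]
    list(name = a$name, element = a$element,
         molecule_id = as.integer(a$molecule_id), role = a$role,
         charge = a$charge, vdw_radius = a$vdw_radius)
  })
  yaml::write_yaml(list(atoms = atoms), path)
  invisible(path)
}

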