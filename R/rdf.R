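#' Radial distribution functions in a finite sphere
#'
#' g(r) between two site selections, averaged over frames:
#' \deqn{g(r) = \langle h(r) \rangle / (N_A \rho_B 4\pi r^2 \Delta r)}
#' where h(r) is the per-frame histogram of A-B distances. Because the
#' simulation sphere is finite and non-periodic, the reference density
#' \eqn{\rho_B} is estimated from the B sites inside a concentric
#' sub-sphere of radius \code{r_norm} (default 0.75 of the sphere
#' radius), which avoids the depletion bias near the wall.
#'
#' @param traj trajectory
#' @param sel_A,sel_B integer atom indices of the two selections
#' @param r_min,r_max histogram range, angstrom
#' @param n_bins number of uniform bins
#' @param r_norm normalization sub-sphere radius, angstrom
#' @param center sphere center (default origin)
#' @return object of class \code{"rdf"}: \code{bin_centers}, \code{g},
#'   \code{rho_B}, \code{n_pairs_per_frame}, \code{dr}
#' @export
compute_rdf <- function(traj, sel_A, sel_B, r_min = 0, r_max = 10,
                        n_bins = 200, r_norm = NULL, center = c(0, 0, 0)) {
  if (length(sel_A) == 0 || length(sel_B) == 0) stop("compute_rdf: empty selection")
  if (r_max <= r_min) stop("compute_rdf: r_max must exceed r_min")
  if (is.null(r_norm)) r_norm <- r_max
  breaks <- seq(r_min, r_max, length.out = n_bins + 1)
  dr <- breaks[2] - breaks[1]
  counts <- numeric(n_bins)
  nb_in <- 0
  for (f in traj$frames) {
    A <- f$xyz[sel_A, , drop = FALSE]
    B <- f$xyz[sel_B, , drop = FALSE]
    d <- sqrt(outer(rowSums(A^2), rep(1, nrow(B))) +
              outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B))
    d <- d[is.finite(d) & d > 0]   # drop self pairs at distance 0
    counts <- counts + tabulate(findInterval(d, breaks, rightmost.closed = TRUE),
                                nbins = n_bins + 1)[seq_len(n_bins)]
    db <- sqrt(rowSums(sweep(B, 2, center, "-")^2))
    nb_in <- nb_in + sum(db <= r_norm)
  }
  nf <- n_frames(traj)
  rho_B <- (nb_in / nf) / (4 / 3 * pi * r_norm^3)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  shell_vol <- 4 * pi * centers^2 * dr
  g <- (counts / nf) / (length(sel_A) * rho_B * shell_vol)
  structure(list(bin_centers = centers, g = g, rho_B = rho_B,
                 n_pairs_per_frame = counts / nf, dr = dr),
            class = "rdf")
}

#' @export
print.rdf <- function(x, ...) {
  cat(sprintf("rdf: %d bins, dr = %.3f A, rho_B = %.5f A^-3\n",
              length(x$g), x$dr, x$rho_B))
  invisible(x)
}

#' Coordination number from a binned RDF
#'
#' \deqn{n(r_{cut}) = 4\pi \rho_B \int_0^{r_{cut}} g(r) r^2 dr}
#' integrated by the trapezoid rule on the bin grid.
#'
#' @param rdf an \code{rdf} object
#' @param r_cut integration limit, angstrom; must lie within the grid
#' @return dimensionless coordination number
#' @export
coordination_number <- function(rdf, r_cut) {
  r <- rdf$bin_centers
  if (r_cut < r[1] || r_cut > r[length(r)]) {
    stop("coordination_number: r_cut outside the RDF grid")
  }
  integrand <- rdf$g * r^2
  keep <- r <= r_cut
  rr <- r[keep]
  yy <- integrand[keep]
  # extend to r_cut by linear interpolation if it falls between bins
  if (rr[length(rr)] < r_cut) {
    yc <- stats::approx(r, integrand, xout = r_cut)$y
    rr <- c(rr, r_cut)
    yy <- c(yy, yc)
  }
  4 * pi * rdf$rho_B * sum(diff(rr) * (yy[-1] + yy[-length(yy)]) / 2)
}

#' Locate the first peak (or following minimum) of an RDF
#'
#' g is smoothed by a centered moving average before the scan; the scan
#' returns the first interior local maximum, or the first local minimum
#' after that maximum. Monotone profiles raise an error rather than
#' returning a boundary.
#'
#' @param rdf an \code{rdf} object (>= 5 bins)
#' @param kind \code{"peak"} or \code{"minimum_after_peak"}
#' @param smooth_window moving-average width in bins (odd, default 5)
#' @return location in angstrom
#' @export
find_first_extremum <- function(rdf, kind = c("peak", "minimum_after_peak"),
                                smooth_window = 5) {
  kind <- match.arg(kind)
  g <- rdf$g
  if (length(g) < 5) stop("find_first_extremum: need at least 5 bins")
  k <- max(1L, smooth_window %/% 2L)
  gs <- stats::filter(g, rep(1 / (2 * k + 1), 2 * k + 1), sides = 2)
  gs <- as.numeric(gs)
  idx <- which(!is.na(gs))
  peak <- NA_integer_
  for (i in idx[-c(1, length(idx))]) {
    if (gs[i] > gs[i - 1] && gs[i] >= gs[i + 1]) { peak <- i; break }
  }
  if (is.na(peak)) stop("find_first_extremum: no local maximum found")
  if (kind == "peak") return(rdf$bin_centers[peak])
  for (i in idx[idx > peak]) {
    if (i == idx[length(idx)]) break
    if (gs[i] < gs[i - 1] && gs[i] <= gs[i + 1]) return(rdf$bin_centers[i])
  }
  stop("find_first_extremum: no minimum after the first peak")
}

#' Subsample a trajectory at a fixed time stride
#'
#' Keeps the frames nearest to the target times t0 + k * stride; used to
#' decorrelate frames before clustering (default analysis stride 10 ps).
#'
#' @param traj trajectory
#' @param stride target spacing, ps; must be >= the native frame spacing
#' @return subsampled trajectory
#' @export
subsample <- function(traj, stride) {
  times <- traj$times
  if (length(times) < 2) return(traj)
  native <- min(diff(times))
  if (stride < native - 1e-9) {
    stop("subsample: stride smaller than the native frame spacing")
  }
  span <- times[length(times)] - times[1]
  targets <- times[1] + stride * 0:(floor(span / stride + 1e-9))
  picks <- vapply(targets, function(t) which.min(abs(times - t)), integer(1))
  picks <- unique(picks)
  trajectory(traj$topology, traj$frames[picks])
}
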