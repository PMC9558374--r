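#' Continuous hydrogen-bond perception
#'
#' A hydrogen bond between a solvent donor H and a solute acceptor O is
#' scored on [0, 1] as a separable function of the H...O distance R and
#' the angle theta at the donor heavy atom between its H and the
#' acceptor (0 degrees = H pointing straight at the acceptor):
#' \deqn{F_{HB}(R, \theta) = f(R)\, g(\theta)}
#' with f(R) = 1 for R <= R0 and a Gaussian fall-off of scale
#' sigma_R * R0 beyond, and g a Gaussian in theta of width sigma_theta.
#' Scores below \code{zero_floor} are returned as exactly zero.
#'
#' @param R0 plateau edge, angstrom (default 1.85)
#' @param sigma_R distance fall-off as a fraction of R0 (default 0.20)
#' @param theta0 ideal angle, degrees (default 0)
#' @param sigma_theta angular width, degrees (default 10)
#' @param zero_floor scores below this are zeroed (default 1e-4)
#' @return parameter list of class \code{"hb_params"}
#' @export
hb_params <- function(R0 = 1.85, sigma_R = 0.20, theta0 = 0,
                      sigma_theta = 10, zero_floor = 1e-4) {
  if (sigma_R <= 0 || sigma_theta <= 0 || zero_floor < 0 || R0 <= 0) {
    stop("hb_params: sigma_R, sigma_theta, R0 must be > 0 and zero_floor >= 0")
  }
  structure(list(R0 = R0, sigma_R = sigma_R, theta0 = theta0,
                 sigma_theta = sigma_theta, zero_floor = zero_floor),
            class = "hb_params")
}

#' Evaluate the continuous hydrogen-bond score
#'
#' Vectorized over R and theta.
#'
#' @param R donor-H to acceptor distance, angstrom (> 0)
#' @param theta donor angle, degrees in [0, 180]
#' @param params \code{hb_params}
#' @return score in [0, 1]
#' @export
f_hb <- function(R, theta, params = hb_params()) {
  if (any(R <= 0)) stop("f_hb: R must be > 0")
  if (any(theta < -180 | theta > 180)) stop("f_hb: theta out of range")
  sR <- params$sigma_R * params$R0
  fr <- ifelse(R <= params$R0, 1, exp(-(R - params$R0)^2 / (2 * sR^2)))
  gt <- exp(-(theta - params$theta0)^2 / (2 * params$sigma_theta^2))
  v <- fr * gt
  v[v < params$zero_floor] <- 0
  v
}

#' Scan a trajectory for solute-solvent hydrogen bonds
#'
#' For every frame and every candidate donor (a solvent H with its bound
#' heavy atom), the (R, theta) geometry against each acceptor site is
#' scored with \code{\link{f_hb}} and the best acceptor is kept. Returns
#' per-donor records, the histogram of the per-frame summed score, and
#' the trajectory mean of that sum.
#'
#' @param traj trajectory
#' @param donors data frame with integer columns \code{h} (donor H atom
#'   index) and \code{heavy} (its bound heavy-atom index); one row per
#'   candidate donor
#' @param acceptors integer indices of acceptor sites on the solute
#' @param params \code{hb_params}
#' @param hist_breaks breaks for the per-frame sum histogram
#' @return list with \code{records} (frame, donor H index, solvent
#'   molecule id, R, theta, f_hb), \code{per_frame_sum}, \code{histogram}
#'   and \code{mean} (the trajectory-average summed score)
#' @export
hb_scan <- function(traj, donors, acceptors, params = hb_params(),
                    hist_breaks = seq(-0.05, 3.05, by = 0.1)) {
  if (nrow(donors) == 0) stop("hb_scan: no donors in topology")
  if (length(acceptors) == 0) stop("hb_scan: no acceptor sites")
  mol_id <- traj$topology$atoms$molecule_id
  recs <- vector("list", n_frames(traj))
  sums <- numeric(n_frames(traj))
  for (fi in seq_len(n_frames(traj))) {
    xyz <- traj$frames[[fi]]$xyz
    best_R <- best_th <- best_f <- numeric(nrow(donors))
    for (di in seq_len(nrow(donors))) {
      h <- xyz[donors$h[di], ]
      heavy <- xyz[donors$heavy[di], ]
      fbest <- -1; Rb <- NA_real_; tb <- NA_real_
      for (ai in acceptors) {
        acc <- xyz[ai, ]
        R <- sqrt(sum((h - acc)^2))
        v1 <- h - heavy
        v2 <- acc - heavy
        cth <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        th <- acos(pmin(1, pmax(-1, cth))) * 180 / pi
        fv <- f_hb(R, th, params)
        if (fv > fbest) { fbest <- fv; Rb <- R; tb <- th }
      }
      best_R[di] <- Rb; best_th[di] <- tb; best_f[di] <- fbest
    }
    recs[[fi]] <- data.frame(frame_index = fi,
                             solvent_molecule_id = mol_id[donors$h],
                             R = best_R, theta = best_th, f_hb = best_f)
    sums[fi] <- sum(best_f)
  }
  records <- do.call(rbind, recs)
  h <- graphics::hist(sums, breaks = hist_breaks, plot = FALSE)
  list(records = records, per_frame_sum = sums,
       histogram = data.frame(mid = h$mids, count = h$counts),
       mean = mean(sums))
}

#' Identify solvent donor H atoms from a topology
#'
#' Donors are solvent hydrogens whose nearest heavy atom within the same
#' molecule (by template geometry) is O or N. Pairing uses the supplied
#' reference frame.
#'
#' @param top topology
#' @param ref_frame a \code{frame} giving the pairing geometry
#' @return data frame with columns \code{h}, \code{heavy}
#' @export
find_donors <- function(top, ref_frame) {
  a <- top$atoms
  hs <- which(a$role == "solvent" & a$element == "H")
  rows <- lapply(hs, function(i) {
    same_mol <- which(a$molecule_id == a$molecule_id[i] &
                      a$element %in% c("O", "N") & a$role == "solvent")
    if (length(same_mol) == 0) return(NULL)
    d <- sqrt(rowSums(sweep(ref_frame$xyz[same_mol, , drop = FALSE], 2,
                            ref_frame$xyz[i, ], "-")^2))
    heavy <- same_mol[which.min(d)]
    if (min(d) > 1.3) return(NULL)  # H not bonded to O/N
    data.frame(h = i, heavy = heavy)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(h = integer(0), heavy = integer(0))
  out
}
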