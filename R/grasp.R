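#' Representative-frame selection (GRASP) and collective frames
#'
#' Each cluster contributes a number of representative frames
#' proportional to its size; within a cluster the frames are chosen by a
#' greedy randomized adaptive search procedure (GRASP) so that their
#' mean feature vector matches the cluster mean as closely as possible.
#' The selected frames are then merged into a single collective frame
#' whose solvent charges are scaled by 1/N, so its electrostatic
#' potential at any point equals the average of the per-frame
#' potentials exactly.
#'
#' @name frame_selection
NULL

#' Proportional (largest-remainder) frame allocation
#'
#' Hamilton apportionment of \code{budget} frames over clusters in
#' proportion to their sizes: integer floors of the exact quotas, then
#' remaining frames to the largest fractional remainders (ties broken by
#' larger cluster, then lower index). Every cluster receives at least
#' one frame.
#'
#' @param cluster_sizes positive integer cluster sizes
#' @param budget total number of frames to allocate (>= number of clusters)
#' @return integer allocation summing to \code{budget}
#' @export
allocate_frames <- function(cluster_sizes, budget) {
  nc <- length(cluster_sizes)
  if (budget < nc) stop("allocate_frames: budget smaller than cluster count")
  if (any(cluster_sizes <= 0)) stop("allocate_frames: sizes must be > 0")
  # exact integer quotas: budget * size = S * floor + remainder
  S <- sum(cluster_sizes)
  num <- budget * cluster_sizes
  alloc <- num %/% S
  rem <- num %% S
  left <- budget - sum(alloc)
  if (left > 0) {
    ord <- order(-rem, -cluster_sizes, seq_len(nc))
    take <- ord[seq_len(left)]
    alloc[take] <- alloc[take] + 1
  }
  # guarantee one frame per cluster, taken from the largest allocation
  # (ties by larger cluster, then lower index)
  while (any(alloc == 0)) {
    i <- order(alloc, -cluster_sizes, seq_len(nc))[1]
    j <- order(-alloc, -cluster_sizes, seq_len(nc))[1]
    alloc[j] <- alloc[j] - 1
    alloc[i] <- 1
  }
  as.integer(alloc)
}

grasp_objective <- function(Phi, subset, target) {
  sum((colMeans(Phi[subset, , drop = FALSE]) - target)^2)
}

#' GRASP selection of representative frames within a cluster
#'
#' Minimizes J(S) = || mean of phi over S - mean of phi over the cluster
#' ||^2 where phi is the reduced feature vector. Each restart performs a
#' greedy randomized construction - at every step the candidate is drawn
#' uniformly from the restricted candidate list of the best
#' ceil(alpha * n_remaining) marginal improvements - followed by
#' first-improvement swap local search; the best restart is returned.
#' Fully reproducible given \code{seed}; \code{alpha = 0} collapses to
#' pure greedy.
#'
#' @param Phi numeric matrix of feature vectors, rows = cluster frames
#' @param n number of frames to select (1 <= n <= cluster size)
#' @param alpha restricted-candidate-list fraction in [0, 1] (default 0.3)
#' @param n_restarts number of multi-start repetitions (default 50)
#' @param seed integer RNG seed
#' @return list with \code{selected} (row indices into \code{Phi}),
#'   \code{objective} (best J), \code{trace} (per-restart J values)
#' @export
grasp_select <- function(Phi, n, alpha = 0.3, n_restarts = 50, seed = 1L) {
  Phi <- as.matrix(Phi)
  m <- nrow(Phi)
  if (n < 1 || n > m) stop("grasp_select: n outside [1, cluster size]")
  if (alpha < 0 || alpha > 1) stop("grasp_select: alpha outside [0, 1]")
  target <- colMeans(Phi)
  if (n == m) {
    return(list(selected = seq_len(m), objective = 0, trace = 0))
  }
  set.seed(seed)
  best_S <- NULL
  best_J <- Inf
  trace <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    # greedy randomized construction; the first element is drawn uniformly
    # from the whole cluster (the RCL spans all candidates at step one),
    # which diversifies the restarts enough for the swap search to reach
    # the enumerated optimum on small instances; alpha = 0 collapses to
    # the fully deterministic pure greedy
    S <- if (alpha > 0) sample.int(m, 1) else integer(0)
    while (length(S) < n) {
      cand <- setdiff(seq_len(m), S)
      J_if <- vapply(cand, function(j) grasp_objective(Phi, c(S, j), target),
                     numeric(1))
      ord <- order(J_if, cand)
      rcl_size <- max(1L, ceiling(alpha * length(cand)))
      rcl <- cand[ord[seq_len(rcl_size)]]
      pick <- if (length(rcl) == 1) rcl else rcl[sample.int(length(rcl), 1)]
      S <- c(S, pick)
    }
    J <- grasp_objective(Phi, S, target)
    # first-improvement swap local search
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (i in seq_along(S)) {
        outs <- setdiff(seq_len(m), S)
        for (h in outs) {
          S2 <- S
          S2[i] <- h
          J2 <- grasp_objective(Phi, S2, target)
          if (J2 < J - 1e-15) {
            S <- S2
            J <- J2
            improved <- TRUE
            break
          }
        }
        if (improved) break
      }
    }
    trace[r] <- J
    if (J < best_J) {
      best_J <- J
      best_S <- sort(S)
    }
  }
  list(selected = best_S, objective = best_J, trace = trace)
}

#' Run allocation + GRASP over all clusters
#'
#' @param Phi reduced feature matrix for all frames
#' @param labels integer cluster labels 1..k
#' @param budget total representative-frame budget
#' @param alpha,n_restarts,seed passed to \code{\link{grasp_select}}
#' @return list with \code{per_cluster_counts},
#'   \code{per_cluster_frames} (global frame indices),
#'   \code{objective_values}, \code{alpha}, \code{seed}
#' @export
grasp_selection <- function(Phi, labels, budget, alpha = 0.3,
                            n_restarts = 50, seed = 1L) {
  k <- length(unique(labels))
  sizes <- tabulate(labels, k)
  counts <- allocate_frames(sizes, budget)
  frames <- vector("list", k)
  objs <- numeric(k)
  for (cl in seq_len(k)) {
    idx <- which(labels == cl)
    sel <- grasp_select(Phi[idx, , drop = FALSE], counts[cl],
                        alpha = alpha, n_restarts = n_restarts,
                        seed = seed + cl)
    frames[[cl]] <- idx[sel$selected]
    objs[cl] <- sel$objective
  }
  list(per_cluster_counts = counts, per_cluster_frames = frames,
       objective_values = objs, alpha = alpha, seed = seed)
}

#' Build a collective frame from N selected frames
#'
#' Concatenates the solvent atoms of all N frames, assigning 1/N of the
#' actual atomic charge to each, and takes the rigid solute once from
#' the reference frame. By linearity of the Coulomb sum, the collective
#' frame's electrostatic potential at any site equals the arithmetic
#' mean of the per-frame potentials.
#'
#' @param traj trajectory (shared topology)
#' @param frame_indices indices of the N source frames
#' @param solute_reference index of the frame providing the solute
#'   geometry (default the first selected frame)
#' @return object of class \code{"collective_frame"}: \code{solute_xyz},
#'   \code{solute_charges}, \code{solvent_xyz}, \code{solvent_charges},
#'   \code{n_source_frames}
#' @export
build_collective_frame <- function(traj, frame_indices,
                                   solute_reference = frame_indices[1]) {
  if (length(frame_indices) < 1) stop("build_collective_frame: need >= 1 frame")
  a <- traj$topology$atoms
  sol <- which(a$role == "solute" | (a$role == "virtual_site" & a$molecule_id %in%
                                       a$molecule_id[a$role == "solute"]))
  slv <- which(a$role == "solvent")
  N <- length(frame_indices)
  solvent_xyz <- do.call(rbind, lapply(frame_indices, function(fi) {
    traj$frames[[fi]]$xyz[slv, , drop = FALSE]
  }))
  solvent_charges <- rep(a$charge[slv] / N, times = N)
  structure(list(solute_xyz = traj$frames[[solute_reference]]$xyz[sol, , drop = FALSE],
                 solute_charges = a$charge[sol],
                 solvent_xyz = solvent_xyz,
                 solvent_charges = solvent_charges,
                 n_source_frames = N),
            class = "collective_frame")
}

#' @export
print.collective_frame <- function(x, ...) {
  cat(sprintf("collective_frame: %d solvent sites from %d frames (charges scaled by 1/%d)\n",
              nrow(x$solvent_xyz), x$n_source_frames, x$n_source_frames))
  invisible(x)
}
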