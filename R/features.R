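#' Solute-solvent interaction feature space
#'
#' Per frame, the two candidate solvent atoms nearest to the midpoint of
#' the N-O bond define the first and second neighbours A1 and A2; the
#' emitted features are the six distances N-A1, N-A2, O-A1, O-A2,
#' LP1-A1, LP2-A2 (angstrom). Ties in the neighbour ranking are broken
#' by the lowest atom index, so the features are invariant to the file
#' order of equivalent candidates.
#'
#' @param traj trajectory
#' @param sites list with integer atom indices \code{N}, \code{O},
#'   \code{LP1}, \code{LP2}
#' @param candidates integer indices of candidate solvent atoms
#'   (typically the polar atoms declared in the topology)
#' @param per_site_neighbors if TRUE, A1/A2 are instead the nearest
#'   candidates to each individual site (alternative anchoring)
#' @return object of class \code{"feature_matrix"}: \code{values}
#'   (frames x 6), \code{feature_labels}, \code{frame_indices}
#' @export
extract_features <- function(traj, sites, candidates,
                             per_site_neighbors = FALSE) {
  for (nm in c("N", "O", "LP1", "LP2")) {
    if (is.null(sites[[nm]])) stop("extract_features: missing site ", nm)
  }
  if (length(candidates) < 2) stop("extract_features: need >= 2 candidate atoms")
  nf <- n_frames(traj)
  vals <- matrix(NA_real_, nf, 6)
  labels <- c("N-A1", "N-A2", "O-A1", "O-A2", "LP1-A1", "LP2-A2")
  for (fi in seq_len(nf)) {
    xyz <- traj$frames[[fi]]$xyz
    cand <- xyz[candidates, , drop = FALSE]
    if (nrow(cand) < 2) stop("extract_features: < 2 candidates in frame ", fi)
    nearest2 <- function(anchor) {
      d <- sqrt(rowSums(sweep(cand, 2, anchor, "-")^2))
      ord <- order(d, seq_along(d))  # ties -> lowest candidate index
      ord[1:2]
    }
    if (per_site_neighbors) {
      rowd <- function(site, rank) {
        id <- nearest2(xyz[site, ])[rank]
        sqrt(sum((xyz[site, ] - cand[id, ])^2))
      }
      vals[fi, ] <- c(rowd(sites$N, 1), rowd(sites$N, 2),
                      rowd(sites$O, 1), rowd(sites$O, 2),
                      rowd(sites$LP1, 1), rowd(sites$LP2, 2))
    } else {
      mid <- (xyz[sites$N, ] + xyz[sites$O, ]) / 2
      a12 <- nearest2(mid)
      A1 <- cand[a12[1], ]; A2 <- cand[a12[2], ]
      dd <- function(site, p) sqrt(sum((xyz[site, ] - p)^2))
      vals[fi, ] <- c(dd(sites$N, A1), dd(sites$N, A2),
                      dd(sites$O, A1), dd(sites$O, A2),
                      dd(sites$LP1, A1), dd(sites$LP2, A2))
    }
  }
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("extract_features: non-positive or missing distance produced")
  }
  structure(list(values = vals, feature_labels = labels,
                 frame_indices = seq_len(nf)),
            class = "feature_matrix")
}

#' PCA reduction of the feature matrix
#'
#' Features are centered but not scaled (they share the angstrom unit).
#' The smallest number of leading components whose cumulative explained
#' variance reaches \code{variance_target} is retained.
#'
#' @param X \code{feature_matrix} or plain numeric matrix (rows = frames)
#' @param variance_target cumulative explained-variance fraction (default 0.90)
#' @return list with \code{model} (means, components,
#'   explained_variance_ratio), \code{reduced} (frames x m scores),
#'   \code{m} components retained
#' @export
pca_fit_transform <- function(X, variance_target = 0.90) {
  vals <- if (inherits(X, "feature_matrix")) X$values else as.matrix(X)
  if (nrow(vals) < 2) stop("pca_fit_transform: need >= 2 frames")
  means <- colMeans(vals)
  centered <- sweep(vals, 2, means, "-")
  total_var <- sum(apply(centered, 2, stats::var))
  if (total_var < 1e-12) {
    warning("pca_fit_transform: zero-variance input; no components retained")
    return(list(model = list(means = means,
                             components = matrix(0, ncol(vals), 0),
                             explained_variance_ratio = numeric(0)),
                reduced = matrix(0, nrow(vals), 0), m = 0L))
  }
  pc <- stats::prcomp(vals, center = TRUE, scale. = FALSE)
  ratio <- pc$sdev^2 / sum(pc$sdev^2)
  m <- which(cumsum(ratio) >= variance_target - 1e-12)[1]
  list(model = list(means = means,
                    components = pc$rotation,
                    explained_variance_ratio = ratio),
       reduced = pc$x[, seq_len(m), drop = FALSE],
       m = as.integer(m))
}

#' Partitioning Around Medoids (multi-start BUILD + SWAP)
#'
#' Classic PAM with Euclidean distance: greedy BUILD seeding followed by
#' best-improvement SWAP until no single medoid/non-medoid exchange
#' lowers the total dissimilarity. Because the single-swap neighbourhood
#' has genuine local optima even on tiny instances, the SWAP phase is
#' additionally restarted from \code{n_starts - 1} seeded random medoid
#' sets and the lowest-cost converged solution is kept; the whole
#' procedure is deterministic given \code{seed}.
#'
#' @param X numeric matrix, rows are points (reduced feature space)
#' @param k number of clusters, 2 <= k <= n (k = n allowed: each point
#'   its own medoid)
#' @param seed integer seed for tie-breaking and the random restarts
#' @param n_starts total SWAP starts (BUILD plus random; default 10)
#' @return list with \code{labels} (1..k per point), \code{medoids}
#'   (row indices), \code{cost} (total distance to assigned medoid)
#' @export
pam_cluster <- function(X, k, seed = 1L, n_starts = 10L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 1 || k > n) stop("pam_cluster: k must be in [1, n]")
  D <- as.matrix(stats::dist(X))
  if (k == n) {
    return(list(labels = seq_len(n), medoids = seq_len(n), cost = 0))
  }
  set.seed(seed)
  tie_pick <- function(cands) if (length(cands) == 1) cands else sample(cands, 1)
  cost_of <- function(meds) sum(apply(D[, meds, drop = FALSE], 1, min))

  # BUILD: first medoid minimizes total distance; then greedy max gain
  tot <- colSums(D)
  medoids <- tie_pick(which(tot == min(tot)))
  dn <- D[, medoids]  # distance to nearest medoid
  while (length(medoids) < k) {
    gains <- vapply(seq_len(n), function(j) {
      if (j %in% medoids) return(-Inf)
      sum(pmax(dn - D[, j], 0))
    }, numeric(1))
    best <- max(gains)
    j <- tie_pick(which(gains >= best - 1e-12 & gains > -Inf))
    medoids <- c(medoids, j)
    dn <- pmin(dn, D[, j])
  }

  swap_converge <- function(meds) {
    cost <- cost_of(meds)
    repeat {
      best_cost <- cost
      best_swap <- NULL
      for (mi in seq_along(meds)) {
        for (h in setdiff(seq_len(n), meds)) {
          cand <- meds
          cand[mi] <- h
          cc <- cost_of(cand)
          if (cc < best_cost - 1e-12) {
            best_cost <- cc
            best_swap <- cand
          }
        }
      }
      if (is.null(best_swap)) break
      meds <- best_swap
      cost <- best_cost
    }
    list(medoids = meds, cost = cost)
  }

  best <- swap_converge(medoids)
  for (s in seq_len(max(0L, n_starts - 1L))) {
    r <- swap_converge(sample.int(n, k))
    if (r$cost < best$cost - 1e-12) best <- r
  }
  labels <- apply(D[, best$medoids, drop = FALSE], 1, which.min)
  list(labels = as.integer(labels), medoids = as.integer(best$medoids),
       cost = best$cost)
}

#' Internal cluster-validation scores
#'
#' SI: mean silhouette (singletons contribute 0). DI: minimum
#' between-cluster point separation over maximum cluster diameter.
#' pSF (Calinski-Harabasz): [B/(k-1)] / [W/(n-k)] with B/W the between-
#' and within-cluster dispersion about cluster means. WSS: total within
#' sum of squared distances to cluster means.
#'
#' @param X numeric matrix, rows are points
#' @param labels integer cluster labels 1..k
#' @return named list with \code{SI}, \code{DI}, \code{pSF}, \code{WSS}
#' @export
validation_scores <- function(X, labels) {
  X <- as.matrix(X)
  n <- nrow(X)
  k <- length(unique(labels))
  if (k < 2) stop("validation_scores: need >= 2 clusters")
  if (any(tabulate(labels, k) == 0)) stop("validation_scores: empty cluster")
  D <- as.matrix(stats::dist(X))

  sil <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    if (sum(own) == 1) return(0)
    a <- sum(D[i, own]) / (sum(own) - 1)
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(D[i, labels == cl]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))

  min_sep <- Inf
  max_diam <- 0
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) > 1) max_diam <- max(max_diam, max(D[idx, idx]))
    other <- which(labels != cl)
    min_sep <- min(min_sep, min(D[idx, other, drop = FALSE]))
  }
  DI <- if (max_diam > 0) min_sep / max_diam else Inf

  grand <- colMeans(X)
  W <- 0; B <- 0
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    mu <- colMeans(X[idx, , drop = FALSE])
    W <- W + sum(sweep(X[idx, , drop = FALSE], 2, mu, "-")^2)
    B <- B + length(idx) * sum((mu - grand)^2)
  }
  pSF <- if (W > 0) (B / (k - 1)) / (W / (n - k)) else Inf

  list(SI = mean(sil), DI = DI, pSF = pSF, WSS = W)
}

#' Choose the number of clusters by a 3-of-4 criterion vote
#'
#' SI, DI and pSF each vote for their maximizing k; WSS votes for the
#' elbow, the interior k maximizing the discrete second difference
#' WSS(k-1) - 2 WSS(k) + WSS(k+1). The k endorsed by at least three
#' criteria wins; failing that, the smallest k among those with the most
#' votes is returned with a low-confidence flag.
#'
#' @param scores data frame with columns \code{k}, \code{SI}, \code{DI},
#'   \code{pSF}, \code{WSS}, one row per candidate k (a contiguous range)
#' @return list with \code{k}, \code{votes} (named per-criterion picks),
#'   \code{confident} (logical)
#' @export
select_k <- function(scores) {
  if (nrow(scores) == 0) stop("select_k: empty score table")
  ks <- scores$k
  votes <- c(SI = ks[which.max(scores$SI)],
             DI = ks[which.max(scores$DI)],
             pSF = ks[which.max(scores$pSF)])
  if (nrow(scores) >= 3) {
    w <- scores$WSS
    second <- w[-c(length(w) - 1, length(w))] - 2 * w[-c(1, length(w))] +
      w[-c(1, 2)]
    votes <- c(votes, WSS = ks[1 + which.max(second)])
  }
  tab <- table(votes)
  top <- max(tab)
  winners <- sort(as.integer(names(tab)[tab == top]))
  list(k = winners[1], votes = votes, confident = top >= 3)
}
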