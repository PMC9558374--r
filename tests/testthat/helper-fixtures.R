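# shared fixture builders; everything is generated in code at test time

# minimal 3-atom topology for I/O tests
toy_topology <- function(n = 3) {
  topology(data.frame(
    name = paste0("A", seq_len(n)), element = rep("O", n),
    molecule_id = seq_len(n), role = "solvent",
    charge = rep(0, n), vdw_radius = rep(1.52, n)))
}

toy_trajectory <- function(n_frames = 2, n = 3, seed = 1) {
  set.seed(seed)
  frames <- lapply(seq_len(n_frames), function(i) {
    frame(matrix(round(rnorm(n * 3), 4), n, 3), time = i - 1)
  })
  trajectory(toy_topology(n), frames)
}

# single-A / many-B trajectory for RDF tests: atom 1 is A at the origin,
# the rest are B placed by `placer(frame_index)` returning an (n-1) x 3 matrix
rdf_trajectory <- function(n_B, n_frames, placer) {
  top <- topology(data.frame(
    name = c("A", paste0("B", seq_len(n_B))),
    element = c("N", rep("O", n_B)),
    molecule_id = seq_len(n_B + 1), role = "solvent",
    charge = 0, vdw_radius = 1.5))
  frames <- lapply(seq_len(n_frames), function(i) {
    frame(rbind(c(0, 0, 0), placer(i)), time = i - 1)
  })
  trajectory(top, frames)
}

random_sphere_points <- function(n, radius) {
  v <- matrix(rnorm(n * 3), n, 3)
  v <- v / sqrt(rowSums(v^2))
  v * radius * runif(n)^(1 / 3)
}

# brute-force coverage oracle: every sampled sphere point falls in a
# replica cell of the generated block
coverage_ok <- function(cell, center, r_max, n_pts = 1e4, seed = 1) {
  set.seed(seed)
  mols <- replicate_cell(cell, center, r_max)
  rng <- attr(mols, "shift_range")
  pts <- sweep(random_sphere_points(n_pts, r_max), 2, center, "+")
  frac <- t(solve(t(cell$lattice), t(sweep(pts, 2, cell$origin, "-"))))
  cells <- floor(frac)
  all(vapply(1:3, function(d) {
    all(cells[, d] >= rng$lo[d] & cells[, d] <= rng$hi[d])
  }, logical(1)))
}

# brute-force PAM: exact optimum over all k-subsets of medoids
brute_force_pam_cost <- function(X, k) {
  D <- as.matrix(dist(X))
  n <- nrow(X)
  best <- Inf
  for (meds in utils::combn(n, k, simplify = FALSE)) {
    cc <- sum(apply(D[, meds, drop = FALSE], 1, min))
    if (cc < best) best <- cc
  }
  best
}

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}
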