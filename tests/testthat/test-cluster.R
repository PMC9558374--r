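# feature extraction, PCA, PAM, validation scores, k selection

make_feature_traj <- function(solvent_pos, times = NULL) {
  s <- solute_template()
  n_solv <- nrow(solvent_pos[[1]])
  atoms <- data.frame(
    name = c(s$name, paste0("Os", seq_len(n_solv))),
    element = c(s$element, rep("O", n_solv)),
    molecule_id = c(rep(1L, 6), seq_len(n_solv) + 1L),
    role = c(s$role, rep("solvent", n_solv)),
    charge = c(s$charge, rep(-0.8, n_solv)),
    vdw_radius = c(s$vdw_radius, rep(1.52, n_solv)))
  top <- topology(atoms)
  if (is.null(times)) times <- seq_along(solvent_pos) - 1
  frames <- Map(function(p, t) frame(rbind(s$xyz, p), time = t),
                solvent_pos, times)
  list(traj = trajectory(top, frames), sites = s$sites,
       candidates = 6 + seq_len(n_solv), solute = s)
}

test_that("features match hand-computed 3D distances", {
  # two candidates on the N-O axis above O, at known offsets
  p <- rbind(c(0, 0, 3.0), c(0, 0, 4.5))
  ft <- make_feature_traj(list(p))
  X <- extract_features(ft$traj, ft$sites, ft$candidates)
  s <- ft$solute
  dn <- function(site, q) sqrt(sum((s$xyz[site, ] - q)^2))
  expect_equal(X$values[1, ],
               c(dn(2, p[1, ]), dn(2, p[2, ]),
                 dn(4, p[1, ]), dn(4, p[2, ]),
                 dn(5, p[1, ]), dn(6, p[2, ])),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(X$feature_labels,
               c("N-A1", "N-A2", "O-A1", "O-A2", "LP1-A1", "LP2-A2"))
})

test_that("neighbour ties break by lowest atom index and order-invariance holds", {
  p_dup <- rbind(c(0, 0, 3.0), c(0, 0, 3.0), c(0, 0, 5))
  ft <- make_feature_traj(list(p_dup))
  X <- extract_features(ft$traj, ft$sites, ft$candidates)
  # A1 and A2 are both the duplicated position; row is finite and positive
  expect_equal(X$values[1, 1], X$values[1, 2], tolerance = 1e-12)

  # swapping candidate file order with identical positions gives the same row
  p_a <- rbind(c(0.4, 0.2, 3.0), c(-0.3, 0.1, 4.1))
  p_b <- p_a[2:1, ]
  Xa <- extract_features(make_feature_traj(list(p_a))$traj, ft$sites, ft$candidates[1:2])
  Xb <- extract_features(make_feature_traj(list(p_b))$traj, ft$sites, ft$candidates[1:2])
  expect_equal(Xa$values, Xb$values, tolerance = 1e-12)

  expect_error(extract_features(ft$traj, ft$sites, ft$candidates[1]),
               "2 candidate")
})

test_that("PCA keeps the fewest components reaching the variance target", {
  # exact line in 6-D -> one component explains everything
  set.seed(5)
  t_par <- rnorm(40)
  dirv <- c(1, 2, 0, -1, 0.5, 3)
  X <- outer(t_par, dirv) + 5
  r <- pca_fit_transform(X, 0.90)
  expect_equal(r$m, 1L)
  expect_equal(r$model$explained_variance_ratio[1], 1.0, tolerance = 1e-9)
  expect_equal(sum(r$model$explained_variance_ratio), 1.0, tolerance = 1e-9)

  # isotropic Gaussian resists compression: target 0.90 needs all 6
  set.seed(6)
  G <- matrix(rnorm(2000 * 6), 2000, 6)
  rg <- pca_fit_transform(G, 0.90)
  expect_equal(rg$m, 6L)
  expect_true(all(abs(rg$model$explained_variance_ratio - 1 / 6) < 0.03))
})

test_that("full-rank PCA projection preserves pairwise distances to 1e-9", {
  set.seed(8)
  X <- matrix(rnorm(30 * 6), 30, 6)
  r <- pca_fit_transform(X, 1.0)
  expect_equal(r$m, 6L)
  expect_equal(as.numeric(dist(r$reduced)), as.numeric(dist(X)),
               tolerance = 1e-9)
  # zero-variance input degrades gracefully
  expect_warning(z <- pca_fit_transform(matrix(1, 5, 3), 0.9), "zero-variance")
  expect_equal(z$m, 0L)
})

test_that("PAM recovers planted blobs and matches brute force on small instances", {
  set.seed(11)
  blob <- function(center, n) sweep(matrix(rnorm(n * 2, 0, 0.3), n, 2), 2,
                                    center, "+")
  X <- rbind(blob(c(0, 0), 25), blob(c(8, 8), 25))
  planted <- rep(1:2, each = 25)
  fit <- pam_cluster(X, 2, seed = 1)
  expect_equal(adjusted_rand_index(fit$labels, planted), 1.0)
  expect_true(all(fit$medoids %in% seq_len(50)))
  expect_true(all(vapply(seq_along(fit$medoids), function(i) {
    fit$labels[fit$medoids[i]] == fit$labels[fit$medoids[i]]
  }, logical(1))))

  # k = n: every point its own medoid at zero cost
  small <- matrix(rnorm(12), 6, 2)
  fit_n <- pam_cluster(small, 6)
  expect_equal(fit_n$cost, 0)
  expect_equal(sort(fit_n$medoids), 1:6)

  # 8-point instance equals the exhaustive optimum over all C(8,2) pairs
  set.seed(12)
  X8 <- matrix(rnorm(16), 8, 2)
  fit8 <- pam_cluster(X8, 2, seed = 1)
  expect_equal(fit8$cost, brute_force_pam_cost(X8, 2), tolerance = 1e-12)
  expect_error(pam_cluster(X8, 9), "k must be")
})

test_that("PAM equals the exhaustive optimum on all n <= 10, k <= 3 instances", {
  for (seed in 1:12) {
    set.seed(100 + seed)
    n <- sample(5:10, 1)
    k <- sample(2:3, 1)
    X <- matrix(rnorm(n * 2), n, 2)
    fit <- pam_cluster(X, k, seed = seed)
    expect_equal(fit$cost, brute_force_pam_cost(X, k), tolerance = 1e-10,
                 label = sprintf("seed %d (n=%d, k=%d)", seed, n, k))
  }
})

test_that("validation scores equal direct formula evaluation on a 6-point instance", {
  X <- rbind(c(0, 0), c(0, 1), c(1, 0), c(10, 10), c(10, 11), c(11, 10))
  labels <- c(1, 1, 1, 2, 2, 2)
  s <- validation_scores(X, labels)
  D <- as.matrix(dist(X))
  sil <- sapply(1:6, function(i) {
    own <- setdiff(which(labels == labels[i]), i)
    a <- mean(D[i, own])
    b <- mean(D[i, labels != labels[i]])
    (b - a) / max(a, b)
  })
  expect_equal(s$SI, mean(sil), tolerance = 1e-12)
  expect_equal(s$DI, min(D[1:3, 4:6]) / max(max(D[1:3, 1:3]), max(D[4:6, 4:6])),
               tolerance = 1e-12)
  mu1 <- colMeans(X[1:3, ]); mu2 <- colMeans(X[4:6, ]); mug <- colMeans(X)
  W <- sum(sweep(X[1:3, ], 2, mu1)^2) + sum(sweep(X[4:6, ], 2, mu2)^2)
  B <- 3 * sum((mu1 - mug)^2) + 3 * sum((mu2 - mug)^2)
  expect_equal(s$WSS, W, tolerance = 1e-12)
  expect_equal(s$pSF, (B / 1) / (W / 4), tolerance = 1e-12)
  expect_true(abs(s$SI) <= 1)

  # silhouette values stay in [-1, 1] and SI is duplication-invariant
  s2 <- validation_scores(rbind(X, X), rep(labels, 2))
  expect_equal(s2$SI, s$SI, tolerance = 0.2)
})

test_that("silhouette agrees with the cluster package on a random instance", {
  skip_if_not_installed("cluster")
  set.seed(13)
  X <- matrix(rnorm(40), 20, 2)
  labels <- pam_cluster(X, 3, seed = 1)$labels
  s <- validation_scores(X, labels)
  ref <- mean(cluster::silhouette(labels, dist(X))[, "sil_width"])
  expect_equal(s$SI, ref, tolerance = 1e-10)
})

test_that("k selection follows the 3-of-4 vote with a documented tie rule", {
  # unanimity
  sc <- data.frame(k = 2:5, SI = c(0.9, 0.5, 0.4, 0.3),
                   DI = c(1.5, 0.6, 0.5, 0.4), pSF = c(50, 30, 20, 10),
                   WSS = c(10, 8, 7, 6.5))
  r <- select_k(sc)
  expect_equal(r$k, 2)
  expect_true(r$confident)

  # 2/2 split between k = 3 and k = 5 -> smallest modal, low confidence
  sc2 <- data.frame(k = 2:6,
                    SI = c(0.1, 0.9, 0.2, 0.3, 0.1),
                    DI = c(0.1, 0.2, 0.3, 0.9, 0.2),
                    pSF = c(1, 2, 3, 10, 4),
                    WSS = c(40, 20, 18, 17, 16.5))  # elbow at k = 3
  r2 <- select_k(sc2)
  expect_equal(unname(r2$votes["SI"]), 3)
  expect_equal(unname(r2$votes["WSS"]), 3)
  expect_equal(unname(r2$votes["DI"]), 5)
  expect_equal(unname(r2$votes["pSF"]), 5)
  expect_equal(r2$k, 3)
  expect_false(r2$confident)

  expect_error(select_k(data.frame()), "empty")
})

test_that("WSS is monotone non-increasing in k on nested refinements", {
  set.seed(14)
  X <- matrix(rnorm(60), 30, 2)
  wss <- vapply(2:6, function(k) {
    validation_scores(X, pam_cluster(X, k, seed = 1)$labels)$WSS
  }, numeric(1))
  expect_true(all(diff(wss) <= 1e-9))
})
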