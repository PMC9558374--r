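# RDF, coordination numbers, hydrogen-bond perception, subsampling

test_that("ideal-gas RDF is 1 within Poisson bin error away from the wall", {
  set.seed(101)
  R_box <- 10
  n_B <- 400
  n_fr <- 25
  traj <- rdf_trajectory(n_B, n_fr, function(i) random_sphere_points(n_B, R_box))
  r <- compute_rdf(traj, sel_A = 1, sel_B = 2:(n_B + 1),
                   r_min = 0, r_max = 8, n_bins = 40, r_norm = 7.5)
  rho <- n_B / (4 / 3 * pi * R_box^3)
  expect_equal(r$rho_B, rho, tolerance = 0.05)
  sel <- r$bin_centers > 1 & r$bin_centers < 6
  expected_counts <- n_fr * rho * 4 * pi * r$bin_centers[sel]^2 * r$dr
  sigma_g <- 1 / sqrt(expected_counts)
  expect_true(all(abs(r$g[sel] - 1) < 3 * sigma_g))
})

test_that("a single B at distance d lights only the bin containing d", {
  traj <- rdf_trajectory(1, 1, function(i) matrix(c(3.21, 0, 0), 1, 3))
  r <- compute_rdf(traj, 1, 2, r_min = 0, r_max = 5, n_bins = 50)
  expect_equal(sum(r$g > 0), 1)
  expect_lt(abs(r$bin_centers[which.max(r$g)] - 3.21), r$dr)
})

test_that("a planted shell at 1.93 A peaks within one bin of 1.93", {
  set.seed(102)
  n_fr <- 40
  traj <- rdf_trajectory(6, n_fr, function(i) {
    shell <- random_sphere_points(2, 1)
    shell <- shell / sqrt(rowSums(shell^2)) * rnorm(2, 1.93, 0.03)
    rbind(shell, random_sphere_points(4, 8) + 3)  # background off-center
  })
  r <- compute_rdf(traj, 1, 2:7, r_min = 0.5, r_max = 6, n_bins = 110)
  expect_lt(abs(r$bin_centers[which.max(r$g)] - 1.93), r$dr + 1e-9)
})

test_that("coordination number integrates the planted two-neighbour shell", {
  set.seed(103)
  traj <- rdf_trajectory(8, 50, function(i) {
    shell <- matrix(rnorm(6), 2, 3)
    shell <- shell / sqrt(rowSums(shell^2)) * rnorm(2, 2.0, 0.05)
    far <- random_sphere_points(6, 3)
    far <- far / pmax(sqrt(rowSums(far^2)), 1e-9) * runif(6, 5, 9)
    rbind(shell, far)
  })
  r <- compute_rdf(traj, 1, 2:9, r_min = 0.5, r_max = 9.5, n_bins = 180,
                   r_norm = 9)
  n <- coordination_number(r, 3.5)
  expect_equal(n, 2.0, tolerance = 0.1)
  # monotone non-decreasing in r_cut
  cuts <- seq(1, 9, by = 0.5)
  ns <- vapply(cuts, function(rc) coordination_number(r, rc), numeric(1))
  expect_true(all(diff(ns) >= -1e-12))
  expect_error(coordination_number(r, 20), "outside")
})

test_that("uniform g integrates to the analytic sphere volume", {
  r <- structure(list(bin_centers = seq(0.05, 4.95, by = 0.1),
                      g = rep(1, 50), rho_B = 0.03, dr = 0.1),
                 class = "rdf")
  expect_equal(coordination_number(r, 4.5),
               0.03 * 4 / 3 * pi * 4.5^3, tolerance = 0.01)
  r$g[] <- 0
  expect_equal(coordination_number(r, 4.5), 0)
})

test_that("first extremum detection finds peaks and inter-peak minima", {
  mk <- function(g) structure(list(bin_centers = seq_along(g) / 10, g = g,
                                   rho_B = 1, dr = 0.1), class = "rdf")
  x <- seq(0.1, 6, by = 0.1)
  bump <- mk(exp(-(x - 2)^2 / 0.18))
  expect_lt(abs(find_first_extremum(bump, "peak") - 2), 0.11)

  two <- mk(exp(-(x - 2)^2 / 0.18) + 0.8 * exp(-(x - 4)^2 / 0.18))
  m <- find_first_extremum(two, "minimum_after_peak")
  expect_gt(m, 2)
  expect_lt(m, 4)
  # brute-force scan agrees
  g2 <- two$g
  expect_lt(abs(m - two$bin_centers[which.min(replace(g2, two$bin_centers < 2 |
                                                        two$bin_centers > 4, Inf))]),
            0.35)

  expect_error(find_first_extremum(mk(x), "peak"), "no local maximum")
})

test_that("f_hb matches its defining properties at the empirical parameters", {
  expect_equal(f_hb(1.85, 0), 1.0)
  expect_equal(f_hb(1.2, 0), 1.0)           # plateau below R0
  expect_equal(f_hb(10, 0), 0.0)            # below the 1e-4 floor
  # monotone decay on a grid beyond (R0, theta0)
  Rs <- seq(1.85, 3.2, by = 0.05)
  ths <- seq(0, 40, by = 2)
  for (th in ths) expect_true(all(diff(f_hb(Rs, rep(th, length(Rs)))) <= 0))
  for (R in Rs) expect_true(all(diff(f_hb(rep(R, length(ths)), ths)) <= 0))
  # symmetric in theta about theta0 = 0
  expect_equal(f_hb(2.0, 12), f_hb(2.0, -12))
  # bounded
  g <- expand.grid(R = seq(0.5, 5, by = 0.25), th = seq(0, 180, by = 10))
  v <- f_hb(g$R, g$th)
  expect_true(all(v >= 0 & v <= 1))
  expect_error(hb_params(sigma_R = -1), "sigma")
})

test_that("a permanently ideal planted hydrogen bond scores ~1 per frame", {
  spec <- regime_spec(list(list(hb_count = 1, r_mean = 1.7, r_sd = 0.02,
                                theta_sd = 0.5, dwell = 1)),
                      n_frames = 30, n_solvent = 4, seed = 21)
  g <- gen_trajectory(spec)
  don <- find_donors(g$trajectory$topology, g$trajectory$frames[[1]])
  acc <- which(g$trajectory$topology$atoms$name == "O")
  hs <- hb_scan(g$trajectory, don, acc)
  expect_equal(hs$mean, 1.0, tolerance = 0.01)
  # bookkeeping identity: mean equals the mean of per-frame sums
  expect_equal(hs$mean, mean(hs$per_frame_sum))
  sums <- tapply(hs$records$f_hb, hs$records$frame_index, sum)
  expect_equal(as.numeric(sums), hs$per_frame_sum)
})

test_that("no donors near the acceptor gives a zero mean", {
  spec <- regime_spec(list(list(hb_count = 0, r_mean = 1.8, r_sd = 0.1,
                                theta_sd = 5, dwell = 1)),
                      n_frames = 10, n_solvent = 4, seed = 22)
  g <- gen_trajectory(spec)
  don <- find_donors(g$trajectory$topology, g$trajectory$frames[[1]])
  acc <- which(g$trajectory$topology$atoms$name == "O")
  hs <- hb_scan(g$trajectory, don, acc)
  expect_equal(hs$mean, 0.0)
})

test_that("a 50/50 bonded/unbonded mixture is bimodal with mean 1/2", {
  spec <- regime_spec(list(
    list(hb_count = 1, r_mean = 1.7, r_sd = 0.02, theta_sd = 0.5, dwell = 0.5),
    list(hb_count = 0, r_mean = 1.7, r_sd = 0.02, theta_sd = 0.5, dwell = 0.5)),
    n_frames = 60, n_solvent = 4, seed = 23)
  g <- gen_trajectory(spec)
  don <- find_donors(g$trajectory$topology, g$trajectory$frames[[1]])
  acc <- which(g$trajectory$topology$atoms$name == "O")
  hs <- hb_scan(g$trajectory, don, acc)
  expect_equal(hs$mean, 0.5, tolerance = 0.05)
  h <- hs$histogram
  near0 <- sum(h$count[h$mid < 0.25])
  near1 <- sum(h$count[h$mid > 0.75 & h$mid < 1.25])
  expect_equal(near0, 30, tolerance = 3)
  expect_equal(near1, 30, tolerance = 3)
  expect_equal(sum(h$count[h$mid >= 0.25 & h$mid <= 0.75]), 0)
})

test_that("subsampling keeps the frames nearest to the stride targets", {
  top <- toy_topology(1)
  mk <- function(times) trajectory(top, lapply(times, function(t) {
    frame(matrix(t, 1, 3), time = t)
  }))
  # identity when stride equals native spacing
  t10 <- mk(seq(0, 1000, by = 10))
  expect_equal(n_frames(subsample(t10, 10)), n_frames(t10))
  # 1000 frames at 1 ps, stride 10 -> floor(999/10)+1 = 100 frames
  t1 <- mk(0:999)
  s <- subsample(t1, 10)
  expect_equal(n_frames(s), 100)
  expect_equal(s$times, seq(0, 990, by = 10))
  # irregular timestamps: picked times within half native spacing of targets
  set.seed(3)
  irr <- sort(cumsum(runif(200, 0.5, 1.5)))
  ti <- mk(irr)
  si <- subsample(ti, 5)
  targets <- irr[1] + 5 * seq(0, floor((max(irr) - irr[1]) / 5))
  for (t in targets) {  # brute-force nearest-time oracle
    expect_true(irr[which.min(abs(irr - t))] %in% si$times)
  }
  expect_error(subsample(t10, 5), "stride")
})
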