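#' End-to-end unsupervised workflow
#'
#' Runs the full chain from a trajectory to a solvatochromic shift
#' table: 10-ps subsampling, interaction-feature extraction, PCA
#' reduction, PAM clustering with 3-of-4 criterion selection of k,
#' proportional GRASP frame selection, collective-frame construction
#' (point-charge export), per-frame PMM excitation energies, Gaussian
#' broadening, cluster-weighted averaging, and the composition of the
#' final per-cluster band positions. Externally computed quantities
#' (centroid maxima with/without explicit QM solvent, vibrationally
#' resolved maxima) enter through the config's shift-table block; the
#' PMM stage supplies the perturbed positions where a QM reference file
#' is given.
#'
#' @param config nested list (or path to a YAML file) with blocks
#'   \code{trajectory} (path + topology or a synthetic spec),
#'   \code{clustering} (\code{stride_ps}, \code{variance_target},
#'   \code{k_min}, \code{k_max}, \code{seed}), \code{grasp}
#'   (\code{budget}, \code{alpha}, \code{n_restarts}), \code{pmm}
#'   (\code{qm_reference} path, \code{hwhm}, grid limits) and
#'   \code{shift_table} (per-solvent externally supplied rows and
#'   weights, reference solvent label)
#' @param outdir directory for stage artifacts (created if missing);
#'   NULL suppresses file output
#' @return list with \code{clustering}, \code{selection},
#'   \code{collective_frames}, \code{pmm_spectra}, \code{shift_table}
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  emit <- function(name, df) {
    if (!is.null(outdir)) {
      utils::write.csv(df, file.path(outdir, name), row.names = FALSE)
    }
  }

  # stage 0: obtain trajectory
  tc <- config$trajectory
  if (!is.null(tc$synthetic_spec)) {
    spec <- do.call(regime_spec, tc$synthetic_spec)
    gen <- gen_trajectory(spec)
    traj <- gen$trajectory
  } else {
    top <- read_topology_yaml(tc$topology)
    traj <- read_trajectory(tc$path, top)
  }

  # validate late-stage inputs up front so analysis stages never rerun
  # against a missing QM reference
  ref <- NULL
  if (!is.null(config$pmm$qm_reference)) {
    if (!file.exists(config$pmm$qm_reference)) {
      stop("run_pipeline: QM reference file not found: ",
           config$pmm$qm_reference)
    }
    ref <- read_qm_reference(config$pmm$qm_reference)
  }

  cl <- config$clustering
  if (is.null(cl)) cl <- list()
  stride <- cl$stride_ps %||% 10
  vtarget <- cl$variance_target %||% 0.90
  k_min <- cl$k_min %||% 2
  k_max <- cl$k_max %||% 20
  seed <- cl$seed %||% 1L

  # stage 1: subsample + features + PCA
  sub <- subsample(traj, stride)
  a <- sub$topology$atoms
  sites <- list(N = which(a$name == "N")[1], O = which(a$name == "O")[1],
                LP1 = which(a$name == "LP1")[1],
                LP2 = which(a$name == "LP2")[1])
  candidates <- which(a$role == "solvent" & a$element %in% c("O", "N"))
  feats <- extract_features(sub, sites, candidates)
  red <- pca_fit_transform(feats, vtarget)
  emit("features.csv", as.data.frame(feats$values))

  # stage 2: PAM over the k range, 3-of-4 selection
  k_max_eff <- min(k_max, nrow(red$reduced) - 1)
  score_rows <- lapply(k_min:k_max_eff, function(k) {
    fit <- pam_cluster(red$reduced, k, seed = seed)
    s <- validation_scores(red$reduced, fit$labels)
    data.frame(k = k, SI = s$SI, DI = s$DI, pSF = s$pSF, WSS = s$WSS)
  })
  scores <- do.call(rbind, score_rows)
  pick <- select_k(scores)
  fit <- pam_cluster(red$reduced, pick$k, seed = seed)
  emit("cluster_scores.csv", scores)
  emit("cluster_labels.csv",
       data.frame(frame = seq_along(fit$labels), label = fit$labels))

  # stage 3: GRASP selection + collective frames
  gc_ <- config$grasp
  if (is.null(gc_)) gc_ <- list()
  budget <- gc_$budget %||% max(pick$k, round(0.05 * nrow(red$reduced)))
  sel <- grasp_selection(red$reduced, fit$labels, budget,
                         alpha = gc_$alpha %||% 0.3,
                         n_restarts = gc_$n_restarts %||% 50,
                         seed = seed)
  cframes <- lapply(sel$per_cluster_frames, function(fidx) {
    build_collective_frame(sub, fidx)
  })
  if (!is.null(outdir)) {
    for (i in seq_along(cframes)) {
      write_point_charges(cframes[[i]]$solvent_xyz,
                          cframes[[i]]$solvent_charges,
                          file.path(outdir, sprintf("cframe_cluster%d.pc", i)))
    }
  }

  # stage 4: PMM per cluster + broadened spectra
  pmm_spectra <- NULL
  lambda_pmm <- NULL
  if (!is.null(ref)) {
    pc <- config$pmm
    hwhm <- pc$hwhm %||% 600
    grid_nm <- seq(pc$grid_min %||% 200, pc$grid_max %||% 800,
                   by = pc$grid_step %||% 0.1)
    solute_sites <- which(a$role == "solute")
    charge_sites <- which(a$role == "solvent")
    pmm_spectra <- lapply(seq_len(pick$k), function(clid) {
      res <- pmm_trajectory(sub, ref, solute_sites, charge_sites,
                            frame_indices = which(fit$labels == clid))
      spectrum_from_pmm(res, hwhm = hwhm, grid_nm = grid_nm)
    })
    lambda_pmm <- vapply(pmm_spectra, `[[`, numeric(1), "lambda_max")
  }

  # stage 5: shift table
  shift_table <- NULL
  st <- config$shift_table
  if (!is.null(st)) {
    solvents <- names(st$solvents)
    rows <- lapply(solvents, function(sv) {
      b <- st$solvents[[sv]]
      lam_pmm <- as.numeric(b$lambda_pmm %||% lambda_pmm)
      tot <- mapply(compose_total, as.numeric(b$lambda_cf),
                    as.numeric(b$lambda_c2qm), as.numeric(b$lambda_c0qm),
                    as.numeric(b$lambda_pmm_vib), lam_pmm)
      data.frame(solvent = sv, cluster = seq_along(tot),
                 lambda_cf = as.numeric(b$lambda_cf),
                 lambda_c2qm = as.numeric(b$lambda_c2qm),
                 lambda_c0qm = as.numeric(b$lambda_c0qm),
                 lambda_pmm_vib = as.numeric(b$lambda_pmm_vib),
                 lambda_pmm = lam_pmm,
                 weight = as.numeric(b$weights), total = tot)
    })
    per_cluster <- do.call(rbind, rows)
    avgs <- vapply(solvents, function(sv) {
      r <- per_cluster[per_cluster$solvent == sv, ]
      weighted_average(r$total, r$weight)
    }, numeric(1))
    deltas <- shift_vs_reference(avgs, st$reference)
    shift_table <- list(per_cluster = per_cluster,
                        average = avgs, delta = deltas,
                        reference = st$reference)
    emit("shift_table.csv", per_cluster)
  }

  list(trajectory = traj, subsampled = sub, features = feats,
       pca = red, scores = scores, k = pick, clustering = fit,
       selection = sel, collective_frames = cframes,
       pmm_spectra = pmm_spectra, shift_table = shift_table)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
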