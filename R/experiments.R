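## Experiment pipelines: cluster-area volume scaling, septin ring
## experiments from polarization checkpoints, and the parameter-sensitivity
## harness. All runs are reproducible: per-cell seeds derive from a master
## seed and the cell's (volume index, replicate) position, so adding
## replicates never reshuffles existing ones.

#' Derive a per-cell seed from a master seed
#'
#' Deterministic splittable seeding: `seed(master, i, j)` depends only on
#' the indices, stays within 32-bit integer range, and distinct index
#' combinations give distinct streams.
#'
#' @param master Master seed (integer).
#' @param ... Non-negative integer indices (experiment, volume, replicate,
#'   ...).
#' @return Integer seed.
#' @export
derive_seed <- function(master, ...) {
  idx <- c(...)
  h <- as.double(master) %% 2147483647
  for (k in idx) {
    h <- (h * 48271 + as.double(k) * 1009 + 12345) %% 2147483647
  }
  as.integer(h + 1)
}

# Cheap stable hash of a configuration (hex string).
.config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  v <- utf8ToInt(as.character(s))
  h <- 5381
  for (ch in v) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Experiment configuration
#'
#' @param experiment Identifier string.
#' @param model `"positive"` or `"negative"` feedback for polarization
#'   experiments.
#' @param volumes Cell volumes (fL).
#' @param replicates Replicates per volume.
#' @param protein_slope Protein slope applied to Cdc42/BemGEF totals
#'   (see [scaling_config()]).
#' @param master_seed Master RNG seed.
#' @param target_nodes Mesh resolution (default 2562, the desk-scale
#'   preset; full-fidelity runs use 9451-node meshes).
#' @param delta Initial perturbation magnitude.
#' @param gap_factor Multiplier on the basal hydrolysis rate (GAP
#'   perturbations).
#' @param t_end Integration horizon (s).
#' @param rel_tol,ss_rate_tol Solver tolerances for the preset.
#' @param output_dir Optional directory for CSV output.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(experiment = "cluster_scaling",
                              model = c("positive", "negative"),
                              volumes = c(65, 105, 170, 270),
                              replicates = 3,
                              protein_slope = 0,
                              master_seed = 1L,
                              target_nodes = 2562,
                              delta = 0.05,
                              gap_factor = 1,
                              t_end = 1500,
                              rel_tol = 2e-3,
                              ss_rate_tol = 5e-4,
                              output_dir = NULL) {
  model <- match.arg(model)
  stopifnot(replicates >= 1, all(volumes > 0))
  structure(list(experiment = experiment, model = model, volumes = volumes,
                 replicates = replicates, protein_slope = protein_slope,
                 master_seed = master_seed, target_nodes = target_nodes,
                 delta = delta, gap_factor = gap_factor, t_end = t_end,
                 rel_tol = rel_tol, ss_rate_tol = ss_rate_tol,
                 output_dir = output_dir),
            class = "experiment_config")
}

.base_params <- function(config) {
  if (config$model == "negative")
    negative_feedback_params(gap_factor = config$gap_factor)
  else
    positive_feedback_params(gap_factor = config$gap_factor)
}

#' Cluster-area versus cell-volume scaling experiment
#'
#' For each (volume, replicate): rescale the protein totals by the protein
#' slope, build the mesh, perturb the homogeneous steady state, integrate
#' to a polarized steady state and measure the Cdc42-GTP cluster area.
#' Cells that fail to polarize, or end in a multi-cluster state, are
#' retained in the output with a status flag and excluded from the log-log
#' fit.
#'
#' @param config An [experiment_config()].
#' @param progress Print one line per cell.
#' @return List of class `scaling_experiment`: `cells` (data frame),
#'   `scaling` (a [fit_loglog_slope()] result or `NULL` if fewer than 3
#'   usable cells), `config`, `config_hash`.
#' @export
run_cluster_scaling <- function(config = experiment_config(),
                                progress = FALSE) {
  base <- .base_params(config)
  sc <- scaling_config(protein_slope = config$protein_slope)
  hash <- .config_hash(unclass(config))
  ver <- as.character(utils::packageVersion("septring"))
  solver <- solver_config(t_end = config$t_end, rel_tol = config$rel_tol,
                          ss_rate_tol = config$ss_rate_tol)
  rows <- list()
  for (iv in seq_along(config$volumes)) {
    V <- config$volumes[iv]
    params <- scale_amounts_with_volume(base, V, sc)
    eta <- membrane_cytosol_ratio(volume_to_radius(V))
    wm <- tryCatch(well_mixed_steady_state(params, eta), error = function(e) NULL)
    for (ir in seq_len(config$replicates)) {
      seed <- derive_seed(config$master_seed, iv, ir)
      row <- data.frame(volume_fL = V, replicate = ir, seed = seed,
                        protein_slope = config$protein_slope,
                        cluster_area_um2 = NA_real_, fraction = NA_real_,
                        max_Cdc42T = NA_real_, n_clusters = NA_integer_,
                        polarized = FALSE, steady = FALSE,
                        status = "ok", config_hash = hash, version = ver)
      res <- tryCatch({
        traj <- polarize_cell(V, params, target_nodes = config$target_nodes,
                              seed = seed, delta = config$delta,
                              config = solver, wm = wm)
        fld <- traj$state$fields[, "Cdc42T"]
        pol <- is_polarized(fld)
        row$polarized <- pol
        row$steady <- traj$steady_state
        row$max_Cdc42T <- max(fld)
        if (pol) {
          cm <- cluster_area(fld, traj$mesh)
          row$cluster_area_um2 <- cm$area
          row$fraction <- cm$fraction
          row$n_clusters <- cm$n_clusters
          if (cm$n_clusters > 1L) row$status <- "multi_cluster"
        } else {
          row$status <- "not_polarized"
        }
        row
      }, error = function(e) { row$status <- paste0("error: ", conditionMessage(e)); row })
      if (progress)
        message(sprintf("V = %g fL rep %d: %s area = %.3g um^2",
                        V, ir, res$status, res$cluster_area_um2))
      rows[[length(rows) + 1L]] <- res
    }
  }
  cells <- do.call(rbind, rows)
  usable <- cells$status == "ok" & cells$polarized
  scaling <- if (sum(usable) >= 3 && length(unique(cells$volume_fL[usable])) >= 2)
    fit_loglog_slope(cells$volume_fL[usable], cells$cluster_area_um2[usable])
  else NULL
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(cells, file.path(config$output_dir,
                               paste0(config$experiment, "_cells.csv")),
              row.names = FALSE)
  }
  structure(list(cells = cells, scaling = scaling, config = config,
                 config_hash = hash),
            class = "scaling_experiment")
}

#' @export
print.scaling_experiment <- function(x, ...) {
  cat(sprintf("scaling_experiment '%s' (%s model): %d cells, %d usable\n",
              x$config$experiment, x$config$model, nrow(x$cells),
              sum(x$cells$status == "ok" & x$cells$polarized)))
  if (!is.null(x$scaling)) print(x$scaling)
  invisible(x)
}

## ---- septin ring experiments ----------------------------------------------

#' Polarization checkpoint for the septin module
#'
#' Runs the Cdc42 polarization module (the positive-feedback cycle with the
#' septin model's Cdc42 parameters) to a polarized steady state, then
#' assembles the initial septin-model state: the Cdc42 cluster from the
#' checkpoint, all septin-module membrane species at zero, and the septin,
#' Axl2 and GapS pools fully cytosolic.
#'
#' @param params A [septin_params()] object.
#' @param volume Cell volume (fL).
#' @param target_nodes Mesh resolution.
#' @param seed Perturbation seed.
#' @param t_end Polarization horizon (s).
#' @param rel_tol,ss_rate_tol Solver tolerances.
#' @return List of class `septin_checkpoint`: `state` (a `membrane_state`
#'   for the septin model, t = 0), `mesh`, `eta`, `params`.
#' @export
septin_checkpoint <- function(params = septin_params(), volume = 33,
                              target_nodes = 642, seed = 1L, t_end = 2000,
                              rel_tol = 2e-3, ss_rate_tol = 5e-4) {
  pol <- positive_feedback_params(
    k1a = params$k1a, k1b = params$k1b, k2a = params$k2a, k2b = params$k2b,
    k3 = params$k3, k4a = params$k4a, k4b = params$k4b, k5a = params$k5a,
    k5b = params$k5b, k7 = params$k7, Dm = params$Dm,
    Cdc42_tot = params$Cdc42_tot, BemGEF_tot = params$BemGEF_tot)
  traj <- polarize_cell(volume, pol, target_nodes = target_nodes,
                        seed = seed,
                        config = solver_config(t_end = t_end,
                                               rel_tol = rel_tol,
                                               ss_rate_tol = ss_rate_tol))
  Fp <- traj$state$fields
  N <- nrow(Fp)
  F <- matrix(0, N, length(.sep_species),
              dimnames = list(NULL, .sep_species))
  F[, c("Cdc42T", "Cdc42D", "BemGEF42", "BemGEFm")] <-
    Fp[, c("Cdc42T", "Cdc42D", "BemGEF42", "BemGEFm")]
  cyto <- c(Cdc42I = unname(traj$state$cyto[["Cdc42I"]]),
            BemGEFc = unname(traj$state$cyto[["BemGEFc"]]),
            GapSc = params$GapS_tot, Axl2c = params$Axl2_tot,
            Sc = params$Septin_tot)
  structure(list(state = membrane_state(F, cyto, t = 0), mesh = traj$mesh,
                 eta = traj$eta, params = params, volume = volume,
                 polarized = is_polarized(Fp[, "Cdc42T"])),
            class = "septin_checkpoint")
}

#' Run a septin ring experiment from a checkpoint
#'
#' Integrates the SBE or SBER model from a Cdc42-GTP cluster checkpoint
#' with the configured exocytosis settings until `t_end`, then measures
#' ring diameter (from the polymerised septin field), ring formation time
#' (from the max-node Cdc42-GTP trace) and the eligible-node fraction.
#'
#' @param checkpoint A [septin_checkpoint()].
#' @param mode `"SBER"` or `"SBE"`.
#' @param exo An [exo_params()] (set `rate = 0` to disable exocytosis).
#' @param t_end Septin-module horizon (s).
#' @param seeds Vector of event-process seeds (one run per seed).
#' @param rel_tol Solver tolerance.
#' @param progress Print progress.
#' @return Data frame with one row per seed: ring diameter, formation
#'   time, eligible fraction at start, status.
#' @export
run_septin_experiment <- function(checkpoint, mode = c("SBER", "SBE"),
                                  exo = exo_params(), t_end = 300,
                                  seeds = 1L, rel_tol = 2e-3,
                                  progress = FALSE) {
  mode <- match.arg(mode)
  params <- checkpoint$params
  if (mode == "SBE") params <- .sbe_params(params)
  model <- septin_model(params, mode)
  elig0 <- attr(eligible_nodes(checkpoint$state$fields[, "Cdc42T"],
                               exo$epsilon), "fraction")
  rows <- lapply(seeds, function(sd) {
    cfg <- solver_config(t_end = t_end, rel_tol = rel_tol,
                         ss_rate_tol = 0,     # run the full horizon
                         dt_max = 2, snap_every = 5,
                         err_check_every = 2L)
    traj <- tryCatch(
      integrate_model(model, params, checkpoint$mesh, checkpoint$eta,
                      checkpoint$state, cfg,
                      exo = if (exo$rate > 0) exo else NULL,
                      exo_seed = sd, progress = progress),
      error = function(e) e)
    if (inherits(traj, "error"))
      return(data.frame(seed = sd, mode = mode, epsilon = exo$epsilon,
                        exo_rate = exo$rate, ring_diameter_um = NA_real_,
                        formation_time_s = NA_real_, eligible_frac = elig0,
                        max_P = NA_real_, status = paste0("error: ", conditionMessage(traj))))
    P <- traj$state$fields[, "P"]
    diam <- tryCatch(ring_diameter_field(P, checkpoint$mesh)$diameter,
                     error = function(e) NA_real_)
    ft <- ring_formation_time(traj$summary$t, traj$summary$max_Cdc42T)
    data.frame(seed = sd, mode = mode, epsilon = exo$epsilon,
               exo_rate = exo$rate, ring_diameter_um = diam,
               formation_time_s = ft, eligible_frac = elig0,
               max_P = max(P),
               status = if (is.na(diam)) "no_ring" else "ok")
  })
  do.call(rbind, rows)
}

#' Sensitivity of the diffused-exocytosis ring enlargement
#'
#' For each septin-module parameter and factor (0.5, 2.0), reruns the
#' diffused- versus focused-exocytosis comparison and records whether
#' diffused exocytosis still enlarges the ring.
#'
#' @param volume Cell volume (fL).
#' @param parameters Parameter names to perturb.
#' @param factors Multiplicative factors.
#' @param eps_focused,eps_diffused Eligibility thresholds of the two arms.
#' @param t_end Septin-module horizon per run (s).
#' @param target_nodes Mesh resolution.
#' @param seeds Event seeds per arm.
#' @param checkpoint_seed Seed of the shared polarization checkpoint.
#' @param progress Print one line per row.
#' @return Data frame: parameter, factor, mean diameters of both arms,
#'   verdict (`enlarged`), status.
#' @export
run_sensitivity <- function(volume = 33,
                            parameters = c("k12a", "k12b", "k13", "k15",
                                           "k16", "k17", "k18", "k19",
                                           "k20", "k21", "k22", "k23",
                                           "k24", "k25"),
                            factors = c(0.5, 2.0),
                            eps_focused = 0.9, eps_diffused = 0.1,
                            t_end = 200, target_nodes = 642, seeds = 1:2,
                            checkpoint_seed = 1L, progress = FALSE) {
  rows <- list()
  # parameters outside the Cdc42 polarization cycle share one checkpoint
  cycle_pars <- c("k1a", "k1b", "k2a", "k2b", "k3", "k4a", "k4b",
                  "k5a", "k5b", "k7", "Dm")
  cp_shared <- NULL
  for (pm in parameters) for (fc in factors) {
    params <- septin_params()
    params[[pm]] <- params[[pm]] * fc
    row <- data.frame(parameter = pm, factor = fc,
                      diam_diffused = NA_real_, diam_focused = NA_real_,
                      enlarged = NA, status = "ok")
    res <- tryCatch({
      if (pm %in% cycle_pars) {
        cp <- septin_checkpoint(params, volume = volume,
                                target_nodes = target_nodes,
                                seed = checkpoint_seed)
      } else {
        if (is.null(cp_shared))
          cp_shared <- septin_checkpoint(septin_params(), volume = volume,
                                         target_nodes = target_nodes,
                                         seed = checkpoint_seed)
        cp <- cp_shared
        cp$params <- params
      }
      d1 <- run_septin_experiment(cp, "SBER",
                                  exo_params(epsilon = eps_diffused),
                                  t_end = t_end, seeds = seeds)
      d0 <- run_septin_experiment(cp, "SBER",
                                  exo_params(epsilon = eps_focused),
                                  t_end = t_end, seeds = seeds)
      row$diam_diffused <- mean(d1$ring_diameter_um, na.rm = TRUE)
      row$diam_focused <- mean(d0$ring_diameter_um, na.rm = TRUE)
      row$enlarged <- isTRUE(row$diam_diffused > row$diam_focused)
      row
    }, error = function(e) { row$status <- paste0("error: ", conditionMessage(e)); row })
    if (progress)
      message(sprintf("%s x %.1f: diffused %.3g vs focused %.3g",
                      pm, fc, res$diam_diffused, res$diam_focused))
    rows[[length(rows) + 1L]] <- res
  }
  do.call(rbind, rows)
}
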