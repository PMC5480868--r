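#' End-to-end rigidity pipeline over conditions
#'
#' For each supplied condition ensemble: build constraint networks per
#' frame (hydrogen-bond detection, energy filter, optional Mg handling),
#' optionally add the ligand constraints, decompose with the pebble game,
#' and accumulate p_lrc profiles; then derive delta-p_lrc per variant and,
#' when all four conditions are present, the Coop table with t-tests.
#' Outputs can be written as delimited text with a header recording the
#' configuration and seed.
#'
#' @param ensembles Named list of `rna_ensemble` objects; names from
#'   \{`apt_apo`, `apt_lig`, `loop_apo`, `loop_lig`\}. A `*_lig` entry may
#'   be omitted: it is then derived from the corresponding `*_apo`
#'   ensemble by adding ligand constraints to every frame network.
#' @param config List of settings: `e_cut` (default -0.6), `d_max` (3.5),
#'   `angle_min` (120), `include_mg` (TRUE), `binding` (c(47, 51, 74)),
#'   `stride` (1, snapshot stride for the rigidity analysis), `traj`
#'   (optional per-frame trajectory assignment, recycled per condition),
#'   `df` (2, t-test degrees of freedom), `out_dir` (optional output
#'   directory). Unknown keys are rejected.
#' @return List: `profiles` (named `plrc_profile`s), `delta` (named
#'   `delta_profile`s per variant), `coop` (a `coop_result` with t-tests,
#'   or NULL with a warning when conditions are missing), `config`.
#' @export
run_rigidity_pipeline <- function(ensembles, config = list()) {
  config <- validate_config(config, defaults = list(
    e_cut = -0.6, d_max = 3.5, angle_min = 120, include_mg = TRUE,
    binding = c(47L, 51L, 74L), stride = 1L, traj = NULL, df = 2,
    out_dir = NULL, coop_nucleotides = NULL))
  known <- c("apt_apo", "apt_lig", "loop_apo", "loop_lig")
  if (is.null(names(ensembles)) || !all(names(ensembles) %in% known)) {
    abort(paste("ensembles must be named from:", paste(known, collapse = ", ")))
  }
  profiles <- list()
  for (nm in names(ensembles)) {
    ens <- ensembles[[nm]]
    stopifnot(inherits(ens, "rna_ensemble"))
    frames <- seq(1, ens$n_frames, by = config$stride)
    nets <- lapply(frames, function(f) {
      st <- ensemble_frame(ens, f)
      build_network(st, e_cut = config$e_cut, include_mg = config$include_mg)
    })
    traj <- config$traj %||% rep(1L, ens$n_frames)
    profiles[[nm]] <- plrc_from_networks(nets, ens$topology,
                                         traj = traj[frames], condition = nm)
    lig_nm <- sub("_apo$", "_lig", nm)
    if (grepl("_apo$", nm) && !lig_nm %in% names(ensembles)) {
      st1 <- ensemble_frame(ens, 1)
      nets_lig <- lapply(nets, function(nt)
        add_ligand_constraints(nt, st1, binding = config$binding))
      profiles[[lig_nm]] <- plrc_from_networks(nets_lig, ens$topology,
                                               traj = traj[frames],
                                               condition = lig_nm)
    }
  }
  delta <- list()
  for (v in c("apt", "loop")) {
    if (all(paste0(v, c("_lig", "_apo")) %in% names(profiles))) {
      delta[[v]] <- delta_plrc(profiles[[paste0(v, "_lig")]],
                               profiles[[paste0(v, "_apo")]])
    }
  }
  coop_tab <- NULL
  need <- c("apt_lig", "apt_apo", "loop_lig", "loop_apo")
  if (all(need %in% names(profiles))) {
    coop_tab <- coop(profiles$apt_lig, profiles$apt_apo,
                     profiles$loop_lig, profiles$loop_apo,
                     nucleotides = config$coop_nucleotides)
    coop_tab <- coop_ttest(coop_tab, df = config$df)
  } else {
    warn("missing conditions for Coop; reporting p_lrc profiles only")
  }
  out <- list(profiles = profiles, delta = delta, coop = coop_tab,
              config = config)
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
  out
}

#' Trajectory-metric pipeline
#'
#' RMSF, core selection, core-fitted RMSD, radius of gyration (omitting
#' P1), RAC, PCA on phosphorus atoms and, when ions are present, Mg
#' hydration tracking and the occupancy grid — with the discard window
#' applied once by the ensemble reader.
#'
#' @param ensemble An `rna_ensemble`.
#' @param region_map A `region_map` for the topology.
#' @param config List: `core_fraction` (0.8), `traj` (optional), `grid_spacing`
#'   (0.4), `chi_binwidth` (5), `out_dir` (optional). Unknown keys are
#'   rejected.
#' @return List of metric objects: `rmsf`, `core`, `rmsd`, `rg`, `rac`,
#'   `pca`, `hydration` (if Mg present), `grid` (if Mg present), `chi`.
#' @export
run_traj_metrics <- function(ensemble, region_map, config = list()) {
  config <- validate_config(config, defaults = list(
    core_fraction = 0.8, traj = NULL, grid_spacing = 0.4, chi_binwidth = 5,
    out_dir = NULL))
  stopifnot(inherits(ensemble, "rna_ensemble"))
  topo <- ensemble$topology
  prof <- rmsf(ensemble, traj = config$traj)
  core <- select_core(prof, fraction = config$core_fraction)
  core_sel <- select_atoms(topo, resids = as.integer(core))
  prof_core <- rmsf(ensemble, fit_selection = core_sel, traj = config$traj)
  rmsd <- rmsd_series(ensemble, fit_selection = core_sel)
  rg <- radius_of_gyration(ensemble, region_map, exclude_region = "P1")
  rc <- rac(ensemble)
  pc <- pca_project(ensemble)
  hyd <- NULL; grid <- NULL
  if (any(topo$atoms$category == "MG")) {
    hyd <- mg_hydration(ensemble)
    grid <- occupancy_grid(ensemble, spacing = config$grid_spacing)
  }
  chi <- chi_histogram(ensemble, binwidth = config$chi_binwidth)
  out <- list(rmsf = prof_core, core = core, rmsd = rmsd, rg = rg, rac = rc,
              pca = pc, hydration = hyd, grid = grid, chi = chi,
              config = config)
  if (!is.null(config$out_dir)) write_metric_outputs(out, config$out_dir)
  out
}

validate_config <- function(config, defaults) {
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    abort(paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  }
  for (nm in names(config)) defaults[[nm]] <- config[[nm]]
  defaults
}

output_header <- function(config) {
  cfg <- config[!vapply(config, is.null, TRUE)]
  flat <- vapply(names(cfg), function(nm)
    paste0(nm, "=", paste(format(cfg[[nm]]), collapse = ",")), "")
  c("# riborigid output",
    paste0("# version ", as.character(utils::packageVersion("riborigid"))),
    paste0("# config ", paste(flat, collapse = "; ")),
    paste0("# config_hash ", config_hash(flat)))
}

config_hash <- function(flat) {
  # small deterministic checksum of the flattened configuration
  x <- utf8ToInt(paste(flat, collapse = ";"))
  format(sum(x * seq_along(x)) %% 1e9)
}

write_table_with_header <- function(tab, path, config) {
  writeLines(output_header(config), path)
  suppressWarnings(write.table(as.data.frame(tab), path, append = TRUE,
                               row.names = FALSE, quote = FALSE, sep = "\t"))
  invisible(path)
}

write_pipeline_outputs <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(out$profiles)) {
    write_table_with_header(out$profiles[[nm]],
                            file.path(dir, paste0("plrc_", nm, ".tsv")),
                            out$config)
  }
  for (nm in names(out$delta)) {
    write_table_with_header(out$delta[[nm]],
                            file.path(dir, paste0("delta_plrc_", nm, ".tsv")),
                            out$config)
  }
  if (!is.null(out$coop)) {
    write_table_with_header(out$coop, file.path(dir, "coop.tsv"), out$config)
  }
  invisible(dir)
}

write_metric_outputs <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table_with_header(out$rmsf, file.path(dir, "rmsf.tsv"), out$config)
  write_table_with_header(tibble(resid = as.integer(out$core)),
                          file.path(dir, "core_nucleotides.tsv"), out$config)
  write_table_with_header(out$rmsd, file.path(dir, "rmsd.tsv"), out$config)
  write_table_with_header(out$rg, file.path(dir, "rg.tsv"), out$config)
  write_table_with_header(out$rac, file.path(dir, "rac.tsv"), out$config)
  write_table_with_header(out$pca$projections,
                          file.path(dir, "pca_projections.tsv"), out$config)
  if (!is.null(out$hydration)) {
    write_table_with_header(out$hydration, file.path(dir, "mg_hydration.tsv"),
                            out$config)
  }
  if (!is.null(out$grid)) write_grid(out$grid, file.path(dir, "grid.txt"))
  write_table_with_header(out$chi, file.path(dir, "chi_histograms.tsv"),
                          out$config)
  invisible(dir)
}
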