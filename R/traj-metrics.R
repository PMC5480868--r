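#' Select atom rows of a structure
#'
#' @param structure An `rna_structure`.
#' @param resids Restrict to these nucleotide ids (RNA atoms).
#' @param names Restrict to these atom names.
#' @param elements Restrict to these element symbols.
#' @param category Atom category (default `"RNA"`; `NULL` for all).
#' @param heavy_only Drop hydrogens.
#' @return Integer vector of atom row indices.
#' @export
select_atoms <- function(structure, resids = NULL, names = NULL,
                         elements = NULL, category = "RNA",
                         heavy_only = FALSE) {
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(category)) keep <- keep & a$category %in% category
  if (!is.null(resids)) keep <- keep & a$resid %in% resids
  if (!is.null(names)) keep <- keep & a$name %in% names
  if (!is.null(elements)) keep <- keep & a$element %in% elements
  if (heavy_only) keep <- keep & a$element != "H"
  which(keep)
}

#' Per-nucleotide root mean-square fluctuations
#'
#' Each frame is least-squares fitted (mass-weighted) onto the reference
#' over `fit_selection`; per-atom RMSF is computed about the mean fitted
#' structure and averaged per nucleotide (all atoms by default). With a
#' `traj` assignment, fitting and RMSF run per trajectory and the profile
#' reports their mean and SEM.
#'
#' @param ensemble An `rna_ensemble` with at least two frames.
#' @param fit_selection Atom rows used for fitting (default: all RNA
#'   atoms).
#' @param traj Optional trajectory assignment per frame.
#' @param heavy_only Average RMSF over heavy atoms only.
#' @return An `rmsf_profile` tibble (resid, rmsf, sem) with per-atom
#'   values in attribute `per_atom`.
#' @export
rmsf <- function(ensemble, fit_selection = NULL, traj = NULL,
                 heavy_only = FALSE) {
  stopifnot(inherits(ensemble, "rna_ensemble"))
  if (ensemble$n_frames < 2) abort("RMSF needs at least two frames")
  topo <- ensemble$topology
  if (is.null(fit_selection)) fit_selection <- select_atoms(topo)
  if (length(fit_selection) == 0) abort("empty fit selection")
  if (is.null(traj)) traj <- rep(1L, ensemble$n_frames)
  w <- topo$atoms$mass[fit_selection]
  per_traj_atom <- lapply(split(seq_len(ensemble$n_frames), traj),
                          function(idx) {
    ref <- ensemble$xyz[idx[1], ]
    fitted <- t(vapply(idx, function(f)
      fit_frame(ensemble$xyz[f, ], ref, fit_selection, w),
      numeric(ncol(ensemble$xyz))))
    mean_xyz <- colMeans(fitted)
    dev2 <- sweep(fitted, 2, mean_xyz)^2
    per_coord <- colMeans(dev2)
    sqrt(per_coord[c(TRUE, FALSE, FALSE)] + per_coord[c(FALSE, TRUE, FALSE)] +
           per_coord[c(FALSE, FALSE, TRUE)])
  })
  atom_mat <- do.call(cbind, per_traj_atom)
  a <- topo$atoms
  sel <- a$category == "RNA" & (!heavy_only | a$element != "H")
  nt_traj <- rowsum(atom_mat[sel, , drop = FALSE], a$resid[sel]) /
    as.vector(table(a$resid[sel]))
  resids <- as.integer(rownames(nt_traj))
  ord <- match(topo$nucleotides$resid, resids)
  nt_traj <- nt_traj[ord, , drop = FALSE]
  ntraj <- ncol(nt_traj)
  out <- tibble(
    resid = topo$nucleotides$resid,
    rmsf = rowMeans(nt_traj),
    sem = if (ntraj > 1) apply(nt_traj, 1, sd) / sqrt(ntraj) else NA_real_)
  structure(out, class = c("rmsf_profile", class(out)),
            per_atom = rowMeans(atom_mat), per_traj = nt_traj,
            fit_selection = fit_selection)
}

#' Core-nucleotide selection (least-fluctuating fraction)
#'
#' Returns the `round(fraction x n)` nucleotides with the lowest RMSF
#' (ties broken toward the lower nucleotide id); for a 67-nucleotide
#' aptamer at the default fraction this is 54 nucleotides.
#'
#' @param profile An `rmsf_profile`.
#' @param fraction Fraction to keep, in (0, 1]; default 0.8.
#' @return Sorted integer vector of nucleotide ids (class
#'   `core_selection`).
#' @export
select_core <- function(profile, fraction = 0.8) {
  stopifnot(inherits(profile, "rmsf_profile"))
  if (!is.finite(fraction) || fraction <= 0 || fraction > 1) {
    abort("fraction must lie in (0, 1]")
  }
  k <- round(fraction * nrow(profile))
  ord <- order(profile$rmsf, profile$resid)
  ids <- sort(profile$resid[ord[seq_len(k)]])
  structure(ids, class = "core_selection", fraction = fraction)
}

#' Per-frame RMSD after best-fit superposition
#'
#' Each frame is fitted (mass-weighted) onto the reference over
#' `fit_selection`; the RMSD is then evaluated over `measure_selection`.
#' Substructure-internal deviations are obtained by fitting on the
#' substructure itself.
#'
#' @param ensemble An `rna_ensemble`.
#' @param reference Flat coordinate vector (defaults to the first frame).
#' @param fit_selection,measure_selection Atom rows (defaults: all RNA
#'   atoms).
#' @param traj Optional trajectory assignment.
#' @return An `rmsd_series` tibble (frame, time, traj, rmsd).
#' @export
rmsd_series <- function(ensemble, reference = NULL, fit_selection = NULL,
                        measure_selection = NULL, traj = NULL) {
  stopifnot(inherits(ensemble, "rna_ensemble"))
  topo <- ensemble$topology
  if (is.null(fit_selection)) fit_selection <- select_atoms(topo)
  if (is.null(measure_selection)) measure_selection <- select_atoms(topo)
  if (length(fit_selection) == 0 || length(measure_selection) == 0) {
    abort("selections must be non-empty")
  }
  if (is.null(reference)) reference <- ensemble$xyz[1, ]
  if (length(reference) != ncol(ensemble$xyz)) {
    abort("reference does not match the ensemble topology")
  }
  w <- topo$atoms$mass[fit_selection]
  ref_m <- matrix(reference, ncol = 3, byrow = TRUE)
  vals <- vapply(seq_len(ensemble$n_frames), function(f) {
    fitted <- fit_frame(ensemble$xyz[f, ], reference, fit_selection, w)
    fm <- matrix(fitted, ncol = 3, byrow = TRUE)
    sqrt(mean(rowSums((fm[measure_selection, , drop = FALSE] -
                         ref_m[measure_selection, , drop = FALSE])^2)))
  }, 1)
  out <- tibble(frame = seq_len(ensemble$n_frames), time = ensemble$time,
                traj = traj %||% 1L, rmsd = vals)
  structure(out, class = c("rmsd_series", class(out)))
}

#' Radius of gyration, omitting a region
#'
#' Mass-weighted radius of gyration over all RNA atoms outside the
#' excluded region (default P1), per frame for an ensemble or as a single
#' value for a structure.
#'
#' @param x An `rna_ensemble` or `rna_structure`.
#' @param region_map A `region_map` (required when excluding a region).
#' @param exclude_region Region label(s) to omit; `NULL` to keep all.
#' @return Numeric scalar for a structure; tibble (frame, time, rg) for an
#'   ensemble.
#' @export
radius_of_gyration <- function(x, region_map = NULL, exclude_region = "P1") {
  topo <- if (inherits(x, "rna_ensemble")) x$topology else x
  stopifnot(inherits(topo, "rna_structure"))
  sel <- select_atoms(topo)
  if (!is.null(exclude_region)) {
    if (is.null(region_map)) abort("region_map needed to exclude a region")
    drop_ids <- region_nucleotides(region_map, exclude_region)
    sel <- setdiff(sel, select_atoms(topo, resids = drop_ids))
  }
  if (length(sel) < 2) abort("region exclusion leaves fewer than 2 atoms")
  m <- topo$atoms$mass[sel]
  rg_of <- function(flat) {
    xyz <- matrix(flat, ncol = 3, byrow = TRUE)[sel, , drop = FALSE]
    ctr <- colSums(xyz * m) / sum(m)
    sqrt(sum(m * rowSums(sweep(xyz, 2, ctr)^2)) / sum(m))
  }
  if (inherits(x, "rna_structure")) return(rg_of(structure_xyz(x)))
  tibble(frame = seq_len(x$n_frames), time = x$time,
         rg = vapply(seq_len(x$n_frames), function(f) rg_of(x$xyz[f, ]), 1))
}

#' RMSD average correlation (RAC)
#'
#' For each window length w, coordinates are averaged over w consecutive
#' frames (running windows), each averaged structure is best-fitted to the
#' reference, and RAC(w) is the mean RMSD. RAC(1) equals the plain mean
#' RMSD to the reference. By default the reference is the first frame; a
#' variant against the ensemble-average structure is available (it yields
#' smaller values).
#'
#' @param ensemble An `rna_ensemble` (at least 2 frames).
#' @param windows Window lengths (frames); defaults to 1..floor(N/2).
#'   Windows exceeding the frame count are dropped with a message.
#' @param fit_selection Atom rows for fitting/measuring (default all RNA).
#' @param vs_average Use the average structure as reference.
#' @return A `rac_curve` tibble (window, rac).
#' @export
rac <- function(ensemble, windows = NULL, fit_selection = NULL,
                vs_average = FALSE) {
  stopifnot(inherits(ensemble, "rna_ensemble"))
  n <- ensemble$n_frames
  if (n < 2) abort("RAC needs at least two frames")
  topo <- ensemble$topology
  if (is.null(fit_selection)) fit_selection <- select_atoms(topo)
  if (is.null(windows)) windows <- seq_len(max(1, floor(n / 2)))
  if (any(windows > n)) {
    inform(paste("dropping RAC windows exceeding", n, "frames"))
    windows <- windows[windows <= n]
  }
  w <- topo$atoms$mass[fit_selection]
  reference <- if (vs_average) colMeans(ensemble$xyz) else ensemble$xyz[1, ]
  ref_m <- matrix(reference, ncol = 3, byrow = TRUE)
  vals <- vapply(windows, function(win) {
    starts <- seq_len(n - win + 1)
    mean(vapply(starts, function(s) {
      avg <- colMeans(ensemble$xyz[s:(s + win - 1), , drop = FALSE])
      fitted <- fit_frame(avg, reference, fit_selection, w)
      fm <- matrix(fitted, ncol = 3, byrow = TRUE)
      sqrt(mean(rowSums((fm[fit_selection, , drop = FALSE] -
                           ref_m[fit_selection, , drop = FALSE])^2)))
    }, 1))
  }, 1)
  out <- tibble(window = windows, rac = vals)
  structure(out, class = c("rac_curve", class(out)))
}

#' Principal component analysis of phosphorus coordinates
#'
#' Frames from all supplied ensembles are fitted to a common reference
#' (the first frame of the first ensemble) over the selection, the pooled
#' covariance of the selected coordinates is eigen-decomposed, and every
#' frame is projected onto the leading components. Trajectory and
#' first/second-half labels are attached for overlap checks.
#'
#' @param ensembles An `rna_ensemble` or list of them (shared topology).
#' @param selection Atom rows (default: phosphorus atoms).
#' @param n_components Number of components to report (default 3).
#' @param fit Superpose frames onto the reference first (disable when the
#'   frames are already aligned or the selection is too small to define a
#'   superposition).
#' @return A `pca_projection`: list with `eigenvalues`, `vectors`,
#'   `var_explained` and a `projections` tibble (ensemble, frame, half,
#'   PC1..).
#' @export
pca_project <- function(ensembles, selection = NULL, n_components = 3,
                        fit = TRUE) {
  if (inherits(ensembles, "rna_ensemble")) ensembles <- list(ensembles)
  topo <- ensembles[[1]]$topology
  if (is.null(selection)) selection <- select_atoms(topo, elements = "P")
  if (length(selection) == 0) abort("empty atom selection")
  w <- topo$atoms$mass[selection]
  reference <- ensembles[[1]]$xyz[1, ]
  rows <- list(); meta <- list()
  for (e in seq_along(ensembles)) {
    ens <- ensembles[[e]]
    stopifnot(ncol(ens$xyz) == length(reference))
    fitted <- if (fit) {
      t(vapply(seq_len(ens$n_frames), function(f)
        fit_frame(ens$xyz[f, ], reference, selection, w),
        numeric(length(reference))))
    } else ens$xyz
    cols <- as.vector(t(outer(selection, 1:3, function(s, k) 3 * (s - 1) + k)))
    rows[[e]] <- fitted[, sort(cols), drop = FALSE]
    meta[[e]] <- tibble(
      ensemble = e, frame = seq_len(ens$n_frames),
      half = ifelse(seq_len(ens$n_frames) <= ens$n_frames / 2, 1L, 2L))
  }
  xmat <- do.call(rbind, rows)
  xc <- sweep(xmat, 2, colMeans(xmat))
  cv <- crossprod(xc) / (nrow(xc) - 1)
  eig <- eigen(cv, symmetric = TRUE)
  pos <- sum(eig$values > 1e-10 * max(eig$values))
  k <- min(n_components, pos)
  if (k < n_components) {
    inform(paste("covariance supports only", k, "components"))
  }
  proj <- xc %*% eig$vectors[, seq_len(k), drop = FALSE]
  colnames(proj) <- paste0("PC", seq_len(k))
  out <- list(
    eigenvalues = eig$values[seq_len(pos)],
    vectors = eig$vectors[, seq_len(k), drop = FALSE],
    var_explained = eig$values[seq_len(pos)] / sum(pmax(eig$values, 0)),
    projections = bind_cols(bind_rows(meta), as_tibble(proj)))
  class(out) <- "pca_projection"
  out
}

#' Magnesium hydration and chelation tracking
#'
#' Per frame and ion: number of water molecules (water oxygens) within the
#' first-shell cutoff, whether any RNA atom lies within the chelation
#' cutoff, and whether the ion is hexahydrated (exactly six shell waters
#' and no chelation).
#'
#' @param ensemble An `rna_ensemble` containing MG and WATER atoms.
#' @param cutoff First-shell / chelation distance (A), default 3.5.
#' @return A `hydration_series` tibble (frame, time, ion, n_waters,
#'   chelated, hexahydrated); empty with a warning when no Mg is present.
#' @export
mg_hydration <- function(ensemble, cutoff = 3.5) {
  stopifnot(inherits(ensemble, "rna_ensemble"))
  a <- ensemble$topology$atoms
  mg <- which(a$category == "MG")
  if (length(mg) == 0) {
    warn("no Mg2+ ions in the topology")
    return(structure(tibble(frame = integer(), time = numeric(),
                            ion = integer(), n_waters = integer(),
                            chelated = logical(), hexahydrated = logical()),
                     class = c("hydration_series", "tbl_df", "tbl",
                               "data.frame")))
  }
  wat <- which(a$category == "WATER" & a$element == "O")
  rna <- which(a$category == "RNA" & a$element != "H")
  res <- list()
  for (f in seq_len(ensemble$n_frames)) {
    xyz <- matrix(ensemble$xyz[f, ], ncol = 3, byrow = TRUE)
    for (m in mg) {
      dw <- if (length(wat) > 0) {
        sqrt(rowSums(sweep(xyz[wat, , drop = FALSE], 2, xyz[m, ])^2))
      } else numeric()
      dr <- if (length(rna) > 0) {
        sqrt(rowSums(sweep(xyz[rna, , drop = FALSE], 2, xyz[m, ])^2))
      } else numeric()
      nw <- sum(dw <= cutoff)
      chel <- any(dr < cutoff)
      res[[length(res) + 1]] <- tibble(
        frame = f, time = ensemble$time[f], ion = a$serial[m],
        n_waters = as.integer(nw), chelated = chel,
        hexahydrated = nw == 6L && !chel)
    }
  }
  out <- bind_rows(res)
  structure(out, class = c("hydration_series", class(out)))
}

#' Ion occupancy grid and site occupancies
#'
#' Counts, per 3D grid cell, the frames in which at least one Mg2+ ion
#' falls inside the cell; optionally reports for named reference sites the
#' percentage of frames with any ion within `site_radius`.
#'
#' @param ensemble An `rna_ensemble` (frames aligned to a common
#'   reference).
#' @param spacing Grid spacing (A), default 0.4.
#' @param sites Optional tibble (label, x, y, z) of reference sites.
#' @param site_radius Site occupancy radius (A), default 3.
#' @return A `grid_map`: list with `grid` (ix, iy, iz, x, y, z, count),
#'   `origin`, `spacing`, `n_frames`, and `sites` (label, occupancy).
#' @export
occupancy_grid <- function(ensemble, spacing = 0.4, sites = NULL,
                           site_radius = 3.0) {
  stopifnot(inherits(ensemble, "rna_ensemble"))
  if (!is.finite(spacing) || spacing <= 0) abort("spacing must be positive")
  a <- ensemble$topology$atoms
  mg <- which(a$category == "MG")
  if (length(mg) == 0) abort("no Mg2+ ions in the topology")
  n <- ensemble$n_frames
  pos <- do.call(rbind, lapply(seq_len(n), function(f) {
    xyz <- matrix(ensemble$xyz[f, ], ncol = 3, byrow = TRUE)
    cbind(frame = f, xyz[mg, , drop = FALSE])
  }))
  origin <- floor(apply(pos[, 2:4, drop = FALSE], 2, min) / spacing) * spacing
  idx <- floor(sweep(pos[, 2:4, drop = FALSE], 2, origin) / spacing)
  key <- paste(pos[, 1], idx[, 1], idx[, 2], idx[, 3])  # frame-unique cells
  uk <- !duplicated(key)
  cell <- paste(idx[uk, 1], idx[uk, 2], idx[uk, 3])
  counts <- table(cell)
  parts <- do.call(rbind, strsplit(names(counts), " "))
  grid <- tibble(
    ix = as.integer(parts[, 1]), iy = as.integer(parts[, 2]),
    iz = as.integer(parts[, 3]),
    count = as.integer(counts)) %>%
    mutate(x = origin[1] + (.data$ix + 0.5) * spacing,
           y = origin[2] + (.data$iy + 0.5) * spacing,
           z = origin[3] + (.data$iz + 0.5) * spacing) %>%
    arrange(desc(.data$count))
  site_tab <- NULL
  if (!is.null(sites)) {
    sites <- as_tibble(sites)
    site_tab <- tibble(label = sites$label, occupancy = vapply(
      seq_len(nrow(sites)), function(s) {
        d <- sqrt((pos[, 2] - sites$x[s])^2 + (pos[, 3] - sites$y[s])^2 +
                    (pos[, 4] - sites$z[s])^2)
        100 * length(unique(pos[d <= site_radius, 1])) / n
      }, 1))
  }
  structure(list(grid = grid, origin = origin, spacing = spacing,
                 n_frames = n, sites = site_tab),
            class = "grid_map")
}

#' Write an occupancy grid as plain-text voxels
#' @param gm A `grid_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grid <- function(gm, path) {
  stopifnot(inherits(gm, "grid_map"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# riborigid occupancy grid",
               paste("# origin", paste(format(gm$origin), collapse = " ")),
               paste("# spacing", gm$spacing),
               paste("# n_frames", gm$n_frames),
               "ix iy iz count"), con)
  writeLines(paste(gm$grid$ix, gm$grid$iy, gm$grid$iz, gm$grid$count), con)
  invisible(path)
}

#' Glycosidic (chi) dihedral histograms
#'
#' chi is O4'-C1'-N9-C4 for purines and O4'-C1'-N1-C2 for pyrimidines,
#' reported over [0, 360). Histograms are normalized to unit mass per
#' nucleotide; a pooled histogram over all nucleotides is attached.
#'
#' @param ensemble An `rna_ensemble`.
#' @param binwidth Bin width in degrees, default 5.
#' @return A `chi_histogram` tibble (resid, bin_mid, prob) with attribute
#'   `pooled`.
#' @export
chi_histogram <- function(ensemble, binwidth = 5) {
  stopifnot(inherits(ensemble, "rna_ensemble"))
  a <- ensemble$topology$atoms
  nts <- ensemble$topology$nucleotides
  breaks <- seq(0, 360, by = binwidth)
  rows <- list()
  for (k in seq_len(nrow(nts))) {
    rs <- nts$resid[k]
    purine <- nts$resname[k] %in% c("A", "G")
    names4 <- if (purine) c("O4'", "C1'", "N9", "C4") else
      c("O4'", "C1'", "N1", "C2")
    idx <- vapply(names4, function(nm) {
      r <- which(a$resid == rs & a$name == nm & a$category == "RNA")
      if (length(r) == 1) r else NA_integer_
    }, 1L)
    if (anyNA(idx)) {
      warn(paste("skipping nucleotide", rs, "- chi atoms missing"))
      next
    }
    angs <- vapply(seq_len(ensemble$n_frames), function(f) {
      xyz <- matrix(ensemble$xyz[f, ], ncol = 3, byrow = TRUE)
      dihedral_deg(xyz[idx[1], ], xyz[idx[2], ], xyz[idx[3], ], xyz[idx[4], ])
    }, 1)
    angs <- angs %% 360
    h <- hist(angs, breaks = breaks, plot = FALSE)
    rows[[length(rows) + 1]] <- tibble(
      resid = rs, bin_mid = h$mids, prob = h$counts / sum(h$counts))
  }
  if (length(rows) == 0) abort("no nucleotide had a resolvable chi dihedral")
  out <- bind_rows(rows)
  pooled <- out %>%
    group_by(.data$bin_mid) %>%
    summarise(prob = sum(.data$prob), .groups = "drop") %>%
    mutate(prob = .data$prob / sum(.data$prob))
  structure(out, class = c("chi_histogram", class(out)), pooled = pooled)
}

dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}
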