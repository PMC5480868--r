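#' Per-nucleotide largest-rigid-cluster probability profile
#'
#' For each nucleotide, p_lrc is the fraction of snapshots in which the
#' nucleotide's base N1 atom belongs to the largest rigid cluster
#' (p_lrc(i) = n1(i)/N); the N1 value is projected onto the whole
#' nucleotide. When a `traj` assignment is given, per-trajectory
#' sub-profiles are kept and the SEM is the standard error over
#' trajectories.
#'
#' @param results List of `rigidity_result` objects computed on networks
#'   sharing one topology.
#' @param topology The `rna_structure` the networks were built from.
#' @param traj Optional integer/character vector assigning each snapshot
#'   to a trajectory.
#' @param condition Optional condition label (e.g. `"apt_lig"`).
#' @return A `plrc_profile`: tibble (resid, n1, N, p_lrc, sem) with the
#'   per-trajectory profile matrix in attribute `per_traj`.
#' @export
plrc_profile <- function(results, topology, traj = NULL, condition = NULL) {
  stopifnot(length(results) >= 1, inherits(topology, "rna_structure"))
  body_atoms <- results[[1]]$body_atoms
  n1b <- n1_bodies(topology, body_atoms)
  member <- vapply(results, function(r) {
    stopifnot(inherits(r, "rigidity_result"))
    (r$cluster == r$largest_cluster_id)[n1b]
  }, logical(length(n1b)))
  if (is.null(dim(member))) member <- matrix(member, nrow = length(n1b))
  finish_plrc(member, topology$nucleotides$resid, traj, condition)
}

#' @rdname plrc_profile
#' @param networks List of `constraint_network` objects sharing one
#'   topology; the decomposition runs in compiled code, making this the
#'   fast path for large ensembles.
#' @export
plrc_from_networks <- function(networks, topology, traj = NULL,
                               condition = NULL) {
  stopifnot(length(networks) >= 1)
  n_bodies <- networks[[1]]$n_bodies
  body_atoms <- networks[[1]]$body_atoms
  n1b <- n1_bodies(topology, body_atoms)
  bars_list <- lapply(networks, function(nt) {
    stopifnot(nt$n_bodies == n_bodies)
    cbind(nt$bars$i, nt$bars$j, nt$bars$mult)
  })
  member_all <- .pebble_largest_member_many(n_bodies, bars_list)
  finish_plrc(member_all[n1b, , drop = FALSE],
              topology$nucleotides$resid, traj, condition)
}

n1_bodies <- function(topology, body_atoms) {
  a <- topology$atoms
  vapply(seq_len(nrow(topology$nucleotides)), function(k) {
    nt <- topology$nucleotides[k, ]
    row <- which(a$resid == nt$resid & a$chain == nt$chain &
                   a$category == "RNA" & a$name == "N1")
    if (length(row) != 1) {
      abort(paste("N1 atom missing for nucleotide", nt$resid))
    }
    body <- if (is.null(body_atoms)) row else match(row, body_atoms)
    if (is.na(body)) {
      abort(paste("N1 atom of nucleotide", nt$resid, "is not in the network"))
    }
    body
  }, 1L)
}

finish_plrc <- function(member, resids, traj, condition) {
  n <- ncol(member)
  n1 <- rowSums(member)
  p <- n1 / n
  per_traj <- NULL
  sem <- rep(NA_real_, length(p))
  if (!is.null(traj)) {
    stopifnot(length(traj) == n)
    per_traj <- vapply(split(seq_len(n), traj),
                       function(idx) rowMeans(member[, idx, drop = FALSE]),
                       numeric(length(p)))
    if (is.null(dim(per_traj))) per_traj <- matrix(per_traj, nrow = length(p))
    if (ncol(per_traj) > 1) {
      sem <- apply(per_traj, 1, sd) / sqrt(ncol(per_traj))
    }
  }
  out <- tibble(resid = resids, n1 = as.integer(n1), N = n, p_lrc = p,
                sem = sem)
  structure(out, class = c("plrc_profile", class(out)),
            per_traj = per_traj, condition = condition)
}

#' Ligand-induced change in largest-cluster probability
#'
#' Elementwise difference of two p_lrc profiles on the same topology,
#' ligand-constrained minus apo; the SEM is taken over per-trajectory
#' differences when both profiles carry matching trajectory structure.
#'
#' @param lig,apo `plrc_profile` objects.
#' @return A `delta_profile` tibble (resid, delta_plrc, sem).
#' @export
delta_plrc <- function(lig, apo) {
  stopifnot(inherits(lig, "plrc_profile"), inherits(apo, "plrc_profile"))
  if (!identical(lig$resid, apo$resid)) {
    abort("profiles cover different nucleotide sets")
  }
  delta <- lig$p_lrc - apo$p_lrc
  sem <- rep(NA_real_, length(delta))
  pt_l <- attr(lig, "per_traj"); pt_a <- attr(apo, "per_traj")
  if (!is.null(pt_l) && !is.null(pt_a) && identical(dim(pt_l), dim(pt_a)) &&
      ncol(pt_l) > 1) {
    dt <- pt_l - pt_a
    sem <- apply(dt, 1, sd) / sqrt(ncol(dt))
  }
  out <- tibble(resid = lig$resid, delta_plrc = delta, sem = sem)
  structure(out, class = c("delta_profile", class(out)))
}

#' Cooperativity of tertiary and ligand-mediated stabilization
#'
#' Four-condition log-odds statistic referenced to the state lacking both
#' interaction sets (mutant apo):
#' Coop(i) = ln(p_lig^apt / p_apo^loop) - ln(p_apo^apt / p_apo^loop)
#'         - ln(p_lig^loop / p_apo^loop)
#'         = ln[(p_lig^apt p_apo^loop) / (p_apo^apt p_lig^loop)].
#' Coop > 0 means the two interaction sets together stabilize nucleotide i
#' more than the sum of their separate effects. The SEM is propagated from
#' the four terms: SEM^2 = sum_k (SEM_k / p_k)^2.
#'
#' Nucleotides where any of the four probabilities is zero are flagged
#' undefined (NaN) rather than silently pseudocounted; the optional
#' continuity correction replaces p with (n1 + 1/2)/(N + 1).
#'
#' @param lig_apt,apo_apt,lig_loop,apo_loop `plrc_profile` objects for the
#'   wildtype (apt) and loop-mutant (loop) variants, with and without
#'   ligand constraints.
#' @param nucleotides Nucleotide ids to evaluate (default: the terminal P1
#'   set 15-19, 77-81, intersected with the profile).
#' @param continuity Apply the (n1 + 1/2)/(N + 1) correction.
#' @return A `coop_result` tibble: resid, coop, sem, the four
#'   probabilities, undefined flag.
#' @export
coop <- function(lig_apt, apo_apt, lig_loop, apo_loop, nucleotides = NULL,
                 continuity = FALSE) {
  profs <- list(lig_apt = lig_apt, apo_apt = apo_apt,
                lig_loop = lig_loop, apo_loop = apo_loop)
  for (p in profs) stopifnot(inherits(p, "plrc_profile"))
  resids <- lig_apt$resid
  for (p in profs[-1]) {
    if (!identical(p$resid, resids)) {
      abort("the four profiles cover different nucleotide sets")
    }
  }
  if (is.null(nucleotides)) {
    nucleotides <- intersect(named_nucleotide_sets()$terminal_P1, resids)
    if (length(nucleotides) == 0) nucleotides <- resids
  }
  idx <- match(nucleotides, resids)
  if (anyNA(idx)) {
    abort("requested nucleotides absent from the profiles")
  }
  getp <- function(pr) {
    if (continuity) (pr$n1[idx] + 0.5) / (pr$N[1] + 1) else pr$p_lrc[idx]
  }
  p1 <- getp(lig_apt); p2 <- getp(apo_apt)
  p3 <- getp(lig_loop); p4 <- getp(apo_loop)
  undef <- p1 == 0 | p2 == 0 | p3 == 0 | p4 == 0
  cp <- ifelse(undef, NaN, log((p1 * p4) / (p2 * p3)))
  sems <- cbind(lig_apt$sem[idx] / p1, apo_apt$sem[idx] / p2,
                lig_loop$sem[idx] / p3, apo_loop$sem[idx] / p4)
  sem <- ifelse(undef, NaN, sqrt(rowSums(sems^2)))
  out <- tibble(resid = nucleotides, coop = cp, sem = sem,
                p_lig_apt = p1, p_apo_apt = p2,
                p_lig_loop = p3, p_apo_loop = p4,
                undefined = undef)
  structure(out, class = c("coop_result", class(out)))
}

#' One-sample t-test on cooperativity values
#'
#' Two-sided test of Coop(i) = 0 with t = Coop/SEM on `df` degrees of
#' freedom (default: number of independent trajectories minus one).
#' Significance classes: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
#' `ns` otherwise.
#'
#' @param res A `coop_result`.
#' @param df Degrees of freedom (>= 1).
#' @return The `coop_result` with columns t, p, signif added.
#' @export
coop_ttest <- function(res, df = 2) {
  stopifnot(inherits(res, "coop_result"))
  if (df < 1) abort("df must be at least 1")
  t <- res$coop / res$sem
  p <- 2 * pt(-abs(t), df = df)
  p[!is.na(res$coop) & res$coop == 0] <- 1
  res$t <- t
  res$p <- p
  res$signif <- cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
                    labels = c("***", "**", "*", "ns"))
  res
}

#' Hydrogen-bond occupancy with block-averaged uncertainty
#'
#' Per-frame bond indicators by the geometric criteria (donor--acceptor
#' distance and donor-H-acceptor angle); occupancy is 100 x the indicator
#' mean. Within each trajectory the SEM comes from means over consecutive
#' time blocks (default 10 ns); across trajectories the table reports the
#' mean and the standard error over trajectory occupancies.
#'
#' @param ensemble An `rna_ensemble` with time metadata.
#' @param pairs Tibble of bonds: donor_resid, donor_name, acceptor_resid,
#'   acceptor_name.
#' @param d_max,angle_min Geometric criteria (3.5 A, 120 degrees).
#' @param block_len Block length in ps (default 10000 = 10 ns).
#' @param traj Optional trajectory assignment per frame.
#' @return An `occupancy_table` tibble: one row per bond with occupancy
#'   (%), sem (%), block SEM per trajectory in attribute `per_traj`.
#' @export
hbond_occupancy <- function(ensemble, pairs, d_max = 3.5, angle_min = 120,
                            block_len = 10000, traj = NULL) {
  stopifnot(inherits(ensemble, "rna_ensemble"))
  a <- ensemble$topology$atoms
  pairs <- as_tibble(pairs)
  dr <- integer(nrow(pairs)); ar <- integer(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    d <- which(a$resid == pairs$donor_resid[k] & a$name == pairs$donor_name[k])
    ac <- which(a$resid == pairs$acceptor_resid[k] &
                  a$name == pairs$acceptor_name[k])
    if (length(d) != 1 || length(ac) != 1) {
      abort(paste0("cannot resolve bond ", pairs$donor_resid[k], ":",
                   pairs$donor_name[k], " -> ", pairs$acceptor_resid[k], ":",
                   pairs$acceptor_name[k]))
    }
    dr[k] <- d; ar[k] <- ac
  }
  tm <- ensemble$time
  if (all(is.na(tm))) tm <- seq_len(ensemble$n_frames)
  if (is.null(traj)) traj <- rep(1L, ensemble$n_frames)
  dur <- vapply(split(tm, traj), function(t) {
    sp <- if (length(t) > 1) stats::median(diff(sort(t))) else 1
    diff(range(t)) + sp
  }, 1)
  if (any(block_len > dur)) {
    abort("block_len exceeds the trajectory duration")
  }
  ind <- matrix(FALSE, nrow = ensemble$n_frames, ncol = nrow(pairs))
  don_info <- lapply(seq_len(nrow(pairs)), function(k)
    donor_kind(ensemble$topology, dr[k]))
  for (f in seq_len(ensemble$n_frames)) {
    st <- ensemble_frame(ensemble, f)
    af <- st$atoms
    for (k in seq_len(nrow(pairs))) {
      dpos <- c(af$x[dr[k]], af$y[dr[k]], af$z[dr[k]])
      apos <- c(af$x[ar[k]], af$y[ar[k]], af$z[ar[k]])
      dist <- sqrt(sum((apos - dpos)^2))
      if (dist > d_max) next
      hpos <- attached_hydrogens(st, dr[k])
      if (is.null(hpos)) {
        hpos <- place_donor_hydrogens(st, dr[k], don_info[[k]]$kind,
                                      don_info[[k]]$n_h, toward = apos)
      }
      if (is.null(hpos)) next
      ang <- max(apply(hpos, 1, function(h) angle_deg(dpos, h, apos)))
      ind[f, k] <- ang >= angle_min
    }
  }
  per_traj <- list()
  for (tr in unique(traj)) {
    sel <- which(traj == tr)
    blocks <- floor((tm[sel] - min(tm[sel])) / block_len)
    bm <- vapply(split(sel, blocks), function(idx)
      colMeans(ind[idx, , drop = FALSE]) * 100, numeric(nrow(pairs)))
    if (is.null(dim(bm))) bm <- matrix(bm, nrow = nrow(pairs))
    occ <- colMeans(ind[sel, , drop = FALSE]) * 100
    bsem <- if (ncol(bm) > 1) apply(bm, 1, sd) / sqrt(ncol(bm)) else
      rep(NA_real_, nrow(pairs))
    per_traj[[as.character(tr)]] <- tibble(
      traj = tr, bond = seq_len(nrow(pairs)), occupancy = occ,
      block_sem = bsem, n_blocks = ncol(bm))
  }
  pt <- bind_rows(per_traj)
  ntraj <- length(unique(traj))
  summ <- pt %>%
    group_by(.data$bond) %>%
    summarise(occupancy = mean(.data$occupancy),
              sem = if (ntraj > 1) sd(.data$occupancy) / sqrt(ntraj) else
                .data$block_sem[1],
              .groups = "drop")
  out <- bind_cols(pairs, summ[match(seq_len(nrow(pairs)), summ$bond),
                               c("occupancy", "sem")])
  out$block_len <- block_len
  out$n_traj <- ntraj
  structure(out, class = c("occupancy_table", class(out)), per_traj = pt)
}

donor_kind <- function(structure, row) {
  a <- structure$atoms
  if (a$category[row] == "WATER") return(list(kind = "water", n_h = 2L))
  if (a$name[row] %in% names(sugar_donors)) {
    return(list(kind = "hydroxyl", n_h = sugar_donors[[a$name[row]]]))
  }
  dn <- base_donors(a$resname[row])
  if (a$name[row] %in% names(dn)) {
    return(list(kind = "base", n_h = dn[[a$name[row]]]))
  }
  list(kind = "base", n_h = 1L)
}

#' Base-pair occupancy from member hydrogen bonds
#'
#' Pair occupancy is the mean over the hydrogen bonds connecting the two
#' nucleotides; the SEM is propagated: sqrt(sum SEM_k^2)/k.
#'
#' @param table An `occupancy_table` from [hbond_occupancy()].
#' @param pair_members Named list: base-pair label -> integer vector of
#'   row indices into `table`.
#' @return Tibble: pair, occupancy, sem, n_bonds.
#' @export
basepair_occupancy <- function(table, pair_members) {
  stopifnot(inherits(table, "occupancy_table"))
  if (length(pair_members) == 0) abort("pair_members is empty")
  out <- imap(pair_members, function(rows, label) {
    if (length(rows) == 0) abort(paste("empty member list for", label))
    if (any(rows > nrow(table))) abort(paste("unknown bond row for", label))
    tibble(pair = label,
           occupancy = mean(table$occupancy[rows]),
           sem = sqrt(sum(table$sem[rows]^2)) / length(rows),
           n_bonds = length(rows))
  })
  bind_rows(out)
}
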