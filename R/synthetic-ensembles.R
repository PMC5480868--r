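#' Four-condition ensemble design with known cooperativity
#'
#' Membership probabilities q of the focal nucleotide's N1 body in the
#' largest rigid cluster under each of the four conditions (wildtype /
#' loop-mutant crossed with ligand constraints on / off). The implied
#' analytic cooperativity is
#' c = ln[(q_lig_apt q_apo_loop) / (q_apo_apt q_lig_loop)].
#'
#' @param q_lig_apt,q_apo_apt,q_lig_loop,q_apo_loop Membership
#'   probabilities, each in (0, 1).
#' @param n_snapshots Snapshots per trajectory.
#' @param n_traj Pseudo-trajectories per condition.
#' @param seed Integer seed (mandatory).
#' @return A `coop_design` list with the probabilities, `n_snapshots`,
#'   `n_traj`, `seed` and the analytic value `c`.
#' @export
coop_design <- function(q_lig_apt, q_apo_apt, q_lig_loop, q_apo_loop,
                        n_snapshots = 1000, n_traj = 3, seed) {
  qs <- c(q_lig_apt = q_lig_apt, q_apo_apt = q_apo_apt,
          q_lig_loop = q_lig_loop, q_apo_loop = q_apo_loop)
  if (any(qs <= 0 | qs >= 1)) abort("all membership probabilities must lie in (0, 1)")
  if (missing(seed)) abort("seed is mandatory")
  structure(list(
    q = qs, n_snapshots = as.integer(n_snapshots),
    n_traj = as.integer(n_traj), seed = as.integer(seed),
    c = log((q_lig_apt * q_apo_loop) / (q_apo_apt * q_lig_loop))),
    class = "coop_design")
}

#' Simulate four-condition network ensembles
#'
#' Generates, per condition, `n_traj x n_snapshots` constraint networks on
#' a shared coarse topology: a fully braced four-body core (always the
#' largest rigid cluster) plus a focal body whose link to the core carries
#' six bars (rigid attachment) with the condition's probability q and five
#' bars (one internal hinge mode) otherwise. The focal N1 body therefore
#' belongs to the largest rigid cluster with probability exactly q, and
#' the analytic cooperativity of the design equals `design$c`. Draws are
#' seed-deterministic; the parameters ride along in the output.
#'
#' @param design A [coop_design()].
#' @return List: `topology` (coarse 5-nucleotide structure; the focal
#'   nucleotide is resid 5), `conditions` (named list, each with
#'   `networks` and `traj`), `focal_resid`, `design`.
#' @export
simulate_condition_ensembles <- function(design) {
  stopifnot(inherits(design, "coop_design"))
  tab <- tibble(serial = 1:5, name = "N1", resid = 1:5, resname = "G",
                chain = "A", x = 3 * (1:5), y = 0, z = 0)
  topo <- build_structure_from_table(tab)
  topo$bonds <- tibble(i = 1:4, j = 2:5, locked = FALSE)
  core <- tibble(i = 1:3, j = 2:4, mult = 6L, type = "COVALENT_LOCKED",
                 energy = NA_real_)
  net_on <- new_constraint_network(
    5, bind_rows(core, tibble(i = 4L, j = 5L, mult = 6L,
                              type = "COVALENT_LOCKED", energy = NA_real_)),
    body_atoms = 1:5)
  net_off <- new_constraint_network(
    5, bind_rows(core, tibble(i = 4L, j = 5L, mult = 5L,
                              type = "COVALENT_ROTATABLE", energy = NA_real_)),
    body_atoms = 1:5)
  n <- design$n_snapshots * design$n_traj
  conditions <- list()
  for (ci in seq_along(design$q)) {
    withr_seed(design$seed + 7919L * ci)
    on <- runif(n) < design$q[ci]
    conditions[[names(design$q)[ci]]] <- list(
      networks = lapply(on, function(o) if (o) net_on else net_off),
      traj = rep(seq_len(design$n_traj), each = design$n_snapshots))
  }
  list(topology = topo, conditions = conditions, focal_resid = 5L,
       design = design)
}

#' Estimate cooperativity on a simulated four-condition bundle
#'
#' Runs the full pipeline on the output of
#' [simulate_condition_ensembles()]: pebble-game decomposition of every
#' network, p_lrc profiles per condition with per-trajectory SEM, and the
#' Coop statistic for the focal nucleotide.
#'
#' @param bundle Output of [simulate_condition_ensembles()].
#' @param continuity Passed to [coop()].
#' @return A `coop_result` (single row, the focal nucleotide).
#' @export
estimate_coop <- function(bundle, continuity = FALSE) {
  prof <- lapply(names(bundle$conditions), function(nm) {
    cond <- bundle$conditions[[nm]]
    plrc_from_networks(cond$networks, bundle$topology, traj = cond$traj,
                       condition = nm)
  })
  names(prof) <- names(bundle$conditions)
  coop(prof$q_lig_apt, prof$q_apo_apt, prof$q_lig_loop, prof$q_apo_loop,
       nucleotides = bundle$focal_resid, continuity = continuity)
}

#' Simulate a coordinate trajectory with prescribed statistical structure
#'
#' Frames are the reference coordinates plus independent Gaussian
#' displacements with a per-region (or global) standard deviation per
#' coordinate; optionally a global rigid-body motion is superimposed.
#' Designated hydrogen bonds switch between an "on" distance and an "off"
#' distance following a two-state Markov (telegraph) process with a
#' prescribed stationary on-fraction. Hexahydrated ions (Mg2+ plus six
#' octahedral water oxygens) can be added as fixed, diffusing, or
#' water-shedding species.
#'
#' @param reference An `rna_structure` providing the reference
#'   coordinates.
#' @param n_frames Number of frames.
#' @param seed Integer seed (mandatory).
#' @param sigma Global per-coordinate displacement SD (A), or a named
#'   vector of per-region SDs (requires `region_map`).
#' @param region_map A `region_map` when `sigma` is per-region.
#' @param global_motion Superimpose a random rigid-body rotation and
#'   translation per frame.
#' @param hbond_spec Tibble (donor_resid, donor_name, acceptor_resid,
#'   acceptor_name, p_on, rate) of telegraph-switched bonds; optional
#'   columns d_on (default 2.9) and d_off (default 4.3). The acceptor atom
#'   is repositioned along the reference donor-acceptor direction and is
#'   exempt from jitter.
#' @param ion_spec Tibble (x, y, z) of ion sites; optional columns mode
#'   (`"fixed"`, `"diffusing"`, `"shedding"`), n_waters (default 6),
#'   shed_frame, step (diffusion step SD, A).
#' @param frame_spacing Time per frame (ps), default 20.
#' @return An `rna_ensemble` (topology extended by any ions/waters);
#'   generator parameters are attached as attribute `params` and the
#'   telegraph state matrix as attribute `hbond_states`.
#' @export
simulate_trajectory <- function(reference, n_frames, seed, sigma = 0.3,
                                region_map = NULL, global_motion = FALSE,
                                hbond_spec = NULL, ion_spec = NULL,
                                frame_spacing = 20) {
  stopifnot(inherits(reference, "rna_structure"))
  if (missing(seed)) abort("seed is mandatory")
  if (any(unlist(sigma) < 0)) abort("sigma must be non-negative")
  withr_seed(seed)
  topo <- reference
  a <- topo$atoms

  # per-atom displacement SD
  sig_atom <- rep(if (is.null(names(sigma))) sigma[1] else 0, nrow(a))
  if (!is.null(names(sigma))) {
    if (is.null(region_map)) abort("per-region sigma needs a region_map")
    reg_of <- setNames(region_map$region, region_map$resid)
    idx <- a$category == "RNA"
    sig_atom[idx] <- unname(sigma[reg_of[as.character(a$resid[idx])]])
    sig_atom[is.na(sig_atom)] <- mean(sigma)
  }

  # ions: extend the topology
  ion_atoms <- NULL
  if (!is.null(ion_spec)) {
    ion_spec <- as_tibble(ion_spec)
    if (!"mode" %in% names(ion_spec)) ion_spec$mode <- "fixed"
    if (!"n_waters" %in% names(ion_spec)) ion_spec$n_waters <- 6L
    if (!"shed_frame" %in% names(ion_spec)) ion_spec$shed_frame <- NA_integer_
    if (!"step" %in% names(ion_spec)) ion_spec$step <- 0.5
    oct <- rbind(c(2.07, 0, 0), c(-2.07, 0, 0), c(0, 2.07, 0),
                 c(0, -2.07, 0), c(0, 0, 2.07), c(0, 0, -2.07))
    rows <- list()
    serial0 <- max(a$serial)
    for (k in seq_len(nrow(ion_spec))) {
      ctr <- c(ion_spec$x[k], ion_spec$y[k], ion_spec$z[k])
      rows[[length(rows) + 1]] <- tibble(
        serial = serial0 + 1L, name = "MG", resid = 900L + k,
        resname = "MG", chain = "B", x = ctr[1], y = ctr[2], z = ctr[3])
      serial0 <- serial0 + 1L
      nw <- ion_spec$n_waters[k]
      for (wk in seq_len(nw)) {
        rows[[length(rows) + 1]] <- tibble(
          serial = serial0 + 1L, name = "O", resid = 950L + 10L * k + wk,
          resname = "HOH", chain = "B",
          x = ctr[1] + oct[wk, 1], y = ctr[2] + oct[wk, 2],
          z = ctr[3] + oct[wk, 3])
        serial0 <- serial0 + 1L
      }
    }
    ion_atoms <- bind_rows(rows)
    topo <- build_structure_from_table(bind_rows(
      a[, c("serial", "name", "resid", "resname", "chain", "x", "y", "z")],
      ion_atoms))
    a <- topo$atoms
    sig_atom <- c(sig_atom, rep(0, nrow(ion_atoms)))
  }
  ref_flat <- structure_xyz(topo)
  natoms <- nrow(a)

  # telegraph states for designated hydrogen bonds
  hb_states <- NULL
  hb_idx <- NULL
  if (!is.null(hbond_spec)) {
    hbond_spec <- as_tibble(hbond_spec)
    if (!"d_on" %in% names(hbond_spec)) hbond_spec$d_on <- 2.9
    if (!"d_off" %in% names(hbond_spec)) hbond_spec$d_off <- 4.3
    hb_idx <- lapply(seq_len(nrow(hbond_spec)), function(k) {
      d <- which(a$resid == hbond_spec$donor_resid[k] &
                   a$name == hbond_spec$donor_name[k])
      ac <- which(a$resid == hbond_spec$acceptor_resid[k] &
                    a$name == hbond_spec$acceptor_name[k])
      if (length(d) != 1 || length(ac) != 1) {
        abort("hbond_spec bond cannot be resolved in the reference")
      }
      list(d = d, a = ac)
    })
    hb_states <- matrix(FALSE, nrow = n_frames, ncol = nrow(hbond_spec))
    for (k in seq_len(nrow(hbond_spec))) {
      p_on <- hbond_spec$p_on[k]; rate <- hbond_spec$rate[k]
      b <- rate * p_on; a_off <- rate * (1 - p_on)
      s <- runif(1) < p_on
      for (f in seq_len(n_frames)) {
        hb_states[f, k] <- s
        s <- if (s) (runif(1) >= a_off) else (runif(1) < b)
      }
      # the acceptor is driven by the telegraph process, not jittered
      sig_atom[hb_idx[[k]]$a] <- 0
    }
  }

  xyz <- matrix(NA_real_, nrow = n_frames, ncol = 3 * natoms)
  sig_flat <- rep(sig_atom, each = 3)
  for (f in seq_len(n_frames)) {
    fr <- ref_flat + rnorm(3 * natoms, 0, sig_flat)
    if (!is.null(hb_idx)) {
      for (k in seq_along(hb_idx)) {
        di <- hb_idx[[k]]$d; ai <- hb_idx[[k]]$a
        dref <- ref_flat[3 * (di - 1) + 1:3]
        aref <- ref_flat[3 * (ai - 1) + 1:3]
        u <- (aref - dref) / sqrt(sum((aref - dref)^2))
        dcur <- fr[3 * (di - 1) + 1:3]
        dd <- if (hb_states[f, k]) hbond_spec$d_on[k] else hbond_spec$d_off[k]
        fr[3 * (ai - 1) + 1:3] <- dcur + dd * u
      }
    }
    if (!is.null(ion_spec)) {
      serial0 <- max(reference$atoms$serial)
      off <- 0L
      for (k in seq_len(nrow(ion_spec))) {
        nw <- ion_spec$n_waters[k]
        rows_k <- which(a$serial > serial0 + off &
                          a$serial <= serial0 + off + 1L + nw)
        drift <- if (ion_spec$mode[k] == "diffusing") {
          sqrt(f) * ion_spec$step[k] * ion_drift(seed, k)
        } else c(0, 0, 0)
        for (r in rows_k) {
          fr[3 * (r - 1) + 1:3] <- fr[3 * (r - 1) + 1:3] + drift
        }
        if (ion_spec$mode[k] == "shedding" && !is.na(ion_spec$shed_frame[k]) &&
            f >= ion_spec$shed_frame[k]) {
          # move the last two shell waters out of the first shell
          shed <- tail(rows_k, 2)
          for (r in shed) {
            v <- fr[3 * (r - 1) + 1:3] - fr[3 * (rows_k[1] - 1) + 1:3]
            v <- v / sqrt(sum(v^2))
            fr[3 * (r - 1) + 1:3] <- fr[3 * (rows_k[1] - 1) + 1:3] + 8 * v
          }
        }
        off <- off + 1L + nw
      }
    }
    if (global_motion) {
      th <- runif(3, -pi / 8, pi / 8); tr <- runif(3, -5, 5)
      rot <- rot_xyz(th)
      m <- matrix(fr, ncol = 3, byrow = TRUE) %*% rot
      fr <- as.numeric(t(sweep(m, 2, tr, `+`)))
    }
    xyz[f, ] <- fr
  }
  ens <- read_ensemble(topo, xyz, frame_spacing = frame_spacing, discard = 0)
  attr(ens, "params") <- list(seed = seed, sigma = sigma,
                              n_frames = n_frames,
                              frame_spacing = frame_spacing,
                              global_motion = global_motion)
  attr(ens, "hbond_states") <- hb_states
  ens
}

# deterministic per-ion unit drift direction derived from the seed
ion_drift <- function(seed, k) {
  old <- .Random.seed
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed + 31L * k)
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

rot_xyz <- function(th) {
  rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0),
              c(-sin(th[2]), 0, cos(th[2])))
  rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
              c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  rx %*% ry %*% rz
}
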