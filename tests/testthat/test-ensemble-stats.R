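# build a plrc_profile directly from known probabilities (for the Coop
# arithmetic checks, independent of the rigidity machinery)
profile_from_p <- function(p, N = 1000, sem = NULL, resid = seq_along(p)) {
  out <- tibble::tibble(resid = resid, n1 = as.integer(round(p * N)),
                        N = N, p_lrc = p,
                        sem = sem %||% rep(0.01, length(p)))
  structure(out, class = c("plrc_profile", class(out)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("p_lrc is the membership fraction of the base N1 atom", {
  topo <- coarse_topology()
  nets <- list(core_net(6), core_net(6), core_net(6), core_net(5))
  results <- lapply(nets, pebble_game_decompose)
  prof <- plrc_profile(results, topo)
  expect_equal(prof$p_lrc[prof$resid == 5], 0.75)
  expect_equal(prof$n1[prof$resid == 5], 3L)
  expect_true(all(prof$p_lrc[prof$resid %in% 1:4] == 1))

  # fully rigid in every snapshot: p_lrc identically 1
  rigid <- lapply(1:3, function(i) pebble_game_decompose(core_net(6)))
  expect_true(all(plrc_profile(rigid, topo)$p_lrc == 1))

  # the fast compiled path agrees with the per-result path
  prof2 <- plrc_from_networks(nets, topo)
  expect_equal(prof2$p_lrc, prof$p_lrc)
})

test_that("empirical membership matches a Bernoulli design within 3 sigma", {
  q <- 0.3; N <- 1000
  des <- coop_design(q, 0.5, 0.5, 0.5, n_snapshots = N, n_traj = 1, seed = 9)
  bundle <- simulate_condition_ensembles(des)
  prof <- plrc_from_networks(bundle$conditions$q_lig_apt$networks,
                             bundle$topology)
  expect_lt(abs(prof$p_lrc[prof$resid == 5] - q), 3 * sqrt(q * (1 - q) / N))
})

test_that("delta p_lrc is the elementwise difference with trajectory SEM", {
  topo <- coarse_topology()
  nets_on <- lapply(c(6, 6, 6, 6, 6, 5), core_net)
  nets_off <- lapply(c(5, 6, 5, 5, 6, 5), core_net)
  traj <- rep(1:3, each = 2)
  lig <- plrc_from_networks(nets_on, topo, traj = traj)
  apo <- plrc_from_networks(nets_off, topo, traj = traj)
  d <- delta_plrc(lig, apo)
  # focal memberships: lig (1,1,1,1,1,0), apo (0,1,0,0,1,0)
  expect_equal(d$delta_plrc[d$resid == 5], 5 / 6 - 2 / 6)
  # per-trajectory deltas: (1-0.5, 1-0, 0.5-0.5) = (0.5, 1, 0)
  expect_equal(d$sem[d$resid == 5], sd(c(0.5, 1, 0)) / sqrt(3))

  expect_equal(delta_plrc(lig, lig)$delta_plrc, rep(0, 5))

  apo_bad <- apo[apo$resid != 5, ]
  class(apo_bad) <- class(apo)
  expect_error(delta_plrc(lig, apo_bad), "different nucleotide sets")
})

test_that("Coop follows the four-condition log-odds formula", {
  # identical profiles: zero
  p <- profile_from_p(c(0.5, 0.7))
  cc <- coop(p, p, p, p, nucleotides = 1:2)
  expect_equal(cc$coop, c(0, 0))

  # purely additive effects cancel
  cc2 <- coop(profile_from_p(0.8), profile_from_p(0.4),
              profile_from_p(0.4), profile_from_p(0.2), nucleotides = 1)
  expect_equal(cc2$coop, 0)

  # direct evaluation
  cc3 <- coop(profile_from_p(0.9), profile_from_p(0.6),
              profile_from_p(0.7), profile_from_p(0.5), nucleotides = 1)
  expect_equal(cc3$coop, log(0.45 / 0.42))

  # identity between the difference-of-logs and the single-log forms
  p1 <- 0.83; p2 <- 0.41; p3 <- 0.66; p4 <- 0.37
  cc4 <- coop(profile_from_p(p1), profile_from_p(p2),
              profile_from_p(p3), profile_from_p(p4), nucleotides = 1)
  alt <- log(p1 / p4) - (log(p2 / p4) + log(p3 / p4))
  expect_equal(cc4$coop, alt, tolerance = 1e-12)

  # swapping lig and apo in both variants flips the sign
  cc5 <- coop(profile_from_p(p2), profile_from_p(p1),
              profile_from_p(p4), profile_from_p(p3), nucleotides = 1)
  expect_equal(cc5$coop, -cc4$coop, tolerance = 1e-12)

  # error propagation from the four terms
  s <- c(0.02, 0.03, 0.01, 0.015)
  cc6 <- coop(profile_from_p(p1, sem = s[1]), profile_from_p(p2, sem = s[2]),
              profile_from_p(p3, sem = s[3]), profile_from_p(p4, sem = s[4]),
              nucleotides = 1)
  expect_equal(cc6$sem,
               sqrt(sum((s / c(p1, p2, p3, p4))^2)), tolerance = 1e-12)
})

test_that("zero probabilities are flagged undefined, not pseudocounted", {
  cc <- coop(profile_from_p(0.9), profile_from_p(0),
             profile_from_p(0.7), profile_from_p(0.5), nucleotides = 1)
  expect_true(cc$undefined)
  expect_true(is.nan(cc$coop))
  cc2 <- coop(profile_from_p(0.9), profile_from_p(0, N = 100),
              profile_from_p(0.7), profile_from_p(0.5), nucleotides = 1,
              continuity = TRUE)
  expect_true(is.finite(cc2$coop))
})

test_that("the one-sample t-test classifies significance", {
  base <- profile_from_p(0.9)
  cc <- coop(base, profile_from_p(0.9), profile_from_p(0.9),
             profile_from_p(0.9), nucleotides = 1)
  tt <- coop_ttest(cc, df = 2)
  expect_equal(tt$p, 1)
  expect_equal(as.character(tt$signif), "ns")

  # |t| very large: class ***
  cc_big <- coop(profile_from_p(0.9, sem = 1e-9), profile_from_p(0.6, sem = 1e-9),
                 profile_from_p(0.7, sem = 1e-9), profile_from_p(0.5, sem = 1e-9),
                 nucleotides = 1)
  tt2 <- coop_ttest(cc_big, df = 2)
  expect_equal(as.character(tt2$signif), "***")

  # worked reconstruction: Coop = 0.065, SEM = 0.021 on 2 df is not
  # significant at 0.05 under this df choice
  cc3 <- cc
  cc3$coop <- 0.065; cc3$sem <- 0.021
  tt3 <- coop_ttest(cc3, df = 2)
  expect_equal(tt3$t, 0.065 / 0.021, tolerance = 1e-12)
  expect_gt(tt3$p, 0.05)
  expect_lt(tt3$p, 0.12)
  expect_equal(as.character(tt3$signif), "ns")

  expect_error(coop_ttest(cc, df = 0), "df")
})

test_that("hydrogen-bond occupancy and block averaging behave", {
  toy <- get_toy()
  st <- toy$structure
  pairs <- tibble::tibble(donor_resid = 37, donor_name = "N1",
                          acceptor_resid = 61, acceptor_name = "N3")
  # static ensemble: the designed bond is always present -> 100%
  flat <- riborigid:::structure_xyz(st)
  xyz <- matrix(rep(flat, 6), nrow = 6, byrow = TRUE)
  ens <- read_ensemble(st, xyz, frame_spacing = 10)
  occ <- hbond_occupancy(ens, pairs, block_len = 20)
  expect_equal(occ$occupancy, 100)

  # alternating on/off frames -> 50%, balanced blocks -> zero block SEM
  a <- st$atoms
  ai <- which(a$resid == 61 & a$name == "N3")
  off <- flat
  off[3 * (ai - 1) + 1:3] <- off[3 * (ai - 1) + 1:3] + c(8, 0, 0)
  xyz2 <- matrix(rep(c(flat, off), 4), nrow = 8, byrow = TRUE)
  ens2 <- read_ensemble(st, xyz2, frame_spacing = 10)
  occ2 <- hbond_occupancy(ens2, pairs, block_len = 20)
  expect_equal(occ2$occupancy, 50)
  pt <- attr(occ2, "per_traj")
  expect_equal(pt$block_sem, 0)

  # occupancy is invariant to block length; only the SEM changes
  occ3 <- hbond_occupancy(ens2, pairs, block_len = 40)
  expect_equal(occ3$occupancy, occ2$occupancy)

  expect_error(hbond_occupancy(ens2, pairs, block_len = 1e6), "block_len")
})

test_that("telegraph-switched bonds recover the stationary occupancy", {
  toy <- get_toy()
  spec <- tibble::tibble(donor_resid = 37, donor_name = "N1",
                         acceptor_resid = 61, acceptor_name = "N3",
                         p_on = 0.7, rate = 0.8)
  ens <- simulate_trajectory(toy$structure, n_frames = 400, seed = 21,
                             sigma = 0.05, hbond_spec = spec)
  occ <- hbond_occupancy(ens, spec[, 1:4], block_len = 400)
  # detection fidelity: the measured occupancy equals the realized state
  # fraction of the driving telegraph process
  realized <- 100 * mean(attr(ens, "hbond_states"))
  expect_equal(occ$occupancy, realized, tolerance = 1e-8)
  # the realized fraction sits within the autocorrelation-corrected
  # 3 sigma band of the stationary value (rho = 1 - rate per step)
  rho <- 1 - 0.8
  band <- 3 * 100 * sqrt(0.7 * 0.3 / 400 * (1 + rho) / (1 - rho))
  expect_lt(abs(realized - 70), band)
})

test_that("base-pair occupancy averages members with propagated SEM", {
  tab <- tibble::tibble(
    donor_resid = c(1, 1, 2), donor_name = "N1",
    acceptor_resid = c(9, 9, 8), acceptor_name = "O4",
    occupancy = c(100, 50, 80), sem = c(2, 2, 2),
    block_len = 10, n_traj = 1)
  class(tab) <- c("occupancy_table", class(tab))
  bp <- basepair_occupancy(tab, list(p19 = c(1, 2), p28 = 3))
  expect_equal(bp$occupancy, c(75, 80))
  expect_equal(bp$sem[1], sqrt(8) / 2)
  expect_equal(bp$sem[2], 2)
  bp3 <- basepair_occupancy(tab, list(x = 1:3))
  expect_equal(bp3$sem, sqrt(12) / 3, tolerance = 1e-12)
  expect_error(basepair_occupancy(tab, list()), "empty")
  expect_error(basepair_occupancy(tab, list(a = integer())), "empty")
})
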