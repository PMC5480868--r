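test_that("fixture network generators are deterministic and documented", {
  bp <- make_fixture_network("braced_pair")
  expect_equal(bp$n_bodies, 2)
  expect_equal(n_bars(bp), 6)
  ch <- make_fixture_network("chain", n = 4)
  expect_equal(nrow(ch$bars), 3)
  r1 <- make_fixture_network("random", n = 8, seed = 1)
  r2 <- make_fixture_network("random", n = 8, seed = 1)
  expect_identical(r1$bars, r2$bars)
  expect_false(identical(r1$bars,
                         make_fixture_network("random", n = 8, seed = 2)$bars))
  expect_error(make_fixture_network("random", n = 60), "50")
})

test_that("the toy aptamer realizes its designed hydrogen-bond sets", {
  for (mut in c(FALSE, TRUE)) {
    toy <- get_toy(mutant = mut)
    hb <- detect_hbonds(toy$structure)
    des <- toy$designed_hbonds
    kf <- paste(hb$donor_resid, hb$donor_name,
                hb$acceptor_resid, hb$acceptor_name)
    kd <- paste(des$donor_resid, des$donor_name,
                des$acceptor_resid, des$acceptor_name)
    expect_true(all(kd %in% kf),
                info = paste("missing designed bonds:",
                             paste(kd[!kd %in% kf], collapse = "; ")))
  }
  # the mutant's designed upper-quadruple set is two bonds smaller
  up <- function(toy) {
    d <- toy$designed_hbonds
    sum(d$donor_resid %in% c(34, 37, 61, 65) &
          d$acceptor_resid %in% c(34, 37, 61, 65))
  }
  expect_equal(up(get_toy()) - up(get_toy(mutant = TRUE)), 2)
})

test_that("the toy aptamer has a sound structure and region map", {
  toy <- get_toy()
  st <- toy$structure
  expect_equal(nrow(st$nucleotides), 67)
  expect_equal(range(st$nucleotides$resid), c(15, 81))
  # every nucleotide exposes its N1 atom (the p_lrc anchor)
  for (r in st$nucleotides$resid) {
    expect_equal(sum(st$atoms$resid == r & st$atoms$name == "N1"), 1)
  }
  # coarse granularity
  coarse <- make_toy_aptamer(granularity = "coarse")
  expect_equal(nrow(coarse$structure$nucleotides), 67)
  expect_equal(nrow(coarse$structure$atoms), 67)
})

test_that("condition ensembles hit their design frequencies", {
  des <- coop_design(0.9, 0.6, 0.7, 0.5, n_snapshots = 400, n_traj = 1,
                     seed = 77)
  bundle <- simulate_condition_ensembles(des)
  for (nm in names(bundle$conditions)) {
    prof <- plrc_from_networks(bundle$conditions[[nm]]$networks,
                               bundle$topology)
    q <- des$q[[nm]]
    expect_lt(abs(prof$p_lrc[prof$resid == 5] - q),
              3 * sqrt(q * (1 - q) / 400),
              label = paste("frequency for", nm))
  }
  # seeded determinism of the full estimate
  c1 <- estimate_coop(simulate_condition_ensembles(des))
  c2 <- estimate_coop(simulate_condition_ensembles(des))
  expect_identical(c1$coop, c2$coop)
  expect_error(coop_design(0, 0.5, 0.5, 0.5, seed = 1), "probabilities")
})

test_that("the trajectory simulator reproduces its prescribed structure", {
  toy <- get_toy()
  # zero amplitude: no fluctuations
  e0 <- simulate_trajectory(toy$structure, n_frames = 4, seed = 61, sigma = 0)
  expect_lt(max(rmsf(e0)$rmsf), 1e-12)

  # per-region amplitudes: the prescribed ordering is recovered
  sig <- c(P1 = 0.15, P2 = 0.1, P3 = 0.1, L2 = 0.2, L3 = 0.2,
           "J1/2" = 0.3, "J2/3" = 0.6, "J3/1" = 0.3)
  ens <- simulate_trajectory(toy$structure, n_frames = 60, seed = 62,
                             sigma = sig, region_map = toy$regions)
  pr <- rmsf(ens)
  reg <- toy$regions
  mean_of <- function(lbl) mean(pr$rmsf[pr$resid %in%
                                          reg$resid[reg$region == lbl]])
  expect_lt(mean_of("P2"), mean_of("J2/3"))
  expect_lt(mean_of("P2"), mean_of("L2"))

  # identical seeds give identical ensembles
  a <- simulate_trajectory(toy$structure, n_frames = 5, seed = 63, sigma = 0.2)
  b <- simulate_trajectory(toy$structure, n_frames = 5, seed = 63, sigma = 0.2)
  expect_identical(a$xyz, b$xyz)
  expect_false(identical(
    a$xyz, simulate_trajectory(toy$structure, n_frames = 5, seed = 64,
                               sigma = 0.2)$xyz))

  # generators record their parameters
  expect_equal(attr(a, "params")$seed, 63)
  expect_error(simulate_trajectory(toy$structure, n_frames = 2, sigma = 0.1),
               "seed")
})

test_that("shedding ions lose shell waters at the designated frame", {
  toy <- get_toy()
  spec <- tibble::tibble(x = 40, y = 0, z = 0, mode = "shedding",
                         shed_frame = 3)
  ens <- simulate_trajectory(toy$structure, n_frames = 4, seed = 65,
                             sigma = 0, ion_spec = spec)
  h <- mg_hydration(ens)
  expect_true(all(h$n_waters[h$frame < 3] == 6))
  expect_true(all(h$n_waters[h$frame >= 3] == 4))
  expect_true(all(h$hexahydrated[h$frame < 3]))
  expect_false(any(h$hexahydrated[h$frame >= 3]))
})
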