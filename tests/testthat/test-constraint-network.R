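test_that("hydrogen-bond detection honors the geometric criteria", {
  # ideal geometry: N-H...O collinear at 2.9 A
  st <- g_plus_acceptor(2.9, 0)
  hb <- detect_hbonds(st)
  expect_true(any(hb$donor_name == "N1" & hb$acceptor_name == "O4"))

  # beyond the 3.5 A distance cutoff
  st2 <- g_plus_acceptor(3.6, 0)
  hb2 <- detect_hbonds(st2)
  expect_false(any(hb2$donor_name == "N1" & hb2$acceptor_name == "O4"))

  # acceptor 75 degrees off the hydrogen direction: D-H-A angle ~107
  st3 <- g_plus_acceptor(2.9, 75)
  hb3 <- detect_hbonds(st3)
  expect_false(any(hb3$donor_name == "N1" & hb3$acceptor_name == "O4"))
})

test_that("the hydrogen-bond energy has the right shape", {
  e_ideal <- hbond_energy(2.8, 180)
  expect_equal(e_ideal, -8)
  # weaker with distance beyond the optimum
  expect_lte(hbond_energy(2.9, 180), hbond_energy(3.4, 180))
  expect_lte(hbond_energy(2.8, 180), hbond_energy(2.9, 180))
  # short contacts clamp at the optimum rather than turning repulsive
  expect_equal(hbond_energy(2.5, 180), e_ideal)
  # weaker as the angle bends
  expect_lt(hbond_energy(2.9, 175), hbond_energy(2.9, 130))
  # salt bridges pass any cutoff
  expect_lt(hbond_energy(3.4, 125, salt_bridge = TRUE), -0.6)
  expect_lt(hbond_energy(3.4, 125, salt_bridge = TRUE), -1.0)
})

test_that("hydrophobic tethers follow the surface-gap rule", {
  mk <- function(d) {
    tab <- tibble::tibble(
      serial = 1:2, name = c("C5", "C5"), resid = 1:2,
      resname = c("A", "A"), chain = "A", x = c(0, d), y = 0, z = 0)
    riborigid:::build_structure_from_table(tab)
  }
  # gap = d - 3.4; threshold 0.25
  expect_equal(nrow(detect_hydrophobics(mk(3.5))), 1)
  expect_equal(nrow(detect_hydrophobics(mk(5.0))), 0)

  # stacked-pair fixture: tether set equals an independent enumeration
  toy <- get_toy()$structure
  sub_rows <- toy$atoms$resid %in% c(25, 26, 45, 46)
  sub <- toy
  sub$atoms <- toy$atoms[sub_rows, ]
  old_idx <- which(sub_rows)
  keepb <- toy$bonds$i %in% old_idx & toy$bonds$j %in% old_idx
  sub$bonds <- tibble::tibble(
    i = match(toy$bonds$i[keepb], old_idx),
    j = match(toy$bonds$j[keepb], old_idx),
    locked = toy$bonds$locked[keepb])
  sub$nucleotides <- toy$nucleotides[toy$nucleotides$resid %in%
                                       c(25, 26, 45, 46), ]
  got <- detect_hydrophobics(sub)
  # oracle: brute-force scan over C pairs, closest contact per residue pair
  a <- sub$atoms
  cs <- which(a$element == "C")
  best <- list()
  for (i in cs) for (j in cs) {
    if (i >= j || a$resid[i] == a$resid[j]) next
    d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                (a$z[i] - a$z[j])^2)
    if (d - 3.4 > 0.25) next
    key <- paste(min(a$resid[i], a$resid[j]), max(a$resid[i], a$resid[j]))
    if (is.null(best[[key]]) || d < best[[key]]$d) {
      best[[key]] <- list(i = min(i, j), j = max(i, j), d = d)
    }
  }
  expect_equal(nrow(got), length(best))
  got_keys <- paste(got$i, got$j)
  oracle_keys <- vapply(best, function(b) paste(b$i, b$j), "")
  expect_setequal(got_keys, unname(oracle_keys))
})

test_that("network construction filters bonds by energy and handles Mg", {
  st <- g_plus_acceptor(2.9, 0)
  hb <- detect_hbonds(st)
  # a bond weaker than the cutoff contributes no HBOND bars
  hb_weak <- hb
  hb_weak$energy <- -0.5
  net_weak <- build_network(st, e_cut = -0.6, hbonds = hb_weak)
  expect_equal(sum(net_weak$bars$type == "HBOND"), 0)

  # lowering the cutoff never adds bars (subset relation)
  toy <- get_toy()$structure
  hb_toy <- detect_hbonds(toy)
  hp_toy <- detect_hydrophobics(toy)
  n06 <- build_network(toy, e_cut = -0.6, hbonds = hb_toy,
                       hydrophobics = hp_toy)
  n10 <- build_network(toy, e_cut = -1.0, hbonds = hb_toy,
                       hydrophobics = hp_toy)
  key <- function(n) paste(n$bars$i, n$bars$j, n$bars$type)
  expect_true(all(key(n10) %in% key(n06)))
  expect_lte(n_bars(n10), n_bars(n06))

  # hexahydrated Mg fixture: 6 coordination bar groups
  stm <- suppressWarnings(read_structure(mg_water_pdb()))
  netm <- build_network(stm)
  expect_equal(sum(netm$bars$type == "MG_COORD"), 6)

  expect_error(build_network(toy, e_cut = 0.5), "negative")
})

test_that("network construction is deterministic", {
  toy <- get_toy()$structure
  n1 <- build_network(toy)
  n2 <- build_network(toy)
  expect_identical(n1$bars, n2$bars)
  f1 <- tempfile(); f2 <- tempfile()
  write_network(n1, f1); write_network(n2, f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("ligand constraints are additive, idempotent, and rigidify the site", {
  toy <- get_toy()$structure
  net <- build_network(toy)
  net_l <- add_ligand_constraints(net, toy)
  # purely additive
  key <- function(n) paste(n$bars$i, n$bars$j, n$bars$type)
  expect_true(all(key(net) %in% key(net_l)))
  expect_equal(sum(net_l$bars$type == "LIGAND"), 3)
  # idempotent
  net_l2 <- add_ligand_constraints(net_l, toy)
  expect_identical(net_l$bars, net_l2$bars)

  # empty site: binding nucleobases in different rigid clusters;
  # with constraints: one cluster
  a <- toy$atoms
  n1 <- vapply(c(47, 51, 74), function(r)
    which(a$resid == r & a$name == "N1"), 1L)
  bodies <- match(n1, net$body_atoms)
  apo <- pebble_game_decompose(net)
  expect_equal(length(unique(apo$cluster[bodies])), 3)
  lig <- pebble_game_decompose(net_l)
  expect_equal(length(unique(lig$cluster[bodies])), 1)

  # missing binding nucleotide is an error
  broken <- toy
  keep <- broken$atoms$resid != 74
  broken$atoms <- broken$atoms[keep, ]
  expect_error(add_ligand_constraints(net, broken, binding = c(47, 51, 74)),
               "74")
})

test_that("network files round trip", {
  net <- make_fixture_network("random", n = 8, seed = 5)
  f <- tempfile()
  write_network(net, f)
  net2 <- read_network(f)
  expect_equal(net2$n_bodies, net$n_bodies)
  expect_equal(net2$bars$i, net$bars$i)
  expect_equal(net2$bars$mult, net$bars$mult)
  expect_equal(net2$bars$type, net$bars$type)
  unlink(f)
})
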