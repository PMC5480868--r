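test_that("fixture networks decompose as designed", {
  r <- pebble_game_decompose(make_fixture_network("braced_pair"))
  expect_equal(length(r$cluster_sizes), 1)
  expect_equal(r$floppy_modes_internal, 0)
  expect_equal(r$independent_bars, 6)

  r2 <- pebble_game_decompose(make_fixture_network("hinge_pair"))
  expect_equal(length(r2$cluster_sizes), 2)
  expect_equal(r2$floppy_modes_internal, 1)

  r3 <- pebble_game_decompose(make_fixture_network("chain", n = 4))
  expect_equal(r3$floppy_modes_internal, 3)

  r4 <- pebble_game_decompose(make_fixture_network("ring", n = 5))
  expect_equal(length(r4$cluster_sizes), 1)
  expect_equal(r4$redundant_bars, 6)

  empty <- structure(
    list(n_bodies = 0L,
         bars = tibble::tibble(i = integer(), j = integer(),
                               mult = integer(), type = character(),
                               energy = numeric())),
    class = "constraint_network")
  expect_error(pebble_game_decompose(empty), "empty")
})

test_that("the pebble game agrees with the generic rank oracle", {
  set.seed(7)
  for (s in 1:40) {
    n <- sample(3:8, 1)
    net <- make_fixture_network("random", n = n, seed = 1000 + s)
    pg <- pebble_game_decompose(net)
    rk <- brute_force_rank(net, seed = 2000 + s)
    expect_equal(pg$independent_bars, rk,
                 info = paste("rank mismatch at seed", s))
    cl <- brute_force_clusters(net, seed = 3000 + s)
    expect_true(all(outer(pg$cluster, pg$cluster, "==") ==
                      outer(cl, cl, "==")),
                info = paste("partition mismatch at seed", s))
  }
})

test_that("decomposition is invariant to bar input order", {
  net <- make_fixture_network("random", n = 8, seed = 11)
  r1 <- pebble_game_decompose(net)
  set.seed(1)
  perm <- sample(nrow(net$bars))
  net2 <- new_constraint_network(net$n_bodies, net$bars[perm, ],
                                 body_atoms = net$body_atoms)
  r2 <- pebble_game_decompose(net2)
  expect_equal(r2$independent_bars, r1$independent_bars)
  expect_equal(r2$cluster, r1$cluster)
})

test_that("adding bars never adds floppy modes nor splits clusters", {
  # within one connected component; a bar bridging two components turns
  # their six relative rigid-body motions into internal modes instead
  for (s in 1:10) {
    net <- make_fixture_network("random", n = 6, seed = 500 + s)
    r1 <- pebble_game_decompose(net)
    set.seed(s)
    comp_of <- r1$component
    big <- as.integer(names(which.max(table(comp_of))))
    members <- which(comp_of == big)
    if (length(members) < 2) next
    uv <- sample(members, 2)
    extra <- tibble::tibble(
      i = uv[1], j = uv[2], mult = sample(6, 1),
      type = "COVALENT_LOCKED", energy = NA_real_)
    net2 <- new_constraint_network(6, rbind(net$bars, extra))
    r2 <- pebble_game_decompose(net2)
    expect_lte(r2$floppy_modes_internal, r1$floppy_modes_internal)
    # old clusters stay together: the new partition refines upward
    for (cl in unique(r1$cluster)) {
      members <- which(r1$cluster == cl)
      expect_equal(length(unique(r2$cluster[members])), 1)
    }
  }
})

test_that("counts are conserved", {
  for (s in 1:5) {
    net <- make_fixture_network("random", n = 7, seed = 600 + s)
    r <- pebble_game_decompose(net)
    expect_equal(sum(r$cluster_sizes), net$n_bodies)
    expect_equal(r$independent_bars + r$redundant_bars, n_bars(net))
    expect_gte(r$floppy_modes_internal, 0)
  }
})

test_that("the largest cluster is reported with the documented tie rule", {
  # two rigid pairs: (1,2) and (3,4); tie broken toward body 1's cluster
  bars <- tibble::tibble(i = c(1L, 3L), j = c(2L, 4L), mult = 6L,
                         type = "COVALENT_LOCKED", energy = NA_real_)
  r <- pebble_game_decompose(new_constraint_network(4, bars))
  expect_setequal(largest_rigid_cluster(r), c(1, 2))

  # fully rigid network: every body
  r2 <- pebble_game_decompose(make_fixture_network("ring", n = 6))
  expect_setequal(largest_rigid_cluster(r2), 1:6)
})

test_that("the rank oracle matches counting on reference cases", {
  expect_equal(brute_force_rank(make_fixture_network("braced_pair")), 6)
  lone <- new_constraint_network(
    1, tibble::tibble(i = integer(), j = integer(), mult = integer(),
                      type = character(), energy = numeric()))
  expect_equal(brute_force_rank(lone), 0)
  # complete graph on 4 bodies, 5 bars per edge: rank = 6*4 - 6 = 18
  pairs <- utils::combn(4, 2)
  k4 <- new_constraint_network(4, tibble::tibble(
    i = pairs[1, ], j = pairs[2, ], mult = 5L,
    type = "COVALENT_LOCKED", energy = NA_real_))
  expect_equal(brute_force_rank(k4), 18)
  expect_equal(pebble_game_decompose(k4)$independent_bars, 18)
})

test_that("tidy and glance summarize a decomposition", {
  net <- make_fixture_network("chain", n = 4)
  r <- pebble_game_decompose(net)
  td <- tidy(r)
  expect_equal(nrow(td), 4)
  expect_true(all(c("body", "cluster", "in_largest") %in% names(td)))
  gl <- glance(r)
  expect_equal(gl$n_bodies, 4)
  expect_equal(gl$floppy_modes_internal, 3)
})
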