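#' Fixture constraint networks with known rigidity
#'
#' Deterministic small networks used to exercise the pebble game:
#' * `braced_pair`: two bodies joined by 6 bars — one rigid cluster, no
#'   internal floppy modes;
#' * `hinge_pair`: two bodies joined by 5 bars — one internal mode, two
#'   singleton clusters;
#' * `chain`: `n` bodies joined consecutively by 5-bar links — `n - 1`
#'   internal modes;
#' * `ring`: `n` bodies in a cycle of 6-bar links — fully rigid;
#' * `random`: `n` bodies with random edges and multiplicities 1..6,
#'   seed-deterministic, intended for oracle comparison (hence `n <= 50`).
#'
#' @param kind One of `"braced_pair"`, `"hinge_pair"`, `"chain"`, `"ring"`,
#'   `"random"`.
#' @param n Number of bodies (for `chain`, `ring`, `random`).
#' @param seed Integer seed (mandatory for `random`).
#' @param edge_prob Probability that a body pair receives a bar group
#'   (`random` only).
#' @return A `constraint_network`; parameters are recorded in its `log`.
#' @export
make_fixture_network <- function(kind = c("braced_pair", "hinge_pair",
                                          "chain", "ring", "random"),
                                 n = 4L, seed = 1L, edge_prob = 0.5) {
  kind <- match.arg(kind)
  lg <- list(kind = kind, n = n, seed = seed)
  bar <- function(i, j, mult) {
    tibble(i = as.integer(i), j = as.integer(j), mult = as.integer(mult),
           type = "COVALENT_LOCKED", energy = NA_real_)
  }
  net <- switch(kind,
    braced_pair = new_constraint_network(2, bar(1, 2, 6), log = lg),
    hinge_pair = new_constraint_network(2, bar(1, 2, 5), log = lg),
    chain = {
      stopifnot(n >= 2)
      new_constraint_network(n, bar(seq_len(n - 1), seq_len(n - 1) + 1, 5),
                             log = lg)
    },
    ring = {
      stopifnot(n >= 3)
      new_constraint_network(
        n, bar(seq_len(n), c(seq_len(n - 1) + 1, 1), 6), log = lg)
    },
    random = {
      if (n > 50) abort("random fixture networks are limited to n <= 50")
      stopifnot(n >= 2)
      withr_seed(seed)
      pairs <- expand.grid(i = seq_len(n), j = seq_len(n))
      pairs <- pairs[pairs$i < pairs$j, ]
      keep <- runif(nrow(pairs)) < edge_prob
      pairs <- pairs[keep, , drop = FALSE]
      if (nrow(pairs) == 0) pairs <- data.frame(i = 1L, j = 2L)
      new_constraint_network(
        n,
        tibble(i = as.integer(pairs$i), j = as.integer(pairs$j),
               mult = sample.int(6, nrow(pairs), replace = TRUE),
               type = "COVALENT_LOCKED", energy = NA_real_),
        log = lg)
    })
  net
}
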