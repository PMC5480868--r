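#' Constraint-network object
#'
#' A body-bar constraint network: one body per heavy atom (bonded hydrogens
#' absorbed into their parent), and multi-edges ("bars") with a multiplicity
#' between 1 and 6 and a provenance tag. This is the object the pebble game
#' consumes.
#'
#' @param n_bodies Number of bodies (vertices).
#' @param bars A data frame with columns `i`, `j` (body indices), `mult`
#'   (bar multiplicity, 1..6), `type` (one of `"COVALENT_ROTATABLE"`,
#'   `"COVALENT_LOCKED"`, `"HBOND"`, `"HYDROPHOBIC"`, `"MG_COORD"`,
#'   `"LIGAND"`) and `energy` (kcal/mol; `NA` where not applicable).
#' @param body_atoms Optional integer vector mapping each body to the row
#'   index of its atom in the source structure's atom table.
#' @param e_cut Hydrogen-bond energy cutoff (kcal/mol) used when the network
#'   was built, if any.
#' @param log Named list of build metadata (counts, parameters).
#'
#' @return An object of class `constraint_network`.
#' @export
new_constraint_network <- function(n_bodies, bars, body_atoms = NULL,
                                   e_cut = NA_real_, log = list()) {
  stopifnot(is.numeric(n_bodies), n_bodies >= 1)
  bars <- as_tibble(bars)
  needed <- c("i", "j", "mult", "type", "energy")
  if (!all(needed %in% names(bars))) {
    abort(paste("bars must have columns", paste(needed, collapse = ", ")))
  }
  if (nrow(bars) > 0) {
    if (any(bars$i == bars$j)) abort("self-edges are not allowed")
    if (any(bars$i < 1 | bars$j < 1 | bars$i > n_bodies | bars$j > n_bodies)) {
      abort("bar endpoints must be valid bodies")
    }
    if (any(bars$mult < 1 | bars$mult > 6)) {
      abort("bar multiplicities must lie in 1..6")
    }
    bad <- setdiff(unique(bars$type), bar_types())
    if (length(bad) > 0) {
      abort(paste("unknown bar provenance:", paste(bad, collapse = ", ")))
    }
    # canonical order: i < j, then sorted, for byte-for-byte determinism
    swap <- bars$i > bars$j
    tmp <- bars$i[swap]; bars$i[swap] <- bars$j[swap]; bars$j[swap] <- tmp
    bars <- arrange(bars, .data$i, .data$j, .data$type, .data$mult)
  }
  structure(
    list(n_bodies = as.integer(n_bodies), bars = bars,
         body_atoms = body_atoms, e_cut = e_cut, log = log),
    class = "constraint_network")
}

bar_types <- function() {
  c("COVALENT_ROTATABLE", "COVALENT_LOCKED", "HBOND", "HYDROPHOBIC",
    "MG_COORD", "LIGAND")
}

#' @export
print.constraint_network <- function(x, ...) {
  cat("<constraint_network> ", x$n_bodies, " bodies, ",
      nrow(x$bars), " bar groups (", sum(x$bars$mult), " bars)\n", sep = "")
  if (!is.na(x$e_cut)) cat("  e_cut:", x$e_cut, "kcal/mol\n")
  if (nrow(x$bars) > 0) {
    tab <- table(x$bars$type)
    cat("  ", paste(names(tab), tab, sep = ":", collapse = "  "), "\n", sep = "")
  }
  invisible(x)
}

#' Total bar count of a network
#' @param net A `constraint_network`.
#' @return Integer: the sum of bar multiplicities.
#' @export
n_bars <- function(net) {
  stopifnot(inherits(net, "constraint_network"))
  if (nrow(net$bars) == 0) 0L else sum(net$bars$mult)
}

#' Write / read a network as a plain-text dataset file
#'
#' One bar record per line (`body_i body_j mult type energy`) after a body
#' table, with a commented header carrying the energy cutoff. The format is
#' self-contained so generated networks are indistinguishable from networks
#' built from structures.
#'
#' @param net A `constraint_network`.
#' @param path File path.
#' @return `write_network` returns `path` invisibly; `read_network` returns
#'   a `constraint_network`.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "constraint_network"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# riborigid constraint network",
    paste0("# e_cut ", format(net$e_cut)),
    paste0("# n_bodies ", net$n_bodies),
    paste0("# n_bar_groups ", nrow(net$bars))), con)
  if (!is.null(net$body_atoms)) {
    writeLines(paste("BODY", seq_len(net$n_bodies), net$body_atoms), con)
  } else {
    writeLines(paste("BODY", seq_len(net$n_bodies), NA), con)
  }
  if (nrow(net$bars) > 0) {
    writeLines(paste("BAR", net$bars$i, net$bars$j, net$bars$mult,
                     net$bars$type, format(net$bars$energy, digits = 10)), con)
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  e_cut <- suppressWarnings(
    as.numeric(sub("^# e_cut ", "", grep("^# e_cut ", lines,
                                         value = TRUE)[1])))
  n_bodies <- as.integer(sub("^# n_bodies ", "",
                             grep("^# n_bodies ", lines, value = TRUE)[1]))
  body_lines <- grep("^BODY ", lines, value = TRUE)
  body_atoms <- suppressWarnings(
    as.integer(vapply(strsplit(body_lines, " +"), `[`, "", 3)))
  if (all(is.na(body_atoms))) body_atoms <- NULL
  bar_lines <- grep("^BAR ", lines, value = TRUE)
  if (length(bar_lines) > 0) {
    parts <- strsplit(bar_lines, " +")
    bars <- tibble(
      i = as.integer(vapply(parts, `[`, "", 2)),
      j = as.integer(vapply(parts, `[`, "", 3)),
      mult = as.integer(vapply(parts, `[`, "", 4)),
      type = vapply(parts, `[`, "", 5),
      energy = suppressWarnings(as.numeric(vapply(parts, `[`, "", 6))))
  } else {
    bars <- tibble(i = integer(), j = integer(), mult = integer(),
                   type = character(), energy = numeric())
  }
  new_constraint_network(n_bodies, bars, body_atoms = body_atoms, e_cut = e_cut)
}
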