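#' Build a body-bar constraint network from a structure
#'
#' Bodies are the retained heavy atoms (RNA always; Mg2+ when
#' `include_mg`; waters only when inside an Mg2+ first hydration shell,
#' i.e. water oxygen within `mg_cut` of an ion — bulk water is discarded).
#' Bars: covalent bonds from the topology (locked bonds, e.g. ring and
#' partial-double bonds, get the locked multiplicity; others the rotatable
#' one); hydrogen bonds with `energy <= e_cut`; hydrophobic tethers;
#' Mg--water and Mg--RNA contacts within `mg_cut` as covalent-strength
#' coordination bars; water--RNA contacts enter through the hydrogen-bond
#' set. Counts are recorded in the network's build log.
#'
#' @param structure An `rna_structure`.
#' @param e_cut Hydrogen-bond energy cutoff (kcal/mol); must be negative.
#' @param include_mg Include Mg2+ ions and their first-shell waters.
#' @param hbonds Hydrogen bonds from [detect_hbonds()] on the same
#'   structure (computed if `NULL`).
#' @param hydrophobics Tethers from [detect_hydrophobics()] (computed if
#'   `NULL`).
#' @param mg_cut First-shell / chelation distance cutoff (A), default 3.5.
#' @param mults Named multiplicities per provenance (overridable):
#'   rotatable covalent 5, locked covalent 6, hydrogen bond 5,
#'   hydrophobic 2, Mg coordination 6.
#' @return A [new_constraint_network()] whose `body_atoms` maps bodies to
#'   atom rows of `structure`.
#' @export
build_network <- function(structure, e_cut = -0.6, include_mg = TRUE,
                          hbonds = NULL, hydrophobics = NULL, mg_cut = 3.5,
                          mults = c(COVALENT_ROTATABLE = 5, COVALENT_LOCKED = 6,
                                    HBOND = 5, HYDROPHOBIC = 2, MG_COORD = 6)) {
  stopifnot(inherits(structure, "rna_structure"))
  if (!is.finite(e_cut) || e_cut >= 0) {
    abort("e_cut must be negative (the cutoff keeps attractive bonds)")
  }
  a <- structure$atoms
  if (is.null(hbonds)) hbonds <- detect_hbonds(structure)
  if (is.null(hydrophobics)) hydrophobics <- detect_hydrophobics(structure)

  mg_rows <- which(a$category == "MG")
  wat_o <- which(a$category == "WATER" & a$element == "O")
  shell <- integer(0)
  mg_bars <- list()
  if (include_mg && length(mg_rows) > 0) {
    for (m in mg_rows) {
      if (length(wat_o) > 0) {
        dd <- sqrt((a$x[wat_o] - a$x[m])^2 + (a$y[wat_o] - a$y[m])^2 +
                     (a$z[wat_o] - a$z[m])^2)
        sh <- wat_o[dd <= mg_cut]
        shell <- c(shell, sh)
        if (length(sh) > 0) {
          mg_bars[[length(mg_bars) + 1]] <- tibble(ai = m, aj = sh)
        }
      }
      rna_heavy <- which(a$category == "RNA" & a$element != "H")
      dd <- sqrt((a$x[rna_heavy] - a$x[m])^2 + (a$y[rna_heavy] - a$y[m])^2 +
                   (a$z[rna_heavy] - a$z[m])^2)
      ch <- rna_heavy[dd <= mg_cut]
      if (length(ch) > 0) {
        mg_bars[[length(mg_bars) + 1]] <- tibble(ai = m, aj = ch)
      }
    }
  }

  retained <- which(
    (a$category == "RNA" & a$element != "H") |
      (include_mg & a$category == "MG") |
      (seq_len(nrow(a)) %in% shell))
  atom2body <- rep(NA_integer_, nrow(a))
  atom2body[retained] <- seq_along(retained)

  bars <- list()
  cov <- structure$bonds
  keep <- !is.na(atom2body[cov$i]) & !is.na(atom2body[cov$j])
  cov <- cov[keep, , drop = FALSE]
  if (nrow(cov) > 0) {
    bars$covalent <- tibble(
      i = atom2body[cov$i], j = atom2body[cov$j],
      mult = as.integer(ifelse(cov$locked, mults[["COVALENT_LOCKED"]],
                               mults[["COVALENT_ROTATABLE"]])),
      type = ifelse(cov$locked, "COVALENT_LOCKED", "COVALENT_ROTATABLE"),
      energy = NA_real_)
  }
  hb <- hbonds[hbonds$energy <= e_cut, , drop = FALSE]
  hb <- hb[!is.na(atom2body[hb$donor]) & !is.na(atom2body[hb$acceptor]), ,
           drop = FALSE]
  if (nrow(hb) > 0) {
    bars$hbond <- tibble(
      i = atom2body[hb$donor], j = atom2body[hb$acceptor],
      mult = as.integer(mults[["HBOND"]]), type = "HBOND",
      energy = hb$energy)
  }
  hp <- hydrophobics[!is.na(atom2body[hydrophobics$i]) &
                       !is.na(atom2body[hydrophobics$j]), , drop = FALSE]
  if (nrow(hp) > 0) {
    bars$hydrophobic <- tibble(
      i = atom2body[hp$i], j = atom2body[hp$j],
      mult = as.integer(mults[["HYDROPHOBIC"]]), type = "HYDROPHOBIC",
      energy = NA_real_)
  }
  if (length(mg_bars) > 0) {
    mb <- bind_rows(mg_bars)
    bars$mg <- tibble(
      i = atom2body[mb$ai], j = atom2body[mb$aj],
      mult = as.integer(mults[["MG_COORD"]]), type = "MG_COORD",
      energy = NA_real_)
  }
  allbars <- bind_rows(bars)
  if (nrow(allbars) > 0) {
    sw <- allbars$i > allbars$j
    tmp <- allbars$i[sw]; allbars$i[sw] <- allbars$j[sw]; allbars$j[sw] <- tmp
    # one bar group per (pair, provenance): strongest energy kept
    allbars <- allbars %>%
      group_by(.data$i, .data$j, .data$type) %>%
      summarise(mult = max(.data$mult),
                energy = ifelse(all(is.na(.data$energy)), NA_real_,
                                min(.data$energy, na.rm = TRUE)),
                .groups = "drop")
    allbars <- allbars[, c("i", "j", "mult", "type", "energy")]
  } else {
    allbars <- tibble(i = integer(), j = integer(), mult = integer(),
                      type = character(), energy = numeric())
  }
  lg <- list(
    n_atoms = nrow(a), n_bodies = length(retained),
    n_mg = length(mg_rows[include_mg]), n_shell_waters = length(unique(shell)),
    n_hbonds_detected = nrow(hbonds), n_hbonds_kept = nrow(hb),
    n_hydrophobic = nrow(hp), e_cut = e_cut)
  new_constraint_network(length(retained), allbars,
                         body_atoms = retained, e_cut = e_cut, log = lg)
}

#' Model a bound ligand by pairwise binding-site constraints
#'
#' Adds LIGAND-tagged, locked-strength bars connecting the base N1 atoms
#' of the binding nucleotides pairwise, which places the three binding
#' nucleobases in one rigid cluster (the bases themselves are internally
#' rigid through their locked ring bonds). This "weak coupling" scheme adds
#' no stacking constraints. The input network is not modified; applying the
#' operation twice yields the same bar set.
#'
#' @param net A `constraint_network` built from `structure`.
#' @param structure The source `rna_structure`.
#' @param binding Nucleotide ids of the binding triplet (default 47, 51,
#'   74).
#' @return A new `constraint_network` with the added bars.
#' @export
add_ligand_constraints <- function(net, structure, binding = c(47L, 51L, 74L)) {
  stopifnot(inherits(net, "constraint_network"),
            inherits(structure, "rna_structure"))
  a <- structure$atoms
  bodies <- integer(length(binding))
  for (k in seq_along(binding)) {
    row <- which(a$resid == binding[k] & a$category == "RNA" &
                   a$name == "N1")
    if (length(row) != 1) {
      abort(paste0("binding nucleotide ", binding[k],
                   " (base N1 atom) not found in structure"))
    }
    body <- match(row, net$body_atoms)
    if (is.na(body)) {
      abort(paste("binding nucleotide", binding[k], "is not in the network"))
    }
    bodies[k] <- body
  }
  pairs <- utils::combn(sort(bodies), 2)
  lig <- tibble(i = pairs[1, ], j = pairs[2, ], mult = 6L,
                type = "LIGAND", energy = NA_real_)
  bars <- bind_rows(net$bars, lig) %>%
    distinct(.data$i, .data$j, .data$type, .keep_all = TRUE)
  new_constraint_network(net$n_bodies, bars, body_atoms = net$body_atoms,
                         e_cut = net$e_cut,
                         log = c(net$log, list(ligand_binding = binding)))
}
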