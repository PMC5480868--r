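#' Read an RNA structure from a PDB file
#'
#' Parses ATOM/HETATM records (delegating the record parsing to bio3d),
#' assigns each atom a category (`RNA`, `MG`, `WATER`, `OTHER`) from its
#' residue name, and derives covalent connectivity from internal residue
#' templates for the standard ribonucleotides plus inter-residue O3'-P
#' links; residues outside the templates fall back to distance-based
#' bonding (< 1.8 A between heavy atoms) and are categorized `OTHER` with
#' a warning. Alternate locations keep the highest-occupancy conformer;
#' insertion codes raise an error.
#'
#' @param pdb_source Path to a PDB file, or a character vector of PDB
#'   record lines.
#' @return An object of class `rna_structure`: a list with `atoms` (a
#'   tibble of serial, name, element, resid, resname, chain, x, y, z,
#'   mass, category), `bonds` (atom-row pairs with a `locked` flag) and
#'   `nucleotides` (ordered residue table).
#' @export
read_structure <- function(pdb_source) {
  path <- pdb_source
  if (length(pdb_source) > 1 || grepl("\n", pdb_source[1]) ||
      !file.exists(pdb_source[1])) {
    if (length(pdb_source) == 1 && !grepl("\n", pdb_source) &&
        !grepl("^(ATOM|HETATM|MODEL|REMARK|HEADER|CRYST|END|TER)", pdb_source)) {
      abort(paste("file not found:", pdb_source))
    }
    path <- tempfile(fileext = ".pdb")
    writeLines(unlist(strsplit(pdb_source, "\n")), path)
    on.exit(unlink(path))
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  if (any(!is.na(at$insert) & at$insert != "")) {
    abort("insertion codes are not supported")
  }
  # alternate locations: keep the highest-occupancy conformer per atom site
  if (any(!is.na(at$alt) & at$alt != "")) {
    key <- paste(at$chain, at$resno, at$elety)
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(idx) {
      if (length(idx) == 1) return(idx)
      occ <- at$o[idx]; occ[is.na(occ)] <- 0
      idx[order(-occ, at$alt[idx])][1]
    }))
    at <- at[sort(keep), , drop = FALSE]
  }
  if (anyDuplicated(at$eleno)) abort("duplicate atom serials in PDB input")
  build_structure_from_table(tibble(
    serial = as.integer(at$eleno),
    name = trimws(at$elety),
    resid = as.integer(at$resno),
    resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    x = at$x, y = at$y, z = at$z))
}

# shared constructor used by the PDB reader and the synthetic generators;
# `tab` needs serial, name, resid, resname, chain, x, y, z
build_structure_from_table <- function(tab) {
  rn <- normalize_resname(tab$resname)
  cat_res <- atom_category(rn)
  if (any(cat_res == "OTHER")) {
    warn(paste("unknown residue name(s) categorized OTHER:",
               paste(unique(tab$resname[cat_res == "OTHER"]), collapse = ", ")))
  }
  el <- guess_element(tab$name, rn)
  atoms <- tibble(
    serial = as.integer(tab$serial),
    name = tab$name,
    element = el,
    resid = as.integer(tab$resid),
    resname = rn,
    chain = tab$chain,
    x = tab$x, y = tab$y, z = tab$z,
    mass = unname(element_masses[el]),
    category = cat_res)
  if (any(is.na(atoms$mass))) {
    atoms$mass[is.na(atoms$mass)] <- 12.011
  }
  stopifnot(all(is.finite(atoms$x)), all(is.finite(atoms$y)),
            all(is.finite(atoms$z)))
  nuc <- atoms %>%
    filter(.data$category == "RNA") %>%
    distinct(.data$chain, .data$resid, .data$resname)
  for (ch in unique(nuc$chain)) {
    r <- nuc$resid[nuc$chain == ch]
    if (any(diff(r) <= 0)) {
      abort("nucleotide numbering must be strictly increasing within a chain")
    }
  }
  bonds <- derive_bonds(atoms)
  structure(list(atoms = atoms, bonds = bonds,
                 nucleotides = select(nuc, resid = "resid",
                                      resname = "resname", chain = "chain")),
            class = "rna_structure")
}

derive_bonds <- function(atoms) {
  out <- list()
  heavy <- atoms$element != "H"
  # template bonds within RNA residues
  rna_idx <- which(atoms$category == "RNA")
  if (length(rna_idx) > 0) {
    by_res <- split(rna_idx, paste(atoms$chain[rna_idx], atoms$resid[rna_idx]))
    for (idx in by_res) {
      base <- atoms$resname[idx[1]]
      tmpl <- residue_template_bonds(base)
      pos <- setNames(idx, atoms$name[idx])
      ok <- tmpl$a1 %in% names(pos) & tmpl$a2 %in% names(pos)
      if (any(ok)) {
        out[[length(out) + 1]] <- tibble(
          i = unname(pos[tmpl$a1[ok]]), j = unname(pos[tmpl$a2[ok]]),
          locked = tmpl$locked[ok])
      }
    }
    # inter-residue O3' -> P links between consecutive nucleotides
    nuc <- atoms %>%
      filter(.data$category == "RNA") %>%
      distinct(.data$chain, .data$resid)
    for (ch in unique(nuc$chain)) {
      rs <- sort(nuc$resid[nuc$chain == ch])
      for (k in seq_len(length(rs) - 1)) {
        o3 <- which(atoms$chain == ch & atoms$resid == rs[k] &
                      atoms$name == "O3'")
        p <- which(atoms$chain == ch & atoms$resid == rs[k + 1] &
                     atoms$name == "P")
        if (length(o3) == 1 && length(p) == 1) {
          out[[length(out) + 1]] <- tibble(i = o3, j = p, locked = FALSE)
        }
      }
    }
  }
  # distance-based fallback for OTHER residues
  oth <- which(atoms$category == "OTHER" & heavy)
  if (length(oth) > 1) {
    xyz <- as.matrix(atoms[oth, c("x", "y", "z")])
    d <- as.matrix(stats::dist(xyz))
    pr <- which(upper.tri(d) & d < 1.8, arr.ind = TRUE)
    if (nrow(pr) > 0) {
      out[[length(out) + 1]] <- tibble(i = oth[pr[, 1]], j = oth[pr[, 2]],
                                       locked = FALSE)
    }
  }
  # hydrogens bond to the nearest heavy atom of the same residue
  hyd <- which(atoms$element == "H")
  if (length(hyd) > 0) {
    for (h in hyd) {
      cand <- which(heavy & atoms$resid == atoms$resid[h] &
                      atoms$chain == atoms$chain[h])
      if (length(cand) == 0) next
      dd <- sqrt((atoms$x[cand] - atoms$x[h])^2 +
                   (atoms$y[cand] - atoms$y[h])^2 +
                   (atoms$z[cand] - atoms$z[h])^2)
      k <- cand[which.min(dd)]
      if (min(dd) < 1.3) {
        out[[length(out) + 1]] <- tibble(i = k, j = h, locked = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(i = integer(), j = integer(), locked = logical()))
  }
  bind_rows(out) %>% distinct() %>% arrange(.data$i, .data$j)
}

#' @export
print.rna_structure <- function(x, ...) {
  cat("<rna_structure> ", nrow(x$atoms), " atoms, ",
      nrow(x$nucleotides), " nucleotides, ",
      nrow(x$bonds), " covalent bonds\n", sep = "")
  tab <- table(x$atoms$category)
  cat("  ", paste(names(tab), tab, sep = ":", collapse = "  "), "\n", sep = "")
  invisible(x)
}

#' Write a structure (optionally an ensemble) as PDB
#'
#' @param structure An `rna_structure`.
#' @param path Output path.
#' @param xyz Optional frames matrix (frames x 3*n_atoms) to emit a
#'   multi-model PDB.
#' @param b Optional per-atom B-factor column values.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path, xyz = NULL, b = NULL) {
  a <- structure$atoms
  if (is.null(xyz)) xyz <- matrix(structure_xyz(structure), nrow = 1)
  bio3d::write.pdb(
    file = path, xyz = xyz,
    type = ifelse(a$category == "RNA", "ATOM", "HETATM"),
    resno = a$resid, resid = a$resname, eleno = a$serial, elety = a$name,
    chain = a$chain, o = rep(1, nrow(a)),
    b = if (is.null(b)) rep(0, nrow(a)) else b,
    elesy = a$element)
  invisible(path)
}

# flat coordinate vector (x1,y1,z1,x2,...) of a structure
structure_xyz <- function(structure) {
  as.numeric(t(as.matrix(structure$atoms[, c("x", "y", "z")])))
}

set_structure_xyz <- function(structure, flat) {
  m <- matrix(flat, ncol = 3, byrow = TRUE)
  structure$atoms$x <- m[, 1]
  structure$atoms$y <- m[, 2]
  structure$atoms$z <- m[, 3]
  structure
}

#' Read a conformational ensemble sharing one topology
#'
#' Accepts a multi-model PDB path, a whitespace-delimited per-frame XYZ
#' table (columns frame, atom index, x, y, z), or a numeric matrix with
#' one frame per row. When `frame_spacing` is given, frames with
#' `time <= discard` are dropped.
#'
#' @param topology An `rna_structure`.
#' @param frames_source Multi-model PDB path, XYZ table path/data frame,
#'   or frames matrix.
#' @param frame_spacing Time per frame in ps (optional).
#' @param discard Leading time span (ps) to exclude from analysis.
#' @return An object of class `rna_ensemble` with elements `topology`,
#'   `xyz` (frames x 3*n_atoms), `time` (ps or NA) and `n_frames`.
#' @export
read_ensemble <- function(topology, frames_source, frame_spacing = NULL,
                          discard = 0) {
  stopifnot(inherits(topology, "rna_structure"))
  natoms <- nrow(topology$atoms)
  if (is.matrix(frames_source)) {
    xyz <- frames_source
  } else if (is.data.frame(frames_source)) {
    xyz <- xyz_table_to_matrix(frames_source, natoms)
  } else if (is.character(frames_source) && file.exists(frames_source)) {
    first <- readLines(frames_source, n = 50)
    if (any(grepl("^(MODEL|ATOM|HETATM)", first))) {
      pdb <- bio3d::read.pdb(frames_source, multi = TRUE, verbose = FALSE)
      xyz <- pdb$xyz
      if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
    } else {
      tab <- read.table(frames_source, header = FALSE,
                        col.names = c("frame", "atom", "x", "y", "z"))
      xyz <- xyz_table_to_matrix(tab, natoms)
    }
  } else {
    abort("frames_source must be a matrix, data frame, or existing file path")
  }
  if (nrow(xyz) == 0) abort("ensemble must contain at least one frame")
  if (ncol(xyz) != 3 * natoms) {
    abort(paste0("frame atom count (", ncol(xyz) / 3,
                 ") does not match topology (", natoms, ")"))
  }
  tm <- rep(NA_real_, nrow(xyz))
  if (!is.null(frame_spacing)) {
    tm <- seq_len(nrow(xyz)) * frame_spacing
    keep <- tm > discard
    xyz <- xyz[keep, , drop = FALSE]
    tm <- tm[keep]
    if (nrow(xyz) == 0) abort("discard window removed every frame")
  }
  structure(list(topology = topology, xyz = xyz, time = tm,
                 frame_spacing = frame_spacing %||% NA_real_,
                 discard = discard, n_frames = nrow(xyz)),
            class = "rna_ensemble")
}

xyz_table_to_matrix <- function(tab, natoms) {
  names(tab)[1:5] <- c("frame", "atom", "x", "y", "z")
  frames <- sort(unique(tab$frame))
  xyz <- matrix(NA_real_, nrow = length(frames), ncol = 3 * natoms)
  for (fi in seq_along(frames)) {
    sub <- tab[tab$frame == frames[fi], ]
    if (nrow(sub) != natoms) {
      abort(paste0("frame ", frames[fi], " has ", nrow(sub),
                   " atoms; topology has ", natoms))
    }
    sub <- sub[order(sub$atom), ]
    xyz[fi, ] <- as.numeric(t(as.matrix(sub[, c("x", "y", "z")])))
  }
  xyz
}

#' @export
print.rna_ensemble <- function(x, ...) {
  cat("<rna_ensemble> ", x$n_frames, " frames x ",
      nrow(x$topology$atoms), " atoms", sep = "")
  if (!is.na(x$frame_spacing)) {
    cat(" (", x$frame_spacing, " ps/frame, discard ", x$discard, " ps)",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

# frame as a structure (coordinates replaced)
ensemble_frame <- function(ensemble, i) {
  set_structure_xyz(ensemble$topology, ensemble$xyz[i, ])
}
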