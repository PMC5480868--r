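# Internal residue templates for standard ribonucleotides: covalent bonds
# (with a locked flag for bonds with hindered rotation: ring bonds and
# partial-double exocyclic bonds), hydrogen-bond donors/acceptors, element
# masses and van-der-Waals radii. Connectivity is template-driven for RNA;
# distance inference is used only for residues outside the templates.

element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    P = 30.974, S = 32.06, MG = 24.305, NA. = 22.99,
                    K = 39.098)

vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80,
               H = 1.20, MG = 1.73)

backbone_atoms <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'",
                    "C3'", "O3'", "C2'", "O2'", "C1'")

backbone_bonds <- function() {
  b <- function(a1, a2, locked = FALSE) tibble(a1 = a1, a2 = a2, locked = locked)
  bind_rows(
    b("P", "OP1", TRUE), b("P", "OP2", TRUE), b("P", "O5'"),
    b("O5'", "C5'"), b("C5'", "C4'"), b("C4'", "O4'"), b("C4'", "C3'"),
    b("C3'", "O3'"), b("C3'", "C2'"), b("C2'", "O2'"), b("C2'", "C1'"),
    b("C1'", "O4'"))
}

base_bonds <- function(base) {
  b <- function(a1, a2, locked = TRUE) tibble(a1 = a1, a2 = a2, locked = locked)
  switch(base,
    A = bind_rows(
      b("C1'", "N9", locked = FALSE),
      b("N9", "C8"), b("C8", "N7"), b("N7", "C5"), b("C5", "C6"),
      b("C6", "N6"), b("C6", "N1"), b("N1", "C2"), b("C2", "N3"),
      b("N3", "C4"), b("C4", "C5"), b("C4", "N9")),
    G = bind_rows(
      b("C1'", "N9", locked = FALSE),
      b("N9", "C8"), b("C8", "N7"), b("N7", "C5"), b("C5", "C6"),
      b("C6", "O6"), b("C6", "N1"), b("N1", "C2"), b("C2", "N2"),
      b("C2", "N3"), b("N3", "C4"), b("C4", "C5"), b("C4", "N9")),
    C = bind_rows(
      b("C1'", "N1", locked = FALSE),
      b("N1", "C2"), b("C2", "O2"), b("C2", "N3"), b("N3", "C4"),
      b("C4", "N4"), b("C4", "C5"), b("C5", "C6"), b("C6", "N1")),
    U = bind_rows(
      b("C1'", "N1", locked = FALSE),
      b("N1", "C2"), b("C2", "O2"), b("C2", "N3"), b("N3", "C4"),
      b("C4", "O4"), b("C4", "C5"), b("C5", "C6"), b("C6", "N1")),
    abort(paste("no template for base", base)))
}

residue_template_bonds <- function(base) {
  bind_rows(backbone_bonds(), base_bonds(base))
}

# donors: atom name -> number of polar hydrogens it carries
base_donors <- function(base) {
  switch(base,
    A = c("N6" = 2L),
    G = c("N1" = 1L, "N2" = 2L),
    C = c("N4" = 2L),
    U = c("N3" = 1L),
    integer())
}

sugar_donors <- c("O2'" = 1L)

base_acceptors <- function(base) {
  switch(base,
    A = c("N1", "N3", "N7"),
    G = c("O6", "N3", "N7"),
    C = c("O2", "N3"),
    U = c("O2", "O4"),
    character())
}

sugar_acceptors <- c("O2'", "O3'", "O4'", "O5'")
phosphate_acceptors <- c("OP1", "OP2")  # charged: salt-bridge class

base_n1_name <- function(base) {
  # anchor atom used to project cluster membership onto a nucleotide
  "N1"
}

normalize_resname <- function(resname) {
  rn <- toupper(trimws(resname))
  rn <- sub("^R?([ACGU])[35N]?$", "\\1", rn)
  rn[rn == "ADE"] <- "A"; rn[rn == "GUA"] <- "G"
  rn[rn == "CYT"] <- "C"; rn[rn == "URA"] <- "U"; rn[rn == "URI"] <- "U"
  rn[rn %in% c("HOH", "WAT", "TIP3", "T3P", "SPC", "SOL")] <- "HOH"
  rn[rn %in% c("MG", "MG2")] <- "MG"
  rn
}

atom_category <- function(resname_norm) {
  dplyr::case_when(
    resname_norm %in% c("A", "C", "G", "U") ~ "RNA",
    resname_norm == "MG" ~ "MG",
    resname_norm == "HOH" ~ "WATER",
    TRUE ~ "OTHER")
}

guess_element <- function(name, resname_norm) {
  el <- ifelse(resname_norm == "MG", "MG",
               toupper(substr(trimws(name), 1, 1)))
  el[el %in% c("1", "2", "3", "4", "5")] <-
    toupper(substr(sub("^[0-9]+", "", trimws(name[el %in% c("1","2","3","4","5")])), 1, 1))
  el
}
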