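# shared fixtures, all generated in code

# minimal PDB records for hand-built structures
pdb_line <- function(serial, name, resname, resid, x, y, z, het = FALSE) {
  sprintf("%-6s%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (het) "HETATM" else "ATOM", serial,
          ifelse(nchar(name) < 4, paste0(" ", name), name),
          resname, resid, x, y, z, 1, 0, substr(trimws(name), 1, 1))
}

one_nt_pdb <- function() {
  c(pdb_line(1, "P", "G", 15, 0, 0, 0),
    pdb_line(2, "O5'", "G", 15, 1.4, 0.5, 0),
    pdb_line(3, "C5'", "G", 15, 2.5, 1.2, 0.3),
    pdb_line(4, "N1", "G", 15, 5, 3, 1),
    "END")
}

mg_water_pdb <- function() {
  lines <- c(pdb_line(1, "MG", "MG", 101, 0, 0, 0, het = TRUE))
  oct <- rbind(c(2.07, 0, 0), c(-2.07, 0, 0), c(0, 2.07, 0),
               c(0, -2.07, 0), c(0, 0, 2.07), c(0, 0, -2.07))
  for (k in 1:6) {
    lines <- c(lines, pdb_line(1 + k, "O", "HOH", 200 + k,
                               oct[k, 1], oct[k, 2], oct[k, 3], het = TRUE))
  }
  c(lines, "END")
}

three_nt_pdb <- function() {
  lines <- character()
  s <- 0
  for (r in 1:3) {
    base <- c("G", "C", "A")[r]
    lines <- c(lines,
      pdb_line(s + 1, "P", base, r, 6 * r, 0, 0),
      pdb_line(s + 2, "O5'", base, r, 6 * r + 1, 0.5, 0),
      pdb_line(s + 3, "C5'", base, r, 6 * r + 2, 1.2, 0),
      pdb_line(s + 4, "C4'", base, r, 6 * r + 3, 1.8, 0),
      pdb_line(s + 5, "C3'", base, r, 6 * r + 4, 1.2, 0),
      pdb_line(s + 6, "O3'", base, r, 6 * r + 5, 0.5, 0))
    s <- s + 6
  }
  c(lines, "END")
}

# a structure with one full guanine base plus a lone acceptor atom placed
# at a controlled position relative to the G:N1 hydrogen direction
g_plus_acceptor <- function(dist, angle_dev_deg = 0) {
  tm <- riborigid:::base_template_2d("G")
  n1 <- tm["N1", ]
  ctr <- riborigid:::base_ring_center_2d(tm)
  hdir <- riborigid:::h_candidates_2d(tm, "N1")[1, ]
  th <- angle_dev_deg * pi / 180
  rot <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  dirv <- as.numeric(rot %*% hdir)
  apos <- n1 + dist * dirv
  tab <- tibble::tibble(
    serial = seq_len(nrow(tm) + 1),
    name = c(rownames(tm), "O4"),
    resid = c(rep(1L, nrow(tm)), 2L),
    resname = c(rep("G", nrow(tm)), "U"),
    chain = "A",
    x = c(tm[, 1], apos[1]), y = c(tm[, 2], apos[2]), z = 0)
  riborigid:::build_structure_from_table(tab)
}

# coarse 5-body topology matching simulate_condition_ensembles()
coarse_topology <- function() {
  tab <- tibble::tibble(serial = 1:5, name = "N1", resid = 1:5,
                        resname = "G", chain = "A",
                        x = 3 * (1:5), y = 0, z = 0)
  topo <- riborigid:::build_structure_from_table(tab)
  topo$bonds <- tibble::tibble(i = 1:4, j = 2:5, locked = FALSE)
  topo
}

core_net <- function(focal_mult) {
  riborigid::new_constraint_network(
    5,
    tibble::tibble(i = c(1:3, 4L), j = c(2:4, 5L),
                   mult = c(6L, 6L, 6L, as.integer(focal_mult)),
                   type = "COVALENT_LOCKED", energy = NA_real_),
    body_atoms = 1:5)
}

withr_tempfile <- function() tempfile(fileext = ".pdb")

# coordinates keyed by (resid, atom name), order-independent
coords_by_key <- function(st) {
  k <- paste(st$atoms$resid, st$atoms$name)
  m <- as.matrix(st$atoms[, c("x", "y", "z")])
  rownames(m) <- k
  m[order(k), , drop = FALSE]
}

# cached toy aptamer (construction involves placement optimizations)
toy_cache <- new.env()
get_toy <- function(mutant = FALSE) {
  key <- if (mutant) "mut" else "wt"
  if (is.null(toy_cache[[key]])) toy_cache[[key]] <- make_toy_aptamer(mutant)
  toy_cache[[key]]
}
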