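#' Mayo-style hydrogen-bond energy
#'
#' Distance term: a 12-10 potential with well depth `v0` at the optimal
#' donor--acceptor separation `r0` (clamped at the optimum, so shorter
#' contacts are never penalized); angular term: `cos^4` of the deviation
#' from donor-H-acceptor linearity. Salt bridges receive a fixed strong
#' energy so they survive any cutoff.
#'
#' @param distance_da Donor--acceptor distance (A).
#' @param angle_dha Donor-hydrogen-acceptor angle (degrees).
#' @param salt_bridge Logical; fixed-energy salt-bridge class.
#' @param v0 Well depth (kcal/mol), default 8.
#' @param r0 Optimal donor--acceptor distance (A), default 2.8.
#' @param salt_energy Energy assigned to salt bridges (kcal/mol).
#' @return Energy in kcal/mol (negative = favorable), in `[-v0, 0]` for
#'   ordinary hydrogen bonds.
#' @export
hbond_energy <- function(distance_da, angle_dha, salt_bridge = FALSE,
                         v0 = 8, r0 = 2.8, salt_energy = -10) {
  u <- r0 / pmax(distance_da, r0)
  radial <- v0 * (5 * u^12 - 6 * u^10)
  dev <- pmax(0, 180 - angle_dha) * pi / 180
  angular <- ifelse(dev >= pi / 2, 0, cos(dev)^4)
  e <- radial * angular
  ifelse(rep_len(salt_bridge, length(e)), salt_energy, e)
}

# donor table: heavy atoms that carry polar hydrogens (row, n_h, kind)
donor_atoms <- function(structure) {
  a <- structure$atoms
  rows <- integer(); nh <- integer(); kind <- character()
  for (k in which(a$category == "RNA" & a$element != "H")) {
    dn <- base_donors(a$resname[k])
    if (a$name[k] %in% names(dn)) {
      rows <- c(rows, k); nh <- c(nh, dn[[a$name[k]]]); kind <- c(kind, "base")
    } else if (a$name[k] %in% names(sugar_donors)) {
      rows <- c(rows, k); nh <- c(nh, sugar_donors[[a$name[k]]])
      kind <- c(kind, "hydroxyl")
    }
  }
  wat <- which(a$category == "WATER" & a$element == "O")
  if (length(wat) > 0) {
    rows <- c(rows, wat); nh <- c(nh, rep(2L, length(wat)))
    kind <- c(kind, rep("water", length(wat)))
  }
  tibble(row = rows, n_h = nh, kind = kind)
}

acceptor_atoms <- function(structure) {
  a <- structure$atoms
  rows <- integer(); salt <- logical()
  for (k in which(a$category == "RNA" & a$element != "H")) {
    acc <- c(base_acceptors(a$resname[k]), sugar_acceptors,
             phosphate_acceptors)
    if (a$name[k] %in% acc) {
      rows <- c(rows, k)
      salt <- c(salt, a$name[k] %in% phosphate_acceptors)
    }
  }
  wat <- which(a$category == "WATER" & a$element == "O")
  rows <- c(rows, wat); salt <- c(salt, rep(FALSE, length(wat)))
  tibble(row = rows, charged = salt)
}

# covalent adjacency (heavy atoms) and the set of 1-2/1-3 excluded pairs
bonded_exclusions <- function(structure) {
  b <- structure$bonds
  a <- structure$atoms
  heavy <- b[a$element[b$i] != "H" & a$element[b$j] != "H", ]
  adj <- split(c(heavy$j, heavy$i), c(heavy$i, heavy$j))
  key12 <- paste(pmin(heavy$i, heavy$j), pmax(heavy$i, heavy$j))
  key13 <- character()
  for (mid in names(adj)) {
    nb <- adj[[mid]]
    if (length(nb) > 1) {
      pr <- utils::combn(sort(nb), 2)
      key13 <- c(key13, paste(pr[1, ], pr[2, ]))
    }
  }
  unique(c(key12, key13))
}

# idealized hydrogen placement on a donor; returns a matrix of H positions
place_donor_hydrogens <- function(structure, row, kind, n_h,
                                  toward = NULL) {
  a <- structure$atoms
  d <- c(a$x[row], a$y[row], a$z[row])
  b <- structure$bonds
  nb <- c(b$j[b$i == row], b$i[b$j == row])
  nb <- nb[a$element[nb] != "H"]
  unitv <- function(v) v / sqrt(sum(v^2))
  coord <- function(k) c(a$x[k], a$y[k], a$z[k])
  blen <- if (a$element[row] == "O") 0.96 else 1.01
  if (kind == "water") {
    # shell waters tumble freely: orient the hydrogen toward the
    # candidate acceptor (optimal torsion)
    if (is.null(toward)) return(NULL)
    v <- unitv(toward - d)
    return(matrix(d + blen * v, nrow = 1))
  }
  if (kind == "hydroxyl") {
    # fixed placement: tetrahedral angle at the oxygen, torsion anti to
    # the carbon's reference neighbor (for O2', anti to C1')
    if (length(nb) == 0) return(NULL)
    cpos <- coord(nb[1])
    u <- unitv(d - cpos)
    nb2 <- c(b$j[b$i == nb[1]], b$i[b$j == nb[1]])
    nb2 <- setdiff(nb2[a$element[nb2] != "H"], row)
    ref <- if (length(nb2) > 0) {
      pref <- nb2[a$name[nb2] == "C1'"]
      coord(if (length(pref) > 0) pref[1] else nb2[1])
    } else cpos + c(1, 0, 0)
    nrm <- cross3(u, unitv(ref - cpos))
    if (sqrt(sum(nrm^2)) < 1e-6) nrm <- cross3(u, c(0, 0, 1))
    m <- unitv(cross3(unitv(nrm), u))
    if (sum(m * unitv(ref - cpos)) > 0) m <- -m  # anti to the reference
    return(matrix(d + blen * (0.334 * u + 0.94 * m), nrow = 1))
  }
  if (length(nb) >= 2) {
    v <- -unitv(unitv(coord(nb[1]) - d) + unitv(coord(nb[2]) - d))
    return(matrix(d + blen * v, nrow = 1))
  }
  if (length(nb) == 1) {
    # planar amino group: two hydrogens at 120 degrees from the C-N bond,
    # in the plane defined by the neighbor's own bonds
    cpos <- coord(nb[1])
    v <- unitv(d - cpos)
    nb2 <- c(b$j[b$i == nb[1]], b$i[b$j == nb[1]])
    nb2 <- setdiff(nb2[a$element[nb2] != "H"], row)
    if (length(nb2) >= 1) {
      w <- unitv(coord(nb2[1]) - cpos)
      nrm <- cross3(v, w)
      if (sqrt(sum(nrm^2)) < 1e-6) nrm <- cross3(v, c(1, 0, 0))
    } else {
      nrm <- cross3(v, c(0, 0, 1))
      if (sqrt(sum(nrm^2)) < 1e-6) nrm <- cross3(v, c(1, 0, 0))
    }
    u <- unitv(cross3(unitv(nrm), v))
    h1 <- d + blen * (cos(pi / 3) * v + sin(pi / 3) * u)
    h2 <- d + blen * (cos(pi / 3) * v - sin(pi / 3) * u)
    return(rbind(h1, h2)[seq_len(n_h), , drop = FALSE])
  }
  NULL
}

#' Detect hydrogen bonds by geometric criteria
#'
#' Scans donor/acceptor pairs; a bond requires donor--acceptor distance at
#' most `d_max` and donor-H-acceptor angle at least `angle_min`. Donor
#' hydrogens are taken from the structure if present, otherwise placed by
#' ideal geometry (ring/amino donors) or oriented toward the acceptor
#' (hydroxyl and water donors, which are torsionally free); 1-2 and 1-3
#' covalently connected pairs are excluded. Each bond carries a
#' [hbond_energy()] value. The result is sorted by (donor, acceptor).
#'
#' @param structure An `rna_structure`.
#' @param d_max Maximum donor--acceptor distance (A), default 3.5.
#' @param angle_min Minimum donor-H-acceptor angle (degrees), default 120.
#' @param charged_donors Optional atom-name set treated as charged donors;
#'   pairs of a charged donor with a charged (phosphate) acceptor are
#'   tagged salt bridges.
#' @return Tibble: donor, acceptor (atom rows), donor_name, acceptor_name,
#'   donor_resid, acceptor_resid, distance_da, angle_dha, salt_bridge,
#'   energy.
#' @export
detect_hbonds <- function(structure, d_max = 3.5, angle_min = 120,
                          charged_donors = character()) {
  a <- structure$atoms
  don <- donor_atoms(structure)
  acc <- acceptor_atoms(structure)
  if (nrow(don) == 0 || nrow(acc) == 0) return(empty_hbond_table())
  excl <- bonded_exclusions(structure)
  dm <- as.matrix(don[, "row"]); am <- as.matrix(acc[, "row"])
  dx <- a$x[don$row]; dy <- a$y[don$row]; dz <- a$z[don$row]
  ax <- a$x[acc$row]; ay <- a$y[acc$row]; az <- a$z[acc$row]
  out <- list()
  for (k in seq_len(nrow(don))) {
    dr <- don$row[k]
    dist2 <- (ax - dx[k])^2 + (ay - dy[k])^2 + (az - dz[k])^2
    # intra-residue pairs are excluded: at this resolution they reflect
    # sugar geometry, not interactions that should constrain the network
    cand <- which(dist2 <= d_max^2 & acc$row != dr &
                    !(a$resid[acc$row] == a$resid[dr] &
                        a$chain[acc$row] == a$chain[dr]))
    if (length(cand) == 0) next
    keyk <- paste(pmin(dr, acc$row[cand]), pmax(dr, acc$row[cand]))
    cand <- cand[!(keyk %in% excl)]
    for (ci in cand) {
      ar <- acc$row[ci]
      apos <- c(a$x[ar], a$y[ar], a$z[ar])
      hpos <- attached_hydrogens(structure, dr)
      if (is.null(hpos)) {
        hpos <- place_donor_hydrogens(structure, dr, don$kind[k], don$n_h[k],
                                      toward = apos)
      }
      if (is.null(hpos)) next
      dpos <- c(a$x[dr], a$y[dr], a$z[dr])
      angs <- apply(hpos, 1, function(h) angle_deg(dpos, h, apos))
      ang <- max(angs)
      if (ang < angle_min) next
      dist <- sqrt(sum((apos - dpos)^2))
      salt <- (a$name[dr] %in% charged_donors) && acc$charged[ci]
      out[[length(out) + 1]] <- tibble(
        donor = dr, acceptor = ar,
        donor_name = a$name[dr], acceptor_name = a$name[ar],
        donor_resid = a$resid[dr], acceptor_resid = a$resid[ar],
        distance_da = dist, angle_dha = ang, salt_bridge = salt,
        energy = hbond_energy(dist, ang, salt))
    }
  }
  if (length(out) == 0) return(empty_hbond_table())
  bind_rows(out) %>% arrange(.data$donor, .data$acceptor)
}

empty_hbond_table <- function() {
  tibble(donor = integer(), acceptor = integer(),
         donor_name = character(), acceptor_name = character(),
         donor_resid = integer(), acceptor_resid = integer(),
         distance_da = numeric(), angle_dha = numeric(),
         salt_bridge = logical(), energy = numeric())
}

# hydrogens covalently attached to a heavy atom, or NULL
attached_hydrogens <- function(structure, row) {
  a <- structure$atoms
  b <- structure$bonds
  hs <- c(b$j[b$i == row], b$i[b$j == row])
  hs <- hs[a$element[hs] == "H"]
  if (length(hs) == 0) return(NULL)
  as.matrix(a[hs, c("x", "y", "z")])
}

angle_deg <- function(p1, p2, p3) {
  v1 <- p1 - p2; v2 <- p3 - p2
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Detect hydrophobic tethers
#'
#' Pairs of carbon/sulfur atoms whose inter-surface separation (distance
#' minus summed van-der-Waals radii) is at most `gap_max`; 1-2 and 1-3
#' covalently connected pairs are excluded. Ordering is deterministic.
#'
#' @param structure An `rna_structure`.
#' @param gap_max Maximum surface gap (A), default 0.25.
#' @return Tibble: i, j (atom rows), distance, gap.
#' @export
detect_hydrophobics <- function(structure, gap_max = 0.25) {
  a <- structure$atoms
  idx <- which(a$element %in% c("C", "S") & a$category == "RNA")
  if (length(idx) < 2) {
    return(tibble(i = integer(), j = integer(),
                  distance = numeric(), gap = numeric()))
  }
  excl <- bonded_exclusions(structure)
  xyz <- as.matrix(a[idx, c("x", "y", "z")])
  rad <- unname(vdw_radii[a$element[idx]])
  cut <- max(rad) * 2 + gap_max
  d <- as.matrix(stats::dist(xyz))
  pr <- which(upper.tri(d) & d <= cut, arr.ind = TRUE)
  if (nrow(pr) == 0) {
    return(tibble(i = integer(), j = integer(),
                  distance = numeric(), gap = numeric()))
  }
  i <- idx[pr[, 1]]; j <- idx[pr[, 2]]
  dist <- d[pr]
  gap <- dist - rad[pr[, 1]] - rad[pr[, 2]]
  keep <- gap <= gap_max & !(paste(pmin(i, j), pmax(i, j)) %in% excl) &
    !(a$resid[i] == a$resid[j] & a$chain[i] == a$chain[j])
  lo <- pmin(i, j)[keep]; hi <- pmax(i, j)[keep]
  out <- tibble(i = lo, j = hi, distance = dist[keep], gap = gap[keep])
  # one tether per residue pair (the closest contact): a denser tether
  # set would overconstrain packed structures far beyond what a stacking
  # interaction contributes
  out %>%
    mutate(rpair = paste(pmin(a$resid[.data$i], a$resid[.data$j]),
                         pmax(a$resid[.data$i], a$resid[.data$j]))) %>%
    group_by(.data$rpair) %>%
    slice_min(.data$distance, n = 1, with_ties = FALSE) %>%
    ungroup() %>%
    select(-"rpair") %>%
    arrange(.data$i, .data$j)
}
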