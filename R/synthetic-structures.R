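# Synthetic toy aptamer: a miniature three-way junction with two loop
# base quadruples, a binding triplet, and a terminal helix. All geometry
# is idealized (planar bases built from regular polygons, a fixed local
# sugar/backbone offset template) but designed so that hydrogen-bond
# detection, network construction, and the pebble game behave like they
# do on real structures. Everything here is labelled synthetic: no
# coordinates derive from any deposited structure.

# ---- planar base templates -------------------------------------------------

# 2D coordinates (u = toward the pairing edge, v = in-plane perpendicular)
base_template_2d <- function(base) {
  side <- 1.39
  hex_names <- c("N1", "C2", "N3", "C4", "C5", "C6")
  # hexagon with N1 toward +u so the pairing edge faces +u
  ang <- (seq(0, 300, by = 60) - 0) * pi / 180
  hexv <- cbind(u = side * cos(ang), v = side * sin(ang))
  rownames(hexv) <- hex_names
  rot2 <- function(p, th) {
    out <- cbind(u = p[, 1] * cos(th) - p[, 2] * sin(th),
                 v = p[, 1] * sin(th) + p[, 2] * cos(th))
    rownames(out) <- rownames(p)
    out
  }
  exo <- function(at, len) {
    p <- hexv[at, ]
    p + len * p / sqrt(sum(p^2))
  }
  if (base %in% c("C", "U")) {
    pts <- rbind(
      hexv,
      O2 = exo("C2", 1.23),
      if (base == "C") rbind(N4 = exo("C4", 1.34)) else
        rbind(O4 = exo("C4", 1.23)),
      "C1'" = exo("N1", 1.47))
    pts <- rot2(pts, pi)  # N3/C4 edge (the pairing edge) toward +u
    return(pts)
  }
  # purine: fuse a regular pentagon on the C4-C5 edge; ring order
  # C4 -> N9 -> C8 -> N7 -> C5
  a4 <- hexv["C4", ]; a5 <- hexv["C5", ]
  mid <- (a4 + a5) / 2
  outward <- mid / sqrt(sum(mid^2))
  apo <- side / (2 * tan(pi / 5))
  ctr <- mid + apo * outward
  rot_about <- function(p, c0, th) {
    d <- p - c0
    c0 + c(d[1] * cos(th) - d[2] * sin(th), d[1] * sin(th) + d[2] * cos(th))
  }
  th <- 2 * pi / 5
  # choose the rotation sign that carries C4 to C5 in four steps
  s1 <- rot_about(a4, ctr, 4 * th); s2 <- rot_about(a4, ctr, -4 * th)
  sgn <- if (sum((s1 - a5)^2) < sum((s2 - a5)^2)) 1 else -1
  n9 <- rot_about(a4, ctr, sgn * th)
  c8 <- rot_about(a4, ctr, sgn * 2 * th)
  n7 <- rot_about(a4, ctr, sgn * 3 * th)
  pent <- rbind(N9 = n9, C8 = c8, N7 = n7)
  glyc <- n9 + 1.47 * (n9 - ctr) / sqrt(sum((n9 - ctr)^2))
  pts <- rbind(
    hexv, pent,
    if (base == "A") rbind(N6 = exo("C6", 1.34)) else
      rbind(O6 = exo("C6", 1.23), N2 = exo("C2", 1.34)),
    "C1'" = glyc)
  colnames(pts) <- c("u", "v")
  # orient so the N1/C6 (Watson-Crick) edge faces +u
  edge <- (pts["N1", ] + pts["C6", ]) / 2
  th0 <- atan2(edge[2], edge[1])
  rot2(pts, -th0)
}

base_ring_center_2d <- function(pts) {
  ring <- intersect(rownames(pts), c("N1", "C2", "N3", "C4", "C5", "C6"))
  colMeans(pts[ring, , drop = FALSE])
}

# weighted 2D Procrustes fit of template points onto targets, reflection
# allowed (a flipped-over base is a 2D mirror image)
fit_points_2d <- function(src, dst, w = NULL, allow_reflection = TRUE) {
  if (is.null(w)) w <- rep(1, nrow(src))
  w <- w / sum(w)
  cs <- colSums(src * w); cd <- colSums(dst * w)
  sc <- sweep(src, 2, cs); dc <- sweep(dst, 2, cd)
  best <- NULL
  for (refl in if (allow_reflection) c(1, -1) else 1) {
    s2 <- sc; s2[, 2] <- refl * s2[, 2]
    h <- t(s2 * w) %*% dc
    sv <- svd(h)
    d <- sign(det(sv$v %*% t(sv$u)))
    r <- sv$u %*% diag(c(1, d)) %*% t(sv$v)
    fitted <- s2 %*% r
    rss <- sum(w * rowSums((fitted - dc)^2))
    if (is.null(best) || rss < best$rss) {
      best <- list(rss = rss, refl = refl, rot = r, cs = cs, cd = cd)
    }
  }
  best
}

apply_fit_2d <- function(pts, fit) {
  p <- sweep(pts, 2, fit$cs)
  p[, 2] <- fit$refl * p[, 2]
  sweep(p %*% fit$rot, 2, fit$cd, `+`)
}

outward_2d <- function(pts, atom) {
  ctr <- base_ring_center_2d(pts)
  v <- pts[atom, ] - ctr
  v / sqrt(sum(v^2))
}

# candidate in-plane hydrogen directions of a donor atom: ring N-H points
# along the bisector away from its two ring neighbors; an amino group has
# two hydrogens at +/- 60 degrees from the C-N bond extension
h_candidates_2d <- function(pts, atom) {
  nbr <- list(N1 = c("C2", "C6"), N3 = c("C2", "C4"),
              N6 = "C6", N4 = "C4", N2 = "C2", "O2'" = character())
  nb <- intersect(nbr[[atom]], rownames(pts))
  unitv <- function(v) v / sqrt(sum(v^2))
  if (length(nb) == 2) {
    d <- -unitv(unitv(pts[nb[1], ] - pts[atom, ]) +
                  unitv(pts[nb[2], ] - pts[atom, ]))
    return(rbind(d))
  }
  ext <- unitv(pts[atom, ] - pts[nb[1], ])
  rot <- function(v, th) c(v[1] * cos(th) - v[2] * sin(th),
                           v[1] * sin(th) + v[2] * cos(th))
  rbind(rot(ext, pi / 3), rot(ext, -pi / 3))
}

# Direction along which the partner atom of a designed bond is placed:
# for a donor on the placed base, the hydrogen direction best aligned
# with `hint`; for an acceptor on the placed base, its outward (lone
# pair proxy) direction blended toward the hint.
bond_dir_2d <- function(pts, atom, role, hint) {
  unitv <- function(v) v / sqrt(sum(v^2))
  hint <- unitv(hint)
  if (role == "donor") {
    cand <- h_candidates_2d(pts, atom)
    return(cand[which.max(cand %*% hint), ])
  }
  unitv(outward_2d(pts, atom) + hint)
}

# place a base template onto absolute 2D targets:
# spec is a tibble with atom_b (template atom or "center"), target
# (list of 2-vectors) and w (weights)
place_on_targets_2d <- function(tmpl_b, spec) {
  src <- t(vapply(spec$atom_b, function(at) {
    if (at == "center") base_ring_center_2d(tmpl_b) else tmpl_b[at, ]
  }, numeric(2)))
  targets <- do.call(rbind, spec$target)
  fit <- fit_points_2d(src, targets, w = spec$w)
  apply_fit_2d(tmpl_b, fit)
}

# Watson-Crick designed bonds (donor atom listed on its own base)
wc_bonds <- function(baseA, baseB) {
  key <- paste0(baseA, baseB)
  switch(key,
    GC = tibble(don_base = c("B", "A", "A"), don = c("N4", "N1", "N2"),
                acc = c("O6", "N3", "O2")),
    CG = tibble(don_base = c("A", "B", "B"), don = c("N4", "N1", "N2"),
                acc = c("O6", "N3", "O2")),
    AU = tibble(don_base = c("B", "A"), don = c("N3", "N6"),
                acc = c("N1", "O4")),
    UA = tibble(don_base = c("A", "B"), don = c("N3", "N6"),
                acc = c("N1", "O4")),
    abort(paste("no Watson-Crick template for", key)))
}

# flat-bottom penalty helpers for the placement objectives
pen_range <- function(x, lo, hi) (pmax(0, lo - x) + pmax(0, x - hi))^2

# objective terms for a set of designed bonds between a movable base
# layout and fixed partner layouts
bond_terms_2d <- function(pts_b, bonds) {
  # bonds: tibble(fixed (list of pts), atom_f, atom_b, donor_side)
  unitv <- function(v) v / sqrt(sum(v^2))
  s <- 0
  for (k in seq_len(nrow(bonds))) {
    pf <- bonds$fixed[[k]]
    fa <- pf[bonds$atom_f[k], ]
    ba <- pts_b[bonds$atom_b[k], ]
    d <- sqrt(sum((ba - fa)^2))
    s <- s + 2 * pen_range(d, 2.75, 3.05)
    if (d < 1e-6) next
    if (bonds$donor_side[k] == "fixed") {
      cand <- h_candidates_2d(pf, bonds$atom_f[k])
      axis <- unitv(ba - fa)
    } else {
      cand <- h_candidates_2d(pts_b, bonds$atom_b[k])
      axis <- unitv(fa - ba)
    }
    s <- s + 8 * pen_range(max(cand %*% axis), cos(25 * pi / 180), 1)
  }
  s
}

clash_term_2d <- function(pts_b, fixed_list, cutoff = 2.45) {
  s <- 0
  for (pf in fixed_list) {
    dd <- sqrt(outer(pts_b[, 1], pf[, 1], "-")^2 +
                 outer(pts_b[, 2], pf[, 2], "-")^2)
    s <- s + sum(pen_range(dd[dd < cutoff], cutoff, Inf))
  }
  s
}

move_pts_2d <- function(pts, par, refl) {
  p <- pts
  if (refl < 0) p[, 2] <- -p[, 2]
  rotm <- rbind(c(cos(par[1]), sin(par[1])),
                c(-sin(par[1]), cos(par[1])))
  out <- p %*% rotm
  out[, 1] <- out[, 1] + par[2]; out[, 2] <- out[, 2] + par[3]
  colnames(out) <- c("u", "v")
  rownames(out) <- rownames(pts)
  out
}

# place a movable base against fixed partners so all designed bonds reach
# bonding distance with workable donor-hydrogen alignment and no clashes;
# coarse grid over rotation/translation/reflection refined by Nelder-Mead
place_base_opt_2d <- function(tmpl_b, bonds, fixed_list, guess,
                              span = 3, theta_step = 15, orient = NULL) {
  score <- function(par, refl, with_clash = TRUE) {
    pb <- move_pts_2d(tmpl_b, par, refl)
    s <- bond_terms_2d(pb, bonds)
    if (!is.null(orient)) {
      s <- s + 2 * pen_range(sum(outward_2d(pb, orient$atom) * orient$dir),
                             cos(30 * pi / 180), 1)
    }
    if (with_clash) s <- s + clash_term_2d(pb, fixed_list)
    s
  }
  best <- NULL
  for (refl in c(1, -1)) {
    for (th in seq(0, 359, by = theta_step) * pi / 180) {
      for (dx in seq(-span, span, by = 1)) {
        for (dy in seq(-span, span, by = 1)) {
          par <- c(th, guess[1] + dx, guess[2] + dy)
          sc <- score(par, refl, with_clash = FALSE)
          if (is.null(best) || sc < best$sc) best <- list(par = par,
                                                          refl = refl, sc = sc)
        }
      }
    }
  }
  opt <- stats::optim(best$par, score, refl = best$refl,
                      method = "Nelder-Mead", control = list(maxit = 800))
  opt <- stats::optim(opt$par, score, refl = best$refl,
                      method = "Nelder-Mead", control = list(maxit = 800))
  move_pts_2d(tmpl_b, opt$par, best$refl)
}

# cache: pair layouts are deterministic and reused across helices
.pair_cache <- new.env(parent = emptyenv())

# 2D layout of a Watson-Crick pair: base A at the template position,
# base B placed by the bond/alignment/clash objective
wc_pair_2d <- function(baseA, baseB, d_hb = 2.9) {
  key <- paste0(baseA, baseB)
  if (!is.null(.pair_cache[[key]])) return(.pair_cache[[key]])
  ta <- base_template_2d(baseA)
  tb <- base_template_2d(baseB)
  bonds <- wc_bonds(baseA, baseB)
  spec <- tibble(
    fixed = rep(list(ta), nrow(bonds)),
    atom_f = ifelse(bonds$don_base == "B", bonds$acc, bonds$don),
    atom_b = ifelse(bonds$don_base == "B", bonds$don, bonds$acc),
    donor_side = ifelse(bonds$don_base == "A", "fixed", "movable"))
  guess <- c(8, 0)
  pb <- place_base_opt_2d(tb, spec, list(ta), guess, span = 3)
  out <- list(A = ta, B = pb)
  .pair_cache[[key]] <- out
  out
}

# rigid 2D transform of a set of base layouts
transform_block_2d <- function(blk, theta, tx, ty) {
  rotm <- rbind(c(cos(theta), sin(theta)), c(-sin(theta), cos(theta)))
  lapply(blk, function(p) {
    out <- p %*% rotm
    out[, 1] <- out[, 1] + tx; out[, 2] <- out[, 2] + ty
    colnames(out) <- c("u", "v")
    rownames(out) <- rownames(p)
    out
  })
}

# position a top block over a bottom block so the designed bridging bonds
# close at d_hb, donors keep a workable hydrogen direction, and the
# blocks do not clash; coarse grid search refined by Nelder-Mead
# Place a rigid block of bases by anchoring one bridge bond exactly (the
# anchor atom is pinned d_hb along `anchor_dir` from the fixed partner
# atom) and scanning the one remaining rotation about the anchor point;
# the scan score covers any second bridge, donor alignments, and clashes.
place_block_anchored_2d <- function(top, anchor_base, anchor_atom,
                                    anchor_point, bottom, bridges,
                                    d_hb = 2.9) {
  unitv <- function(v) v / sqrt(sum(v^2))
  posed <- function(phi) {
    rotm <- rbind(c(cos(phi), sin(phi)), c(-sin(phi), cos(phi)))
    ref <- top[[anchor_base]][anchor_atom, ]
    lapply(top, function(p) {
      out <- sweep(p, 2, ref) %*% rotm
      out[, 1] <- out[, 1] + anchor_point[1]
      out[, 2] <- out[, 2] + anchor_point[2]
      colnames(out) <- c("u", "v")
      rownames(out) <- rownames(p)
      out
    })
  }
  score <- function(phi) {
    tb <- posed(phi)
    s <- 0
    for (k in seq_len(nrow(bridges))) {
      pbot <- bottom[[bridges$bottom_base[k]]]
      ptop <- tb[[bridges$top_base[k]]]
      b_at <- pbot[bridges$bottom_atom[k], ]
      t_at <- ptop[bridges$top_atom[k], ]
      d <- sqrt(sum((t_at - b_at)^2))
      if (!(bridges$top_base[k] == anchor_base &&
              bridges$top_atom[k] == anchor_atom)) {
        s <- s + 3 * pen_range(d, 2.7, 3.35)
      }
      if (d < 1e-6) next
      if (bridges$donor_side[k] == "bottom") {
        cand <- h_candidates_2d(pbot, bridges$bottom_atom[k])
        axis <- unitv(t_at - b_at)
      } else {
        cand <- h_candidates_2d(ptop, bridges$top_atom[k])
        axis <- unitv(b_at - t_at)
      }
      s <- s + 4 * pen_range(max(cand %*% axis), cos(38 * pi / 180), 1)
    }
    for (bt in names(tb)) s <- s + clash_term_2d(tb[[bt]], bottom)
    s
  }
  phis <- seq(0, 359, by = 2) * pi / 180
  sc <- vapply(phis, score, 1)
  best <- phis[which.min(sc)]
  fine <- seq(best - 3 * pi / 180, best + 3 * pi / 180, length.out = 31)
  posed(fine[which.min(vapply(fine, score, 1))])
}

optimize_block_2d <- function(top, bottom, bridges, guess, d_hb = 2.9) {
  unitv <- function(v) v / sqrt(sum(v^2))
  score <- function(par, with_clash = TRUE) {
    tb <- transform_block_2d(top, par[1], par[2], par[3])
    s <- 0
    for (k in seq_len(nrow(bridges))) {
      pbot <- bottom[[bridges$bottom_base[k]]]
      ptop <- tb[[bridges$top_base[k]]]
      b_at <- pbot[bridges$bottom_atom[k], ]
      t_at <- ptop[bridges$top_atom[k], ]
      d <- sqrt(sum((t_at - b_at)^2))
      s <- s + pen_range(d, 2.75, 3.2)
      if (d < 1e-6) next
      if (bridges$donor_side[k] == "bottom") {
        cand <- h_candidates_2d(pbot, bridges$bottom_atom[k])
        axis <- unitv(t_at - b_at)
      } else {
        cand <- h_candidates_2d(ptop, bridges$top_atom[k])
        axis <- unitv(b_at - t_at)
      }
      s <- s + 4 * pen_range(max(cand %*% axis), cos(38 * pi / 180), 1)
    }
    if (with_clash) {
      for (bt in names(tb)) {
        s <- s + clash_term_2d(tb[[bt]], bottom)
      }
    }
    s
  }
  best <- NULL
  for (th in seq(-60, 60, by = 10) * pi / 180) {
    for (dx in seq(-3, 3, by = 1)) {
      for (dy in seq(-3, 3, by = 1)) {
        par <- c(th, guess[1] + dx, guess[2] + dy)
        sc <- score(par, with_clash = FALSE)
        if (is.null(best) || sc < best$sc) best <- list(par = par, sc = sc)
      }
    }
  }
  opt <- stats::optim(best$par, score, method = "Nelder-Mead",
                      control = list(maxit = 600))
  transform_block_2d(top, opt$par[1], opt$par[2], opt$par[3])
}

# ---- local sugar/backbone offsets ------------------------------------------

sugar_offsets <- function() {
  # idealized ribose + backbone offsets from C1' in the local (u, v, n)
  # basis (u toward the pairing edge, n the base normal); bond lengths
  # are chemically sensible, the pucker is schematic
  list(
    "O4'" = c(-0.6, 1.2, -0.5),
    "C4'" = c(-2.0, 1.0, 0.0),
    "C3'" = c(-2.2, -0.4, 0.7),
    "C2'" = c(-0.9, -1.2, 0.4),
    "O2'" = c(-0.9, -2.4, 1.2),
    "O3'" = c(-3.4, -1.0, 0.3),
    "C5'" = c(-2.4, 2.1, -1.0),
    "O5'" = c(-1.7, 3.3, -0.8),
    "P" = c(-2.2, 4.7, -1.2),
    "OP1" = c(-3.6, 4.8, -1.5),
    "OP2" = c(-1.4, 5.8, -0.5))
}

# embed a 2D base layout plus backbone into 3D given a frame; the sugar
# offsets follow the base's own in-plane orientation (recovered by
# fitting the pristine template onto the placed points)
embed_nucleotide <- function(pts2d, origin, ex, ey, base) {
  en <- cross3(ex, ey)
  pos3 <- t(apply(pts2d, 1, function(p) origin + p[1] * ex + p[2] * ey))
  c1p <- pos3["C1'", ]
  tmpl <- base_template_2d(base)
  fit <- fit_points_2d(tmpl[rownames(pts2d), , drop = FALSE], pts2d)
  dir2 <- function(v) { v[2] <- fit$refl * v[2]; as.numeric(v %*% fit$rot) }
  u2 <- dir2(c(1, 0)); v2 <- dir2(c(0, 1))
  loc <- function(du, dv) {
    (du * u2[1] + dv * v2[1]) * ex + (du * u2[2] + dv * v2[2]) * ey
  }
  off <- sugar_offsets()
  bb <- t(vapply(off, function(o) {
    c1p + loc(o[1], o[2]) + o[3] * en
  }, numeric(3)))
  rownames(bb) <- names(off)
  rbind(pos3, bb)
}

# ---- the toy aptamer -------------------------------------------------------

#' Synthetic toy aptamer structure (miniature three-way junction)
#'
#' Builds an idealized 67-nucleotide structure with author numbering
#' 15-81 that mirrors the architecture of the guanine-riboswitch aptamer
#' domain: helices P1 (7 bp), P2 (8 bp) and P3 (7 bp) around a three-way
#' junction, loops L2/L3 whose designed hydrogen-bond sets form an upper
#' (34/37/61/65) and lower (33/38/60/66) base quadruple, and a spatially
#' separated binding triplet (47, 51, 74). The `mutant` flag builds the
#' loop variant (A37/U61), whose designed bond set in the upper quadruple
#' is two bonds smaller. Coordinates are entirely synthetic and
#' deterministic.
#'
#' @param mutant Build the loop-mutant variant.
#' @param granularity `"full"` (all heavy atoms; hydrogen-bond detection
#'   works) or `"coarse"` (one N1 body per nucleotide; fast pebble-game
#'   demonstrations).
#' @return A list: `structure` (`rna_structure`), `regions`
#'   (`region_map`), `designed_hbonds` (tibble of the loop-quadruple
#'   design), `params`.
#' @export
make_toy_aptamer <- function(mutant = FALSE, granularity = c("full", "coarse")) {
  granularity <- match.arg(granularity)
  seqs <- toy_sequence(mutant)
  if (granularity == "coarse") {
    return(toy_coarse(seqs, mutant))
  }
  frames <- list()   # per-resid: list(pts2d, origin, ex, ey)
  put <- function(resid, pts2d, origin, ex, ey) {
    frames[[as.character(resid)]] <<- list(pts2d = pts2d, origin = origin,
                                           ex = ex, ey = ey)
  }
  rise <- 3.5; twist <- 32 * pi / 180
  ez <- c(0, 0, 1)
  helix <- function(res5, res3, axis_start, axis_dir, junction_first) {
    n_bp <- length(res5)
    for (k in seq_len(n_bp)) {
      i5 <- res5[k]; i3 <- res3[k]
      pr <- wc_pair_2d(seqs[[as.character(i5)]], seqs[[as.character(i3)]])
      h <- if (junction_first) k - 1 else n_bp - k
      th <- twist * h
      # in-plane basis perpendicular to the helix axis, twisted per step
      ref <- if (abs(axis_dir[3]) < 0.9) ez else c(1, 0, 0)
      e1 <- cross3(axis_dir, ref); e1 <- e1 / sqrt(sum(e1^2))
      e2 <- cross3(axis_dir, e1)
      ex <- cos(th) * e1 + sin(th) * e2
      ey <- -sin(th) * e1 + cos(th) * e2
      origin <- axis_start + (h * rise) * axis_dir
      ctrA <- base_ring_center_2d(pr$A); ctrB <- base_ring_center_2d(pr$B)
      mid <- (ctrA + ctrB) / 2
      put(i5, sweep(pr$A, 2, mid), origin, ex, ey)
      put(i3, sweep(pr$B, 2, mid), origin, ex, ey)
    }
  }
  # P1 down from the junction, P2/P3 up and parallel (loop-loop contact)
  helix(21:15, 75:81, c(0, -5, 0), c(0, -1, 0), junction_first = TRUE)
  helix(25:32, 46:39, c(-7, 5, 0), c(0, 1, 0), junction_first = TRUE)
  helix(53:59, 73:67, c(7, 5, 0), c(0, 1, 0), junction_first = TRUE)

  # loop quadruples on two stacked horizontal planes above the arm tops
  quad <- toy_quadruple_layouts(seqs, mutant)
  embed_quad <- function(layout, y0) {
    for (nm in names(layout)) {
      put(as.integer(nm), layout[[nm]], c(0, y0, 0), c(1, 0, 0), c(0, 0, 1))
    }
  }
  embed_quad(quad$upper, 38.0)
  embed_quad(quad$lower, 34.5)

  # unpaired nucleotides on arcs; bases face the junction center
  arc <- function(resids, from, to, lift = 0) {
    n <- length(resids)
    for (k in seq_len(n)) {
      t <- k / (n + 1)
      p <- (1 - t) * from + t * to
      p[3] <- p[3] + lift * sin(pi * t)
      # orient each base edge-on toward the junction center
      dirv <- c(0, 2, 0) - p
      dirv <- dirv / sqrt(sum(dirv^2))
      ref <- if (abs(dirv[3]) < 0.9) ez else c(1, 0, 0)
      ey2 <- cross3(dirv, ref); ey2 <- ey2 / sqrt(sum(ey2^2))
      tm <- base_template_2d(seqs[[as.character(resids[k])]])
      put(resids[k], sweep(tm, 2, base_ring_center_2d(tm)), p, dirv, ey2)
    }
  }
  arc(22:24, c(0, -4, -3), c(-7, 3, -3), lift = -2)        # J1/2, below
  arc(35:36, c(-8, 41, 0), c(-4, 41, 0), lift = 2.5)       # L2 cap
  arc(62:64, c(8, 41, 0), c(3, 41, 0), lift = 2.5)         # L3 cap
  # J2/3 (47-52) crosses above the junction; binding nucleotides 47, 51
  # and 74 sit around the junction with their pairing edges facing
  # outward, well separated so the empty site forms no mutual bonds
  arc(c(48:50, 52), c(-6, 3, 9), c(6, 4, 9), lift = 2)
  put_single <- function(resid, p, facing) {
    dirv <- facing / sqrt(sum(facing^2))
    ref <- if (abs(dirv[3]) < 0.9) ez else c(1, 0, 0)
    ey2 <- cross3(dirv, ref); ey2 <- ey2 / sqrt(sum(ey2^2))
    tm <- base_template_2d(seqs[[as.character(resid)]])
    put(resid, sweep(tm, 2, base_ring_center_2d(tm)), p, dirv, ey2)
  }
  put_single(47, c(-5.5, -1, 6), c(-1, 0, 0.2))
  put_single(51, c(5.5, 0, 6), c(1, 0, 0.2))
  put_single(74, c(0, -5.5, 6), c(0, -1, 0.2))

  # assemble the atom table in residue order
  rows <- list()
  serial <- 0L
  for (rs in 15:81) {
    fr <- frames[[as.character(rs)]]
    pos <- embed_nucleotide(fr$pts2d, fr$origin, fr$ex, fr$ey,
                            seqs[[as.character(rs)]])
    rows[[length(rows) + 1]] <- tibble(
      serial = serial + seq_len(nrow(pos)),
      name = rownames(pos),
      resid = rs,
      resname = seqs[[as.character(rs)]],
      chain = "A",
      x = pos[, 1], y = pos[, 2], z = pos[, 3])
    serial <- serial + nrow(pos)
  }
  st <- build_structure_from_table(bind_rows(rows))
  list(structure = st,
       regions = assign_regions(st),
       designed_hbonds = quad$designed,
       params = list(mutant = mutant, granularity = granularity,
                     rise = rise, twist_deg = 32, d_hb = 2.9))
}

toy_sequence <- function(mutant) {
  s <- character()
  s[as.character(15:21)] <- c("G", "C", "G", "A", "C", "U", "G")  # P1 5'
  s[as.character(75:81)] <- c("C", "A", "G", "U", "C", "G", "C")  # P1 3'
  s[as.character(22:24)] <- c("A", "U", "A")                      # J1/2
  s[as.character(25:32)] <- c("G", "C", "A", "G", "U", "C", "G", "A")
  s[as.character(39:46)] <- c("U", "C", "G", "A", "C", "U", "G", "C")
  s[as.character(33:38)] <- c("A", "U", "C", "A", if (mutant) "A" else "G", "G")
  s[as.character(60:66)] <- c("C", if (mutant) "U" else "C", "A", "G", "U",
                              "A", "A")
  s[as.character(47:52)] <- c("U", "G", "A", "C", "U", "A")       # J2/3
  s[as.character(53:59)] <- c("G", "C", "U", "A", "G", "C", "A")  # P3 5'
  s[as.character(67:73)] <- c("U", "G", "C", "U", "A", "G", "C")  # P3 3'
  s[as.character(74)] <- "C"                                      # J3/1
  s
}

# place a base by one designed bond plus an explicit orientation: the new
# base's bonded atom sits d_hb along `dirv` from the placed atom, its ring
# center continues along `dirv`, and `face_atom` is aimed toward
# `face_dir` (unit 2-vector) from the center
place_single_2d <- function(tmpl_new, atom_new, placed, atom_placed, dirv,
                            face_atom, face_dir, d_hb = 2.9) {
  unitv <- function(v) v / sqrt(sum(v^2))
  dirv <- unitv(dirv); face_dir <- unitv(face_dir)
  anchor <- placed[atom_placed, ] + d_hb * dirv
  ctr_off <- sqrt(sum((tmpl_new[atom_new, ] -
                         base_ring_center_2d(tmpl_new))^2))
  ctr_t <- anchor + ctr_off * dirv
  face_off <- sqrt(sum((tmpl_new[face_atom, ] -
                          base_ring_center_2d(tmpl_new))^2))
  spec <- tibble(
    atom_b = c(atom_new, "center", face_atom),
    target = list(anchor, ctr_t, ctr_t + face_off * face_dir),
    w = c(1, 0.6, 0.4))
  place_on_targets_2d(tmpl_new, spec)
}

# designed layouts and hydrogen-bond lists of the two base quadruples;
# the four bases sit in a ring: the central Watson-Crick pair at the
# bottom, the side pair on top, single bonds bridging the flanks
toy_quadruple_layouts <- function(seqs, mutant) {
  d_hb <- 2.9
  designed <- list()
  note <- function(dres, datom, ares, aatom) {
    designed[[length(designed) + 1]] <<- tibble(
      donor_resid = dres, donor_name = datom,
      acceptor_resid = ares, acceptor_name = aatom)
  }

  # ---- upper quadruple: 37 x 61 Watson-Crick at the bottom, the 34 x 65
  # pair stacked above it (rotated 180 degrees so A65 sits over 61), with
  # bridging bonds closing the ring; the top block position is solved
  # numerically so the bridges land at bonding distance
  wc1 <- wc_pair_2d(seqs[["37"]], seqs[["61"]])
  p37 <- wc1$A; p61 <- wc1$B
  if (!mutant) {
    note(61, "N4", 37, "O6"); note(37, "N1", 61, "N3"); note(37, "N2", 61, "O2")
  } else {
    note(61, "N3", 37, "N1"); note(37, "N6", 61, "O4")
  }
  # A65 bridges the pair on its major-groove face: in the wildtype it
  # accepts the free amino hydrogen of C61:N4 on N7 and donates its own
  # free N6 hydrogen to G37:N7 (a triangle of pairs); U34 then pairs A65
  # on the outside. The mutant U61 has no amino donor, so the 61-65
  # bridge disappears along with the third Watson-Crick bond.
  t65 <- base_template_2d(seqs[["65"]])
  bonds65 <- tibble(fixed = list(p37), atom_f = "N7", atom_b = "N6",
                    donor_side = "movable")
  note(65, "N6", 37, "N7")
  if (!mutant) {
    bonds65 <- bind_rows(bonds65, tibble(
      fixed = list(p61), atom_f = "N4", atom_b = "N7",
      donor_side = "fixed"))
    note(61, "N4", 65, "N7")
  }
  c37 <- base_ring_center_2d(p37)
  cpair <- (c37 + base_ring_center_2d(p61)) / 2
  down <- c(4, -6.5) - cpair
  down <- down / sqrt(sum(down^2))
  p65 <- place_base_opt_2d(t65, bonds65, list(p37, p61),
                           guess = c(4, -6.5), span = 3,
                           orient = list(atom = "N1", dir = down))
  c65 <- base_ring_center_2d(p65)
  away <- (c65 - c37) / sqrt(sum((c65 - c37)^2))
  t34 <- base_template_2d(seqs[["34"]])
  bonds34 <- tibble(
    fixed = list(p65, p65), atom_f = c("N1", "N6"), atom_b = c("N3", "O4"),
    donor_side = c("movable", "fixed"))
  note(34, "N3", 65, "N1"); note(65, "N6", 34, "O4")
  p34 <- place_base_opt_2d(t34, bonds34, list(p37, p61, p65),
                           guess = c65 + 7.5 * away, span = 3)
  upper <- list("37" = p37, "61" = p61, "65" = p65, "34" = p34)

  # ---- lower quadruple: 38 x 60 Watson-Crick, A66 off G38:N2,
  # A33 accepting the A66 amino hydrogen
  wc2 <- wc_pair_2d(seqs[["38"]], seqs[["60"]])
  p38 <- wc2$A; p60 <- wc2$B
  note(60, "N4", 38, "O6"); note(38, "N1", 60, "N3"); note(38, "N2", 60, "O2")
  d66 <- bond_dir_2d(p38, "N2", "donor", c(-0.3, 1))
  p66 <- place_single_2d(base_template_2d(seqs[["66"]]), "N3", p38, "N2",
                         d66, face_atom = "N6", face_dir = c(0, 1),
                         d_hb = d_hb)
  note(38, "N2", 66, "N3")
  d33 <- bond_dir_2d(p66, "N6", "donor", c(0, 1))
  p33 <- place_single_2d(base_template_2d(seqs[["33"]]), "N7", p66, "N6",
                         d33, face_atom = "N1", face_dir = c(0, 1),
                         d_hb = d_hb)
  note(66, "N6", 33, "N7")
  lower <- list("38" = p38, "60" = p60, "66" = p66, "33" = p33)

  list(upper = upper, lower = lower, designed = bind_rows(designed))
}

toy_coarse <- function(seqs, mutant) {
  rs <- 15:81
  tab <- tibble(
    serial = seq_along(rs), name = "N1", resid = rs,
    resname = unname(seqs[as.character(rs)]), chain = "A",
    x = as.numeric(rs) * 5, y = 0, z = 0)
  st <- build_structure_from_table(tab)
  st$bonds <- tibble(i = seq_len(length(rs) - 1), j = seq_len(length(rs) - 1) + 1,
                     locked = FALSE)
  list(structure = st, regions = assign_regions(st),
       designed_hbonds = NULL,
       params = list(mutant = mutant, granularity = "coarse"))
}
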