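# Least-squares rigid-body superposition (Kabsch, via SVD), optionally
# mass-weighted. Returns the rotation R and translation t mapping X onto Y
# (rows are points): X %*% R + t ~= Y.
kabsch_fit <- function(x, y, w = NULL) {
  stopifnot(nrow(x) == nrow(y), ncol(x) == 3, ncol(y) == 3)
  if (is.null(w)) w <- rep(1, nrow(x))
  w <- w / sum(w)
  cx <- colSums(x * w); cy <- colSums(y * w)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  h <- t(xc * w) %*% yc
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(rotation = rot, translation = cy - as.numeric(cx %*% rot))
}

apply_fit <- function(x, fit) {
  sweep(x %*% fit$rotation, 2, fit$translation, `+`)
}

# Fit frame coordinates (flat vectors) onto reference over a selection of
# atom rows; returns the transformed flat vector of all atoms.
fit_frame <- function(flat, ref_flat, sel, w = NULL) {
  x <- matrix(flat, ncol = 3, byrow = TRUE)
  y <- matrix(ref_flat, ncol = 3, byrow = TRUE)
  fit <- kabsch_fit(x[sel, , drop = FALSE], y[sel, , drop = FALSE], w)
  as.numeric(t(apply_fit(x, fit)))
}

#' Transplant base coordinates between structures (mutant construction)
#'
#' Builds a variant of `target` in which, after least-squares superposition
#' of `donor` onto `target` over all shared heavy atoms, the base atoms at
#' the given positions are replaced by the donor's (transformed) base
#' atoms; backbone coordinates and every other nucleotide are untouched,
#' and base identities are updated from the donor.
#'
#' @param target,donor `rna_structure` objects sharing backbone atom names
#'   at `positions`.
#' @param positions Non-empty set of nucleotide ids to transplant.
#' @return A new `rna_structure`.
#' @export
transplant_bases <- function(target, donor, positions) {
  stopifnot(inherits(target, "rna_structure"), inherits(donor, "rna_structure"))
  positions <- as.integer(positions)
  if (length(positions) == 0) abort("positions must be non-empty")
  for (p in positions) {
    if (!p %in% target$nucleotides$resid) {
      abort(paste("position", p, "absent in target"))
    }
    if (!p %in% donor$nucleotides$resid) {
      abort(paste("position", p, "absent in donor"))
    }
  }
  ta <- target$atoms; da <- donor$atoms
  t_heavy <- ta$category == "RNA" & ta$element != "H"
  d_heavy <- da$category == "RNA" & da$element != "H"
  tk <- paste(ta$resid, ta$name); dk <- paste(da$resid, da$name)
  shared <- intersect(tk[t_heavy], dk[d_heavy])
  ti <- match(shared, tk); di <- match(shared, dk)
  fit <- kabsch_fit(as.matrix(da[di, c("x", "y", "z")]),
                    as.matrix(ta[ti, c("x", "y", "z")]),
                    w = da$mass[di])
  d_xyz <- apply_fit(as.matrix(da[, c("x", "y", "z")]), fit)
  tab <- ta %>% select("serial", "name", "resid", "resname", "chain",
                       "x", "y", "z")
  for (p in positions) {
    keep <- !(tab$resid == p &
                (!tab$name %in% backbone_atoms) &
                tab$resname %in% c("A", "C", "G", "U"))
    backbone_rows <- tab[tab$resid == p & keep & tab$resname %in%
                           c("A", "C", "G", "U"), ]
    don_rows <- which(da$resid == p & !(da$name %in% backbone_atoms) &
                        da$category == "RNA" & da$element != "H")
    new_base <- tibble(
      serial = NA_integer_,
      name = da$name[don_rows],
      resid = p,
      resname = da$resname[don_rows],
      chain = backbone_rows$chain[1],
      x = d_xyz[don_rows, 1], y = d_xyz[don_rows, 2], z = d_xyz[don_rows, 3])
    tab <- tab[keep, ]
    tab$resname[tab$resid == p & tab$resname %in% c("A", "C", "G", "U")] <-
      da$resname[don_rows[1]]
    tab <- bind_rows(tab, new_base)
  }
  tab <- tab %>% arrange(.data$resid, is.na(.data$serial))
  tab$serial <- seq_len(nrow(tab))
  build_structure_from_table(tab)
}
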