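# Independent oracle implementations used to cross-check the package's
# geometry code, plus shared fixture builders. These deliberately use
# different constructions than the implementations they verify.

# dihedral via in-plane projections and a signed angle (no atan2 on the
# cross-product triple product path used by the implementation)
oracle_dihedral <- function(p1, p2, p3, p4) {
  b <- p3 - p2
  b <- b / sqrt(sum(b^2))
  u <- (p1 - p2) - sum((p1 - p2) * b) * b
  v <- (p4 - p3) - sum((p4 - p3) * b) * b
  u <- u / sqrt(sum(u^2))
  v <- v / sqrt(sum(v^2))
  cosang <- max(-1, min(1, sum(u * v)))
  ang <- acos(cosang) * 180 / pi
  # sign from the handedness of (u, v, b)
  s <- sum(b * c(u[2] * v[3] - u[3] * v[2],
                 u[3] * v[1] - u[1] * v[3],
                 u[1] * v[2] - u[2] * v[1]))
  if (s < 0) -ang else ang
}

# rigid superposition via Horn's quaternion method (eigendecomposition,
# not SVD)
oracle_superpose_rmsd <- function(x, y) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  cx <- colMeans(x)
  cy <- colMeans(y)
  xc <- sweep(x, 2, cx)
  yc <- sweep(y, 2, cy)
  S <- t(xc) %*% yc
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  ev <- eigen(K, symmetric = TRUE)
  q <- ev$vectors[, 1]
  w <- q[1]; xq <- q[2]; yq <- q[3]; zq <- q[4]
  R <- matrix(c(
    1 - 2 * (yq^2 + zq^2), 2 * (xq * yq - w * zq), 2 * (xq * zq + w * yq),
    2 * (xq * yq + w * zq), 1 - 2 * (xq^2 + zq^2), 2 * (yq * zq - w * xq),
    2 * (xq * zq - w * yq), 2 * (yq * zq + w * xq), 1 - 2 * (xq^2 + yq^2)),
    3, 3, byrow = TRUE)
  fit <- t(R %*% t(xc))
  sqrt(mean(rowSums((fit - yc)^2)))
}

# polygon intersection area by rasterization on a fine grid
oracle_overlap_raster <- function(va, vb, h = 0.01) {
  inside <- function(px, py, v) {
    n <- nrow(v)
    ok <- rep(TRUE, length(px))
    for (k in seq_len(n)) {
      a <- v[k, ]
      b <- v[if (k == n) 1 else k + 1, ]
      ok <- ok & ((b[1] - a[1]) * (py - a[2]) -
                    (b[2] - a[2]) * (px - a[1]) >= 0)
    }
    ok
  }
  lo <- pmax(apply(va, 2, min), apply(vb, 2, min)) - h
  hi <- pmin(apply(va, 2, max), apply(vb, 2, max)) + h
  if (any(lo >= hi)) return(0)
  gx <- seq(lo[1] + h / 2, hi[1], by = h)
  gy <- seq(lo[2] + h / 2, hi[2], by = h)
  px <- rep(gx, times = length(gy))
  py <- rep(gy, each = length(gx))
  sum(inside(px, py, va) & inside(px, py, vb)) * h^2
}

# random convex polygon (counter-clockwise) of given radius scale:
# convex hull of random points
random_convex_polygon <- function(n = 7, scale = 1.5) {
  repeat {
    pts <- matrix(stats::runif(2 * (n + 5), -scale, scale), ncol = 2)
    h <- grDevices::chull(pts)
    if (length(h) >= 4) return(pts[rev(h), , drop = FALSE])
  }
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# duplex fixture with a planted G(syn)-G(anti) Hoogsteen mismatch at
# strand-1 position `pos` (two WC flanks on each side when pos allows)
gg_mismatch_fixture <- function(seq = "CGCGGGCGC", pos = 5) {
  n <- nchar(seq)
  hx <- build_ideal_helix(seq, form = "B")
  j <- sprintf("B:%d", n + 1 - pos)
  i <- sprintf("A:%d", pos)
  hx <- mutate_base(hx, j, "G", form = "B")
  hg_place(hx, i, j, hg_template("GG"))
}

# minimal two-model PDB text with an altloc pair on one atom
write_mini_pdb <- function(path) {
  lines <- c(
    "REMARK   2 RESOLUTION.    1.80 ANGSTROMS.",
    "MODEL        1",
    "ATOM      1  C1' ADG A   1      -4.000   1.000   0.000  1.00  0.00           C",
    "ATOM      2  C1'BDG A   1      -4.100   1.100   0.000  0.30  0.00           C",
    "ATOM      3  N9   DG A   1      -2.600   1.200   0.000  1.00  0.00           N",
    "ATOM      4  C4   DG A   1      -1.900   2.300   0.100  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      5  C1'  DG A   1      40.000  41.000  42.000  1.00  0.00           C",
    "ATOM      6  N9   DG A   1      42.600  41.200  40.000  1.00  0.00           N",
    "ENDMDL",
    "END")
  writeLines(lines, path)
  path
}

write_mini_cif <- function(path) {
  lines <- c(
    "data_TEST",
    "_refine.ls_d_res_high 2.10",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 C \"C1'\" . G A 1 -4.000 1.000 0.000 1.00 1",
    "ATOM 2 C \"C1'\" B G A 1 -4.100 1.100 0.000 0.30 1",
    "ATOM 3 N N9 . G A 1 -2.600 1.200 0.000 1.00 1",
    "ATOM 4 N N9 . G A 1 40.000 40.000 40.000 1.00 2")
  writeLines(lines, path)
  path
}
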