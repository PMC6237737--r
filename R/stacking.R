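## Base-stacking overlap: project the bases of a dinucleotide step onto
## the mean pair plane and measure intersection areas of the base
## polygons (convex hulls of the projected ring, optionally with
## exocyclic substituents).

.best_plane_normal <- function(xyz) {
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  n <- sv$v[, 3]
  list(center = ctr, normal = n)
}

.pair_base_xyz <- function(structure, pair, exocyclic = TRUE) {
  get1 <- function(sel) {
    s <- .parse_resid(sel)
    r <- .res_atoms(structure, s$chain, s$resno, s$icode)
    if (!nrow(r)) stop("residue not found: ", sel)
    nm <- intersect(base_atoms(r$resname[1], exocyclic = exocyclic),
                    r$atom)
    if (length(nm) < 3) stop("fewer than 3 base atoms in ", sel)
    as.matrix(r[match(nm, r$atom), c("x", "y", "z")])
  }
  list(i = get1(pair[1]), j = get1(pair[2]))
}

#' Projection frame for a base-pair step
#'
#' Builds an orthonormal frame whose z axis is the mean of the two
#' base-pair plane normals (signs aligned), centered on the step. All
#' overlap areas for the step are measured in this projection plane.
#'
#' @param structure A [nastructure()].
#' @param pair1,pair2 Character vectors `c(i, j)` of `"chain:resno"`
#'   selectors for the two stacked pairs.
#' @return List with `origin`, `ex`, `ey`, `normal`.
#' @export
project_step <- function(structure, pair1, pair2) {
  b1 <- .pair_base_xyz(structure, pair1)
  b2 <- .pair_base_xyz(structure, pair2)
  p1 <- .best_plane_normal(rbind(b1$i, b1$j))
  p2 <- .best_plane_normal(rbind(b2$i, b2$j))
  n2 <- if (sum(p1$normal * p2$normal) < 0) -p2$normal else p2$normal
  n <- p1$normal + n2
  if (.vnorm(n) < 1e-8) stop("degenerate step: opposed pair normals")
  n <- .vunit(n)
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  ex <- .vunit(.vcross(ref, n))
  list(origin = (p1$center + p2$center) / 2, ex = ex,
       ey = .vcross(n, ex), normal = n)
}

#' Projected base polygon
#'
#' Convex hull of a residue's base heavy atoms projected into a step
#' frame.
#'
#' @param structure A [nastructure()].
#' @param residue `"chain:resno"` selector.
#' @param frame A frame from [project_step()].
#' @param exocyclic Include exocyclic substituents in the hull.
#' @return Object of class `"base_polygon"`: list with `vertices` (n x 2,
#'   counter-clockwise), `area`, `residue`, `exocyclic`.
#' @export
base_polygon <- function(structure, residue, frame, exocyclic = TRUE) {
  s <- .parse_resid(residue)
  r <- .res_atoms(structure, s$chain, s$resno, s$icode)
  if (!nrow(r)) stop("residue not found: ", residue)
  nm <- intersect(base_atoms(r$resname[1], exocyclic = exocyclic), r$atom)
  xyz <- as.matrix(r[match(nm, r$atom), c("x", "y", "z")])
  rel <- sweep(xyz, 2, frame$origin)
  pts <- cbind(rel %*% frame$ex, rel %*% frame$ey)
  h <- grDevices::chull(pts)          # clockwise order
  v <- pts[rev(h), , drop = FALSE]    # counter-clockwise
  structure(list(vertices = v, area = .poly_area(v), residue = residue,
                 exocyclic = exocyclic),
            class = "base_polygon")
}

.poly_area <- function(v) {
  if (is.null(v) || nrow(v) < 3) return(0)
  x <- v[, 1]; y <- v[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

## Sutherland-Hodgman clipping of a polygon by a convex clip polygon.
## Both counter-clockwise; returns vertex matrix (possibly empty).
.clip_convex <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (k in seq_len(nc)) {
    if (is.null(out) || nrow(out) == 0) return(out)
    a <- clip[k, ]
    b <- clip[if (k == nc) 1 else k + 1, ]
    edge <- b - a
    inside <- function(p) edge[1] * (p[2] - a[2]) -
      edge[2] * (p[1] - a[1]) >= -1e-12
    inp <- out
    out <- matrix(numeric(0), 0, 2)
    np <- nrow(inp)
    for (m in seq_len(np)) {
      p <- inp[m, ]
      q <- inp[if (m == np) 1 else m + 1, ]
      pin <- inside(p)
      qin <- inside(q)
      if (pin) out <- rbind(out, p)
      if (xor(pin, qin)) {
        d <- q - p
        denom <- d[1] * edge[2] - d[2] * edge[1]
        t <- ((a[1] - p[1]) * edge[2] - (a[2] - p[2]) * edge[1]) / denom
        out <- rbind(out, p + t * d)
      }
    }
  }
  out
}

#' Intersection area of two base polygons
#'
#' Polygon-clipping intersection area; symmetric in its arguments, never
#' negative and never larger than either polygon.
#'
#' @param poly_a,poly_b [base_polygon()] objects (or bare vertex
#'   matrices) in the same projection frame.
#' @return Area in square angstrom.
#' @export
overlap_area <- function(poly_a, poly_b) {
  va <- if (inherits(poly_a, "base_polygon")) poly_a$vertices else poly_a
  vb <- if (inherits(poly_b, "base_polygon")) poly_b$vertices else poly_b
  .poly_area(.clip_convex(va, vb))
}

#' Overlap table for one base-pair step
#'
#' Overlap areas between the four base combinations of a step: the two
#' same-strand stackings and the two cross-strand stackings, plus their
#' total.
#'
#' @inheritParams project_step
#' @param exocyclic Include exocyclic substituents.
#' @return Data frame with columns `combination`, `residue_a`,
#'   `residue_b`, `overlap`; the total is in the last row.
#' @export
step_overlap <- function(structure, pair1, pair2, exocyclic = TRUE) {
  fr <- project_step(structure, pair1, pair2)
  pg <- function(sel) base_polygon(structure, sel, fr,
                                   exocyclic = exocyclic)
  combos <- list(same_strand_1 = c(pair1[1], pair2[1]),
                 same_strand_2 = c(pair1[2], pair2[2]),
                 cross_1 = c(pair1[1], pair2[2]),
                 cross_2 = c(pair1[2], pair2[1]))
  rows <- lapply(names(combos), function(nm) {
    ab <- combos[[nm]]
    data.frame(combination = nm, residue_a = ab[1], residue_b = ab[2],
               overlap = overlap_area(pg(ab[1]), pg(ab[2])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rbind(out, data.frame(combination = "total", residue_a = "",
                        residue_b = "", overlap = sum(out$overlap),
                        stringsAsFactors = FALSE))
}

#' Stacking-overlap change of a mismatched triplet versus its idealized
#' Watson-Crick counterpart
#'
#' Computes per-step and total base-overlap areas for a three-pair
#' triplet (central mismatch plus both flanking pairs) and for an
#' idealized reference duplex built from the sequence of the mismatched
#' strand containing the syn base, then reports the difference
#' (mismatch minus reference). Modified bases enter through their
#' canonical parents: only canonical base heavy atoms contribute to the
#' polygons.
#'
#' @param structure A [nastructure()] containing the triplet.
#' @param pairs 3 x 2 matrix (or data frame) of `"chain:resno"`
#'   selectors, rows ordered 5' to 3' on the syn-purine strand, columns
#'   (syn-strand residue, partner).
#' @param form Helix form for the reference duplex (`"A"` or `"B"`).
#' @param exocyclic Include exocyclic substituents.
#' @return List with `mismatch` and `reference` step tables, `delta`
#'   (per-step data frame) and `delta_total`.
#' @export
triplet_overlap_change <- function(structure, pairs, form = c("B", "A"),
                                   exocyclic = TRUE) {
  form <- match.arg(form)
  pairs <- as.matrix(pairs)
  if (nrow(pairs) != 3)
    stop("a triplet needs exactly 3 pairs (mismatch plus both flanks)")
  seq_syn <- vapply(pairs[, 1], function(sel) {
    s <- .parse_resid(sel)
    r <- .res_atoms(structure, s$chain, s$resno, s$icode)
    if (!nrow(r)) stop("missing flank residue: ", sel)
    p <- parent_base(r$resname[1])
    if (is.na(p)) stop("unrecognized residue ", r$resname[1], " at ", sel)
    if (p == "T" && form == "A") p <- "U"
    if (p == "U" && form == "B") p <- "T"
    p
  }, "")
  ref <- build_ideal_helix(paste(seq_syn, collapse = ""), form = form)
  rp <- helix_pairs(ref)

  steps <- function(str, pr) {
    s1 <- step_overlap(str, pr[1, ], pr[2, ], exocyclic = exocyclic)
    s2 <- step_overlap(str, pr[2, ], pr[3, ], exocyclic = exocyclic)
    data.frame(step = rep(c("step_1_2", "step_2_3"), each = nrow(s1)),
               rbind(s1, s2), stringsAsFactors = FALSE)
  }
  mm <- steps(structure, pairs)
  rf <- steps(ref, as.matrix(rp))
  tot <- function(df) sum(df$overlap[df$combination == "total"])
  step_tot <- function(df, s) sum(df$overlap[df$step == s &
                                               df$combination == "total"])
  delta <- data.frame(step = c("step_1_2", "step_2_3"),
                      mismatch = vapply(c("step_1_2", "step_2_3"),
                                        function(s) step_tot(mm, s), 0),
                      reference = vapply(c("step_1_2", "step_2_3"),
                                         function(s) step_tot(rf, s), 0))
  delta$delta <- delta$mismatch - delta$reference
  list(mismatch = mm, reference = rf, delta = delta,
       delta_total = tot(mm) - tot(rf))
}
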