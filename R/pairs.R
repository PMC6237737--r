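#' Geometry of a candidate base pair
#'
#' Measures the C1'-C1' distance and all inter-base donor/acceptor
#' heavy-atom contacts within `hbond_scan` angstrom between two residues,
#' then assigns a pair class:
#'
#' * `WC` - complementary parents (A:T/U, G:C), both glycosidic torsions
#'   anti, at least two hydrogen bonds under `hbond_max`, and C1'-C1' in
#'   `[9.8, 11.0]` angstrom;
#' * `HG` - exactly one purine partner in syn, C1'-C1' under
#'   `c1c1_hg_max` (9.5 angstrom) and at least one hydrogen bond under
#'   `hbond_max`;
#' * `wobble` - G with U/T, both anti, at least two hydrogen bonds;
#' * `other` - everything else.
#'
#' When hydrogen positions are present, the hydrogen-donor-acceptor angle
#' is reported for each contact; the geometric class uses heavy-atom
#' distances only (the angle criterion belongs to trajectory analysis).
#'
#' @param structure A [nastructure()].
#' @param i,j Residue selectors, `"chain:resno"` strings or lists from
#'   internal addressing.
#' @param hbond_max Heavy-atom hydrogen-bond cutoff for classification
#'   (angstrom).
#' @param hbond_scan Wider listing cutoff for the contact table.
#' @return Object of class `"pair_geometry"`: residue labels and names,
#'   `c1c1_distance`, `hbonds` data frame (donor residue/atom, acceptor
#'   residue/atom, distance, angle), and `pair_class`.
#' @export
pair_geometry <- function(structure, i, j, hbond_max = 3.5,
                          hbond_scan = 4.0) {
  si <- if (is.character(i)) .parse_resid(i) else i
  sj <- if (is.character(j)) .parse_resid(j) else j
  ri <- .res_atoms(structure, si$chain, si$resno, si$icode %||% "")
  rj <- .res_atoms(structure, sj$chain, sj$resno, sj$icode %||% "")
  if (!nrow(ri) || !nrow(rj)) stop("pair_geometry: residue not found")
  c1i <- .atom_xyz(ri, "C1'")
  c1j <- .atom_xyz(rj, "C1'")
  if (is.null(c1i) || is.null(c1j))
    stop("pair_geometry: C1' atom missing")
  c1c1 <- .vnorm(c1i - c1j)

  pi_ <- parent_base(ri$resname[1])
  pj <- parent_base(rj$resname[1])
  hb <- .interbase_hbonds(ri, rj, pi_, pj, hbond_scan)

  chi_i <- .residue_chi(structure, si)
  chi_j <- .residue_chi(structure, sj)
  cls_i <- classify_glycosidic(chi_i)
  cls_j <- classify_glycosidic(chi_j)

  nhb <- if (nrow(hb)) sum(hb$distance < hbond_max) else 0L
  pair_class <- "other"
  syn_purine <- (is_purine(ri$resname[1]) && identical(cls_i, "syn")) +
    (is_purine(rj$resname[1]) && identical(cls_j, "syn"))
  if (!is.na(pi_) && !is.na(pj)) {
    if (.wc_partner(pi_, pj) && identical(cls_i, "anti") &&
        identical(cls_j, "anti") && nhb >= 2 &&
        c1c1 >= 9.8 && c1c1 <= 11.0) {
      pair_class <- "WC"
    } else if (syn_purine == 1 && nhb >= 1 &&
               (c1c1 < 9.5 || (is_purine(ri$resname[1]) &&
                               is_purine(rj$resname[1])))) {
      # purine-pyrimidine Hoogsteen pairs constrict C1'-C1'; the larger
      # purine-purine pairs hydrogen bond without constriction
      pair_class <- "HG"
    } else if (((pi_ == "G" && pj %in% c("U", "T")) ||
                (pj == "G" && pi_ %in% c("U", "T"))) &&
               identical(cls_i, "anti") && identical(cls_j, "anti") &&
               nhb >= 2) {
      pair_class <- "wobble"
    }
  }
  structure(list(residue_i = .res_label(si$chain, si$resno, si$icode %||% ""),
                 residue_j = .res_label(sj$chain, sj$resno, sj$icode %||% ""),
                 resname_i = ri$resname[1], resname_j = rj$resname[1],
                 c1c1_distance = c1c1, hbonds = hb,
                 chi_i = chi_i, chi_j = chi_j,
                 chi_class_i = cls_i, chi_class_j = cls_j,
                 pair_class = pair_class),
            class = "pair_geometry")
}

.residue_chi <- function(structure, sel) {
  res <- .res_atoms(structure, sel$chain, sel$resno, sel$icode %||% "")
  ga <- tryCatch(.glyco_atoms(res$resname[1]), error = function(e) NULL)
  if (is.null(ga)) return(NA_real_)
  .safe_dihedral(.atom_xyz(res, ga[1]), .atom_xyz(res, ga[2]),
                 .atom_xyz(res, ga[3]), .atom_xyz(res, ga[4]))
}

## All donor/acceptor heavy-atom contacts between the base moieties of two
## residues. Hydrogens, when present, supply the H-donor-acceptor angle.
.interbase_hbonds <- function(ri, rj, pi_, pj, cutoff) {
  empty <- data.frame(donor_res = character(), donor = character(),
                      acceptor_res = character(), acceptor = character(),
                      distance = numeric(), angle = numeric(),
                      stringsAsFactors = FALSE)
  if (is.na(pi_) || is.na(pj)) return(empty)
  rows <- list()
  add <- function(don_res, don_df, don_atoms, acc_res, acc_df, acc_atoms) {
    for (d in intersect(don_atoms, don_df$atom)) {
      pd <- .atom_xyz(don_df, d)
      for (a in intersect(acc_atoms, acc_df$atom)) {
        pa <- .atom_xyz(acc_df, a)
        dist <- .vnorm(pd - pa)
        if (dist <= cutoff) {
          ang <- .hda_angle(don_df, d, pa)
          rows[[length(rows) + 1L]] <<- data.frame(
            donor_res = don_res, donor = d,
            acceptor_res = acc_res, acceptor = a,
            distance = dist, angle = ang, stringsAsFactors = FALSE)
        }
      }
    }
  }
  add("i", ri, .hb_donors[[pi_]], "j", rj, .hb_acceptors[[pj]])
  add("j", rj, .hb_donors[[pj]], "i", ri, .hb_acceptors[[pi_]])
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  ## a given atom pair may qualify in both directions (e.g. cytosine N3);
  ## keep one listing per unordered atom pair
  key <- apply(out, 1, function(r) {
    paste(sort(c(paste(r[["donor_res"]], r[["donor"]]),
                 paste(r[["acceptor_res"]], r[["acceptor"]]))),
          collapse = "|")
  })
  out <- out[!duplicated(key), , drop = FALSE]
  out[order(out$distance), , drop = FALSE]
}

## hydrogen-donor-acceptor angle when an attached hydrogen is present
.hda_angle <- function(don_df, donor, acceptor_xyz) {
  hy <- don_df[don_df$element == "H" | grepl("^H", don_df$atom), ,
               drop = FALSE]
  if (!nrow(hy)) return(NA_real_)
  pd <- .atom_xyz(don_df, donor)
  best <- NA_real_
  for (k in seq_len(nrow(hy))) {
    ph <- as.numeric(hy[k, c("x", "y", "z")])
    if (.vnorm(ph - pd) < 1.3) {
      # angle at the donor between D->H and D->A; small means near-linear
      ang <- bond_angle(ph, pd, acceptor_xyz)
      if (is.na(best) || ang < best) best <- ang
    }
  }
  best
}

#' @export
print.pair_geometry <- function(x, ...) {
  cat(sprintf("%s (%s) - %s (%s): %s, C1'-C1' = %.2f A, %d contact(s)\n",
              x$residue_i, x$resname_i, x$residue_j, x$resname_j,
              x$pair_class, x$c1c1_distance, nrow(x$hbonds)))
  invisible(x)
}

#' Per-pair geometry table for a list of residue pairs
#'
#' @param structure A [nastructure()].
#' @param pairs Two-column matrix or data frame of `"chain:resno"`
#'   selectors.
#' @param ... Passed to [pair_geometry()].
#' @return Data frame with one row per pair in a stable column order.
#' @export
pair_table <- function(structure, pairs, ...) {
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    pg <- pair_geometry(structure, pairs[k, 1], pairs[k, 2], ...)
    data.frame(residue_i = pg$residue_i, residue_j = pg$residue_j,
               resname_i = pg$resname_i, resname_j = pg$resname_j,
               pair_class = pg$pair_class,
               c1c1_distance = pg$c1c1_distance,
               n_hbonds = nrow(pg$hbonds),
               min_hbond = if (nrow(pg$hbonds)) min(pg$hbonds$distance)
                           else NA_real_,
               chi_class_i = pg$chi_class_i, chi_class_j = pg$chi_class_j,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
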