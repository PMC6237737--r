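#' Survey configuration for the purine-purine mismatch scan
#'
#' @param resolution_cutoff Keep structures with resolution strictly
#'   below this value (angstrom). Structures lacking resolution metadata
#'   are kept with a warning.
#' @param exclude Character vector of structure ids dropped before
#'   analysis (distorted or non-representative geometries).
#' @param flank_pairs Number of Watson-Crick pairs required on each side
#'   of the mismatch on both strands.
#' @param hbond_max Heavy-atom hydrogen-bond cutoff (angstrom) for the
#'   mismatch contact requirement.
#' @return A list of class `"survey_config"`.
#' @export
survey_config <- function(resolution_cutoff = 3.0,
                          exclude = c("1OH6", "1OH7"),
                          flank_pairs = 2L, hbond_max = 3.5) {
  stopifnot(resolution_cutoff > 0, flank_pairs >= 1)
  structure(list(resolution_cutoff = resolution_cutoff,
                 exclude = toupper(exclude),
                 flank_pairs = as.integer(flank_pairs),
                 hbond_max = hbond_max),
            class = "survey_config")
}

#' Find purine-purine mismatches in a duplex-like context
#'
#' Scans a structure for purine pairs (canonical bases or whitelisted
#' modified derivatives) in hydrogen-bonding contact (at least one
#' inter-base donor-acceptor distance under the cutoff) whose neighboring
#' residues on both strands form Watson-Crick pairs for `flank_pairs`
#' steps on each side. Each hit is classified by the glycosidic torsions
#' of the two bases; `hg_flag` marks syn-anti (Hoogsteen-type) geometry.
#'
#' @param structure A [nastructure()].
#' @param config A [survey_config()].
#' @return Data frame of hits (possibly empty): structure id, residue
#'   selectors and names, mismatch type (`A-A`, `A-G`, `G-G`), chi values
#'   and classes, `chi_pair` (e.g. `"syn-anti"`), `hg_flag`, C1'-C1'
#'   distance, and the seven torsions of each residue.
#' @export
find_pp_mismatches <- function(structure, config = survey_config()) {
  empty <- data.frame()
  if (toupper(structure$id) %in% config$exclude) return(empty)
  if (is.finite(structure$resolution)) {
    if (structure$resolution >= config$resolution_cutoff) return(empty)
  } else {
    warning("structure ", structure$id,
            ": no resolution metadata; resolution filter skipped")
  }
  rt <- residues(structure)
  pur <- which(is_purine(rt$resname))
  if (length(pur) < 2) return(empty)

  hits <- list()
  for (a in pur) {
    for (b in pur) {
      if (a >= b) next
      if (rt$chain[a] == rt$chain[b] &&
          abs(rt$resno[a] - rt$resno[b]) < 3) next  # same-strand neighbors
      ra <- .res_atoms(structure, rt$chain[a], rt$resno[a], rt$icode[a])
      rb <- .res_atoms(structure, rt$chain[b], rt$resno[b], rt$icode[b])
      c1a <- .atom_xyz(ra, "C1'")
      c1b <- .atom_xyz(rb, "C1'")
      if (is.null(c1a) || is.null(c1b)) next
      if (.vnorm(c1a - c1b) > 12.5) next
      hb <- .interbase_hbonds(ra, rb, parent_base(ra$resname[1]),
                              parent_base(rb$resname[1]),
                              config$hbond_max)
      if (!nrow(hb)) next
      if (!.wc_flanked(structure, rt, a, b, config$flank_pairs)) next
      hits[[length(hits) + 1L]] <- .mismatch_row(structure, rt, a, b)
    }
  }
  if (!length(hits)) return(empty)
  out <- do.call(rbind, hits)
  out[order(out$residue_i, out$residue_j), , drop = FALSE]
}

## neighbors i+-k / j-+k must form WC pairs for k = 1..flank on both sides
.wc_flanked <- function(structure, rt, a, b, flank) {
  idx_of <- function(chain, pos_in_chain) {
    w <- which(rt$chain == chain)
    if (pos_in_chain < 1 || pos_in_chain > length(w)) return(NA_integer_)
    w[pos_in_chain]
  }
  chain_pos <- function(k) match(k, which(rt$chain == rt$chain[k]))
  pa <- chain_pos(a)
  pb <- chain_pos(b)
  for (s in c(-1, 1)) {
    for (k in seq_len(flank)) {
      ia <- idx_of(rt$chain[a], pa + s * k)
      ib <- idx_of(rt$chain[b], pb - s * k)
      if (is.na(ia) || is.na(ib)) return(FALSE)
      pg <- tryCatch(
        pair_geometry(structure,
                      list(chain = rt$chain[ia], resno = rt$resno[ia],
                           icode = rt$icode[ia]),
                      list(chain = rt$chain[ib], resno = rt$resno[ib],
                           icode = rt$icode[ib])),
        error = function(e) NULL)
      if (is.null(pg) || pg$pair_class != "WC") return(FALSE)
    }
  }
  TRUE
}

.mismatch_row <- function(structure, rt, a, b) {
  sel <- function(k) list(chain = rt$chain[k], resno = rt$resno[k],
                          icode = rt$icode[k])
  pg <- pair_geometry(structure, sel(a), sel(b))
  ca <- residue_conformation(structure, rt$chain[a], rt$resno[a],
                             rt$icode[a])
  cb <- residue_conformation(structure, rt$chain[b], rt$resno[b],
                             rt$icode[b])
  parents <- sort(parent_base(c(rt$resname[a], rt$resname[b])))
  chi_pair <- paste(pg$chi_class_i, pg$chi_class_j, sep = "-")
  tor <- function(cc, suff) {
    v <- as.list(cc$torsions)
    names(v) <- paste0(names(v), suff)
    v
  }
  data.frame(structure_id = structure$id,
             residue_i = pg$residue_i, residue_j = pg$residue_j,
             resname_i = rt$resname[a], resname_j = rt$resname[b],
             mismatch_type = paste(parents, collapse = "-"),
             chi_i = pg$chi_i, chi_j = pg$chi_j,
             chi_class_i = pg$chi_class_i, chi_class_j = pg$chi_class_j,
             chi_pair = chi_pair,
             hg_flag = sum(c(pg$chi_class_i, pg$chi_class_j) == "syn") == 1 &&
               all(c(pg$chi_class_i, pg$chi_class_j) %in%
                     c("syn", "anti")),
             c1c1_distance = pg$c1c1_distance,
             tor(ca, "_i"), tor(cb, "_j"),
             stringsAsFactors = FALSE)
}

#' Run the mismatch survey over a corpus of structure files
#'
#' @param paths Character vector of PDB/mmCIF files, or a directory.
#' @param config A [survey_config()].
#' @return Combined hit table (see [find_pp_mismatches()]), sorted by
#'   structure id then residues; the result is independent of input file
#'   order.
#' @export
survey_corpus <- function(paths, config = survey_config()) {
  if (length(paths) == 1 && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.(pdb|cif)$",
                        full.names = TRUE)
  hits <- lapply(paths, function(p) {
    st <- parse_structure(p)
    find_pp_mismatches(st, config)
  })
  hits <- hits[vapply(hits, nrow, 0L) > 0]
  if (!length(hits)) return(data.frame())
  out <- do.call(rbind, hits)
  out <- out[order(out$structure_id, out$residue_i, out$residue_j), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

## circular statistics (degrees) ---------------------------------------

.circ_mean <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) return(NA_real_)
  r <- x * pi / 180
  atan2(mean(sin(r)), mean(cos(r))) * 180 / pi
}

.circ_sd <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  r <- x * pi / 180
  Rbar <- sqrt(mean(sin(r))^2 + mean(cos(r))^2)
  Rbar <- min(1, Rbar)
  sqrt(-2 * log(Rbar)) * 180 / pi
}

#' Torsion summary of survey hits against a Watson-Crick baseline
#'
#' Circular means and standard deviations of the seven torsions for the
#' syn residues of the hits, their anti partners, and a baseline set of
#' canonical Watson-Crick residues, plus the fraction of syn residues
#' with both alpha and gamma in the trans rotamer.
#'
#' @param hits Hit table from [find_pp_mismatches()] /
#'   [survey_corpus()].
#' @param baseline List of [residue_conformation()] objects (e.g. from
#'   residues of an ideal helix) or a [torsion_table()] data frame.
#' @return List with `summary` (data frame: group x torsion circular
#'   mean/SD), `n` per group, and `frac_syn_alpha_gamma_trans`.
#' @export
torsion_report <- function(hits, baseline) {
  tor_names <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta",
                 "chi")
  if (is.data.frame(baseline)) {
    base_df <- baseline[, tor_names, drop = FALSE]
  } else {
    base_df <- do.call(rbind, lapply(baseline, function(rc)
      as.data.frame(as.list(rc$torsions))))
  }
  if (!nrow(hits)) {
    groups <- list(baseline = base_df)
  } else {
    syn_i <- hits$chi_class_i == "syn"
    pick <- function(which_syn) {
      sel <- if (which_syn) ifelse(syn_i, "_i", "_j")
             else ifelse(syn_i, "_j", "_i")
      out <- lapply(seq_len(nrow(hits)), function(k)
        stats::setNames(as.numeric(hits[k, paste0(tor_names, sel[k])]),
                        tor_names))
      as.data.frame(do.call(rbind, out))
    }
    keep <- hits$hg_flag
    groups <- list(syn = pick(TRUE)[keep, , drop = FALSE],
                   anti_partner = pick(FALSE)[keep, , drop = FALSE],
                   baseline = base_df)
  }
  rows <- lapply(names(groups), function(g) {
    df <- groups[[g]]
    data.frame(group = g, torsion = tor_names,
               circ_mean = vapply(tor_names,
                                  function(t) .circ_mean(df[[t]]), 0),
               circ_sd = vapply(tor_names,
                                function(t) .circ_sd(df[[t]]), 0),
               n = nrow(df), stringsAsFactors = FALSE)
  })
  frac <- NA_real_
  if (nrow(hits) && any(hits$hg_flag)) {
    sdf <- groups$syn
    frac <- mean(classify_rotamer(sdf$alpha) == "trans" &
                   classify_rotamer(sdf$gamma) == "trans")
  }
  list(summary = do.call(rbind, rows),
       n = vapply(groups, nrow, 0L),
       frac_syn_alpha_gamma_trans = frac)
}
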