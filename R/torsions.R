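#' Classify a glycosidic torsion as syn, anti or intermediate
#'
#' Uses the strict ranges syn: 0 < chi < 90 and anti: -180 < chi < -90.
#' Values on either boundary, and everything else, map to
#' `"intermediate"`. Inputs are normalized to `(-180, 180]` first, so
#' `chi + 360k` classifies identically.
#'
#' @param chi Glycosidic torsion(s), degrees.
#' @return Character vector of `"syn"`, `"anti"`, `"intermediate"` (`NA` in,
#'   `NA` out).
#' @export
classify_glycosidic <- function(chi) {
  chi <- .wrap180(chi)
  out <- rep(NA_character_, length(chi))
  ok <- !is.na(chi)
  out[ok] <- "intermediate"
  out[ok & chi > 0 & chi < 90] <- "syn"
  out[ok & chi > -180 & chi < -90] <- "anti"
  out
}

#' Classify a backbone torsion into rotamer bins
#'
#' gauche+ for (0, 120], gauche- for (-120, 0], trans otherwise.
#'
#' @param angle Torsion angle(s), degrees.
#' @return Character vector of `"gauche+"`, `"gauche-"`, `"trans"`.
#' @export
classify_rotamer <- function(angle) {
  a <- .wrap180(angle)
  out <- rep(NA_character_, length(a))
  ok <- !is.na(a)
  out[ok] <- "trans"
  out[ok & a > 0 & a <= 120] <- "gauche+"
  out[ok & a > -120 & a <= 0] <- "gauche-"
  out
}

.wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[!is.na(y) & y == -180] <- 180
  y
}

## Pseudorotation phase/amplitude from the five endocyclic sugar torsions
## nu0..nu4 (Altona-Sundaralingam construction).
.pseudorotation <- function(nu) {
  if (any(is.na(nu))) return(c(phase = NA_real_, amplitude = NA_real_))
  num <- (nu[5] + nu[2]) - (nu[4] + nu[1])
  den <- 2 * nu[3] * (sin(36 * pi / 180) + sin(72 * pi / 180))
  P <- atan2(num, den) * 180 / pi
  amp <- nu[3] / cos(P * pi / 180)
  if (amp < 0) {
    # resolve sign so the amplitude is positive
    P <- P + 180
    amp <- -amp
  }
  P <- P %% 360
  c(phase = P, amplitude = amp)
}

.safe_dihedral <- function(p1, p2, p3, p4) {
  if (is.null(p1) || is.null(p2) || is.null(p3) || is.null(p4))
    return(NA_real_)
  tryCatch(dihedral(p1, p2, p3, p4), error = function(e) NA_real_)
}

#' Per-residue backbone and glycosidic conformation
#'
#' Computes the seven standard nucleotide torsions (alpha..zeta, chi), the
#' sugar pseudorotation phase and amplitude, the syn/anti class of chi and
#' the rotamer bin of each backbone torsion. Torsions spanning a missing
#' neighbor or missing atoms are reported as `NA` rather than failing.
#'
#' @param structure A [nastructure()].
#' @param chain,resno,icode Residue address (or pass a `"chain:resno"`
#'   string as `chain`).
#' @return Object of class `"residue_conformation"`: a list with `residue`,
#'   `resname`, `torsions` (named numeric: alpha, beta, gamma, delta,
#'   epsilon, zeta, chi), `pucker_phase`, `pucker_amplitude`, `chi_class`
#'   and `rotamers` (named character).
#' @export
residue_conformation <- function(structure, chain, resno = NULL,
                                 icode = "") {
  if (is.null(resno)) {
    sel <- .parse_resid(chain)
    chain <- sel$chain; resno <- sel$resno; icode <- sel$icode
  }
  res <- .res_atoms(structure, chain, resno, icode)
  if (!nrow(res)) stop("residue not found: ", .res_label(chain, resno, icode))
  resname <- res$resname[1]
  at <- function(n) .atom_xyz(res, n)

  ## neighbours along the chain, by file order within the chain
  rtab <- residues(structure)
  rtab <- rtab[rtab$chain == chain, , drop = FALSE]
  i <- which(rtab$resno == resno & rtab$icode == icode)
  prev <- if (length(i) && i > 1)
    .res_atoms(structure, chain, rtab$resno[i - 1], rtab$icode[i - 1])
  else NULL
  nxt <- if (length(i) && i < nrow(rtab))
    .res_atoms(structure, chain, rtab$resno[i + 1], rtab$icode[i + 1])
  else NULL
  atp <- function(n) if (is.null(prev)) NULL else .atom_xyz(prev, n)
  atn <- function(n) if (is.null(nxt)) NULL else .atom_xyz(nxt, n)

  tor <- c(
    alpha = .safe_dihedral(atp("O3'"), at("P"), at("O5'"), at("C5'")),
    beta = .safe_dihedral(at("P"), at("O5'"), at("C5'"), at("C4'")),
    gamma = .safe_dihedral(at("O5'"), at("C5'"), at("C4'"), at("C3'")),
    delta = .safe_dihedral(at("C5'"), at("C4'"), at("C3'"), at("O3'")),
    epsilon = .safe_dihedral(at("C4'"), at("C3'"), at("O3'"), atn("P")),
    zeta = .safe_dihedral(at("C3'"), at("O3'"), atn("P"), atn("O5'"))
  )
  ga <- .glyco_atoms(resname)
  tor["chi"] <- .safe_dihedral(at(ga[1]), at(ga[2]), at(ga[3]), at(ga[4]))

  nu <- c(.safe_dihedral(at("C4'"), at("O4'"), at("C1'"), at("C2'")),
          .safe_dihedral(at("O4'"), at("C1'"), at("C2'"), at("C3'")),
          .safe_dihedral(at("C1'"), at("C2'"), at("C3'"), at("C4'")),
          .safe_dihedral(at("C2'"), at("C3'"), at("C4'"), at("O4'")),
          .safe_dihedral(at("C3'"), at("C4'"), at("O4'"), at("C1'")))
  pk <- .pseudorotation(nu)

  structure(list(residue = .res_label(chain, resno, icode),
                 resname = resname,
                 torsions = tor,
                 nu = nu,
                 pucker_phase = unname(pk["phase"]),
                 pucker_amplitude = unname(pk["amplitude"]),
                 chi_class = classify_glycosidic(tor[["chi"]]),
                 rotamers = vapply(tor[1:6], classify_rotamer, "")),
            class = "residue_conformation")
}

#' @export
print.residue_conformation <- function(x, ...) {
  cat(sprintf("%s (%s): chi = %.1f (%s)", x$residue, x$resname,
              x$torsions[["chi"]], x$chi_class))
  if (is.finite(x$pucker_phase))
    cat(sprintf(", pucker P = %.1f deg (%s)", x$pucker_phase,
                pucker_region(x$pucker_phase)))
  cat("\n")
  tv <- x$torsions[1:6]
  cat("  ", paste(sprintf("%s=%.1f", names(tv), tv), collapse = " "), "\n")
  invisible(x)
}

#' Name the canonical pucker region of a pseudorotation phase
#'
#' @param phase Phase angle(s) in degrees `[0, 360)`.
#' @return Character vector such as `"C3'-endo"` (0-36), `"C2'-endo"`
#'   (144-180), or `"other"`.
#' @export
pucker_region <- function(phase) {
  out <- rep(NA_character_, length(phase))
  ok <- is.finite(phase)
  p <- phase[ok] %% 360
  lab <- rep("other", length(p))
  lab[p >= 0 & p <= 36] <- "C3'-endo"
  lab[p > 36 & p <= 72] <- "C4'-exo"
  lab[p > 72 & p <= 108] <- "O4'-endo"
  lab[p > 108 & p < 144] <- "C1'-exo"
  lab[p >= 144 & p <= 180] <- "C2'-endo"
  out[ok] <- lab
  out
}

#' Torsion table for every residue of a structure
#'
#' @param structure A [nastructure()].
#' @return Data frame with one row per residue: address, residue name,
#'   seven torsions, pucker phase/amplitude and classifications, in a
#'   stable column order.
#' @export
torsion_table <- function(structure) {
  rt <- residues(structure)
  rows <- lapply(seq_len(nrow(rt)), function(i) {
    rc <- residue_conformation(structure, rt$chain[i], rt$resno[i],
                               rt$icode[i])
    data.frame(residue = rc$residue, resname = rc$resname,
               alpha = rc$torsions[["alpha"]], beta = rc$torsions[["beta"]],
               gamma = rc$torsions[["gamma"]], delta = rc$torsions[["delta"]],
               epsilon = rc$torsions[["epsilon"]],
               zeta = rc$torsions[["zeta"]], chi = rc$torsions[["chi"]],
               pucker_phase = rc$pucker_phase,
               pucker_amplitude = rc$pucker_amplitude,
               chi_class = rc$chi_class,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
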