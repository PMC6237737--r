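## Nucleotide chemistry tables: canonical parents, ring systems, hydrogen
## bond donors/acceptors, glycosidic atom definitions.

## Canonical parent of each supported residue name. The modified-residue
## whitelist is extensible via inst/extdata/templates/modified_residues.txt.
.builtin_parents <- c(
  A = "A", G = "G", C = "C", U = "U", T = "T",
  DA = "A", DG = "G", DC = "C", DT = "T", DU = "U",
  ADE = "A", GUA = "G", CYT = "C", URA = "U", THY = "T"
)

.modified_parent_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- tryCatch(.hg_extdata("templates", "modified_residues.txt"),
                    error = function(e) NULL)
      cache <<- if (is.null(p)) {
        data.frame(resname = character(), parent = character())
      } else {
        utils::read.table(p, header = TRUE, stringsAsFactors = FALSE,
                          comment.char = "#")
      }
    }
    cache
  }
})

#' Canonical parent base of a residue name
#'
#' Maps canonical and whitelisted modified residue names (e.g. `1MA`,
#' `1MG`, `I`, `BGM`) to their canonical parent base letter.
#'
#' @param resname Residue name(s) as authored in the coordinate file.
#' @return Character vector of `"A"`, `"G"`, `"C"`, `"U"`, `"T"`, with
#'   `NA` for unrecognized names.
#' @export
parent_base <- function(resname) {
  resname <- toupper(trimws(resname))
  out <- unname(.builtin_parents[resname])
  mod <- .modified_parent_table()
  i <- is.na(out) & resname %in% mod$resname
  out[i] <- mod$parent[match(resname[i], mod$resname)]
  out
}

#' Is a residue a purine (by canonical parent)?
#' @param resname Residue name(s).
#' @return Logical vector; `NA` maps to `FALSE`.
#' @export
is_purine <- function(resname) {
  p <- parent_base(resname)
  !is.na(p) & p %in% c("A", "G")
}

.is_pyrimidine <- function(resname) {
  p <- parent_base(resname)
  !is.na(p) & p %in% c("C", "U", "T")
}

## Base heavy atoms. Ring atoms define the stacking polygon; exocyclic
## atoms are the substituents included in the "with exocyclic" mode.
.base_ring_atoms <- list(
  pur = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  pyr = c("N1", "C2", "N3", "C4", "C5", "C6")
)

.base_exocyclic <- list(
  A = "N6",
  G = c("O6", "N2"),
  C = c("O2", "N4"),
  U = c("O2", "O4"),
  T = c("O2", "O4", "C7", "C5M")
)

#' Base heavy atom names for a residue
#' @param resname Residue name.
#' @param exocyclic Include exocyclic substituents.
#' @return Character vector of atom names (superset; match against the
#'   atoms actually present).
#' @export
base_atoms <- function(resname, exocyclic = TRUE) {
  p <- parent_base(resname)
  if (is.na(p)) stop("unknown residue name: ", resname)
  ring <- if (p %in% c("A", "G")) .base_ring_atoms$pur else .base_ring_atoms$pyr
  if (exocyclic) c(ring, .base_exocyclic[[p]]) else ring
}

## Hydrogen-bonding base atoms. Cytosine N3 appears in both lists because
## it accepts in the neutral base and donates when protonated (G-C+ HG).
.hb_donors <- list(A = "N6", G = c("N1", "N2"), C = c("N4", "N3"),
                   U = "N3", T = "N3")
.hb_acceptors <- list(A = c("N1", "N3", "N7"), G = c("O6", "N3", "N7"),
                      C = c("O2", "N3"), U = c("O2", "O4"),
                      T = c("O2", "O4"))

.glyco_atoms <- function(resname) {
  p <- parent_base(resname)
  if (is.na(p)) stop("unknown residue name: ", resname)
  if (p %in% c("A", "G")) c("O4'", "C1'", "N9", "C4")
  else c("O4'", "C1'", "N1", "C2")
}

.glyco_n <- function(resname) .glyco_atoms(resname)[3]

## Watson-Crick complements on canonical parents (U and T interchangeable).
.wc_partner <- function(pa, pb) {
  (pa == "A" & pb %in% c("T", "U")) | (pb == "A" & pa %in% c("T", "U")) |
    (pa == "G" & pb == "C") | (pb == "G" & pa == "C")
}
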