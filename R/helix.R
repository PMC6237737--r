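## Idealized duplex construction from embedded fiber-style templates.
##
## The per-form nucleotide templates live in inst/extdata/templates as
## plain text (synthetic idealized geometry constructed by
## data-raw/make_templates.py). Each template holds one strand-1
## nucleotide per base in a base-pair frame whose helical symmetry
## operation is a twist about z plus a rise along z; the strand-2 residue
## of a pair is the 180-degree rotation about y of the complementary
## base's template (the pair dyad), which also makes the two backbones
## exact dyad images.

.template_cache <- new.env(parent = emptyenv())

.load_fiber_template <- function(form) {
  key <- paste0("fiber_", form)
  if (!is.null(.template_cache[[key]])) return(.template_cache[[key]])
  path <- .hg_extdata("templates",
                      sprintf("synthetic_fiber_%s.txt", form))
  df <- utils::read.table(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  tpl <- split(df, df$resname)
  .template_cache[[key]] <- tpl
  tpl
}

.form_defaults <- list(
  A = list(twist = 32.7, rise = 2.81,
           comp = c(A = "U", U = "A", G = "C", C = "G"),
           resname = c(A = "A", U = "U", G = "G", C = "C")),
  B = list(twist = 36.0, rise = 3.38,
           comp = c(A = "T", T = "A", G = "C", C = "G"),
           resname = c(A = "DA", T = "DT", G = "DG", C = "DC"))
)

.ry180 <- function(m) {
  m[, 1] <- -m[, 1]
  m[, 3] <- -m[, 3]
  m
}

#' Build an idealized A- or B-form duplex
#'
#' Constructs a regular duplex from embedded idealized nucleotide
#' templates: form A (RNA chemistry, C3'-endo sugars; default twist 32.7
#' degrees, rise 2.81 angstrom) or form B (DNA chemistry, C2'-endo
#' sugars; twist 36.0 degrees, rise 3.38 angstrom). The complementary
#' strand is generated automatically. Strand 1 is chain A numbered 5' to
#' 3'; the antiparallel strand is chain B, also numbered 5' to 3'. The
#' 5'-terminal phosphate group of each chain is omitted. Output is
#' deterministic: identical specs give identical structures.
#'
#' @param sequence Strand-1 sequence, 5' to 3'. Alphabet `ACGU` for form
#'   A, `ACGT` for form B; length at least 2.
#' @param form `"A"` or `"B"`.
#' @param twist,rise Optional step-parameter overrides (degrees,
#'   angstrom).
#' @return A [nastructure()] of the duplex.
#' @examples
#' hx <- build_ideal_helix("GCGAUC", form = "A")
#' torsion_table(hx)$chi_class
#' @export
build_ideal_helix <- function(sequence, form = c("B", "A"), twist = NULL,
                              rise = NULL) {
  form <- match.arg(form)
  fd <- .form_defaults[[form]]
  twist <- twist %||% fd$twist
  rise <- rise %||% fd$rise
  bases <- .split_seq(sequence)
  if (length(bases) < 2)
    stop("sequence must have length >= 2")
  bad <- setdiff(bases, names(fd$comp))
  if (length(bad))
    stop("invalid base(s) for form ", form, ": ",
         paste(unique(bad), collapse = ", "))
  tpl <- .load_fiber_template(form)
  n <- length(bases)
  comp <- fd$comp[bases]

  rows <- list()
  emit <- function(chain, resno, resname, df, pair_idx, flip) {
    xyz <- as.matrix(df[, c("x", "y", "z")])
    if (flip) xyz <- .ry180(xyz)
    Rm <- .rot_z(twist * pair_idx)
    xyz <- t(Rm %*% t(xyz))
    xyz[, 3] <- xyz[, 3] + rise * pair_idx
    keep <- rep(TRUE, nrow(df))
    if (resno == 1)  # 5'-terminal residue: no phosphate group
      keep <- !(df$atom %in% c("P", "OP1", "OP2"))
    data.frame(chain = chain, resno = resno, icode = "",
               resname = resname, atom = df$atom[keep],
               x = xyz[keep, 1], y = xyz[keep, 2], z = xyz[keep, 3],
               occ = 1, element = df$element[keep],
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    rn <- fd$resname[[bases[i]]]
    rows[[length(rows) + 1L]] <- emit("A", i, rn, tpl[[rn]], i - 1L, FALSE)
  }
  for (k in seq_len(n)) {    # chain B residue k sits at pair n - k
    pair_idx <- n - k
    rn <- fd$resname[[comp[pair_idx + 1L]]]
    rows[[length(rows) + 1L]] <- emit("B", k, rn, tpl[[rn]], pair_idx, TRUE)
  }
  nastructure(do.call(rbind, rows), id = sprintf("ideal_%s_%s", form,
                                                 paste(bases, collapse = "")))
}

#' Pair partner table of an ideal duplex
#'
#' For a duplex built by [build_ideal_helix()], returns the residue
#' selectors of each base pair (chain A position i pairs chain B position
#' n + 1 - i).
#'
#' @param structure A duplex from [build_ideal_helix()].
#' @return Data frame with columns `i`, `j` of `"chain:resno"` selectors.
#' @export
helix_pairs <- function(structure) {
  rt <- residues(structure)
  n <- sum(rt$chain == "A")
  data.frame(i = paste0("A:", seq_len(n)),
             j = paste0("B:", n + 1L - seq_len(n)),
             stringsAsFactors = FALSE)
}

#' Flip a purine base about its glycosidic bond
#'
#' Rotates the base atoms of the selected purine 180 degrees about the
#' C1'-N9 axis, converting anti to syn (and back: the operation is an
#' exact involution). Sugar and backbone atoms are untouched.
#'
#' @param structure A [nastructure()].
#' @param residue `"chain:resno"` selector of a purine residue.
#' @return The modified structure.
#' @export
syn_flip <- function(structure, residue) {
  sel <- .parse_resid(residue)
  res <- .res_atoms(structure, sel$chain, sel$resno, sel$icode)
  if (!nrow(res)) stop("residue not found: ", residue)
  if (!is_purine(res$resname[1]))
    stop("syn_flip requires a purine; ", residue, " is ",
         res$resname[1])
  c1 <- .atom_xyz(res, "C1'")
  n9 <- .atom_xyz(res, "N9")
  if (is.null(c1) || is.null(n9))
    stop("syn_flip: C1' or N9 missing in ", residue)
  Rm <- .rot_axis(n9 - c1, 180)
  batoms <- setdiff(intersect(base_atoms(res$resname[1]), res$atom), "N9")
  a <- structure$atoms
  idx <- which(a$chain == sel$chain & a$resno == sel$resno &
                 a$icode == sel$icode & a$atom %in% batoms)
  xyz <- as.matrix(a[idx, c("x", "y", "z")])
  xyz <- sweep(t(Rm %*% t(sweep(xyz, 2, n9))), 2, n9, "+")
  a[idx, c("x", "y", "z")] <- xyz
  structure$atoms <- a
  structure
}

#' Replace a base with another canonical base in place
#'
#' Swaps the base moiety of a residue for the template base of
#' `new_base`, aligned on the existing glycosidic frame (N position,
#' N-C1' direction and base face). Used to create mismatches in ideal
#' duplexes, e.g. mutating a C to an anti G before Hoogsteen placement of
#' a G-G template.
#'
#' @param structure A [nastructure()].
#' @param residue `"chain:resno"` selector.
#' @param new_base One of `"A"`, `"G"`, `"C"`, `"U"`, `"T"`.
#' @param form Template form supplying the new base geometry (`"A"` or
#'   `"B"`); defaults to the chemistry matching `new_base`.
#' @return The modified structure (residue renamed to the canonical name
#'   of `new_base` in the template chemistry).
#' @export
mutate_base <- function(structure, residue, new_base,
                        form = if (new_base %in% c("U")) "A" else "B") {
  sel <- .parse_resid(residue)
  res <- .res_atoms(structure, sel$chain, sel$resno, sel$icode)
  if (!nrow(res)) stop("residue not found: ", residue)
  old_rn <- res$resname[1]
  tpl <- .load_fiber_template(form)
  new_rn <- .form_defaults[[form]]$resname[[new_base]]
  tdf <- tpl[[new_rn]]

  frame_of <- function(c1, n, ref) {
    ex <- .vunit(c1 - n)
    ez <- .vunit(.vcross(ex, ref - n))
    cbind(ex, .vcross(ez, ex), ez)
  }
  ref_atom <- function(rn) if (is_purine(rn)) "C4" else "C2"
  # old glycosidic frame
  c1_o <- .atom_xyz(res, "C1'")
  n_o <- .atom_xyz(res, .glyco_n(old_rn))
  r_o <- .atom_xyz(res, ref_atom(old_rn))
  if (is.null(c1_o) || is.null(n_o) || is.null(r_o))
    stop("mutate_base: glycosidic frame atoms missing in ", residue)
  Fo <- frame_of(c1_o, n_o, r_o)
  # template glycosidic frame
  t_xyz <- function(nm) as.numeric(tdf[match(nm, tdf$atom),
                                       c("x", "y", "z")])
  Fn <- frame_of(t_xyz("C1'"), t_xyz(.glyco_n(new_rn)),
                 t_xyz(ref_atom(new_rn)))
  Rm <- Fo %*% t(Fn)
  shift <- n_o - as.numeric(Rm %*% t_xyz(.glyco_n(new_rn)))

  new_batoms <- intersect(base_atoms(new_rn), tdf$atom)
  bxyz <- as.matrix(tdf[match(new_batoms, tdf$atom), c("x", "y", "z")])
  bxyz <- t(Rm %*% t(bxyz)) + matrix(shift, length(new_batoms), 3,
                                     byrow = TRUE)
  a <- structure$atoms
  drop_idx <- which(a$chain == sel$chain & a$resno == sel$resno &
                      a$icode == sel$icode &
                      a$atom %in% base_atoms(old_rn))
  keep <- a[-drop_idx, , drop = FALSE]
  add <- data.frame(chain = sel$chain, resno = sel$resno,
                    icode = sel$icode, resname = new_rn,
                    atom = new_batoms, x = bxyz[, 1], y = bxyz[, 2],
                    z = bxyz[, 3], occ = 1,
                    element = substr(new_batoms, 1, 1),
                    stringsAsFactors = FALSE)
  keep$resname[keep$chain == sel$chain & keep$resno == sel$resno &
                 keep$icode == sel$icode] <- new_rn
  ## reinsert keeping residue order: append base atoms after the sugar
  pos <- which(keep$chain == sel$chain & keep$resno == sel$resno &
                 keep$icode == sel$icode)
  at <- max(pos)
  out <- rbind(keep[seq_len(at), , drop = FALSE], add,
               if (at < nrow(keep)) keep[(at + 1):nrow(keep), ,
                                         drop = FALSE])
  nastructure(out, resolution = structure$resolution, id = structure$id)
}

#' Load a packaged Hoogsteen base-pair template
#'
#' @param name `"AT"`, `"AU"`, `"GC"` or `"GG"`; the syn purine is chain
#'   A, the partner chain B.
#' @return A [nastructure()] of the two-residue template pair.
#' @export
hg_template <- function(name = c("AT", "AU", "GC", "GG")) {
  name <- match.arg(name)
  form <- if (name %in% c("AU", "GC")) "A" else "B"
  path <- .hg_extdata("templates",
                      sprintf("synthetic_hg_%s_%s.txt", name, form))
  df <- utils::read.table(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  df$icode <- ""
  df$occ <- 1
  nastructure(df[, c("chain", "resno", "icode", "resname", "atom",
                     "x", "y", "z", "occ", "element")],
              id = paste0("hg_", name))
}

#' Install a Hoogsteen pair by template superposition
#'
#' Superposes a Hoogsteen pair template onto a target base pair by
#' least squares over the matched base heavy atoms of both residues
#' (the target purine is flipped syn first when still anti), then
#' installs the template geometry. With `full_residues = TRUE` (default)
#' both complete nucleotides are replaced by the transformed template
#' residues, so the constricted C1'-C1' distance and Hoogsteen hydrogen
#' bonds of the template carry over to the product; with
#' `full_residues = FALSE` only the base atoms are swapped and the
#' sugar-phosphate backbone keeps its original (e.g. Watson-Crick
#' spread) geometry, as a starting point for subsequent relaxation.
#' Base identities (canonical parents, modifications stripped) must
#' match between template and target.
#'
#' @param structure A [nastructure()].
#' @param i Selector of the residue to become the syn purine.
#' @param j Selector of its pairing partner.
#' @param template A two-residue template from [hg_template()] (chain A =
#'   syn purine) or a compatible [nastructure()].
#' @param full_residues Replace the whole nucleotides (default) or only
#'   the base moieties.
#' @return The modified structure, with attribute `"superposition_rmsd"`.
#' @export
hg_place <- function(structure, i, j, template, full_residues = TRUE) {
  si <- .parse_resid(i)
  sj <- .parse_resid(j)
  ri <- .res_atoms(structure, si$chain, si$resno, si$icode)
  rj <- .res_atoms(structure, sj$chain, sj$resno, sj$icode)
  if (!nrow(ri) || !nrow(rj)) stop("hg_place: target residues not found")
  tr <- residues(template)
  ti <- .res_atoms(template, tr$chain[1], tr$resno[1], tr$icode[1])
  tj <- .res_atoms(template, tr$chain[2], tr$resno[2], tr$icode[2])
  if (!identical(parent_base(ti$resname[1]), parent_base(ri$resname[1])) ||
      !identical(parent_base(tj$resname[1]), parent_base(rj$resname[1])))
    stop("hg_place: base identity mismatch (template ",
         parent_base(ti$resname[1]), "-", parent_base(tj$resname[1]),
         ", target ", parent_base(ri$resname[1]), "-",
         parent_base(rj$resname[1]), ")")

  ## ensure the target purine is syn before superposing
  chi <- .residue_chi(structure, si)
  if (!identical(classify_glycosidic(chi), "syn")) {
    structure <- syn_flip(structure, i)
    ri <- .res_atoms(structure, si$chain, si$resno, si$icode)
  }

  match_set <- function(tres, res) {
    nm <- intersect(intersect(base_atoms(tres$resname[1]), tres$atom),
                    res$atom)
    list(nm = nm,
         t = as.matrix(tres[match(nm, tres$atom), c("x", "y", "z")]),
         s = as.matrix(res[match(nm, res$atom), c("x", "y", "z")]))
  }
  mi <- match_set(ti, ri)
  mj <- match_set(tj, rj)
  if (nrow(mi$t) + nrow(mj$t) < 3)
    stop("hg_place: too few matched base atoms for superposition")
  sup <- superpose(rbind(mi$t, mj$t), rbind(mi$s, mj$s))

  replace_base <- function(a, sel, tres) {
    nm <- if (full_residues) tres$atom
          else intersect(base_atoms(tres$resname[1]), tres$atom)
    txyz <- sup$transform(as.matrix(tres[match(nm, tres$atom),
                                         c("x", "y", "z")]))
    idx <- which(a$chain == sel$chain & a$resno == sel$resno &
                   a$icode == sel$icode & a$atom %in% nm)
    ## drop target base atoms not present in the template (e.g. extra
    ## substituents) and add any template atoms missing from the target
    have <- a$atom[idx]
    for (k in seq_along(nm)) {
      w <- idx[match(nm[k], have)]
      if (!is.na(w)) {
        a[w, c("x", "y", "z")] <- txyz[k, ]
      } else {
        new <- a[idx[1], , drop = FALSE]
        new$atom <- nm[k]
        new$element <- substr(nm[k], 1, 1)
        new[, c("x", "y", "z")] <- txyz[k, , drop = FALSE]
        a <- rbind(a, new)
      }
    }
    a
  }
  a <- structure$atoms
  a <- replace_base(a, si, ti)
  a <- replace_base(a, sj, tj)
  out <- nastructure(a, resolution = structure$resolution,
                     id = structure$id)
  attr(out, "superposition_rmsd") <- sup$rmsd
  out
}
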