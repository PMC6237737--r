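#' Load a nearest-neighbor parameter set
#'
#' DNA: Watson-Crick doublets from the unified 1998 set with G.G/T.T
#' single-internal-mismatch doublets; mismatches are modeled as doublet
#' pairs (`mismatch_model = "doublet"`). RNA: Watson-Crick doublets from
#' the 1998 set with U.U/G.G mismatches as Turner-2004 1x1 internal
#' loops (`mismatch_model = "loop11"`), since RNA internal-mismatch
#' energetics are published as loop terms rather than separable
#' doublets. Tables are packaged plain-text resources with source
#' citations in their headers.
#'
#' @param alphabet `"DNA"` or `"RNA"`.
#' @return Object of class `"nn_params"`.
#' @export
nn_params <- function(alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  rd <- function(f) utils::read.table(.hg_extdata("nn", f), header = TRUE,
                                      sep = "\t", comment.char = "#",
                                      stringsAsFactors = FALSE)
  if (alphabet == "DNA") {
    wc <- rd("dna_nn_santalucia1998.tsv")
    mm <- rd("dna_mm_peyret1999.tsv")
    tab <- rbind(wc, mm)
    loop11 <- NULL
  } else {
    tab <- rd("rna_nn_xia1998.tsv")
    loop11 <- rd("rna_loop11_turner2004.tsv")
    loop11$dS <- (loop11$dH - loop11$dG37) / 310.15 * 1000
  }
  doublets <- tab[!tab$doublet %in% c("init", "init_AT", "init_GC",
                                      "sym", "term_AU"), ]
  special <- tab[tab$doublet %in% c("init", "init_AT", "init_GC",
                                    "sym", "term_AU"), ]
  structure(list(alphabet = alphabet,
                 doublets = doublets,
                 special = special,
                 loop11 = loop11,
                 mismatch_model = if (alphabet == "DNA") "doublet"
                                  else "loop11",
                 reference_Na = 1.0,
                 provenance = if (alphabet == "DNA")
                   "SantaLucia 1998 unified WC + Peyret 1999 G.G/T.T"
                 else "Xia 1998 WC + Turner 2004 1x1 internal loops"),
            class = "nn_params")
}

#' @export
print.nn_params <- function(x, ...) {
  cat(sprintf("%s nearest-neighbor parameter set (%s)\n", x$alphabet,
              x$provenance))
  cat(sprintf("  %d doublets; mismatch model: %s\n", nrow(x$doublets),
              x$mismatch_model))
  invisible(x)
}

.nn_lookup <- function(params, top2, bot2) {
  key <- paste0(top2, "/", bot2)
  flip <- paste0(rev(.split_seq(bot2)), collapse = "")
  flip <- paste0(flip, "/",
                 paste0(rev(.split_seq(top2)), collapse = ""))
  d <- params$doublets
  i <- match(key, d$doublet)
  if (is.na(i)) i <- match(flip, d$doublet)
  if (is.na(i))
    stop("missing nearest-neighbor parameter for doublet ", key)
  c(dH = d$dH[i], dS = d$dS[i])
}

.nn_special <- function(params, what) {
  s <- params$special
  i <- match(what, s$doublet)
  if (is.na(i)) return(c(dH = 0, dS = 0))
  c(dH = s$dH[i], dS = s$dS[i])
}

.loop11_lookup <- function(params, x5, y3, mm) {
  l <- params$loop11
  i <- which(l$mismatch == paste0(mm, collapse = "") & l$x5 == x5 &
               l$y3 == y3)
  if (!length(i))
    stop("missing 1x1 loop parameter for ", x5, "-",
         paste(mm, collapse = "."), "-", y3)
  c(dH = l$dH[i], dS = l$dS[i])
}

## sodium entropy correction (applied to DNA): 0.368 * phosphates/2 *
## ln[Na+] cal/mol/K with phosphates = 2*(L-1); zero at the 1 M
## reference condition. No correction is defined for the RNA set.
.salt_dS <- function(params, L, Na) {
  if (params$alphabet != "DNA" || Na == params$reference_Na) return(0)
  0.368 * (L - 1) * log(Na)
}

#' Duplex free energy under the nearest-neighbor model
#'
#' Sums stacked-doublet enthalpies and entropies along an aligned duplex
#' (at most one internal mismatch), applies the sodium entropy
#' correction (DNA), optionally adds initiation/symmetry terms, and
#' returns `dG = dH - T_eval * dS`.
#'
#' @param top Top strand, 5' to 3'.
#' @param bottom Bottom strand aligned with `top` (i.e. written 3' to
#'   5'), same length.
#' @param params An [nn_params()].
#' @param Na Sodium concentration, mol/L.
#' @param T_eval Evaluation temperature, kelvin.
#' @param initiation Include helix initiation (and terminal/symmetry)
#'   terms; set `FALSE` to mimic a mismatch embedded in a longer
#'   non-palindromic duplex.
#' @return List with `dG`, `dH`, `dS` (kcal/mol, kcal/mol, cal/mol/K)
#'   and the mismatch position (`NA` if none).
#' @export
duplex_dg <- function(top, bottom, params, Na = 1.0, T_eval = 298.15,
                      initiation = TRUE) {
  tb <- .split_seq(top)
  bb <- .split_seq(bottom)
  if (!length(tb)) stop("empty sequence")
  if (length(tb) != length(bb)) stop("strands must have equal length")
  if (length(tb) < 2) stop("duplex must have at least 2 base pairs")
  comp <- .complement(tb, params$alphabet)
  mmpos <- which(bb != comp)
  if (length(mmpos) > 1)
    stop("at most one internal mismatch is supported (found ",
         length(mmpos), ")")
  if (length(mmpos) && (mmpos == 1 || mmpos == length(tb)))
    stop("the mismatch must not be terminal")
  L <- length(tb)
  dH <- 0
  dS <- 0
  for (p in seq_len(L - 1)) {
    if (params$mismatch_model == "loop11" && length(mmpos) &&
        (p == mmpos - 1 || p == mmpos)) next
    v <- .nn_lookup(params, paste0(tb[p], tb[p + 1]),
                    paste0(bb[p], bb[p + 1]))
    dH <- dH + v["dH"]
    dS <- dS + v["dS"]
  }
  if (params$mismatch_model == "loop11" && length(mmpos)) {
    v <- .loop11_lookup(params, tb[mmpos - 1], tb[mmpos + 1],
                        c(tb[mmpos], bb[mmpos]))
    dH <- dH + v["dH"]
    dS <- dS + v["dS"]
  }
  if (initiation) {
    if (params$alphabet == "DNA") {
      for (endb in c(tb[1], tb[L])) {
        v <- .nn_special(params, if (endb %in% c("A", "T")) "init_AT"
                                 else "init_GC")
        dH <- dH + v["dH"]
        dS <- dS + v["dS"]
      }
    } else {
      v <- .nn_special(params, "init")
      dH <- dH + v["dH"]
      dS <- dS + v["dS"]
      for (p in c(1, L)) {
        if (tb[p] %in% c("A", "U") && bb[p] %in% c("A", "U")) {
          v <- .nn_special(params, "term_AU")
          dH <- dH + v["dH"]
          dS <- dS + v["dS"]
        }
      }
    }
    if (identical(tb, rev(bb))) {   # self-complementary duplex
      v <- .nn_special(params, "sym")
      dH <- dH + v["dH"]
      dS <- dS + v["dS"]
    }
  }
  dS <- dS + .salt_dS(params, L, Na)
  list(dG = unname(dH - T_eval * dS / 1000),
       dH = unname(dH), dS = unname(dS),
       mismatch_position = if (length(mmpos)) mmpos else NA_integer_)
}

#' Destabilization from replacing a central Watson-Crick pair with a
#' mismatch
#'
#' `ddG = dG(duplex with mismatch) - dG(duplex with the WC pair)` for the
#' flanking context `5'-X W Y-3'` over `3'-X' M Y'-5'`. By
#' nearest-neighbor locality the result depends only on the immediate
#' flanks. Initiation terms are excluded (they cancel and the convention
#' mimics an interior position of a long duplex).
#'
#' @param x5,y3 Flanking top-strand bases (5' and 3' of the center).
#' @param central_wc Length-2 vector: the WC pair `c(top, bottom)`,
#'   e.g. `c("G", "C")`.
#' @param central_mm Length-2 vector: the mismatch `c(top, bottom)`,
#'   e.g. `c("U", "U")`.
#' @param params An [nn_params()].
#' @param Na Sodium concentration, mol/L.
#' @param T_eval Evaluation temperature, kelvin.
#' @return `ddG` in kcal/mol (positive = mismatch destabilizes).
#' @export
mismatch_ddg <- function(x5, y3, central_wc, central_mm, params,
                         Na = 0.15, T_eval = 298.15) {
  comp <- function(b) .complement(b, params$alphabet)
  top <- paste0(x5, central_wc[1], y3)
  bot_wc <- paste0(comp(x5), central_wc[2], comp(y3))
  bot_mm <- paste0(comp(x5), central_mm[2], comp(y3))
  top_mm <- paste0(x5, central_mm[1], y3)
  g_wc <- duplex_dg(top, bot_wc, params, Na, T_eval, initiation = FALSE)
  g_mm <- duplex_dg(top_mm, bot_mm, params, Na, T_eval,
                    initiation = FALSE)
  g_mm$dG - g_wc$dG
}

#' Mismatch destabilization over all 16 flanking contexts
#'
#' Enumerates every combination of Watson-Crick flanking bases around
#' the central pair and summarizes the destabilization range, as in the
#' comparison of U.U (RNA) versus T.T (DNA) substitutions of a central
#' G-C pair.
#'
#' @inheritParams mismatch_ddg
#' @return List with `table` (16 rows: `x5`, `y3`, `ddG`) and `min`,
#'   `max`, `mean`.
#' @examples
#' \donttest{
#' rna <- context_sweep(c("G", "C"), c("U", "U"), nn_params("RNA"))
#' c(rna$min, rna$max)   # destabilization range, kcal/mol
#' }
#' @export
context_sweep <- function(central_wc, central_mm, params, Na = 0.15,
                          T_eval = 298.15) {
  bases <- if (params$alphabet == "DNA") c("A", "C", "G", "T")
           else c("A", "C", "G", "U")
  grid <- expand.grid(x5 = bases, y3 = bases, stringsAsFactors = FALSE)
  grid$ddG <- vapply(seq_len(nrow(grid)), function(k)
    mismatch_ddg(grid$x5[k], grid$y3[k], central_wc, central_mm, params,
                 Na, T_eval), 0)
  list(table = grid, min = min(grid$ddG), max = max(grid$ddG),
       mean = mean(grid$ddG))
}
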