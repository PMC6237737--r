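#' Nucleic-acid structure container
#'
#' A light wrapper holding one model's atoms as a data frame with columns
#' `chain`, `resno`, `icode`, `resname`, `atom`, `x`, `y`, `z`, `occ`,
#' `element`, plus optional `resolution` (angstrom) and `id` metadata.
#'
#' @param atoms Data frame with the columns listed above.
#' @param resolution Crystallographic resolution in angstrom, or `NA`.
#' @param id Structure identifier (e.g. a PDB id), or `""`.
#' @return Object of class `"nastructure"`.
#' @export
nastructure <- function(atoms, resolution = NA_real_, id = "") {
  need <- c("chain", "resno", "icode", "resname", "atom",
            "x", "y", "z", "occ", "element")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (any(!is.finite(atoms$x)) || any(!is.finite(atoms$y)) ||
      any(!is.finite(atoms$z)))
    stop("non-finite coordinates in atom table")
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$atom)
  if (anyDuplicated(key))
    stop("duplicate (residue, atom) after altloc resolution: ",
         key[which(duplicated(key))[1]])
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, resolution = resolution,
                 id = as.character(id)),
            class = "nastructure")
}

#' @export
print.nastructure <- function(x, ...) {
  rs <- unique(paste(x$atoms$chain, x$atoms$resno, x$atoms$icode))
  cat(sprintf("nastructure%s: %d atoms, %d residues, %d chain(s)",
              if (nzchar(x$id)) paste0(" ", x$id) else "",
              nrow(x$atoms), length(rs), length(unique(x$atoms$chain))))
  if (is.finite(x$resolution))
    cat(sprintf(", resolution %.2f A", x$resolution))
  cat("\n")
  invisible(x)
}

## Keep the highest-occupancy altloc per (residue, atom); ties -> first seen.
.resolve_altloc <- function(df) {
  key <- paste(df$chain, df$resno, df$icode, df$atom)
  ord <- order(factor(key, levels = unique(key)), -df$occ,
               seq_len(nrow(df)))
  df <- df[ord, , drop = FALSE]
  df[!duplicated(paste(df$chain, df$resno, df$icode, df$atom)), ,
     drop = FALSE]
}

#' Parse a nucleic-acid coordinate file
#'
#' Reads PDB (via bio3d) or mmCIF (built-in `atom_site` reader). Only model
#' 1 is retained; for alternate locations the highest-occupancy copy wins
#' (ties resolved to the first in file). Hetero residues (modified
#' nucleotides such as m1G) are kept under their author residue names.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return A [nastructure()] object, with `resolution` filled from the
#'   header when present.
#' @export
parse_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  if (format == "pdb") .parse_pdb(path) else .parse_mmcif(path)
}

.parse_pdb <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e)
                    stop("cannot parse PDB file '", path, "': ",
                         conditionMessage(e)))
  a <- pdb$atom
  df <- data.frame(chain = ifelse(is.na(a$chain), "A", a$chain),
                   resno = a$resno,
                   icode = ifelse(is.na(a$insert), "", a$insert),
                   resname = trimws(a$resid),
                   atom = trimws(a$elety),
                   x = a$x, y = a$y, z = a$z,
                   occ = ifelse(is.na(a$o), 1, a$o),
                   element = trimws(ifelse(is.na(a$elesy) | a$elesy == "",
                                           substr(trimws(a$elety), 1, 1),
                                           a$elesy)),
                   stringsAsFactors = FALSE)
  df <- .resolve_altloc(df)
  res <- NA_real_
  hdr <- grep("^REMARK   2 RESOLUTION", readLines(path, warn = FALSE),
              value = TRUE)
  if (length(hdr)) {
    m <- regmatches(hdr[1], regexec("([0-9]+\\.[0-9]+)", hdr[1]))[[1]]
    if (length(m)) res <- as.numeric(m[1])
  }
  nastructure(df, resolution = res,
              id = sub("\\.[^.]*$", "", basename(path)))
}

## Minimal mmCIF tokenizer: whitespace-separated, honoring single/double
## quotes (enough for atom_site records).
.cif_tokens <- function(line) {
  toks <- regmatches(line,
                     gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line))[[1]]
  gsub("^['\"]|['\"]$", "", toks)
}

.parse_mmcif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ## locate the atom_site loop
  i <- grep("^\\s*_atom_site\\.", lines)
  if (!length(i))
    stop("cannot parse mmCIF file '", path,
         "': no _atom_site category found")
  start <- min(i)
  cols <- character()
  j <- start
  while (j <= length(lines) && grepl("^\\s*_atom_site\\.", lines[j])) {
    cols <- c(cols, sub("^\\s*_atom_site\\.(\\S+).*$", "\\1", lines[j]))
    j <- j + 1
  }
  rows <- list()
  while (j <= length(lines)) {
    l <- lines[j]
    if (grepl("^\\s*(#|loop_|_\\S+|data_)", l) || !nzchar(trimws(l))) break
    tk <- .cif_tokens(l)
    if (length(tk) != length(cols))
      stop("cannot parse mmCIF file '", path, "' at line ", j,
           ": expected ", length(cols), " fields, found ", length(tk))
    rows[[length(rows) + 1L]] <- tk
    j <- j + 1
  }
  m <- do.call(rbind, rows)
  colnames(m) <- cols
  get <- function(nm, alt = NULL, default = NA_character_) {
    if (nm %in% cols) m[, nm]
    else if (!is.null(alt) && alt %in% cols) m[, alt]
    else rep(default, nrow(m))
  }
  model <- get("pdbx_PDB_model_num", default = "1")
  keep <- model == model[1]
  num <- function(v) suppressWarnings(as.numeric(v))
  df <- data.frame(chain = get("auth_asym_id", "label_asym_id", "A")[keep],
                   resno = as.integer(num(get("auth_seq_id",
                                              "label_seq_id", "0")[keep])),
                   icode = ifelse(get("pdbx_PDB_ins_code",
                                      default = "?")[keep] %in% c("?", "."),
                                  "", get("pdbx_PDB_ins_code",
                                          default = "?")[keep]),
                   resname = get("auth_comp_id", "label_comp_id")[keep],
                   atom = get("auth_atom_id", "label_atom_id")[keep],
                   x = num(get("Cartn_x")[keep]),
                   y = num(get("Cartn_y")[keep]),
                   z = num(get("Cartn_z")[keep]),
                   occ = ifelse(is.na(num(get("occupancy",
                                              default = "1")[keep])), 1,
                                num(get("occupancy", default = "1")[keep])),
                   element = get("type_symbol", default = "")[keep],
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$x)))
    stop("cannot parse mmCIF file '", path, "': bad Cartn_x field")
  df <- .resolve_altloc(df)
  res <- NA_real_
  rl <- grep("_reflns\\.d_resolution_high|_refine\\.ls_d_res_high", lines,
             value = TRUE)
  if (length(rl)) {
    v <- suppressWarnings(as.numeric(.cif_tokens(rl[1])[2]))
    if (is.finite(v)) res <- v
  }
  nastructure(df, resolution = res,
              id = sub("\\.[^.]*$", "", basename(path)))
}

#' Write a structure as a PDB file
#'
#' @param structure A [nastructure()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  a <- structure$atoms
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = a$resno, resid = a$resname,
                   eleno = seq_len(nrow(a)), elety = a$atom,
                   chain = a$chain, insert = ifelse(a$icode == "", NA,
                                                   a$icode),
                   o = a$occ, b = rep(0, nrow(a)), elesy = a$element)
  invisible(path)
}

#' Residue table of a structure
#'
#' @param structure A [nastructure()].
#' @return Data frame with one row per residue (`chain`, `resno`, `icode`,
#'   `resname`) in file order.
#' @export
residues <- function(structure) {
  a <- structure$atoms
  key <- paste(a$chain, a$resno, a$icode)
  a[!duplicated(key), c("chain", "resno", "icode", "resname")]
}

## Atom lookup helpers -------------------------------------------------

.res_atoms <- function(structure, chain, resno, icode = "") {
  a <- structure$atoms
  a[a$chain == chain & a$resno == resno & a$icode == icode, , drop = FALSE]
}

.atom_xyz <- function(res_df, name) {
  i <- match(name, res_df$atom)
  if (is.na(i)) return(NULL)
  as.numeric(res_df[i, c("x", "y", "z")])
}

.res_label <- function(chain, resno, icode = "") {
  paste0(chain, ":", resno, if (nzchar(icode)) icode else "")
}

## parse "chain:resno" selections
.parse_resid <- function(id) {
  m <- regmatches(id, regexec("^([^:]+):(-?[0-9]+)([A-Za-z]?)$", id))[[1]]
  if (length(m) != 4) stop("bad residue selector '", id,
                           "'; expected chain:resno")
  list(chain = m[2], resno = as.integer(m[3]), icode = m[4])
}
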