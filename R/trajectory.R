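#' Hoogsteen classification criteria for trajectory frames
#'
#' The geometric definition of a formed Hoogsteen base pair applied per
#' frame: constricted C1'-C1' distance, syn glycosidic torsion of the
#' purine, and all required hydrogen bonds formed, with an optional
#' hydrogen-donor-acceptor angle cutoff.
#'
#' @param c1c1_max C1'-C1' upper bound, angstrom (strict `<`).
#' @param chi_range Two-element degrees interval for the syn purine chi
#'   (strict bounds).
#' @param hbond_max Donor-acceptor heavy-atom upper bound, angstrom
#'   (strict `<`).
#' @param angle_max Optional hydrogen-donor-acceptor angle upper bound in
#'   degrees (`NA` disables the criterion; 30 is the conventional value).
#' @return A list of class `"hg_criteria"`.
#' @export
hg_criteria <- function(c1c1_max = 9.5, chi_range = c(0, 90),
                        hbond_max = 3.5, angle_max = NA_real_) {
  stopifnot(c1c1_max > 0, hbond_max > 0, length(chi_range) == 2,
            chi_range[1] < chi_range[2], chi_range[1] > -180,
            chi_range[2] <= 180)
  structure(list(c1c1_max = c1c1_max, chi_range = chi_range,
                 hbond_max = hbond_max, angle_max = angle_max),
            class = "hg_criteria")
}

#' Classify trajectory frames as Hoogsteen-paired
#'
#' A frame counts as Hoogsteen when all criteria hold simultaneously:
#' `c1c1 < c1c1_max`, `chi` strictly inside `chi_range`, every required
#' hydrogen-bond distance `< hbond_max`, and (when enabled) every
#' corresponding angle `< angle_max`.
#'
#' @param frames Data frame of per-frame descriptors with columns `c1c1`,
#'   `chi`, one distance column per required hydrogen bond, and optional
#'   matching `<name>_angle` columns.
#' @param criteria An [hg_criteria()].
#' @param hbonds Character vector naming the required hydrogen-bond
#'   distance columns (default: every column ending in `_dist`).
#' @return Logical vector, one element per frame.
#' @export
classify_frames <- function(frames, criteria = hg_criteria(),
                            hbonds = NULL) {
  stopifnot(is.data.frame(frames))
  hbonds <- hbonds %||% grep("_dist$", names(frames), value = TRUE)
  need <- c("c1c1", "chi", hbonds)
  miss <- setdiff(need, names(frames))
  if (length(miss))
    stop("missing trajectory descriptor column(s): ",
         paste(miss, collapse = ", "))
  ok <- frames$c1c1 < criteria$c1c1_max &
    frames$chi > criteria$chi_range[1] &
    frames$chi < criteria$chi_range[2]
  for (hb in hbonds) ok <- ok & frames[[hb]] < criteria$hbond_max
  if (is.finite(criteria$angle_max)) {
    for (hb in hbonds) {
      ac <- sub("_dist$", "_angle", hb)
      if (ac %in% names(frames))
        ok <- ok & frames[[ac]] < criteria$angle_max
    }
  }
  ok
}

## integrated autocorrelation time of a binary/numeric series via the
## initial-positive-sequence estimator
.iact <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  v <- mean(x^2)
  if (v == 0 || n < 4) return(0)
  tau <- 0
  for (k in seq_len(n - 2)) {
    rho <- mean(x[1:(n - k)] * x[(k + 1):n]) / v
    if (rho <= 0) break
    tau <- tau + rho
  }
  tau
}

#' Occupancy of a state with autocorrelation-aware standard error
#'
#' Mean of a logical flag series with a binomial standard error computed
#' on the effective sample size `n_eff = n / (2*tau + 1)`, where `tau` is
#' the integrated autocorrelation time of the series
#' (initial-positive-sequence estimator).
#'
#' @param flags Logical (or 0/1) vector, at least one frame.
#' @return List with `occupancy`, `se`, `n`, `n_eff`, `tau`.
#' @export
occupancy <- function(flags) {
  if (!length(flags)) stop("occupancy: empty flag series")
  x <- as.numeric(flags)
  f <- mean(x)
  tau <- .iact(x)
  n_eff <- length(x) / (2 * tau + 1)
  se <- if (f == 0 || f == 1) 0 else sqrt(f * (1 - f) / n_eff)
  list(occupancy = f, se = se, n = length(x), n_eff = n_eff, tau = tau)
}

#' Two-state population free energy
#'
#' `dG = -R*T*log(f/(1-f))` in kcal/mol: positive when the state is
#' minor, zero at `f = 0.5`, antisymmetric under `f -> 1-f`.
#'
#' @param f State population in (0, 1).
#' @param T Temperature, kelvin.
#' @return Free energy, kcal/mol.
#' @examples
#' dg_from_population(0.4)    # about +0.24: minor constricted state
#' dg_from_population(0.995)  # about -3.13: stably formed state
#' @export
dg_from_population <- function(f, T = 298) {
  if (any(!is.finite(f)) || any(f <= 0) || any(f >= 1))
    stop("population must lie strictly inside (0, 1); at f = 0 or 1 ",
         "the free energy is unbounded - report a bound from 1/n instead")
  -R_KCAL * T * log(f / (1 - f))
}

#' Inverse of [dg_from_population()]
#' @param dg Free energy, kcal/mol.
#' @param T Temperature, kelvin.
#' @return Population in (0, 1).
#' @export
population_from_dg <- function(dg, T = 298) {
  stats::plogis(-dg / (R_KCAL * T))
}

#' Per-frame heavy-atom RMSD against a reference structure
#'
#' Least-squares superposed RMSD of selected atoms for each frame of a
#' coordinate series; the standard trajectory convergence diagnostic
#' (heavy atoms, terminal residues excluded).
#'
#' @param reference A [nastructure()].
#' @param frames List of coordinate matrices (n_atoms x 3, rows matching
#'   the selected reference atoms) or of [nastructure()] objects with
#'   identical atom ordering.
#' @param exclude_terminal Drop the first and last residue of every
#'   chain from the selection.
#' @param heavy_only Drop hydrogens.
#' @return Numeric vector of RMSDs (angstrom), one per frame.
#' @export
rmsd_series <- function(reference, frames, exclude_terminal = TRUE,
                        heavy_only = TRUE) {
  a <- reference$atoms
  keep <- rep(TRUE, nrow(a))
  if (heavy_only) keep <- keep & !(a$element == "H" | grepl("^H", a$atom))
  if (exclude_terminal) {
    rt <- residues(reference)
    term <- do.call(rbind, lapply(split(rt, rt$chain), function(ch)
      ch[c(1, nrow(ch)), , drop = FALSE]))
    tk <- paste(term$chain, term$resno, term$icode)
    keep <- keep & !(paste(a$chain, a$resno, a$icode) %in% tk)
  }
  ref_xyz <- as.matrix(a[keep, c("x", "y", "z")])
  vapply(frames, function(fr) {
    full <- if (inherits(fr, "nastructure"))
      as.matrix(fr$atoms[, c("x", "y", "z")])
    else as.matrix(fr)
    if (nrow(full) != nrow(a))
      stop("rmsd_series: atom count mismatch between frame and reference")
    rmsd_superposed(full[keep, , drop = FALSE], ref_xyz)
  }, 0)
}

#' Read a trajectory descriptor table
#'
#' Delimited text with a header row: one row per frame, columns `frame`,
#' `c1c1`, `chi`, `<hbond>_dist` (and optional `<hbond>_angle`).
#'
#' @param path File path.
#' @return Data frame sorted by frame index.
#' @export
read_frame_series <- function(path) {
  df <- utils::read.table(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!"frame" %in% names(df)) df$frame <- seq_len(nrow(df))
  df <- df[order(df$frame), , drop = FALSE]
  if (any(diff(df$frame) <= 0))
    stop("frame indices must be strictly increasing")
  df
}
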