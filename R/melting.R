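#' Construct a melting curve object
#'
#' Bundles an absorbance-versus-temperature trace with the metadata needed by
#' the two-state analysis: the total strand concentration and whether the
#' melting species is a bimolecular duplex or a unimolecular hairpin.
#'
#' @param temperature Numeric vector of temperatures in kelvin, strictly
#'   increasing.
#' @param absorbance Numeric vector of A260 readings (dimensionless), same
#'   length as `temperature`.
#' @param Ct Total strand concentration in mol/L. Required (positive) for
#'   `kind = "duplex"`; ignored for hairpins.
#' @param kind `"duplex"` or `"hairpin"`.
#' @param label Free-text sample label.
#' @return An object of class `"melting_curve"`: a list with elements
#'   `temperature`, `absorbance`, `Ct`, `kind`, `label`.
#' @examples
#' tr <- seq(290, 360, length.out = 100)
#' tp <- list(m_ds = -1e-4, b_ds = 0.62, m_ss = 3e-4, b_ss = 0.80,
#'            Tm = 330, dH = -55)
#' a <- absorbance_model(tp, kind = "duplex", T = tr)
#' mc <- melting_curve(tr, a, Ct = 3e-6, kind = "duplex")
#' @export
melting_curve <- function(temperature, absorbance, Ct = NA_real_,
                          kind = c("duplex", "hairpin"), label = "") {
  kind <- match.arg(kind)
  temperature <- as.numeric(temperature)
  absorbance <- as.numeric(absorbance)
  if (length(temperature) != length(absorbance))
    stop("temperature and absorbance must have equal length")
  if (length(temperature) < 8)
    stop("a melting curve needs at least 8 points")
  if (any(diff(temperature) <= 0))
    stop("temperatures must be strictly increasing")
  if (any(!is.finite(temperature)) || any(!is.finite(absorbance)))
    stop("non-finite values in melting curve")
  if (kind == "duplex" && (!is.finite(Ct) || Ct <= 0))
    stop("duplex curves require a positive total strand concentration Ct")
  structure(list(temperature = temperature, absorbance = absorbance,
                 Ct = Ct, kind = kind, label = as.character(label)),
            class = "melting_curve")
}

#' @export
print.melting_curve <- function(x, ...) {
  cat(sprintf("Melting curve%s: %d points, %.1f-%.1f K, kind = %s",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$temperature), min(x$temperature), max(x$temperature),
              x$kind))
  if (x$kind == "duplex") cat(sprintf(", Ct = %.3g M", x$Ct))
  cat("\n")
  invisible(x)
}

.check_temps <- function(T, Tm) {
  if (any(T <= 0) || any(Tm <= 0))
    stop("temperatures must be positive (kelvin)")
}

#' Duplex fraction under the two-state bimolecular melting model
#'
#' Fraction of strands in the double-stranded state at temperature `T`,
#' given the melting temperature and the enthalpy of duplex formation
#' (negative for a favorable association). With
#' \eqn{e = \exp[(1/T_m - 1/T)\,\Delta H/R]}, the fraction is
#' \deqn{f = \frac{1 + 4e - \sqrt{1 + 8e}}{4e}.}
#'
#' @param T Temperature(s), kelvin.
#' @param Tm Melting temperature, kelvin.
#' @param dH Enthalpy in kcal/mol (association convention: negative).
#' @return Fraction(s) in `[0, 1]`; exactly 0.5 at `T == Tm`.
#' @seealso [hairpin_fraction()] for the unimolecular analogue.
#' @export
duplex_fraction <- function(T, Tm, dH) {
  .check_temps(T, Tm)
  x <- (1 / Tm - 1 / T) * dH / R_KCAL
  e <- exp(x)
  f <- (1 + 4 * e - sqrt(1 + 8 * e)) / (4 * e)
  # e -> Inf limit is 1; guard overflow
  f[is.infinite(e)] <- 1
  f
}

#' Folded fraction under the two-state hairpin melting model
#'
#' Logistic form \eqn{f = e^x / (1 + e^x)} with the same exponent
#' \eqn{x = (1/T_m - 1/T)\,\Delta H/R} as [duplex_fraction()].
#'
#' @inheritParams duplex_fraction
#' @return Fraction(s) in `[0, 1]`; exactly 0.5 at `T == Tm`.
#' @export
hairpin_fraction <- function(T, Tm, dH) {
  .check_temps(T, Tm)
  x <- (1 / Tm - 1 / T) * dH / R_KCAL
  stats::plogis(x)
}

#' Two-state absorbance model with linear baselines
#'
#' Predicted A260 as a mixture of linear double- and single-stranded
#' baselines weighted by the kind-appropriate folded fraction:
#' `A260 = (m_ds*T + b_ds)*f + (m_ss*T + b_ss)*(1 - f)`.
#'
#' @param params List (or coefficient vector) with elements/names
#'   `m_ds`, `b_ds`, `m_ss`, `b_ss`, `Tm`, `dH`.
#' @param kind `"duplex"` or `"hairpin"`; selects the fraction model.
#' @param T Temperatures, kelvin.
#' @param Ct Unused by the model itself (the bimolecular fraction is
#'   parameterized by `Tm` directly); accepted for interface symmetry.
#' @return Predicted absorbance vector.
#' @export
absorbance_model <- function(params, kind = c("duplex", "hairpin"), T,
                             Ct = NA_real_) {
  kind <- match.arg(kind)
  p <- as.list(params)
  need <- c("m_ds", "b_ds", "m_ss", "b_ss", "Tm", "dH")
  if (!all(need %in% names(p)))
    stop("params must contain: ", paste(need, collapse = ", "))
  f <- switch(kind,
              duplex = duplex_fraction(T, p$Tm, p$dH),
              hairpin = hairpin_fraction(T, p$Tm, p$dH))
  (p$m_ds * T + p$b_ds) * f + (p$m_ss * T + p$b_ss) * (1 - f)
}

#' Read a melting curve from delimited text
#'
#' The format is two data columns (temperature, absorbance) preceded by
#' `# key: value` header lines carrying `kind`, `Ct` and the temperature
#' `units` (`K` or `C`).
#'
#' @param path File path.
#' @return A [melting_curve()] object.
#' @export
read_melting_curve <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", h))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- trimws(m[3])
  }
  dat <- utils::read.table(text = lines[!grepl("^#", lines) & nzchar(lines)])
  temp <- dat[[1]]
  units <- toupper(kv$units %||% "K")
  if (units == "C") temp <- temp + 273.15
  melting_curve(temp, dat[[2]],
                Ct = as.numeric(kv$Ct %||% NA),
                kind = kv$kind %||% "duplex",
                label = kv$label %||% "")
}

#' Write a melting curve as delimited text
#'
#' @param curve A [melting_curve()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_melting_curve <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# kind: %s", curve$kind),
               sprintf("# Ct: %g", curve$Ct),
               "# units: K",
               sprintf("# label: %s", curve$label)), con)
  utils::write.table(data.frame(curve$temperature, curve$absorbance),
                     con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
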