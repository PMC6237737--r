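#' Thermodynamic parameters of a melting transition
#'
#' Container for `(dH, dS, dG)` at a stated evaluation temperature, with an
#' optional one-standard-deviation uncertainty on `dG`.
#'
#' @param dH Enthalpy, kcal/mol.
#' @param dS Entropy, kcal/mol/K.
#' @param T_eval Evaluation temperature, kelvin.
#' @param sigma_dG One standard deviation of `dG`, kcal/mol (optional).
#' @param label Free-text label.
#' @return Object of class `"thermo_params"`; `dG` is computed as
#'   `dH - T_eval * dS`.
#' @export
thermo_params <- function(dH, dS, T_eval, sigma_dG = NA_real_, label = "") {
  stopifnot(is.finite(dH), is.finite(dS), is.finite(T_eval), T_eval > 0)
  structure(list(dH = dH, dS = dS, dG = dH - T_eval * dS, T_eval = T_eval,
                 sigma_dG = sigma_dG, label = as.character(label)),
            class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, ...) {
  cat(sprintf("%sdH = %.2f kcal/mol, dS = %.4f kcal/mol/K, dG(%.2f K) = %.2f",
              if (nzchar(x$label)) paste0(x$label, ": ") else "",
              x$dH, x$dS, x$T_eval, x$dG))
  if (is.finite(x$sigma_dG)) cat(sprintf(" +/- %.2f", x$sigma_dG))
  cat(" kcal/mol\n")
  invisible(x)
}

#' Thermodynamic parameters from a melting fit
#'
#' Converts the fitted `(Tm, dH)` into entropy and free energy. For a
#' bimolecular duplex, `dS = dH/Tm - R*ln(Ct/2)`; for a unimolecular
#' hairpin, `dS = dH/Tm`. In both cases `dG = dH - T_eval*dS` with
#' `R = 1.987e-3` kcal/mol/K.
#'
#' @param fit A `meltfit`, or any list with elements `Tm` and `dH` (kelvin,
#'   kcal/mol).
#' @param kind `"duplex"` or `"hairpin"`; defaults to the fit's own kind.
#' @param Ct Total strand concentration (mol/L); required for duplexes,
#'   ignored (with a message) for hairpins. Defaults to the fitted curve's
#'   `Ct` when available.
#' @param T_eval Evaluation temperature, kelvin.
#' @param label Label carried onto the result.
#' @return A [thermo_params()] object.
#' @export
thermo_from_fit <- function(fit, kind = NULL, Ct = NULL, T_eval = 298.15,
                            label = "") {
  if (inherits(fit, "meltfit")) {
    kind <- kind %||% fit$kind
    Ct <- Ct %||% fit$curve$Ct
    Tm <- fit$coefficients[["Tm"]]
    dH <- fit$coefficients[["dH"]]
  } else {
    p <- as.list(fit)
    Tm <- p$Tm
    dH <- p$dH
    kind <- kind %||% "duplex"
  }
  kind <- match.arg(kind, c("duplex", "hairpin"))
  if (kind == "duplex") {
    if (is.null(Ct) || !is.finite(Ct) || Ct <= 0)
      stop("duplex thermodynamics require a positive Ct")
    dS <- dH / Tm - R_KCAL * log(Ct / 2)
  } else {
    if (!is.null(Ct) && is.finite(Ct))
      message("hairpin model: supplied Ct ignored (unimolecular transition)")
    dS <- dH / Tm
  }
  thermo_params(dH, dS, T_eval, label = label)
}

#' Aggregate replicate measurements into one thermodynamic estimate
#'
#' Computes `dG` per replicate and reports the mean with the sample standard
#' deviation as `sigma_dG`, matching triplicate-measurement error reporting.
#'
#' @param params List of [thermo_params()] objects at a common `T_eval`.
#' @param label Label for the aggregate.
#' @return A [thermo_params()] with mean `dH`, `dS` and `sigma_dG` set to
#'   `sd(dG)` across replicates (`NA` for a single replicate).
#' @export
thermo_replicates <- function(params, label = "") {
  stopifnot(length(params) >= 1,
            all(vapply(params, inherits, TRUE, "thermo_params")))
  te <- vapply(params, `[[`, 0, "T_eval")
  if (diff(range(te)) > 1e-9)
    stop("replicates must share T_eval")
  dg <- vapply(params, `[[`, 0, "dG")
  out <- thermo_params(mean(vapply(params, `[[`, 0, "dH")),
                       mean(vapply(params, `[[`, 0, "dS")),
                       te[1], label = label)
  out$sigma_dG <- if (length(dg) > 1) stats::sd(dg) else NA_real_
  # mean of per-replicate dG (equals dH_bar - T dS_bar by linearity)
  out$dG <- mean(dg)
  out
}

.dg_value <- function(x) {
  if (inherits(x, "thermo_params")) c(x$dG, x$sigma_dG, x$T_eval)
  else if (inherits(x, "thermo_delta")) c(x$value, x$sigma, x$T_eval)
  else stop("operand must be thermo_params or thermo_delta")
}

#' Free-energy difference with error propagation
#'
#' `ddg(a, b)` forms `a - b` on the free-energy scale, propagating
#' independent one-standard-deviation errors as
#' `sigma = sqrt(sigma_a^2 + sigma_b^2)`. Operands may be
#' [thermo_params()] objects or previously formed deltas, enabling
#' double-difference bookkeeping such as
#' \eqn{\Delta\Delta G_{constrict} = \Delta G^{RNA} - \Delta G^{DNA}}.
#'
#' @param a,b Operands (`thermo_params` or `thermo_delta`) at the same
#'   `T_eval`.
#' @param label Name for the difference (e.g. `"ddG_constrict"`).
#' @return Object of class `"thermo_delta"` with `value`, `sigma`,
#'   `T_eval`, `label` and `operands`.
#' @examples
#' rna <- thermo_delta_value(0.3, label = "dG_constrict_RNA")
#' dna <- thermo_delta_value(-3.1, label = "dG_constrict_DNA")
#' ddg(rna, dna, label = "ddG_constrict")$value  # 3.4
#' @export
ddg <- function(a, b, label = "") {
  va <- .dg_value(a)
  vb <- .dg_value(b)
  if (is.finite(va[3]) && is.finite(vb[3]) && abs(va[3] - vb[3]) > 1e-9)
    stop("operands evaluated at different temperatures (",
         va[3], " vs ", vb[3], " K)")
  sig <- if (is.finite(va[2]) && is.finite(vb[2]))
    sqrt(va[2]^2 + vb[2]^2) else NA_real_
  structure(list(value = va[1] - vb[1], sigma = sig,
                 T_eval = if (is.finite(va[3])) va[3] else vb[3],
                 label = as.character(label),
                 operands = list(a = a, b = b)),
            class = "thermo_delta")
}

#' Wrap a literature or externally derived free-energy value as a delta
#'
#' Convenience constructor for feeding scalar free-energy values (for
#' example per-system population free energies) into the [ddg()] ledger.
#'
#' @param value Free energy, kcal/mol.
#' @param sigma Optional one-standard-deviation error.
#' @param T_eval Evaluation temperature (kelvin), `NA` when not applicable.
#' @param label Label.
#' @return A `"thermo_delta"` object with empty operands.
#' @export
thermo_delta_value <- function(value, sigma = NA_real_, T_eval = NA_real_,
                               label = "") {
  structure(list(value = value, sigma = sigma, T_eval = T_eval,
                 label = as.character(label), operands = list()),
            class = "thermo_delta")
}

#' @export
print.thermo_delta <- function(x, ...) {
  cat(sprintf("%s = %.3g", if (nzchar(x$label)) x$label else "ddG", x$value))
  if (is.finite(x$sigma)) cat(sprintf(" +/- %.3g", x$sigma))
  cat(" kcal/mol\n")
  invisible(x)
}

.check_interval <- function(x, what) {
  if (length(x) != 2 || any(!is.finite(x)) || x[1] > x[2])
    stop(what, " must be a finite [lo, hi] interval with lo <= hi")
  as.numeric(x)
}

#' Interval difference of free-energy ranges
#'
#' For ranges `[lo_a, hi_a]` and `[lo_b, hi_b]` the difference interval is
#' `[lo_a - hi_b, hi_a - lo_b]`, reproducing range arithmetic such as
#' (5.8-7) - (3-4.3) = 1.5-4 kcal/mol.
#'
#' @param range_a,range_b Numeric length-2 `[lo, hi]` vectors, kcal/mol.
#' @return Numeric `[lo, hi]` difference interval.
#' @seealso [interval_sum()] for combining independent penalties.
#' @export
interval_ddg <- function(range_a, range_b) {
  a <- .check_interval(range_a, "range_a")
  b <- .check_interval(range_b, "range_b")
  c(a[1] - b[2], a[2] - b[1])
}

#' Interval sum of free-energy ranges
#'
#' `[lo_a + lo_b, hi_a + hi_b]`; used to combine independent energetic
#' penalties into a total range.
#'
#' @inheritParams interval_ddg
#' @return Numeric `[lo, hi]` sum interval.
#' @export
interval_sum <- function(range_a, range_b) {
  a <- .check_interval(range_a, "range_a")
  b <- .check_interval(range_b, "range_b")
  c(a[1] + b[1], a[2] + b[2])
}

#' Combined chemical-shift perturbation
#'
#' Combines proton and carbon chemical-shift perturbations from a 2D CH
#' HSQC as \eqn{\Delta\omega = \sqrt{\Delta\omega_H^2 +
#' (\gamma_{ratio}\,\Delta\omega_C)^2}} and flags values at or above the
#' 0.4 ppm significance threshold. The default scaling factor is the
#' gyromagnetic-ratio quotient \eqn{\gamma_H/\gamma_C = 3.976}; set
#' `inverse_ratio = TRUE` to use \eqn{\gamma_C/\gamma_H} instead (the
#' common down-weighting convention).
#'
#' @param dwH Proton perturbation, ppm.
#' @param dwC Carbon perturbation, ppm.
#' @param gamma_ratio Scaling applied to the carbon term.
#' @param inverse_ratio If `TRUE`, use `1/gamma_ratio`.
#' @param threshold Significance threshold, ppm.
#' @return Object of class `"shift_perturbation"` with fields `dwH`, `dwC`,
#'   `gamma_ratio`, `dw` and `significant`. Vector inputs give vector
#'   `dw`/`significant`.
#' @export
csp <- function(dwH, dwC, gamma_ratio = 3.976, inverse_ratio = FALSE,
                threshold = 0.4) {
  stopifnot(all(is.finite(dwH)), all(is.finite(dwC)),
            is.finite(gamma_ratio), gamma_ratio > 0)
  g <- if (inverse_ratio) 1 / gamma_ratio else gamma_ratio
  dw <- sqrt(dwH^2 + (g * dwC)^2)
  structure(list(dwH = dwH, dwC = dwC, gamma_ratio = g, dw = dw,
                 significant = dw >= threshold),
            class = "shift_perturbation")
}

#' @export
print.shift_perturbation <- function(x, ...) {
  cat(sprintf("CSP: dw = %s ppm (%s)\n",
              paste(signif(x$dw, 4), collapse = ", "),
              paste(ifelse(x$significant, "significant", "ns"),
                    collapse = ", ")))
  invisible(x)
}
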