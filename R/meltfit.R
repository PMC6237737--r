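#' Fit the two-state melting model to an absorbance curve
#'
#' Least-squares estimation of the six two-state parameters (`m_ds`, `b_ds`,
#' `m_ss`, `b_ss`, `Tm`, `dH`) from an A260-versus-temperature trace, using
#' the linear-baseline mixture model of [absorbance_model()]. This is the
#' package's central fitted-model constructor; the returned object supports
#' `print`, `summary`, `coef`, `vcov`, `predict`, `residuals`, `fitted`,
#' `plot` and `simulate` methods.
#'
#' Starting values are deterministic: baselines from ordinary least squares
#' on the first and last 15% of points, `Tm` from the temperature of the
#' steepest absorbance change (on the baseline-normalized curve), and
#' `dH = -50` kcal/mol unless overridden.
#'
#' @param curve A [melting_curve()] object.
#' @param start Optional named list overriding any of the six starting
#'   values.
#' @param control Passed to [minpack.lm::nls.lm.control()]; default raises
#'   the iteration cap.
#' @return An object of class `"meltfit"` with elements `coefficients`
#'   (named numeric of the six parameters), `vcov`, `curve`, `kind`,
#'   `residual_rms`, `convergence` and the underlying `fit`.
#' @examples
#' sp <- sim_spec_melt(Tm = 330, dH = -55, noise_sd = 0)
#' fit <- fit_melting(synth_melting_curve(sp, seed = 1))
#' coef(fit)[c("Tm", "dH")]
#' @export
fit_melting <- function(curve, start = NULL, control = NULL) {
  stopifnot(inherits(curve, "melting_curve"))
  T <- curve$temperature
  A <- curve$absorbance
  n <- length(T)

  amp <- diff(range(A))
  if (amp < .Machine$double.eps^0.5)
    stop("fit_melting: curve shows no transition (constant absorbance)")
  noise0 <- stats::sd(diff(A)) / sqrt(2)
  if (is.finite(noise0) && noise0 > 0 && amp < 5 * noise0)
    warning("transition amplitude is < 5x the point-to-point noise; fit may be unreliable")

  ## deterministic initial-guess policy
  k <- max(3L, ceiling(0.15 * n))
  lo <- seq_len(k)
  hi <- seq(n - k + 1L, n)
  c_lo <- stats::coef(stats::lm(A[lo] ~ T[lo]))
  c_hi <- stats::coef(stats::lm(A[hi] ~ T[hi]))
  # folded (duplex) baseline is the low-temperature one
  s0 <- list(m_ds = unname(c_lo[2]), b_ds = unname(c_lo[1]),
             m_ss = unname(c_hi[2]), b_ss = unname(c_hi[1]))
  base_ds <- s0$m_ds * T + s0$b_ds
  base_ss <- s0$m_ss * T + s0$b_ss
  denom <- base_ss - base_ds
  frac <- (A - base_ds) / ifelse(abs(denom) < 1e-12, 1e-12, denom)
  dmid <- abs(diff(frac) / diff(T))
  s0$Tm <- (T[which.max(dmid)] + T[which.max(dmid) + 1L]) / 2
  s0$dH <- -50
  if (!is.null(start)) s0[names(start)] <- start

  ctrl <- control %||% minpack.lm::nls.lm.control(maxiter = 200)
  kind <- curve$kind
  mfun <- function(m_ds, b_ds, m_ss, b_ss, Tm, dH)
    absorbance_model(list(m_ds = m_ds, b_ds = b_ds, m_ss = m_ss,
                          b_ss = b_ss, Tm = Tm, dH = dH),
                     kind = kind, T = T)
  fit <- tryCatch(
    minpack.lm::nlsLM(A ~ mfun(m_ds, b_ds, m_ss, b_ss, Tm, dH),
                      start = s0, control = ctrl),
    error = function(e) e)
  if (inherits(fit, "error"))
    stop("fit_melting: nonlinear fit failed to converge: ",
         conditionMessage(fit),
         "\n  starting values: ",
         paste(sprintf("%s=%.4g", names(s0), unlist(s0)), collapse = ", "))

  cf <- stats::coef(fit)
  res <- stats::residuals(fit)
  rms <- sqrt(mean(res^2))
  if (!is.finite(rms)) stop("fit_melting: non-finite residuals")
  vc <- tryCatch(stats::vcov(fit), error = function(e) {
    matrix(NA_real_, 6, 6, dimnames = list(names(cf), names(cf)))
  })
  warn_tm <- cf[["Tm"]] < min(T) - 30 || cf[["Tm"]] > max(T) + 30
  if (warn_tm)
    warning(sprintf("fitted Tm (%.1f K) lies outside the data range %.1f-%.1f K by more than 30 K",
                    cf[["Tm"]], min(T), max(T)))
  structure(list(coefficients = cf, vcov = vc, curve = curve,
                 kind = curve$kind, residual_rms = rms,
                 tm_out_of_range = warn_tm,
                 convergence = fit$convInfo %||% list(), fit = fit),
            class = "meltfit")
}

#' @export
coef.meltfit <- function(object, ...) object$coefficients

#' @export
vcov.meltfit <- function(object, ...) object$vcov

#' @export
print.meltfit <- function(x, ...) {
  cat(sprintf("Two-state %s melting fit\n", x$kind))
  cat(sprintf("  Tm = %.2f K, dH = %.2f kcal/mol\n",
              x$coefficients[["Tm"]], x$coefficients[["dH"]]))
  cat(sprintf("  residual RMS = %.3g over %d points\n",
              x$residual_rms, length(x$curve$temperature)))
  invisible(x)
}

#' @export
summary.meltfit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  out <- data.frame(estimate = object$coefficients, std_error = se)
  structure(list(table = out, kind = object$kind,
                 residual_rms = object$residual_rms,
                 label = object$curve$label),
            class = "summary.meltfit")
}

#' @export
print.summary.meltfit <- function(x, ...) {
  cat(sprintf("Two-state %s melting fit%s\n", x$kind,
              if (nzchar(x$label)) paste0(" '", x$label, "'") else ""))
  print(round(x$table, 6))
  cat(sprintf("Residual RMS: %.3g\n", x$residual_rms))
  invisible(x)
}

#' @export
predict.meltfit <- function(object, newdata = NULL, ...) {
  T <- if (is.null(newdata)) object$curve$temperature
       else if (is.list(newdata)) newdata$temperature else newdata
  absorbance_model(as.list(object$coefficients), kind = object$kind, T = T)
}

#' @export
fitted.meltfit <- function(object, ...) predict(object)

#' @export
residuals.meltfit <- function(object, ...) {
  object$curve$absorbance - predict(object)
}

#' @export
plot.meltfit <- function(x, ...) {
  T <- x$curve$temperature
  graphics::plot(T, x$curve$absorbance, pch = 16, cex = 0.5,
                 xlab = "Temperature (K)", ylab = "A260",
                 main = sprintf("Two-state %s fit: Tm = %.1f K", x$kind,
                                x$coefficients[["Tm"]]), ...)
  Tg <- seq(min(T), max(T), length.out = 400)
  graphics::lines(Tg, predict(x, Tg), col = "firebrick", lwd = 2)
  p <- x$coefficients
  graphics::abline(p[["b_ds"]], p[["m_ds"]], lty = 3, col = "grey40")
  graphics::abline(p[["b_ss"]], p[["m_ss"]], lty = 3, col = "grey40")
  invisible(x)
}

#' Simulate melting curves from a fitted model
#'
#' Draws `nsim` noisy curves at the fitted parameter values, with Gaussian
#' noise at the fitted residual RMS (or `noise_sd` if given).
#'
#' @param object A `meltfit`.
#' @param nsim Number of simulated curves.
#' @param seed Optional integer seed.
#' @param noise_sd Noise standard deviation; defaults to the residual RMS.
#' @param ... Unused.
#' @return A list of [melting_curve()] objects.
#' @export
simulate.meltfit <- function(object, nsim = 1, seed = NULL,
                             noise_sd = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sdv <- noise_sd %||% object$residual_rms
  mu <- predict(object)
  T <- object$curve$temperature
  lapply(seq_len(nsim), function(i)
    melting_curve(T, mu + stats::rnorm(length(T), 0, sdv),
                  Ct = object$curve$Ct, kind = object$kind,
                  label = sprintf("sim%02d", i)))
}
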