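## Synthetic-data generators: every stage of the pipeline can run on
## inputs with known ground truth. All generators are pure functions of
## (spec, seed).

#' Simulation spec for synthetic melting curves
#'
#' @param Tm,dH True melting temperature (K) and formation enthalpy
#'   (kcal/mol, negative).
#' @param m_ds,b_ds,m_ss,b_ss Baseline slopes/intercepts (per kelvin,
#'   absorbance).
#' @param Ct Total strand concentration, mol/L.
#' @param kind `"duplex"` or `"hairpin"`.
#' @param T_range,n Temperature grid: range (K) and number of points.
#' @param noise_sd Gaussian noise standard deviation (absorbance units).
#' @return List of class `"sim_spec_melt"`.
#' @export
sim_spec_melt <- function(Tm = 330, dH = -55, m_ds = -2e-4, b_ds = 0.70,
                          m_ss = 3e-4, b_ss = 0.78, Ct = 3e-6,
                          kind = c("duplex", "hairpin"),
                          T_range = c(Tm - 35, Tm + 35), n = 120,
                          noise_sd = 0) {
  kind <- match.arg(kind)
  stopifnot(noise_sd >= 0, n >= 8, Tm > 0)
  structure(list(Tm = Tm, dH = dH, m_ds = m_ds, b_ds = b_ds, m_ss = m_ss,
                 b_ss = b_ss, Ct = Ct, kind = kind, T_range = T_range,
                 n = as.integer(n), noise_sd = noise_sd),
            class = "sim_spec_melt")
}

#' Generate a synthetic melting curve
#'
#' Evaluates the two-state absorbance model at the spec's true
#' parameters and adds Gaussian noise; reproducible under `seed`.
#'
#' @param spec A [sim_spec_melt()].
#' @param seed Integer seed.
#' @return A [melting_curve()]; the true parameters are attached as
#'   attribute `"truth"`.
#' @export
synth_melting_curve <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "sim_spec_melt"))
  T <- seq(spec$T_range[1], spec$T_range[2], length.out = spec$n)
  mu <- absorbance_model(spec, kind = spec$kind, T = T)
  noise <- if (spec$noise_sd > 0) {
    set.seed(seed)
    stats::rnorm(length(T), 0, spec$noise_sd)
  } else rep(0, length(T))
  out <- melting_curve(T, mu + noise, Ct = spec$Ct, kind = spec$kind,
                       label = sprintf("synthetic seed=%d", seed))
  attr(out, "truth") <- spec
  out
}

#' Simulation spec for synthetic two-state trajectories
#'
#' Defines a two-state (Hoogsteen-formed / open) Markov chain with a
#' stationary Hoogsteen occupancy and per-state descriptor values that
#' respectively satisfy and violate the default classification criteria.
#' The open state emulates splayed-apart bases: the C1'-C1' distance is
#' no longer constricted and the purine N7 hydrogen bond is broken,
#' while chi stays syn. Descriptor jitter is truncated at 3 standard
#' deviations and sized so state labels can never cross a classification
#' threshold.
#'
#' @param f_hg Stationary Hoogsteen occupancy in (0, 1).
#' @param switch_rate Per-frame switching propensity in (0, 1]; 1 gives
#'   an i.i.d. series, small values give long-correlated ones.
#' @param n_frames Number of frames.
#' @param hg_values,open_values Named lists of state descriptor centers
#'   (`c1c1`, `chi`, `N7_dist`, `N7_angle`).
#' @param jitter_sd Descriptor jitter standard deviation.
#' @param temperature Kelvin, carried into the series attributes.
#' @return List of class `"sim_spec_traj"`.
#' @export
sim_spec_traj <- function(f_hg = 0.4, switch_rate = 0.2, n_frames = 10000,
                          hg_values = list(c1c1 = 8.6, chi = 45,
                                           N7_dist = 2.9, N7_angle = 12),
                          open_values = list(c1c1 = 11.5, chi = 45,
                                             N7_dist = 6.0,
                                             N7_angle = 60),
                          jitter_sd = 0.12, temperature = 298) {
  stopifnot(f_hg >= 0, f_hg <= 1, switch_rate > 0, switch_rate <= 1,
            n_frames >= 1, jitter_sd >= 0)
  structure(list(f_hg = f_hg, switch_rate = switch_rate,
                 n_frames = as.integer(n_frames), hg_values = hg_values,
                 open_values = open_values, jitter_sd = jitter_sd,
                 temperature = temperature),
            class = "sim_spec_traj")
}

#' Generate a synthetic two-state trajectory descriptor series
#'
#' Simulates the hidden Hoogsteen/open state as a two-state Markov chain
#' with stationary occupancy `f_hg` (transition probabilities
#' `switch_rate * f_hg` into and `switch_rate * (1 - f_hg)` out of the
#' Hoogsteen state), then emits per-frame descriptors from the
#' state-specific centers plus truncated Gaussian jitter.
#'
#' @param spec A [sim_spec_traj()].
#' @param seed Integer seed.
#' @return Data frame with columns `frame`, `c1c1`, `chi`, `N7_dist`,
#'   `N7_angle` and the hidden `state` (`"HG"`/`"open"`); attributes
#'   `"spec"` and `"seed"` record provenance.
#' @export
synth_trajectory <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "sim_spec_traj"))
  set.seed(seed)
  n <- spec$n_frames
  f <- spec$f_hg
  state <- logical(n)
  if (f == 0) {
    # all open
  } else if (f == 1) {
    state[] <- TRUE
  } else {
    p_in <- spec$switch_rate * f        # open -> HG
    p_out <- spec$switch_rate * (1 - f) # HG -> open
    state[1] <- stats::runif(1) < f
    u <- stats::runif(n)
    for (k in 2:n) {
      state[k] <- if (state[k - 1]) u[k] >= p_out else u[k] < p_in
    }
  }
  jit <- function(m) {
    z <- stats::rnorm(m, 0, spec$jitter_sd)
    pmin(pmax(z, -3 * spec$jitter_sd), 3 * spec$jitter_sd)
  }
  pick <- function(fld) ifelse(state, spec$hg_values[[fld]],
                               spec$open_values[[fld]])
  out <- data.frame(frame = seq_len(n),
                    c1c1 = pick("c1c1") + jit(n),
                    chi = pick("chi") + jit(n) * 20,
                    N7_dist = pick("N7_dist") + jit(n),
                    N7_angle = pick("N7_angle") + jit(n) * 20,
                    state = ifelse(state, "HG", "open"),
                    stringsAsFactors = FALSE)
  attr(out, "spec") <- spec
  attr(out, "seed") <- seed
  attr(out, "temperature") <- spec$temperature
  out
}

#' Write a trajectory descriptor series as delimited text
#'
#' @param frames Data frame from [synth_trajectory()] (the hidden state
#'   column is dropped on output).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frame_series <- function(frames, path) {
  df <- frames[, setdiff(names(frames), "state"), drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  sd <- attr(frames, "seed")
  if (!is.null(sd)) writeLines(sprintf("# seed: %d", sd), con)
  utils::write.table(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
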