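test_that("both folded-fraction models give exactly 1/2 at Tm", {
  for (dH in c(-120, -60, -25, -5)) {
    for (Tm in c(300, 330, 360)) {
      expect_identical(duplex_fraction(Tm, Tm, dH), 0.5)
      expect_identical(hairpin_fraction(Tm, Tm, dH), 0.5)
    }
  }
})

test_that("duplex fraction matches its closed form and limits", {
  # frozen high-precision evaluation of the printed closed form
  expect_equal(duplex_fraction(320, 330, -60), 0.84445973024867921,
               tolerance = 1e-12)
  # folded at low temperature, unfolded at high temperature (dH < 0)
  expect_lt(abs(duplex_fraction(200, 330, -60) - 1), 1e-10)
  expect_lt(duplex_fraction(5000, 330, -60), 1e-3)
  expect_error(duplex_fraction(-5, 330, -60), "positive")
})

test_that("hairpin fraction is the logistic of the melting exponent", {
  # x = ln 3 must give 3/4: choose dH so that (1/Tm - 1/T) dH / R = ln 3
  Tm <- 340; T <- 360
  dH <- log(3) * 1.987e-3 / (1 / Tm - 1 / T)
  expect_equal(hairpin_fraction(T, Tm, dH), 0.75, tolerance = 1e-12)
  # frozen independent evaluation at extended precision
  expect_equal(hairpin_fraction(360, 340, -40), 0.035938198000952412,
               tolerance = 1e-12)
})

test_that("folded fraction is monotone in temperature for fixed dH", {
  Tg <- seq(280, 380, by = 0.5)
  for (dH in c(-80, -30)) {
    expect_true(all(diff(duplex_fraction(Tg, 330, dH)) < 0))
    expect_true(all(diff(hairpin_fraction(Tg, 330, dH)) < 0))
  }
  # sign of dH flips the direction
  expect_true(all(diff(duplex_fraction(Tg, 330, 40)) > 0))
})

test_that("absorbance model composes the baselines with the fraction", {
  p <- list(m_ds = -2e-4, b_ds = 0.7, m_ss = 3e-4, b_ss = 0.8,
            Tm = 330, dH = -55)
  Tg <- seq(290, 370, length.out = 50)
  f <- duplex_fraction(Tg, p$Tm, p$dH)
  by_hand <- (p$m_ds * Tg + p$b_ds) * f + (p$m_ss * Tg + p$b_ss) * (1 - f)
  expect_equal(absorbance_model(p, "duplex", Tg), by_hand)
  # saturated limits reduce to single baselines
  expect_equal(absorbance_model(p, "duplex", 230), p$m_ds * 230 + p$b_ds,
               tolerance = 1e-7)
  expect_equal(absorbance_model(p, "duplex", 5000),
               p$m_ss * 5000 + p$b_ss, tolerance = 1e-4)
  expect_error(absorbance_model(p, "triplex", Tg))
})

test_that("noiseless synthetic curves are recovered to 1e-6", {
  for (kind in c("duplex", "hairpin")) {
    sp <- sim_spec_melt(Tm = 328.5, dH = -62, kind = kind, noise_sd = 0)
    fit <- fit_melting(synth_melting_curve(sp, seed = 3))
    cf <- coef(fit)
    truth <- c(m_ds = sp$m_ds, b_ds = sp$b_ds, m_ss = sp$m_ss,
               b_ss = sp$b_ss, Tm = sp$Tm, dH = sp$dH)
    expect_equal(cf[names(truth)], truth, tolerance = 1e-6)
    expect_lt(fit$residual_rms, 1e-8)
  }
})

test_that("constant absorbance (no transition) fails loudly", {
  mc <- melting_curve(seq(300, 360, length.out = 40), rep(0.7, 40),
                      Ct = 3e-6, kind = "duplex")
  expect_error(fit_melting(mc), "no transition")
})

test_that("parameter recovery at 0.2% amplitude noise is unbiased", {
  sp0 <- sim_spec_melt(Tm = 330, dH = -55, noise_sd = 0)
  amp <- diff(range(synth_melting_curve(sp0, seed = 1)$absorbance))
  sp <- sim_spec_melt(Tm = 330, dH = -55, noise_sd = 0.002 * amp)
  tm_err <- dh_rel <- numeric(50)
  for (s in 1:50) {
    cf <- coef(fit_melting(synth_melting_curve(sp, seed = s)))
    tm_err[s] <- cf[["Tm"]] - 330
    dh_rel[s] <- (cf[["dH"]] - (-55)) / -55
  }
  expect_lt(stats::median(abs(tm_err)), 0.5)
  expect_lt(stats::median(abs(dh_rel)), 0.05)
  expect_lt(abs(mean(tm_err)), 0.1)       # bias
  expect_lt(abs(mean(dh_rel)), 0.02)
})

test_that("melting curves round-trip through delimited text", {
  sp <- sim_spec_melt(Tm = 325, dH = -48, noise_sd = 1e-3)
  mc <- synth_melting_curve(sp, seed = 11)
  path <- withr::local_tempfile(fileext = ".txt")
  write_melting_curve(mc, path)
  back <- read_melting_curve(path)
  expect_equal(back$temperature, mc$temperature, tolerance = 1e-8)
  expect_equal(back$absorbance, mc$absorbance, tolerance = 1e-8)
  expect_identical(back$kind, "duplex")
  expect_equal(back$Ct, mc$Ct)
})

test_that("meltfit methods are coherent", {
  sp <- sim_spec_melt(Tm = 330, dH = -55, noise_sd = 5e-4)
  fit <- fit_melting(synth_melting_curve(sp, seed = 2))
  expect_s3_class(fit, "meltfit")
  expect_equal(residuals(fit),
               fit$curve$absorbance - predict(fit))
  expect_equal(dim(vcov(fit)), c(6L, 6L))
  sm <- summary(fit)
  expect_true(all(is.finite(sm$table$std_error)))
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "melting_curve")
  # determinism of the whole pipeline under a fixed seed
  fit2 <- fit_melting(synth_melting_curve(sp, seed = 2))
  expect_identical(coef(fit), coef(fit2))
})

test_that("malformed curves are rejected", {
  expect_error(melting_curve(1:10, 1:9), "equal length")
  expect_error(melting_curve(c(1:4, 4, 5:9), rep(1, 10) + 1:10 / 10),
               "increasing")
  expect_error(melting_curve(301:310, rnorm(10), Ct = -1,
                             kind = "duplex"), "Ct")
  expect_error(melting_curve(301:306, rnorm(6)), "at least 8")
})
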