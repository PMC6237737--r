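test_that("frame classification applies every criterion strictly", {
  fr <- data.frame(c1c1 = c(9.6, 8.8, 8.8, 8.8, 8.8),
                   chi = c(45, 45, 95, 45, 45),
                   N7_dist = c(2.9, 2.9, 2.9, 3.6, 2.9),
                   N7_angle = c(10, 10, 10, 10, 40))
  expect_identical(classify_frames(fr),
                   c(FALSE, TRUE, FALSE, FALSE, TRUE))
  # enabling the angle cutoff can only shrink the set
  with_angle <- classify_frames(fr, hg_criteria(angle_max = 30))
  expect_identical(with_angle, c(FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_true(all(with_angle <= classify_frames(fr)))
  expect_error(classify_frames(fr[, -1]), "c1c1")
})

test_that("loosening any threshold never removes frames from the set", {
  tr <- synth_trajectory(sim_spec_traj(f_hg = 0.5, n_frames = 2000,
                                       jitter_sd = 0.3), seed = 21)
  base <- classify_frames(tr, hg_criteria())
  looser <- list(hg_criteria(c1c1_max = 10.5),
                 hg_criteria(hbond_max = 4.0),
                 hg_criteria(chi_range = c(-10, 100)))
  for (cr in looser) {
    expect_true(all(base <= classify_frames(tr, cr)))
  }
})

test_that("occupancy handles degenerate and alternating series", {
  all_true <- occupancy(rep(TRUE, 100))
  expect_identical(all_true$occupancy, 1)
  expect_identical(all_true$se, 0)
  expect_equal(occupancy(rep(c(TRUE, FALSE), 50))$occupancy, 0.5)
  expect_error(occupancy(logical(0)), "empty")
})

test_that("synthetic trajectories recover the construction fraction", {
  spec <- sim_spec_traj(f_hg = 0.4, n_frames = 10000)
  tr <- synth_trajectory(spec, seed = 5)
  flags <- classify_frames(tr)
  # classification equals the hidden state exactly by construction
  expect_identical(flags, tr$state == "HG")
  oc <- occupancy(flags)
  expect_lt(abs(oc$occupancy - 0.4), 3 * max(oc$se, 1e-3))
  expect_gt(oc$tau, 0)          # correlated chain
  expect_lt(oc$n_eff, oc$n)
})

test_that("iid switching gives near-zero autocorrelation time", {
  tr <- synth_trajectory(sim_spec_traj(f_hg = 0.4, switch_rate = 1,
                                       n_frames = 8000), seed = 6)
  oc <- occupancy(classify_frames(tr))
  expect_lt(oc$tau, 0.1)
  expect_gt(oc$n_eff / oc$n, 0.8)
})

test_that("population free energy has the printed fixed points", {
  expect_identical(dg_from_population(0.5), 0)
  expect_equal(dg_from_population(0.995, T = 298), -3.1343034126448148,
               tolerance = 1e-10)
  expect_equal(dg_from_population(0.4, T = 298), 0.24008643260365494,
               tolerance = 1e-10)
  # antisymmetry and logistic inversion on (0, 1)
  f <- seq(0.05, 0.95, by = 0.05)
  expect_equal(dg_from_population(f), -dg_from_population(1 - f),
               tolerance = 1e-12)
  expect_equal(population_from_dg(dg_from_population(f)), f,
               tolerance = 1e-12)
  expect_error(dg_from_population(1), "strictly inside")
  expect_error(dg_from_population(0), "strictly inside")
})

test_that("per-frame RMSD is zero for rigid copies and matches the
           quaternion oracle otherwise", {
  ref <- build_ideal_helix("GCGC", form = "B")
  sel <- with(ref$atoms, !(resno %in% c(1, 4)) &
                !grepl("^H", atom))
  xyz <- as.matrix(ref$atoms[, c("x", "y", "z")])
  set.seed(22)
  R <- random_rotation()
  rot <- t(R %*% t(xyz)) + matrix(c(1, 2, 3), nrow(xyz), 3, byrow = TRUE)
  jig <- xyz + matrix(stats::rnorm(length(xyz), sd = 0.3), nrow(xyz), 3)
  out <- rmsd_series(ref, list(xyz, rot, jig))
  expect_lt(out[1], 1e-12)
  expect_lt(out[2], 1e-6)
  expect_equal(out[3], oracle_superpose_rmsd(jig[sel, ], xyz[sel, ]),
               tolerance = 1e-9)
  expect_error(rmsd_series(ref, list(xyz[-1, ])), "mismatch")
})

test_that("descriptor series round-trip through delimited text", {
  tr <- synth_trajectory(sim_spec_traj(f_hg = 0.3, n_frames = 200),
                         seed = 31)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_frame_series(tr, path)
  back <- read_frame_series(path)
  expect_equal(back$c1c1, tr$c1c1, tolerance = 1e-9)
  expect_identical(classify_frames(back), classify_frames(tr))
})
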