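test_that("glycosidic classification follows the strict printed ranges", {
  expect_identical(classify_glycosidic(45), "syn")
  expect_identical(classify_glycosidic(-120), "anti")
  expect_identical(classify_glycosidic(120), "intermediate")
  # open-interval boundaries are unassigned -> intermediate
  expect_identical(classify_glycosidic(c(0, 90, -90, 180)),
                   rep("intermediate", 4))
  expect_identical(classify_glycosidic(89.999), "syn")
  expect_identical(classify_glycosidic(-179.999), "anti")
})

test_that("glycosidic classification is stable under 360-degree wraps", {
  set.seed(12)
  chi <- stats::runif(50, -180, 180)
  for (k in c(-2, -1, 1, 3)) {
    expect_identical(classify_glycosidic(chi + 360 * k),
                     classify_glycosidic(chi))
  }
})

test_that("backbone rotamer bins are gauche+/gauche-/trans", {
  expect_identical(classify_rotamer(60), "gauche+")
  expect_identical(classify_rotamer(-60), "gauche-")
  expect_identical(classify_rotamer(175), "trans")
  expect_identical(classify_rotamer(-150), "trans")
  expect_identical(classify_rotamer(c(120, -120, 0)),
                   c("gauche+", "trans", "gauche-"))
})

test_that("ideal helices carry the expected sugar pucker and chi class", {
  ta <- torsion_table(build_ideal_helix("GCGAUC", form = "A"))
  expect_true(all(ta$pucker_phase >= 0 & ta$pucker_phase <= 36))
  expect_true(all(pucker_region(ta$pucker_phase) == "C3'-endo"))
  expect_true(all(ta$chi_class == "anti"))
  tb <- torsion_table(build_ideal_helix("GCGATC", form = "B"))
  expect_true(all(tb$pucker_phase >= 144 & tb$pucker_phase <= 180))
  expect_true(all(pucker_region(tb$pucker_phase) == "C2'-endo"))
  expect_true(all(tb$chi_class == "anti"))
})

test_that("a 180-degree glycosidic flip shifts chi by 180 degrees", {
  hx <- build_ideal_helix("CGCATACGC", form = "B")
  chi0 <- residue_conformation(hx, "A:4")$torsions[["chi"]]
  chi1 <- residue_conformation(syn_flip(hx, "A:4"),
                               "A:4")$torsions[["chi"]]
  d <- (chi1 - chi0) %% 360
  expect_equal(min(d, 360 - d), 180, tolerance = 1e-6)
})

test_that("missing atoms yield absent torsions, not failure", {
  hx <- build_ideal_helix("GCGC", form = "B")
  a <- hx$atoms
  st <- nastructure(a[!(a$chain == "A" & a$resno == 2 & a$atom == "O4'"), ],
                    id = "x")
  rc <- residue_conformation(st, "A:2")
  expect_true(is.na(rc$torsions[["chi"]]))
  expect_true(is.na(rc$pucker_phase))
  # backbone torsions not involving O4' survive
  expect_false(is.na(rc$torsions[["gamma"]]))
  # 5'-terminal residue has no alpha (no upstream phosphate donor)
  expect_true(is.na(residue_conformation(st, "A:1")$torsions[["alpha"]]))
})

test_that("pair geometry is symmetric in its arguments", {
  hx <- build_ideal_helix("GCGAUC", form = "A")
  ij <- pair_geometry(hx, "A:2", "B:5")
  ji <- pair_geometry(hx, "B:5", "A:2")
  expect_equal(ij$c1c1_distance, ji$c1c1_distance)
  expect_identical(ij$pair_class, ji$pair_class)
  pairs_of <- function(pg) {
    sort(paste(pmin(pg$hbonds$donor, pg$hbonds$acceptor),
               pmax(pg$hbonds$donor, pg$hbonds$acceptor)))
  }
  expect_identical(pairs_of(ij), pairs_of(ji))
})

test_that("ideal WC pairs classify WC with in-range C1'-C1'", {
  for (form in c("A", "B")) {
    seqs <- if (form == "A") "GCAU" else "GCAT"
    hx <- build_ideal_helix(seqs, form = form)
    pt <- pair_table(hx, helix_pairs(hx))
    expect_true(all(pt$pair_class == "WC"))
    expect_true(all(pt$c1c1_distance >= 9.8 & pt$c1c1_distance <= 11.0))
  }
})

test_that("separated bases lose their pair class and hydrogen bonds", {
  hx <- build_ideal_helix("CGCATACGC", form = "B")
  a <- hx$atoms
  idx <- a$chain == "B" & a$resno == 6
  a[idx, c("x", "y", "z")] <- a[idx, c("x", "y", "z")] + 5
  st <- nastructure(a, id = "pulled")
  pg <- pair_geometry(st, "A:4", "B:6")
  expect_identical(pg$pair_class, "other")
  expect_true(nrow(pg$hbonds) == 0 || min(pg$hbonds$distance) >= 3.5)
})
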