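test_that("helix construction is deterministic and validates input", {
  h1 <- build_ideal_helix("GCGAUC", form = "A")
  h2 <- build_ideal_helix("GCGAUC", form = "A")
  expect_identical(h1$atoms, h2$atoms)
  expect_error(build_ideal_helix("G", form = "B"), "length")
  expect_error(build_ideal_helix("GCXA", form = "B"), "invalid base")
  expect_error(build_ideal_helix("GCAU", form = "B"), "invalid base")
  expect_error(build_ideal_helix("GCAT", form = "A"), "invalid base")
})

test_that("the complementary strand satisfies WC complementarity", {
  hx <- build_ideal_helix("ATTGCCGA", form = "B")
  rt <- residues(hx)
  top <- rt$resname[rt$chain == "A"]
  bot <- rev(rt$resname[rt$chain == "B"])  # aligned with top
  comp <- c(DA = "DT", DT = "DA", DG = "DC", DC = "DG")
  expect_identical(unname(comp[top]), bot)
})

test_that("B-form twist and rise emerge from the generated coordinates", {
  hx <- build_ideal_helix("GCGCGC", form = "B")
  hp <- helix_pairs(hx)
  c1 <- function(sel) {
    s <- parse_sel <- strsplit(sel, ":")[[1]]
    r <- hx$atoms[hx$atoms$chain == s[1] & hx$atoms$resno == s[2] &
                    hx$atoms$atom == "C1'", ]
    as.numeric(r[1, c("x", "y", "z")])
  }
  v <- vapply(seq_len(nrow(hp)),
              function(k) c1(hp$i[k]) - c1(hp$j[k]), numeric(3))
  tw <- vapply(seq_len(ncol(v) - 1), function(k) {
    a <- v[1:2, k]; b <- v[1:2, k + 1]
    atan2(a[1] * b[2] - a[2] * b[1], sum(a * b)) * 180 / pi
  }, 0)
  expect_lt(abs(mean(tw) - 36), 1)
  # consecutive pair-center separation approximates the rise
  centers <- vapply(seq_len(nrow(hp)), function(k) {
    ij <- c(hp$i[k], hp$j[k])
    xyz <- do.call(rbind, lapply(ij, function(sel) {
      s <- strsplit(sel, ":")[[1]]
      r <- hx$atoms[hx$atoms$chain == s[1] & hx$atoms$resno == s[2], ]
      as.matrix(r[r$atom %in% base_atoms(r$resname[1]),
                  c("x", "y", "z")])
    }))
    colMeans(xyz)
  }, numeric(3))
  sep <- sqrt(rowSums(diff(t(centers))^2))
  expect_true(all(abs(sep - 3.38) <= 0.1))
})

test_that("syn flip is an exact involution that only moves base atoms", {
  hx <- build_ideal_helix("CGCATACGC", form = "B")
  f1 <- syn_flip(hx, "A:4")
  f2 <- syn_flip(f1, "A:4")
  expect_equal(as.matrix(f2$atoms[, c("x", "y", "z")]),
               as.matrix(hx$atoms[, c("x", "y", "z")]),
               tolerance = 1e-6)
  moved <- which(rowSums(abs(
    as.matrix(f1$atoms[, c("x", "y", "z")]) -
      as.matrix(hx$atoms[, c("x", "y", "z")]))) > 1e-9)
  expect_true(all(f1$atoms$resno[moved] == 4 &
                    f1$atoms$chain[moved] == "A"))
  expect_true(all(f1$atoms$atom[moved] %in% base_atoms("DA")))
  expect_error(syn_flip(hx, "B:6"), "purine")  # thymine target
})

test_that("flipping an anti purine yields a syn-classifiable chi", {
  hx <- build_ideal_helix("CGCATACGC", form = "B")
  f1 <- syn_flip(hx, "A:4")
  cls <- residue_conformation(f1, "A:4")$chi_class
  expect_true(cls %in% c("syn", "intermediate"))
  expect_identical(classify_glycosidic(
    residue_conformation(hx, "A:4")$torsions[["chi"]] + 180 - 360),
    cls)
})

test_that("hg_place is the identity on its own template", {
  tpl <- hg_template("AT")
  out <- hg_place(tpl, "A:1", "B:1", hg_template("AT"))
  expect_equal(as.matrix(out$atoms[, c("x", "y", "z")]),
               as.matrix(tpl$atoms[, c("x", "y", "z")]),
               tolerance = 1e-6)
  expect_lt(attr(out, "superposition_rmsd"), 1e-9)
})

test_that("a placed A(syn)-T template satisfies the Hoogsteen criteria", {
  hx <- build_ideal_helix("CGCATACGC", form = "B")
  out <- hg_place(hx, "A:4", "B:6", hg_template("AT"))
  pg <- pair_geometry(out, "A:4", "B:6")
  expect_identical(pg$pair_class, "HG")
  expect_lt(pg$c1c1_distance, 9.5)
  expect_identical(pg$chi_class_i, "syn")
  n7 <- pg$hbonds[pg$hbonds$acceptor == "N7" | pg$hbonds$donor == "N7", ]
  expect_gt(nrow(n7), 0)
  expect_lt(min(n7$distance), 3.5)
})

test_that("hg_place superposition RMSD matches the quaternion oracle", {
  hx <- build_ideal_helix("CGCATACGC", form = "B")
  flipped <- syn_flip(hx, "A:4")
  tpl <- hg_template("AT")
  out <- hg_place(hx, "A:4", "B:6", tpl)
  # rebuild the matched coordinate sets exactly as hg_place does
  get_base <- function(st, sel, rn) {
    s <- strsplit(sel, ":")[[1]]
    r <- st$atoms[st$atoms$chain == s[1] & st$atoms$resno == s[2], ]
    nm <- intersect(base_atoms(rn), r$atom)
    as.matrix(r[match(nm, r$atom), c("x", "y", "z")])
  }
  tx <- rbind(get_base(tpl, "A:1", "DA"), get_base(tpl, "B:1", "DT"))
  sx <- rbind(get_base(flipped, "A:4", "DA"),
              get_base(flipped, "B:6", "DT"))
  expect_equal(attr(out, "superposition_rmsd"),
               oracle_superpose_rmsd(tx, sx), tolerance = 1e-9)
})

test_that("hg_place rejects identity mismatches", {
  hx <- build_ideal_helix("CGCATACGC", form = "B")
  expect_error(hg_place(hx, "A:4", "B:6", hg_template("GG")),
               "identity mismatch")
})

test_that("mutate_base swaps a base in the existing glycosidic frame", {
  hx <- build_ideal_helix("GCGAUC", form = "A")
  mut <- mutate_base(hx, "A:5", "C", form = "A")
  rt <- residues(mut)
  expect_identical(rt$resname[rt$chain == "A"][5], "C")
  # the new base matches the template C placed at that position exactly
  ref <- build_ideal_helix("GCGACC", form = "A")
  get <- function(st, nm) {
    r <- st$atoms[st$atoms$chain == "A" & st$atoms$resno == 5, ]
    as.numeric(r[r$atom == nm, c("x", "y", "z")])
  }
  for (nm in c("N1", "C2", "O2", "N4", "C5")) {
    expect_equal(get(mut, nm), get(ref, nm), tolerance = 1e-4)
  }
})
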