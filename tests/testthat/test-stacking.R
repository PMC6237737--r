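test_that("overlap area handles the analytic reference cases", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(overlap_area(sq, sq), 1)
  expect_equal(overlap_area(sq, sweep(sq, 2, c(0.5, 0), "+")), 0.5)
  expect_equal(overlap_area(sq, sweep(sq, 2, c(20, 0), "+")), 0)
  tri <- cbind(c(0, 2, 0), c(0, 0, 2))
  expect_equal(overlap_area(tri, sq),
               overlap_area(sq, tri))   # symmetry
})

test_that("clipped overlap matches the rasterization oracle", {
  set.seed(13)
  for (k in 1:100) {
    a <- random_convex_polygon(sample(5:9, 1))
    b <- sweep(random_convex_polygon(sample(5:9, 1)), 2,
               stats::runif(2, -0.8, 0.8), "+")
    got <- overlap_area(a, b)
    want <- oracle_overlap_raster(a, b, h = 0.01)
    if (want > 0.05) {
      expect_lt(abs(got - want) / want, 0.005)
    } else {
      expect_lt(abs(got - want), 5e-3)
    }
  }
})

test_that("overlap is invariant to in-plane rotation of the frame", {
  set.seed(14)
  a <- random_convex_polygon(7)
  b <- sweep(random_convex_polygon(6), 2, c(0.4, -0.2), "+")
  base <- overlap_area(a, b)
  for (th in c(0.3, 1.2, 2.8)) {
    R2 <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
    expect_equal(overlap_area(a %*% R2, b %*% R2), base,
                 tolerance = 1e-9)
  }
})

test_that("step overlap is invariant under rigid motion of the step", {
  hx <- build_ideal_helix("GCGCGC", form = "B")
  hp <- as.matrix(helix_pairs(hx))
  base <- step_overlap(hx, hp[3, ], hp[4, ])
  set.seed(15)
  R <- random_rotation()
  tv <- stats::rnorm(3, sd = 8)
  a <- hx$atoms
  a[, c("x", "y", "z")] <- t(R %*% t(as.matrix(a[, c("x", "y", "z")]))) +
    matrix(tv, nrow(a), 3, byrow = TRUE)
  moved <- nastructure(a, id = "moved")
  got <- step_overlap(moved, hp[3, ], hp[4, ])
  expect_equal(got$overlap, base$overlap, tolerance = 1e-6)
})

test_that("projection frame behaves for coplanar and reversed steps", {
  hx <- build_ideal_helix("GCGCGC", form = "B")
  hp <- as.matrix(helix_pairs(hx))
  fr <- project_step(hx, hp[2, ], hp[3, ])
  fr_rev <- project_step(hx, hp[3, ], hp[2, ])
  # same plane regardless of step direction (normal up to sign)
  expect_equal(abs(sum(fr$normal * fr_rev$normal)), 1, tolerance = 1e-6)
  # projection preserves in-plane distances for coplanar points
  p1 <- base_polygon(hx, hp[2, 1], fr)
  expect_gt(p1$area, 0)
})

test_that("including exocyclic atoms never shrinks a base polygon", {
  for (form in c("A", "B")) {
    hx <- build_ideal_helix(if (form == "A") "GCAUGC" else "GCATGC",
                            form = form)
    hp <- as.matrix(helix_pairs(hx))
    fr <- project_step(hx, hp[2, ], hp[3, ])
    for (sel in c(hp[2, ], hp[3, ])) {
      with_exo <- base_polygon(hx, sel, fr, exocyclic = TRUE)$area
      without <- base_polygon(hx, sel, fr, exocyclic = FALSE)$area
      expect_gte(with_exo, without - 1e-12)
    }
  }
})

test_that("a reference triplet compared to itself gives zero change", {
  hx <- build_ideal_helix("TAG", form = "B")
  hp <- as.matrix(helix_pairs(hx))
  out <- triplet_overlap_change(hx, hp, form = "B")
  expect_equal(out$delta$delta, c(0, 0), tolerance = 1e-9)
  expect_equal(out$delta_total, 0, tolerance = 1e-9)
})

test_that("a syn-flipped central pair changes the overlap as the
           rasterization oracle says", {
  hx <- build_ideal_helix("TGC", form = "B")
  hx <- mutate_base(hx, "B:2", "G", form = "B")
  mm <- hg_place(hx, "A:2", "B:2", hg_template("GG"))
  hp <- as.matrix(helix_pairs(mm))
  out <- triplet_overlap_change(mm, hp, form = "B")
  expect_true(is.finite(out$delta_total))
  # independent recomputation of the mismatch-side total via the
  # rasterization oracle
  raster_total <- 0
  for (step in list(hp[1:2, ], hp[2:3, ])) {
    fr <- project_step(mm, step[1, ], step[2, ])
    combos <- list(c(step[1, 1], step[2, 1]), c(step[1, 2], step[2, 2]),
                   c(step[1, 1], step[2, 2]), c(step[1, 2], step[2, 1]))
    for (cb in combos) {
      va <- base_polygon(mm, cb[1], fr)$vertices
      vb <- base_polygon(mm, cb[2], fr)$vertices
      raster_total <- raster_total + oracle_overlap_raster(va, vb,
                                                           h = 0.01)
    }
  }
  mm_total <- sum(out$mismatch$overlap[out$mismatch$combination ==
                                         "total"])
  expect_lt(abs(mm_total - raster_total) / max(raster_total, 1), 0.005)
  expect_error(triplet_overlap_change(mm, hp[1:2, ], form = "B"),
               "3 pairs")
})
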