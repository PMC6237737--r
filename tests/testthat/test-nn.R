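# independent table-lookup oracle: read the packaged parameter files
# directly and sum doublets by hand
nn_oracle_dg <- function(top, bottom, alphabet, T_eval) {
  file <- if (alphabet == "DNA") "dna_nn_santalucia1998.tsv"
          else "rna_nn_xia1998.tsv"
  tab <- read.table(system.file("extdata", "nn", file,
                                package = "hgduplex"),
                    header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  if (alphabet == "DNA") {
    mm <- read.table(system.file("extdata", "nn",
                                 "dna_mm_peyret1999.tsv",
                                 package = "hgduplex"),
                     header = TRUE, sep = "\t", comment.char = "#",
                     stringsAsFactors = FALSE)
    tab <- rbind(tab, mm)
  }
  look <- function(t2, b2) {
    k1 <- paste0(t2, "/", b2)
    k2 <- paste0(paste(rev(strsplit(b2, "")[[1]]), collapse = ""), "/",
                 paste(rev(strsplit(t2, "")[[1]]), collapse = ""))
    i <- match(k1, tab$doublet)
    if (is.na(i)) i <- match(k2, tab$doublet)
    c(tab$dH[i], tab$dS[i])
  }
  tb <- strsplit(top, "")[[1]]
  bb <- strsplit(bottom, "")[[1]]
  dH <- 0; dS <- 0
  for (p in seq_len(length(tb) - 1)) {
    v <- look(paste0(tb[p], tb[p + 1]), paste0(bb[p], bb[p + 1]))
    dH <- dH + v[1]; dS <- dS + v[2]
  }
  dH - T_eval * dS / 1000
}

test_that("duplex_dg equals the manual doublet summation", {
  p <- nn_params("DNA")
  got <- duplex_dg("ATGCAT", "TACGTA", p, Na = 1, T_eval = 310.15,
                   initiation = FALSE)
  want <- nn_oracle_dg("ATGCAT", "TACGTA", "DNA", 310.15)
  expect_equal(got$dG, want, tolerance = 1e-10)
  # and for RNA
  pr <- nn_params("RNA")
  got_r <- duplex_dg("AUGGCA", "UACCGU", pr, Na = 1, T_eval = 310.15,
                     initiation = FALSE)
  expect_equal(got_r$dG, nn_oracle_dg("AUGGCA", "UACCGU", "RNA", 310.15),
               tolerance = 1e-10)
})

test_that("strand flip leaves the duplex free energy unchanged", {
  p <- nn_params("DNA")
  rev_comp_view <- function(top, bottom) {
    # read the duplex from the other strand: new top = reverse(bottom
    # aligned) and vice versa
    list(top = paste(rev(strsplit(bottom, "")[[1]]), collapse = ""),
         bottom = paste(rev(strsplit(top, "")[[1]]), collapse = ""))
  }
  for (duplex in list(c("ATGCAT", "TACGTA"), c("GGACGT", "CCTGCA"))) {
    v <- rev_comp_view(duplex[1], duplex[2])
    g1 <- duplex_dg(duplex[1], duplex[2], p, initiation = TRUE)
    g2 <- duplex_dg(v$top, v$bottom, p, initiation = TRUE)
    expect_equal(g1$dG, g2$dG, tolerance = 1e-10)
  }
})

test_that("degenerate inputs are rejected with named errors", {
  p <- nn_params("DNA")
  expect_error(duplex_dg("", "", p), "empty|length")
  expect_error(duplex_dg("ATG", "TA", p), "equal length")
  expect_error(duplex_dg("ATGCAT", "TAGATA", p), "one internal mismatch")
  expect_error(duplex_dg("TTGCAT", "GACGTA", p), "terminal")
  expect_error(duplex_dg("AXGCAT", "TACGTA", p), "invalid")
})

test_that("nearest-neighbor free energy is additive over doublets", {
  p <- nn_params("DNA")
  # concatenating two duplexes adds their energies plus the junction
  # doublet (initiation zeroed)
  g_all <- duplex_dg("ATGCAT", "TACGTA", p, initiation = FALSE)
  g_a <- duplex_dg("ATG", "TAC", p, initiation = FALSE)
  g_b <- duplex_dg("CAT", "GTA", p, initiation = FALSE)
  junction <- nn_oracle_dg("GC", "CG", "DNA", 298.15)
  expect_equal(g_all$dG, g_a$dG + g_b$dG + junction, tolerance = 1e-10)
})

test_that("salt correction vanishes at the 1 M reference and cancels in
           ddG", {
  p <- nn_params("DNA")
  g_ref <- duplex_dg("ATGCAT", "TACGTA", p, Na = 1.0,
                     initiation = FALSE)
  g_low <- duplex_dg("ATGCAT", "TACGTA", p, Na = 0.15,
                     initiation = FALSE)
  expect_false(isTRUE(all.equal(g_ref$dG, g_low$dG)))
  expect_equal(g_low$dS - g_ref$dS, 0.368 * 5 * log(0.15),
               tolerance = 1e-10)
  d_ref <- mismatch_ddg("A", "T", c("G", "C"), c("T", "T"), p, Na = 1.0)
  d_low <- mismatch_ddg("A", "T", c("G", "C"), c("T", "T"), p, Na = 0.15)
  expect_equal(d_ref, d_low, tolerance = 1e-10)  # equal lengths cancel
})

test_that("identity substitution and locality hold for mismatch_ddg", {
  p <- nn_params("DNA")
  for (x in c("A", "C", "G", "T")) {
    for (y in c("A", "C", "G", "T")) {
      expect_equal(mismatch_ddg(x, y, c("G", "C"), c("G", "C"), p), 0,
                   tolerance = 1e-12)
    }
  }
  # ddG depends only on the immediate flanks: embed in longer duplexes
  long_ddg <- function(pre, post) {
    comp <- c(A = "T", T = "A", G = "C", C = "G")
    mk <- function(center) {
      top <- paste0(pre, "A", center[1], "T", post)
      bot <- paste0(
        paste(comp[strsplit(pre, "")[[1]]], collapse = ""), "T",
        center[2], "A",
        paste(comp[strsplit(post, "")[[1]]], collapse = ""))
      duplex_dg(top, bot, p, initiation = FALSE)$dG
    }
    mk(c("T", "T")) - mk(c("G", "C"))
  }
  expect_equal(long_ddg("GG", "CC"), long_ddg("AT", "TA"),
               tolerance = 1e-10)
  expect_equal(long_ddg("GG", "CC"),
               mismatch_ddg("A", "T", c("G", "C"), c("T", "T"), p),
               tolerance = 1e-10)
})

test_that("every T.T context matches the manual oracle", {
  p <- nn_params("DNA")
  comp <- c(A = "T", T = "A", G = "C", C = "G")
  for (x in c("A", "C", "G", "T")) {
    for (y in c("A", "C", "G", "T")) {
      got <- mismatch_ddg(x, y, c("G", "C"), c("T", "T"), p, Na = 0.15,
                          T_eval = 298.15)
      want <- (nn_oracle_dg(paste0(x, "T", y),
                            paste0(comp[x], "T", comp[y]),
                            "DNA", 298.15) -
                 nn_oracle_dg(paste0(x, "G", y),
                              paste0(comp[x], "C", comp[y]),
                              "DNA", 298.15))
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("missing parameters raise errors naming the doublet", {
  p <- nn_params("DNA")
  expect_error(duplex_dg("ACCCAT", "TGAGTA", p),
               "missing nearest-neighbor parameter")
})

test_that("a constant toy table collapses the sweep", {
  p <- nn_params("DNA")
  p$doublets$dH <- -8
  p$doublets$dS <- -22
  sweep <- context_sweep(c("G", "C"), c("T", "T"), p)
  expect_equal(sweep$min, sweep$max, tolerance = 1e-10)
  expect_equal(sweep$min, sweep$mean, tolerance = 1e-10)
})

test_that("RNA mismatch energetics agree with an independent
           thermodynamic evaluator", {
  # RNAeval (ViennaRNA) computes the same Turner-2004 duplex energies;
  # compare the U.U-for-GC substitution in two contexts at 37 C
  rnaeval <- function(top, bot_rev, struct) {
    out <- system2("RNAeval", c("-T", "37", "-d2"),
                   input = paste0(top, "&", bot_rev, "\n", struct),
                   stdout = TRUE, stderr = FALSE)
    as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1",
                   out[length(out)]))
  }
  p <- nn_params("RNA")
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  for (ctx in list(c("G", "C"), c("A", "U"))) {
    x <- ctx[1]; y <- ctx[2]
    top_wc <- paste0("GGC", x, "G", y, "CGG")
    bot_wc <- paste(comp[strsplit(top_wc, "")[[1]]], collapse = "")
    top_mm <- paste0(substr(top_wc, 1, 4), "U", substr(top_wc, 6, 9))
    bot_mm <- paste0(substr(bot_wc, 1, 4), "U", substr(bot_wc, 6, 9))
    n <- nchar(top_wc)
    wc_struct <- paste0(strrep("(", n), "&", strrep(")", n))
    mm_struct <- paste0(strrep("(", 4), ".", strrep("(", n - 5), "&",
                        strrep(")", n - 5), ".", strrep(")", 4))
    vienna <- rnaeval(top_mm, paste(rev(strsplit(bot_mm, "")[[1]]),
                                    collapse = ""), mm_struct) -
      rnaeval(top_wc, paste(rev(strsplit(bot_wc, "")[[1]]),
                            collapse = ""), wc_struct)
    got <- mismatch_ddg(x, y, c("G", "C"), c("U", "U"), p, Na = 1,
                        T_eval = 310.15)
    expect_lt(abs(got - vienna), 0.05)
  }
})
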