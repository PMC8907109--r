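test_that("terminal enumeration counts follow |series| x (n-1)", {
  fr <- oligo_terminal_fragments(S1C)
  expect_equal(nrow(fr), 8 * 12)
  fr2 <- oligo_terminal_fragments(S1C, series = c("a", "w"))
  expect_equal(nrow(fr2), 2 * 12)
  expect_equal(nrow(oligo_terminal_fragments("A")), 0L)
  withp <- oligo_terminal_fragments(S1C, series = "a",
                                    include_precursor = TRUE)
  expect_equal(sum(withp$kind == "precursor"), 1L)
  expect_equal(nrow(withp), 13L)
})

test_that("complementary terminal pairs conserve the strand mass", {
  set.seed(11)
  pairs <- list(c("a", "w"), c("b", "x"), c("c", "y"), c("d", "z"))
  for (rep in 1:25) {
    n <- sample(3:20, 1)
    s <- random_dna(n)
    M <- orc$oligo(s)
    fr <- oligo_terminal_fragments(s)
    for (pr in pairs) for (i in seq_len(n - 1)) {
      m5 <- frag_by_label(fr, paste0(pr[1], i))$neutral_mass
      m3 <- frag_by_label(fr, paste0(pr[2], n - i))$neutral_mass
      expect_equal(m5 + m3, M, tolerance = 1e-9)
    }
  }
})

test_that("a6 of S1c anchors the smallest platinated fragment", {
  fr <- oligo_terminal_fragments(S1C, series = "a", polymer = "S1c")
  a6 <- frag_by_label(fr, "a6")
  expect_equal(a6$neutral_mass, 1788.3348, tolerance = 1e-4)
  sp <- build_species(a6, adducts = c("Pt(NH3)2" = 1), protons_removed = 5)
  expect_equal(sp$mz, 670.7721, tolerance = 2e-3)  # printed, ~1 ppm
  expect_equal(sp$z, -3L)
})

test_that("oligo a-series equals b-series minus water; base losses subtract the neutral base", {
  fr <- oligo_terminal_fragments(S1C, series = c("a", "b"),
                                 base_loss = "at-cleavage")
  for (i in 1:12) {
    ai <- frag_by_label(fr, paste0("a", i))$neutral_mass
    bi <- frag_by_label(fr, paste0("b", i))$neutral_mass
    expect_equal(bi - ai, orc$H2O, tolerance = 1e-9)
  }
  # a7-B(G): base at the cleavage-side residue (position 7 of S1c = C)
  r <- strsplit(S1C, "")[[1]]
  a5 <- frag_by_label(fr, "a5")
  a5b <- frag_by_label(fr, paste0("a5-B(", r[5], ")"))
  expect_equal(a5$neutral_mass - a5b$neutral_mass, orc$base[[r[5]]],
               tolerance = 1e-9)
  expect_equal(a5b$base_loss_pos, 5L)
})

test_that("internal fragment counts match the brute-force proper-overlap recount", {
  set.seed(23)
  for (n in c(4, 7, 13, 20)) {
    s <- random_dna(n)
    fr <- oligo_internal_fragments(s, series3 = c("w", "x"),
                                   series5 = c("a", "b"))
    brute <- 0L
    for (i in seq_len(n - 1)) for (j in seq_len(n - 1)) {
      p <- n - i + 1L; q <- j
      if (p > 1L && q < n && p <= q) brute <- brute + 1L
    }
    expect_equal(nrow(fr), 4L * brute)
    expect_equal(brute, (n - 1) * (n - 2) / 2)
  }
})

test_that("internal formulas agree with the terminal-subtraction oracle", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(5:15, 1)
    s <- random_dna(n)
    M <- orc$oligo(s)
    term <- oligo_terminal_fragments(s)
    intr <- oligo_internal_fragments(s, series3 = c("w", "y"),
                                     series5 = c("a", "d"))
    pick <- intr[sample(nrow(intr), min(12, nrow(intr))), ]
    for (k in seq_len(nrow(pick))) {
      row <- pick[k, ]
      # internal(p..q) = 3'-terminal frag covering p..n
      #                + 5'-terminal frag covering 1..q - whole strand
      i3 <- n - row$start + 1L
      lab3 <- paste0(row$series3, i3)
      lab5 <- paste0(row$series5, row$end)
      expected <- frag_by_label(term, lab3)$neutral_mass +
        frag_by_label(term, lab5)$neutral_mass - M
      expect_equal(row$neutral_mass, expected, tolerance = 1e-9)
    }
  }
})

test_that("printed S1c internal-fragment ions are reproduced", {
  intr <- oligo_internal_fragments(S1C, base_loss = "at-3'-cleavage",
                                   polymer = "S1c")
  mz1 <- function(lab, pr, z)
    build_species(frag_by_label(intr, lab), protons_removed = pr)$mz
  expect_equal(mz1("w7:a8-B", 1, -1), 466.0422, tolerance = 2e-3)
  expect_equal(mz1("w7:a12-B", 2, -2), 842.1213, tolerance = 2e-3)
  expect_equal(mz1("w10:a9-B", 2, -2), 858.1162, tolerance = 2e-3)
  expect_equal(mz1("w10:a10-B", 2, -2), 1014.6450, tolerance = 2e-3)
  expect_equal(mz1("w10:a6-B", 1, -1), 810.0944, tolerance = 2e-3)
  expect_equal(mz1("w10:a7-B", 1, -1), 1139.1469, tolerance = 2e-3)
  expect_equal(mz1("w7:a10-B", 1, -1), 1068.1462, tolerance = 2e-3)
  # base-loss position is the 3'-side cleavage residue q
  w78 <- frag_by_label(intr, "w7:a8-B")
  expect_equal(w78$base_loss_pos, 8L)
  expect_identical(w78$base_loss, "C")
})

test_that("peptide fragments follow the b/a/y formulas and complementarity", {
  fr <- peptide_fragments(P1, polymer = "P1")
  M <- orc$pep(P1)
  n <- nchar(P1)
  expect_equal(frag_by_label(fr, "b2")$neutral_mass, 212.1525,
               tolerance = 1e-4)
  expect_equal(frag_by_label(fr, "y4")$neutral_mass, 502.2639,
               tolerance = 1e-4)
  for (i in seq_len(n - 1)) {
    bi <- frag_by_label(fr, paste0("b", i))$neutral_mass
    yi <- frag_by_label(fr, paste0("y", n - i))$neutral_mass
    expect_equal(bi + yi, M, tolerance = 1e-9)
    ai <- frag_by_label(fr, paste0("a", i))$neutral_mass
    expect_equal(bi - ai, monoisotopic_mass("CO"), tolerance = 1e-9)
  }
  # printed platinated peptide fragments
  sp_b2 <- build_species(frag_by_label(fr, "b2"),
                         adducts = c("Pt(NH3)" = 1), protons_removed = 1,
                         menu = default_adducts("pos"))
  expect_equal(sp_b2$mz, 423.1354, tolerance = 2e-3)
  expect_equal(sp_b2$z, 1L)
  sp_y4 <- build_species(frag_by_label(fr, "y4"),
                         adducts = c("Pt(NH3)2" = 1), protons_removed = 1,
                         menu = default_adducts("pos"))
  expect_equal(sp_y4$mz, 730.2734, tolerance = 2e-3)
})

test_that("peptide internal enumeration covers every interior window", {
  fr <- peptide_fragments("GAVLKE", series = "b", internal = TRUE)
  internal <- fr[fr$kind == "internal", ]
  n <- 6
  amide <- internal[!grepl("a$", internal$label), ]
  expect_equal(nrow(amide), (n - 2) * (n - 1) / 2)
  expect_true(all(internal$start >= 2 & internal$end <= n - 1))
  # amide-type internal = bare residue sum
  i24 <- internal[internal$label == "i2:4", ]
  expect_equal(i24$neutral_mass,
               sum(orc$res[c("A", "V", "L")]), tolerance = 1e-9)
})

test_that("neutral-loss variants subtract the loss formula when feasible", {
  fr <- oligo_terminal_fragments("ACGT", series = "w",
                                 neutral_losses = "H2O")
  plain <- frag_by_label(fr, "w2")
  lost <- frag_by_label(fr, "w2-H2O")
  expect_equal(plain$neutral_mass - lost$neutral_mass, orc$H2O,
               tolerance = 1e-9)
})
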