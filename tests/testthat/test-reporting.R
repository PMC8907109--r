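# build a small deterministic "match list" without running the matcher:
# any species tibble with a similarity column is accepted by the reporters
fake_matches <- function(seq, labs, adduct_sets, similarities = 0.95) {
  fr <- dplyr::bind_rows(
    oligo_terminal_fragments(seq, base_loss = "at-cleavage", polymer = "S"),
    oligo_internal_fragments(seq, base_loss = "at-3'-cleavage", polymer = "S"))
  rows <- purrr::map2_dfr(labs, adduct_sets, function(lab, ad) {
    build_species(fr[fr$label == lab, ][1, ], adducts = ad,
                  protons_removed = if (is.null(ad)) 2 else 6)
  })
  rows$similarity <- rep_len(similarities, nrow(rows))
  rows
}

test_that("an empty match list yields an empty, zeroed fragment map", {
  empty <- fake_matches(S1, character(0), list())
  map <- build_fragment_map(empty, S1)
  expect_equal(nrow(map$tracks), 0L)
  expect_equal(nrow(map$positions), 13L)
  expect_true(all(map$positions$platinated == 0L))
  expect_true(all(map$positions$unplatinated == 0L))
  g <- glance(map)
  expect_equal(g$n_matches, 0L)
})

test_that("a single platinated a9 match covers positions 1..9", {
  m <- fake_matches(S1, "a9", list(c("Pt(NH3)2" = 1)))
  map <- build_fragment_map(m, S1)
  pos <- tidy(map)
  expect_equal(pos$platinated, c(rep(1L, 9), rep(0L, 4)))
  expect_equal(sum(pos$unplatinated), 0L)
})

test_that("per-position counts equal a brute-force recount on random match sets", {
  set.seed(13)
  fr <- dplyr::bind_rows(
    oligo_terminal_fragments(S1C, polymer = "S"),
    oligo_internal_fragments(S1C, polymer = "S"))
  for (rep in 1:5) {
    pick <- fr[sample(nrow(fr), 15), ]
    plat <- sample(c(TRUE, FALSE), 15, TRUE)
    m <- dplyr::bind_rows(lapply(seq_len(15), function(i)
      build_species(pick[i, ],
                    adducts = if (plat[i]) c("Pt" = 1) else NULL,
                    protons_removed = if (plat[i]) 4 else 2)))
    m$similarity <- runif(15, 0.75, 1)
    map <- build_fragment_map(m, S1C)
    brute_p <- brute_u <- integer(13)
    for (i in seq_len(15)) {
      idx <- m$start[i]:m$end[i]
      if (m$platinated[i]) brute_p[idx] <- brute_p[idx] + 1L
      else brute_u[idx] <- brute_u[idx] + 1L
    }
    expect_equal(map$positions$platinated, brute_p)
    expect_equal(map$positions$unplatinated, brute_u)
    # histogram total equals the sum of interval lengths
    expect_equal(sum(map$positions$platinated) +
                   sum(map$positions$unplatinated),
                 sum(m$end - m$start + 1))
  }
})

test_that("region classification splits evidence sets and sums to 100", {
  m <- fake_matches(S1, c("a3", "w4"),
                    list(c("Pt" = 1), c("Pt" = 1)))
  reg <- classify_regions(m)
  plat <- reg[reg$set == "platinated", ]
  expect_equal(plat$percent[plat$class == "5'-end"], 50)
  expect_equal(plat$percent[plat$class == "3'-end"], 50)
  expect_equal(plat$percent[plat$class == "Middle"], 0)
  expect_equal(sum(plat$percent), 100, tolerance = 0.01)
  # no unplatinated evidence: flagged, percentages 0
  unplat <- reg[reg$set == "unplatinated", ]
  expect_true(all(unplat$empty_set))
  expect_equal(sum(unplat$percent), 0)
  # class counts sum to the total per evidence set
  expect_equal(sum(reg$n), nrow(m))
})

test_that("region percentages equal a brute-force recount on random sets", {
  set.seed(17)
  fr <- dplyr::bind_rows(
    oligo_terminal_fragments(S1C, polymer = "S"),
    oligo_internal_fragments(S1C, polymer = "S"))
  pick <- fr[sample(nrow(fr), 20), ]
  plat <- sample(c(TRUE, FALSE), 20, TRUE)
  m <- dplyr::bind_rows(lapply(seq_len(20), function(i)
    build_species(pick[i, ],
                  adducts = if (plat[i]) c("Pt(NH3)" = 1) else NULL,
                  protons_removed = if (plat[i]) 4 else 2)))
  m$similarity <- 0.9
  reg <- classify_regions(m)
  cls <- c(`terminal-5'` = "5'-end", `terminal-3'` = "3'-end",
           internal = "Middle")
  for (s in c("platinated", "unplatinated")) {
    sub <- m[m$platinated == (s == "platinated"), ]
    for (cl in unique(cls)) {
      expected <- if (nrow(sub)) 100 * sum(cls[sub$kind] == cl) / nrow(sub)
      else 0
      got <- reg$percent[reg$set == s & reg$class == cl]
      expect_equal(got, expected)
    }
  }
})

test_that("residue histograms count covering fragments per position", {
  fr <- peptide_fragments(P1, polymer = "P1")
  y4 <- build_species(fr[fr$label == "y4", ], adducts = c("Pt(NH3)2" = 1),
                      protons_removed = 3, menu = default_adducts("pos"))
  y4$similarity <- 0.95
  h <- residue_histogram(y4, P1)
  expect_equal(which(h$platinated == 1L), 8:11)
  # complementary b_i / y_{n-i} pairs cover each position exactly once
  n <- nchar(P1)
  for (i in c(2, 5, 8)) {
    pair <- dplyr::bind_rows(fr[fr$label == paste0("b", i), ],
                             fr[fr$label == paste0("y", n - i), ])
    sp <- build_species(pair, protons_added = 1,
                        menu = default_adducts("pos"))
    sp$similarity <- 1
    h2 <- residue_histogram(sp, P1)
    expect_true(all(h2$unplatinated == 1L))
  }
})

test_that("maps refuse mixed sequences and out-of-range intervals", {
  a <- fake_matches(S1, "a3", list(NULL))
  b <- fake_matches(S1, "w2", list(NULL))
  b$polymer <- "other"
  expect_error(build_fragment_map(dplyr::bind_rows(a, b), S1), "one polymer")
  expect_error(build_fragment_map(a, "AC"), "outside")
})

test_that("plot builders return ggplot objects", {
  m <- fake_matches(S1, c("a3", "w4", "w7:a8"),
                    list(c("Pt" = 1), NULL, NULL))
  map <- build_fragment_map(m, S1)
  expect_s3_class(autoplot(map), "ggplot")
  expect_s3_class(plot_region_summary(classify_regions(m)), "ggplot")
  expect_s3_class(plot_residue_histogram(residue_histogram(m, S1)), "ggplot")
  expect_s3_class(tidy(map), "tbl_df")
  j <- tempfile(fileext = ".json")
  write_fragment_map(map, j)
  expect_true(jsonlite::validate(paste(readLines(j), collapse = "")))
})
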