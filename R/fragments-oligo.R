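## Oligonucleotide CID fragment enumeration in the McLuckey nomenclature:
## 5'-retaining series a/b/c/d and 3'-retaining series w/x/y/z, indexed by
## cleavage position, plus double-cleavage internal fragments labelled by
## the cleavage pair (e.g. "w7:a8").  A fragment's neutral formula is the
## sum of its nucleosides and linkages plus an end-group delta per cleaved
## end; the deltas are fixed by the complementarity identities
## a_i + w_{n-i} = M (and b/x, c/y, d/z alike).

OLIGO_ELEMENTS <- c("C", "H", "N", "O", "P")

## end chemistry at the 3' side of a 5'-retaining fragment
end3_delta <- function(series) {
  switch(series,
    d = HPO3(),
    c = fml_subtract(HPO3(), H2O()),
    b = fml(),
    a = fml(setNames(c(-2L, -1L), c("H", "O"))),
    abort(sprintf("unknown 5'-series '%s'", series)))
}

## end chemistry at the 5' side of a 3'-retaining fragment
end5_delta <- function(series) {
  switch(series,
    w = HPO3(),
    x = fml_subtract(HPO3(), H2O()),
    y = fml(),
    z = fml(setNames(c(-2L, -1L), c("H", "O"))),
    abort(sprintf("unknown 3'-series '%s'", series)))
}

## per-sequence geometry: cumulative nucleoside counts so that
## piece(p, q) = cum[q+1,] - cum[p,] + (q - p) * linkage
oligo_geometry <- function(residues) {
  nt <- nucleoside_table()
  nucmat <- do.call(rbind, lapply(nt[residues], counts_vec,
                                  elements = OLIGO_ELEMENTS))
  list(cum = rbind(0, apply(nucmat, 2, cumsum)),
       link = counts_vec(linkage_delta(), OLIGO_ELEMENTS),
       basemat = do.call(rbind, lapply(nucleobase_formulas()[residues],
                                       counts_vec,
                                       elements = OLIGO_ELEMENTS)))
}

piece_counts <- function(geo, p, q) {
  geo$cum[q + 1L, , drop = FALSE] - geo$cum[p, , drop = FALSE] +
    outer(q - p, geo$link)
}

#' Enumerate terminal CID fragments of a DNA oligonucleotide
#'
#' For an n-mer, each selected series yields fragments at cleavage indices
#' 1..n-1: 5'-retaining a/b/c/d cover positions `1..i`, 3'-retaining
#' w/x/y/z cover `n-i+1..n`.  `base_loss = "at-cleavage"` adds `-B`
#' variants that lose the neutral nucleobase at the cleavage-side residue
#' (position i for a/b/c/d, position n-i+1 for w/x/y/z);
#' `"any"` loses each base in the covered interval in turn.
#'
#' @param seq DNA sequence, 5' to 3'.
#' @param series Subset of `c("a","b","c","d","w","x","y","z")`.
#' @param base_loss One of `"none"`, `"at-cleavage"`, `"any"`.
#' @param neutral_losses Optional character vector of neutral-loss formulas
#'   (e.g. `"H2O"`) applied to every fragment as additional variants.
#' @param include_precursor Also emit the intact strand as a
#'   `kind = "precursor"` row.
#' @param polymer Name used in labels and reports.
#' @param five_prime,three_prime Terminal chemistry of the strand.
#' @return A tibble of fragments (label, covered positions, neutral formula
#'   and mass); one row per fragment variant.
#' @examples
#' frags <- oligo_terminal_fragments("TACGTGCCAATAC", series = c("a", "w"))
#' dplyr::filter(frags, label == "a6")
#' @export
oligo_terminal_fragments <- function(seq,
                                     series = c("a", "b", "c", "d",
                                                "w", "x", "y", "z"),
                                     base_loss = c("none", "at-cleavage", "any"),
                                     neutral_losses = NULL,
                                     include_precursor = FALSE,
                                     polymer = "seq1",
                                     five_prime = c("OH", "phosphate"),
                                     three_prime = c("OH", "phosphate")) {
  base_loss <- match.arg(base_loss)
  five_prime <- match.arg(five_prime)
  three_prime <- match.arg(three_prime)
  stopifnot(length(series) >= 1)
  series <- match.arg(series, c("a", "b", "c", "d", "w", "x", "y", "z"),
                      several.ok = TRUE)
  r <- split_residues(seq, c("A", "C", "G", "T"), "DNA")
  n <- length(r)
  geo <- oligo_geometry(r)
  phos5 <- if (five_prime == "phosphate")
    counts_vec(HPO3(), OLIGO_ELEMENTS) else numeric(length(OLIGO_ELEMENTS))
  phos3 <- if (three_prime == "phosphate")
    counts_vec(HPO3(), OLIGO_ELEMENTS) else numeric(length(OLIGO_ELEMENTS))

  pieces <- list()
  for (ser in series) {
    if (n == 1L) break
    i <- seq_len(n - 1L)
    is5 <- ser %in% c("a", "b", "c", "d")
    if (is5) {
      start <- rep(1L, n - 1L); end <- i
      mat <- piece_counts(geo, rep(1L, n - 1L), i) +
        outer(rep(1, n - 1L), counts_vec(end3_delta(ser), OLIGO_ELEMENTS) +
                phos5)
      cleave <- i
    } else {
      start <- n - i + 1L; end <- rep(n, n - 1L)
      mat <- piece_counts(geo, start, rep(n, n - 1L)) +
        outer(rep(1, n - 1L), counts_vec(end5_delta(ser), OLIGO_ELEMENTS) +
                phos3)
      cleave <- start
    }
    base <- fragment_tbl(polymer, if (is5) "terminal-5'" else "terminal-3'",
                         if (is5) ser else NA_character_,
                         if (is5) NA_character_ else ser,
                         i, start, end, NA_integer_, NA_character_,
                         paste0(ser, i), mat, OLIGO_ELEMENTS)
    pieces[[length(pieces) + 1L]] <- base
    if (base_loss != "none") {
      # one -B variant per (fragment, loss position)
      sel <- if (base_loss == "at-cleavage") {
        data.frame(frag = seq_len(n - 1L), pos = cleave)
      } else {
        do.call(rbind, lapply(seq_len(n - 1L), function(k)
          data.frame(frag = k, pos = start[k]:end[k])))
      }
      lmat <- mat[sel$frag, , drop = FALSE] -
        geo$basemat[sel$pos, , drop = FALSE]
      pieces[[length(pieces) + 1L]] <-
        fragment_tbl(polymer, if (is5) "terminal-5'" else "terminal-3'",
                     if (is5) ser else NA_character_,
                     if (is5) NA_character_ else ser,
                     i[sel$frag], start[sel$frag], end[sel$frag],
                     sel$pos, r[sel$pos],
                     paste0(ser, i[sel$frag], "-B(", r[sel$pos], ")"),
                     lmat, OLIGO_ELEMENTS)
    }
  }

  if (include_precursor) {
    f <- oligo_formula(seq, five_prime, three_prime)
    pieces[[length(pieces) + 1L]] <-
      fragment_tbl(polymer, "precursor", NA_character_, NA_character_,
                   NA_integer_, 1L, n, NA_integer_, NA_character_, polymer,
                   matrix(counts_vec(f, OLIGO_ELEMENTS), nrow = 1,
                          dimnames = list(NULL, OLIGO_ELEMENTS)),
                   OLIGO_ELEMENTS)
  }
  out <- if (length(pieces)) dplyr::bind_rows(pieces) else empty_fragments()
  apply_neutral_losses(out, neutral_losses)
}

#' Enumerate internal (double-cleavage) fragments of a DNA oligonucleotide
#'
#' An internal fragment arises from one cleavage of each kind: a
#' 3'-retaining cut of length `i` (series w/x/y/z, fixing the fragment's
#' 5'-end chemistry) and a 5'-retaining cut at `j` (series a/b/c/d, fixing
#' its 3'-end chemistry), with a proper overlap `p..q = (n-i+1)..j` that
#' touches neither terminus (`1 < p <= q < n`).  Labels follow the
#' cleavage pair, e.g. `"w7:a8"`; `base_loss = "at-3'-cleavage"` adds `-B`
#' variants losing the base at position `q` (the 3'-side cleavage
#' residue).
#'
#' @inheritParams oligo_terminal_fragments
#' @param series3 3'-retaining series subset (5'-end chemistry of the
#'   internal fragment), default `"w"`.
#' @param series5 5'-retaining series subset (3'-end chemistry), default
#'   `"a"`.
#' @param base_loss `"none"`, `"at-3'-cleavage"` or `"any"`.
#' @return A tibble of internal fragments.
#' @examples
#' ifr <- oligo_internal_fragments("TACGTGCCAATAC",
#'                                 base_loss = "at-3'-cleavage")
#' dplyr::filter(ifr, label == "w7:a8-B")
#' @export
oligo_internal_fragments <- function(seq, series3 = "w", series5 = "a",
                                     base_loss = c("none", "at-3'-cleavage",
                                                   "any"),
                                     polymer = "seq1") {
  base_loss <- match.arg(base_loss)
  series3 <- match.arg(series3, c("w", "x", "y", "z"), several.ok = TRUE)
  series5 <- match.arg(series5, c("a", "b", "c", "d"), several.ok = TRUE)
  r <- split_residues(seq, c("A", "C", "G", "T"), "DNA")
  n <- length(r)
  if (n < 3L) return(empty_fragments())
  geo <- oligo_geometry(r)
  # all proper overlaps 1 < p <= q < n
  grid <- expand.grid(p = 2:(n - 1L), q = 2:(n - 1L))
  grid <- grid[grid$p <= grid$q, ]
  pieces <- list()
  for (s3 in series3) for (s5 in series5) {
    delta <- counts_vec(end5_delta(s3), OLIGO_ELEMENTS) +
      counts_vec(end3_delta(s5), OLIGO_ELEMENTS)
    mat <- piece_counts(geo, grid$p, grid$q) + outer(rep(1, nrow(grid)), delta)
    i3 <- n - grid$p + 1L
    lab <- paste0(s3, i3, ":", s5, grid$q)
    pieces[[length(pieces) + 1L]] <-
      fragment_tbl(polymer, "internal", s5, s3, NA_integer_,
                   grid$p, grid$q, NA_integer_, NA_character_, lab,
                   mat, OLIGO_ELEMENTS)
    if (base_loss != "none") {
      sel <- if (base_loss == "at-3'-cleavage") {
        data.frame(frag = seq_len(nrow(grid)), pos = grid$q)
      } else {
        do.call(rbind, lapply(seq_len(nrow(grid)), function(k)
          data.frame(frag = k, pos = grid$p[k]:grid$q[k])))
      }
      lmat <- mat[sel$frag, , drop = FALSE] -
        geo$basemat[sel$pos, , drop = FALSE]
      lab_b <- if (base_loss == "at-3'-cleavage") paste0(lab[sel$frag], "-B")
        else paste0(lab[sel$frag], "-B(", r[sel$pos], ")")
      pieces[[length(pieces) + 1L]] <-
        fragment_tbl(polymer, "internal", s5, s3, NA_integer_,
                     grid$p[sel$frag], grid$q[sel$frag],
                     sel$pos, r[sel$pos], lab_b, lmat, OLIGO_ELEMENTS)
    }
  }
  dplyr::bind_rows(pieces)
}
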