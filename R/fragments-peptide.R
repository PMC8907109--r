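## Peptide CID fragments: N-terminal b (residues 1..i) and a (b - CO),
## C-terminal y (residues n-i+1..n plus H2O), and double-cleavage internal
## fragments (amide type = bare residue sum; a type = amide - CO) covering
## p..q with neither terminus included.  Complementarity: b_i + y_{n-i}
## equals the neutral peptide.

PEPTIDE_ELEMENTS <- c("C", "H", "N", "O", "S")

#' Enumerate CID fragments of a peptide
#'
#' @param seq One-letter peptide sequence.
#' @param series Subset of `c("a", "b", "y")`.
#' @param internal Also enumerate internal fragments (amide and a type),
#'   covering every window `p..q` with `2 <= p <= q <= n-1`.
#' @param neutral_losses Optional neutral-loss formulas (e.g. `"NH3"`,
#'   `"H2O"`) applied to every fragment as additional variants.
#' @param include_precursor Also emit the intact peptide as a
#'   `kind = "precursor"` row.
#' @param polymer Name used in labels and reports.
#' @return A tibble of fragments with neutral formulas and masses.
#' @examples
#' peptide_fragments("VLEYLTAEILE", series = c("b", "y"))
#' @export
peptide_fragments <- function(seq, series = c("a", "b", "y"),
                              internal = FALSE, neutral_losses = NULL,
                              include_precursor = FALSE, polymer = "pep1") {
  stopifnot(length(series) >= 1)
  series <- match.arg(series, c("a", "b", "y"), several.ok = TRUE)
  aa <- amino_acid_formulas()
  r <- split_residues(seq, names(aa), "peptide")
  n <- length(r)
  resmat <- do.call(rbind, lapply(aa[r], counts_vec,
                                  elements = PEPTIDE_ELEMENTS))
  cum <- rbind(0, apply(resmat, 2, cumsum))
  piece <- function(p, q) cum[q + 1L, , drop = FALSE] - cum[p, , drop = FALSE]
  water <- counts_vec(H2O(), PEPTIDE_ELEMENTS)
  co <- counts_vec(parse_formula("CO"), PEPTIDE_ELEMENTS)
  pieces <- list()
  add <- function(x) pieces[[length(pieces) + 1L]] <<- x

  if (n > 1L) {
    i <- seq_len(n - 1L)
    bmat <- piece(rep(1L, n - 1L), i)
    if ("b" %in% series)
      add(fragment_tbl(polymer, "terminal-5'", "b", NA_character_, i,
                       1L, i, NA_integer_, NA_character_, paste0("b", i),
                       bmat, PEPTIDE_ELEMENTS))
    if ("a" %in% series) {
      amat <- bmat - outer(rep(1, n - 1L), co)
      ok <- rowSums(amat < 0) == 0
      add(fragment_tbl(polymer, "terminal-5'", "a", NA_character_, i[ok],
                       1L, i[ok], NA_integer_, NA_character_,
                       paste0("a", i[ok]), amat[ok, , drop = FALSE],
                       PEPTIDE_ELEMENTS))
    }
    if ("y" %in% series) {
      ymat <- piece(n - i + 1L, rep(n, n - 1L)) + outer(rep(1, n - 1L), water)
      add(fragment_tbl(polymer, "terminal-3'", NA_character_, "y", i,
                       n - i + 1L, n, NA_integer_, NA_character_,
                       paste0("y", i), ymat, PEPTIDE_ELEMENTS))
    }
  }

  if (internal && n > 2L) {
    grid <- expand.grid(p = 2:(n - 1L), q = 2:(n - 1L))
    grid <- grid[grid$p <= grid$q, ]
    imat <- piece(grid$p, grid$q)
    add(fragment_tbl(polymer, "internal", "b", "y", NA_integer_,
                     grid$p, grid$q, NA_integer_, NA_character_,
                     paste0("i", grid$p, ":", grid$q), imat,
                     PEPTIDE_ELEMENTS))
    amat <- imat - outer(rep(1, nrow(grid)), co)
    ok <- rowSums(amat < 0) == 0
    add(fragment_tbl(polymer, "internal", "a", "y", NA_integer_,
                     grid$p[ok], grid$q[ok], NA_integer_, NA_character_,
                     paste0("i", grid$p[ok], ":", grid$q[ok], "a"),
                     amat[ok, , drop = FALSE], PEPTIDE_ELEMENTS))
  }

  if (include_precursor)
    add(fragment_tbl(polymer, "precursor", NA_character_, NA_character_,
                     NA_integer_, 1L, n, NA_integer_, NA_character_,
                     polymer,
                     matrix(counts_vec(peptide_formula(seq),
                                       PEPTIDE_ELEMENTS), nrow = 1),
                     PEPTIDE_ELEMENTS))

  out <- if (length(pieces)) dplyr::bind_rows(pieces) else empty_fragments()
  apply_neutral_losses(out, neutral_losses)
}
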