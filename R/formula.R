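## Elemental formulas are named integer vectors (element -> count), the
## universal currency for mass arithmetic in the package.  Intermediate
## arithmetic may go negative (e.g. subtracting a neutral loss); callers
## finalize with fml_check() before computing masses or envelopes.

#' Parse a Hill-style molecular formula
#'
#' Accepts concatenated element symbols with optional positive integer
#' counts, e.g. `"C126H166N50O75P12Pt"`.  Multi-letter symbols are matched
#' greedily (longest match first), so `"Pt"` is platinum, never P + t.
#'
#' @param text Formula string.  An empty string yields the empty formula.
#' @return A named integer vector of element counts (class
#'   `"elemental_formula"`).
#' @examples
#' parse_formula("H2O")
#' parse_formula("C126H166N50O75P12Pt")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  text <- gsub("[[:space:]]", "", text)
  if (!nzchar(text)) return(fml())
  known <- unique(isotope_table()$element)
  counts <- integer(0)
  rest <- text
  while (nzchar(rest)) {
    m <- regmatches(rest, regexec("^([A-Z][a-z]?)([0-9]*)", rest))[[1]]
    if (length(m) == 0L || !nzchar(m[1]))
      abort(sprintf("cannot parse formula near '%s'", rest))
    sym <- m[2]
    if (!sym %in% known) {
      # greedy two-letter match failed: retry single letter (e.g. "CH4")
      if (nchar(sym) == 2L && substr(sym, 1L, 1L) %in% known) {
        sym <- substr(sym, 1L, 1L)
        m[1] <- paste0(sym, m[3] <- "")
      } else {
        abort(sprintf("unknown element symbol '%s' in formula '%s'", sym, text))
      }
    }
    # re-extract count after possible symbol shortening
    tail0 <- substr(rest, nchar(sym) + 1L, nchar(rest))
    cnt <- regmatches(tail0, regexpr("^[0-9]*", tail0))
    n <- if (nzchar(cnt)) suppressWarnings(as.integer(cnt)) else 1L
    if (is.na(n) || n <= 0L)
      abort(sprintf("invalid count '%s' for element '%s'", cnt, sym))
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
    rest <- substr(tail0, nchar(cnt) + 1L, nchar(tail0))
  }
  fml(counts)
}

## construct / normalize a formula vector: drop zeros, sort Hill-ish (C, H,
## then alphabetical) for stable string rendering
fml <- function(counts = integer(0)) {
  counts <- counts[counts != 0]
  if (length(counts)) {
    els <- names(counts)
    ord <- order(match(els, c("C", "H"), nomatch = 3L), els)
    counts <- counts[ord]
  }
  structure(as.integer(setNames(counts, names(counts))),
            names = names(counts), class = "elemental_formula")
}

fml_add <- function(a, b) {
  els <- union(names(a), names(b))
  fml(setNames(ifelse(is.na(a[els]), 0L, a[els]) +
                 ifelse(is.na(b[els]), 0L, b[els]), els))
}

fml_subtract <- function(a, b) {
  fml_add(a, fml(setNames(-as.integer(b), names(b))))
}

fml_multiply <- function(a, k) fml(setNames(as.integer(a) * as.integer(k), names(a)))

## finalization guard: no negative counts in a formula handed to mass math
fml_check <- function(f) {
  if (any(f < 0L))
    abort(sprintf("negative element count after losses: %s",
                  formula_string(f, allow_negative = TRUE)))
  f
}

#' Render a formula as a Hill-style string
#'
#' @param f Formula (named integer vector or string).
#' @param allow_negative Render negative counts (debugging aid) instead of
#'   erroring.
#' @return A single string, `""` for the empty formula.
#' @examples
#' formula_string(parse_formula("H2O"))
#' @export
formula_string <- function(f, allow_negative = FALSE) {
  f <- as_formula(f)
  if (!allow_negative) fml_check(f)
  if (!length(f)) return("")
  paste0(names(f), ifelse(abs(f) == 1L & f > 0L, "", f), collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<formula> ", formula_string(x, allow_negative = TRUE), "\n", sep = "")
  invisible(x)
}

as_formula <- function(f) {
  if (inherits(f, "elemental_formula")) f
  else if (is.character(f)) parse_formula(f)
  else if (is.numeric(f) && !is.null(names(f))) fml(setNames(as.integer(f), names(f)))
  else abort("cannot interpret object as an elemental formula")
}

#' Principal-isotope (monoisotopic) mass of a formula
#'
#' Sum over elements of count times the mass of the element's *most
#' abundant* isotope.  For CHNOPS this coincides with the usual lightest-
#' isotope monoisotopic mass; for platinum the principal isotope is 195Pt
#' (194.964792 Da), which is what reproduces published platinated-species
#' m/z values.
#'
#' @param f Formula (named integer vector or string).
#' @return Mass in Da; 0 for the empty formula.
#' @examples
#' monoisotopic_mass("H2O")
#' monoisotopic_mass("C126H166N50O75P12Pt")
#' @export
monoisotopic_mass <- function(f) {
  f <- fml_check(as_formula(f))
  if (!length(f)) return(0)
  pm <- principal_masses()
  missing <- setdiff(names(f), names(pm))
  if (length(missing))
    abort(paste0("no isotope data for element(s): ",
                 paste(missing, collapse = ", ")))
  sum(pm[names(f)] * as.numeric(f))
}

#' m/z of a charged species with explicit charge-carrier bookkeeping
#'
#' The species is described by its total neutral-atom mass plus three
#' charge carriers: electrons removed (one per unit of metal cationic
#' charge, e.g. 2 for a Pt(II) adduct), protons added and protons removed.
#' The signed charge must balance:
#' `z = electrons_removed + protons_added - protons_removed`.
#'
#' @param neutral_mass Total mass of the neutral atoms in Da.
#' @param electrons_removed Units of metal cationic charge (electrons
#'   subtracted at 0.000549 Da each).
#' @param protons_added,protons_removed Proton transfers at
#'   1.00727646688 Da each.
#' @param z Signed charge state (negative for anions); `|z| >= 1`.
#' @return m/z in Th.
#' @examples
#' ion_mz(4145.7212, electrons_removed = 2, protons_removed = 5, z = -3)
#' ion_mz(18.010565, protons_added = 1, z = 1)
#' @export
ion_mz <- function(neutral_mass, electrons_removed = 0, protons_added = 0,
                   protons_removed = 0, z) {
  stopifnot(is.numeric(neutral_mass), length(z) == 1L)
  z <- as.integer(z)
  if (z == 0L) abort("charge state z must be nonzero")
  balance <- electrons_removed + protons_added - protons_removed
  if (any(balance != z))
    abort(sprintf(
      "charge balance mismatch: carriers give %d but z = %d", balance[1], z))
  k <- ms_constants()
  (neutral_mass - electrons_removed * k$electron_mass +
     (protons_added - protons_removed) * k$proton_mass) / abs(z)
}
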