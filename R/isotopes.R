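## Physical constants.  CODATA values; the proton mass (not the hydrogen atom
## mass) is used for protonation/deprotonation, and the electron mass is
## subtracted once per unit of metal cationic charge, so that e.g. a Pt(II)
## adduct contributes m(Pt) - 2 m_e.  This bookkeeping is what reproduces
## Orbitrap-accurate m/z to four decimals.

#' Physical constants used for m/z arithmetic
#'
#' @return A named list with `proton_mass` and `electron_mass` in Da.
#' @examples
#' ms_constants()$proton_mass
#' @export
ms_constants <- function() {
  list(proton_mass = 1.00727646688, electron_mass = 0.00054857990)
}

#' Elemental isotope table
#'
#' Isotopic masses and natural abundances for the elements supported by the
#' package (H, C, N, O, P, S, Na, K, Cl, Pt), read from the plain-text table
#' shipped in `extdata/isotopes.tsv` so every mass in the package is
#' auditable.  The *principal* isotope of an element is its most abundant
#' one; note that for platinum this is 195Pt, which is not the lightest.
#'
#' @return A tibble with columns `element`, `isotope`, `mass`, `abundance`
#'   and logical `principal`.
#' @examples
#' dplyr::filter(isotope_table(), element == "Pt")
#' @export
isotope_table <- function() {
  if (is.null(the$isotopes)) {
    path <- system.file("extdata", "isotopes.tsv", package = "adductms",
                        mustWork = TRUE)
    tab <- as_tibble(read.table(path, header = TRUE, sep = "\t",
                                comment.char = "#",
                                colClasses = c("character", "integer",
                                               "numeric", "numeric")))
    tab <- dplyr::mutate(
      dplyr::group_by(tab, .data$element),
      principal = .data$abundance == max(.data$abundance)
    )
    the$isotopes <- dplyr::ungroup(tab)
  }
  the$isotopes
}

## named vector element -> principal-isotope mass
principal_masses <- function() {
  if (is.null(the$principal)) {
    tab <- dplyr::filter(isotope_table(), .data$principal)
    the$principal <- setNames(tab$mass, tab$element)
  }
  the$principal
}

## list element -> list(mass=, abundance=), abundance-sorted descending
element_distributions <- function() {
  if (is.null(the$eldist)) {
    tab <- isotope_table()
    the$eldist <- lapply(split(tab, tab$element), function(d) {
      o <- order(d$mass)
      list(mass = d$mass[o], abundance = d$abundance[o])
    })
  }
  the$eldist
}
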