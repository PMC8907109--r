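## Isotopologue envelopes by iterative pairwise convolution of per-element
## isotope distributions, with exponentiation-by-squaring over element
## counts.  Centroids closer than `merge_tol` (1 mDa default) are merged by
## abundance-weighted averaging -- appropriate for Orbitrap-resolved
## centroid data, where fine structure within a millidalton is unresolved.

convolve_dist <- function(a, b, merge_tol, floor_rel = 1e-12) {
  m <- outer(a$mass, b$mass, `+`)
  p <- outer(a$abundance, b$abundance, `*`)
  merge_centroids(list(mass = as.numeric(m), abundance = as.numeric(p)),
                  merge_tol, floor_rel)
}

## cluster sorted centroids whose consecutive gaps are < tol; centroid mass
## is the abundance-weighted mean
merge_centroids <- function(d, merge_tol, floor_rel = 0) {
  o <- order(d$mass)
  mass <- d$mass[o]; ab <- d$abundance[o]
  if (length(mass) > 1L) {
    grp <- cumsum(c(1L, diff(mass) >= merge_tol))
    ab_g <- as.numeric(tapply(ab, grp, sum))
    mass_g <- as.numeric(tapply(mass * ab, grp, sum)) / ab_g
    mass <- mass_g; ab <- ab_g
  }
  if (floor_rel > 0) {
    keep <- ab >= floor_rel * max(ab)
    mass <- mass[keep]; ab <- ab[keep]
  }
  list(mass = mass, abundance = ab)
}

dist_power <- function(d, n, merge_tol) {
  # exponentiation by squaring of the convolution power
  res <- NULL
  sq <- d
  while (n > 0L) {
    if (n %% 2L == 1L)
      res <- if (is.null(res)) sq else convolve_dist(res, sq, merge_tol)
    n <- n %/% 2L
    if (n > 0L) sq <- convolve_dist(sq, sq, merge_tol)
  }
  res
}

#' Isotopologue envelope of a formula
#'
#' Convolves the natural isotope distributions of every atom in the formula
#' into the centroided envelope of isotopologue masses and relative
#' abundances.  Peaks below `prune` times the base (most abundant) peak are
#' dropped and the remainder renormalized to sum to 1.  Platinum-containing
#' formulas get the characteristic multi-peak shape of Pt's six isotopes,
#' and their most abundant isotopologue is generally *not* the lowest-mass
#' one.
#'
#' @param f Formula (named integer vector or string).
#' @param prune Relative-abundance threshold in `[0, 1)`; peaks below
#'   `prune * max` are dropped (default `1e-4`).
#' @param merge_tol Centroid merge width in Da (default 1 mDa).
#' @return A tibble with columns `mass` (Da, strictly increasing) and
#'   `abundance` (summing to 1).
#' @examples
#' isotope_pattern("Pt", prune = 0)
#' isotope_pattern("C100")
#' @export
isotope_pattern <- function(f, prune = 1e-4, merge_tol = 1e-3) {
  f <- fml_check(as_formula(f))
  stopifnot(prune >= 0, prune < 1)
  if (!length(f))
    return(tibble(mass = numeric(0), abundance = numeric(0)))
  key <- paste0(formula_string(f), "|", prune, "|", merge_tol)
  if (is.null(the$env_cache)) the$env_cache <- new.env(parent = emptyenv())
  hit <- the$env_cache[[key]]
  if (!is.null(hit)) return(hit)
  eld <- element_distributions()
  missing <- setdiff(names(f), names(eld))
  if (length(missing))
    abort(paste0("no isotope data for element(s): ",
                 paste(missing, collapse = ", ")))
  acc <- NULL
  for (el in names(f)) {
    p <- dist_power(eld[[el]], as.integer(f[[el]]), merge_tol)
    acc <- if (is.null(acc)) p else convolve_dist(acc, p, merge_tol)
  }
  keep <- acc$abundance >= prune * max(acc$abundance)
  mass <- acc$mass[keep]; ab <- acc$abundance[keep]
  out <- tibble(mass = mass, abundance = ab / sum(ab))
  the$env_cache[[key]] <- out
  out
}

## Envelope of a charged species in m/z space: shift each isotopologue by
## the charge-carrier mass delta, divide by |z|, then merge fine isotopic
## structure the instrument cannot resolve (width = mz / resolution, the
## FWHM of an FT analyser at its nominal resolving power).  At R = 120000
## this collapses the sub-mDa fine structure of Pt-containing formulas
## into one centroid per nominal isotopologue while keeping the 1.003/|z|
## isotopologue spacing fully resolved.
envelope_mz <- function(f, electrons_removed, protons_added, protons_removed,
                        z, prune = 1e-4, resolution = 120000) {
  pat <- isotope_pattern(f, prune = min(prune, 1e-4))
  k <- ms_constants()
  delta <- -electrons_removed * k$electron_mass +
    (protons_added - protons_removed) * k$proton_mass
  mz <- (pat$mass + delta) / abs(z)
  merged <- merge_centroids(list(mass = mz, abundance = pat$abundance),
                            merge_tol = mean(mz) / resolution)
  keep <- merged$abundance >= prune * max(merged$abundance)
  ab <- merged$abundance[keep]
  tibble(mz = merged$mass[keep], abundance = ab / sum(ab))
}
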