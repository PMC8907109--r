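## Charged-species construction.  Metal binding is modeled purely as a
## formula + cationic-charge delta: a Pt(II) adduct adds the neutral atoms
## PtN2H6 (for Pt(NH3)2) and removes two electrons; covalent H displacement
## at the binding site is absorbed into the species' net proton count,
## matching the "[M + Pt(NH3)2 - 8H]6-" bookkeeping of published spectra.
## Alkali exchange (Na/K for H) is a +1 cationic adduct whose paired proton
## removal is counted in the species' protons_removed.

#' Built-in adduct menu
#'
#' @param polarity `"neg"` (oligonucleotides: Pt adducts plus Na/K
#'   exchange) or `"pos"` (peptides: Pt adducts only).
#' @param max_count Maximum copies of each adduct per species.
#' @return A tibble with columns `name`, `formula`, `cationic_charge`,
#'   `max_count` -- the format accepted by [expand_search_space()]; custom
#'   menus can be built the same way (or read with [read_adduct_menu()]).
#' @examples
#' default_adducts("neg")
#' @export
default_adducts <- function(polarity = c("neg", "pos"), max_count = 3L) {
  polarity <- match.arg(polarity)
  menu <- tibble(
    name = c("Pt", "Pt(NH3)", "Pt(NH3)2", "Na", "K"),
    formula = c("Pt", "H3NPt", "H6N2Pt", "Na", "K"),
    cationic_charge = c(2L, 2L, 2L, 1L, 1L),
    max_count = as.integer(max_count))
  if (polarity == "pos") menu[menu$name != "Na" & menu$name != "K", ]
  else menu
}

#' Read an adduct menu from a JSON config file
#'
#' The file holds an array of objects with fields `name`, `formula`,
#' `cationic_charge` and optional `max_count` (default 3).
#'
#' @param path JSON file.
#' @return An adduct-menu tibble.
#' @export
read_adduct_menu <- function(path) {
  x <- jsonlite::fromJSON(path)
  stopifnot(all(c("name", "formula", "cationic_charge") %in% names(x)))
  if (is.null(x$max_count)) x$max_count <- 3L
  for (f in x$formula) parse_formula(f)  # validate
  tibble(name = as.character(x$name), formula = as.character(x$formula),
         cationic_charge = as.integer(x$cationic_charge),
         max_count = as.integer(x$max_count))
}

adduct_label <- function(names, counts) {
  keep <- counts > 0L
  if (!any(keep)) return("")
  paste0(ifelse(counts[keep] > 1L, counts[keep], ""), names[keep],
         collapse = " + ")
}

species_label <- function(frag_label, adduct_lab, protons_added,
                          protons_removed, z) {
  parts <- frag_label
  if (nzchar(adduct_lab)) parts <- paste(parts, "+", adduct_lab)
  if (protons_added > 0L) parts <- paste0(parts, " + ", protons_added, "H")
  if (protons_removed > 0L) parts <- paste0(parts, " - ", protons_removed, "H")
  paste0("[", parts, "]", abs(z), if (z < 0L) "-" else "+")
}

#' Build a charged adducted species from a fragment
#'
#' Computes the species' theoretical m/z from the total neutral-atom mass
#' with one electron mass subtracted per unit of metal cationic charge and
#' proton-mass transfers; the signed charge is
#' `z = cationic charge + protons added - protons removed` and must be
#' nonzero.
#'
#' @param fragments A fragment tibble (one or more rows) from the
#'   enumeration functions, or anything with `label`, `formula` columns.
#' @param adducts Named integer vector of adduct counts, e.g.
#'   `c("Pt(NH3)2" = 1)`; names must appear in `menu`.  `NULL` for a bare
#'   (de)protonated species.
#' @param protons_added,protons_removed Proton transfer counts.
#' @param menu Adduct-menu tibble (see [default_adducts()]).
#' @return A species tibble: the fragment columns plus `adducts`,
#'   `cationic_charge`, `protons_added`, `protons_removed`, `z`, `formula`
#'   (total neutral atoms), `mz`, `platinated` and `species_label`.
#' @examples
#' pre <- oligo_terminal_fragments("GTATTGGCACGTA", series = "a",
#'                                 include_precursor = TRUE, polymer = "S1")
#' build_species(dplyr::filter(pre, kind == "precursor"),
#'               adducts = c("Pt(NH3)2" = 1), protons_removed = 8)
#' @export
build_species <- function(fragments, adducts = NULL, protons_added = 0,
                          protons_removed = 0,
                          menu = default_adducts("neg")) {
  protons_added <- as.integer(protons_added)
  protons_removed <- as.integer(protons_removed)
  stopifnot(protons_added >= 0L, protons_removed >= 0L)
  counts <- integer(nrow(menu))
  names(counts) <- menu$name
  if (!is.null(adducts) && length(adducts)) {
    bad <- setdiff(names(adducts), menu$name)
    if (length(bad))
      abort(paste0("adduct(s) not in menu: ", paste(bad, collapse = ", ")))
    counts[names(adducts)] <- as.integer(adducts)
  }
  cationic <- sum(counts * menu$cationic_charge)
  z <- cationic + protons_added - protons_removed
  if (z == 0L) abort("species has zero net charge")
  delta <- fml()
  for (i in seq_along(counts))
    if (counts[i] > 0L)
      delta <- fml_add(delta, fml_multiply(parse_formula(menu$formula[i]),
                                           counts[i]))
  adduct_lab <- adduct_label(menu$name, counts)
  platinated <- any(counts > 0L &
                      purrr::map_lgl(menu$formula,
                                     ~ "Pt" %in% names(parse_formula(.x))))
  purrr::map_dfr(seq_len(nrow(fragments)), function(i) {
    fr <- fragments[i, ]
    total <- fml_add(parse_formula(fr$formula), delta)
    # proton transfers must leave a physical H count
    if (sum(total[names(total) == "H"], 0L) - protons_removed < 0L)
      abort(sprintf("cannot remove %d protons from %s", protons_removed,
                    formula_string(total)))
    dplyr::mutate(
      dplyr::rename(fr, frag_label = "label", frag_formula = "formula"),
      adducts = adduct_lab,
      cationic_charge = cationic,
      protons_added = protons_added,
      protons_removed = protons_removed,
      z = z,
      formula = formula_string(total),
      mz = ion_mz(monoisotopic_mass(total), cationic, protons_added,
                  protons_removed, z),
      platinated = platinated,
      species_label = species_label(fr$label, adduct_lab, protons_added,
                                    protons_removed, z))
  })
}

#' Isotopologue envelope of a species in m/z space
#'
#' The envelope is centroided at the instrument's resolving power:
#' isotopologues closer than `mz / resolution` (FWHM) are merged into one
#' peak, so fine isotopic structure the analyser cannot separate appears
#' as a single centroid, as in real centroided data.
#'
#' @param species One row of a species tibble from [build_species()] or
#'   [expand_search_space()].
#' @param prune Envelope pruning threshold, see [isotope_pattern()].
#' @param resolution Resolving power used to merge fine structure
#'   (default 120000).
#' @return Tibble with `mz` and `abundance` columns.
#' @export
species_envelope <- function(species, prune = 1e-4, resolution = 120000) {
  stopifnot(nrow(species) == 1L)
  envelope_mz(parse_formula(species$formula), species$cationic_charge,
              species$protons_added, species$protons_removed, species$z,
              prune = prune, resolution = resolution)
}

#' Expand fragments into the full charged-species search space
#'
#' Cartesian expansion of fragments over adduct multisets (0..`max_count`
#' copies of each menu adduct) and charge states.  For each combination the
#' proton transfers are set to reach the target charge: protons are added
#' when the target exceeds the adducts' cationic charge and removed
#' otherwise (the universal pattern of ESI adduct series).  Species are
#' deduplicated by (ion formula, z) and ordered by m/z then label.
#'
#' @param fragments Fragment tibble.
#' @param menu Adduct-menu tibble.
#' @param charges Vector of charge magnitudes, e.g. `1:6`.
#' @param polarity `"neg"` or `"pos"`.
#' @param cap Maximum number of species; beyond it the list is truncated
#'   (lowest m/z kept) with a warning, or an error if `strict`.
#' @param strict Error instead of truncating when `cap` is exceeded.
#' @return A species tibble as in [build_species()].
#' @examples
#' fr <- oligo_terminal_fragments("GTATTG", series = "w", polymer = "S")
#' expand_search_space(fr, menu = default_adducts("neg", max_count = 1),
#'                     charges = 1:2)
#' @export
expand_search_space <- function(fragments, menu = default_adducts("neg"),
                                charges = 1:6,
                                polarity = c("neg", "pos"),
                                cap = 200000L, strict = FALSE) {
  polarity <- match.arg(polarity)
  stopifnot(nrow(fragments) >= 1L, cap > 0)
  charges <- sort(unique(as.integer(charges)))
  stopifnot(all(charges >= 1L))
  sign_z <- if (polarity == "neg") -1L else 1L

  ## adduct combinations: counts 0..max per adduct
  grids <- lapply(menu$max_count, function(m) 0:m)
  combos <- as.matrix(expand.grid(grids))
  colnames(combos) <- menu$name
  combo_charge <- as.integer(combos %*% menu$cationic_charge)
  ad_forms <- lapply(menu$formula, parse_formula)
  elements <- sort(unique(c(unlist(lapply(ad_forms, names)),
                            unlist(lapply(fragments$formula,
                                          function(s) names(parse_formula(s)))))))
  ad_mat <- do.call(rbind, lapply(ad_forms, function(f) {
    v <- setNames(integer(length(elements)), elements)
    v[names(f)] <- as.integer(f)
    v
  }))
  combo_elem <- combos %*% ad_mat                 # combos x elements
  combo_mass <- as.numeric(combo_elem %*% principal_masses()[elements])
  combo_lab <- vapply(seq_len(nrow(combos)), function(i)
    adduct_label(menu$name, combos[i, ]), character(1))
  pt_el <- match("Pt", elements)
  combo_pt <- if (is.na(pt_el)) rep(FALSE, nrow(combos)) else combo_elem[, pt_el] > 0

  frag_mat <- do.call(rbind, lapply(fragments$formula, function(s) {
    f <- parse_formula(s)
    v <- setNames(integer(length(elements)), elements)
    v[names(f)] <- as.integer(f)
    v
  }))
  frag_mass <- fragments$neutral_mass

  idx <- expand.grid(frag = seq_len(nrow(fragments)),
                     combo = seq_len(nrow(combos)),
                     zmag = charges)
  n_total <- nrow(idx)
  z <- sign_z * idx$zmag
  cat_ch <- combo_charge[idx$combo]
  net <- z - cat_ch
  pa <- pmax(net, 0L)
  pr <- pmax(-net, 0L)
  k <- ms_constants()
  neutral <- frag_mass[idx$frag] + combo_mass[idx$combo]
  mz <- (neutral - cat_ch * k$electron_mass + (pa - pr) * k$proton_mass) /
    abs(z)

  ## ion formula (H adjusted by net proton transfer) for dedup; drop
  ## species whose proton removals exceed the available hydrogens
  elem_tot <- frag_mat[idx$frag, , drop = FALSE] +
    combo_elem[idx$combo, , drop = FALSE]
  h_el <- match("H", elements)
  h_ion <- elem_tot[, h_el] + (pa - pr)
  ok <- h_ion >= 0L
  elem_ion <- elem_tot
  elem_ion[, h_el] <- h_ion
  key <- paste(do.call(paste, c(as.data.frame(elem_ion), sep = ",")), z)
  keep <- ok & !duplicated(key)

  if (sum(keep) > cap) {
    if (strict)
      abort(sprintf("search space has %d species, exceeding cap %d",
                    sum(keep), cap))
    warn(sprintf("search space truncated to cap = %d species (of %d)",
                 cap, sum(keep)))
    ord_keep <- which(keep)[order(mz[keep])][seq_len(cap)]
    keep <- logical(n_total)
    keep[ord_keep] <- TRUE
  }

  sel <- which(keep)
  out <- fragments[idx$frag[sel], ]
  out <- dplyr::rename(out, frag_label = "label", frag_formula = "formula")
  out$adducts <- combo_lab[idx$combo[sel]]
  out$cationic_charge <- cat_ch[sel]
  out$protons_added <- pa[sel]
  out$protons_removed <- pr[sel]
  out$z <- z[sel]
  out$formula <- formula_strings(elem_tot[sel, , drop = FALSE], elements)
  out$mz <- mz[sel]
  out$platinated <- combo_pt[idx$combo[sel]]
  lab <- out$frag_label
  al <- combo_lab[idx$combo[sel]]
  lab <- ifelse(nzchar(al), paste(lab, "+", al), lab)
  lab <- ifelse(pa[sel] > 0L, paste0(lab, " + ", pa[sel], "H"), lab)
  lab <- ifelse(pr[sel] > 0L, paste0(lab, " - ", pr[sel], "H"), lab)
  out$species_label <- paste0("[", lab, "]", abs(z[sel]),
                              ifelse(z[sel] < 0L, "-", "+"))
  out <- out[order(out$mz, out$species_label), ]
  tibble::as_tibble(out)
}
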