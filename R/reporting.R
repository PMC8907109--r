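## Evidence summaries.  "Platinated" means the species carries at least
## one metal-containing adduct (alkali exchange alone does not count);
## region classes follow fragment topology: fragments retaining the 5'
## terminus (or peptide N terminus: a/b) are "5'-end", those retaining the
## 3' terminus (peptide y) are "3'-end", and double-cleavage internal
## fragments are "Middle".

match_tracks <- function(matches) {
  dplyr::transmute(
    matches,
    label = .data$species_label,
    frag_label = .data$frag_label,
    kind = .data$kind,
    start = .data$start, end = .data$end,
    platinated = .data$platinated,
    similarity = .data$similarity)
}

#' Build a fragment map from a match list
#'
#' Groups matched fragments into 5'-terminal, 3'-terminal and internal
#' tracks over the sequence and tallies, per position, how many platinated
#' and unplatinated fragments cover it.
#'
#' @param matches Match tibble from [match_spectrum()] (or any species
#'   tibble with `kind`, `start`, `end`, `platinated`, `similarity`,
#'   `species_label` columns).  All rows must reference one polymer.
#' @param sequence The polymer sequence the matches refer to.
#' @return An object of class `fragment_map` with elements `sequence`,
#'   `tracks` (one row per match) and `positions` (per-position platinated
#'   / unplatinated coverage counts).  Has [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()] methods.
#' @examples
#' fr <- oligo_terminal_fragments("GTATTG", series = c("a", "w"))
#' sp <- build_species(fr, protons_removed = 1)
#' sp$similarity <- 1
#' build_fragment_map(sp, "GTATTG")
#' @export
build_fragment_map <- function(matches, sequence) {
  residues <- strsplit(toupper(gsub("[[:space:]]", "", sequence)), "")[[1]]
  n <- length(residues)
  if (nrow(matches)) {
    if (length(unique(matches$polymer)) > 1L)
      abort("match list mixes more than one polymer")
    if (any(matches$start < 1L | matches$end > n))
      abort("match interval outside the sequence")
  }
  tracks <- if (nrow(matches)) match_tracks(matches) else
    tibble(label = character(), frag_label = character(),
           kind = character(), start = integer(), end = integer(),
           platinated = logical(), similarity = numeric())
  tracks <- tracks[order(tracks$kind, tracks$start, tracks$end,
                         tracks$label), ]
  pos <- tibble(position = seq_len(n), residue = residues,
                platinated = 0L, unplatinated = 0L)
  for (i in seq_len(nrow(tracks))) {
    idx <- tracks$start[i]:tracks$end[i]
    col <- if (tracks$platinated[i]) "platinated" else "unplatinated"
    pos[[col]][idx] <- pos[[col]][idx] + 1L
  }
  structure(list(sequence = paste(residues, collapse = ""),
                 tracks = tracks, positions = pos),
            class = "fragment_map")
}

#' @export
print.fragment_map <- function(x, ...) {
  cat("<fragment_map> ", x$sequence, "\n",
      "  ", nrow(x$tracks), " matched fragments (",
      sum(x$tracks$platinated), " platinated)\n", sep = "")
  invisible(x)
}

#' @rdname build_fragment_map
#' @param x A `fragment_map`.
#' @param ... Unused.
#' @export
tidy.fragment_map <- function(x, ...) x$positions

#' @rdname build_fragment_map
#' @export
glance.fragment_map <- function(x, ...) {
  tibble(n_positions = nrow(x$positions),
         n_matches = nrow(x$tracks),
         n_platinated = sum(x$tracks$platinated),
         n_internal = sum(x$tracks$kind == "internal"),
         mean_similarity = if (nrow(x$tracks)) mean(x$tracks$similarity)
         else NA_real_)
}

region_class <- function(kind) {
  dplyr::case_match(kind,
                    "terminal-5'" ~ "5'-end",
                    "terminal-3'" ~ "3'-end",
                    "internal" ~ "Middle",
                    .default = NA_character_)
}

#' Classify matched fragments into 5'-end / 3'-end / Middle regions
#'
#' Percentages are computed separately over the platinated and the
#' unplatinated evidence sets; precursor matches are excluded.  By default
#' each unique species counts once; set `distinct_fragments = TRUE` to
#' collapse charge states / adduct forms of the same fragment first.
#'
#' @param matches Match tibble.
#' @param distinct_fragments Count each underlying fragment once instead
#'   of each species.
#' @return A tibble with one row per class and evidence set: `class`,
#'   `set` (`"platinated"`/`"unplatinated"`), `n`, `percent`, and
#'   `empty_set` flagging an evidence set with no members (its percentages
#'   are reported as 0).
#' @export
classify_regions <- function(matches, distinct_fragments = FALSE) {
  m <- matches[matches$kind != "precursor", , drop = FALSE]
  if (nrow(m) && distinct_fragments)
    m <- dplyr::distinct(m, .data$polymer, .data$frag_label,
                         .keep_all = TRUE)
  classes <- c("5'-end", "3'-end", "Middle")
  grid <- tidyr::expand_grid(class = classes,
                             set = c("platinated", "unplatinated"))
  if (!nrow(m)) {
    return(dplyr::mutate(grid, n = 0L, percent = 0, empty_set = TRUE))
  }
  m$class <- region_class(m$kind)
  m$set <- ifelse(m$platinated, "platinated", "unplatinated")
  tab <- dplyr::count(m, .data$class, .data$set)
  out <- dplyr::left_join(grid, tab, by = c("class", "set"))
  out$n[is.na(out$n)] <- 0L
  out <- dplyr::group_by(out, .data$set)
  out <- dplyr::mutate(out,
                       total = sum(.data$n),
                       percent = ifelse(.data$total > 0,
                                        100 * .data$n / .data$total, 0),
                       empty_set = .data$total == 0L)
  dplyr::select(dplyr::ungroup(out), -"total")
}

#' Per-position residue occurrence histogram
#'
#' For each sequence position, counts the matched fragments (terminal and
#' internal) whose covered interval includes it, split into platinated and
#' unplatinated evidence.
#'
#' @param matches Match tibble.
#' @param sequence Polymer sequence.
#' @return Tibble with `position`, `residue`, `platinated`, `unplatinated`
#'   counts.
#' @export
residue_histogram <- function(matches, sequence) {
  map <- build_fragment_map(matches[matches$kind != "precursor", ,
                                    drop = FALSE], sequence)
  map$positions
}

#' Write a fragment-map report as JSON
#'
#' @param map A `fragment_map`.
#' @param path Output JSON path.
#' @return `map`, invisibly.
#' @export
write_fragment_map <- function(map, path) {
  jsonlite::write_json(
    list(sequence = map$sequence, tracks = map$tracks,
         positions = map$positions),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(map)
}
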