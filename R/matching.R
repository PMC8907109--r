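## Envelope-to-peak matching.  Each theoretical isotopologue is assigned
## the nearest experimental centroid within a ppm tolerance (greedily in
## descending abundance order; a peak serves at most one isotopologue per
## species, but isobaric species may reuse peaks).  The similarity score is
## the total-variation overlap of the aligned, unit-normalized intensity
## vectors: 1 - 0.5 * sum |I_theo - I_exp|, which is 1 iff the envelope
## shapes agree and 0 when nothing is matched.

#' Read a centroided peak list
#'
#' Supports plain two-column text (m/z, intensity; whitespace- or
#' tab-delimited; `#` comment lines skipped) and MGF (first `BEGIN IONS`
#' block by default).
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"txt"` or `"mgf"`.
#' @param block For MGF, which ions block to read (default 1).
#' @return A tibble with columns `mz`, `intensity`, sorted by m/z, with a
#'   `pepmass` attribute for MGF input when present.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("# demo", "100.0 10", "200.0 5"), f)
#' read_peaklist(f)
#' @export
read_peaklist <- function(path, format = c("auto", "txt", "mgf"), block = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("spectrum file not found: %s", path))
  if (format == "auto")
    format <- if (grepl("\\.mgf$", path, ignore.case = TRUE)) "mgf" else "txt"
  lines <- readLines(path, warn = FALSE)
  pepmass <- NULL
  if (format == "mgf") {
    begins <- grep("^BEGIN IONS", lines)
    ends <- grep("^END IONS", lines)
    if (length(begins) < block || length(ends) < block)
      abort(sprintf("MGF block %d not found in %s", block, path))
    body <- lines[(begins[block] + 1L):(ends[block] - 1L)]
    pm <- grep("^PEPMASS=", body, value = TRUE)
    if (length(pm))
      pepmass <- as.numeric(strsplit(sub("^PEPMASS=", "", pm[1]), "\\s+")[[1]][1])
    keep <- !grepl("^[A-Z]+=", body)
    lines <- body[keep]
    offset <- begins[block]
  } else {
    offset <- 0L
  }
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep) + offset
  lines <- lines[keep]
  if (!length(lines)) abort(sprintf("empty spectrum: %s", path))
  parts <- strsplit(trimws(lines), "[\\s,;]+", perl = TRUE)
  mz <- numeric(length(parts)); int <- numeric(length(parts))
  for (i in seq_along(parts)) {
    v <- suppressWarnings(as.numeric(parts[[i]][1:2]))
    if (length(parts[[i]]) < 2L || anyNA(v))
      abort(sprintf("malformed peak line %d in %s: '%s'", lineno[i], path,
                    lines[i]))
    mz[i] <- v[1]; int[i] <- v[2]
  }
  if (any(mz <= 0) || any(int < 0))
    abort(sprintf("nonpositive m/z or negative intensity in %s", path))
  o <- order(mz)
  out <- tibble(mz = mz[o], intensity = int[o])
  attr(out, "pepmass") <- pepmass
  out
}

## assign isotopologues to peaks: returns integer vector (peak index or NA)
assign_peaks <- function(env_mz, env_ab, peaks_mz, ppm_tol) {
  assigned <- rep(NA_integer_, length(env_mz))
  used <- logical(length(peaks_mz))
  for (i in order(env_ab, decreasing = TRUE)) {
    tol <- env_mz[i] * ppm_tol * 1e-6
    d <- abs(peaks_mz - env_mz[i])
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol) {
      assigned[i] <- j
      used[j] <- TRUE
    }
  }
  assigned
}

#' Total-variation similarity between an envelope and a spectrum
#'
#' Each isotopologue takes the nearest unused peak within `ppm_tol`
#' (unmatched isotopologues contribute zero observed intensity).  The
#' theoretical abundances and the matched intensities are each normalized
#' to unit sum over the envelope support, and the score is
#' `1 - 0.5 * sum(|theoretical - observed|)`.
#'
#' @param envelope Tibble with `mz` and `abundance` (e.g. from
#'   [species_envelope()]).
#' @param peaks Peak-list tibble (`mz`, `intensity`).
#' @param ppm_tol Match tolerance in ppm.
#' @return Score in `[0, 1]`; 0 when no isotopologue is matched.
#' @export
envelope_similarity <- function(envelope, peaks, ppm_tol = 5) {
  stopifnot(nrow(envelope) >= 1L)
  if (!nrow(peaks)) return(0)
  a <- assign_peaks(envelope$mz, envelope$abundance, peaks$mz, ppm_tol)
  obs <- ifelse(is.na(a), 0, peaks$intensity[a])
  if (sum(obs) <= 0) return(0)
  theo <- envelope$abundance / sum(envelope$abundance)
  obs <- obs / sum(obs)
  1 - 0.5 * sum(abs(theo - obs))
}

## single-linkage isobar grouping of sorted principal m/z values
isobar_groups <- function(mz_sorted, ppm_tol) {
  if (!length(mz_sorted)) return(integer(0))
  gap <- diff(mz_sorted) > mz_sorted[-length(mz_sorted)] * ppm_tol * 1e-6
  cumsum(c(1L, as.integer(gap)))
}

#' Match theoretical species against a centroided spectrum
#'
#' For every candidate species the isotopologue envelope is aligned to the
#' spectrum within `ppm_tol` and scored with [envelope_similarity()].  A
#' species is reported when its score reaches `min_similarity` *and* its
#' principal (most abundant) isotopologue found a peak.  Species whose
#' principal m/z values fall within `ppm_tol` of each other share an
#' `isobar_group` id; isobaric assignments are reported side by side, never
#' silently resolved.
#'
#' @param species Species tibble from [build_species()] /
#'   [expand_search_space()].
#' @param peaks Peak-list tibble.
#' @param ppm_tol Tolerance in ppm (default 5, Orbitrap-scale).
#' @param min_similarity Similarity filter (default 0.75; use 0.90 for
#'   full-scan survey matching).
#' @param prune Envelope pruning threshold passed to [isotope_pattern()].
#' @return A tibble of matches sorted by similarity (descending) then
#'   absolute ppm error: the species columns plus `similarity`, `mz_obs`,
#'   `ppm`, `n_matched` and `isobar_group`.
#' @export
match_spectrum <- function(species, peaks, ppm_tol = 5,
                           min_similarity = 0.75, prune = 1e-4) {
  stopifnot(nrow(species) >= 1L)
  ## cheap prefilter: any peak within an envelope-width window of the
  ## species' principal-isotope m/z
  win <- 4 / pmax(abs(species$z), 1L)
  lo <- findInterval(species$mz - win, peaks$mz)
  hi <- findInterval(species$mz + win, peaks$mz)
  cand <- which(hi > lo)
  res <- purrr::map_dfr(cand, function(i) {
    sp <- species[i, ]
    env <- species_envelope(sp, prune = prune)
    a <- assign_peaks(env$mz, env$abundance, peaks$mz, ppm_tol)
    principal <- which.max(env$abundance)
    if (is.na(a[principal])) return(NULL)
    obs <- ifelse(is.na(a), 0, peaks$intensity[a])
    if (sum(obs) <= 0) return(NULL)
    theo <- env$abundance / sum(env$abundance)
    sim <- 1 - 0.5 * sum(abs(theo - obs / sum(obs)))
    mz_obs <- peaks$mz[a[principal]]
    dplyr::mutate(sp,
                  similarity = sim,
                  mz_principal = env$mz[principal],
                  mz_obs = mz_obs,
                  ppm = (mz_obs - env$mz[principal]) / env$mz[principal] * 1e6,
                  n_matched = sum(!is.na(a)))
  })
  if (is.null(res) || !nrow(res)) {
    res <- dplyr::mutate(species[0, ], similarity = numeric(0),
                         mz_principal = numeric(0), mz_obs = numeric(0),
                         ppm = numeric(0), n_matched = integer(0),
                         isobar_group = integer(0))
    return(res)
  }
  res <- res[res$similarity >= min_similarity, ]
  o <- order(res$mz_principal)
  grp <- integer(nrow(res))
  grp[o] <- isobar_groups(res$mz_principal[o], ppm_tol)
  res$isobar_group <- grp
  res[order(-res$similarity, abs(res$ppm), res$species_label), ]
}

#' Write a match table to TSV and JSON
#'
#' @param matches Match tibble from [match_spectrum()].
#' @param path_tsv,path_json Output paths (`NULL` to skip either).
#' @return `matches`, invisibly.
#' @export
write_match_report <- function(matches, path_tsv = NULL, path_json = NULL) {
  cols <- intersect(c("species_label", "frag_label", "adducts", "formula",
                      "z", "mz", "mz_obs", "ppm", "similarity",
                      "isobar_group", "platinated", "kind", "start", "end"),
                    names(matches))
  out <- matches[, cols]
  if (!is.null(path_tsv))
    utils::write.table(out, path_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(out, path_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(matches)
}
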