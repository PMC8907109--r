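## Seeded simulator of isotopically resolved centroid spectra.  Each
## planted species contributes its isotopologue envelope scaled so the
## base isotopologue carries the species' relative abundance; m/z jitter
## is multiplicative (ppm-scale, as instruments drift), intensities get
## log-normal multiplicative noise, and decoy peaks are uniform in m/z
## with exponentially distributed intensities.  The same seed reproduces
## the spectrum exactly.

#' Simulate a centroided spectrum from planted species
#'
#' @param species Species tibble ([build_species()] /
#'   [expand_search_space()]) of the planted ions.
#' @param abundances Relative base-peak abundance per species (recycled;
#'   default 1).
#' @param mz_jitter_ppm Gaussian m/z jitter sigma, in ppm.
#' @param intensity_sigma Log-normal multiplicative intensity noise sigma
#'   (natural-log scale).
#' @param n_decoys Number of uniform decoy noise peaks.
#' @param decoy_mz_range m/z range for decoys; defaults to the planted
#'   envelope range widened by 10 percent.
#' @param decoy_intensity Mean (exponential) decoy intensity, as a
#'   fraction of the largest planted peak.
#' @param prune Envelope pruning threshold.
#' @param seed Integer seed fixing the full output; `NULL` leaves the RNG
#'   state alone.
#' @return A peak-list tibble (`mz`, `intensity`) sorted by m/z.
#' @examples
#' fr <- oligo_terminal_fragments("GTATTG", series = "w")
#' sp <- build_species(fr[3, ], protons_removed = 1)
#' simulate_spectrum(sp, n_decoys = 5, seed = 1)
#' @export
simulate_spectrum <- function(species, abundances = 1,
                              mz_jitter_ppm = 0, intensity_sigma = 0,
                              n_decoys = 0, decoy_mz_range = NULL,
                              decoy_intensity = 0.05, prune = 1e-4,
                              seed = NULL) {
  if (nrow(species) == 0L && n_decoys == 0L)
    abort("nothing to simulate: no planted species and no decoys")
  stopifnot(mz_jitter_ppm >= 0, intensity_sigma >= 0, n_decoys >= 0)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
  }
  abundances <- rep_len(abundances, max(nrow(species), 1L))
  mz <- numeric(0); int <- numeric(0)
  for (i in seq_len(nrow(species))) {
    env <- species_envelope(species[i, ], prune = prune)
    m <- env$mz * (1 + rnorm(nrow(env), 0, mz_jitter_ppm) * 1e-6)
    a <- env$abundance / max(env$abundance) * abundances[i]
    if (intensity_sigma > 0)
      a <- a * exp(rnorm(nrow(env), 0, intensity_sigma))
    mz <- c(mz, m); int <- c(int, a)
  }
  if (n_decoys > 0) {
    if (is.null(decoy_mz_range)) {
      rng <- if (length(mz)) range(mz) else c(100, 2000)
      pad <- 0.05 * diff(rng) + 1
      decoy_mz_range <- c(max(rng[1] - pad, 1), rng[2] + pad)
    }
    base <- if (length(int)) max(int) else 1
    mz <- c(mz, runif(n_decoys, decoy_mz_range[1], decoy_mz_range[2]))
    int <- c(int, rexp(n_decoys, rate = 1 / (decoy_intensity * base)))
  }
  o <- order(mz)
  tibble(mz = mz[o], intensity = int[o])
}

#' Write a peak list as plain text or MGF
#'
#' The text dialect written here is the one [read_peaklist()] consumes, so
#' simulated spectra round-trip exactly.
#'
#' @param peaks Peak-list tibble.
#' @param path Output path.
#' @param format `"txt"` (two columns) or `"mgf"` (single ions block).
#' @param pepmass Optional precursor m/z recorded in the MGF header.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(peaks, path, format = c("txt", "mgf"),
                           pepmass = NULL) {
  format <- match.arg(format)
  rows <- sprintf("%.6f %.8g", peaks$mz, peaks$intensity)
  lines <- switch(format,
    txt = c("# m/z intensity", rows),
    mgf = c("BEGIN IONS", "TITLE=simulated",
            if (!is.null(pepmass)) sprintf("PEPMASS=%.6f", pepmass),
            rows, "END IONS"))
  writeLines(lines, path)
  invisible(path)
}
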