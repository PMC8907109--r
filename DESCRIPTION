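Package: adductms
Title: In-Silico Fragmentation and Isotope-Pattern Matching for
    Metal-Adduct Localization on Oligonucleotides and Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for localizing platinum-drug adducts (and other metal
    or alkali adducts) on DNA oligonucleotides and peptides from
    high-resolution tandem mass spectra.  Enumerates theoretical CID
    fragments (oligonucleotide a/b/c/d and w/x/y/z terminal series,
    base-loss and double-cleavage internal fragments; peptide a/b/y and
    internal fragments), expands them into charged adducted species with
    exact proton and electron mass bookkeeping, computes isotopologue
    envelopes by convolution of elemental isotope distributions, matches
    envelopes to centroided peak lists within a ppm tolerance using a
    total-variation similarity score, and summarizes the evidence as
    fragment maps, terminus/middle region abundances and per-residue
    occurrence histograms.  Includes a seeded simulator of isotopically
    resolved centroid spectra for validation without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
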