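## Residue composition tables.  Oligonucleotides are summed as 2'-deoxy-
## nucleosides joined by phosphodiester linkages (+HPO3 -H2O per bond);
## synthetic oligos default to 5'-OH / 3'-OH termini, the convention under
## which published platinated-strand m/z values are reproduced.  Peptides
## are summed as amino-acid residues plus one water (H-...-OH).

nucleoside_table <- function() {
  if (!is.null(the$nuc)) return(the$nuc)
  the$nuc <- list(A = parse_formula("C10H13N5O3"),   # 2'-deoxyadenosine
       C = parse_formula("C9H13N3O4"),    # 2'-deoxycytidine
       G = parse_formula("C10H13N5O4"),   # 2'-deoxyguanosine
       T = parse_formula("C10H14N2O5"))   # thymidine
  the$nuc
}

#' Neutral nucleobase formulas (BH)
#'
#' Formulas of the neutral bases released in base-loss (`-B`) fragments.
#'
#' @return Named list of formulas for A, C, G, T.
#' @export
nucleobase_formulas <- function() {
  if (!is.null(the$bases)) return(the$bases)
  the$bases <- list(A = parse_formula("C5H5N5"),       # adenine
       C = parse_formula("C4H5N3O"),      # cytosine
       G = parse_formula("C5H5N5O"),      # guanine
       T = parse_formula("C5H6N2O2"))     # thymine
  the$bases
}

#' Amino-acid residue formulas
#'
#' Residue (dehydrated) formulas of the 20 canonical amino acids; a peptide
#' is the sum of its residues plus H2O.
#'
#' @return Named list of 20 formulas keyed by one-letter code.
#' @export
amino_acid_formulas <- function() {
  if (!is.null(the$aa)) return(the$aa)
  the$aa <- lapply(c(G = "C2H3NO",  A = "C3H5NO",   S = "C3H5NO2",  P = "C5H7NO",
           V = "C5H9NO",  T = "C4H7NO2",  C = "C3H5NOS",  L = "C6H11NO",
           I = "C6H11NO", N = "C4H6N2O2", D = "C4H5NO3",  Q = "C5H8N2O2",
           K = "C6H12N2O", E = "C5H7NO3", M = "C5H9NOS",  H = "C6H7N3O",
           F = "C9H9NO",  R = "C6H12N4O", Y = "C9H9NO2",  W = "C11H10N2O"),
         parse_formula)
  the$aa
}

H2O  <- function() parse_formula("H2O")
HPO3 <- function() parse_formula("HO3P")
linkage_delta <- function() fml_subtract(HPO3(), H2O())

split_residues <- function(seq, alphabet, what) {
  stopifnot(is.character(seq), length(seq) == 1L)
  r <- strsplit(toupper(gsub("[[:space:]]", "", seq)), "")[[1]]
  if (!length(r)) abort(sprintf("empty %s sequence", what))
  bad <- which(!r %in% alphabet)
  if (length(bad))
    abort(sprintf("invalid %s residue '%s' at position %d",
                  what, r[bad[1]], bad[1]))
  r
}

#' Neutral formula of a DNA oligonucleotide
#'
#' Sum of deoxynucleoside formulas plus one phosphodiester linkage delta
#' (`+HPO3 -H2O`) per internucleotide bond, plus `+HPO3` per configured
#' terminal phosphate.  Positions are 1-based from the 5' end.
#'
#' @param seq Sequence string over A/C/G/T, written 5' to 3'.
#' @param five_prime,three_prime Terminal chemistry, `"OH"` (default, the
#'   synthetic-oligo convention) or `"phosphate"`.
#' @return An `elemental_formula`.
#' @examples
#' monoisotopic_mass(oligo_formula("GTATTGGCACGTA"))  # S1, 3987.7040 Da
#' @export
oligo_formula <- function(seq, five_prime = c("OH", "phosphate"),
                          three_prime = c("OH", "phosphate")) {
  five_prime <- match.arg(five_prime)
  three_prime <- match.arg(three_prime)
  r <- split_residues(seq, c("A", "C", "G", "T"), "DNA")
  nt <- nucleoside_table()
  f <- Reduce(fml_add, nt[r])
  if (length(r) > 1L)
    f <- fml_add(f, fml_multiply(linkage_delta(), length(r) - 1L))
  if (five_prime == "phosphate") f <- fml_add(f, HPO3())
  if (three_prime == "phosphate") f <- fml_add(f, HPO3())
  f
}

#' Neutral formula of a peptide
#'
#' Sum of residue formulas plus H2O (free N-terminal amine, C-terminal
#' acid).  Positions are 1-based from the N terminus.
#'
#' @param seq One-letter sequence over the 20 canonical amino acids.
#' @return An `elemental_formula`.
#' @examples
#' monoisotopic_mass(peptide_formula("VLEYLTAEILE"))  # P1, 1291.6911 Da
#' @export
peptide_formula <- function(seq) {
  r <- split_residues(seq, names(amino_acid_formulas()), "peptide")
  fml_add(Reduce(fml_add, amino_acid_formulas()[r]), H2O())
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readBStringSet()]; record ids become
#' sequence names.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    abort("reading FASTA requires the Biostrings package")
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
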