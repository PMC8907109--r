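---
title: "Localizing platinum adducts on oligonucleotides and peptides: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing platinum adducts on oligonucleotides and peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cisplatin and related Pt(II) drugs form covalent adducts on DNA (classically
at guanine N7, with GG and GTG steps preferred) and on nucleophilic protein
side chains (methionine thioethers, aspartate/glutamate carboxylates). In a
tandem mass spectrometry experiment a platinated precursor ion — an intact
oligonucleotide strand or peptide carrying Pt, Pt(NH₃) or Pt(NH₃)₂ — is
isolated and fragmented by CID. Each backbone cleavage splits the sequence
into complementary pieces; fragments that retain the metal bracket the
binding site. The analysis problem is scale: every cleavage type, base loss,
internal (double-cleavage) product, adduct composition and charge state is a
candidate, and each candidate is not a single peak but an isotopologue
envelope, made broad and distinctive by platinum's six natural isotopes.
`adductms` enumerates that candidate space exactly, predicts every envelope,
matches envelopes against the centroided spectrum, and summarizes which
parts of the sequence the platinated evidence covers.

## Mass model

**Elemental formulas** are the universal currency (`parse_formula()`,
element-count vectors; Hill-style rendering). All isotope masses and
abundances live in a plain-text table (`inst/extdata/isotopes.tsv`,
IUPAC/CIAAW values) so every number the package produces is auditable.

**Principal-isotope masses.** "Monoisotopic" mass is computed with each
element's *most abundant* isotope. For CHNOPS these coincide with the
lightest isotopes, but for platinum the principal isotope is ¹⁹⁵Pt
(194.964792 Da, 33.8%), not the lightest ¹⁹⁰Pt. This convention — not an
average mass, not the lightest isotope — is the one that reproduces
published Orbitrap m/z values of platinated species to four decimal places.
It also means the most abundant isotopologue of a Pt-containing formula is
generally not its lowest-mass one.

**Charge bookkeeping.** A species is a neutral atom collection plus three
charge carriers: electrons removed (one per unit of metal cationic charge —
two for each Pt(II) adduct, one for each alkali exchange), protons added and
protons removed. With m_p = 1.00727646688 Da and m_e = 0.00054858 Da,

    m/z = (M − n_e·m_e + (n_add − n_rem)·m_p) / |z|,
    z   = n_e + n_add − n_rem  (signed).

The electron correction matters: for `[S1 + Pt(NH3)2 − 8H]⁶⁻` it shifts the
ion by 1.1 mDa, well above Orbitrap precision at 120k resolving power.
Metal binding is modeled purely as this formula-plus-cationic-charge delta;
the covalent H displacement at the binding site is absorbed into the
species' net proton count, matching the `[M + Pt(NH3)2 − 8H]` bookkeeping
used in the literature. No coordination chemistry is modeled.

## Biopolymer chemistry

Oligonucleotides are sums of 2′-deoxynucleosides (dA = C₁₀H₁₃N₅O₃,
dC = C₉H₁₃N₃O₄, dG = C₁₀H₁₃N₅O₄, dT = C₁₀H₁₄N₂O₅) joined by phosphodiester
linkages (+HPO₃ −H₂O per bond). Synthetic oligos default to 5′-OH/3′-OH
termini — the convention under which the published platinated-strand values
are reproduced — with terminal phosphates configurable. Peptides are sums
of the 20 canonical residue formulas plus H₂O. An internal consistency
check (each nucleoside = nucleobase + deoxyribose − H₂O) is part of the
test suite.

## Fragment chemistry

Terminal oligonucleotide fragments follow the McLuckey nomenclature. For an
n-mer, cleavage index i runs 1..n−1; writing `piece(p, q)` for the bare
nucleoside-plus-linkage segment, the end-group deltas are:

| 5′-retaining | 3′-end delta | 3′-retaining | 5′-end delta |
|---|---|---|---|
| d | +HPO₃ | w | +HPO₃ |
| c | +HPO₃ −H₂O | x | +HPO₃ −H₂O |
| b | 0 | y | 0 |
| a | −H₂O | z | −H₂O |

These deltas are fixed by the complementarity identities
a_i + w_{n−i} = M (likewise b/x, c/y, d/z), which the test suite asserts
for a thousand random sequences. Base-loss variants (`a6-B(G)`) subtract
the neutral base; by default the lost base is the residue at the cleavage
side of the fragment (position i for 5′ series, n−i+1 for 3′ series), with
an "any covered position" mode available.

Internal fragments combine one 3′-retaining cut (length i, fixing the
fragment's 5′-end chemistry) and one 5′-retaining cut at j (fixing its
3′-end chemistry), with proper overlap p..q = (n−i+1)..j, 1 < p ≤ q < n.
Labels follow the cleavage pair (`w7:a8-B`), lower-cased canonically. The
`-B` base loss is taken at position q, the 3′-side cleavage residue: this
choice — rather than "any internal base", which remains available as a
mode — is what reproduces the published internal-fragment values
(466.0422, 842.1213, 858.1162, 1014.6450) exactly, and it matches the
mechanistic picture in which base loss accompanies the a-type cleavage.
An independent subtraction oracle (internal = 3′-terminal piece +
5′-terminal piece − intact strand) cross-checks every internal formula in
the tests.

Peptides get b_i (residues 1..i), a_i = b_i − CO, y_i (residues n−i+1..n
plus H₂O) and internal fragments (amide type = bare residue sum; a type =
amide − CO), with b_i + y_{n−i} = M as the conservation identity. ETD c/z
ions are out of scope. The exotic neutral-loss fragment variants seen in
some oligonucleotide work (d−H₂O, z−CH₂) are available through the
`neutral_losses` argument but are not enabled by default.

## Isotopologue envelopes

`isotope_pattern()` convolves per-element isotope distributions
(exponentiation-by-squaring over element counts), merging centroids within
1 mDa in neutral-mass space and pruning below `prune` (default 1e-4)
relative to the base peak before renormalizing to unit sum. A convolution
oracle — pattern(f₁+f₂) must equal pattern(f₁) ⊛ pattern(f₂) — is tested
on small formulas.

For a charged species the envelope is shifted by the charge-carrier delta,
divided by |z|, and then **centroided at the instrument's resolving
power**: peaks closer than m/z / R (default R = 120 000, a standard
Orbitrap product-ion setting) are merged by abundance-weighted averaging.
This step reflects what centroided data actually contain. A platinated
formula has 70–100 isotopologues above 1e-4 when fine structure is kept,
most of them sub-mDa apart — no centroided spectrum resolves those, and
matching against them peak-for-peak would be meaningless. After merging,
an envelope has one centroid per nominal isotopologue, spaced ≈ 1.00336/|z|
(asserted within 1 mDa in the tests for CHNOP species).

## Matching and scoring

Experimental spectra are centroided peak lists: two-column text
(m/z, intensity) or MGF. For each candidate species, every isotopologue is
assigned the nearest unassigned peak within a ppm tolerance, greedily in
descending abundance order; a peak serves at most one isotopologue of a
given species but may serve many species — isobars are expected and are
reported side by side under a shared `isobar_group` id, never silently
resolved.

The similarity score is the total-variation overlap of the aligned,
unit-normalized intensity vectors:

    s = 1 − ½ · Σ_k | I_theo,k − I_obs,k |  ∈ [0, 1],

with unmatched isotopologues contributing zero observed intensity and both
vectors normalized over the envelope support. The score is 1 exactly when
the envelope shapes agree, 0 when nothing matches, and is invariant to
uniform intensity scaling. The original web tools this workflow follows do
not publish their score definition; total-variation overlap was chosen
because it is bounded, scale-free and shape-sensitive. Cosine similarity
on the same aligned vectors would behave similarly; the TV form has the
convenient property that single-isotopologue spurious matches are heavily
penalized. A match additionally requires the principal (most abundant)
isotopologue to be matched, and its peak provides the reported ppm error.

Defaults: 5 ppm tolerance (consistent with the 1–3 ppm errors typical of
externally calibrated Orbitrap data), similarity filter 0.75 for MS/MS
assignment and 0.90 for full-scan survey matching. The filter threshold is
an ordinary argument — whether 0.75 is a hard cut or a display default in
the original tools is ambiguous, so here it is explicit and configurable.
No intensity floor is applied by default.

## Search-space expansion

`expand_search_space()` crosses fragments × adduct multisets (0..max per
menu adduct; default menu Pt/Pt(NH₃)/Pt(NH₃)₂ as +2 cationic, Na/K
exchange as +1, the latter negative-mode only) × charge magnitudes
(defaults 1–6 negative for oligonucleotides, 1–5 positive for peptides).
Proton transfers are chosen to reach the target charge (added above the
adducts' cationic charge, removed below it — the universal ESI pattern).
Species are deduplicated by (ion formula, z) — isomeric internal fragments
legitimately collapse, since no mass spectrometer distinguishes them —
ordered deterministically by m/z then label, and truncated at a
configurable cap with a warning (or an error in strict mode). The default
per-adduct maximum of 3 covers the tri-platinated species observed in
practice; the command-line wrapper defaults to 1 to keep interactive runs
small.

## The synthetic-spectrum generator

`simulate_spectrum()` is the package's test surface, standing in for raw
data that public repositories do not hold for this kind of experiment. It
emulates an isotopically resolved centroid spectrum of planted ion
species: each species contributes its envelope with the base isotopologue
scaled to the species' relative abundance, m/z jitter is multiplicative
Gaussian in ppm (instrument calibration drift), intensity noise is
log-normal multiplicative (ion-statistics variation), and decoy peaks are
uniform in m/z with exponential intensities (chemical noise). A seed fixes
the output exactly, and the writer emits the same text dialect the reader
consumes, so simulated spectra round-trip.

What the generator does *not* emulate — and therefore what passing tests do
not demonstrate about real data: peak-shape and centroiding artifacts,
envelope distortion from co-isolated precursors, detector saturation,
intensity-dependent missingness of weak isotopologues, and chimeric
spectra. The standard validation condition used across the tests (ten
planted platinated species, 2 ppm jitter, 20% intensity noise, fifty
decoys, fixed seed, ≥ 90% recovered at the 0.75 filter) probes assignment
logic and tolerance behavior, not instrument physics.

## Numerical choices and degenerate inputs

* Envelope merge width 1 mDa (neutral mass), prune 1e-4 of base peak;
  resolution-based m/z merging as above.
* Formula arithmetic may go negative transiently (losses); any finalized
  formula with a negative count is an error, and proton removals beyond
  the available hydrogens are rejected (or silently skipped during bulk
  expansion, where they are simply impossible species).
* Single-residue polymers have no cleavage sites: terminal enumeration
  returns an empty table, not an error.
* Ties in peak assignment are resolved by processing isotopologues in
  descending abundance; equal-distance peaks resolve to the lower index
  (deterministic).
* Match ordering: similarity descending, then |ppm| ascending, then label;
  expansion ordering: m/z, then label. All outputs are reproducible from
  config + seed.
* Region percentages count unique species by default; a flag collapses
  charge states and adduct forms of the same fragment first. "Platinated"
  means ≥ 1 metal-containing adduct — alkali exchange alone does not
  count.

## Problem sizes in the test suite

The suite validates mass conservation on 1000 random sequences (n ≤ 20),
enumeration combinatorics against brute-force recounts (n ≤ 20), envelope
oracles on small formulas, and matcher behavior on simulated spectra with
tens of planted species and ~200-species to ~10⁴-species search spaces —
sizes chosen so the whole suite runs in well under a minute per property
group while still exercising every code path a full-size analysis uses.

## Known limitations

* No charge-state deconvolution, in-source fragmentation, isotope
  labeling, FDR estimation by decoys, or profile-mode peak picking.
* RNA, modified nucleotides and post-translational modifications beyond
  user-supplied formula deltas are unsupported.
* One base loss per fragment; multiple simultaneous base losses and
  cyclic rearrangement products are not enumerated.
* Site localization is reported as evidence coverage, not as a calibrated
  site probability.
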