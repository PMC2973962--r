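---
title: "Quantifying ambivalent alpha-helices: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ambivalent alpha-helices: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ambihelix)
```

## The problem

A peptide's local conformation is not fixed by its sequence alone: the same
amino-acid fragment can be an α-helix in one protein and a strand, turn or
coil in another ("chameleon" or ambivalent sequences). Such fragments
matter for local structure prediction, protein design and the
helix-to-sheet transitions implicated in misfolding diseases. `ambihelix`
measures this ambivalence systematically: it extracts every helix from a
non-redundant query database of DSSP-annotated chains, locates every exact
recurrence of each helix sequence in a second (target) database, and asks
how much helicity the sequence retains at each recurrence.

## Model and definitions

**Helix definition.** Residues annotated `H` (α-helix) or `G` (3-10 helix)
in the 8-state DSSP alphabet are helical; `B, E, I, S, T, -` are
non-helical. Binarization precedes run-finding, so a run mixing `H` and `G`
is one helix. Runs shorter than 5 residues are neglected (`min_length`,
default 5): shorter fragments are dominated by spurious single-turn
assignments.

**Mapping.** For a helix of N residues and a target chain of M residues the
reference algorithm forms the N×M indicator matrix A(i, j) = 1 iff helix
residue i equals chain residue j, and reports an occurrence at l whenever
the diagonal sum Σ A(1+m, l+m), m = 0..N−1, equals N
(`map_helix_naive()`). All occurrences are retained, including overlapping
ones and several per chain — nothing in the definition deduplicates.
`map_helix_fast()` produces identical output through an exact
`Biostrings::vmatchPattern()` scan and is the production route; equality of
the two routes (and of a third, regex-based textbook matcher) is asserted
over a thousand randomized instances in the test suite. Matching is exact
over the 20 standard letters; nonstandard residues are stored as `X` and
never match, so helices containing `X` are flagged and skipped.

**Conformational shift.** An occurrence's shift is
`100 × (#non-helical positions) / N` over the mapped window only — flanking
context never enters the shift. A helix with several occurrences is placed
in the *highest* decade bin reached (bin 0 for a maximum shift of exactly
0; otherwise the smallest multiple of 10 at or above the maximum, i.e.
left-open/right-closed decades: (0,10] → 10, (10,20] → 20, ...). Classes:
conserved (max shift 0), variable (some occurrence at exactly 100%),
partially ambivalent otherwise, unmapped when no occurrence exists. A
non-integer maximum shift above 90 can place a *partial* helix in bin 100;
variability additionally requires a complete (100%) occurrence.

**Self-matches.** Whether a helix should be scored against chains of its
own structure is genuinely open; by default `exclude_self = TRUE` drops
occurrences whose target `structure_id` equals the helix's source
structure, because self-identity would contribute tautological 0% shifts
and deflate the shift statistics. The flag is configurable and the
exclusion is on structure id, not chain id, so other chains of the same
crystal are also excluded.

**Chain breaks.** Crystallographic chains with unresolved gaps are split at
DSSP `!` rows into independent records (`A`, `A.2`, ...). This prevents a
sequence match from spanning a physical discontinuity; the alternative
(concatenating across the break) would fabricate peptides that do not
exist.

**Conformational parameter.** For amino acid i in residue group j,
CP_ij = (n_ij/Σn_ij) / (N_i/ΣN_i). The background N_i is computed over
*all* residues of the query database, not only helical ones, because the
parameter is meant to normalize by overall database composition. Every
emitted table satisfies Σ_i f_i·CP_ij = 1 (f_i the background fraction)
to 1e-9 — an identity the tests assert on all tables. Amino acids absent
from the background get an absent (NA) parameter rather than an infinity,
which matters for small synthetic databases. For the "non-helical
conformation" group of variable helices, residues are counted once per
occurrence (not per unique sequence): the statistic is occurrence-centric
throughout, and this default is configurable upstream by deduplicating the
occurrence table. Per-bin curves pool query-helix residues only; the
occurrence residues are sequence-identical by construction, so pooling them
would merely reweight bins by occurrence multiplicity.

**Flanking sequences.** Up to 4 residues immediately before the helix
N-terminus and after the C-terminus (`flank_width`, default 4), truncated
at chain boundaries. Flank statistics are kept separate by terminus —
helix initiation and termination involve different residues, so averaging
the two flanks would mask the anisotropy of interest. Flank CP tables are
computed for three populations: the helical conformations of variable
helices, their fully non-helical occurrences, and conserved helices.

**Solvent accessibility.** DSSP's absolute accessibility (Å²) is divided
by the residue's maximum accessibility in an extended Gly-X-Gly tripeptide,
giving relative solvent accessibility in [0, 1]. No canonical Gly-X-Gly
table is universal, so the package embeds the Miller, Janin, Lesk & Chothia
(1987, J Mol Biol 196:641) values as its default and accepts a two-column
TSV override. Observed values occasionally exceed the tripeptide maximum;
they are capped at 1 and the capped count is reported as an attribute
rather than silently discarded. Per-flank mean RSA values are histogrammed
(default bin width 0.1, right-closed bins) as within-class fractions.

## The synthetic-data generator

Real inputs for this analysis are large culled snapshots of the PDB and
SCOP; the generator replaces them with seeded databases in which every
quantity of interest is planted and therefore known exactly:

* each `plant_spec()` yields one query chain whose helix (length ≥ 5,
  residues drawn from a configurable weight map) is fully helical and
  embedded in non-helical context, plus one target chain per prescribed
  occurrence carrying the identical sequence with
  `round(shift·N/100)` positions made non-helical;
* shifted positions form a contiguous C-terminal block by default
  (mimicking end-fraying, the common mode in real partial helices), with a
  `"scattered"` option; the non-helical codes are drawn uniformly from
  `{B,E,I,S,T,-}` since only the binary distinction can affect any
  statistic — this deliberately exercises the binarization rule;
* helical codes are drawn H:G = 0.85:0.15 so 3-10 positions occur at
  roughly their natural minority rate within helices;
* flanks of width 4 are planted on both sides with per-terminus weight
  maps, enabling known N/C anisotropy; accessibility is drawn from
  per-class Beta distributions (helix interior Beta(1.5, 4), coil and
  flanks Beta(2, 2) unless overridden) scaled by the Gly-X-Gly maxima;
* metadata emulate a well-determined X-ray set: resolution ~ U(1.0, 2.8) Å,
  R-factor ~ U(0.15, 0.28), SCOP fold/domain labels shared or not per
  occurrence flag;
* a shift that would round to a different conformational class than
  planted (e.g. 3% of a 5-residue helix) is rejected as infeasible rather
  than silently realized as 0%.

After generation every planted sequence is counted (overlap-aware) in both
databases; on any accidental extra occurrence the whole generation is
retried with a derived sub-seed (20 tries, then an error). Identical seeds
give byte-identical databases, and the pipeline run on them is itself
byte-reproducible.

What the generator does *not* emulate: evolutionary sequence correlations,
realistic length/composition distributions, homology between chains, or 3D
coordinates. Passing tests therefore demonstrate algorithmic correctness
and statistical calibration on planted ground truth, not database-scale
biological conclusions; database-wide percentages (fraction conserved,
concordance rates, helix counts) are properties of a particular snapshot
and are intentionally out of scope.

## Numerical and design choices

* Positions are 0-based internally only at the string-arithmetic level;
  all records and formats use 1-based inclusive coordinates matching PDB
  conventions.
* The quality filter keeps boundary values (resolution ≤ 3.0 Å, R ≤ 0.3,
  inclusive) and drops chains with missing values while the corresponding
  cutoff is active — an unknown R-factor cannot certify quality.
* Statistical recovery checks run at 10,000 residues per planted group
  (500 helices of length 20) with bands of ±3 binomial Monte-Carlo
  standard errors around the planted sampling frequency; the enrichment
  ratio is assessed against the empirically measured background frequency,
  since the background is itself part of the statistic's definition.
* Determinism: all randomness flows from a single integer seed; numbers
  are serialized at up to 15 significant digits so chain tables round-trip
  field-for-field.

## Limitations

* Exact matching only: near-identical sequences (one substitution) are
  distinct by design, as the analysis is defined on identical fragments.
* Concordance uses chain-level SCOP labels; a chain spanning several
  domains is represented by a single label.
* The DSSP reader targets classic fixed-width DSSP text; mmCIF-style DSSP
  output should be converted or supplied as a chain table.
* With `exclude_self = FALSE` every helix trivially becomes conserved via
  its own self-occurrence when query and target databases coincide — the
  tests use this as a sanity invariant, but analyses should keep the
  exclusion on.
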