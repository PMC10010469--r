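---
title: "Methods: building a structurally annotated AQP missense-variant database"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building a structurally annotated AQP missense-variant database}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquavar)
```

## The problem and the pipeline

Human aquaporins (AQP0–AQP12) share the hour-glass fold: six transmembrane
helices (TM1–TM6) and two half-helices (LB, LE) that meet mid-membrane,
forming a channel with two constrictions — the Asn-Pro-Ala (NPA) motifs at
the start of each half-helix, and the aromatic/arginine (Ar/R) selectivity
filter. A missense SNP's likely consequence depends on where its residue
sits in this architecture. `aquavar` builds that positional context in four
stages: validated ingest of variant dumps, six-group substitution
classification, structure-based generic numbering with functional-site
flags, and geometric region classification on tetrameric structures; the
results are joined into a queryable CSV database.

## Ingest and validation

Raw records carry the rsID, homolog, reference/alternate codon, the codon
position of the nucleotide change, the residue index in the primary
isoform, the reference/alternate amino acid, a deprecation flag and free
disease text. Validation enforces the genetic code: the codons must
translate to the stated amino acids, differ at exactly one position, and
that position must match the declared one. Synonymous changes, stop gains,
deprecated entries and codon-inconsistent records are rejected with
categorised reasons; the filter report always balances (kept plus removals
equals input). Only primary-isoform numbering is supported; records using
another isoform's coordinates are invalid input, not remapped.

Two choices here were genuinely open:

* **Duplicate key.** Duplicates are collapsed on (rsID, homolog, residue
  index, alternate amino acid) — one biological event per protein change
  per rsID. Collapsing on rsID alone would merge distinct protein changes
  reported under one accession; collapsing on the protein change alone
  would conflate independent genomic events.
* **Absent codons.** Real dumps do not always carry codon fields. Such
  records are kept with codon validation skipped and a `codon_unverified`
  flag rather than rejected, so the flag preserves the audit trail.

Kept entries receive identifiers `dbAQPSNP-<GENE>-<5-digit serial>` in kept
order, serial per homolog.

## Six-group substitution classification

The 20 standard amino acids partition into six groups: small and weakly
polar (SWP: Gly, Ala, Cys, Ser, Thr), aliphatic hydrophobic (AH: Leu, Ile,
Val, Met), charged (Asp, Glu, Lys, Arg, His), neutral polar (Asn, Gln),
aromatic (Phe, Trp, Tyr) and proline alone — proline kinks helices and is
kept separate. A substitution is *group-conservative* when both residues
share a group. The 6×6 substitution-pattern matrix is directional (rows =
from-group, columns = to-group) and is not symmetrised, matching the
row-wise reading of the reference tally. The counting unit is one variant
record, so identical protein changes under distinct rsIDs count separately.
Selenocysteine and pyrrolysine are rejected rather than silently grouped.

The packaged reference count matrix (`aqp_substitution_counts()`) stores
only the 36 cells; all marginals are derived by recomputation. The stored
cells are internally consistent with the row totals and the 2978 grand
total of the reference tally; two of its printed column totals differ by
1–2 from the column sums of its own cells, so deriving marginals from cells
is the only self-consistent choice.

## Generic numbering

Each segment has a most-conserved anchor residue numbered 50; position
`i` inside the segment gets offset `50 + (i − anchor)`, rendered as
`1.50 … 6.50`, `LB.50`, `LE.50`. Segment spans and anchors are
configuration, not computed: deriving anchors requires conservation
analysis over large MIP alignments, which is out of scope. The packaged
AQP4 map uses the reference anchor set (E44 = 1.50, G78 = 2.50, N97 =
LB.50, Q122 = 3.50, E163 = 4.50, G194 = 5.50, N213 = LE.50, P237 = 6.50);
its span *boundaries* are package fixtures chosen as typical helix lengths
around the anchors and are documented as non-authoritative. Positions
before TM1, after TM6 or between segments are tagged `NTERM`, `CTERM` or
`LOOP` (with the flanking segments recorded), so loop statistics can be
reported as a class.

Functional sites are purely positional: `NPA_LB` = {LB.50, LB.51, LB.52},
`NPA_LE` = {LE.50, LE.51, LE.52}, `ARR_SF` = {2.49, 5.57, LE.47, LE.53}.
Wild types that deviate from Asn-Pro-Ala (e.g. an Ala at LB.51 in AQP7)
are therefore flagged by position, never by residue letter.

Instance counting at these sites depends only on generic positions, so the
packaged site listing is expanded into variant records through
*synthetic* per-homolog maps (`synthetic_segment_maps()`, copies of the
AQP4 map with the homolog name swapped): any internally consistent map
yields the same per-site tallies. These maps are stand-ins and are named
and documented as synthetic.

## Structural regions

Every resolved residue of a tetrameric model receives exactly one of six
labels. The distance rules use heavy atoms and a strict `<= 4.0` Å
comparison with no tolerance:

* **Helix–helix interface** — a *backbone* atom of a helix residue within
  4 Å of *any* atom of a residue in a different helix of the same chain.
  The backbone restriction applies only on the query side; the asymmetry
  follows the literal wording of the two rules, which differ between the
  helix and monomer criteria. Half-helices LB/LE count as helices here:
  they pack against the TM helices in the hour-glass fold.
* **Monomer–monomer interface** — any atom of a residue within 4 Å of any
  atom of a different chain.
* **Channel-facing** — needs an explicit metric. The operationalisation:
  fit the monomer's pore axis as the least-squares line through the CA
  atoms of all helix-span residues (for the pseudo-symmetric bundle this is
  the channel axis), then require (a) the CA inside the membrane slab,
  (b) minimum side-chain heavy-atom distance to the axis at most `r_pore`
  (default 6.0 Å, exposed in the API), and (c) the side-chain centroid no
  farther from the axis than the CA — the side chain points inward.
  Glycine uses its CA as side-chain surrogate.
* **Cytoplasmic / extracellular** — CA outside the slab, by slab side. The
  slab is an input (two z planes plus which side is extracellular, models
  pre-oriented with the membrane normal on z); no membrane-boundary
  prediction is performed.
* **Lipid-facing** — the residual class inside the slab.

Because one residue can satisfy several criteria, labels are assigned by
precedence: slab side first, then channel-facing, helix interface, monomer
interface, lipid-facing. The residual definition of lipid-facing and the
one-label-per-residue statistics imply *some* precedence; placing
channel-facing above the interfaces is this package's documented
interpretation (functional context dominates packing context). The
assignment carries per-residue evidence (CA z, slab membership, side-chain
axis distance, interface contact flags) so the precedence can be audited.

PDB input goes through `bio3d`: `ATOM` records only, hydrogens dropped,
alternate locations resolved to the highest occupancy (ties to altloc `A`,
then file order). Pairwise-distance tests are computed with exact
per-coordinate arithmetic identical to a naive all-pairs scan, so interface
membership is bit-identical to the brute-force oracle used in the tests.
Variants at positions not resolved in the structure stay in the database
with region `UNMAPPED`; statistics tally them separately from the
per-region counts.

## The synthetic generator

`build_monomer()` places ideal α-helices (1.5 Å rise per residue, 3.6
residues per turn, 2.3 Å CA radius; N, CA, C, O plus a CB placed radially
outward from the helix axis) on a ring about the z axis. Defaults: 8
helices of 24 residues on a ring of radius 11.75 Å, giving adjacent
helix-axis separations of ~9 Å — close packing with genuine 4 Å backbone
contacts — and a bundle that pokes ~2 residues beyond a ±15 Å slab on each
side, so all six region labels occur. Residues whose CB direction is
within 40° of the bundle axis become channel probes: the CB is re-placed on
the CA→axis segment at an axis distance of exactly 4 Å, and those residues
form the planted channel-facing truth. The generator self-checks before
returning: the classifier must recover the planted set exactly, and any
CA–CA pair under 2 Å aborts generation. `build_tetramer()` makes chains
A–D as exact 90° rotations about z; at the default 23 Å monomer-axis
spacing neighbouring chains are in 4 Å contact, and contacts vanish above
roughly 25 Å.

What the generator does *not* emulate: real side chains beyond CB (region
rules are exercised via backbone and CB only), loops between helices,
irregular helix geometry, and the genuine hour-glass taper. Passing the
geometric suites on these bundles validates the *rules* — distance
criteria, precedence, partition, rigid invariance — not the biological
accuracy of any particular span or slab configuration on real structures.

`sample_variants()` emits variant tables with *exact* per-cell group-pair
counts (not multinomial draws), so matrix recovery is exact by
construction. Codons are attached only where the amino-acid pair is
reachable by a single nucleotide change; unreachable pairs carry blank
codons and the `codon_unverified` flag rather than inconsistent codons.
A requested Pro→Pro cell is an error: proline is a single-member group, so
a within-group missense change cannot exist. All generation is
deterministic per seed and leaves the caller's RNG state untouched.

## Numerical and degenerate-input choices

* Distance comparisons are strict `<=` at the stated cutoff; no epsilon.
* The pore-axis fit requires ≥3 non-collinear CA atoms and orients the
  direction toward +z (sign convention only; distances are unaffected).
* Empty variant lists, empty queries and all-zero matrices are valid inputs
  returning empty/zero results, not errors.
* Single-chain models have an empty monomer interface (with a warning), so
  monomer-level analyses degrade gracefully.
* CSV serialisation is RFC-4180 with a fixed header; blank codon fields
  encode codon-absent records, and parsing validates every label with the
  offending row number in the error.

## Problem sizes and limitations

The test suite exercises bundles up to the 768-residue (3840-atom) default
tetramer, where the interface classifiers are compared against a full
brute-force distance-matrix oracle; the complete suite runs in about a
minute on one CPU. Known limitations: region classification assumes a
pre-oriented model and an externally supplied slab; channel-facing depends
on the `r_pore` and inward-centroid operationalisation described above;
per-homolog segment spans are configuration and the packaged non-AQP4 maps
are synthetic stand-ins; and disease text is carried verbatim from input —
no pathogenicity curation is performed.
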