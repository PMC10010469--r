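# aquavar

Structural annotation of missense SNPs in human aquaporins.

Humans carry 13 aquaporin (AQP) homologs, AQP0–AQP12 — membrane channels
that conduct water and small neutral solutes through a conserved hour-glass
fold of six transmembrane helices (TM1–TM6) and two half-helices (LB, LE).
Thousands of single-nucleotide polymorphisms cause missense substitutions in
these proteins, and whether a given substitution is likely to matter depends
on *where* it lands: in one of the two Asn-Pro-Ala (NPA) constrictions, in
the aromatic/arginine (Ar/R) selectivity filter, lining the channel, packed
against another helix, at the tetramer interface, facing the lipid, or out
in a loop or terminus.

`aquavar` implements the full construction pipeline for such a structurally
annotated variant database, for structural biologists and geneticists who
want to triage AQP missense variants:

* **Ingest** — parse dbSNP-style dumps (JSON-lines or CSV), validate each
  codon change against the standard genetic code, and remove duplicates,
  deprecated, synonymous and nonsense entries with a balanced filter report.
* **Substitution pattern** — classify amino acids into six physicochemical
  groups (SWP = {G,A,C,S,T}, AH = {L,I,V,M}, CHARGED = {D,E,K,R,H},
  NP = {N,Q}, AROMATIC = {F,W,Y}, PRO = {P}) and aggregate variants into the
  directional 6×6 substitution-pattern matrix with marginals.
* **Generic numbering** — map residue indices to the structure-based generic
  numbering scheme in which the most conserved position of each segment is
  numbered 50 (so 3.47 is three residues before the TM3 anchor, LB.52 two
  after the LB anchor), and flag the functionally critical positions: the
  NPA motifs (LB.50–52, LE.50–52) and the Ar/R selectivity filter (2.49,
  5.57, LE.47, LE.53).
* **Structural regions** — classify every resolved residue of a tetrameric
  structure into one of six regions using 4 Å heavy-atom distance criteria
  (helix–helix and monomer–monomer interfaces), a pore-axis rule for
  channel-facing residues, and a membrane slab separating cytoplasmic from
  extracellular positions, with lipid-facing as the residual class.
* **Database** — join everything into annotated entries; write/read the CSV
  database, compute statistics-page aggregations, and answer conjunctive
  advanced-search queries.
* **Synthetic data** — generate ideal-helix bundle tetramers whose
  channel/interface labels are known by construction, and variant tables
  whose group-pair counts are exact, so every stage is testable without any
  external download.

## Worked example

Parse a small JSON-lines dump (one duplicate, one nonsense entry), filter
it, and annotate the kept variants with the packaged AQP4 segment map:

```r
library(aquavar)

parsed   <- parse_snp_dump("dump.jsonl", format = "jsonl")
filtered <- apply_snp_filters(parsed$records)
filtered$report
#> Missense variant filter report
#>   input records             4
#>   duplicates removed        1
#>   deprecated removed        0
#>   synonymous removed        0
#>   nonsense removed          1
#>   invalid removed           0
#>   kept                      2

ann <- annotate_variants(filtered$variants, list(AQP4 = aqp4_segment_map()))
ann[, c("db_id", "rsid", "residue_index", "ref_aa", "alt_aa",
        "generic_number", "functional_site", "ref_group", "alt_group",
        "conservative")]
#>                 db_id   rsid residue_index ref_aa alt_aa generic_number
#> 1 dbAQPSNP-AQP4-00001 rs1000            97      N      T          LB.50
#> 2 dbAQPSNP-AQP4-00002 rs1001           216      R      C          LE.53
#>   functional_site ref_group alt_group conservative
#> 1          NPA_LB        NP       SWP        FALSE
#> 2          ARR_SF   CHARGED       SWP        FALSE
```

The first variant hits the asparagine of the LB NPA motif (N97, generic
LB.50) and the second replaces the selectivity-filter arginine (R216,
LE.53) with cysteine — both non-conservative changes at the channel's two
constrictions. `write_aqpsnp_csv()` / `read_aqpsnp_csv()` serialise the
entries, `aqpsnp_statistics()` aggregates them, and `query_aqpsnp()` runs
conjunctive searches such as *all AQP0 entries at the helix–helix interface
where a charged residue becomes aromatic*:

```r
query_aqpsnp(entries, homolog = "AQP0", region = "HELIX_INTERFACE",
             ref_group = "CHARGED", alt_group = "AROMATIC")
```

For structures, `read_structure()` loads a PDB file (altloc and hydrogen
rules applied) and `classify_regions()` assigns each resolved residue its
region given per-chain helix spans and a membrane slab:

```r
model <- read_structure("3gd8_tetramer.pdb")
ra    <- classify_regions(model, spans, membrane_slab(-15, 15, "+z"))
region_counts(ra)
```

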