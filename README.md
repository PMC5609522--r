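# aqpkit

Annotation and profiling of plant aquaporin (MIP) gene families in R.

Aquaporins are membrane channels that move water and small uncharged
solutes (urea, boric acid, H2O2, NH3, CO2, silicic acid) across plant
membranes. Annotating a newly sequenced genome's aquaporin complement is a
stereotyped but fiddly exercise: screen the proteome for the conserved
six-transmembrane hourglass fold with its two Asn-Pro-Ala (NPA) loop
motifs, read the diagnostic residues off an alignment — the ar/R
selectivity filter (H2, H5, LE1, LE2), the five Froger positions (P1–P5)
and the nine substrate specificity-determining positions (SDP1–SDP9) —
place each candidate into the PIP / TIP / NIP / SIP / XIP subfamilies,
then layer on genome context (chromosome distribution, tandem
duplications, exon structure and alternative splicing) and expression
evidence. `aqpkit` packages that whole workflow as tested, deterministic
functions, together with the curated catalog and residue tables for the
sugar beet (*Beta vulgaris*) family and a synthetic-data generator that
plants known ground truth for every stage.

## What the package computes

* **Screening** (`screen_proteome`): a candidate passes when it has ≥ 2
  NPA-like motifs (`NP[ASTLV]`) spaced 60–180 residues apart, ≥ 4
  predicted transmembrane segments (sliding-window Kyte–Doolittle
  hydropathy), a length of 200–400 aa and ≥ 30% global-alignment identity
  to a reference aquaporin. Protein properties (`compute_mw`,
  `compute_pi`, `predict_tm_segments`) are computed in-package.
* **Residue extraction** (`global_align` + `extract_profile`): each
  candidate is aligned (Needleman–Wunsch, BLOSUM62, affine gaps) to an
  annotated anchor whose sidecar maps every diagnostic label to a column;
  the query residues in those columns form its `ResidueProfile`.
* **Classification** (`build_distance_matrix`, `nj_tree`,
  `assign_subfamily`, `bootstrap_support`): distances are
  1 − alignment identity; an in-house neighbor-joining tree places each
  query, which is named after the unanimous label of its smallest
  enclosing clade (nearest reference as fallback).
* **Substrate calling** (`match_pattern`, `call_substrates`,
  `call_printed_sdps`): SDP residues are matched position-by-position
  against the typical transporter signatures (urea, boric acid, CO2,
  H2O2, NH3, silicic acid); nine matches is a FULL call, a single
  mismatch is NEAR — the near-miss logic that surfaces "novel-type"
  variants. Data-driven ar/R rules (`apply_arr_rules`) add annotations
  such as the water-typical F-H-T-R filter.
* **Genome context** (`parse_locus_tag`, `chromosome_distribution`,
  `find_tandem_pairs`, `exon_counts`, `detect_exon_skipping`).
* **Expression** (`heatmap_matrix`, `stress_response`,
  `expression_breadth`) starting from an RPKM matrix.
* **Synthetic data** (`make_proteome`, `make_annotation`,
  `make_expression`): deterministic fixtures with planted residues,
  tandem pairs, a skipped exon and expression classes.
* **Orchestration** (`run_pipeline`): one call from FASTA (+ optional
  GFF3 / RPKM) to a combined annotation report with a run manifest.

## Worked example

```r
library(aqpkit)

## the curated sugar beet catalog
family_tally(load_catalog())
#> PIP TIP NIP SIP XIP
#>   7   8   9   3   1
chromosome_distribution(load_catalog())
#> chr1 chr2 chr3 chr4 chr5 chr6 chr7 chr8 chr9
#>    2    7    3    0    3    2    3    2    6

## screen a (here: synthetic) proteome against the subgroup scaffolds
gen <- make_proteome(n_aqp = 3, n_decoy = 5, seed = 7)
res <- screen_proteome(gen$proteome, subgroup_scaffolds()$sequences)
res[, c("protein_id", "n_npa", "tm_count", "best_ref_identity", "passed")]
#>    protein_id n_npa tm_count best_ref_identity passed
#> 1 AQP001_PIP1     2        6             0.979   TRUE
#> 2 AQP002_PIP2     2        6             0.955   TRUE
#> 3 AQP003_TIP1     2        6             0.958   TRUE
#> 4    DECOY001     0        0             0.146  FALSE
#> ...

## read the diagnostic residues off the anchor alignment
anchor <- load_anchor()
s <- as.character(gen$proteome[["AQP002_PIP2"]])
p <- extract_profile(global_align(s, anchor, query_id = "AQP002_PIP2"),
                     anchor)
p
#> Residue profile for AQP002_PIP2
#>   NPA: NPA / NPA
#>   ar/R: F-H-T-R
#>   Froger: Q-S-A-F-W
#>   SDP: H-P-F-L-L-P-G-G-N

## substrate calls and ar/R annotations
calls <- call_substrates(list(p), load_patterns())
subset(calls, call != "NO")
#>      query_id substrate pattern_class call n_match mismatches
#> 6 AQP002_PIP2      urea       typical FULL       9
apply_arr_rules(p)$rule_id
#> [1] "water_typical"
```

The PIP2-type candidate shows the canonical dual NPA pore, the
water-typical F-H-T-R selectivity filter, the PIP Froger signature
Q-S-A-F-W and a FULL urea-type SDP match — the combination expected for a
plasma-membrane water channel with urea permeability.

## Vignette

`vignettes/aquaporin-annotation.Rmd` documents the models and procedures
(screening thresholds, anchor annotation, the SDP matching rules and
their edge cases, the neighbor-joining and bootstrap details, the
synthetic-data design) and the reasoning behind every default.
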