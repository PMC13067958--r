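---
title: "Methods: screening reclassified Lactobacillus genomes for probiotic potential"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening reclassified Lactobacillus genomes for probiotic potential}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and model of the analysis

`probioscreen` implements, as reusable and tested R functions, the
computational stages of a family-wide comparative survey of lactic acid
bacteria formerly classified in the genus *Lactobacillus* (now split
across *Lactiplantibacillus*, *Lacticaseibacillus*, *Ligilactobacillus*
and related genera). The pipeline consumes per-genome annotated
assemblies — nucleotide FASTA, GFF3 with CDS features, protein FASTA —
plus per-genome metadata (species label, isolation-source category,
CheckM-style completeness and contamination), and produces:

1. an assembly-quality gate and species-representation filter;
2. a regex screen of CDS annotation text (gene, product, note fields)
   against a curated probiotic-marker panel, with presence, count and
   proportion matrices at marker, subcategory and category level;
3. local-alignment confirmation of marker candidates against a reference
   protein panel, with per-marker regex/alignment concordance;
4. threshold retention of antimicrobial-resistance (AMR) and
   virulence-factor (VF) hits plus annotation-term screens for
   biogenic-amine decarboxylases and hemolysin/cytolysin genes, rolled up
   into species prevalence tables;
5. consolidation of bacteriocin detector output into loci, subclass
   assignment (I, IIa-IId, III, other) and species-level
   abundance/diversity summaries;
6. filtering and aggregation of CAZyme search output (classes GH, GT,
   PL, CE, AA, CBM);
7. a desk-scale supra-pan-genome: greedy ortholog clustering at 95%
   amino-acid identity, a soft-core/shell/cloud partition and gene
   accumulation curves;
8. descriptive statistics, notably a Kruskal-Wallis comparison of genome
   size across isolation-source categories.

Genome retrieval, Prokka annotation, CheckM, the external detectors
(BAGEL-style bacteriocin HMMs, DIAMOND CAZy searches, ABRicate) and
phylogenetics are deliberately out of scope: their outputs are consumed
as standard tabular formats, and a synthetic-cohort generator supplies
equivalent fixtures with known ground truth.

## Decision rules and their parameters

All inequality gates are inclusive on the stated side. They are constants
of the relevant module, overridable per call:

| rule | default | where |
|---|---|---|
| completeness | >= 95% | `apply_gate()` |
| contamination | <= 5% | `apply_gate()` |
| contig count | <= 200, or N50 >= 50 kb rescues | `apply_gate()` |
| species representation | >= 10 passing genomes | `filter_species_representation()` |
| marker confirmation | identity >= 40%, query coverage >= 70%, E <= 1e-5 | `confirmation_decision()` |
| AMR retention | coverage >= 50%, identity >= 90% | `safety_panel("AMR")` |
| VF retention | coverage >= 70%, identity >= 90% | `safety_panel("VF")` |
| CAZyme filter | E < 1e-102 (strict), top hit per query | `filter_and_assign()` |
| ortholog clustering | identity >= 95%, shorter-sequence coverage >= 80% | `cluster_families()` |
| pan-genome partition | soft-core >= 95%, shell 15-95%, cloud < 15% prevalence | `partition()` |

N50 is the smallest contig length L such that contigs of length >= L
contain at least half of the assembly. GC% excludes ambiguity codes from
both numerator and denominator. Coverage in the safety screen is
query-relative, which the output headers state explicitly, because the
upstream tools do not fix the convention.

### Alignment statistics

Protein-BLAST-style confirmation is computed with exact Smith-Waterman
local alignment (via `Biostrings::pairwiseAlignment`) under BLOSUM62 with
affine gap costs open 11 / extend 1 — the protein-BLAST defaults — so the
published decision thresholds transfer unchanged; there is no heuristic
seeding because reference panels are small. Percent identity counts
identical aligned pairs over all alignment columns *including gap
columns* (the conservative convention; conventions differ, so this is
stated explicitly), and query coverage is the aligned query span over the
query length. E-values use the Karlin-Altschul form
`E = K * m * n * exp(-lambda * S)` with the standard gapped BLOSUM62
constants `lambda = 0.267`, `K = 0.041`, where `m` is the query length
and `n` the total residue count of the marker's reference set. These are
not BLAST's composition-adjusted statistics; they are only used against
the fixed `1e-5` threshold, far from the regime where the difference
matters. When no positive-scoring local alignment exists the result is
reported as zero identity and coverage rather than `NA`, so threshold
logic never propagates missingness.

The nucleotide path used by the safety screen reuses the same
dynamic-programming core with match +2 / mismatch -3, gap open 5 /
extend 2. An adapter (`import_external_alignments()`) accepts 12-column
BLAST-style tabular output when an external aligner was used instead.

### Marker panel, lexicon and category taxonomy

The packaged panel (`inst/extdata/marker_panel.tsv`) reconstructs the
curated marker list from its published description: bile-salt hydrolase
(*bsh*), the glutamate decarboxylase system (*gadA/B/C*), sortase and
LPXTG adhesins, sortase-dependent pili, EPS biosynthesis scaffolding
(*eps*, *wzx/wzy*, *wzb/wzc*, *gtf*, *rfb*, *ugd*, *gnd*), chaperones and
oxidative-stress enzymes, folate/riboflavin/thiamine operons, F0F1
ATPase subunits (*atpA-H*), the arginine deiminase system (*arcA-T*),
mucus/collagen/fibronectin-binding proteins and S-layer proteins,
bacteriocin and reuterin terms, PTS and sugar transporters, and
CRISPR-Cas (*cas*) genes. *dltA* appears in the panel because it belongs
to the sequence-validated marker subset even though it is not part of
the category listing; its D-alanylation pattern is a reconstruction.
Word boundaries are encoded in the patterns themselves; the engine only
supplies case-insensitivity. The panel is ordinary TSV so users can
replace it wholesale; `load_panel()` validates regexes, field sets and
uniqueness at load time.

The category taxonomy is stored on each panel row. The published
category figure announces seven collapsed groups but enumerates eight
names; the enumerated list is authoritative here, so
`marker_categories()` returns those eight names verbatim and nothing in
the code depends on the count being seven. Multi-marker matches on one
CDS are all kept (deduplicated only per CDS x marker), because
abundance roll-ups are reported at category level and no precedence rule
is published.

### Bacteriocin consolidation, subclasses and tiers

Only structural-role detector hits can found loci. Two structural hits
merge when they share a name and overlap by more than 50% of the shorter
span — the published account says only "overlapping or redundant", so
the 50% parameter is exposed (`min_overlap`) and the operation is
idempotent by construction (single linkage over the redundancy
relation, keeping the highest-scoring span). Total abundance therefore
counts structural loci, not whole-cluster genes; satellite immunity,
transport and biosynthetic genes never inflate counts.

Subclass assignment is normalized exact-name lookup in a packaged,
editable mapping covering every bacteriocin named in the survey's
species summary (plantaricins and two-peptide relatives as IIb,
pediocin-like peptides as IIa, circular acidocin B as IIc, leaderless
and linear unmodified peptides as IId, nisins/lacticin 3147/mutacin II
as class I lantibiotics, enterolysin A/helveticin J/zoocin A as class
III); unmapped names fall into `other` rather than erroring.

Production tiers reproduce the published species notes with a rule the
source never states: `strong` at total abundance >= 500, `moderate`
strictly between 50 and 500, `low_none` otherwise. The thresholds were
chosen to separate the printed table rows (54 is Moderate, 50 is
Low/none) and the full 35-row table ships in `inst/extdata/` so the rule
is re-verified programmatically by the test suite — if the rule ever
disagrees with a row, the test fails rather than silently relabeling.

### Pan-genome clustering

Roary-scale pipelines are replaced by a greedy centroid pass in the
CD-HIT tradition: proteins sorted by decreasing length (ties broken by
id) either join the first centroid they match — local identity >= 95%
with >= 80% coverage of the shorter sequence, which prevents domain-level
chaining — or found a new family named after themselves. A shared-12-mer
prefilter skips alignments against centroids with no exact 12-mer in
common; at >= 95% identity, true family members share many exact
12-mers, while unrelated proteins essentially never do, so the filter
changes runtime, not results, on the separated fixtures where greedy
clustering provably agrees with exhaustive single linkage (a property
the tests check against an all-pairs oracle). On real data with
borderline families at the threshold, greedy clustering is an
approximation; agreement with single linkage is guaranteed only when
within-family identity clears the threshold and between-family identity
stays well below it. Paralogs within one genome may share a family;
prevalence counts distinct genomes, matching the partition definitions.
Accumulation curves are means over seeded permutations of genome order
and are non-decreasing by construction.

## The synthetic-cohort generator

`simulate_cohort()` is first-class, tested code: it emulates the cohort
structure the pipeline was built for, at desk scale, with every planted
feature recorded in a manifest so downstream stages have exact ground
truth.

What it emulates, and the defaults that define the study conditions:

* three species of twelve genomes each (uneven counts allowed), roughly
  150 genes per genome; genome length 60-120 kb — the real survey's
  1.21-4.05 Mb scaled down by about a factor of 30 so a full cohort
  simulates in seconds;
* GC sampled per species from 32.5-53%, the observed family-wide range,
  with the intergenic background acting as a running corrector so each
  finished contig lands within a point of its genome's target even
  though shared gene families sit at the cohort's mid-range GC;
* isolation sources drawn from the six categories at weights
  approximating the survey's metadata fractions (fermentation 0.18,
  environment 0.08, human 0.22, animal 0.12, other 0.14, missing 0.26);
* markers planted as exact reference copies, substitution-diverged
  copies with a controlled identity (within half a residue of target;
  substitutions only, so coverage stays 100%), or decoys — unrelated
  sequences carrying marker-consistent annotation text drawn from a
  packaged product lexicon, exercising the false-positive path of
  annotation-driven screening;
* bacteriocin loci planted with known names and subclasses, emitted both
  as CDS features and as detector-style raw hits that include redundant
  overlapping duplicates and non-structural satellite rows;
* AMR/VF genes planted as nucleotide fragments of a synthetic reference
  panel, truncated to a target coverage and substituted to a target
  identity (defaults straddle the retention thresholds on both sides),
  alongside term-screen plants (hdcA, tyrP, hly) and sub-threshold
  chaff rows;
* a gene-family plan (core families in every genome, an accessory pool
  carried probabilistically, and private genes per genome) whose
  per-copy divergence is capped at 1% of codons so any two copies stay
  within 2% of each other — comfortably inside the 95% clustering
  threshold — and whose private genes make the pan-genome open: each
  added genome contributes its `unique_gene_rate` new families, so the
  accumulation curve's final slope equals that rate in expectation;
* DIAMOND-style CAZyme rows with a known best hit per query (E well
  below 1e-102), occasional weaker secondary hits, chaff above the
  cutoff, and all three subject-label dialects.

All randomness flows from the single `seed` in the config; identical
configs give byte-identical cohorts, which the determinism tests check
at the file level after a full pipeline run.

What the generator does *not* emulate — and hence what green tests do
not show about real data: no phylogeny, recombination, codon usage or
realistic intergenic structure; annotation text comes from a controlled
lexicon, so it cannot measure regex recall against the free-text
variability of real annotation pipelines; reference panels are synthetic
stand-ins, so confirmation accuracy against curated public databases is
not measured; and background proteins are i.i.d. random, which makes
between-family identity unrealistically low and clustering
correspondingly easy. The tests demonstrate that the decision rules are
implemented exactly and that recovery is perfect when the planted signal
matches the rules — not that the rules themselves are optimal for real
genomes.

## Numerical and degenerate-input choices

* Translation uses the bacterial/archaeal code (table 11); the annotated
  first residue is kept (no forced Met) so self-translations agree with
  supplied protein FASTA; ambiguous codons translate to X; CDS spans not
  divisible by three are skipped with a warning naming the feature.
* Coordinates are 1-based inclusive everywhere; half-open conversion is
  confined to the GFF3 reader/writer (rtracklayer underneath).
* Proportion rows with zero hits stay all-zero and are flagged in an
  attribute instead of producing 0/0.
* Concordance for a marker with zero candidates is `NA`, never 0.
* Ties are broken deterministically everywhere: best alignment by score,
  then E-value, then accession; CAZyme top-1 by bit score, then E-value,
  then subject label; dominant bacteriocins lexicographically.
* A single top-level pipeline seed derives named per-stage seeds
  (`derive_seeds()`), so skipping a stage does not shift another stage's
  random stream.
* The Kruskal-Wallis comparison excludes the `missing` source category
  by default (a flag includes it), needs at least two non-empty groups,
  and uses the tie-corrected statistic via `stats::kruskal.test`.

## Problem sizes used by the tests and acceptance script

The shipped checks run on: the 36-genome recall cohort (~150 genes per
genome) for marker recovery and concordance; a 15-genome cohort with 20
core + 5 private families per genome for pan-genome recovery; an
8-genome cohort for the byte-identity determinism check; 200 random
peptide pairs (<= 30 aa) against the brute-force alignment oracle; and
the 35-row published species summary for the tier rule. These sizes were
chosen so the full suite completes in about two minutes while every
recovery check remains exact rather than statistical.

## Known limitations

* The packaged regex panel is a reconstruction from the published marker
  list, not the survey's supplementary file; both panel and lexicon are
  plain TSV precisely so they can be swapped for the original.
* Greedy centroid clustering is order-dependent in principle; the
  deterministic length-then-id ordering makes runs reproducible, but
  families straddling the identity threshold can split where exhaustive
  linkage would merge them.
* E-values are classical Karlin-Altschul, not composition-adjusted;
  they should not be compared with BLAST output beyond the thresholded
  decision.
* The safety screen reports VF hits without interpreting them; the
  source material itself is ambivalent about whether classical virulence
  factors occur in these taxa, so interpretation is left to the user.
* Whether bacteriocin abundance should count whole clusters rather than
  structural loci is unstated in the source; structural-locus counting
  is used and documented, and satellite genes are retained in the raw
  hit tables for users who want the other convention.
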