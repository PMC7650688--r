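---
title: "Interpreting a 21-gene PAH panel: models, thresholds and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting a 21-gene PAH panel: models, thresholds and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapanel)
```

## Scope and data model

`hapanel` implements the interpretation layer of a targeted
pulmonary-arterial-hypertension (PAH) gene panel: everything after
alignment and variant calling, and before the clinical report. The unit
of work is a cohort — a multi-sample VCF restricted to the panel
targets, a per-target read-depth matrix, sequencer-level QC metrics, a
pedigree file, and offline annotation snapshots. Wet-lab steps, read
alignment and survival statistics are out of scope by design.

The panel itself (HAP v1.2) comprises 21 genes. Nine of them —
*ACVRL1*, *BMPR2*, *CAV1*, *EIF2AK4*, *ENG*, *GDF2*, *KCNK3*, *SMAD9*
and *TBX4* — are tagged `established` (the genes with a higher level of
published evidence in PAH); the remainder (*ABCC8*, *NOTCH3*, *CPS1*,
*SARS2*, *SMAD1*, *SMAD5*, *CBLN2*, …) are `candidate`. The tier matters
in exactly one place: PVS1 (null variant in a gene where loss of
function is an established disease mechanism) only fires in established
genes.

### The toy transcript model

The commercial capture design is not public and the interpretation
logic is coordinate-agnostic, so the package carries its own synthetic
reference: one contig per gene, plus-strand CDS split into exons with
300 bp introns, canonical GT/AG splice dinucleotides, and 25 bp of
flanking intron per capture target. Coding sequence is drawn from sense
codons under a fixed internal seed, then *patched* so that every variant
in the bundled case set sits in the codon context its printed protein
effect implies — e.g. TBX4 codon 340 is CGA, so `c.1018C>T` really is a
nonsense change, and the ABCC8 intron after `c.579` really carries a G
at donor position +5. Mapping between cDNA and genomic space
(`cdna_to_genomic()` / `genomic_to_cdna()`) is exact and reversible.
What this model does **not** emulate: real gene structure (exon counts
and sizes are invented), GC/mappability bias, paralogy, or real
population haplotypes. Tests passing on this model therefore validate
the *logic* of the pipeline, not its behaviour on any particular human
reference build.

Coordinate conventions are fixed at module boundaries: BED intervals
are 0-based half-open; VCF positions are 1-based; conversion happens
only inside the panel model.

## Sample QC

Per-sample metrics follow standard capture QC: the fraction of target
bases at ≥ 20× (the headline gate, threshold 0.95, inclusive
comparison), mean target depth, uniformity (fraction of target bases
within 0.2×–2× of the sample mean), capture efficiency (on-target read
fraction, reported from the sequencer metrics table), duplicate
fraction and raw error rate (reported, never gating — no published rule
exists for them), and transition/transversion ratios stratified by
known/novel site status. A stratum with zero transversions reports
`NA`, never infinity.

Defaults in `qc_config()`: coverage floor 0.95 (prescribed), on-target
floor 0.70 and known-site Ti/Tv band [2.0, 4.5] (conventional), and a
`min_titv_sites = 20` guard — with fewer classifiable SNVs the
per-sample ratio is too unstable to gate on. Every threshold is a
config entry, and every breach appends a named reason to the sample's
report.

## Annotation and consequence

Annotation is strictly snapshot-based: four packaged TSVs (population
frequencies in long format, predictor tallies, clinical assertions,
known-site ids) keyed by normalized `(chrom, pos, ref, alt)`. A variant
absent from every frequency source has `popmax_af = NA`, which all
downstream logic treats as "not observed" — rarer than any recorded
frequency. When several sources record a variant, the maximum
frequency wins. Conflicting clinical assertions are exposed as
`conflicting`, never silently resolved.

Consequence calling on the toy model applies rules in a fixed order:
new stop codon → `stop_gained`; CDS indel with net length not divisible
by three → `frameshift` (else `inframe_indel`); intronic offsets ±1/2 →
`splice_canonical`, ±3..8 → `splice_region` (a common annotator
convention; ±3..8 and the last 3 exonic bases of non-terminal exons);
remaining CDS SNVs by codon comparison. Indels are left-aligned and
parsimony-trimmed against the packaged reference before any lookup, so
equivalent homopolymer representations collapse to one key.

## Prioritization

The cascade preserves the quality → population-frequency → effect
architecture of panel filtering pipelines, with all numbers explicit
and logged per variant:

1. **quality**: depth ≥ 10 and GQ ≥ 30. Failures are *kept* but flagged
   `candidate_needs_confirmation` if they survive later stages — the
   orthogonal-validation rule (only variants failing quality criteria
   need Sanger confirmation).
2. **frequency**: drop popmax AF > 1e-3, unless a prior pathogenic
   clinical assertion rescues the variant (founder variants can drift
   above rarity cutoffs in sub-populations).
3. **gene**: drop off-panel records.
4. **consequence**: drop synonymous and deep-intronic records, same
   rescue.

Holding everything else fixed, lowering the population frequency can
never turn a kept variant into a dropped one, and every record lands in
exactly one of candidates/dropped with a stage-by-stage trace.

## ACMG evidence engine

`default_evidence()` maps annotations onto evidence codes through
explicit cutoffs (all in `acmg_config()`):

| code | trigger | default |
|------|---------|---------|
| PVS1 | stop_gained / frameshift / canonical splice in an established gene | — |
| PM2  | popmax absent or below the rarity cutoff | 1e-4 |
| BS1 / BA1 | popmax above 1e-3 / above 0.05 | exclusive bands |
| PP3 / BP4 | predictor consensus ≥ 0.5 / ≤ 0.2, with ≥ 3 predictors | — |
| PP5 / BP6 | prior pathogenic / benign assertion | — |
| PP1  | cosegregation support supplied | — |

The PM2 cutoff of 1e-4 is the practical choice for a dominant disease
with reduced penetrance; at 1e-5 the published TBX4 nonsense variant
(gnomAD-exomes 2.81e-5) would lose its rarity evidence despite being a
textbook pathogenic call.

`combine_evidence()` implements the published combining table
(Pathogenic, Likely pathogenic, Benign, Likely benign) with one
documented convention: conflicts are handled at the *code* level — any
verdict on one side in the presence of evidence codes from the other
side yields VUS, so `{BA1, PM2}` is VUS rather than Benign. The
exhaustive test oracle is an independent nested-if transcription of the
same table, checked over every evidence subset of size ≤ 4. Strength
overrides (e.g. downgrading PS4 to moderate) re-weight codes before
counting. CNV calls never enter this engine; their classification stays
`Not_applicable`.

## Read-depth CNV calling

No algorithmic description exists for the original panel-CNV tool, so
the caller is a standard cross-sample read-depth design with declared
semantics: (1) divide each cell by its sample's median target depth
(library size), (2) divide by the across-sample median of its target
(target bias), so diploid cells sit near ratio 1; (3) per target,
compute a *robust* z-score (median/MAD) — a mean/σ score would be
dragged by the very carrier it is trying to detect, and for cohorts of
n ≤ 8 the maximum attainable |z| of a single outlier, (n−1)/√n, never
even reaches the 2.5 threshold; (4) call gain at ratio ≥ 1.35 and
|z| ≥ 2.5, loss at ratio ≤ 0.65 and |z| ≥ 2.5; (5) merge adjacent
called targets per gene and sample. Cohorts below 8 samples emit
low-confidence calls; zero-variance targets are skipped with a warning.
Whole-cohort background (not a matched reference set) is used. CNV
calling should run on QC-passing samples — coverage-failed samples
otherwise surface as legitimate but meaningless loss calls.

At the simulated study conditions (24 samples, negative-binomial depth
with mean 350 and size 200, single-target events at ratio 1.5/0.5) the
benchmark over 50 cohorts achieves ≥ 0.9 sensitivity with ≤ 1 false
call per cohort — the margins are real but not extravagant, which is
faithful to single-exon CNV calling on capture panels.

## Family genetics

Digenic candidacy is deliberately inclusive: any patient with candidate
variants (P/LP/VUS — the published digenic families pair a P with a
VUS) in two or more distinct genes, with CNV calls counting as
gene-level candidates. Two variants in one gene are routed to the
biallelic logic instead: homozygous → `biallelic_hom`; two
heterozygous variants are `compound_het` only when the parental
genotypes admit *only* the trans phase; cis-only pairs are demoted to
`single_het`; ambiguous phase (e.g. a parent carrying both variants) is
reported as untested rather than guessed; a child allele absent from
both typed parents flags `inconsistent` — a data problem, not an
exception. The implementation's carrier logic is verified against
exhaustive enumeration of all 16 parental transmission patterns across
all 81 trio genotype combinations.

Segregation checks never count an unaffected carrier against a variant
— with ~20% penetrance in the main PAH gene, unaffected carriers are
the expectation — but they do note them for the report.

## Synthetic cohorts

`sim_config()` defaults *are* the emulated study conditions: 300
samples, 11% planted QC failures (`floor(n × 0.11) = 33`), 30% carrier
fraction, half of planted candidates truncating (1 bp frameshift
duplications in established genes, absent from all frequency sources —
classifying Likely pathogenic at minimum) and half rare missense with
deliberately mixed predictor votes (3/10 deleterious — landing VUS by
construction), five digenic pairs, one homozygous-founder and one
compound-heterozygous EIF2AK4 case with a trio pedigree, one planted
single-exon BMPR2 duplication at ratio 1.5, twelve common known
background SNVs drawn at transition:transversion odds 3.2, and
negative-binomial per-target depth (mean 350, size 200 — the ~9%
coefficient of variation typical of per-target mean depths on a small
capture panel after averaging within targets). QC failures are planted
by depressing a random 8–20% of target bases below 20×, leaving a
clear margin on both sides of the 95% gate. Generation is fully
reproducible from the seed and never touches the caller's RNG stream.

What the generator does **not** emulate: correlated GC bias across
samples, batch effects, strand artifacts, mosaicism, or population
structure in the background variants. End-to-end recovery on these
cohorts (≥ 95% of planted pathogenic variants returning P/LP, all
digenic pairs recovered among QC-passing samples) therefore
demonstrates internal consistency of the pipeline, not expected
performance on real sequencing runs.

## The worked-example case set

The bundled case tables transcribe the published variant tables
verbatim — including their transcript-version inconsistencies
(`NM_000352.4` vs `.3` vs unversioned for ABCC8; two different CPS1
accessions), footnote spacing inside protein descriptors, and rows
repeated across tables. A normalization layer deduplicates by
(patient, transcript accession, cDNA descriptor), preferring rows that
carry a printed ACMG class; rows printed without a genotype are taken
as heterozygous; rows printed without a class still count as reported
candidates in cohort tallies. The companion annotation snapshots are
*synthetic stand-ins* for the proprietary databases originally
consulted: they carry the single published control-population
frequency, mixed predictor votes for the missense VUS rows, and prior
pathogenic assertions for the previously reported truncating variants.

Re-running the engine over the annotated case set reproduces the
printed classification for every truncating pathogenic row and every
missense VUS row. The known divergences are reported, not hidden: the
intronic BMPR2 deletion printed P classifies VUS here (no PVS1 for a
splice-region deletion without a functional study); the ABCC8 missense
printed LP classifies VUS (its supporting functional evidence is not in
the snapshots); and the GDF2 nonsense variant printed VUS classifies
Likely pathogenic (the original text itself calls it pathogenic in one
place and VUS in the table).

## Numerical and edge-case conventions

* Left-alignment extends through the anchor base and trims shared
  prefixes; the test oracle recomputes the minimal representation by
  maximal common suffix/prefix trimming of the fully edited sequence.
* Proportions with zero denominators (`predictor_consensus(0, 0)`,
  Ti/Tv with no transversions) are `NA`, never `Inf` or 0.
* The hemodynamic triad returns `NA` (undetermined) when any of mPAP,
  PAWP or PVR is missing — distinct from a negative determination.
* Cohort percentages are always emitted with their raw
  numerator/denominator, because patient-level and variant-level
  denominators genuinely differ in this kind of study.
* Problem sizes in the validation suite — 10,000 substitutions per
  Ti/Tv stratum, 50 simulated 24-sample CNV cohorts, one full
  300-sample end-to-end cohort — were chosen as the smallest sizes at
  which the quantities of interest are stable to well within their
  acceptance bands.

## Known limitations

* The HGVS dialect covers what clinical panel tables actually print
  (substitutions, del/dup/ins/delins with offsets and ranges); it does
  not parse inversions, mosaic or uncertain-breakpoint descriptors.
* Protein descriptors are carried as validated opaque strings, not
  recomputed — full protein-effect prediction would need a real
  reference proteome.
* The CNV caller does not resolve breakpoints and is not designed for
  mosaic events or exome/genome-scale segmentation.
* Phasing uses pedigree logic only; read-backed phasing is out of
  scope.
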