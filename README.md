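# hapanel

Interpretation toolkit for **HAP v1.2**, a 21-gene targeted capture panel
for pulmonary arterial hypertension (PAH). Starting from a multi-sample
VCF, a per-target read-depth matrix, a pedigree file and offline
annotation snapshots, the package reproduces the full interpretation
workflow of a clinical PAH panel:

1. **Sample QC** — coverage distribution (95% of target bases at ≥ 20×),
   capture efficiency and uniformity, Ti/Tv ratios in coding regions
   (≈ 3.2 at known sites, ≈ 2.9 at novel sites), with a configurable gate.
2. **Annotation** — snapshot-based joins against population-frequency,
   in-silico-predictor and clinical-assertion tables (never a live
   query), plus functional consequence calling on a packaged transcript
   model.
3. **Prioritization** — a staged cascade (variant quality → population
   frequency → panel membership → consequence), with full per-variant
   traces; low-quality survivors are flagged for orthogonal confirmation
   rather than dropped.
4. **ACMG classification** — an auditable evidence engine
   (PVS1/PS/PM/PP/BA1/BS/BP) implementing the published combining rules
   into the five-tier Pathogenic … Benign scale.
5. **CNV calling** — cross-sample read-depth ratios on capture targets
   (two-stage median normalization, robust per-target z-scores), the
   mechanism that detects events like a single-exon *BMPR2* duplication.
6. **Family genetics** — digenic co-occurrence detection, biallelic
   *EIF2AK4* logic (homozygous founder variants and trio-phased compound
   heterozygotes), and Mendelian segregation checks that treat unaffected
   carriers as reduced penetrance, not inconsistency.
7. **Cohort reporting** — per-gene / per-etiology / per-class tallies and
   the precapillary-PH hemodynamic eligibility triad
   (mPAP ≥ 25 mmHg, PAWP ≤ 15 mmHg, PVR > 3 WU).

Because no patient-level sequence data are publicly deposited for this
kind of cohort, the package ships two data sources of its own:

* a **worked-example case set** (`load_case_fixture()`): the published
  digenic-family, ABCC8 and associated-PAH variant tables transcribed
  verbatim (transcript-version quirks included), mapped onto a packaged
  toy transcript model, plus the biallelic *EIF2AK4* PVOD cases;
* a **synthetic cohort generator** (`generate_cohort()`): 300-sample
  cohorts with planted truth — QC failures, pathogenic truncating
  variants, rare missense VUS, digenic pairs, biallelic cases and
  single-exon CNVs — so every pipeline stage can be validated offline.

## Worked example

```r
library(hapanel)

fx  <- load_case_fixture()
dig <- detect_cooccurrence(fx$variants, fx$cnvs)
dig$patient_id
#> [1] "HTP070" "HTP081" "HTP466" "HTP474" "HTP611"

summarize_cohort(fx$patients, fx$variants, fx$cnvs)
#> Cohort summary
#>   sequenced:           25
#>   failed QC:           0/25 (0.0%)
#>   analyzed:            25
#>   carriers:            25/25 (100.0%)
#>   candidate variants:  31
#>   class distribution:  Pathogenic=10  Likely_pathogenic=1  VUS=14
#>   digenic patients:    5

detect_biallelic(fx$variants, "EIF2AK4", fx$ped)[, c("patient_id", "kind",
                                                     "segregation")]
#>   patient_id          kind segregation
#> 1     PVOD01 biallelic_hom    untested
#> 2     PVOD02  compound_het  consistent
#> 3     PVOD03  compound_het  consistent
```

Five families carry candidate variants in two genes (including one where
the second event is the exon-2 *BMPR2* duplication found by the depth
caller); the PVOD sibling pair is compound heterozygous with one variant
per parent. Re-classifying the annotated case set with
`classify_records()` reproduces the printed class for every truncating
pathogenic row and every missense VUS row.

A full synthetic study, end to end:

```r
co  <- generate_cohort(sim_config(n_samples = 300, seed = 7))
dir <- tempfile(); write_cohort(co, dir)

qc   <- qc_gate(compute_sample_qc(co$depth, metrics = co$metrics))
sum(!qc$passed)
#> [1] 33     # = floor(300 x 0.11), exactly the planted failures

recs <- read_vcf(file.path(dir, "cohort.vcf"))
ann  <- annotate_variants(recs, load_snapshots(file.path(dir, "snapshots")))
cand <- prioritize(ann)$candidates
cls  <- classify_records(cand)
```

All planted truncating variants in established genes return as
Pathogenic/Likely pathogenic among QC-passing samples, and all five
planted digenic pairs are recovered.

There is also a thin command-line front end in `inst/cli/hap.R`
(`panel`, `simulate`, `qc`, `cnv`, `interpret` subcommands). CNV calling
is intended to run on QC-passing samples: depth-depressed QC failures
otherwise surface as (correctly) grotesque loss calls.

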