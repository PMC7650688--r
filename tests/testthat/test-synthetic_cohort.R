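# The generator runs at reduced scale here; the full 300-sample study
# conditions are exercised in the acceptance suite.

small_cfg <- function(seed = 11) {
  sim_config(n_samples = 60L, seed = seed, digenic_pairs = 2L,
             n_background = 6L)
}

test_that("generation is reproducible and respects planted counts", {
  c1 <- generate_cohort(small_cfg())
  c2 <- generate_cohort(small_cfg())
  expect_identical(c1$sites, c2$sites)
  expect_identical(c1$dosage, c2$dosage)
  expect_identical(c1$depth$depth, c2$depth$depth)
  expect_equal(length(c1$truth$qc_fail), floor(60 * 0.11))
  expect_equal(length(c1$truth$digenic_samples), 2L)
  # digenic samples carry candidates in two distinct genes
  for (s in c1$truth$digenic_samples) {
    pl <- c1$truth$plants[c1$truth$plants$sample_id == s, ]
    expect_gte(length(unique(pl$gene)), 2L)
  }
  c3 <- generate_cohort(small_cfg(seed = 12))
  expect_false(identical(c1$sites, c3$sites))
})

test_that("contradictory configurations are rejected", {
  expect_error(sim_config(n_samples = 10, seed = 1,
                          carrier_fraction = 1.2), "fractions")
  expect_error(sim_config(seed = 1, n_samples = 10, carrier_fraction = 0.1,
                          digenic_pairs = 5), "special cases")
  expect_error(sim_config(n_samples = 10), "seed")
})

test_that("written cohorts round-trip byte-identically and load back", {
  co <- generate_cohort(small_cfg())
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(co, d1)
  write_cohort(co, d2)
  for (f in c("cohort.vcf", "depths.tsv", "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  recs <- read_vcf(file.path(d1, "cohort.vcf"), test_panel())
  expect_gt(nrow(recs), 0)
  expect_false(any(recs$off_target))
  # every planted variant appears among the parsed records
  tp <- co$truth$plants
  key <- function(d) paste(d$sample_id, d$chrom, d$pos, d$ref, d$alt)
  expect_true(all(key(tp) %in% key(recs)))
  snaps <- load_snapshots(file.path(d1, "snapshots"))
  expect_s3_class(snaps, "hap_snapshots")
})

test_that("planted QC failures are exactly the gated samples", {
  co <- generate_cohort(small_cfg(seed = 19))
  qc <- qc_gate(compute_sample_qc(co$depth, metrics = co$metrics))
  expect_setequal(qc$sample_id[!qc$passed], co$truth$qc_fail)
  expect_true(all(grepl("coverage",
                        qc$failure_reasons[!qc$passed])))
})

test_that("planted truncating variants classify P/LP end to end", {
  co <- generate_cohort(small_cfg(seed = 23))
  panel <- test_panel()
  d <- withr::local_tempdir()
  write_cohort(co, d)
  recs <- read_vcf(file.path(d, "cohort.vcf"), panel)
  ann <- annotate_variants(recs, load_snapshots(file.path(d, "snapshots")))
  pri <- prioritize(ann, panel)
  cls <- classify_records(pri$candidates, panel)
  qc <- qc_gate(compute_sample_qc(co$depth, metrics = co$metrics))
  pass <- qc$sample_id[qc$passed]
  tp <- co$truth$plants
  key <- function(x) paste(x$sample_id, x$chrom, x$pos, x$ref, x$alt)
  want <- tp[tp$intended == "pathogenic" & tp$sample_id %in% pass, ]
  got <- cls[cls$acmg %in% c("Pathogenic", "Likely_pathogenic"), ]
  expect_gte(mean(key(want) %in% key(got)), 0.95)
  # planted VUS land VUS (mixed predictors, rare missense)
  want_vus <- tp[tp$intended == "vus" & tp$sample_id %in% pass, ]
  got_vus <- cls[cls$acmg == "VUS", ]
  expect_gte(mean(key(want_vus) %in% key(got_vus)), 0.95)
})

test_that("the planted single-exon duplication is recovered", {
  co <- generate_cohort(small_cfg(seed = 29))
  qc <- qc_gate(compute_sample_qc(co$depth, metrics = co$metrics))
  keep <- qc$sample_id[qc$passed]
  m <- depth_matrix(co$depth$targets,
                    co$depth$depth[, keep, drop = FALSE])
  calls <- call_cnvs(normalize_depth(m), m$targets)
  tr <- co$truth$cnvs
  hit <- calls[calls$sample_id == tr$sample_id[1] &
                 calls$gene == tr$gene[1] & calls$kind == "gain", ]
  expect_equal(nrow(hit), 1L)
  expect_match(hit$targets, tr$label[1], fixed = TRUE)
})
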