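test_that("popmax is the max over sources and absence stays absent", {
  model <- test_model()
  v <- hgvs_to_vcf("NOTCH3:NM_000435.2:c.181C>T", model)
  snaps <- structure(list(
    freq = data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref,
                      alt = v$alt,
                      source = c("gnomad_exomes_like",
                                 "thousand_genomes_like"),
                      af = c(1e-4, 3e-4)),
    pred = data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      n_deleterious = integer(0), n_total = integer(0),
                      cadd_like = numeric(0)),
    clin = data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      assertion = character(0)),
    known = data.frame(chrom = character(0), pos = integer(0),
                       ref = character(0), alt = character(0),
                       dbsnp_id = character(0))), class = "hap_snapshots")
  rec <- data.frame(sample_id = "S1", chrom = v$chrom, pos = v$pos,
                    ref = v$ref, alt = v$alt, gene = v$gene)
  ann <- annotate_variants(rec, snaps, model)
  expect_equal(ann$popmax_af, 3e-4)
  # a variant absent from all tables
  rec2 <- data.frame(sample_id = "S1", chrom = v$chrom, pos = v$pos + 3L,
                     ref = "A", alt = "G", gene = v$gene)
  rec2$ref <- substr(contig_seq(model, v$chrom), rec2$pos, rec2$pos)
  rec2$alt <- setdiff(c("A", "C", "G", "T"), rec2$ref)[1]
  ann2 <- annotate_variants(rec2, snaps, model)
  expect_true(is.na(ann2$popmax_af))
  expect_equal(ann2$clinical_assertion, "none")
  expect_false(ann2$known)
})

test_that("bundled snapshot carries the published TBX4 control frequency", {
  ann <- test_fixture_annotated()
  tbx4 <- ann[ann$gene == "TBX4" & grepl("c.1018C>T", ann$variant,
                                         fixed = TRUE), ]
  expect_equal(unique(tbx4$popmax_af), 2.81e-5)
  expect_equal(unique(tbx4$consequence), "stop_gained")
})

test_that("annotation is pure: identical inputs give identical bundles", {
  fx <- test_fixture()
  a1 <- annotate_variants(fx$variants, fx$snapshots)
  a2 <- annotate_variants(fx$variants, fx$snapshots)
  expect_identical(a1, a2)
})

test_that("snapshot schema mismatches are load errors", {
  d <- withr::local_tempdir()
  write.table(data.frame(chrom = "x", pos = 1, ref = "A", alt = "G"),
              file.path(d, "freq.tsv"), sep = "\t", row.names = FALSE)
  expect_error(load_snapshots(d), "schema mismatch")
})

test_that("predictor consensus is a guarded proportion", {
  expect_equal(predictor_consensus(7L, 10L), 0.7)
  expect_equal(predictor_consensus(10L, 10L), 1.0)
  expect_true(is.na(predictor_consensus(0L, 0L)))
  expect_error(predictor_consensus(5L, 3L))
})

test_that("consequence_call classifies the canonical variant archetypes", {
  model <- test_model()
  # CGA -> TGA nonsense (TBX4 codon 340)
  v <- hgvs_to_vcf("TBX4:NM_018488.3:c.1018C>T", model)
  expect_equal(consequence_call(v$chrom, v$pos, v$ref, v$alt, model),
               "stop_gained")
  # single-base duplication in CDS -> frameshift
  v <- hgvs_to_vcf("EIF2AK4:NM_001013703.3:c.4392dup", model)
  expect_equal(consequence_call(v$chrom, v$pos, v$ref, v$alt, model),
               "frameshift")
  # donor +1 -> canonical splice
  v <- hgvs_to_vcf("ABCC8:NM_000352.3:c.2694+1G>A", model)
  expect_equal(consequence_call(v$chrom, v$pos, v$ref, v$alt, model),
               "splice_canonical")
  # intronic -5.._-2 deletion -> splice region
  v <- hgvs_to_vcf("BMPR2:NM_001204.6:c.77-5_77-2delTTTA", model)
  expect_equal(consequence_call(v$chrom, v$pos, v$ref, v$alt, model),
               "splice_region")
  # donor +5 -> splice region
  v <- hgvs_to_vcf("ABCC8:NM_000352.3:c.579+5G>A", model)
  expect_equal(consequence_call(v$chrom, v$pos, v$ref, v$alt, model),
               "splice_region")
  expect_error(consequence_call("ctg_nowhere", 10L, "A", "G", model),
               "outside")
})

test_that("SNV consequences agree with a codon-translation oracle", {
  model <- test_model()
  genes <- names(model$genes)
  withr::with_seed(77, {
    n_checked <- 0
    while (n_checked < 500) {
      g <- sample(genes, 1)
      gm <- model$genes[[g]]
      cpos <- sample.int(gm$cds_len, 1)
      ex <- gm$exons
      i <- which(cpos >= ex$c_start & cpos <= ex$c_end)
      # skip the splice-region override zone (last 3 bases, non-terminal)
      if (i < nrow(ex) && cpos > ex$c_end[i] - 3L) next
      idx <- (cpos - 1) %/% 3 + 1
      off <- (cpos - 1) %% 3 + 1
      codon <- substr(gm$cds, 3 * idx - 2, 3 * idx)
      ref <- substr(codon, off, off)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      # oracle: full-CDS translation comparison via Biostrings
      mut <- gm$cds
      substr(mut, cpos, cpos) <- alt
      p_ref <- as.character(Biostrings::translate(Biostrings::DNAString(
        gm$cds)))
      p_alt <- as.character(Biostrings::translate(Biostrings::DNAString(
        mut)))
      aa_r <- substr(p_ref, idx, idx)
      aa_a <- substr(p_alt, idx, idx)
      want <- if (aa_a == "*" && aa_r != "*") "stop_gained" else
        if (aa_r == aa_a) "synonymous" else
          if (aa_r == "*") "other" else "missense"
      gpos <- cdna_to_genomic(model, g, cpos)$pos
      got <- consequence_call(gm$contig, gpos, ref, alt, model)
      expect_identical(got, want)
      n_checked <- n_checked + 1
    }
  })
})
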