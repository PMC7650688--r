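test_that("indel normalization matches the shift-minimization oracle", {
  withr::with_seed(23, {
    for (i in 1:200) {
      seq <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                   collapse = "")
      pos <- sample(15:40, 1)
      if (runif(1) < 0.5) {              # deletion, possibly with padding
        len <- sample(1:4, 1)
        ref <- substr(seq, pos, pos + len)
        alt <- substr(seq, pos, pos)
      } else {                           # insertion
        ins <- paste(sample(c("A", "C", "G", "T"), sample(1:3, 1),
                            replace = TRUE), collapse = "")
        ref <- substr(seq, pos, pos)
        alt <- paste0(ref, ins)
      }
      # pad both alleles with shared downstream context so the input is
      # deliberately non-minimal
      pad <- substr(seq, pos + nchar(ref), pos + nchar(ref) + 2)
      got <- normalize_variant(pos, paste0(ref, pad), paste0(alt, pad), seq)
      want <- normalize_oracle(pos, paste0(ref, pad), paste0(alt, pad), seq)
      expect_equal(got, want)
    }
  })
})

test_that("equivalent homopolymer indel representations normalize equally", {
  seq <- "GGGCAAAAAATTTCGG"
  # deletion of one A written at two positions within the A-run
  a <- normalize_variant(4L, "CA", "C", seq)
  b <- normalize_variant(9L, "AA", "A", seq)
  expect_equal(a, b)
  # insertion of A written at either end of the run
  a <- normalize_variant(4L, "C", "CA", seq)
  b <- normalize_variant(10L, "A", "AA", seq)
  expect_equal(a, b)
})

test_that("read_vcf decomposes sites and counts carriers", {
  model <- test_model()
  gm <- model$genes$BMPR2
  pos <- gm$exons$g_start[3] + 5L
  seq <- gm$seq
  b <- substr(seq, pos, pos)
  alt1 <- setdiff(c("A", "C", "G", "T"), b)[1]
  alt2 <- setdiff(c("A", "C", "G", "T"), b)[2]
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", gm$contig, nchar(seq)),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "P1", "P2", "P3"), collapse = "\t"),
    paste(c(gm$contig, pos, ".", b, paste0(alt1, ",", alt2), "99", "PASS",
            ".", "GT:GQ:DP", "0/1:80:40", "0/2:70:35", "0/0:99:50"),
          collapse = "\t")), vcf)
  recs <- read_vcf(vcf, test_panel(), model)
  expect_equal(nrow(recs), 2L)                   # one per carrier
  expect_setequal(recs$alt, c(alt1, alt2))       # decomposed
  expect_equal(unique(recs$gene), "BMPR2")
  expect_true(all(!recs$off_target))
  expect_equal(recs$zygosity, c("het", "het"))
})

test_that("read_vcf validates the reference against the packaged slice", {
  model <- test_model()
  gm <- model$genes$TBX4
  pos <- gm$exons$g_start[1] + 3L
  wrong <- setdiff(c("A", "C", "G", "T"),
                   substr(gm$seq, pos, pos))[1]
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "P1"), collapse = "\t"),
    paste(c(gm$contig, pos, ".", wrong, "A", "99", "PASS", ".", "GT",
            "0/1"), collapse = "\t")), vcf)
  expect_error(suppressWarnings(read_vcf(vcf, test_panel(), model)),
               "reference mismatch")
})

test_that("report table writes sorted rows and round-trips", {
  fx <- test_fixture()
  apah <- fx$variants[fx$variants$etiology %in% c("CHD", "CTD"), ]
  path <- withr::local_tempfile(fileext = ".tsv")
  write_report_table(apah, path)
  back <- read_report_table(path)
  expect_equal(nrow(back), 15L)
  expect_equal(back$patient_id, sort(back$patient_id))
  expect_setequal(back$variant, apah$variant)
  expect_setequal(back$acmg, apah$acmg)
  # empty input -> header-only file
  write_report_table(apah[0, ], path)
  expect_equal(nrow(read_report_table(path)), 0L)
})
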