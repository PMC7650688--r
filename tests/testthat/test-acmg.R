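test_that("combining rules reproduce the guideline spot checks", {
  expect_equal(combine_evidence(character(0)), "VUS")
  expect_equal(combine_evidence(c("PVS1", "PS3")), "Pathogenic")
  expect_equal(combine_evidence(c("PVS1", "PM2")), "Likely_pathogenic")
  expect_equal(combine_evidence(c("PVS1", "PM2", "PP5")), "Pathogenic")
  expect_equal(combine_evidence(c("BA1", "PM2")), "VUS")  # conflict
  expect_equal(combine_evidence(c("PM2", "PP3")), "VUS")
  expect_equal(combine_evidence("BA1"), "Benign")
  expect_equal(combine_evidence(c("BS1", "BS2")), "Benign")
  expect_equal(combine_evidence(c("BS1", "BP4")), "Likely_benign")
  expect_equal(combine_evidence(c("PS1", "PS2")), "Pathogenic")
  expect_equal(combine_evidence(c("PM1", "PM2", "PM3")),
               "Likely_pathogenic")
  expect_error(combine_evidence("PX9"), "unknown")
})

test_that("strength overrides reweight codes before combining", {
  # PS4 downgraded to moderate: 1 PS -> 0 PS + 1 PM
  expect_equal(combine_evidence(c("PS3", "PS4"),
                                strength_overrides = c(PS4 = "moderate")),
               "Likely_pathogenic")
  expect_error(combine_evidence("PM2", strength_overrides = c(PS4 = "strong")),
               "absent")
})

test_that("combine_evidence equals the transcription oracle on small sets", {
  codes <- acmg_codes()
  combos <- c(list(character(0)), as.list(codes),
              combn(codes, 2, simplify = FALSE),
              combn(codes, 3, simplify = FALSE))
  for (cs in combos) {
    expect_identical(combine_evidence(cs), acmg_oracle(cs))
  }
})

test_that("adding pathogenic codes never moves a verdict toward benign", {
  rank <- c(Benign = 1, Likely_benign = 2, VUS = 3,
            Likely_pathogenic = 4, Pathogenic = 5)
  path_codes <- c("PVS1", paste0("PS", 1:4), paste0("PM", 1:6),
                  paste0("PP", 1:5))
  withr::with_seed(13, {
    for (i in 1:200) {
      base <- sample(path_codes, sample(0:3, 1))
      extra <- sample(setdiff(path_codes, base), 1)
      expect_gte(rank[combine_evidence(c(base, extra))],
                 rank[combine_evidence(base)])
    }
  })
})

test_that("default evidence reproduces the printed classes on fixture rows", {
  ann <- test_fixture_annotated()
  cls <- classify_records(ann, test_panel())
  printed <- ann$acmg
  # all P rows with truncating consequences must classify Pathogenic
  trunc_p <- !is.na(printed) & printed == "P" &
    cls$consequence %in% c("stop_gained", "frameshift")
  expect_gt(sum(trunc_p), 0)
  expect_true(all(cls$acmg[trunc_p] == "Pathogenic"))
  # all VUS missense rows with no assertions must classify VUS
  vus_mis <- !is.na(printed) & printed == "VUS" &
    cls$consequence == "missense" & cls$clinical_assertion == "none"
  expect_gt(sum(vus_mis), 0)
  expect_true(all(cls$acmg[vus_mis] == "VUS"))
  # mismatches on other rows are reported, not hidden
  mismatch <- cls[!is.na(printed) &
                    printed %in% c("P", "LP") &
                    !(cls$acmg %in% c("Pathogenic", "Likely_pathogenic")), ]
  expect_true(all(c("HTP070", "HTP466") %in% mismatch$patient_id))
})

test_that("default evidence thresholds drive the expected codes", {
  panel <- test_panel()
  mk <- function(gene, consequence, af, ndel = 0L, ntot = 0L,
                 clin = "none") {
    list(gene = gene, consequence = consequence, popmax_af = af,
         n_deleterious = ndel, n_total = ntot, clinical_assertion = clin)
  }
  # truncating in established gene, rare, previously reported
  ev <- default_evidence(mk("TBX4", "stop_gained", 2.81e-5,
                            clin = "pathogenic_reported"), panel)
  expect_setequal(ev, c("PVS1", "PM2", "PP5"))
  expect_equal(combine_evidence(ev), "Pathogenic")
  # rare missense with mixed predictors in a candidate gene
  ev <- default_evidence(mk("NOTCH3", "missense", NA, 3L, 10L), panel)
  expect_setequal(ev, "PM2")
  expect_equal(combine_evidence(ev), "VUS")
  # common variant
  ev <- default_evidence(mk("NOTCH3", "missense", 0.1), panel)
  expect_setequal(ev, "BA1")
  expect_equal(combine_evidence(ev), "Benign")
  # truncating in a candidate gene never gets PVS1
  ev <- default_evidence(mk("ABCC8", "splice_canonical", NA), panel)
  expect_false("PVS1" %in% ev)
  # segregation support adds PP1
  ev <- default_evidence(mk("BMPR2", "missense", NA), panel,
                         segregation = TRUE)
  expect_true("PP1" %in% ev)
  expect_error(default_evidence(list(gene = "BMPR2"), panel),
               "not annotated")
})
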