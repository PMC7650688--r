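test_that("case set yields exactly the five digenic families", {
  fx <- test_fixture()
  dig <- detect_cooccurrence(fx$variants, fx$cnvs)
  expect_equal(sort(dig$patient_id),
               c("HTP070", "HTP081", "HTP466", "HTP474", "HTP611"))
  expect_true(all(dig$kind == "digenic_candidate"))
  # the CNV-backed family pairs BMPR2 with NOTCH3
  expect_equal(dig$genes[dig$patient_id == "HTP081"], "BMPR2;NOTCH3")
})

test_that("single-gene and same-gene carriers are never digenic", {
  one <- data.frame(patient_id = "A", gene = "BMPR2", acmg = "P")
  expect_equal(nrow(detect_cooccurrence(one)), 0L)
  two_same <- data.frame(patient_id = c("A", "A"),
                         gene = c("EIF2AK4", "EIF2AK4"),
                         acmg = c("P", "P"))
  expect_equal(nrow(detect_cooccurrence(two_same)), 0L)
})

test_that("biallelic detection finds the PVOD cases with trio phasing", {
  fx <- test_fixture()
  bi <- detect_biallelic(fx$variants, "EIF2AK4", fx$ped)
  expect_setequal(bi$patient_id, c("PVOD01", "PVOD02", "PVOD03"))
  expect_equal(bi$kind[bi$patient_id == "PVOD01"], "biallelic_hom")
  expect_equal(bi$kind[bi$patient_id == "PVOD02"], "compound_het")
  expect_equal(bi$segregation[bi$patient_id == "PVOD02"], "consistent")
})

test_that("cis pairs and untested pairs are distinguished", {
  cands <- data.frame(patient_id = "C1", gene = "EIF2AK4",
                      zygosity = c("het", "het"),
                      variant = c("v1", "v2"), acmg = "P")
  # no pedigree: compound het, untested
  bi <- detect_biallelic(cands, "EIF2AK4")
  expect_equal(bi$kind, "compound_het")
  expect_equal(bi$segregation, "untested")
  # both variants from the mother: cis
  ped <- pedigree(
    data.frame(family_id = "F", individual_id = c("fa", "mo", "C1"),
               father_id = c(NA, NA, "fa"), mother_id = c(NA, NA, "mo"),
               sex = c(1, 2, 1), affected = c(1, 1, 2)),
    genotypes = data.frame(individual_id = c("mo", "mo", "C1", "C1"),
                           variant = c("v1", "v2", "v1", "v2"),
                           zygosity = "het"))
  bi <- detect_biallelic(cands, "EIF2AK4", ped)
  expect_equal(bi$kind, "single_het")
  # child allele absent from both parents: inconsistent, no exception
  ped2 <- pedigree(
    ped$members,
    genotypes = data.frame(individual_id = c("C1", "C1"),
                           variant = c("v1", "v2"), zygosity = "het"))
  bi2 <- detect_biallelic(cands, "EIF2AK4", ped2)
  expect_equal(bi2$segregation, "inconsistent")
})

test_that("phase decision matches exhaustive transmission enumeration", {
  members <- data.frame(family_id = "F",
                        individual_id = c("fa", "mo", "kid"),
                        father_id = c(NA, NA, "fa"),
                        mother_id = c(NA, NA, "mo"),
                        sex = c(1, 2, 1), affected = c(1, 1, 2))
  cands <- data.frame(patient_id = "kid", gene = "EIF2AK4",
                      zygosity = c("het", "het"),
                      variant = c("v1", "v2"), acmg = "P")
  dos_rows <- function(id, v, d) {
    if (d == 0) NULL else
      data.frame(individual_id = id, variant = v,
                 zygosity = if (d == 2) "hom" else "het")
  }
  for (f1 in 0:2) for (f2 in 0:2) for (m1 in 0:2) for (m2 in 0:2) {
    g <- rbind(dos_rows("fa", "v1", f1), dos_rows("fa", "v2", f2),
               dos_rows("mo", "v1", m1), dos_rows("mo", "v2", m2),
               dos_rows("kid", "v1", 1), dos_rows("kid", "v2", 1))
    ped <- pedigree(members, genotypes = g)
    got <- detect_biallelic(cands, "EIF2AK4", ped)
    want <- phase_oracle(f1, f2, m1, m2)
    if (length(want) == 0) {
      expect_equal(got$segregation, "inconsistent")
    } else if (identical(want, "trans")) {
      expect_equal(got$kind, "compound_het")
      expect_equal(got$segregation, "consistent")
    } else if (identical(want, "cis")) {
      expect_equal(got$kind, "single_het")
    } else {
      expect_equal(got$segregation, "untested")  # phase unresolved
    }
  }
})

test_that("segregation notes unaffected carriers without inconsistency", {
  members <- data.frame(family_id = "F",
                        individual_id = c("mo", "fa", "kid"),
                        father_id = c(NA, NA, "fa"),
                        mother_id = c(NA, NA, "mo"),
                        sex = c(2, 1, 1), affected = c(1, 1, 2))
  # affected child inherits from healthy mother: consistent + note
  ped <- pedigree(members,
                  genotypes = data.frame(
                    individual_id = c("mo", "kid"), variant = "v1",
                    zygosity = "het"))
  f <- data.frame(patient_id = "kid", kind = "single_het", variants = "v1",
                  segregation = "untested")
  out <- segregation_check(f, ped)
  expect_equal(out$segregation, "consistent")
  expect_match(out$penetrance_note, "reduced penetrance")
  # hom-alt child of two explicitly typed hom-ref parents: impossible
  ped2 <- pedigree(members,
                   genotypes = data.frame(
                     individual_id = c("kid", "fa", "mo"), variant = "v1",
                     zygosity = c("hom", "ref", "ref")))
  out2 <- segregation_check(f, ped2)
  expect_equal(out2$segregation, "inconsistent")
  # no relative genotypes at all
  ped3 <- pedigree(members,
                   genotypes = data.frame(individual_id = "kid",
                                          variant = "v1",
                                          zygosity = "het"))
  out3 <- segregation_check(f, ped3)
  expect_equal(out3$segregation, "untested")
})

test_that("pedigree loader rejects cycles and unresolved parents", {
  bad <- data.frame(family_id = "F", individual_id = c("a", "b"),
                    father_id = c("b", "a"), mother_id = c(NA, NA),
                    sex = 1, affected = 1)
  expect_error(pedigree(bad), "ancestor")
  ped_file <- withr::local_tempfile(fileext = ".ped")
  writeLines("F\tkid\tghost\t0\t1\t2", ped_file)
  expect_error(read_ped(ped_file), "not in pedigree")
})
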