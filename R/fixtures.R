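#' Bundled worked-example case set
#'
#' Loads the curated case tables shipped with the package: the five
#' digenic two-gene families, the nine ABCC8 carriers, the fifteen
#' associated-PAH (CHD/CTD) variants, and the biallelic EIF2AK4 PVOD
#' cases (a homozygous founder missense and a compound-heterozygous
#' sibling pair with a trio pedigree). Variant strings are stored as
#' printed in the original clinical report tables, including their
#' transcript-version inconsistencies; a normalization layer resolves
#' rows reported in more than one table by (patient, transcript
#' accession, cDNA descriptor), preferring rows that carry an ACMG class.
#' Table rows without a printed genotype are taken as heterozygous. PVOD
#' patient identifiers are synthetic (the report published none). The
#' single-exon BMPR2 duplication is carried as a CNV case, not a small
#' variant: it is a depth-level event whose classification stays
#' `Not_applicable`.
#'
#' The companion annotation snapshots under
#' `extdata/case_snapshots_synthetic/` are synthetic stand-ins for the
#' proprietary databases the original interpretation consulted: they
#' record the one published control-population frequency (TBX4 c.1018C>T,
#' gnomAD-exomes-like 2.81e-5), mixed in-silico votes for the missense
#' VUS rows, and prior pathogenic assertions for the previously reported
#' truncating variants.
#'
#' @return list of class `hap_fixture`: `patients`, `variants`, `cnvs`,
#'   `ped`, `snapshots`
#' @export
load_case_fixture <- function() {
  ext <- system.file("extdata", package = "hapanel")
  read_cases <- function(f) {
    read_tsv_strict(file.path(ext, f),
                    required = c("patient_id", "etiology", "variant",
                                 "zygosity", "acmg"))
  }
  raw <- rbind(read_cases("digenic_families.tsv"),
               read_cases("abcc8_variants.tsv"),
               read_cases("apah_variants.tsv"),
               read_cases("pvod_biallelic.tsv"))
  raw$acmg[raw$acmg %in% c(".", "")] <- NA_character_
  raw$zygosity[raw$zygosity %in% c(".", "")] <- NA_character_
  model <- toy_transcript_model()

  parsed <- lapply(raw$variant, parse_hgvs)
  mapped <- lapply(parsed, hgvs_to_vcf, model = model)
  cdna_desc <- vapply(parsed, function(h) {
    sub("^[^:]*:?NM_[0-9.]+:", "", format_hgvs(h))
  }, character(1))
  v <- data.frame(
    patient_id = raw$patient_id,
    etiology = ifelse(raw$etiology == "CREST-PAH", "CTD", raw$etiology),
    subtype = ifelse(raw$etiology == "CREST-PAH", "CREST", NA_character_),
    variant_printed = raw$variant,
    variant = vapply(parsed, format_hgvs, character(1)),
    gene = vapply(mapped, `[[`, character(1), "gene"),
    transcript = vapply(parsed, `[[`, character(1), "transcript"),
    cdna_pos = vapply(parsed, `[[`, integer(1), "start"),
    protein = vapply(parsed, `[[`, character(1), "protein"),
    chrom = vapply(mapped, `[[`, character(1), "chrom"),
    pos = vapply(mapped, function(m) as.integer(m$pos), integer(1)),
    ref = vapply(mapped, `[[`, character(1), "ref"),
    alt = vapply(mapped, `[[`, character(1), "alt"),
    zygosity = ifelse(is.na(raw$zygosity), "het", tolower(raw$zygosity)),
    acmg = raw$acmg,
    stringsAsFactors = FALSE)

  dk <- paste(v$patient_id, accession_base(v$transcript),
              sub(":p\\..*$", "", cdna_desc))
  ord <- order(dk, is.na(v$acmg))
  v <- v[ord, , drop = FALSE]
  v <- v[!duplicated(dk[ord]), , drop = FALSE]
  rownames(v) <- NULL
  v$sample_id <- v$patient_id

  cnvs <- read_tsv_strict(file.path(ext, "cnv_cases.tsv"),
                          required = c("patient_id", "etiology", "gene",
                                       "label", "kind"))
  cnvs$classification <- "Not_applicable"

  pats <- unique(v[, c("patient_id", "etiology", "subtype")])
  extra <- setdiff(cnvs$patient_id, pats$patient_id)
  if (length(extra)) {
    pats <- rbind(pats, data.frame(patient_id = extra,
                                   etiology = cnvs$etiology[
                                     match(extra, cnvs$patient_id)],
                                   subtype = NA_character_))
  }
  pats <- pats[order(pats$patient_id), , drop = FALSE]
  rownames(pats) <- NULL

  ped <- read_ped(file.path(ext, "pvod_families.ped"),
                  genotypes = file.path(ext, "pvod_genotypes.tsv"))
  snapshots <- load_snapshots(file.path(ext, "case_snapshots_synthetic"))

  structure(list(patients = pats, variants = v, cnvs = cnvs, ped = ped,
                 snapshots = snapshots), class = "hap_fixture")
}
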