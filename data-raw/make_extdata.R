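# Regenerates the derived extdata files:
#   - hap_v12_genes.tsv / hap_v12_targets.bed (the bundled panel files)
#   - case_snapshots_synthetic/ (annotation snapshots for the case set,
#     keyed by toy-model genomic coordinates)
# Rerun after any change to the toy transcript model or the case tables.
# Usage: Rscript data-raw/make_extdata.R  (from the package root)

pkgload::load_all(".", quiet = TRUE)

ext <- "inst/extdata"
panel <- hap_panel()
write_panel(panel, file.path(ext, "hap_v12_genes.tsv"),
            file.path(ext, "hap_v12_targets.bed"))

snapdir <- file.path(ext, "case_snapshots_synthetic")
dir.create(snapdir, showWarnings = FALSE)

model <- toy_transcript_model()
cases <- rbind(
  read.table(file.path(ext, "digenic_families.tsv"), header = TRUE,
             sep = "\t", quote = ""),
  read.table(file.path(ext, "abcc8_variants.tsv"), header = TRUE,
             sep = "\t", quote = ""),
  read.table(file.path(ext, "apah_variants.tsv"), header = TRUE,
             sep = "\t", quote = ""),
  read.table(file.path(ext, "pvod_biallelic.tsv"), header = TRUE,
             sep = "\t", quote = "")
)
parsed <- lapply(cases$variant, parse_hgvs)
mapped <- lapply(parsed, hgvs_to_vcf, model = model)
key <- data.frame(
  variant = vapply(parsed, format_hgvs, character(1)),
  gene = vapply(mapped, `[[`, character(1), "gene"),
  chrom = vapply(mapped, `[[`, character(1), "chrom"),
  pos = vapply(mapped, function(m) as.integer(m$pos), integer(1)),
  ref = vapply(mapped, `[[`, character(1), "ref"),
  alt = vapply(mapped, `[[`, character(1), "alt"),
  protein = vapply(parsed, `[[`, character(1), "protein")
)
key <- key[!duplicated(paste(key$chrom, key$pos, key$ref, key$alt)), ]

# population frequency: the one published control AF; everything else absent
tbx4 <- key[grepl("c\\.1018C>T", key$variant), ][1, ]
freq <- data.frame(chrom = tbx4$chrom, pos = tbx4$pos, ref = tbx4$ref,
                   alt = tbx4$alt, source = "gnomad_exomes_like",
                   af = 2.81e-5)

# mixed in-silico votes for missense rows (predominantly non-deleterious
# for the SMAD1 change, mixed elsewhere); truncating rows carry none
is_missense <- grepl("^p\\.\\([A-Z][a-z]{2}\\d+[A-Z][a-z]{2}\\)$", key$protein)
mis <- key[is_missense & !is.na(key$protein), ]
pred <- data.frame(chrom = mis$chrom, pos = mis$pos, ref = mis$ref,
                   alt = mis$alt,
                   n_deleterious = ifelse(mis$gene == "SMAD1", 2L, 3L),
                   n_total = ifelse(mis$gene == "SMAD1", 11L, 10L),
                   cadd_like = 15.0)

# prior pathogenic assertions for the previously reported variants
reported <- key[grepl("c\\.2674delG|c\\.1018C>T|c\\.1112dupC|c\\.3344C>T|c\\.3766C>T|c\\.4392dup|c\\.77-5_77-2del",
                      key$variant), ]
clin <- data.frame(chrom = reported$chrom, pos = reported$pos,
                   ref = reported$ref, alt = reported$alt,
                   assertion = "pathogenic_reported")

known <- data.frame(chrom = character(0), pos = integer(0),
                    ref = character(0), alt = character(0),
                    dbsnp_id = character(0))

wt <- function(df, f) write.table(df, file.path(snapdir, f), sep = "\t",
                                  quote = FALSE, row.names = FALSE)
wt(freq, "freq.tsv")
wt(pred, "predictors.tsv")
wt(clin, "clinical.tsv")
wt(known, "known_sites.tsv")
cat("wrote", nrow(key), "distinct case variants;",
    nrow(pred), "predictor rows;", nrow(clin), "assertions\n")
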