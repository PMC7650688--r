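#' Normalize a variant against a reference sequence
#'
#' Trims shared allele bases and left-aligns indels: while the two alleles
#' end in the same base the common base is dropped, extending to the left
#' with the preceding reference base whenever an allele would become empty;
#' finally shared leading bases (beyond the single anchor base an indel
#' needs) are trimmed. SNVs pass through unchanged. Two equivalent
#' representations of one indel in a homopolymer normalize to the same
#' (pos, ref, alt).
#'
#' @param pos 1-based position of the first `ref` base
#' @param ref,alt allele strings (non-empty, `ref != alt`)
#' @param seq reference sequence of the contig (single string)
#' @return list with `pos`, `ref`, `alt`
#' @export
normalize_variant <- function(pos, ref, alt, seq) {
  stopifnot(nzchar(ref), nzchar(alt))
  if (ref == alt) stop("ref and alt are identical")
  if (substr(seq, pos, pos + nchar(ref) - 1L) != ref) {
    stop("reference mismatch at position ", pos, ": expected '",
         substr(seq, pos, pos + nchar(ref) - 1L), "', got '", ref, "'")
  }
  repeat {
    changed <- FALSE
    # drop identical trailing base
    while (nchar(ref) > 0L && nchar(alt) > 0L &&
           substr(ref, nchar(ref), nchar(ref)) ==
           substr(alt, nchar(alt), nchar(alt))) {
      ref <- substr(ref, 1L, nchar(ref) - 1L)
      alt <- substr(alt, 1L, nchar(alt) - 1L)
      changed <- TRUE
      if (nchar(ref) == 0L || nchar(alt) == 0L) break
    }
    # an empty allele: prepend the preceding reference base
    if (nchar(ref) == 0L || nchar(alt) == 0L) {
      if (pos == 1L) {
        stop("cannot left-extend past the start of the contig")
      }
      b <- substr(seq, pos - 1L, pos - 1L)
      ref <- paste0(b, ref)
      alt <- paste0(b, alt)
      pos <- pos - 1L
      changed <- TRUE
      next
    }
    if (!changed) break
  }
  # trim identical leading bases, keeping one anchor base for indels
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = ref, alt = alt)
}

#' Project a parsed HGVS description onto the toy genome
#'
#' Maps a transcript-space description to a normalized VCF-style
#' (chrom, pos, ref, alt) on the packaged toy transcript model, validating
#' any stated reference bases against the model sequence.
#'
#' @param h a `hap_hgvs` object or a string passed to [parse_hgvs()]
#' @param model a [toy_transcript_model()]
#' @return list with `gene`, `chrom`, `pos`, `ref`, `alt`
#' @export
hgvs_to_vcf <- function(h, model = toy_transcript_model()) {
  if (is.character(h)) h <- parse_hgvs(h)
  stopifnot(inherits(h, "hap_hgvs"))
  gene <- unname(model$by_accession[accession_base(h$transcript)])
  if (is.na(gene) && !is.na(h$gene)) gene <- h$gene
  if (is.na(gene) || is.null(model$genes[[gene]])) {
    stop("transcript ", h$transcript, " not in the toy model")
  }
  g1 <- cdna_to_genomic(model, gene, h$start, h$start_offset)
  g2 <- if (!is.na(h$end)) {
    cdna_to_genomic(model, gene, h$end, h$end_offset)
  } else g1
  seq <- contig_seq(model, g1$contig)
  span <- substr(seq, g1$pos, g2$pos)

  if (h$kind == "substitution") {
    if (span != h$ref) {
      stop("reference mismatch for ", format_hgvs(h), ": model has '", span,
           "'")
    }
    v <- list(pos = g1$pos, ref = h$ref, alt = h$alt)
  } else if (h$kind == "deletion") {
    if (!is.na(h$seq) && span != h$seq) {
      stop("reference mismatch for ", format_hgvs(h), ": model has '", span,
           "'")
    }
    anchor <- substr(seq, g1$pos - 1L, g1$pos - 1L)
    v <- normalize_variant(g1$pos - 1L, paste0(anchor, span), anchor, seq)
  } else if (h$kind == "duplication") {
    if (!is.na(h$seq) && span != h$seq) {
      stop("reference mismatch for ", format_hgvs(h), ": model has '", span,
           "'")
    }
    last <- substr(seq, g2$pos, g2$pos)
    v <- normalize_variant(g2$pos, last, paste0(last, span), seq)
  } else if (h$kind == "insertion") {
    anchor <- substr(seq, g1$pos, g1$pos)
    v <- normalize_variant(g1$pos, anchor, paste0(anchor, h$seq), seq)
  } else { # delins
    anchor <- substr(seq, g1$pos - 1L, g1$pos - 1L)
    v <- normalize_variant(g1$pos - 1L, paste0(anchor, span),
                           paste0(anchor, h$alt), seq)
  }
  list(gene = gene, chrom = g1$contig, pos = v$pos, ref = v$ref, alt = v$alt)
}

#' Read panel variants from a VCF
#'
#' Parses a (multi-sample) VCF, emitting one record per sample and
#' alternate allele with a non-reference genotype. Multi-allelic sites are
#' decomposed, indels are left-aligned against the packaged reference
#' slice when the contig belongs to the toy model, and records outside the
#' panel targets are flagged `off_target` rather than dropped.
#'
#' @param path VCF path (4.2; FORMAT must carry GT, optionally GQ and DP)
#' @param panel a `hap_panel` used for target membership
#' @param model the reference model used for left-alignment
#' @return data.frame of variant records: `sample_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `gene`, `zygosity`, `quality`, `depth`, `off_target`
#' @export
read_vcf <- function(path, panel = hap_panel(),
                     model = toy_transcript_model()) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) {          # single-site VCFs drop to a vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  }
  if (nrow(v@gt) == 0L || !"FORMAT" %in% colnames(v@gt)) {
    stop("VCF has no genotype (FORMAT/GT) data: ", path)
  }
  fmt <- strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)
  samples <- setdiff(colnames(v@gt), "FORMAT")
  out <- list()
  k <- 0L
  for (i in seq_len(nrow(fix))) {
    keys <- fmt[[i]]
    if (!"GT" %in% keys) stop("missing GT in FORMAT at site ", i)
    chrom <- fix[i, "CHROM"]
    pos <- as.integer(fix[i, "POS"])
    ref <- fix[i, "REF"]
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    seq <- if (!is.na(gene_for_contig(model, chrom))) {
      contig_seq(model, chrom)
    } else NULL
    if (!is.null(seq) &&
        substr(seq, pos, pos + nchar(ref) - 1L) != ref) {
      stop("reference mismatch against packaged slice at ", chrom, ":", pos)
    }
    for (s in samples) {
      cell <- v@gt[i, s]
      if (is.na(cell) || cell %in% c(".", "./.", ".|.")) next
      parts <- strsplit(cell, ":", fixed = TRUE)[[1]]
      gtv <- parts[match("GT", keys)]
      if (is.na(gtv) || gtv %in% c(".", "./.", ".|.")) next
      alleles <- strsplit(gtv, "[/|]")[[1]]
      alleles <- suppressWarnings(as.integer(alleles))
      if (all(is.na(alleles))) next
      gq <- suppressWarnings(as.numeric(parts[match("GQ", keys)]))
      dp <- suppressWarnings(as.numeric(parts[match("DP", keys)]))
      for (ai in unique(alleles[!is.na(alleles) & alleles > 0L])) {
        if (ai > length(alts)) next
        zyg <- if (length(alleles) == 1L) "hemi" else
          if (sum(alleles == ai, na.rm = TRUE) == 2L) "hom" else "het"
        p2 <- pos; r2 <- ref; a2 <- alts[ai]
        if (!is.null(seq) && (nchar(r2) > 1L || nchar(a2) > 1L)) {
          n <- normalize_variant(pos, r2, a2, seq)
          p2 <- n$pos; r2 <- n$ref; a2 <- n$alt
        }
        k <- k + 1L
        out[[k]] <- data.frame(
          sample_id = s, chrom = chrom, pos = p2, ref = r2, alt = a2,
          zygosity = zyg,
          quality = if (length(gq)) gq else NA_real_,
          depth = if (length(dp)) dp else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  rec <- if (k) do.call(rbind, out) else
    data.frame(sample_id = character(0), chrom = character(0),
               pos = integer(0), ref = character(0), alt = character(0),
               zygosity = character(0), quality = numeric(0),
               depth = numeric(0))
  rec$gene <- if (nrow(rec)) gene_at(panel, rec$chrom, rec$pos) else
    character(0)
  rec$off_target <- is.na(rec$gene)
  rownames(rec) <- NULL
  rec
}

#' Write the per-patient variant report table
#'
#' Layout mirrors a clinical panel report: patient identifier, PAH
#' etiology, variant string, genotype and ACMG classification, sorted by
#' (patient, gene, cDNA position). [read_report_table()] round-trips it.
#'
#' @param records data.frame with columns `patient_id`, `etiology`,
#'   `variant`, `zygosity`, `acmg` (plus optional `gene`, `cdna_pos` used
#'   for ordering)
#' @param path output TSV path
#' @return invisibly, `path`
#' @export
write_report_table <- function(records, path) {
  cols <- c("patient_id", "etiology", "variant", "zygosity", "acmg")
  stopifnot(all(cols %in% names(records)))
  ord <- order(records$patient_id,
               if ("gene" %in% names(records)) records$gene else
                 rep("", nrow(records)),
               if ("cdna_pos" %in% names(records)) records$cdna_pos else
                 seq_len(nrow(records)))
  out <- records[ord, cols, drop = FALSE]
  names(out) <- c("Patient_ID", "PAH_Etiology", "Variant", "GT",
                  "ACMG_Classification")
  write_tsv(out, path)
}

#' @rdname write_report_table
#' @export
read_report_table <- function(path) {
  df <- read_tsv_strict(path, required = c("Patient_ID", "PAH_Etiology",
                                           "Variant", "GT",
                                           "ACMG_Classification"))
  names(df) <- c("patient_id", "etiology", "variant", "zygosity", "acmg")
  df
}
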