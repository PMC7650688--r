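#' Load offline annotation snapshots
#'
#' Annotation is snapshot-based: small packaged TSVs emulate population
#' frequency resources, in-silico predictor tallies and clinical-database
#' assertions, keyed by normalized (chrom, pos, ref, alt). No live queries
#' are ever made.
#'
#' Expected files in `dir`:
#' \describe{
#'   \item{freq.tsv}{`chrom, pos, ref, alt, source, af` (long format, one
#'     row per frequency source)}
#'   \item{predictors.tsv}{`chrom, pos, ref, alt, n_deleterious, n_total,
#'     cadd_like`}
#'   \item{clinical.tsv}{`chrom, pos, ref, alt, assertion` with assertion in
#'     pathogenic_reported / benign_reported / conflicting}
#'   \item{known_sites.tsv}{`chrom, pos, ref, alt, dbsnp_id`}
#' }
#'
#' @param dir directory containing the four snapshot TSVs
#' @return list of data.frames (class `hap_snapshots`)
#' @export
load_snapshots <- function(dir) {
  key_cols <- c("chrom", "pos", "ref", "alt")
  s <- list(
    freq = read_tsv_strict(file.path(dir, "freq.tsv"),
                           required = c(key_cols, "source", "af")),
    pred = read_tsv_strict(file.path(dir, "predictors.tsv"),
                           required = c(key_cols, "n_deleterious", "n_total",
                                        "cadd_like")),
    clin = read_tsv_strict(file.path(dir, "clinical.tsv"),
                           required = c(key_cols, "assertion")),
    known = read_tsv_strict(file.path(dir, "known_sites.tsv"),
                            required = c(key_cols, "dbsnp_id"))
  )
  structure(s, class = "hap_snapshots")
}

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Annotate variant records against snapshots
#'
#' Joins each record to the snapshot tables and computes its functional
#' consequence on the toy transcript model. A variant absent from all
#' frequency sources gets `popmax_af = NA` ("not observed"), which
#' downstream logic treats as rarer than any recorded frequency; when
#' present in several sources the maximum is taken.
#'
#' @param records variant record data.frame (from [read_vcf()] or the
#'   fixture loader)
#' @param snapshots a `hap_snapshots` object
#' @param model toy transcript model for consequence calling
#' @return `records` with annotation columns appended: `dbsnp_id`, `known`,
#'   `popmax_af`, `n_deleterious`, `n_total`, `cadd_like`,
#'   `clinical_assertion`, `consequence`
#' @export
annotate_variants <- function(records, snapshots,
                              model = toy_transcript_model()) {
  stopifnot(inherits(snapshots, "hap_snapshots"))
  key <- variant_key(records$chrom, records$pos, records$ref, records$alt)
  fr <- snapshots$freq
  fr_key <- variant_key(fr$chrom, fr$pos, fr$ref, fr$alt)
  records$popmax_af <- vapply(key, function(k) {
    afs <- fr$af[fr_key == k]
    if (length(afs)) max(afs) else NA_real_
  }, numeric(1), USE.NAMES = FALSE)

  pr <- snapshots$pred
  m <- match(key, variant_key(pr$chrom, pr$pos, pr$ref, pr$alt))
  records$n_deleterious <- ifelse(is.na(m), 0L, pr$n_deleterious[m])
  records$n_total <- ifelse(is.na(m), 0L, pr$n_total[m])
  records$cadd_like <- ifelse(is.na(m), NA_real_, pr$cadd_like[m])

  cl <- snapshots$clin
  m <- match(key, variant_key(cl$chrom, cl$pos, cl$ref, cl$alt))
  records$clinical_assertion <- ifelse(is.na(m), "none", cl$assertion[m])

  kn <- snapshots$known
  m <- match(key, variant_key(kn$chrom, kn$pos, kn$ref, kn$alt))
  records$dbsnp_id <- ifelse(is.na(m), NA_character_, kn$dbsnp_id[m])
  records$known <- !is.na(m)

  records$consequence <- vapply(seq_len(nrow(records)), function(i) {
    if (is.na(gene_for_contig(model, records$chrom[i]))) {
      return("other")
    }
    consequence_call(records$chrom[i], records$pos[i], records$ref[i],
                     records$alt[i], model)
  }, character(1))
  records
}

#' Share of in-silico predictors voting deleterious
#'
#' The in-silico summary counts the predictors calling a deleterious
#' effect over the total with a prediction available; with no predictors
#' the consensus is undefined (`NA`).
#'
#' @param n_deleterious,n_total predictor counts
#'   (`n_deleterious <= n_total`)
#' @return proportion, or `NA` when `n_total` is 0
#' @export
predictor_consensus <- function(n_deleterious, n_total) {
  stopifnot(all(n_total >= 0), all(n_deleterious <= n_total))
  ifelse(n_total == 0L, NA_real_, n_deleterious / n_total)
}

#' Functional consequence of a variant on the toy transcript model
#'
#' Rule order: a new stop codon is `stop_gained`; a CDS indel whose net
#' length is not a multiple of three is `frameshift` (otherwise
#' `inframe_indel`); intronic positions at offsets +-1/2 are
#' `splice_canonical` and +-3..8 `splice_region`, as are SNVs in the last
#' three exonic bases of a non-terminal exon; remaining CDS SNVs are
#' classified by codon comparison (`missense` / `synonymous`); anything
#' deeper intronic is `intronic`.
#'
#' @param chrom model contig
#' @param pos 1-based position of the (anchored) `ref` allele
#' @param ref,alt normalized alleles
#' @param model toy transcript model
#' @return one of `missense`, `stop_gained`, `frameshift`,
#'   `splice_canonical`, `splice_region`, `inframe_indel`, `synonymous`,
#'   `intronic`, `other`
#' @export
consequence_call <- function(chrom, pos, ref, alt,
                             model = toy_transcript_model()) {
  sym <- gene_for_contig(model, chrom)
  if (is.na(sym)) stop("record outside the transcript model: ", chrom)
  gm <- model$genes[[sym]]
  net <- nchar(alt) - nchar(ref)

  if (nchar(ref) == 1L && nchar(alt) == 1L) {
    loc <- genomic_to_cdna(model, chrom, pos)
    if (is.na(loc$cpos)) return("other")
    if (loc$offset != 0L) {
      a <- abs(loc$offset)
      if (a <= 2L) return("splice_canonical")
      if (a <= 8L) return("splice_region")
      return("intronic")
    }
    idx <- (loc$cpos - 1L) %/% 3L + 1L
    off <- (loc$cpos - 1L) %% 3L + 1L
    codon <- codon_at(model, sym, idx)
    if (substr(codon, off, off) != ref) {
      stop("reference mismatch at ", chrom, ":", pos)
    }
    newc <- codon
    substr(newc, off, off) <- alt
    aa_old <- translate_codon(codon)
    aa_new <- translate_codon(newc)
    if (aa_new == "*" && aa_old != "*") return("stop_gained")
    ex <- loc$exon
    if (!is.na(ex) && ex < nrow(gm$exons) &&
        loc$cpos > gm$exons$c_end[ex] - 3L) {
      return("splice_region")
    }
    if (aa_old == aa_new) return("synonymous")
    if (aa_old == "*") return("other")
    return("missense")
  }

  # indel: bases affected are those after the anchor
  del_range <- if (nchar(ref) > 1L) (pos + 1L):(pos + nchar(ref) - 1L) else
    c(pos, pos + 1L)
  locs <- lapply(del_range, function(g) genomic_to_cdna(model, chrom, g))
  offs <- vapply(locs, function(l) {
    if (is.na(l$cpos)) NA_integer_ else l$offset
  }, integer(1))
  if (all(is.na(offs))) return("other")
  if (all(offs != 0L, na.rm = TRUE)) {
    a <- min(abs(offs), na.rm = TRUE)
    if (a <= 2L) return("splice_canonical")
    if (a <= 8L) return("splice_region")
    return("intronic")
  }
  if (nchar(ref) == 1L && net > 0L) {
    # pure insertion between pos and pos+1; CDS only if both flanks exonic
    if (any(offs == 0L, na.rm = TRUE) && !any(offs != 0L, na.rm = TRUE)) {
      return(if (net %% 3L != 0L) "frameshift" else "inframe_indel")
    }
    a <- min(abs(offs[offs != 0L]), na.rm = TRUE)
    if (a <= 2L) return("splice_canonical")
    if (a <= 8L) return("splice_region")
    return("intronic")
  }
  if (net %% 3L != 0L) "frameshift" else "inframe_indel"
}
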