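#' Toy transcript model backing the packaged panel
#'
#' The commercial capture design behind HAP v1.2 is not public, and the
#' pipeline logic is coordinate-agnostic, so the package carries a small
#' synthetic transcript model: one contig per gene, plus-strand coding
#' sequence split into exons with 300 bp introns and canonical GT/AG splice
#' dinucleotides. The coding sequence of each gene is drawn from sense codons
#' under a fixed internal seed and then patched so that every variant of the
#' bundled case set has the reference allele and codon context its printed
#' protein effect implies (e.g. TBX4 codon 340 is CGA so that c.1018C>T is a
#' nonsense change).
#'
#' @return A model object: a named list of per-gene descriptors (`symbol`,
#'   `transcript`, `contig`, `cds`, `seq`, `exons` with cDNA and genomic
#'   bounds) plus an accession-to-gene lookup.
#' @export
toy_transcript_model <- function() {
  if (!is.null(.hap_env$model)) return(.hap_env$model)
  tab <- hap_gene_table()
  genes <- vector("list", nrow(tab))
  names(genes) <- tab$symbol
  for (i in seq_len(nrow(tab))) {
    genes[[i]] <- build_gene_model(tab$symbol[i], tab$transcript[i],
                                   .hap_exon_ends[[tab$symbol[i]]], i)
  }
  acc <- stats::setNames(tab$symbol, accession_base(tab$transcript))
  model <- structure(list(genes = genes, by_accession = acc),
                     class = "hap_model")
  .hap_env$model <- model
  model
}

#' Gene-level metadata of the HAP v1.2 panel
#'
#' The 21 panel genes with one canonical transcript each, an evidence tier
#' (`established` for the genes with a higher level of published evidence in
#' PAH, `candidate` otherwise) and an inheritance hint.
#'
#' @return data.frame with columns `symbol`, `transcript`, `evidence_tier`,
#'   `inheritance_hint`.
#' @export
hap_gene_table <- function() {
  est <- c("ACVRL1", "BMPR2", "CAV1", "EIF2AK4", "ENG", "GDF2", "KCNK3",
           "SMAD9", "TBX4")
  ar <- c(EIF2AK4 = "AR", MMACHC = "AR", SARS2 = "AR", CPS1 = "either")
  df <- data.frame(
    symbol = c("ABCC8", "ACVRL1", "BMPR1B", "BMPR2", "CAV1", "CBLN2", "CPS1",
               "EIF2AK4", "ENG", "GDF2", "KCNA5", "KCNK3", "MMACHC", "NOTCH3",
               "SARS2", "SMAD1", "SMAD4", "SMAD5", "SMAD9", "TBX4", "TOPBP1"),
    transcript = c("NM_000352.4", "NM_000020.3", "NM_001203.2", "NM_001204.6",
                   "NM_001753.5", "NM_182511.3", "NM_001875.4",
                   "NM_001013703.3", "NM_001114753.2", "NM_016204.3",
                   "NM_002234.3", "NM_002246.2", "NM_015506.2", "NM_000435.2",
                   "NM_017827.3", "NM_005900.2", "NM_005359.5",
                   "NM_001001420.2", "NM_005905.5", "NM_018488.3",
                   "NM_007027.3"),
    stringsAsFactors = FALSE
  )
  df$evidence_tier <- ifelse(df$symbol %in% est, "established", "candidate")
  df$inheritance_hint <- ifelse(df$symbol %in% names(ar),
                                unname(ar[df$symbol]), "AD")
  df$inheritance_hint[is.na(df$inheritance_hint)] <- "AD"
  df
}

# cumulative cDNA exon end positions per gene; the last entry is the CDS length
.hap_exon_ends <- list(
  ABCC8   = c(579L, 1200L, 1800L, 2694L, 3300L, 3900L, 4400L, 4749L),
  ACVRL1  = c(500L, 1512L),
  BMPR1B  = c(700L, 1509L),
  BMPR2   = c(76L, 600L, 1200L, 1900L, 2500L, 3114L),
  CAV1    = c(537L),
  CBLN2   = c(300L, 579L),
  CPS1    = c(1500L, 3000L, 4503L),
  EIF2AK4 = c(1200L, 2400L, 3600L, 4899L),
  ENG     = c(900L, 1977L),
  GDF2    = c(400L, 1290L),
  KCNA5   = c(1842L),
  KCNK3   = c(1185L),
  MMACHC  = c(849L),
  NOTCH3  = c(1000L, 2000L, 3000L, 4000L, 5000L, 6000L, 6966L),
  SARS2   = c(800L, 1557L),
  SMAD1   = c(700L, 1398L),
  SMAD4   = c(800L, 1659L),
  SMAD5   = c(700L, 1398L),
  SMAD9   = c(700L, 1404L),
  TBX4    = c(500L, 1100L, 1641L),
  TOPBP1  = c(1500L, 3000L, 4596L)
)

# codon patches anchoring the bundled case set's protein effects
.hap_codon_patches <- list(
  ABCC8   = list(`477` = "GTG", `548` = "ACG", `808` = "CAA", `1080` = "GTC",
                 `1097` = "CAC", `1132` = "GAC", `1326` = "GAA"),
  BMPR2   = list(`892` = "GAA"),
  CBLN2   = list(`88` = "TCT"),
  CPS1    = list(`346` = "GCA", `1016` = "ACG", `1418` = "CCT"),
  EIF2AK4 = list(`1115` = "CCT", `1256` = "CGA", `1464` = "AAA"),
  GDF2    = list(`214` = "TGG"),
  NOTCH3  = list(`61` = "CGG", `655` = "AAC", `1735` = "GAG", `2033` = "CCT",
                 `2178` = "CCA"),
  SARS2   = list(`46` = "GAG"),
  SMAD1   = list(`246` = "ATG"),
  SMAD5   = list(`255` = "ATC"),
  TBX4    = list(`340` = "CGA", `371` = "CCA")
)

# intron-edge patches: list(gene, intron index, side, replacement)
.hap_intron_patches <- list(
  list(gene = "ABCC8", intron = 1L, side = "start", value = "GTAAG"),
  list(gene = "BMPR2", intron = 1L, side = "end",   value = "TTTAG")
)

.hap_sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

build_gene_model <- function(symbol, transcript, exon_ends, idx) {
  cds_len <- exon_ends[length(exon_ends)]
  stopifnot(cds_len %% 3L == 0L)
  n_ex <- length(exon_ends)
  c_start <- c(1L, utils::head(exon_ends, -1L) + 1L)
  w <- exon_ends - c_start + 1L
  pad <- 100L
  intron_len <- 300L
  g_start <- integer(n_ex)
  g <- pad + 1L
  for (i in seq_len(n_ex)) {
    g_start[i] <- g
    g <- g + w[i] + intron_len
  }
  g_end <- g_start + w - 1L

  sense <- .hap_sense_codons()
  seqparts <- with_seed(202400L + idx, {
    codons <- sample(sense, cds_len / 3L, replace = TRUE)
    codons[length(codons)] <- "TAA"
    introns <- replicate(max(n_ex - 1L, 0L), paste(
      sample(c("A", "C", "G", "T"), intron_len, replace = TRUE),
      collapse = ""))
    pads <- replicate(2L, paste(
      sample(c("A", "C", "G", "T"), pad, replace = TRUE), collapse = ""))
    list(codons = codons, introns = as.character(introns), pads = pads)
  })

  codons <- seqparts$codons
  patches <- .hap_codon_patches[[symbol]]
  if (!is.null(patches)) {
    for (nm in names(patches)) codons[as.integer(nm)] <- patches[[nm]]
  }
  cds <- paste(codons, collapse = "")

  introns <- seqparts$introns
  if (n_ex > 1L) {
    for (j in seq_len(n_ex - 1L)) {
      substr(introns[j], 1L, 2L) <- "GT"
      substr(introns[j], intron_len - 1L, intron_len) <- "AG"
    }
  }
  for (p in .hap_intron_patches) {
    if (p$gene == symbol && p$intron <= length(introns)) {
      v <- p$value
      if (p$side == "start") {
        substr(introns[p$intron], 1L, nchar(v)) <- v
      } else {
        substr(introns[p$intron], intron_len - nchar(v) + 1L, intron_len) <- v
      }
    }
  }

  exon_seq <- substring(cds, c_start, exon_ends)
  body <- character(0)
  for (i in seq_len(n_ex)) {
    body <- c(body, exon_seq[i])
    if (i < n_ex) body <- c(body, introns[i])
  }
  seq <- paste0(seqparts$pads[1], paste(body, collapse = ""), seqparts$pads[2])

  list(symbol = symbol, transcript = transcript,
       contig = paste0("ctg_", symbol), cds = cds, seq = seq,
       cds_len = cds_len,
       exons = data.frame(c_start = c_start, c_end = exon_ends,
                          g_start = g_start, g_end = g_end))
}

model_gene <- function(model, symbol) {
  gm <- model$genes[[symbol]]
  if (is.null(gm)) stop("gene not in transcript model: ", symbol)
  gm
}

gene_for_contig <- function(model, contig) {
  sym <- sub("^ctg_", "", contig)
  if (is.null(model$genes[[sym]])) return(NA_character_)
  sym
}

#' Reference sequence of one model contig
#' @param model a [toy_transcript_model()] object
#' @param contig contig name (`"ctg_<SYMBOL>"`)
#' @return single character string
#' @export
contig_seq <- function(model, contig) {
  sym <- gene_for_contig(model, contig)
  if (is.na(sym)) stop("unknown contig: ", contig)
  model$genes[[sym]]$seq
}

#' Map a cDNA coordinate onto the toy genome
#'
#' Converts a coding position (1-based, optionally with an intronic offset,
#' e.g. c.579+5) to a 1-based genomic position on the gene's contig.
#'
#' @param model a [toy_transcript_model()] object
#' @param gene gene symbol
#' @param pos coding (cDNA) position
#' @param offset intronic offset (0 for exonic positions)
#' @return list with `contig` and `pos`
#' @export
cdna_to_genomic <- function(model, gene, pos, offset = 0L) {
  gm <- model_gene(model, gene)
  ex <- gm$exons
  if (pos < 1L || pos > gm$cds_len) {
    stop("cDNA position ", pos, " outside CDS of ", gene)
  }
  i <- which(pos >= ex$c_start & pos <= ex$c_end)
  g <- ex$g_start[i] + (pos - ex$c_start[i])
  if (offset != 0L) {
    if (offset > 0L && pos != ex$c_end[i]) {
      stop("positive intronic offset requires the last base of an exon (c.",
           pos, " in ", gene, ")")
    }
    if (offset < 0L && pos != ex$c_start[i]) {
      stop("negative intronic offset requires the first base of an exon (c.",
           pos, " in ", gene, ")")
    }
    g <- g + offset
  }
  list(contig = gm$contig, pos = as.integer(g))
}

#' Locate a genomic position within the toy transcript model
#'
#' Inverse of [cdna_to_genomic()]: classifies a contig position as exonic
#' (offset 0) or intronic (nearest exon boundary plus signed offset).
#' Positions in the padding outside the transcript return `NA` fields.
#'
#' @inheritParams contig_seq
#' @param pos 1-based genomic position on `contig`
#' @return list with `gene`, `cpos`, `offset`, `exon` (index or NA)
#' @export
genomic_to_cdna <- function(model, contig, pos) {
  sym <- gene_for_contig(model, contig)
  if (is.na(sym)) stop("unknown contig: ", contig)
  ex <- model$genes[[sym]]$exons
  i <- which(pos >= ex$g_start & pos <= ex$g_end)
  if (length(i) == 1L) {
    return(list(gene = sym, cpos = ex$c_start[i] + (pos - ex$g_start[i]),
                offset = 0L, exon = i))
  }
  n <- nrow(ex)
  for (j in seq_len(n - 1L)) {
    if (pos > ex$g_end[j] && pos < ex$g_start[j + 1L]) {
      d_prev <- pos - ex$g_end[j]
      d_next <- ex$g_start[j + 1L] - pos
      if (d_prev <= d_next) {
        return(list(gene = sym, cpos = ex$c_end[j], offset = d_prev, exon = NA))
      }
      return(list(gene = sym, cpos = ex$c_start[j + 1L], offset = -d_next,
                  exon = NA))
    }
  }
  list(gene = sym, cpos = NA_integer_, offset = NA_integer_, exon = NA)
}

codon_at <- function(model, gene, codon_index) {
  gm <- model_gene(model, gene)
  substr(gm$cds, 3L * codon_index - 2L, 3L * codon_index)
}

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[toupper(codon)])
}
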