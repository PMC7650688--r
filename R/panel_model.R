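#' Panel definition objects
#'
#' A panel bundles gene-level metadata (symbol, canonical transcript,
#' evidence tier, inheritance hint) with its capture target regions
#' (BED-style 0-based half-open intervals). Every region must name a gene
#' present in the gene list; regions are stored sorted by (chrom, start).
#'
#' @param name panel name
#' @param genes data.frame with columns `symbol`, `transcript`,
#'   `evidence_tier`, `inheritance_hint`
#' @param regions data.frame with columns `chrom`, `start`, `end`, `gene`,
#'   `label`
#' @return object of class `hap_panel`
#' @export
panel_definition <- function(name, genes, regions) {
  need_g <- c("symbol", "transcript", "evidence_tier", "inheritance_hint")
  need_r <- c("chrom", "start", "end", "gene", "label")
  stopifnot(all(need_g %in% names(genes)), all(need_r %in% names(regions)))
  if (anyDuplicated(genes$symbol)) {
    stop("duplicate gene symbol in panel: ",
         genes$symbol[duplicated(genes$symbol)][1])
  }
  bad_tx <- genes$symbol[!grepl("^NM_\\d+(\\.\\d+)?$", genes$transcript)]
  if (length(bad_tx)) {
    stop("transcript accession not NM_* for gene(s): ",
         paste(bad_tx, collapse = ", "))
  }
  if (nrow(regions)) {
    if (any(regions$start >= regions$end)) {
      stop("region with start >= end: ",
           regions$label[regions$start >= regions$end][1])
    }
    orphan <- setdiff(unique(regions$gene), genes$symbol)
    if (length(orphan)) {
      stop("consistency error: region names gene(s) absent from gene list: ",
           paste(orphan, collapse = ", "))
    }
    regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
    rownames(regions) <- NULL
    for (g in unique(regions$gene)) {
      r <- regions[regions$gene == g, , drop = FALSE]
      r <- r[order(r$chrom, r$start), , drop = FALSE]
      ov <- r$start[-1] < r$end[-nrow(r)] & r$chrom[-1] == r$chrom[-nrow(r)]
      if (nrow(r) > 1 && any(ov)) {
        stop("self-overlapping targets within gene ", g)
      }
    }
  }
  p <- structure(list(name = name, genes = genes, regions = regions),
                 class = "hap_panel")
  if (nrow(genes) == 0L) warning("panel '", name, "' has no genes")
  p
}

#' @export
print.hap_panel <- function(x, ...) {
  cat("HAP panel definition: ", x$name, "\n", sep = "")
  cat("  genes:   ", nrow(x$genes),
      " (", sum(x$genes$evidence_tier == "established"), " established)\n",
      sep = "")
  cat("  targets: ", nrow(x$regions), "\n", sep = "")
  invisible(x)
}

#' The bundled HAP v1.2 panel
#'
#' Builds the default 21-gene panel directly from the packaged toy transcript
#' model: one target per coding exon, padded by 25 bp of flanking intron on
#' each side, labelled `SYMBOL_exNN`.
#'
#' @param flank intronic padding added to each exon target (bp)
#' @return a `hap_panel` object with exactly 21 genes
#' @export
hap_panel <- function(flank = 25L) {
  model <- toy_transcript_model()
  genes <- hap_gene_table()
  regions <- do.call(rbind, lapply(model$genes, function(gm) {
    ex <- gm$exons
    data.frame(chrom = gm$contig,
               start = pmax(ex$g_start - 1L - flank, 0L),
               end = ex$g_end + flank,
               gene = gm$symbol,
               label = sprintf("%s_ex%02d", gm$symbol, seq_len(nrow(ex))),
               stringsAsFactors = FALSE)
  }))
  rownames(regions) <- NULL
  panel_definition("HAP v1.2", genes, regions)
}

#' Load a panel from a gene TSV and a target BED
#'
#' The gene file is a header-ed TSV with columns `symbol`, `transcript`,
#' `evidence_tier`, `inheritance_hint`. The BED file is tab-separated,
#' 0-based half-open, with at least four columns
#' (chrom, start, end, gene label) and an optional fifth target label.
#'
#' @param genes_file path to gene metadata TSV
#' @param bed_file path to target BED
#' @param name panel name stored in the object
#' @return a `hap_panel`
#' @export
load_panel <- function(genes_file, bed_file, name = "HAP v1.2") {
  genes <- read_tsv_strict(genes_file,
                           required = c("symbol", "transcript",
                                        "evidence_tier", "inheritance_hint"))
  lines <- readLines(bed_file)
  lines <- lines[nzchar(lines)]
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 4L) {
      stop("malformed BED line ", i, ": expected >= 4 tab-separated fields")
    }
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end)) {
      stop("malformed BED line ", i, ": non-integer coordinates")
    }
    rows[[i]] <- data.frame(chrom = f[1], start = start, end = end,
                            gene = f[4],
                            label = if (length(f) >= 5L) f[5] else
                              paste0(f[4], "_", i),
                            stringsAsFactors = FALSE)
  }
  regions <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               gene = character(0), label = character(0))
  panel_definition(name, genes, regions)
}

#' Write a panel back to its gene TSV / BED file pair
#'
#' Inverse of [load_panel()]; `load_panel(write_panel(p))` round-trips.
#'
#' @param panel a `hap_panel`
#' @inheritParams load_panel
#' @return invisibly, the two paths
#' @export
write_panel <- function(panel, genes_file, bed_file) {
  stopifnot(inherits(panel, "hap_panel"))
  write_tsv(panel$genes, genes_file)
  bed <- panel$regions[, c("chrom", "start", "end", "gene", "label")]
  utils::write.table(bed, bed_file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(genes_file, bed_file))
}

#' Which panel gene covers a position?
#'
#' Queries are 1-based (VCF convention); targets are stored 0-based
#' half-open (BED convention), so a 1-based position `p` falls in a target
#' iff `start < p <= end`.
#'
#' @param panel a `hap_panel`
#' @param chrom chromosome/contig name
#' @param pos 1-based position (vectorised)
#' @return gene symbol per position, `NA` when off-target
#' @export
gene_at <- function(panel, chrom, pos) {
  stopifnot(inherits(panel, "hap_panel"))
  r <- panel$regions
  vapply(seq_along(pos), function(i) {
    hit <- which(r$chrom == chrom[min(i, length(chrom))] &
                   r$start < pos[i] & pos[i] <= r$end)
    if (length(hit)) r$gene[hit[1]] else NA_character_
  }, character(1))
}
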