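#' Parse a transcript-level HGVS-style variant string
#'
#' Handles the dialect used in clinical panel reports: an optional leading
#' gene symbol, a versioned (or unversioned) RefSeq transcript accession,
#' an optional `(GENE)` alias or `exonNN` segment, a cDNA descriptor and an
#' optional protein descriptor, all joined by colons, e.g.
#' `"BMPR2:NM_001204.6:c.77-5_77-2delTTTA"` or
#' `"NM_018488.3:c.1018C>T:p.(Arg340*)"`.
#'
#' Supported cDNA forms: substitutions (`c.1018C>T`), deletions and
#' duplications with or without the stated sequence (`c.3288_3289del`,
#' `c.1112dupC`), insertions (`c.10_11insA`) and deletion-insertions
#' (`c.10delinsGG`). Positions may carry intronic offsets (`c.579+5`,
#' `c.77-5`) and ranges (`N_M`). Parsing is idempotent under
#' [format_hgvs()].
#'
#' @param text variant string
#' @return object of class `hap_hgvs`: fields `gene`, `transcript`,
#'   `kind` (substitution/deletion/duplication/insertion/delins), `start`,
#'   `start_offset`, `end`, `end_offset`, `ref`, `alt`, `seq`, `protein`
#' @export
parse_hgvs <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  raw <- gsub("\\s+", "", text)  # tolerate stray spacing, e.g. "p.(Arg340 *)"
  toks <- strsplit(raw, ":", fixed = TRUE)[[1]]
  gene <- NA_character_
  transcript <- NA_character_
  cdna <- NA_character_
  protein <- NA_character_
  for (tk in toks) {
    if (grepl("^NM_\\d+(\\.\\d+)?(\\([A-Za-z0-9_]+\\))?$", tk)) {
      transcript <- sub("\\(.*\\)$", "", tk)
    } else if (grepl("^c\\.", tk)) {
      cdna <- sub("^c\\.", "", tk)
    } else if (grepl("^p\\.", tk)) {
      protein <- tk
    } else if (grepl("^exon\\d+$", tk, ignore.case = TRUE)) {
      next
    } else if (grepl("^[A-Z][A-Z0-9-]*$", tk) && is.na(gene)) {
      gene <- tk
    } else {
      stop("cannot parse HGVS token '", tk, "' in: ", text)
    }
  }
  if (is.na(transcript)) stop("missing NM_ transcript prefix in: ", text)
  if (is.na(cdna)) stop("missing c. descriptor in: ", text)

  pos_re <- "(\\d+)([+-]\\d+)?"
  rng_re <- paste0("^", pos_re, "(?:_", pos_re, ")?")
  m <- regmatches(cdna, regexec(paste0(rng_re, "(.*)$"), cdna))[[1]]
  if (length(m) == 0L || !nzchar(m[2])) {
    stop("cannot parse cDNA descriptor 'c.", cdna, "'")
  }
  start <- as.integer(m[2])
  start_offset <- if (nzchar(m[3])) as.integer(m[3]) else 0L
  end <- if (nzchar(m[4])) as.integer(m[4]) else NA_integer_
  end_offset <- if (nzchar(m[5])) as.integer(m[5]) else 0L
  tail <- m[6]

  kind <- ref <- alt <- seq <- NA_character_
  if (grepl("^([ACGT])>([ACGT])$", tail)) {
    kind <- "substitution"
    ref <- sub(">.*", "", tail)
    alt <- sub(".*>", "", tail)
    if (!is.na(end)) stop("substitution cannot span a range: c.", cdna)
  } else if (grepl("^delins([ACGT]+)$", tail)) {
    kind <- "delins"
    seq <- sub("^delins", "", tail)
    alt <- seq
  } else if (grepl("^del([ACGT]*)$", tail)) {
    kind <- "deletion"
    seq <- sub("^del", "", tail)
    if (!nzchar(seq)) seq <- NA_character_
    ref <- seq
  } else if (grepl("^dup([ACGT]*)$", tail)) {
    kind <- "duplication"
    seq <- sub("^dup", "", tail)
    if (!nzchar(seq)) seq <- NA_character_
    alt <- seq
  } else if (grepl("^ins([ACGT]+)$", tail)) {
    kind <- "insertion"
    if (is.na(end)) stop("insertion requires a position range: c.", cdna)
    seq <- sub("^ins", "", tail)
    alt <- seq
  } else {
    stop("cannot parse cDNA descriptor 'c.", cdna, "' (offending token: '",
         tail, "')")
  }
  if (!is.na(seq) && !is.na(end) && kind %in% c("deletion", "duplication")) {
    span <- if (start == end && start_offset != 0L && end_offset != 0L) {
      end_offset - start_offset + 1L   # fully intronic range, same anchor base
    } else if (start_offset == 0L && end_offset == 0L) {
      end - start + 1L                 # fully exonic range
    } else {
      NA_integer_                      # mixed anchors: length not checkable
    }
    if (!is.na(span) && nchar(seq) != span) {
      stop("stated sequence length disagrees with range in c.", cdna)
    }
  }
  if (!is.na(protein)) {
    protein <- sub("^p\\.\\(?", "", sub("\\)$", "", protein))
    protein <- paste0("p.(", protein, ")")
  }
  structure(list(gene = gene, transcript = transcript, kind = kind,
                 start = start, start_offset = start_offset,
                 end = end, end_offset = end_offset,
                 ref = ref, alt = alt, seq = seq, protein = protein),
            class = "hap_hgvs")
}

#' Canonical string form of a parsed HGVS description
#'
#' `parse_hgvs(format_hgvs(h))` reproduces `h`; formatting a freshly parsed
#' string yields the canonical layout
#' `GENE:TRANSCRIPT:c.DESC[:p.(EFFECT)]`.
#'
#' @param h a `hap_hgvs` object
#' @return character string
#' @export
format_hgvs <- function(h) {
  stopifnot(inherits(h, "hap_hgvs"))
  fmt_pos <- function(p, o) {
    paste0(p, if (o > 0L) paste0("+", o) else if (o < 0L) as.character(o)
           else "")
  }
  loc <- fmt_pos(h$start, h$start_offset)
  if (!is.na(h$end)) loc <- paste0(loc, "_", fmt_pos(h$end, h$end_offset))
  desc <- switch(h$kind,
    substitution = paste0(loc, h$ref, ">", h$alt),
    deletion = paste0(loc, "del", if (!is.na(h$seq)) h$seq else ""),
    duplication = paste0(loc, "dup", if (!is.na(h$seq)) h$seq else ""),
    insertion = paste0(loc, "ins", h$seq),
    delins = paste0(loc, "delins", h$seq),
    stop("unknown HGVS kind: ", h$kind)
  )
  out <- paste0(h$transcript, ":c.", desc)
  if (!is.na(h$gene)) out <- paste0(h$gene, ":", out)
  if (!is.na(h$protein)) out <- paste0(out, ":", h$protein)
  out
}

#' @export
print.hap_hgvs <- function(x, ...) {
  cat(format_hgvs(x), "\n")
  invisible(x)
}
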