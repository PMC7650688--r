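#' Read a PED pedigree file
#'
#' Standard 6-column whitespace-separated PED: family, individual, father,
#' mother, sex (1 male / 2 female / 0 unknown), affected (2 affected /
#' 1 unaffected / 0 unknown). `0` parent ids denote founders.
#'
#' @param path PED file
#' @param genotypes optional TSV path or data.frame with columns
#'   `individual_id`, `variant`, `zygosity` (het/hom) giving per-relative
#'   carrier status for specific variants
#' @return object of class `hap_pedigree`: `members` data.frame plus
#'   `genotypes`
#' @export
read_ped <- function(path, genotypes = NULL) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 6L) stop("PED file needs 6 columns: ", path)
  names(df)[1:6] <- c("family_id", "individual_id", "father_id", "mother_id",
                      "sex", "affected")
  df$father_id[df$father_id == "0"] <- NA_character_
  df$mother_id[df$mother_id == "0"] <- NA_character_
  for (p in c("father_id", "mother_id")) {
    unresolved <- !is.na(df[[p]]) & !(df[[p]] %in% df$individual_id)
    if (any(unresolved)) {
      stop("parent id not in pedigree: ",
           paste(df[[p]][unresolved], collapse = ", "))
    }
  }
  if (is.character(genotypes)) {
    genotypes <- read_tsv_strict(genotypes,
                                 required = c("individual_id", "variant",
                                              "zygosity"))
  }
  pedigree(df, genotypes)
}

#' @rdname read_ped
#' @param members pedigree members data.frame (see [read_ped()])
#' @export
pedigree <- function(members, genotypes = NULL) {
  # reject cyclic ancestry
  anc <- function(id, seen = character(0)) {
    if (id %in% seen) stop("individual is its own ancestor: ", id)
    row <- members[members$individual_id == id, , drop = FALSE]
    if (!nrow(row)) return(invisible(NULL))
    for (p in c(row$father_id, row$mother_id)) {
      if (!is.na(p)) anc(p, c(seen, id))
    }
  }
  for (id in members$individual_id) anc(id)
  structure(list(members = members, genotypes = genotypes),
            class = "hap_pedigree")
}

# allele dosage (0/1/2) of `individual` for `variant`; NA when untyped
ped_dosage <- function(ped, individual, variant) {
  g <- ped$genotypes
  if (is.null(g)) return(NA_integer_)
  hit <- g[g$individual_id == individual & g$variant == variant, ,
           drop = FALSE]
  if (!nrow(hit)) return(0L)  # typed pedigree: absence of a row = non-carrier
  switch(hit$zygosity[1], hom = 2L, het = 1L, hemi = 1L, 0L)
}

ped_typed <- function(ped, individual) {
  !is.null(ped$genotypes) &&
    individual %in% ped$genotypes$individual_id ||
    (!is.null(attr(ped$genotypes, "typed")) &&
       individual %in% attr(ped$genotypes, "typed"))
}

#' Detect digenic co-occurrence of candidate variants
#'
#' One finding per patient carrying candidate variants (ACMG class
#' Pathogenic / Likely pathogenic / VUS) in two or more distinct genes.
#' CNV calls count as gene-level candidates (the mechanism behind a
#' single-exon duplication pairing with a small variant in another gene).
#' Two variants in one gene are not digenic; they are routed to the
#' biallelic logic.
#'
#' @param candidates classified record data.frame with `patient_id` (or
#'   `sample_id`), `gene`, `acmg`
#' @param cnvs optional CNV call data.frame with `sample_id`/`patient_id`
#'   and `gene`
#' @return data.frame of findings: `patient_id`, `kind`, `genes`,
#'   `n_variants`, `classes`
#' @export
detect_cooccurrence <- function(candidates, cnvs = NULL) {
  pid <- function(df) {
    if ("patient_id" %in% names(df)) df$patient_id else df$sample_id
  }
  keep <- is.na(candidates$acmg) |
    candidates$acmg %in% c("Pathogenic", "Likely_pathogenic", "VUS",
                           "P", "LP")
  small <- data.frame(patient_id = pid(candidates)[keep],
                      gene = candidates$gene[keep],
                      class = candidates$acmg[keep],
                      stringsAsFactors = FALSE)
  if (!is.null(cnvs) && nrow(cnvs)) {
    small <- rbind(small, data.frame(patient_id = pid(cnvs),
                                     gene = cnvs$gene,
                                     class = "Not_applicable",
                                     stringsAsFactors = FALSE))
  }
  out <- list()
  for (p in unique(small$patient_id)) {
    sub <- small[small$patient_id == p, , drop = FALSE]
    genes <- sort(unique(sub$gene))
    if (length(genes) >= 2L) {
      sub <- sub[order(sub$gene), , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        patient_id = p, kind = "digenic_candidate",
        genes = paste(genes, collapse = ";"),
        n_variants = nrow(sub),
        classes = paste(sub$class, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(patient_id = character(0), kind = character(0),
               genes = character(0), n_variants = integer(0),
               classes = character(0))
}

# feasible transmission phases for two heterozygous child variants given
# parental dosages; returns subset of c("trans", "cis"), empty = conflict
feasible_phases <- function(f1, f2, m1, m2) {
  can_give <- function(d, a) {
    if (is.na(d)) TRUE else if (a == 1L) d > 0L else d < 2L
  }
  phases <- character(0)
  for (a1 in 0:1) for (a2 in 0:1) {
    # father transmits a1 at site 1 and a2 at site 2; mother the complement
    ok <- can_give(f1, a1) && can_give(f2, a2) &&
      can_give(m1, 1L - a1) && can_give(m2, 1L - a2)
    if (!ok) next
    phases <- c(phases, if (a1 == a2) "cis" else "trans")
  }
  unique(phases)
}

#' Detect biallelic candidates in one gene
#'
#' A homozygous candidate yields a `biallelic_hom` finding. Two
#' heterozygous candidates in the gene are compound heterozygous only if
#' the parental genotypes place one variant on each parental haplotype
#' (in trans); both inherited from one parent is a cis pair, reported as
#' `single_het`; without parental genotypes the pair is reported
#' `compound_het` with segregation `untested`. A child carrying an allele
#' absent from both typed parents flags `inconsistent` rather than
#' raising an error.
#'
#' @param candidates classified record data.frame (`patient_id`/`sample_id`,
#'   `gene`, `zygosity`, `variant` or a key, `acmg`)
#' @param gene gene symbol to scan (biallelic PVOD logic defaults to
#'   EIF2AK4)
#' @param ped optional `hap_pedigree` with relative genotypes
#' @return data.frame of findings: `patient_id`, `kind`, `variants`,
#'   `segregation`
#' @export
detect_biallelic <- function(candidates, gene = "EIF2AK4", ped = NULL) {
  pid <- if ("patient_id" %in% names(candidates)) candidates$patient_id else
    candidates$sample_id
  vkey <- if ("variant" %in% names(candidates)) candidates$variant else
    variant_key(candidates$chrom, candidates$pos, candidates$ref,
                candidates$alt)
  sub <- data.frame(patient_id = pid, gene = candidates$gene,
                    zygosity = candidates$zygosity, variant = vkey,
                    stringsAsFactors = FALSE)
  sub <- sub[sub$gene == gene, , drop = FALSE]
  out <- list()
  emit <- function(...) out[[length(out) + 1L]] <<- data.frame(
    ..., stringsAsFactors = FALSE)
  for (p in unique(sub$patient_id)) {
    vs <- sub[sub$patient_id == p, , drop = FALSE]
    if (any(vs$zygosity == "hom")) {
      emit(patient_id = p, kind = "biallelic_hom",
           variants = paste(vs$variant[vs$zygosity == "hom"],
                            collapse = ";"),
           segregation = "untested")
      next
    }
    hets <- vs[vs$zygosity == "het", , drop = FALSE]
    if (nrow(hets) < 2L) next
    v1 <- hets$variant[1]; v2 <- hets$variant[2]
    parents <- NULL
    if (!is.null(ped)) {
      row <- ped$members[ped$members$individual_id == p, , drop = FALSE]
      if (nrow(row) && !is.na(row$father_id) && !is.na(row$mother_id) &&
          !is.null(ped$genotypes)) {
        parents <- c(row$father_id, row$mother_id)
      }
    }
    if (is.null(parents)) {
      emit(patient_id = p, kind = "compound_het",
           variants = paste(v1, v2, sep = ";"), segregation = "untested")
      next
    }
    f1 <- ped_dosage(ped, parents[1], v1)
    f2 <- ped_dosage(ped, parents[1], v2)
    m1 <- ped_dosage(ped, parents[2], v1)
    m2 <- ped_dosage(ped, parents[2], v2)
    phases <- feasible_phases(f1, f2, m1, m2)
    if (length(phases) == 0L) {
      emit(patient_id = p, kind = "compound_het",
           variants = paste(v1, v2, sep = ";"), segregation = "inconsistent")
    } else if (identical(phases, "trans")) {
      emit(patient_id = p, kind = "compound_het",
           variants = paste(v1, v2, sep = ";"), segregation = "consistent")
    } else if (identical(phases, "cis")) {
      emit(patient_id = p, kind = "single_het",
           variants = paste(v1, v2, sep = ";"), segregation = "consistent")
    } else {
      emit(patient_id = p, kind = "compound_het",
           variants = paste(v1, v2, sep = ";"), segregation = "untested")
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(patient_id = character(0), kind = character(0),
               variants = character(0), segregation = character(0))
}

#' Check Mendelian consistency of a finding against a pedigree
#'
#' Consistent when every typed relative's carrier pattern admits a
#' Mendelian transmission of the proband's genotype. Unaffected carriers
#' are noted (reduced penetrance is the rule, not the exception, in
#' dominant PAH genes) but never falsify segregation. A child genotype
#' impossible given both typed parents (e.g. hom alt child of two hom ref
#' parents) flags `inconsistent`.
#'
#' @param finding one-row finding data.frame (from [detect_biallelic()] or
#'   [detect_cooccurrence()]) or a list with `patient_id` and `variants`
#'   (";"-separated)
#' @param ped a `hap_pedigree` with genotypes
#' @return the finding with `segregation` updated and a `penetrance_note`
#'   column added
#' @export
segregation_check <- function(finding, ped) {
  stopifnot(inherits(ped, "hap_pedigree"))
  p <- finding$patient_id[1]
  vars <- strsplit(finding$variants[1], ";", fixed = TRUE)[[1]]
  g <- ped$genotypes
  if (is.null(g) || !nrow(g[g$individual_id != p, , drop = FALSE])) {
    finding$segregation <- "untested"
    finding$penetrance_note <- NA_character_
    return(finding)
  }
  row <- ped$members[ped$members$individual_id == p, , drop = FALSE]
  consistent <- TRUE
  notes <- character(0)
  for (v in vars) {
    child <- ped_dosage(ped, p, v)
    if (is.na(child)) child <- 1L
    if (nrow(row) && !is.na(row$father_id) && !is.na(row$mother_id)) {
      fd <- ped_dosage(ped, row$father_id, v)
      md <- ped_dosage(ped, row$mother_id, v)
      if (!is.na(fd) && !is.na(md)) {
        # child must receive one allele from each parent
        ok <- FALSE
        for (fa in 0:1) for (ma in 0:1) {
          give <- function(d, a) if (a == 1L) d > 0L else d < 2L
          if (give(fd, fa) && give(md, ma) && fa + ma == child) ok <- TRUE
        }
        if (!ok) consistent <- FALSE
      }
    }
    carriers <- g$individual_id[g$variant == v & g$individual_id != p]
    for (cr in carriers) {
      mrow <- ped$members[ped$members$individual_id == cr, , drop = FALSE]
      if (nrow(mrow) && mrow$affected == 1) {
        notes <- c(notes, paste0("unaffected carrier ", cr, " (", v,
                                 "): reduced penetrance"))
      }
    }
  }
  finding$segregation <- if (consistent) "consistent" else "inconsistent"
  finding$penetrance_note <- if (length(notes)) {
    paste(notes, collapse = "; ")
  } else NA_character_
  finding
}
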