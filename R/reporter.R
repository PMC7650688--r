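#' Hemodynamic eligibility: precapillary pulmonary hypertension
#'
#' The classical right-heart-catheterization triad: mean pulmonary
#' arterial pressure >= 25 mmHg at rest, pulmonary artery wedge pressure
#' <= 15 mmHg, and pulmonary vascular resistance > 3 Wood units. Any
#' missing value yields `NA` (undetermined), which is distinct from
#' `FALSE`.
#'
#' @param mpap mean pulmonary arterial pressure (mmHg)
#' @param pawp pulmonary artery wedge pressure (mmHg)
#' @param pvr pulmonary vascular resistance (Wood units)
#' @return logical (vectorised), `NA` when undetermined
#' @export
check_precapillary_ph <- function(mpap, pawp, pvr) {
  ifelse(is.na(mpap) | is.na(pawp) | is.na(pvr), NA,
         mpap >= 25 & pawp <= 15 & pvr > 3)
}

#' Aggregate per-patient results into a cohort summary
#'
#' Deterministic counts over classified candidate variants: cohort-level
#' yield (carriers of at least one candidate), the class distribution,
#' per-gene and per-etiology tallies, and the digenic count. Percentages
#' are always reported alongside their raw fractions, since patient-level
#' and variant-level denominators differ.
#'
#' @param patients data.frame with `patient_id`, `etiology` (and optional
#'   `subtype`)
#' @param variants classified records with `patient_id`, `gene`, `acmg`
#' @param cnvs optional CNV calls (`patient_id`/`sample_id`, `gene`)
#' @param qc optional gated QC reports ([qc_gate()]) for the sequencing
#'   denominator
#' @return object of class `hap_summary`
#' @export
summarize_cohort <- function(patients, variants, cnvs = NULL, qc = NULL) {
  if (anyDuplicated(patients$patient_id)) {
    stop("duplicate patient ids: ",
         paste(unique(patients$patient_id[
           duplicated(patients$patient_id)]), collapse = ", "))
  }
  norm_class <- function(x) {
    map <- c(P = "Pathogenic", LP = "Likely_pathogenic", VUS = "VUS",
             LB = "Likely_benign", B = "Benign", `N/A` = "Not_applicable")
    out <- ifelse(x %in% names(map), map[x], x)
    unname(out)
  }
  v <- variants
  v$acmg <- norm_class(v$acmg)
  # reported variants without a printed class still count as candidates
  candidate <- is.na(v$acmg) |
    v$acmg %in% c("Pathogenic", "Likely_pathogenic", "VUS")
  v <- v[candidate, , drop = FALSE]
  et <- patients$etiology[match(v$patient_id, patients$patient_id)]

  n_sequenced <- if (!is.null(qc)) nrow(qc) else nrow(patients)
  n_failed <- if (!is.null(qc)) sum(!qc$passed) else 0L
  per_class <- table(factor(v$acmg, levels = c("Pathogenic",
                                               "Likely_pathogenic", "VUS")))
  pg <- list()
  for (g in unique(v$gene)) {
    sel <- v$gene == g
    pg[[length(pg) + 1L]] <- data.frame(
      gene = g,
      n_plp = sum(v$acmg[sel] %in% c("Pathogenic", "Likely_pathogenic")),
      n_vus = sum(v$acmg[sel] == "VUS", na.rm = TRUE),
      n_total = sum(sel), stringsAsFactors = FALSE)
  }
  per_gene <- if (length(pg)) do.call(rbind, pg) else
    data.frame(gene = character(0), n_plp = integer(0), n_vus = integer(0),
               n_total = integer(0))
  per_gene <- per_gene[order(-per_gene$n_plp, -per_gene$n_total,
                             per_gene$gene), , drop = FALSE]
  rownames(per_gene) <- NULL

  pe <- list()
  for (e in unique(et)) {
    sel <- !is.na(et) & et == e
    pe[[length(pe) + 1L]] <- data.frame(
      etiology = e,
      n_variants = sum(sel),
      n_patients = length(unique(v$patient_id[sel])),
      n_pathogenic = sum(v$acmg[sel] == "Pathogenic", na.rm = TRUE),
      stringsAsFactors = FALSE)
  }
  per_etiology <- if (length(pe)) do.call(rbind, pe) else
    data.frame(etiology = character(0), n_variants = integer(0),
               n_patients = integer(0), n_pathogenic = integer(0))

  digenic <- detect_cooccurrence(v, cnvs)
  carriers <- unique(c(v$patient_id,
                       if (!is.null(cnvs) && nrow(cnvs)) {
                         if ("patient_id" %in% names(cnvs)) {
                           cnvs$patient_id
                         } else cnvs$sample_id
                       }))
  structure(list(
    n_sequenced = n_sequenced,
    n_failed_qc = n_failed,
    n_analyzed = n_sequenced - n_failed,
    n_carriers = length(carriers),
    n_candidate_variants = nrow(v),
    per_class = per_class,
    per_gene = per_gene,
    per_etiology = per_etiology,
    digenic_count = nrow(digenic),
    digenic = digenic
  ), class = "hap_summary")
}

#' @export
print.hap_summary <- function(x, ...) {
  frac <- function(n, d) sprintf("%d/%d (%.1f%%)", n, d,
                                 if (d > 0) 100 * n / d else 0)
  cat("Cohort summary\n")
  cat("  sequenced:          ", x$n_sequenced, "\n")
  cat("  failed QC:          ", frac(x$n_failed_qc, x$n_sequenced), "\n")
  cat("  analyzed:           ", x$n_analyzed, "\n")
  cat("  carriers:           ", frac(x$n_carriers, x$n_analyzed), "\n")
  cat("  candidate variants: ", x$n_candidate_variants, "\n")
  cat("  class distribution: ",
      paste(names(x$per_class), as.integer(x$per_class), sep = "=",
            collapse = "  "), "\n")
  cat("  digenic patients:   ", x$digenic_count, "\n")
  invisible(x)
}

#' Cohort-level and per-gene frequency tables
#'
#' The two surfaces of the cohort mutation-frequency figure: (a)
#' cohort-level fractions (carriers of pathogenic/likely pathogenic
#' variants, VUS-only carriers, negatives, QC failures) and (b) a per-gene
#' bar table of P/LP and VUS counts.
#'
#' @param summary a `hap_summary`
#' @param variants the classified records the summary was built from
#' @param patients the patient table used for the summary
#' @return list of two data.frames, `cohort` and `per_gene`
#' @export
render_figure2_tables <- function(summary, variants, patients) {
  stopifnot(inherits(summary, "hap_summary"))
  norm <- c(P = "Pathogenic", LP = "Likely_pathogenic")
  cls <- ifelse(variants$acmg %in% names(norm), norm[variants$acmg],
                variants$acmg)
  plp_pat <- unique(variants$patient_id[
    cls %in% c("Pathogenic", "Likely_pathogenic")])
  vus_pat <- setdiff(unique(variants$patient_id[cls %in% "VUS"]), plp_pat)
  n_an <- summary$n_analyzed
  cohort <- data.frame(
    category = c("P_LP_carrier", "VUS_only", "negative", "failed_qc"),
    n = c(length(plp_pat), length(vus_pat),
          max(n_an - length(plp_pat) - length(vus_pat), 0L),
          summary$n_failed_qc),
    denominator = c(n_an, n_an, n_an, summary$n_sequenced),
    stringsAsFactors = FALSE)
  cohort$fraction <- ifelse(cohort$denominator > 0,
                            cohort$n / cohort$denominator, 0)
  list(cohort = cohort, per_gene = summary$per_gene)
}
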