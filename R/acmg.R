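#' Valid ACMG/AMP evidence codes
#' @return character vector of the 28 evidence codes
#' @export
acmg_codes <- function() {
  c("PVS1", paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5),
    "BA1", paste0("BS", 1:4), paste0("BP", 1:7))
}

code_strength <- function(code) {
  if (code == "PVS1") return("very_strong")
  if (grepl("^PS", code)) return("strong")
  if (grepl("^PM", code)) return("moderate")
  if (grepl("^PP", code)) return("supporting")
  if (code == "BA1") return("stand_alone")
  if (grepl("^BS", code)) return("strong")
  "supporting"
}

#' Combine ACMG evidence codes into the five-tier classification
#'
#' Implements the published combining rules. Pathogenic: PVS1 with (>=1 PS,
#' >=2 PM, 1 PM + 1 PP, or >=2 PP); >=2 PS; or 1 PS with (>=3 PM,
#' 2 PM + >=2 PP, or 1 PM + >=4 PP). Likely pathogenic: PVS1 + 1 PM;
#' 1 PS + 1-2 PM; 1 PS + >=2 PP; >=3 PM; 2 PM + >=2 PP; or 1 PM + >=4 PP.
#' Benign: BA1 or >=2 BS. Likely benign: 1 BS + 1 BP or >=2 BP.
#'
#' Conflict handling is code-level: a verdict on one side in the presence
#' of any evidence code from the other side yields VUS (so e.g.
#' \{BA1, PM2\} is VUS, not Benign). Everything else is VUS.
#'
#' @param codes character vector of evidence codes
#' @param strength_overrides optional named character vector mapping a
#'   present code to an adjusted strength (`very_strong`, `strong`,
#'   `moderate`, `supporting`); pathogenic-side codes only
#' @return one of `Pathogenic`, `Likely_pathogenic`, `VUS`,
#'   `Likely_benign`, `Benign`
#' @export
combine_evidence <- function(codes, strength_overrides = NULL) {
  codes <- unique(codes)
  bad <- setdiff(codes, acmg_codes())
  if (length(bad)) stop("unknown ACMG code(s): ", paste(bad, collapse = ", "))
  if (!is.null(strength_overrides)) {
    orphan <- setdiff(names(strength_overrides), codes)
    if (length(orphan)) {
      stop("strength override for absent code(s): ",
           paste(orphan, collapse = ", "))
    }
  }
  strengths <- vapply(codes, function(cd) {
    if (cd %in% names(strength_overrides)) strength_overrides[[cd]] else
      code_strength(cd)
  }, character(1))
  path_codes <- codes[grepl("^P", codes)]
  ben_codes <- setdiff(codes, path_codes)
  n_pvs <- sum(strengths[path_codes] == "very_strong")
  n_ps <- sum(strengths[path_codes] == "strong")
  n_pm <- sum(strengths[path_codes] == "moderate")
  n_pp <- sum(strengths[path_codes] == "supporting")
  ba1 <- "BA1" %in% ben_codes
  n_bs <- sum(grepl("^BS", ben_codes))
  n_bp <- sum(grepl("^BP", ben_codes))

  pathogenic <-
    (n_pvs >= 1 && (n_ps >= 1 || n_pm >= 2 || (n_pm == 1 && n_pp >= 1) ||
                      n_pp >= 2)) ||
    n_ps >= 2 ||
    (n_ps == 1 && (n_pm >= 3 || (n_pm == 2 && n_pp >= 2) ||
                     (n_pm == 1 && n_pp >= 4)))
  likely_path <- !pathogenic && (
    (n_pvs >= 1 && n_pm == 1) ||
      (n_ps == 1 && n_pm >= 1 && n_pm <= 2) ||
      (n_ps == 1 && n_pp >= 2) ||
      n_pm >= 3 ||
      (n_pm == 2 && n_pp >= 2) ||
      (n_pm == 1 && n_pp >= 4))
  benign <- ba1 || n_bs >= 2
  likely_ben <- !benign && ((n_bs == 1 && n_bp >= 1) || n_bp >= 2)

  path_verdict <- if (pathogenic) "Pathogenic" else
    if (likely_path) "Likely_pathogenic" else NA_character_
  ben_verdict <- if (benign) "Benign" else
    if (likely_ben) "Likely_benign" else NA_character_

  has_path_codes <- length(path_codes) > 0L
  has_ben_codes <- length(ben_codes) > 0L
  if ((!is.na(path_verdict) && has_ben_codes) ||
      (!is.na(ben_verdict) && has_path_codes)) {
    return("VUS")
  }
  if (!is.na(path_verdict)) return(path_verdict)
  if (!is.na(ben_verdict)) return(ben_verdict)
  "VUS"
}

#' Default evidence-assignment thresholds
#'
#' The annotation inputs (frequencies, predictor tallies, assertions) map
#' onto evidence codes through explicit, auditable cutoffs; none of them is
#' prescribed by guideline text, so all are configurable.
#'
#' @param pm2_af popmax frequency below which PM2 (absent/rare) fires
#' @param bs1_af frequency above which BS1 fires (up to `ba1_af`)
#' @param ba1_af stand-alone benign frequency cutoff
#' @param pp3_consensus minimum deleterious predictor share for PP3
#' @param bp4_consensus maximum deleterious predictor share for BP4
#' @param min_predictors predictors required before PP3/BP4 can fire
#' @return named list
#' @export
acmg_config <- function(pm2_af = 1e-4, bs1_af = 1e-3, ba1_af = 0.05,
                        pp3_consensus = 0.5, bp4_consensus = 0.2,
                        min_predictors = 3L) {
  list(pm2_af = pm2_af, bs1_af = bs1_af, ba1_af = ba1_af,
       pp3_consensus = pp3_consensus, bp4_consensus = bp4_consensus,
       min_predictors = min_predictors)
}

#' Deterministic evidence assignment for an annotated record
#'
#' Maps annotations onto codes: PVS1 for truncating consequences
#' (stop_gained, frameshift, canonical splice) in an established
#' loss-of-function gene; PM2 when the popmax frequency is absent or below
#' the rarity cutoff; BA1/BS1 from high frequencies; PP3/BP4 from the
#' predictor consensus when enough predictors voted; PP5/BP6 from prior
#' clinical assertions; PP1 when segregation support is supplied.
#'
#' @param record one annotated record (single-row data.frame or list with
#'   fields `gene`, `consequence`, `popmax_af`, `n_deleterious`, `n_total`,
#'   `clinical_assertion`)
#' @param panel a `hap_panel` providing the evidence tier per gene
#' @param config an [acmg_config()]
#' @param segregation logical: cosegregation support available
#' @return character vector of evidence codes
#' @export
default_evidence <- function(record, panel = hap_panel(),
                             config = acmg_config(), segregation = FALSE) {
  need <- c("gene", "consequence", "popmax_af", "n_deleterious", "n_total",
            "clinical_assertion")
  if (!all(need %in% names(record))) {
    stop("record is not annotated (missing: ",
         paste(setdiff(need, names(record)), collapse = ", "), ")")
  }
  codes <- character(0)
  tier <- panel$genes$evidence_tier[match(record$gene, panel$genes$symbol)]
  if (!is.na(record$consequence) &&
      record$consequence %in% c("stop_gained", "frameshift",
                                "splice_canonical") &&
      isTRUE(tier == "established")) {
    codes <- c(codes, "PVS1")
  }
  af <- record$popmax_af
  if (is.na(af) || af < config$pm2_af) {
    codes <- c(codes, "PM2")
  } else if (af > config$ba1_af) {
    codes <- c(codes, "BA1")
  } else if (af > config$bs1_af) {
    codes <- c(codes, "BS1")
  }
  cons <- predictor_consensus(record$n_deleterious, record$n_total)
  if (!is.na(cons) && record$n_total >= config$min_predictors) {
    if (cons >= config$pp3_consensus) codes <- c(codes, "PP3")
    if (cons <= config$bp4_consensus) codes <- c(codes, "BP4")
  }
  if (record$clinical_assertion == "pathogenic_reported") {
    codes <- c(codes, "PP5")
  }
  if (record$clinical_assertion == "benign_reported") {
    codes <- c(codes, "BP6")
  }
  if (isTRUE(segregation)) codes <- c(codes, "PP1")
  codes
}

#' Classify a table of annotated records
#'
#' Convenience wrapper: [default_evidence()] then [combine_evidence()] per
#' record, returning the records with `evidence` and `acmg` columns. CNV
#' calls never pass through this engine (their classification stays
#' `Not_applicable`).
#'
#' @param records annotated record data.frame
#' @inheritParams default_evidence
#' @return `records` with `evidence` (";"-joined codes) and `acmg` columns
#' @export
classify_records <- function(records, panel = hap_panel(),
                             config = acmg_config()) {
  ev <- character(nrow(records))
  cls <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    codes <- default_evidence(records[i, , drop = FALSE], panel, config,
                              segregation = isTRUE(records$segregation[i]))
    ev[i] <- paste(codes, collapse = ";")
    cls[i] <- combine_evidence(codes)
  }
  records$evidence <- ev
  records$acmg <- cls
  records
}
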