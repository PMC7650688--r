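#' Prioritization cascade thresholds
#'
#' The cascade preserves the architecture of quality -> population
#' frequency -> panel membership -> consequence filtering; every number is
#' an explicit, logged default.
#'
#' @param min_dp minimum read depth for the quality stage
#' @param min_gq minimum genotype quality for the quality stage
#' @param max_af popmax frequency above which a variant is dropped
#'   (unless rescued by a prior pathogenic assertion)
#' @return named list
#' @export
prioritizer_config <- function(min_dp = 10, min_gq = 30, max_af = 1e-3) {
  list(min_dp = min_dp, min_gq = min_gq, max_af = max_af)
}

#' Prioritize annotated variant records
#'
#' Stages, in order:
#' \enumerate{
#'   \item quality: depth >= `min_dp` and genotype quality >= `min_gq`;
#'     failures are never dropped here, but survivors of the later stages
#'     are flagged `candidate_needs_confirmation` (orthogonal-confirmation
#'     rule: only variants failing the quality criteria need Sanger
#'     validation);
#'   \item frequency: drop when popmax frequency exceeds `max_af`, unless a
#'     prior pathogenic clinical assertion rescues the variant;
#'   \item gene: drop off-panel records;
#'   \item consequence: drop synonymous and deep-intronic records (beyond
#'     the splice region), again subject to the assertion rescue.
#' }
#' Every record lands in exactly one of candidates / dropped, and each
#' carries a full stage-by-stage trace.
#'
#' @param records annotated records (see [annotate_variants()])
#' @param panel a `hap_panel`
#' @param config a [prioritizer_config()]
#' @return list with `candidates` (records plus `final` column) and
#'   `traces` (long data.frame: key, stage, decision, reason)
#' @export
prioritize <- function(records, panel = hap_panel(),
                       config = prioritizer_config()) {
  need <- c("popmax_af", "consequence", "clinical_assertion")
  if (!all(need %in% names(records))) {
    stop("records must be annotated before prioritization (missing: ",
         paste(setdiff(need, names(records)), collapse = ", "), ")")
  }
  n <- nrow(records)
  key <- paste(records$sample_id, variant_key(records$chrom, records$pos,
                                              records$ref, records$alt),
               sep = "@")
  trace <- list()
  add <- function(k, stage, decision, reason) {
    trace[[length(trace) + 1L]] <<- data.frame(
      key = k, stage = stage, decision = decision, reason = reason,
      stringsAsFactors = FALSE)
  }
  final <- character(n)
  rescued <- records$clinical_assertion == "pathogenic_reported"
  for (i in seq_len(n)) {
    dp <- records$depth[i]
    gq <- records$quality[i]
    q_ok <- (is.na(dp) || dp >= config$min_dp) &&
      (is.na(gq) || gq >= config$min_gq)
    add(key[i], "quality", "keep",
        if (q_ok) sprintf("DP=%s GQ=%s", dp, gq) else
          sprintf("DP=%s GQ=%s below threshold; confirmation required",
                  dp, gq))
    af <- records$popmax_af[i]
    if (!is.na(af) && af > config$max_af && !rescued[i]) {
      add(key[i], "frequency", "drop",
          sprintf("popmax AF %.3g > %.3g", af, config$max_af))
      final[i] <- "dropped"
      next
    }
    add(key[i], "frequency", "keep",
        if (!is.na(af) && af > config$max_af) {
          sprintf("popmax AF %.3g rescued by prior pathogenic assertion", af)
        } else if (is.na(af)) "not observed in any source" else
          sprintf("popmax AF %.3g", af))
    g <- records$gene[i]
    if (is.na(g) || !(g %in% panel$genes$symbol)) {
      add(key[i], "gene", "drop", "off-panel gene")
      final[i] <- "dropped"
      next
    }
    add(key[i], "gene", "keep", g)
    cons <- records$consequence[i]
    if (!is.na(cons) && cons %in% c("synonymous", "intronic") &&
        !rescued[i]) {
      add(key[i], "consequence", "drop", cons)
      final[i] <- "dropped"
      next
    }
    add(key[i], "consequence", "keep", cons)
    final[i] <- if (q_ok) "candidate" else "candidate_needs_confirmation"
  }
  records$final <- final
  traces <- if (length(trace)) do.call(rbind, trace) else
    data.frame(key = character(0), stage = character(0),
               decision = character(0), reason = character(0))
  list(candidates = records[records$final != "dropped", , drop = FALSE],
       dropped = records[records$final == "dropped", , drop = FALSE],
       traces = traces)
}

#' Human-readable account of one filter trace
#'
#' @param traces the `traces` data.frame from [prioritize()]
#' @param key the record key to explain
#' @return character vector, one line per stage
#' @export
explain_trace <- function(traces, key) {
  tr <- traces[traces$key == key, , drop = FALSE]
  if (!nrow(tr)) stop("no trace recorded for key: ", key)
  sprintf("%-11s %-4s %s", tr$stage, tr$decision, tr$reason)
}
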