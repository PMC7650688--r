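#' Fraction of target bases covered at or above a depth threshold
#'
#' The headline capture-QC rule is "95% of target bases at >= 20x"; the
#' threshold comparison is inclusive.
#'
#' @param depths per-base depth vector over the target space
#' @param threshold depth cutoff (> 0)
#' @param weights optional base counts when `depths` holds per-target means
#' @return proportion in \[0, 1\]
#' @export
coverage_fraction <- function(depths, threshold = 20, weights = NULL) {
  if (length(depths) == 0L) stop("empty target set")
  stopifnot(threshold > 0)
  if (is.null(weights)) weights <- rep(1, length(depths))
  stopifnot(length(weights) == length(depths))
  sum(weights[depths >= threshold]) / sum(weights)
}

#' Transition/transversion ratio by known/novel stratum
#'
#' Counts SNVs only (indels and multi-base alleles are ignored).
#' Transitions are A<->G and C<->T. A stratum with zero transversions
#' reports `NA` (undefined), never infinity.
#'
#' @param ref,alt allele vectors
#' @param known logical vector: variant present at a known (dbSNP-like) site
#' @return list with `titv_known`, `titv_novel`, `n_known`, `n_novel`
#' @export
titv_ratio <- function(ref, alt, known) {
  stopifnot(length(ref) == length(alt), length(ref) == length(known))
  snv <- nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    ref != alt
  is_ti <- (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
    (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
  ratio_of <- function(sel) {
    ti <- sum(snv & sel & is_ti)
    tv <- sum(snv & sel & !is_ti)
    if (tv == 0L) NA_real_ else ti / tv
  }
  list(titv_known = ratio_of(known), titv_novel = ratio_of(!known),
       n_known = sum(snv & known), n_novel = sum(snv & !known))
}

#' Default QC gate thresholds
#'
#' Only the coverage rule (95% of target bases at >= 20x) is prescribed;
#' the capture-efficiency floor and the Ti/Tv band are conventional
#' capture-QC defaults and all values are configurable. The Ti/Tv gate is
#' only applied to samples with at least `min_titv_sites` classifiable
#' SNVs; below that the ratio is too unstable to gate on.
#'
#' @param min_fraction_20x minimum fraction of target bases at >= 20x
#' @param min_on_target minimum on-target read fraction
#' @param titv_band acceptable (low, high) band for known-site Ti/Tv
#' @param min_titv_sites minimum known SNVs before the Ti/Tv gate applies
#' @return named list of thresholds
#' @export
qc_config <- function(min_fraction_20x = 0.95, min_on_target = 0.70,
                      titv_band = c(2.0, 4.5), min_titv_sites = 20L) {
  list(min_fraction_20x = min_fraction_20x, min_on_target = min_on_target,
       titv_band = titv_band, min_titv_sites = min_titv_sites)
}

#' Compute per-sample QC reports from a depth matrix
#'
#' Expands per-target mean depths to base space (each target's bases carry
#' the target mean), then derives coverage at 20x, mean target depth and
#' uniformity (fraction of target bases within 0.2x-2x of the sample mean).
#' Optional variant records add per-sample Ti/Tv; an optional metrics table
#' supplies sequencer-level fields (total reads, on-target fraction,
#' duplicate fraction, error rate), which are reported as given.
#'
#' @param depth a `hap_depth` matrix from [depth_matrix()] /
#'   [read_depth_matrix()]
#' @param variants optional annotated record data.frame with `sample_id`,
#'   `ref`, `alt` and logical `known`
#' @param metrics optional data.frame keyed by `sample_id` with any of
#'   `total_reads`, `on_target_fraction`, `duplicate_fraction`,
#'   `error_rate`
#' @return data.frame, one row per sample (a QC report without the gate
#'   applied; see [qc_gate()])
#' @export
compute_sample_qc <- function(depth, variants = NULL, metrics = NULL) {
  stopifnot(inherits(depth, "hap_depth"))
  w <- depth$targets$end - depth$targets$start
  rep_df <- data.frame(sample_id = depth$samples, stringsAsFactors = FALSE)
  rep_df$mean_depth <- apply(depth$depth, 2L, function(d) {
    sum(d * w) / sum(w)
  })
  rep_df$fraction_at_20x <- apply(depth$depth, 2L, coverage_fraction,
                                  threshold = 20, weights = w)
  rep_df$uniformity <- vapply(seq_along(depth$samples), function(j) {
    m <- rep_df$mean_depth[j]
    d <- depth$depth[, j]
    sum(w[d >= 0.2 * m & d <= 2 * m]) / sum(w)
  }, numeric(1))
  rep_df$titv_known <- NA_real_
  rep_df$titv_novel <- NA_real_
  rep_df$n_titv_sites <- 0L
  if (!is.null(variants) && nrow(variants)) {
    stopifnot(all(c("sample_id", "ref", "alt", "known") %in% names(variants)))
    for (j in seq_along(depth$samples)) {
      vs <- variants[variants$sample_id == depth$samples[j], , drop = FALSE]
      if (!nrow(vs)) next
      tt <- titv_ratio(vs$ref, vs$alt, vs$known)
      rep_df$titv_known[j] <- tt$titv_known
      rep_df$titv_novel[j] <- tt$titv_novel
      rep_df$n_titv_sites[j] <- tt$n_known
    }
  }
  for (col in c("total_reads", "on_target_fraction", "duplicate_fraction",
                "error_rate")) {
    rep_df[[col]] <- NA_real_
    if (!is.null(metrics) && col %in% names(metrics)) {
      rep_df[[col]] <- metrics[[col]][match(rep_df$sample_id,
                                            metrics$sample_id)]
    }
  }
  rep_df
}

#' Apply the QC gate to sample reports
#'
#' A sample fails when its coverage fraction at 20x drops below the floor,
#' its on-target fraction (when known) is below the configured minimum, or
#' its known-site Ti/Tv (when estimable from enough sites) falls outside
#' the band. Each breach appends one reason; `passed` is true iff no
#' reasons accrued. Library complexity and raw error rate are reported but
#' never gate by default.
#'
#' @param reports data.frame from [compute_sample_qc()]
#' @param config thresholds from [qc_config()]
#' @return `reports` with `passed` and `failure_reasons` filled
#' @export
qc_gate <- function(reports, config = qc_config()) {
  reasons <- vector("list", nrow(reports))
  for (i in seq_len(nrow(reports))) {
    r <- character(0)
    if (reports$fraction_at_20x[i] < config$min_fraction_20x) {
      r <- c(r, "coverage")
    }
    ot <- reports$on_target_fraction[i]
    if (!is.na(ot) && ot < config$min_on_target) r <- c(r, "on_target")
    tk <- reports$titv_known[i]
    if (!is.na(tk) && reports$n_titv_sites[i] >= config$min_titv_sites &&
        (tk < config$titv_band[1] || tk > config$titv_band[2])) {
      r <- c(r, "titv")
    }
    reasons[[i]] <- r
  }
  reports$failure_reasons <- vapply(reasons, paste, character(1),
                                    collapse = ";")
  reports$passed <- !nzchar(reports$failure_reasons)
  reports
}
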