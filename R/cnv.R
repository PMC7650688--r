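#' Per-target per-sample depth matrices
#'
#' Container for mean per-target read depth across a cohort: a targets
#' data.frame (the panel regions) and a targets x samples numeric matrix.
#'
#' @param targets data.frame with `chrom`, `start`, `end`, `gene`, `label`
#' @param depth numeric matrix, rows matching `targets`, columns samples
#' @param samples sample identifiers (defaults to `colnames(depth)`)
#' @return object of class `hap_depth`
#' @export
depth_matrix <- function(targets, depth, samples = colnames(depth)) {
  depth <- as.matrix(depth)
  stopifnot(nrow(depth) == nrow(targets), length(samples) == ncol(depth),
            all(depth >= 0))
  colnames(depth) <- samples
  structure(list(targets = targets, samples = samples, depth = depth),
            class = "hap_depth")
}

#' @rdname depth_matrix
#' @param path TSV with columns `chrom`, `start`, `end`, `gene`, `label`
#'   followed by one column per sample
#' @export
read_depth_matrix <- function(path) {
  df <- read_tsv_strict(path, required = c("chrom", "start", "end", "gene",
                                           "label"))
  meta <- c("chrom", "start", "end", "gene", "label")
  depth_matrix(df[meta], as.matrix(df[setdiff(names(df), meta)]))
}

#' @rdname depth_matrix
#' @param m a `hap_depth`
#' @export
write_depth_matrix <- function(m, path) {
  stopifnot(inherits(m, "hap_depth"))
  write_tsv(cbind(m$targets, as.data.frame(m$depth)), path)
}

#' CNV-calling thresholds
#'
#' A cell is called when its normalized ratio breaches the ratio threshold
#' and deviates from the target's cross-sample distribution by at least
#' `min_z` standard deviations; with fewer than `min_ref` usable samples
#' calls are emitted but marked low-confidence.
#'
#' @param min_ratio_gain minimum normalized ratio for a gain
#' @param max_ratio_loss maximum normalized ratio for a loss
#' @param min_z minimum |z| against the per-target ratio distribution
#' @param min_ref reference cohort size below which calls are
#'   low-confidence
#' @return named list
#' @export
cnv_config <- function(min_ratio_gain = 1.35, max_ratio_loss = 0.65,
                       min_z = 2.5, min_ref = 8L) {
  list(min_ratio_gain = min_ratio_gain, max_ratio_loss = max_ratio_loss,
       min_z = min_z, min_ref = min_ref)
}

#' Normalize a depth matrix to copy-ratio space
#'
#' Two-stage median normalization: each cell is divided by its sample's
#' median target depth (library-size correction), then by the
#' across-sample median of its target (target-bias correction), so a
#' diploid cell sits near ratio 1. Samples with median depth 0 are
#' excluded with a warning; fewer than two usable samples is an error.
#'
#' @param m a `hap_depth`
#' @return numeric ratio matrix (targets x usable samples) with the
#'   usable sample names as columns
#' @export
normalize_depth <- function(m) {
  stopifnot(inherits(m, "hap_depth"))
  med <- apply(m$depth, 2L, stats::median)
  usable <- med > 0
  if (any(!usable)) {
    warning("excluding sample(s) with zero median depth: ",
            paste(m$samples[!usable], collapse = ", "))
  }
  if (sum(usable) < 2L) stop("fewer than 2 usable samples")
  d <- m$depth[, usable, drop = FALSE]
  d <- sweep(d, 2L, med[usable], "/")
  tmed <- apply(d, 1L, stats::median)
  tmed[tmed == 0] <- NA_real_
  sweep(d, 1L, tmed, "/")
}

#' Call copy-number variants from normalized ratios
#'
#' Per cell, a robust z-score (median/MAD) is computed against the
#' across-sample ratio distribution of that target; gains require ratio >=
#' `min_ratio_gain` and |z| >= `min_z`, losses ratio <= `max_ratio_loss`
#' and |z| >= `min_z`. Adjacent called targets of one gene and sample
#' merge into a single call. Zero-variance targets are skipped with a
#' warning. CNV calls carry classification `Not_applicable`: they bypass
#' the small-variant ACMG engine.
#'
#' @param ratios matrix from [normalize_depth()]
#' @param targets the targets data.frame matching the ratio rows
#' @param config a [cnv_config()]
#' @return data.frame of calls: `sample_id`, `gene`, `targets`, `n_targets`,
#'   `kind`, `ratio`, `zscore`, `low_confidence`, `classification`
#' @export
call_cnvs <- function(ratios, targets, config = cnv_config()) {
  stopifnot(nrow(ratios) == nrow(targets))
  n_s <- ncol(ratios)
  low_conf <- n_s < config$min_ref
  # robust location/scale per target: a single true CNV carrier must not
  # drag the reference distribution with it
  mu <- apply(ratios, 1L, stats::median, na.rm = TRUE)
  sdv <- apply(ratios, 1L, stats::mad, na.rm = TRUE)
  degenerate <- !is.na(sdv) & sdv == 0
  if (any(degenerate)) {
    warning("skipping zero-variance target(s): ",
            paste(targets$label[degenerate], collapse = ", "))
  }
  calls <- list()
  for (j in seq_len(n_s)) {
    z <- (ratios[, j] - mu) / sdv
    z[degenerate | is.na(sdv)] <- NA_real_
    r <- ratios[, j]
    hit_gain <- !is.na(z) & r >= config$min_ratio_gain &
      abs(z) >= config$min_z
    hit_loss <- !is.na(z) & r <= config$max_ratio_loss &
      abs(z) >= config$min_z
    kind <- ifelse(hit_gain, "gain", ifelse(hit_loss, "loss", NA))
    # merge runs of adjacent called targets within a gene
    i <- 1L
    while (i <= length(kind)) {
      if (is.na(kind[i])) { i <- i + 1L; next }
      j2 <- i
      while (j2 + 1L <= length(kind) && !is.na(kind[j2 + 1L]) &&
             kind[j2 + 1L] == kind[i] &&
             targets$gene[j2 + 1L] == targets$gene[i] &&
             targets$chrom[j2 + 1L] == targets$chrom[i]) {
        j2 <- j2 + 1L
      }
      idx <- i:j2
      calls[[length(calls) + 1L]] <- data.frame(
        sample_id = colnames(ratios)[j],
        gene = targets$gene[i],
        targets = paste(targets$label[idx], collapse = ","),
        n_targets = length(idx),
        kind = kind[i],
        ratio = mean(r[idx]),
        zscore = z[idx][which.max(abs(z[idx]))],
        low_confidence = low_conf,
        classification = "Not_applicable",
        stringsAsFactors = FALSE)
      i <- j2 + 1L
    }
  }
  if (length(calls)) do.call(rbind, calls) else
    data.frame(sample_id = character(0), gene = character(0),
               targets = character(0), n_targets = integer(0),
               kind = character(0), ratio = numeric(0), zscore = numeric(0),
               low_confidence = logical(0), classification = character(0))
}
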