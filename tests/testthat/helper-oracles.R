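# Independent oracles used across the suite. Each is a deliberately
# different formulation from the implementation it checks.

# Literal nested-if transcription of the published ACMG combining table,
# including the code-level conflict convention documented by the package.
acmg_oracle <- function(codes) {
  pvs <- "PVS1" %in% codes
  ps <- sum(codes %in% paste0("PS", 1:4))
  pm <- sum(codes %in% paste0("PM", 1:6))
  pp <- sum(codes %in% paste0("PP", 1:5))
  ba1 <- "BA1" %in% codes
  bs <- sum(codes %in% paste0("BS", 1:4))
  bp <- sum(codes %in% paste0("BP", 1:7))

  path <- FALSE
  if (pvs && ps >= 1) path <- TRUE
  if (pvs && pm >= 2) path <- TRUE
  if (pvs && pm >= 1 && pp >= 1) path <- TRUE
  if (pvs && pp >= 2) path <- TRUE
  if (ps >= 2) path <- TRUE
  if (ps == 1 && pm >= 3) path <- TRUE
  if (ps == 1 && pm == 2 && pp >= 2) path <- TRUE
  if (ps == 1 && pm == 1 && pp >= 4) path <- TRUE
  lp <- FALSE
  if (!path) {
    if (pvs && pm == 1) lp <- TRUE
    if (ps == 1 && (pm == 1 || pm == 2)) lp <- TRUE
    if (ps == 1 && pp >= 2) lp <- TRUE
    if (pm >= 3) lp <- TRUE
    if (pm == 2 && pp >= 2) lp <- TRUE
    if (pm == 1 && pp >= 4) lp <- TRUE
  }
  ben <- ba1 || bs >= 2
  lb <- !ben && ((bs == 1 && bp >= 1) || bp >= 2)

  any_path_code <- pvs || ps > 0 || pm > 0 || pp > 0
  any_ben_code <- ba1 || bs > 0 || bp > 0
  if ((path || lp) && any_ben_code) return("VUS")
  if ((ben || lb) && any_path_code) return("VUS")
  if (path) return("Pathogenic")
  if (lp) return("Likely_pathogenic")
  if (ben) return("Benign")
  if (lb) return("Likely_benign")
  "VUS"
}

# Minimal leftmost representation of an edit, found by maximal common
# suffix / prefix trimming of the full edited sequence (never by the
# shift loop the implementation uses).
normalize_oracle <- function(pos, ref, alt, seq) {
  n <- nchar(seq)
  edited <- paste0(substr(seq, 1, pos - 1), alt,
                   substr(seq, pos + nchar(ref), n))
  a <- strsplit(seq, "")[[1]]
  b <- strsplit(edited, "")[[1]]
  la <- length(a); lb <- length(b)
  s <- 0
  while (s < min(la, lb) && a[la - s] == b[lb - s]) s <- s + 1
  p <- 0
  while (p < min(la, lb) - s && a[p + 1] == b[p + 1]) p <- p + 1
  refm <- if (p + 1 <= la - s) paste(a[(p + 1):(la - s)], collapse = "") else ""
  altm <- if (p + 1 <= lb - s) paste(b[(p + 1):(lb - s)], collapse = "") else ""
  if (nchar(refm) == 0 || nchar(altm) == 0) {
    refm <- paste0(a[p], refm)
    altm <- paste0(a[p], altm)
    p <- p - 1
  }
  list(pos = p + 1L, ref = refm, alt = altm)
}

# Exhaustive enumeration of parental transmissions for two het child
# variants: which phase configurations are feasible?
phase_oracle <- function(f1, f2, m1, m2) {
  can_give <- function(d, a) if (is.na(d)) TRUE else
    if (a == 1) d > 0 else d < 2
  phases <- character(0)
  for (fa1 in 0:1) for (fa2 in 0:1) for (ma1 in 0:1) for (ma2 in 0:1) {
    if (fa1 + ma1 != 1 || fa2 + ma2 != 1) next  # child het at both sites
    if (!can_give(f1, fa1) || !can_give(f2, fa2)) next
    if (!can_give(m1, ma1) || !can_give(m2, ma2)) next
    phases <- c(phases, if (fa1 == fa2) "cis" else "trans")
  }
  sort(unique(phases))
}
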