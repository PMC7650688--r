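#' Simulation configuration for synthetic cohorts
#'
#' Defaults emulate the shape of the study cohort the package's worked
#' example comes from: 300 sequenced samples of which 11% fail QC, about
#' 30% of samples carrying a candidate variant, five digenic two-gene
#' carriers, one homozygous-founder and one compound-heterozygous
#' biallelic EIF2AK4 case, one planted single-exon duplication, per-target
#' depth drawn negative-binomially, and known-site substitutions drawn at
#' transition:transversion odds 3.2 (2.9 for novel sites).
#'
#' @param n_samples cohort size
#' @param seed integer seed (mandatory; generation is reproducible)
#' @param qc_fail_fraction fraction of samples planted to fail the
#'   coverage gate (count = `floor(n_samples * qc_fail_fraction)`)
#' @param carrier_fraction fraction of samples given one candidate variant
#' @param pathogenic_share share of planted candidates that are truncating
#'   (the rest are rare missense with mixed predictor votes, landing VUS)
#' @param digenic_pairs number of samples given candidates in two genes
#' @param biallelic_hom,biallelic_comphet number of homozygous-founder and
#'   compound-heterozygous EIF2AK4 cases
#' @param planted_cnvs list of `list(gene=, label=, ratio=)` depth events
#' @param n_background number of common known background SNV sites
#' @param depth_mean,depth_size negative-binomial per-target depth model
#' @param titv_known,titv_novel transition:transversion odds per stratum
#' @return validated config list (class `hap_sim_config`)
#' @export
sim_config <- function(n_samples = 300L, seed, qc_fail_fraction = 0.11,
                       carrier_fraction = 0.30, pathogenic_share = 0.5,
                       digenic_pairs = 5L, biallelic_hom = 1L,
                       biallelic_comphet = 1L,
                       planted_cnvs = list(list(gene = "BMPR2",
                                                label = "BMPR2_ex02",
                                                ratio = 1.5)),
                       n_background = 12L, depth_mean = 350,
                       depth_size = 200, titv_known = 3.2,
                       titv_novel = 2.9) {
  if (missing(seed)) stop("seed is mandatory")
  fracs <- c(qc_fail_fraction, carrier_fraction, pathogenic_share)
  if (any(fracs < 0 | fracs > 1)) {
    stop("fractions must lie in [0, 1]")
  }
  if (digenic_pairs + biallelic_hom + biallelic_comphet >
        n_samples * carrier_fraction) {
    stop("more special cases requested than carriers available")
  }
  structure(list(n_samples = as.integer(n_samples), seed = as.integer(seed),
                 qc_fail_fraction = qc_fail_fraction,
                 carrier_fraction = carrier_fraction,
                 pathogenic_share = pathogenic_share,
                 digenic_pairs = as.integer(digenic_pairs),
                 biallelic_hom = as.integer(biallelic_hom),
                 biallelic_comphet = as.integer(biallelic_comphet),
                 planted_cnvs = planted_cnvs,
                 n_background = as.integer(n_background),
                 depth_mean = depth_mean, depth_size = depth_size,
                 titv_known = titv_known, titv_novel = titv_novel),
            class = "hap_sim_config")
}

ti_partner <- function(b) c(A = "G", G = "A", C = "T", T = "C")[b]

#' Draw substitutions at fixed transition:transversion odds
#'
#' Utility behind the Ti/Tv recovery checks: `n` SNVs whose probability of
#' being a transition is `odds / (odds + 1)`.
#'
#' @param n number of substitutions
#' @param odds transition:transversion odds
#' @param seed RNG seed
#' @return data.frame with `ref` and `alt`
#' @export
simulate_substitutions <- function(n, odds, seed) {
  with_seed(seed, {
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    is_ti <- stats::rbinom(n, 1L, odds / (odds + 1)) == 1L
    alt <- character(n)
    alt[is_ti] <- ti_partner(ref[is_ti])
    tv_choices <- list(A = c("C", "T"), G = c("C", "T"),
                       C = c("A", "G"), T = c("A", "G"))
    for (i in which(!is_ti)) {
      alt[i] <- sample(tv_choices[[ref[i]]], 1L)
    }
    data.frame(ref = ref, alt = alt, stringsAsFactors = FALSE)
  })
}

# pick a CDS position at least `margin` bases from the exon edges
random_cds_pos <- function(model, gene, margin = 10L) {
  gm <- model_gene(model, gene)
  ex <- gm$exons
  ok <- ex$c_end - ex$c_start + 1L > 2L * margin
  i <- if (sum(ok) == 1L) which(ok) else sample(which(ok), 1L)
  sample((ex$c_start[i] + margin):(ex$c_end[i] - margin), 1L)
}

plant_truncating <- function(model, gene) {
  cpos <- random_cds_pos(model, gene)
  g <- cdna_to_genomic(model, gene, cpos)
  seq <- contig_seq(model, g$contig)
  b <- substr(seq, g$pos, g$pos)
  v <- normalize_variant(g$pos, b, paste0(b, b), seq)  # 1 bp duplication
  data.frame(chrom = g$contig, pos = v$pos, ref = v$ref, alt = v$alt,
             gene = gene, stringsAsFactors = FALSE)
}

plant_missense <- function(model, gene) {
  gm <- model_gene(model, gene)
  for (try in 1:50) {
    cpos <- random_cds_pos(model, gene)
    idx <- (cpos - 1L) %/% 3L + 1L
    off <- (cpos - 1L) %% 3L + 1L
    codon <- codon_at(model, gene, idx)
    ref <- substr(codon, off, off)
    for (alt in sample(setdiff(c("A", "C", "G", "T"), ref))) {
      newc <- codon
      substr(newc, off, off) <- alt
      if (translate_codon(newc) != "*" &&
          translate_codon(newc) != translate_codon(codon)) {
        g <- cdna_to_genomic(model, gene, cpos)
        return(data.frame(chrom = gm$contig, pos = g$pos, ref = ref,
                          alt = alt, gene = gene, stringsAsFactors = FALSE))
      }
    }
  }
  stop("could not place a missense variant in ", gene)
}

#' Generate a synthetic cohort with planted truth
#'
#' Produces, fully in memory and reproducibly for a given seed: a
#' site-by-sample genotype table backed by the toy transcript model, a
#' per-target depth matrix with planted coverage failures and CNVs,
#' sequencer-level QC metrics, annotation snapshots covering the planted
#' and background sites, a pedigree for the compound-heterozygous family,
#' and the truth set. Planted pathogenic variants are 1 bp frameshift
#' duplications in established genes, absent from all frequency sources;
#' planted VUS are rare missense changes with mixed predictor votes;
#' background sites are common known SNVs drawn at the known-site Ti/Tv
#' odds. QC failures are planted by depressing coverage below the 95%
#' at >= 20x gate on a random 8-20% of target bases.
#'
#' @param config a [sim_config()]
#' @return list of class `hap_cohort`: `samples`, `sites`, `dosage`
#'   (sites x samples), `depth` (a `hap_depth`), `metrics`, `snapshots`,
#'   `ped`, `truth`, `config`
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "hap_sim_config"))
  model <- toy_transcript_model()
  panel <- hap_panel()
  with_seed(config$seed, {
    n <- config$n_samples
    samples <- sprintf("S%03d", seq_len(n))
    n_fail <- floor(n * config$qc_fail_fraction)
    qc_fail <- sort(sample(samples, n_fail))
    qc_pass <- setdiff(samples, qc_fail)

    n_carrier <- round(n * config$carrier_fraction)
    carriers <- sort(sample(samples, n_carrier))
    special_pool <- intersect(carriers, qc_pass)
    n_special <- config$digenic_pairs + config$biallelic_hom +
      config$biallelic_comphet
    special <- sample(special_pool, n_special)
    digenic_samples <- special[seq_len(config$digenic_pairs)]
    hom_samples <- special[config$digenic_pairs +
                             seq_len(config$biallelic_hom)]
    comphet_samples <- special[config$digenic_pairs + config$biallelic_hom +
                                 seq_len(config$biallelic_comphet)]
    plain_carriers <- setdiff(carriers, c(hom_samples, comphet_samples))

    established <- panel$genes$symbol[
      panel$genes$evidence_tier == "established" &
        panel$genes$symbol != "EIF2AK4"]
    all_genes <- panel$genes$symbol

    sites <- list()
    dosage <- list()  # list of (site_index, sample, dosage)
    used <- character(0)
    add_site <- function(v) {
      key <- variant_key(v$chrom, v$pos, v$ref, v$alt)
      hit <- match(key, used)
      if (!is.na(hit)) return(hit)
      used <<- c(used, key)
      sites[[length(sites) + 1L]] <<- v
      length(sites)
    }
    geno <- list()
    add_gt <- function(si, sample, d) {
      geno[[length(geno) + 1L]] <<- list(si = si, s = sample, d = d)
    }

    truth_rows <- list()
    plant_one <- function(s, intended, gene = NULL) {
      if (is.null(gene)) {
        gene <- if (intended == "pathogenic") {
          sample(established, 1L)
        } else sample(all_genes, 1L)
      }
      v <- if (intended == "pathogenic") plant_truncating(model, gene) else
        plant_missense(model, gene)
      si <- add_site(v)
      add_gt(si, s, 1L)
      truth_rows[[length(truth_rows) + 1L]] <<- data.frame(
        sample_id = s, gene = v$gene, chrom = v$chrom, pos = v$pos,
        ref = v$ref, alt = v$alt, intended = intended, digenic = FALSE,
        stringsAsFactors = FALSE)
      v
    }

    for (s in plain_carriers) {
      intended <- if (stats::runif(1) < config$pathogenic_share) {
        "pathogenic"
      } else "vus"
      plant_one(s, intended)
    }
    # second-gene candidate for digenic samples
    for (s in digenic_samples) {
      g1 <- vapply(truth_rows,
                   function(r) if (r$sample_id == s) r$gene else NA_character_,
                   character(1))
      g1 <- g1[!is.na(g1)]
      gene2 <- sample(setdiff(all_genes, g1), 1L)
      plant_one(s, "vus", gene = gene2)
      for (i in seq_along(truth_rows)) {
        if (truth_rows[[i]]$sample_id == s) truth_rows[[i]]$digenic <- TRUE
      }
    }
    # biallelic EIF2AK4 cases (the PVOD mechanism)
    founder <- hgvs_to_vcf("EIF2AK4:NM_001013703.3:c.3344C>T", model)
    stop1 <- hgvs_to_vcf("EIF2AK4:NM_001013703.3:c.3766C>T", model)
    stop2 <- hgvs_to_vcf("EIF2AK4:NM_001013703.3:c.4392dup", model)
    as_site <- function(v) data.frame(chrom = v$chrom, pos = v$pos,
                                      ref = v$ref, alt = v$alt,
                                      gene = v$gene, stringsAsFactors = FALSE)
    for (s in hom_samples) {
      si <- add_site(as_site(founder))
      add_gt(si, s, 2L)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        sample_id = s, gene = "EIF2AK4", chrom = founder$chrom,
        pos = founder$pos, ref = founder$ref, alt = founder$alt,
        intended = "biallelic_hom", digenic = FALSE, stringsAsFactors = FALSE)
    }
    ped_members <- list()
    ped_geno <- list()
    for (s in comphet_samples) {
      si1 <- add_site(as_site(stop1))
      si2 <- add_site(as_site(stop2))
      add_gt(si1, s, 1L)
      add_gt(si2, s, 1L)
      fa <- paste0(s, "_fa"); mo <- paste0(s, "_mo")
      ped_members[[length(ped_members) + 1L]] <- data.frame(
        family_id = paste0("FAM_", s),
        individual_id = c(fa, mo, s),
        father_id = c(NA, NA, fa), mother_id = c(NA, NA, mo),
        sex = c(1L, 2L, sample(1:2, 1L)), affected = c(1L, 1L, 2L),
        stringsAsFactors = FALSE)
      k1 <- variant_key(stop1$chrom, stop1$pos, stop1$ref, stop1$alt)
      k2 <- variant_key(stop2$chrom, stop2$pos, stop2$ref, stop2$alt)
      ped_geno[[length(ped_geno) + 1L]] <- data.frame(
        individual_id = c(fa, mo, s, s), variant = c(k1, k2, k1, k2),
        zygosity = "het", stringsAsFactors = FALSE)
      for (v in list(stop1, stop2)) {
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          sample_id = s, gene = "EIF2AK4", chrom = v$chrom, pos = v$pos,
          ref = v$ref, alt = v$alt, intended = "biallelic_comphet",
          digenic = FALSE, stringsAsFactors = FALSE)
      }
    }
    # common known background sites at the known-site Ti/Tv odds
    bg_af <- stats::runif(config$n_background, 0.05, 0.35)
    for (b in seq_len(config$n_background)) {
      repeat {
        gene <- sample(all_genes, 1L)
        cpos <- random_cds_pos(model, gene)
        g <- cdna_to_genomic(model, gene, cpos)
        seq <- contig_seq(model, g$contig)
        ref <- substr(seq, g$pos, g$pos)
        is_ti <- stats::rbinom(1L, 1L,
                               config$titv_known /
                                 (config$titv_known + 1)) == 1L
        alt <- if (is_ti) unname(ti_partner(ref)) else
          sample(setdiff(c("A", "C", "G", "T"),
                         c(ref, unname(ti_partner(ref)))), 1L)
        key <- variant_key(g$contig, g$pos, ref, alt)
        if (!key %in% used) break
      }
      si <- add_site(data.frame(chrom = g$contig, pos = g$pos, ref = ref,
                                alt = alt, gene = gene,
                                stringsAsFactors = FALSE))
      dos <- stats::rbinom(n, 2L, bg_af[b])
      for (i in which(dos > 0L)) add_gt(si, samples[i], dos[i])
    }

    sites <- do.call(rbind, sites)
    bg_idx <- if (config$n_background > 0L) {
      (nrow(sites) - config$n_background + 1L):nrow(sites)
    } else integer(0)
    sites$is_background <- seq_len(nrow(sites)) %in% bg_idx
    dosage <- matrix(0L, nrow = nrow(sites), ncol = n,
                     dimnames = list(NULL, samples))
    for (gidx in geno) dosage[gidx$si, gidx$s] <- gidx$d

    # depth matrix with planted coverage failures and CNVs
    targets <- panel$regions
    w <- targets$end - targets$start
    lib <- exp(stats::rnorm(n, 0, 0.05))
    depth <- matrix(0, nrow = nrow(targets), ncol = n,
                    dimnames = list(NULL, samples))
    for (j in seq_len(n)) {
      depth[, j] <- stats::rnbinom(nrow(targets),
                                   mu = config$depth_mean * lib[j],
                                   size = config$depth_size)
    }
    for (s in qc_fail) {
      frac_low <- stats::runif(1, 0.08, 0.20)
      ord <- sample(nrow(targets))
      cum <- cumsum(w[ord]) / sum(w)
      low <- ord[seq_len(which(cum >= frac_low)[1])]
      depth[low, s] <- stats::rnbinom(length(low), mu = 8, size = 50)
    }
    cnv_truth <- list()
    cnv_candidates <- setdiff(qc_pass, c(carriers, qc_fail))
    for (ev in config$planted_cnvs) {
      s <- sample(cnv_candidates, 1L)
      cnv_candidates <- setdiff(cnv_candidates, s)
      rows <- which(targets$label == ev$label)
      depth[rows, s] <- round(depth[rows, s] * ev$ratio)
      cnv_truth[[length(cnv_truth) + 1L]] <- data.frame(
        sample_id = s, gene = ev$gene, label = ev$label, ratio = ev$ratio,
        kind = if (ev$ratio > 1) "gain" else "loss", stringsAsFactors = FALSE)
    }

    metrics <- data.frame(
      sample_id = samples,
      total_reads = round(stats::runif(n, 8e5, 1.6e6)),
      on_target_fraction = stats::runif(n, 0.75, 0.92),
      duplicate_fraction = stats::runif(n, 0.03, 0.12),
      error_rate = stats::runif(n, 0.002, 0.006),
      stringsAsFactors = FALSE)

    truth_plants <- do.call(rbind, truth_rows)
    # snapshots: background sites carry frequencies and dbSNP-like ids;
    # planted VUS carry mixed predictor votes; plants stay absent from
    # every frequency source
    bg <- sites[sites$is_background, , drop = FALSE]
    freq <- rbind(
      data.frame(chrom = bg$chrom, pos = bg$pos, ref = bg$ref, alt = bg$alt,
                 source = "gnomad_exomes_like",
                 af = round(bg_af * stats::runif(config$n_background,
                                                 0.9, 1.1), 5),
                 stringsAsFactors = FALSE),
      data.frame(chrom = bg$chrom, pos = bg$pos, ref = bg$ref, alt = bg$alt,
                 source = "thousand_genomes_like", af = round(bg_af, 5),
                 stringsAsFactors = FALSE))
    vus <- truth_plants[truth_plants$intended == "vus", , drop = FALSE]
    vus <- vus[!duplicated(variant_key(vus$chrom, vus$pos, vus$ref,
                                       vus$alt)), , drop = FALSE]
    pred <- data.frame(chrom = vus$chrom, pos = vus$pos, ref = vus$ref,
                       alt = vus$alt, n_deleterious = 3L, n_total = 10L,
                       cadd_like = round(stats::runif(nrow(vus), 10, 20), 1),
                       stringsAsFactors = FALSE)
    clin <- data.frame(chrom = founder$chrom, pos = founder$pos,
                       ref = founder$ref, alt = founder$alt,
                       assertion = "pathogenic_reported",
                       stringsAsFactors = FALSE)
    known <- data.frame(chrom = bg$chrom, pos = bg$pos, ref = bg$ref,
                        alt = bg$alt,
                        dbsnp_id = sprintf("rs%07d",
                                           sample.int(9.9e6,
                                                      nrow(bg))),
                        stringsAsFactors = FALSE)
    snapshots <- structure(list(freq = freq, pred = pred, clin = clin,
                                known = known), class = "hap_snapshots")
    ped <- if (length(ped_members)) {
      pedigree(do.call(rbind, ped_members), do.call(rbind, ped_geno))
    } else NULL

    structure(list(
      samples = samples,
      sites = sites,
      dosage = dosage,
      depth = depth_matrix(targets, depth),
      metrics = metrics,
      snapshots = snapshots,
      ped = ped,
      truth = list(qc_fail = qc_fail, plants = truth_plants,
                   digenic_samples = sort(digenic_samples),
                   hom_samples = hom_samples,
                   comphet_samples = comphet_samples,
                   cnvs = if (length(cnv_truth)) do.call(rbind, cnv_truth)
                   else NULL),
      config = config), class = "hap_cohort")
  })
}

#' Write a generated cohort to disk
#'
#' Emits the file set the pipeline consumes: `cohort.vcf` (VCF 4.2 with
#' GT:GQ:DP), `depths.tsv`, `metrics.tsv`, `families.ped`,
#' `genotypes.tsv` (pedigree carrier map), `snapshots/` (the four
#' annotation snapshot TSVs) and `truth.tsv`. Deterministic given the
#' cohort object.
#'
#' @param cohort a `hap_cohort` from [generate_cohort()]
#' @param dir output directory (created if needed)
#' @return invisibly, `dir`
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "hap_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "snapshots"), showWarnings = FALSE)
  model <- toy_transcript_model()

  sites <- cohort$sites
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  dosage <- cohort$dosage[ord, , drop = FALSE]
  gq <- 99L
  with_seed(cohort$config$seed + 1L, {
    dp <- matrix(stats::rnbinom(length(dosage), mu = cohort$config$depth_mean,
                                size = cohort$config$depth_size),
                 nrow = nrow(dosage))
  })
  gt_str <- matrix("0/0", nrow = nrow(dosage), ncol = ncol(dosage))
  gt_str[dosage == 1L] <- "0/1"
  gt_str[dosage == 2L] <- "1/1"
  cells <- matrix(paste0(gt_str, ":", gq, ":", dp), nrow = nrow(dosage))

  hdr <- c("##fileformat=VCFv4.2",
           "##source=hapanel_synthetic_cohort",
           vapply(names(model$genes), function(g) {
             sprintf("##contig=<ID=%s,length=%d>", model$genes[[g]]$contig,
                     nchar(model$genes[[g]]$seq))
           }, character(1)),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", cohort$samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(sites)), function(i) {
    paste(c(sites$chrom[i], sites$pos[i], ".", sites$ref[i], sites$alt[i],
            "100", "PASS", ".", "GT:GQ:DP", cells[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), file.path(dir, "cohort.vcf"))

  write_depth_matrix(cohort$depth, file.path(dir, "depths.tsv"))
  write_tsv(cohort$metrics, file.path(dir, "metrics.tsv"))
  write_tsv(cohort$snapshots$freq, file.path(dir, "snapshots", "freq.tsv"))
  write_tsv(cohort$snapshots$pred,
            file.path(dir, "snapshots", "predictors.tsv"))
  write_tsv(cohort$snapshots$clin,
            file.path(dir, "snapshots", "clinical.tsv"))
  write_tsv(cohort$snapshots$known,
            file.path(dir, "snapshots", "known_sites.tsv"))
  write_tsv(cohort$truth$plants, file.path(dir, "truth.tsv"))
  if (!is.null(cohort$ped)) {
    ped <- cohort$ped$members
    ped$father_id[is.na(ped$father_id)] <- "0"
    ped$mother_id[is.na(ped$mother_id)] <- "0"
    utils::write.table(ped, file.path(dir, "families.ped"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    write_tsv(cohort$ped$genotypes, file.path(dir, "genotypes.tsv"))
  }
  invisible(dir)
}
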