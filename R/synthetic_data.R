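#' Simulation configuration for the synthetic cohort generator
#'
#' Defaults emulate the structure of a large targeted-panel dyslipidemia
#' cohort: a phenotype mix dominated by hypertriglyceridemia (40.1%) and
#' familial hypercholesterolemia (28.3%), per-phenotype rare-variant
#' carrier rates near the reported carriage fractions, a normolipidemic
#' score reference of 503 samples, and negative-binomial capture depth
#' around 200x.
#'
#' @param seed integer seed; all randomness in a simulation flows from it
#' @param n_patients number of patient samples (default 200)
#' @param n_reference size of the normolipidemic score reference cohort
#'   (default 503)
#' @param n_depth_reference CNV-free samples appended to the depth matrix
#'   as the caller's reference panel (default 20)
#' @param phenotype_mix named fractions summing to 1
#' @param carrier_rate named per-phenotype probability that a patient
#'   carries a causal rare variant in a phenotype-set gene
#' @param extreme_enrichment odds multiplier applied to trait-raising
#'   allele draws at the phenotype-matched trait's score SNPs in affected
#'   patients (1 = no enrichment)
#' @param depth_mean,depth_dispersion negative-binomial mean and size for
#'   per-target read depth
#' @param cnv_spikes data frame of CNVs to embed: columns `gene`,
#'   `first_label`, `last_label`, `state`, `n_carriers`
#' @param annotation_noise_rate probability that a causal variant's
#'   annotation is corrupted (one prediction tool flipped to benign)
#' @return a list of class `sim_config`
#' @export
sim_config <- function(seed = 1L,
                       n_patients = 200L,
                       n_reference = 503L,
                       n_depth_reference = 20L,
                       phenotype_mix = c(HTG = 0.401, FH = 0.283,
                                         hypoalphalipoproteinemia = 0.06,
                                         lipodystrophy = 0.04,
                                         MODY = 0.034, high_Lpa = 0.05,
                                         unclassified = 0.132),
                       carrier_rate = c(FH = 0.425, HTG = 0.239,
                                        hypoalphalipoproteinemia = 0.30,
                                        lipodystrophy = 0.50, MODY = 0.50,
                                        high_Lpa = 0, unclassified = 0.05),
                       extreme_enrichment = 1.3,
                       depth_mean = 200, depth_dispersion = 1000,
                       cnv_spikes = NULL,
                       annotation_noise_rate = 0.02) {
  if (abs(sum(phenotype_mix) - 1) > 1e-8) {
    stop("phenotype_mix fractions must sum to 1 (got ", sum(phenotype_mix),
         ")")
  }
  if (extreme_enrichment <= 0) stop("extreme_enrichment must be positive")
  if (is.null(cnv_spikes)) {
    cnv_spikes <- data.frame(gene = character(0), first_label = character(0),
                             last_label = character(0), state = character(0),
                             n_carriers = integer(0))
  }
  structure(list(seed = as.integer(seed),
                 n_patients = as.integer(n_patients),
                 n_reference = as.integer(n_reference),
                 n_depth_reference = as.integer(n_depth_reference),
                 phenotype_mix = phenotype_mix,
                 carrier_rate = carrier_rate,
                 extreme_enrichment = extreme_enrichment,
                 depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 cnv_spikes = cnv_spikes,
                 annotation_noise_rate = annotation_noise_rate),
            class = "sim_config")
}

#' Simulate the normolipidemic score reference cohort
#'
#' Genotypes at every score SNP are drawn under Hardy-Weinberg equilibrium
#' from the configured allele frequencies; reference samples carry no rare
#' variants and no CNVs. Seeded from `cfg$seed`; identical configs give
#' identical output.
#'
#' @param cfg a [sim_config()]
#' @param panel a `lipid_panel`
#' @return list with `genotypes` (samples x SNPs matrix of trait-raising
#'   allele counts), `scores` (all-trait score results) and `ref_scores`
#'   (named list trait -> raw-score vector)
#' @export
simulate_reference <- function(cfg, panel) {
  stopifnot(inherits(cfg, "sim_config"), inherits(panel, "lipid_panel"))
  set.seed(cfg$seed)
  sim_reference_(cfg, panel)
}

sim_reference_ <- function(cfg, panel) {
  snps <- panel$score_snps
  ids <- sprintf("ref_%04d", seq_len(cfg$n_reference))
  geno <- hwe_genotypes(cfg$n_reference, snps$ref_allele_freq)
  dimnames(geno) <- list(ids, snps$snp_id)
  scores <- do.call(rbind, lapply(SCORE_TRAITS, function(tt) {
    score_cohort(geno[, snps$trait == tt, drop = FALSE],
                 snps[snps$trait == tt, , drop = FALSE])
  }))
  ref_scores <- lapply(stats::setNames(SCORE_TRAITS, SCORE_TRAITS),
                       function(tt) scores$raw_score[scores$trait == tt])
  list(genotypes = geno, scores = scores, ref_scores = ref_scores)
}

hwe_genotypes <- function(n, freqs) {
  if (any(freqs < 0 | freqs > 1)) {
    stop("allele frequencies must lie in [0, 1]")
  }
  vapply(freqs, function(f) stats::rbinom(n, 2L, f), numeric(n))
}

#' Simulate a patient cohort with known ground truth
#'
#' Generates, per patient: a referral phenotype from the configured mix;
#' with the per-phenotype carrier probability, a causal rare variant in a
#' phenotype-set gene (protein-altering ontology, CADD >= 10, at least one
#' damaging tool call, rare or database-absent MAF; homozygous when the
#' gene is recessive); benign/common filter-fodder variants drawn from a
#' shared pool; score-SNP genotypes under HWE with trait-raising odds
#' multiplied by `extreme_enrichment` at the phenotype-matched trait in
#' affected patients; lipids built from a phenotype baseline plus a
#' polygenic-score contribution, a large rare-variant effect and Gaussian
#' noise; and per-target negative-binomial read depth with embedded CNV
#' depth multipliers (0.5 heterozygous deletion, 0.05 homozygous deletion,
#' 1.5 duplication) for spiked carriers. The depth matrix additionally
#' carries `cfg$n_depth_reference` CNV-free reference samples.
#'
#' Seeded from `cfg$seed`. The returned `truth` table records each
#' sample's spiked facts and the resulting true profile category and
#' diagnosis.
#'
#' @param cfg a [sim_config()]
#' @param panel a `lipid_panel`
#' @param reference output of [simulate_reference()]; generated internally
#'   (from the same seed stream) when `NULL`
#' @return list with elements `variants` (annotated-variant records),
#'   `annotation` (unique-variant annotation table), `geno` (score-SNP
#'   genotype matrix), `scores` (all-trait score results with extreme
#'   flags), `depth` (a `depth_matrix`), `depth_reference_samples`,
#'   `lipids`, `truth`, and `reference`
#' @export
simulate_patients <- function(cfg, panel, reference = NULL) {
  stopifnot(inherits(cfg, "sim_config"), inherits(panel, "lipid_panel"))
  set.seed(cfg$seed)
  if (is.null(reference)) reference <- sim_reference_(cfg, panel)
  sim_patients_(cfg, panel, reference)
}

sim_patients_ <- function(cfg, panel, reference) {
  n <- cfg$n_patients
  ids <- sprintf("P%04d", seq_len(n))
  mix <- cfg$phenotype_mix
  phenotype <- sample(names(mix), n, replace = TRUE, prob = mix)

  # --- causal rare variants -------------------------------------------
  carrier_p <- ifelse(phenotype %in% names(cfg$carrier_rate),
                      cfg$carrier_rate[phenotype], 0)
  carrier <- stats::runif(n) < carrier_p
  causal <- vector("list", n)
  for (i in which(carrier)) {
    gene_set <- phenotype_gene_set(panel, phenotype[i])
    if (length(gene_set) == 0) { carrier[i] <- FALSE; next }
    gene <- sample(gene_set, 1)
    causal[[i]] <- make_causal_variant(panel, gene, ids[i])
  }
  causal_df <- do.call(rbind, causal[!vapply(causal, is.null, logical(1))])

  # --- benign/common filter fodder, from a shared pool ----------------
  pool <- make_fodder_pool(panel, n_pool = 80L)
  fodder <- list()
  for (i in seq_len(n)) {
    k <- stats::rpois(1, 3)
    if (k == 0) next
    pick <- sample(nrow(pool), min(k, nrow(pool)))
    f <- pool[pick, , drop = FALSE]
    f$sample_id <- ids[i]
    f$zygosity <- ifelse(stats::runif(nrow(f)) < 0.2, "homozygous",
                         "heterozygous")
    fodder[[length(fodder) + 1L]] <- f
  }
  fodder_df <- do.call(rbind, fodder)
  variants <- rbind(causal_df, fodder_df)
  variants <- variants[order(variants$sample_id, variants$chromosome,
                             variants$position), , drop = FALSE]
  rownames(variants) <- NULL

  # --- annotation noise: flip one tool call on a causal variant -------
  noisy <- rep(FALSE, n)
  if (cfg$annotation_noise_rate > 0 && !is.null(causal_df)) {
    for (i in which(carrier)) {
      if (stats::runif(1) >= cfg$annotation_noise_rate) next
      row <- which(variants$sample_id == ids[i] &
                     variants$gene == causal[[i]]$gene &
                     variants$position == causal[[i]]$position)[1]
      variants$sift[row] <- "tolerated"
      variants$polyphen2[row] <- "benign"
      variants$mutation_taster[row] <- "polymorphism"
      variants$consequence[row] <- "missense"  # strip any LOF bypass
      noisy[i] <- TRUE
    }
  }
  variants <- validate_annotated_variants(variants)

  # --- score-SNP genotypes with enrichment ----------------------------
  snps <- panel$score_snps
  geno <- matrix(NA_real_, n, nrow(snps), dimnames = list(ids, snps$snp_id))
  matched <- vapply(phenotype, trait_for_phenotype, "")
  for (i in seq_len(n)) {
    f <- snps$ref_allele_freq
    enrich <- phenotype[i] != "unclassified" & snps$trait == matched[i]
    m <- cfg$extreme_enrichment
    f[enrich] <- m * f[enrich] / (1 + (m - 1) * f[enrich])
    geno[i, ] <- stats::rbinom(nrow(snps), 2L, f)
  }
  scores <- do.call(rbind, lapply(SCORE_TRAITS, function(tt) {
    score_cohort(geno[, snps$trait == tt, drop = FALSE],
                 snps[snps$trait == tt, , drop = FALSE],
                 ref_scores = reference$ref_scores[[tt]])
  }))

  # --- CNV spikes and depth matrix ------------------------------------
  targets <- panel_targets(panel)
  spikes <- assign_spikes(cfg$cnv_spikes, phenotype, ids, panel)
  ref_ids <- sprintf("dref_%02d", seq_len(cfg$n_depth_reference))
  depth <- simulate_depth(cfg, targets, c(ids, ref_ids), spikes)

  # --- lipids ----------------------------------------------------------
  lipids <- simulate_lipids(phenotype, carrier, scores, reference, ids)

  # --- ground truth -----------------------------------------------------
  truth <- build_truth(ids, phenotype, carrier, causal, spikes, scores,
                       matched, noisy, panel)

  list(variants = variants,
       annotation = annotation_from_variants(variants),
       geno = geno, scores = scores,
       depth = depth, depth_reference_samples = ref_ids,
       lipids = lipids, truth = truth, reference = reference)
}

random_bases <- function(k, not = NULL) {
  b <- c("A", "C", "G", "T")
  if (!is.null(not)) b <- setdiff(b, not)
  sample(b, k, replace = TRUE)
}

make_causal_variant <- function(panel, gene, sample_id) {
  g <- panel$genes[panel$genes$symbol == gene, ]
  iv <- g$intervals[[1]]
  j <- sample(nrow(iv), 1)
  pos <- sample(iv$start[j]:iv$end[j], 1)
  cons <- sample(c("missense", "frameshift", "stop_gain", "splice_donor",
                   "splice_acceptor", "inframe_indel"), 1,
                 prob = c(0.55, 0.15, 0.12, 0.06, 0.06, 0.06))
  ref <- random_bases(1)
  alt <- if (cons %in% c("frameshift", "inframe_indel")) {
    paste0(ref, paste(random_bases(if (cons == "frameshift") 1 else 3),
                      collapse = ""))
  } else random_bases(1, not = ref)
  zyg <- if (g$inheritance == "recessive") "homozygous" else "heterozygous"
  is_mis <- cons %in% c("missense", "inframe_indel")
  data.frame(
    sample_id = sample_id, gene = gene, chromosome = g$chromosome,
    position = pos, ref_allele = ref, alt_allele = alt, zygosity = zyg,
    consequence = cons,
    population_maf = if (stats::runif(1) < 0.5) NA_real_
                     else stats::runif(1, 0, 0.01),
    cadd_phred = round(stats::runif(1, 12, 40), 1),
    sift = if (is_mis) "deleterious" else "unknown",
    polyphen2 = if (is_mis && stats::runif(1) < 0.8) "damaging"
                else "unknown",
    mutation_taster = if (stats::runif(1) < 0.7) "disease_causing"
                      else "unknown",
    stringsAsFactors = FALSE)
}

make_fodder_pool <- function(panel, n_pool = 80L) {
  g <- panel$genes
  rows <- lapply(seq_len(n_pool), function(k) {
    gi <- sample(nrow(g), 1)
    iv <- g$intervals[[gi]]
    j <- sample(nrow(iv), 1)
    pos <- sample(iv$start[j]:iv$end[j], 1)
    kind <- sample(c("common_missense", "rare_synonymous", "rare_benign"),
                   1, prob = c(0.4, 0.3, 0.3))
    ref <- random_bases(1)
    data.frame(
      sample_id = NA_character_, gene = g$symbol[gi],
      chromosome = g$chromosome[gi], position = pos, ref_allele = ref,
      alt_allele = random_bases(1, not = ref), zygosity = NA_character_,
      consequence = switch(kind, common_missense = "missense",
                           rare_synonymous = "synonymous",
                           rare_benign = "missense"),
      population_maf = switch(kind,
                              common_missense = stats::runif(1, 0.05, 0.4),
                              stats::runif(1, 0, 0.01)),
      cadd_phred = round(stats::runif(1, 0, 9.9), 1),
      sift = "tolerated", polyphen2 = "benign",
      mutation_taster = "polymorphism", stringsAsFactors = FALSE)
  })
  pool <- do.call(rbind, rows)
  pool[!duplicated(variant_key(pool)), , drop = FALSE]
}

assign_spikes <- function(cnv_spikes, phenotype, ids, panel) {
  if (nrow(cnv_spikes) == 0) {
    return(data.frame(sample_id = character(0), gene = character(0),
                      first_label = character(0), last_label = character(0),
                      state = character(0), stringsAsFactors = FALSE))
  }
  targets <- panel_targets(panel)
  out <- list()
  taken <- character(0)
  for (r in seq_len(nrow(cnv_spikes))) {
    sp <- cnv_spikes[r, ]
    tg <- targets[targets$gene == sp$gene, ]
    if (nrow(tg) == 0) stop("CNV spike gene not on panel: ", sp$gene)
    if (!sp$first_label %in% tg$label || !sp$last_label %in% tg$label) {
      stop("CNV spike region ", sp$first_label, " - ", sp$last_label,
           " not among ", sp$gene, " targets")
    }
    # prefer carriers whose phenotype set contains the gene
    match_ph <- vapply(phenotype, function(ph)
      sp$gene %in% phenotype_gene_set(panel, ph), logical(1))
    cand <- setdiff(ids[match_ph], taken)
    if (length(cand) < sp$n_carriers) {
      cand <- c(cand, setdiff(ids, c(cand, taken)))
    }
    chosen <- sample(cand, sp$n_carriers)
    taken <- c(taken, chosen)
    out[[r]] <- data.frame(sample_id = chosen, gene = sp$gene,
                           first_label = sp$first_label,
                           last_label = sp$last_label, state = sp$state,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

simulate_depth <- function(cfg, targets, samples, spikes) {
  nt <- nrow(targets)
  eff <- exp(stats::rnorm(nt, 0, 0.3))        # per-target capture efficiency
  lib <- exp(stats::rnorm(length(samples), 0, 0.15))  # library size factors
  ratio_of <- c(het_deletion = 0.5, hom_deletion = 0.05, duplication = 1.5)
  copy <- matrix(1, nt, length(samples), dimnames = list(NULL, samples))
  for (r in seq_len(nrow(spikes))) {
    idx <- which(targets$gene == spikes$gene[r])
    lab <- targets$label[idx]
    i1 <- idx[match(spikes$first_label[r], lab)]
    i2 <- idx[match(spikes$last_label[r], lab)]
    copy[i1:i2, spikes$sample_id[r]] <- ratio_of[[spikes$state[r]]]
  }
  mu <- outer(cfg$depth_mean * eff, lib) * copy
  d <- matrix(stats::rnbinom(length(mu), size = cfg$depth_dispersion,
                             mu = mu),
              nt, length(samples), dimnames = list(NULL, samples))
  depth_matrix(targets, d)
}

simulate_lipids <- function(phenotype, carrier, scores, reference, ids) {
  n <- length(ids)
  zs <- function(trait) {
    ref <- reference$ref_scores[[trait]]
    raw <- scores$raw_score[scores$trait == trait][match(ids,
             scores$sample_id[scores$trait == trait])]
    (raw - mean(ref)) / stats::sd(ref)
  }
  z_ldl <- zs("LDL"); z_tg <- zs("TG"); z_hdl <- zs("HDL")
  ldl <- 3.0 + 0.55 * z_ldl + stats::rnorm(n, 0, 0.4)
  tg <- 1.2 + 0.45 * z_tg + stats::rnorm(n, 0, 0.35)
  hdl <- 1.3 + 0.15 * z_hdl + stats::rnorm(n, 0, 0.15)
  lpa <- pmax(stats::rlnorm(n, log(12), 0.6), 0.5)

  fh_like <- phenotype %in% c("FH", "familial_combined")
  htg_like <- phenotype %in% c("HTG", "severe_HTG", "familial_combined")
  ldl <- ldl + 2.4 * fh_like + 1.6 * (carrier & fh_like)
  tg <- tg + 1.4 * htg_like + 4.0 * (carrier & htg_like) +
    9.0 * (phenotype == "severe_HTG")
  hdl <- hdl - 0.6 * (phenotype == "hypoalphalipoproteinemia")
  lpa[phenotype == "high_Lpa"] <-
    stats::rlnorm(sum(phenotype == "high_Lpa"), log(60), 0.3)

  data.frame(
    sample_id = ids,
    total_chol = pmax(round(ldl + hdl + 0.45 * pmax(tg, 0), 2), 0.5),
    ldl_chol = pmax(round(ldl, 2), 0.3),
    hdl_chol = pmax(round(hdl, 2), 0.1),
    triglyceride = pmax(round(tg, 2), 0.2),
    lpa = round(lpa, 1),
    referral_phenotype = phenotype,
    prior_diagnosis = fh_like & stats::runif(n) < 0.7,
    stringsAsFactors = FALSE)
}

build_truth <- function(ids, phenotype, carrier, causal, spikes, scores,
                        matched, noisy, panel) {
  n <- length(ids)
  truth <- data.frame(
    sample_id = ids, phenotype = phenotype, carrier = carrier,
    causal_gene = NA_character_, causal_zygosity = NA_character_,
    cnv_gene = NA_character_, cnv_region = NA_character_,
    cnv_state = NA_character_,
    matched_trait = matched, extreme = FALSE,
    annotation_noisy = noisy,
    category = NA_character_, diagnosis = NA_character_,
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (carrier[i]) {
      truth$causal_gene[i] <- causal[[i]]$gene
      truth$causal_zygosity[i] <- causal[[i]]$zygosity
    }
    sp <- spikes[spikes$sample_id == ids[i], , drop = FALSE]
    if (nrow(sp) > 0) {
      truth$cnv_gene[i] <- sp$gene[1]
      truth$cnv_region[i] <- paste(sp$first_label[1], "-", sp$last_label[1])
      truth$cnv_state[i] <- sp$state[1]
    }
    sc <- scores[scores$sample_id == ids[i] & scores$trait == matched[i], ]
    truth$extreme[i] <- isTRUE(sc$extreme[1])
    gene_set <- phenotype_gene_set(panel, phenotype[i])
    fnd <- data.frame(gene = character(0), zygosity = character(0))
    if (carrier[i]) {
      fnd <- rbind(fnd, data.frame(gene = truth$causal_gene[i],
                                   zygosity = truth$causal_zygosity[i]))
    }
    if (!is.na(truth$cnv_gene[i]) && truth$cnv_gene[i] %in% gene_set) {
      fnd <- rbind(fnd, data.frame(
        gene = truth$cnv_gene[i],
        zygosity = ifelse(truth$cnv_state[i] == "hom_deletion",
                          "homozygous", "heterozygous")))
    }
    truth$category[i] <- classify_profile(nrow(fnd), truth$extreme[i])
    truth$diagnosis[i] <- apply_diagnosis_rules(fnd, phenotype[i])
  }
  truth
}

annotation_from_variants <- function(variants) {
  u <- unique_variants(variants)
  data.frame(chrom = u$chromosome, pos = u$position, ref = u$ref_allele,
             alt = u$alt_allele, gene = u$gene, consequence = u$consequence,
             maf = u$population_maf, cadd_phred = u$cadd_phred,
             sift = u$sift, polyphen2 = u$polyphen2,
             mutation_taster = u$mutation_taster, stringsAsFactors = FALSE)
}

#' Write a simulated cohort to disk in standard formats
#'
#' Emits: the patient rare-variant VCF plus annotation TSV, the score-SNP
#' genotype VCFs for patients and reference, per-trait reference score
#' TSVs, the depth matrix TSV, the lipid TSV and the truth table as JSON.
#'
#' @param sim output of [simulate_patients()]
#' @param dir output directory (created if needed)
#' @param panel the `lipid_panel` used for the simulation
#' @return invisibly, a named list of file paths
#' @export
write_cohort <- function(sim, dir, panel) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    variants_vcf = file.path(dir, "patient_variants.vcf"),
    annotation = file.path(dir, "patient_variants_annotation.tsv"),
    score_vcf = file.path(dir, "patient_score_snps.vcf"),
    reference_vcf = file.path(dir, "reference_score_snps.vcf"),
    depth = file.path(dir, "depth_matrix.tsv"),
    lipids = file.path(dir, "lipids.tsv"),
    truth = file.path(dir, "truth.json"))
  write_variant_vcf(sim$variants, paths$variants_vcf)
  write_annotation_table(sim$annotation, paths$annotation)
  write_genotype_vcf(sim$geno, panel$score_snps, paths$score_vcf)
  write_genotype_vcf(sim$reference$genotypes, panel$score_snps,
                     paths$reference_vcf)
  for (tt in names(sim$reference$ref_scores)) {
    p <- file.path(dir, sprintf("reference_scores_%s.tsv", tt))
    write_reference_scores(sim$reference$ref_scores[[tt]], p)
    paths[[paste0("reference_scores_", tt)]] <- p
  }
  write_depth_matrix(sim$depth, paths$depth)
  utils::write.table(sim$lipids, paths$lipids, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(sim$truth, paths$truth, dataframe = "rows",
                       na = "null")
  invisible(paths)
}

vcf_header <- function(samples) {
  c("##fileformat=VCFv4.2",
    "##source=lipidpanel_synthetic",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

#' Write sample-level variant records as a VCF 4.2 file
#'
#' One row per unique variant, GT columns for every sample present in the
#' records (0/1 heterozygous, 1/1 homozygous, 0/0 non-carrier).
#'
#' @param variants annotated-variant data frame
#' @param path output path
#' @param samples sample column order (default: sorted unique ids)
#' @return invisibly, the path
#' @export
write_variant_vcf <- function(variants, path,
                              samples = sort(unique(variants$sample_id))) {
  u <- unique_variants(variants)
  u <- u[order(chromosome_rank(u$chromosome), u$position, u$ref_allele,
               u$alt_allele), , drop = FALSE]
  ukey <- variant_key(u)
  vkey <- variant_key(variants)
  gt <- matrix("0/0", nrow(u), length(samples),
               dimnames = list(NULL, samples))
  gt[cbind(match(vkey, ukey), match(variants$sample_id, samples))] <-
    ifelse(variants$zygosity == "homozygous", "1/1", "0/1")
  body <- paste(u$chromosome, u$position, ".", u$ref_allele, u$alt_allele,
                ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(vcf_header(samples), body), path)
  invisible(path)
}

#' Write a score-SNP genotype matrix as a VCF 4.2 file
#'
#' Genotype counts are of the trait-raising allele; they are converted to
#' alt-allele genotypes using each SNP's REF/ALT definition.
#'
#' @param geno samples x SNPs matrix of trait-raising allele counts
#' @param snps score-SNP table with `snp_id`, `chromosome`, `position`,
#'   `ref_allele`, `alt_allele`, `trait_raising_allele`
#' @param path output path
#' @return invisibly, the path
#' @export
write_genotype_vcf <- function(geno, snps, path) {
  ord <- order(chromosome_rank(snps$chromosome), snps$position)
  snps <- snps[ord, , drop = FALSE]
  samples <- rownames(geno)
  gt_of <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(snps)), function(j) {
    g <- geno[, snps$snp_id[j]]
    n_alt <- if (snps$trait_raising_allele[j] == snps$alt_allele[j]) g
             else 2 - g
    gts <- ifelse(is.na(n_alt), "./.", gt_of[n_alt + 1])
    paste(c(snps$chromosome[j], snps$position[j], snps$snp_id[j],
            snps$ref_allele[j], snps$alt_allele[j], ".", "PASS", ".", "GT",
            gts), collapse = "\t")
  }, character(1))
  writeLines(c(vcf_header(samples), body), path)
  invisible(path)
}
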