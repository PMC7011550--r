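test_that("a fixed seed reproduces the simulation bit for bit", {
  panel <- default_panel()
  cfg <- sim_config(seed = 5, n_patients = 30, n_reference = 50)
  s1 <- simulate_patients(cfg, panel)
  s2 <- simulate_patients(cfg, panel)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$variants, s2$variants)
  expect_identical(s1$depth$depth, s2$depth$depth)

  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  write_cohort(s1, dir1, panel)
  write_cohort(s2, dir2, panel)
  expect_identical(readLines(file.path(dir1, "patient_variants.vcf")),
                   readLines(file.path(dir2, "patient_variants.vcf")))
  expect_identical(readLines(file.path(dir1, "reference_score_snps.vcf")),
                   readLines(file.path(dir2, "reference_score_snps.vcf")))
})

test_that("reference genotypes follow Hardy-Weinberg within 3 SE", {
  panel <- default_panel()
  cfg <- sim_config(seed = 6, n_reference = 10000)
  ref <- simulate_reference(cfg, panel)
  f <- panel$score_snps$ref_allele_freq
  n <- cfg$n_reference
  for (j in seq_len(5)) {  # check a handful of SNPs in depth
    g <- ref$genotypes[, j]
    exp_p <- c((1 - f[j])^2, 2 * f[j] * (1 - f[j]), f[j]^2)
    obs_p <- c(mean(g == 0), mean(g == 1), mean(g == 2))
    se <- sqrt(exp_p * (1 - exp_p) / n)
    expect_true(all(abs(obs_p - exp_p) <= 3 * se),
                label = sprintf("SNP %d HWE", j))
  }
  # degenerate frequencies collapse to fixed genotypes
  expect_true(all(lipidpanel:::hwe_genotypes(100, 0) == 0))
  expect_true(all(lipidpanel:::hwe_genotypes(100, 1) == 2))
})

test_that("a null cohort (no carriers, no enrichment) is mostly category none", {
  panel <- default_panel()
  cfg <- sim_config(seed = 7, n_patients = 150,
                    carrier_rate = c(FH = 0, HTG = 0,
                                     hypoalphalipoproteinemia = 0,
                                     lipodystrophy = 0, MODY = 0,
                                     high_Lpa = 0, unclassified = 0),
                    extreme_enrichment = 1)
  sim <- simulate_patients(cfg, panel)
  expect_true(all(!sim$truth$carrier))
  frac_none <- mean(sim$truth$category == "none")
  # everything except the ~10% extreme base rate should be 'none'
  expect_gte(frac_none, 1 - 0.10 - 3 * sqrt(0.1 * 0.9 / 150))
  expect_true(all(sim$truth$category %in% c("none", "extreme_only")))
})

test_that("generated files round-trip through the io layer", {
  panel <- default_panel()
  cfg <- sim_config(seed = 8, n_patients = 25, n_reference = 40)
  sim <- simulate_patients(cfg, panel)
  dir <- withr::local_tempdir()
  paths <- write_cohort(sim, dir, panel)

  back <- read_annotated_variants(paths$variants_vcf, paths$annotation)
  ord <- function(x) {
    x <- x[order(x$sample_id, x$chromosome, x$position, x$alt_allele), ]
    rownames(x) <- NULL
    x[, sort(names(x))]
  }
  expect_equal(ord(back), ord(sim$variants))

  geno <- score_genotypes_from_vcf(paths$score_vcf, panel$score_snps)
  expect_equal(geno[rownames(sim$geno), colnames(sim$geno)], sim$geno)

  dm <- read_depth_matrix(paths$depth)
  expect_equal(dm$depth, sim$depth$depth)
})

test_that("spiked CNVs are recovered by the caller with exact state", {
  panel <- default_panel()
  spikes <- data.frame(gene = "LDLR", first_label = "Exon 2",
                       last_label = "Exon 6", state = "het_deletion",
                       n_carriers = 5L)
  cfg <- sim_config(seed = 9, n_patients = 40, cnv_spikes = spikes)
  sim <- simulate_patients(cfg, panel)
  carriers <- sim$truth$sample_id[!is.na(sim$truth$cnv_gene)]
  expect_length(carriers, 5)
  hits <- 0
  for (s in carriers) {
    calls <- call_cnvs(sim$depth, s, sim$depth_reference_samples)
    ok <- any(calls$gene == "LDLR" & calls$state == "het_deletion" &
                calls$region == "Exons 2-6")
    hits <- hits + ok
  }
  expect_gte(hits, 4)  # >= 4/5 at default caller parameters
})

test_that("the full pipeline reproduces the truth table on a noise-free cohort", {
  panel <- default_panel()
  spikes <- data.frame(gene = c("LDLR", "PCSK9"),
                       first_label = c("Exon 2", "5'UTR"),
                       last_label = c("Exon 6", "3'UTR"),
                       state = c("het_deletion", "duplication"),
                       n_carriers = c(3L, 2L))
  cfg <- sim_config(seed = 10, n_patients = 80, annotation_noise_rate = 0,
                    cnv_spikes = spikes)
  sim <- simulate_patients(cfg, panel)
  dir <- withr::local_tempdir()
  paths <- write_cohort(sim, dir, panel)

  # run every stage from the files, as the pipeline would
  variants <- read_annotated_variants(paths$variants_vcf, paths$annotation)
  geno <- score_genotypes_from_vcf(paths$score_vcf, panel$score_snps)
  ref_scores <- lapply(setNames(c("LDL", "TG", "HDL"),
                                c("LDL", "TG", "HDL")), function(tt)
    read_reference_scores(paths[[paste0("reference_scores_", tt)]]))
  snps <- panel$score_snps
  scores <- do.call(rbind, lapply(names(ref_scores), function(tt)
    score_cohort(geno[, snps$trait == tt, drop = FALSE],
                 snps[snps$trait == tt, , drop = FALSE],
                 ref_scores = ref_scores[[tt]])))
  dm <- read_depth_matrix(paths$depth)
  lipids <- read.delim(paths$lipids, stringsAsFactors = FALSE)
  calls <- do.call(rbind, lapply(lipids$sample_id, function(s)
    call_cnvs(dm, s, sim$depth_reference_samples)))
  prof <- build_genetic_profiles(variants, calls, scores, lipids, panel)

  truth <- sim$truth[match(prof$sample_id, sim$truth$sample_id), ]
  expect_equal(prof$category, truth$category)
  expect_equal(prof$diagnosis, truth$diagnosis)
  expect_equal(prof$extreme_score, truth$extreme)
})

test_that("category recovery stays above 95% under default annotation noise", {
  panel <- default_panel()
  cfg <- sim_config(seed = 11, n_patients = 120)  # default noise rate
  sim <- simulate_patients(cfg, panel)
  prof <- build_genetic_profiles(sim$variants, NULL, sim$scores,
                                 sim$lipids, panel)
  truth <- sim$truth[match(prof$sample_id, sim$truth$sample_id), ]
  # noise can only flip causal variants to benign; categories still agree
  agree <- mean(prof$category == truth$category)
  expect_gte(agree, 0.95)
})

test_that("invalid spike regions and mixes are rejected", {
  panel <- default_panel()
  expect_error(sim_config(phenotype_mix = c(FH = 0.5)), "sum to 1")
  bad <- data.frame(gene = "NOPE", first_label = "Exon 1",
                    last_label = "Exon 2", state = "het_deletion",
                    n_carriers = 1L)
  cfg <- sim_config(seed = 12, n_patients = 10, cnv_spikes = bad)
  expect_error(simulate_patients(cfg, panel), "not on panel")
})
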