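test_that("percentages round half away from zero to one decimal", {
  expect_equal(round_half_up(0.05, 1), 0.1)
  expect_equal(round_half_up(-0.05, 1), -0.1)
  expect_equal(round_half_up(42.45, 1), 42.5)
  expect_equal(percent_share(1, 3), 33.3)
  expect_error(percent_share(1, 0), "positive")
})

test_that("unit conversion uses the standard lipid factors", {
  expect_equal(convert_units(1, "cholesterol"), 38.67)
  expect_equal(convert_units(1, "triglyceride"), 88.57)
  expect_equal(convert_units(0, "cholesterol"), 0)
  expect_error(convert_units(-1, "cholesterol"), "negative")
})

test_that("phenotype assignment honors thresholds, boundaries and precedence", {
  lp <- function(ldl = NA, tg = NA, lpa = NA) {
    data.frame(ldl_chol = ldl, triglyceride = tg, lpa = lpa)
  }
  expect_equal(assign_phenotype(lp(tg = 12)), "severe_HTG")
  expect_equal(assign_phenotype(lp(ldl = 7, tg = 12)), "severe_HTG")
  expect_equal(assign_phenotype(lp(ldl = 5.0, tg = 0.8)), "unclassified")
  expect_equal(assign_phenotype(lp(ldl = 5.01)), "FH_suspected")
  expect_equal(assign_phenotype(lp(tg = 1.8)), "HTG")
  expect_equal(assign_phenotype(lp(tg = 1.79)), "unclassified")
  expect_equal(assign_phenotype(lp(ldl = 6, tg = 2.5)), "familial_combined")
  expect_equal(assign_phenotype(lp(ldl = 3, lpa = 36)), "high_Lpa")
  expect_equal(assign_phenotype(lp(ldl = 3, lpa = 35.9)), "unclassified")
  expect_error(assign_phenotype(lp()), "no usable lipid")
})

test_that("the four-way profile category covers its truth table", {
  expect_equal(classify_profile(1, FALSE), "rare_only")
  expect_equal(classify_profile(2, TRUE), "rare_plus_extreme")
  expect_equal(classify_profile(0, TRUE), "extreme_only")
  expect_equal(classify_profile(0, FALSE), "none")
})

test_that("allelic state treats hom or two het variants as biallelic", {
  f <- function(genes, zyg) data.frame(gene = genes, zygosity = zyg)
  expect_equal(unname(allelic_state(f("LDLR", "heterozygous"))),
               "heterozygous")
  expect_equal(unname(allelic_state(f("LDLR", "homozygous"))), "biallelic")
  expect_equal(unname(allelic_state(f(c("LPL", "LPL"),
                                      c("heterozygous", "heterozygous")))),
               "biallelic")
  two_genes <- allelic_state(f(c("LDLR", "APOB"),
                               c("heterozygous", "heterozygous")))
  expect_equal(unname(two_genes[c("LDLR", "APOB")]),
               c("heterozygous", "heterozygous"))
})

test_that("diagnosis rules map gene and zygosity as in clinical practice", {
  f <- function(genes, zyg) data.frame(gene = genes, zygosity = zyg)
  expect_equal(apply_diagnosis_rules(f("LDLR", "heterozygous"), "FH"),
               "HeFH")
  expect_equal(apply_diagnosis_rules(f("LDLR", "homozygous"), "FH"),
               "HoFH")  # biallelic rule outranks HeFH
  expect_equal(apply_diagnosis_rules(f(c("LDLR", "LDLR"),
                                       c("heterozygous", "heterozygous")),
                                     "FH"), "HoFH")
  expect_equal(apply_diagnosis_rules(f("ABCG5", "homozygous"), "FH"),
               "Sitosterolemia")
  expect_equal(apply_diagnosis_rules(f(c("LPL", "LPL"),
                                       c("heterozygous", "heterozygous")),
                                     "HTG"),
               "Familial chylomicronemia syndrome")
  expect_equal(apply_diagnosis_rules(f("APOC2", "homozygous"), "HTG"),
               "APOC2 deficiency")
  expect_equal(apply_diagnosis_rules(f("LMNA", "heterozygous"),
                                     "lipodystrophy"), "FPLD2")
  # het LPL in HTG: carrier, but no biallelic diagnosis
  expect_true(is.na(apply_diagnosis_rules(f("LPL", "heterozygous"), "HTG")))
  expect_true(is.na(apply_diagnosis_rules(f("LDLR", "heterozygous")[0, ],
                                          "FH")))
})

test_that("cohort summaries compute counts, percentages and identities", {
  prof <- cohort_from_counts(rare_only = 354, rare_plus_extreme = 39,
                             extreme_only = 76, none = 455)
  s <- summarize_cohort(prof, "FH")
  expect_equal(attr(s, "n"), 924)
  g <- function(m) s[s$metric == m, ]
  expect_equal(g("any_rare_variant")$count, 393)
  expect_equal(g("any_extreme_ps")$count, 115)
  # category identities: the four categories partition the cohort
  expect_equal(sum(s$count[s$metric %in% c("rare_only", "rare_plus_extreme",
                                           "extreme_only", "none")]), 924)
  expect_equal(g("any_rare_variant")$count,
               g("rare_only")$count + g("rare_plus_extreme")$count)
  expect_equal(g("any_extreme_ps")$count,
               g("extreme_only")$count + g("rare_plus_extreme")$count)

  one <- summarize_cohort(cohort_from_counts(0, 0, 0, 1))
  expect_equal(one[one$metric == "none", "percent"], 100.0)
  expect_error(summarize_cohort(cohort_from_counts(0, 0, 0, 0)), "empty")
})

test_that("profiles synthesize variants, CNVs, scores and rules per sample", {
  panel <- tiny_panel()
  variants <- rbind(
    make_variant("P1"),                                   # relevant LDLR het
    make_variant("P2", gene = "LPL", chromosome = "chr8", position = 250,
                 consequence = "frameshift", zygosity = "homozygous",
                 cadd_phred = 30),                         # biallelic LPL
    make_variant("P3", population_maf = 0.2))              # common: irrelevant
  cnvs <- data.frame(sample_id = "P4", gene = "LDLR", region = "Exons 1-3",
                     state = "het_deletion", breakpoint_tag = NA)
  scores <- expand.grid(sample_id = sprintf("P%d", 1:4),
                        trait = c("LDL", "TG", "HDL"),
                        stringsAsFactors = FALSE)
  scores$raw_score <- 0.5
  scores$allele_tally <- 5L
  scores$n_snps_used <- 3L
  scores$percentile <- 50
  scores$extreme <- FALSE
  scores$extreme[scores$sample_id == "P3" & scores$trait == "TG"] <- TRUE
  lipids <- data.frame(
    sample_id = sprintf("P%d", 1:4),
    ldl_chol = c(6.2, 3.0, 2.8, 6.5),
    triglyceride = c(1.0, 12.0, 2.4, 1.1),
    lpa = NA_real_,
    referral_phenotype = c("FH", "severe_HTG", "HTG", "FH"),
    prior_diagnosis = c(TRUE, FALSE, FALSE, FALSE))

  prof <- build_genetic_profiles(variants, cnvs, scores, lipids, panel)
  expect_equal(prof$category,
               c("rare_only", "rare_only", "extreme_only", "rare_only"))
  expect_equal(prof$diagnosis[1], "HeFH")
  expect_equal(prof$report_category[1], "b_confirmation")  # prior diagnosis
  expect_equal(prof$diagnosis[2], "Familial chylomicronemia syndrome")
  expect_equal(prof$report_category[2], "a_diagnosis")
  expect_true(is.na(prof$diagnosis[3]))
  expect_equal(prof$report_category[3], "c_relevant")
  # CNV counts as a rare variant and feeds the diagnosis rules
  expect_equal(prof$n_rare_cnvs[4], 1L)
  expect_equal(prof$diagnosis[4], "HeFH")
  expect_equal(prof$matched_trait, c("LDL", "TG", "TG", "LDL"))
})
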