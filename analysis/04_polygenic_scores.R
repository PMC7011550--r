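#!/usr/bin/env Rscript
# Step 4: weighted polygenic scores and extreme classification.
#
# Extracts score-SNP genotypes from the cohort VCF, computes the three
# trait scores (LDL cholesterol, triglyceride, HDL cholesterol) for every
# patient, and classifies extreme scores (>= 90th percentile of the
# synthetic normolipidemic reference, nearest rank, inclusive).

suppressPackageStartupMessages(library(lipidpanel))

panel <- default_panel()
snps <- panel$score_snps
geno <- score_genotypes_from_vcf("scratch/cohort/patient_score_snps.vcf",
                                 snps)
traits <- c("LDL", "TG", "HDL")
ref_scores <- lapply(setNames(traits, traits), function(tt)
  read_reference_scores(sprintf("scratch/cohort/reference_scores_%s.tsv",
                                tt)))
scores <- do.call(rbind, lapply(traits, function(tt)
  score_cohort(geno[, snps$trait == tt, drop = FALSE],
               snps[snps$trait == tt, , drop = FALSE],
               ref_scores = ref_scores[[tt]])))

dir.create("results", showWarnings = FALSE)
write.table(scores, "results/04_polygenic_scores.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

for (tt in traits) {
  s <- scores[scores$trait == tt, ]
  cat(sprintf("%s score: mean %.3f, extreme (>= P90 of reference): %d/%d (%.1f%%)\n",
              tt, mean(s$raw_score), sum(s$extreme), nrow(s),
              100 * mean(s$extreme)))
}
cat("Score table written to results/04_polygenic_scores.tsv\n")
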