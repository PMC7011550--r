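#!/usr/bin/env Rscript
# Step 5: per-patient genetic profiles and reports.
#
# Combines prioritized rare variants, CNV calls and phenotype-matched
# extreme-score flags into the four-way genetic profile per patient,
# applies the gene/zygosity diagnosis rules, verifies recovery against the
# generator's truth table, and renders example patient reports.

suppressPackageStartupMessages(library(lipidpanel))

panel <- default_panel()
variants <- read_annotated_variants("scratch/cohort/patient_variants.vcf",
                                    "scratch/cohort/patient_variants_annotation.tsv")
cnv_calls <- read.delim("results/03_cnv_calls.tsv",
                        stringsAsFactors = FALSE)
scores <- read.delim("results/04_polygenic_scores.tsv",
                     stringsAsFactors = FALSE)
lipids <- read.delim("scratch/cohort/lipids.tsv", stringsAsFactors = FALSE)

prof <- build_genetic_profiles(variants, cnv_calls, scores, lipids, panel)

dir.create("results", showWarnings = FALSE)
write.table(prof[, setdiff(names(prof), "findings")],
            "results/05_genetic_profiles.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE, na = "NA")

cat("Profile categories:\n")
print(table(prof$category))
cat("\nDiagnoses assigned:\n")
print(table(prof$diagnosis, useNA = "no"))
cat("\nReport categories:\n")
print(table(prof$report_category))

truth <- jsonlite::fromJSON("scratch/cohort/truth.json")
truth <- truth[match(prof$sample_id, truth$sample_id), ]
agree <- mean(prof$category == truth$category)
cat(sprintf("\nCategory recovery vs generator truth: %.1f%%\n", 100 * agree))

# example reports: one of each report category where available
dir.create("results/reports", showWarnings = FALSE)
for (rc in unique(prof$report_category)) {
  i <- which(prof$report_category == rc)[1]
  txt <- render_report(prof[i, ], scores, "text")
  js <- render_report(prof[i, ], scores, "json")
  writeLines(txt, sprintf("results/reports/%s_%s.txt", prof$sample_id[i], rc))
  writeLines(js, sprintf("results/reports/%s_%s.json", prof$sample_id[i], rc))
}
cat("Example reports written under results/reports/\n")
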