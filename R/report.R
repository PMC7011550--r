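#' Render a per-patient report
#'
#' Produces a deterministic machine-readable (JSON) or human-readable
#' (text) report from a sample's genetic profile. Disclosure follows the
#' phenotype-matched rule: although all three trait scores are computed
#' and stored for every sample, only the score matching the referral
#' phenotype appears on the report, shown both as the weighted polygenic
#' score (with reference percentile) and as the simple tally of
#' trait-raising alleles, which patients tend to find easier to grasp.
#'
#' @param profile one row of [build_genetic_profiles()] output (a
#'   data frame of one row, `findings` list-column included)
#' @param scores all-trait score results for the cohort (see
#'   [score_cohort()]); must contain the sample's phenotype-matched trait
#' @param format `"json"` or `"text"`
#' @return a single character scalar holding the rendered report
#' @export
render_report <- function(profile, scores, format = c("json", "text")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(profile), nrow(profile) == 1)
  sid <- profile$sample_id
  sc <- scores[scores$sample_id == sid &
                 scores$trait == profile$matched_trait, , drop = FALSE]
  if (nrow(sc) == 0) {
    stop("no ", profile$matched_trait, " score result for sample ", sid,
         "; the phenotype-matched score is required for reporting")
  }
  sc <- sc[1, ]
  findings <- profile$findings[[1]]
  doc <- list(
    sample_id = sid,
    referral_phenotype = profile$phenotype,
    report_category = profile$report_category,
    diagnosis = if (is.na(profile$diagnosis)) NULL else profile$diagnosis,
    rare_variant_findings = if (nrow(findings) == 0) list() else
      lapply(seq_len(nrow(findings)), function(i) list(
        gene = findings$gene[i],
        description = findings$description[i],
        zygosity = findings$zygosity[i],
        kind = findings$kind[i])),
    disclosed_score = list(
      trait = sc$trait,
      raw_score = sc$raw_score,
      allele_tally = sc$allele_tally,
      n_snps_used = sc$n_snps_used,
      percentile = sc$percentile,
      extreme = sc$extreme),
    notes = report_notes(profile))
  if (format == "json") {
    as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                  null = "null", pretty = TRUE))
  } else {
    render_report_text(doc)
  }
}

report_notes <- function(profile) {
  switch(profile$report_category,
    a_diagnosis = paste0("Findings support a genetically based diagnosis: ",
                         profile$diagnosis, "."),
    b_confirmation = paste0("Findings provide genetic confirmation of the ",
                            "prior clinical diagnosis: ", profile$diagnosis,
                            "."),
    c_relevant = paste("A relevant genetic result was identified: a",
                       "determinant predicted to be damaging and related to",
                       "the referral phenotype, short of a confirmed",
                       "diagnosis."),
    d_negative = paste("Negative result: we were unable to identify any",
                       "sort of genetic determinant related to the",
                       "phenotype."))
}

render_report_text <- function(doc) {
  s <- doc$disclosed_score
  lines <- c(
    "==========================================================",
    " GENETIC REPORT",
    "==========================================================",
    sprintf("Sample:             %s", doc$sample_id),
    sprintf("Referral phenotype: %s", doc$referral_phenotype),
    sprintf("Report category:    %s", doc$report_category),
    if (!is.null(doc$diagnosis))
      sprintf("Diagnosis:          %s", doc$diagnosis),
    "",
    "Rare variant findings:")
  if (length(doc$rare_variant_findings) == 0) {
    lines <- c(lines, "  (none)")
  } else {
    for (f in doc$rare_variant_findings) {
      lines <- c(lines, sprintf("  - %s: %s [%s, %s]", f$gene,
                                f$description, f$zygosity, f$kind))
    }
  }
  lines <- c(lines, "",
    sprintf("Polygenic score (%s, phenotype-matched):", s$trait),
    sprintf("  Weighted score:      %.4f (over %d SNPs)", s$raw_score,
            s$n_snps_used),
    sprintf("  Trait-raising alleles: %d of %d possible", s$allele_tally,
            2L * s$n_snps_used),
    sprintf("  Reference percentile: %.1f%s", s$percentile,
            if (isTRUE(s$extreme)) "  ** extreme (>= 90th percentile) **"
            else ""),
    "",
    doc$notes,
    "==========================================================")
  paste(lines, collapse = "\n")
}
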