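PROFILE_CATEGORIES <- c("rare_only", "rare_plus_extreme", "extreme_only",
                        "none")

#' Round half away from zero
#'
#' Plain decimal rounding where .5 always moves away from zero (unlike
#' base R's round-half-even), matching how clinical tables are typically
#' typeset: 42.45 -> 42.5 and 393/924 -> 42.5%.
#'
#' @param x numeric vector
#' @param digits decimal places (default 1)
#' @return rounded vector
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage share, rounded as printed in cohort tables
#' @param count numerator count
#' @param total denominator count
#' @param digits decimal places (default 1)
#' @return percentage on the 0-100 scale
#' @export
percent_share <- function(count, total, digits = 1) {
  if (any(total <= 0)) stop("total must be positive")
  round_half_up(100 * count / total, digits)
}

#' Convert lipid concentrations from mmol/L to mg/dL
#'
#' Cholesterol: multiply by 38.67. Triglyceride: multiply by 88.57.
#'
#' @param value concentration(s) in mmol/L, non-negative
#' @param analyte `"cholesterol"` or `"triglyceride"`
#' @return concentration(s) in mg/dL
#' @export
convert_units <- function(value, analyte = c("cholesterol", "triglyceride")) {
  analyte <- match.arg(analyte)
  if (any(value < 0, na.rm = TRUE)) {
    stop("lipid concentrations cannot be negative")
  }
  value * switch(analyte, cholesterol = 38.67, triglyceride = 88.57)
}

#' Assign a referral-style phenotype from lipid values
#'
#' Deterministic, precedence-ordered rules on the routine lipid profile
#' (all in mmol/L except Lp(a) in mg/dL):
#' severe hypertriglyceridemia (TG >= 10), then familial combined
#' hyperlipidemia (LDL > 5.0 and TG >= 1.8), then suspected FH
#' (LDL > 5.0, strict), then hypertriglyceridemia (TG >= 1.8, inclusive),
#' then elevated Lp(a) (>= 36 mg/dL, the population top 5th percentile),
#' else unclassified. In practice phenotypes come from referral; this
#' assignment is used when no referral phenotype accompanies a sample.
#'
#' @param lipids data frame with (possibly `NA`) columns `ldl_chol`,
#'   `triglyceride`, `lpa` (others ignored)
#' @return character vector of phenotype keys, one per row
#' @export
assign_phenotype <- function(lipids) {
  n <- nrow(lipids)
  val <- function(col) {
    if (col %in% names(lipids)) lipids[[col]] else rep(NA_real_, n)
  }
  ldl <- val("ldl_chol"); tg <- val("triglyceride"); lpa <- val("lpa")
  all_null <- is.na(ldl) & is.na(tg) & is.na(lpa)
  if (any(all_null)) {
    stop("sample(s) with no usable lipid values at row(s): ",
         paste(utils::head(which(all_null), 5), collapse = ", "))
  }
  gte <- function(x, thr) !is.na(x) & x >= thr
  gt <- function(x, thr) !is.na(x) & x > thr
  out <- rep("unclassified", n)
  out[gte(lpa, 36)] <- "high_Lpa"
  out[gte(tg, 1.8)] <- "HTG"
  out[gt(ldl, 5.0)] <- "FH_suspected"
  out[gt(ldl, 5.0) & gte(tg, 1.8)] <- "familial_combined"
  out[gte(tg, 10)] <- "severe_HTG"
  out
}

#' Four-way genetic profile category
#'
#' Combines rare-variant findings (SNVs, indels and CNVs all count) with
#' the phenotype-matched extreme polygenic score flag.
#'
#' @param n_rare number of relevant rare findings per sample (or logical)
#' @param extreme logical extreme-score flag per sample
#' @return character vector: `rare_only`, `rare_plus_extreme`,
#'   `extreme_only` or `none`
#' @export
classify_profile <- function(n_rare, extreme) {
  has_rare <- as.numeric(n_rare) > 0
  ifelse(has_rare & extreme, "rare_plus_extreme",
         ifelse(has_rare, "rare_only",
                ifelse(extreme, "extreme_only", "none")))
}

#' Diagnosis rules shipped with the package
#'
#' Gene/zygosity to diagnosis mapping for monogenic dyslipidemias and
#' related disorders (e.g. biallelic LDLR/APOB/PCSK9/LDLRAP1 in an FH
#' context is homozygous FH; biallelic ABCG5/ABCG8 reclassifies suspected
#' HoFH as sitosterolemia; biallelic lipolysis-gene variants in
#' hypertriglyceridemia give familial chylomicronemia syndrome). Rule
#' order is priority order: the first matching rule wins.
#'
#' @return data frame with columns `phenotype`, `genes`
#'   (semicolon-separated), `allelic_state`, `diagnosis`
#' @export
default_diagnosis_rules <- function() {
  utils::read.delim(system.file("extdata", "diagnosis_rules.tsv",
                                package = "lipidpanel", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' Per-gene allelic state from unphased findings
#'
#' A gene is biallelic when it carries a homozygous variant or at least
#' two heterozygous variants (phase unknown, assumed in trans; this can
#' over-call compound heterozygotes that are actually in cis).
#'
#' @param findings data frame with columns `gene`, `zygosity`
#' @return named character vector gene -> `"biallelic"`/`"heterozygous"`
#' @export
allelic_state <- function(findings) {
  if (nrow(findings) == 0) return(stats::setNames(character(0), character(0)))
  vapply(split(findings$zygosity, findings$gene), function(z) {
    if (any(z == "homozygous") || length(z) >= 2) "biallelic"
    else "heterozygous"
  }, character(1))
}

#' Apply gene/zygosity diagnosis rules to a sample's relevant findings
#'
#' @param findings data frame of the sample's relevant rare findings,
#'   columns `gene`, `zygosity` (CNV calls mapped: heterozygous deletion
#'   and duplication -> heterozygous, homozygous deletion -> homozygous)
#' @param phenotype the sample's phenotype key
#' @param rules rules table (see [default_diagnosis_rules()]); first
#'   matching rule wins
#' @return the diagnosis label, or `NA_character_` when no rule matches
#' @export
apply_diagnosis_rules <- function(findings, phenotype,
                                  rules = default_diagnosis_rules()) {
  if (nrow(findings) == 0) return(NA_character_)
  states <- allelic_state(findings)
  key <- canonical_phenotype(phenotype)
  for (i in seq_len(nrow(rules))) {
    if (rules$phenotype[i] != "any" && rules$phenotype[i] != key) next
    genes <- trimws(strsplit(rules$genes[i], ";", fixed = TRUE)[[1]])
    hit <- intersect(genes, names(states))
    if (length(hit) == 0) next
    ok <- switch(rules$allelic_state[i],
                 biallelic = any(states[hit] == "biallelic"),
                 heterozygous = TRUE,   # any qualifying variant in the gene
                 either = TRUE,
                 stop("unknown allelic_state in rules: ",
                      rules$allelic_state[i]))
    if (ok) return(rules$diagnosis[i])
  }
  NA_character_
}

#' Trait whose polygenic score matches a referral phenotype
#'
#' LDL cholesterol for FH-spectrum and combined/unclassified phenotypes,
#' triglyceride for the hypertriglyceridemia spectrum, HDL cholesterol for
#' HDL phenotypes. Every phenotype maps to exactly one disclosed trait.
#'
#' @param phenotype phenotype key
#' @return one of `"LDL"`, `"TG"`, `"HDL"`
#' @export
trait_for_phenotype <- function(phenotype) {
  key <- canonical_phenotype(phenotype)
  switch(key,
         FH = "LDL", familial_combined = "LDL", high_Lpa = "LDL",
         hypobetalipoproteinemia = "LDL", unclassified = "LDL",
         HTG = "TG", lipodystrophy = "TG", MODY = "TG",
         hypoalphalipoproteinemia = "HDL", LALD = "LDL",
         "LDL")
}

#' Build per-sample genetic profiles
#'
#' Synthesizes prioritized rare variants, CNV calls and polygenic score
#' results into one profile per sample: referral (or lipid-derived)
#' phenotype, phenotype-relevant rare findings, phenotype-matched extreme
#' score flag, the four-way profile category, a diagnosis where the rules
#' support one, and the report category (a: new genetically based
#' diagnosis; b: genetic confirmation of a prior diagnosis; c: relevant
#' finding short of a diagnosis; d: negative).
#'
#' @param variants annotated-variant data frame (all samples)
#' @param cnv_calls CNV call data frame (all samples; may be empty)
#' @param scores score results for all samples and all three traits, with
#'   `extreme` flags (see [score_cohort()])
#' @param lipids data frame with `sample_id`, lipid columns for
#'   [assign_phenotype()], optional `referral_phenotype` (overrides the
#'   lipid-derived assignment) and optional logical `prior_diagnosis`
#' @param panel a `lipid_panel`
#' @param rules diagnosis rules table
#' @return data frame, one row per sample: `sample_id`, `phenotype`,
#'   `matched_trait`, `n_rare_snvs`, `n_rare_cnvs`, `extreme_score`,
#'   `category`, `diagnosis`, `report_category`, plus a `findings`
#'   list-column of the relevant findings per sample
#' @export
build_genetic_profiles <- function(variants, cnv_calls, scores, lipids,
                                   panel, rules = default_diagnosis_rules()) {
  stopifnot(inherits(panel, "lipid_panel"))
  n <- nrow(lipids)
  if (n == 0) stop("no samples in lipid table")
  has_referral <- "referral_phenotype" %in% names(lipids)
  prior <- if ("prior_diagnosis" %in% names(lipids)) {
    isTRUE_vec(lipids$prior_diagnosis)
  } else rep(FALSE, n)

  assigned <- assign_phenotype(lipids)
  phenotype <- if (has_referral) {
    ifelse(!is.na(lipids$referral_phenotype) &
             nzchar(lipids$referral_phenotype),
           lipids$referral_phenotype, assigned)
  } else assigned

  if (is.null(cnv_calls) || nrow(cnv_calls) == 0) cnv_calls <- empty_cnv_calls()

  out <- data.frame(sample_id = lipids$sample_id, phenotype = phenotype,
                    matched_trait = vapply(phenotype, trait_for_phenotype, ""),
                    n_rare_snvs = 0L, n_rare_cnvs = 0L,
                    extreme_score = FALSE,
                    category = NA_character_, diagnosis = NA_character_,
                    report_category = NA_character_,
                    stringsAsFactors = FALSE)
  findings_list <- vector("list", n)

  for (i in seq_len(n)) {
    sid <- lipids$sample_id[i]
    gene_set <- phenotype_gene_set(panel, phenotype[i])
    sv <- variants[variants$sample_id == sid, , drop = FALSE]
    rel_sv <- sv[is_phenotype_relevant(sv, phenotype[i], panel), ,
                 drop = FALSE]
    cv <- cnv_calls[cnv_calls$sample_id == sid &
                      cnv_calls$gene %in% gene_set, , drop = FALSE]
    snv_f <- if (nrow(rel_sv) > 0) {
      data.frame(gene = rel_sv$gene,
                 description = sprintf("%s:%d %s>%s (%s)",
                                       rel_sv$chromosome, rel_sv$position,
                                       rel_sv$ref_allele, rel_sv$alt_allele,
                                       rel_sv$consequence),
                 zygosity = rel_sv$zygosity, kind = "SNV/indel",
                 stringsAsFactors = FALSE)
    } else NULL
    cnv_f <- if (nrow(cv) > 0) {
      data.frame(gene = cv$gene,
                 description = sprintf("%s %s", cv$region,
                                       sub("_", " ", cv$state)),
                 zygosity = ifelse(cv$state == "hom_deletion",
                                   "homozygous", "heterozygous"),
                 kind = "CNV", stringsAsFactors = FALSE)
    } else NULL
    fnd <- rbind(snv_f, cnv_f)
    if (is.null(fnd)) {
      fnd <- data.frame(gene = character(0), description = character(0),
                        zygosity = character(0), kind = character(0))
    }
    findings_list[[i]] <- fnd

    sc <- scores[scores$sample_id == sid &
                   scores$trait == out$matched_trait[i], , drop = FALSE]
    if (nrow(sc) == 0) {
      stop("no ", out$matched_trait[i], " score result for sample ", sid)
    }
    extreme <- isTRUE(sc$extreme[1])

    out$n_rare_snvs[i] <- if (is.null(snv_f)) 0L else nrow(snv_f)
    out$n_rare_cnvs[i] <- if (is.null(cnv_f)) 0L else nrow(cnv_f)
    out$extreme_score[i] <- extreme
    out$category[i] <- classify_profile(nrow(fnd), extreme)
    out$diagnosis[i] <- apply_diagnosis_rules(fnd, phenotype[i], rules)
    out$report_category[i] <- if (!is.na(out$diagnosis[i])) {
      if (prior[i]) "b_confirmation" else "a_diagnosis"
    } else if (out$category[i] != "none") {
      "c_relevant"
    } else {
      "d_negative"
    }
  }
  out$findings <- findings_list
  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Summarize a phenotypic cohort's genetic characterization
#'
#' Counts and percentages (rounded half away from zero to one decimal) for
#' rare-variant carriage, extreme polygenic scores, and the four profile
#' categories, as presented in cohort characterization tables.
#'
#' @param profiles data frame with a `category` column (as from
#'   [build_genetic_profiles()]), or any vector coercible to the four
#'   category labels via `data.frame(category = ...)`
#' @param phenotype optional label recorded in the output
#' @return data frame with columns `metric`, `count`, `percent` and
#'   attribute `n` (cohort size); metrics: `any_rare_variant`,
#'   `any_extreme_ps`, `rare_only`, `rare_plus_extreme`, `extreme_only`,
#'   `none`
#' @export
summarize_cohort <- function(profiles, phenotype = NULL) {
  cat_vec <- profiles$category
  n <- length(cat_vec)
  if (n == 0) stop("empty cohort")
  bad <- setdiff(unique(cat_vec), PROFILE_CATEGORIES)
  if (length(bad) > 0) {
    stop("unknown profile category label(s): ", paste(bad, collapse = ", "))
  }
  k <- vapply(PROFILE_CATEGORIES, function(cc) sum(cat_vec == cc), integer(1))
  counts <- c(any_rare_variant = k[["rare_only"]] + k[["rare_plus_extreme"]],
              any_extreme_ps = k[["extreme_only"]] + k[["rare_plus_extreme"]],
              k)
  out <- data.frame(metric = names(counts), count = unname(counts),
                    percent = unname(percent_share(counts, n)),
                    stringsAsFactors = FALSE)
  attr(out, "n") <- n
  attr(out, "phenotype") <- phenotype
  out
}

#' Expand published category counts into a profile-category vector
#'
#' Convenience for re-running cohort arithmetic from printed counts.
#'
#' @param rare_only,rare_plus_extreme,extreme_only,none category counts
#' @return data frame with a `category` column of length equal to the sum
#' @export
cohort_from_counts <- function(rare_only, rare_plus_extreme, extreme_only,
                               none) {
  data.frame(category = rep(PROFILE_CATEGORIES,
                            times = c(rare_only, rare_plus_extreme,
                                      extreme_only, none)),
             stringsAsFactors = FALSE)
}
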