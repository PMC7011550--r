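#' Weighted polygenic score for one genotype vector
#'
#' The score is the sum over score SNPs of the trait-raising allele count
#' (0, 1 or 2) multiplied by that allele's GWAS beta coefficient. Missing
#' genotypes contribute nothing; the number of loci actually used is
#' returned so downstream consumers can flag low-coverage scores.
#'
#' @param counts named numeric vector of trait-raising allele counts, names
#'   are snp_ids; values in `{0, 1, 2}` or `NA` for missing
#' @param snps score-SNP data frame (rows of one trait, as from a
#'   `lipid_panel`'s `score_snps`)
#' @return list with `raw_score` (trait units), `n_snps_used`
#' @export
compute_score <- function(counts, snps) {
  if (length(unique(snps$trait)) > 1) {
    stop("score SNPs span multiple traits: ",
         paste(unique(snps$trait), collapse = ", "),
         "; subset to one trait first")
  }
  unknown <- setdiff(names(counts), snps$snp_id)
  if (length(unknown) > 0) {
    stop("genotype count(s) for SNP(s) not in this trait's score: ",
         paste(unknown, collapse = ", "))
  }
  ok <- is.na(counts) | counts %in% c(0, 1, 2)
  if (!all(ok)) {
    stop("allele counts must be 0, 1, 2 or NA; offending SNP(s): ",
         paste(names(counts)[!ok], collapse = ", "))
  }
  g <- counts[match(snps$snp_id, names(counts))]
  used <- !is.na(g)
  list(raw_score = sum(g[used] * snps$beta[used]),
       n_snps_used = sum(used))
}

#' Unweighted tally of trait-raising alleles
#'
#' The simple allele count over non-missing score-SNP loci; used alongside
#' the weighted score on patient-facing reports, where a plain tally is
#' easier to communicate than a weighted statistic.
#'
#' @inheritParams compute_score
#' @return list with `tally` (integer) and `n_snps_used`
#' @export
allele_tally <- function(counts, snps) {
  sc <- compute_score(counts, snps)  # reuse validation
  g <- counts[match(snps$snp_id, names(counts))]
  list(tally = as.integer(sum(g, na.rm = TRUE)), n_snps_used = sc$n_snps_used)
}

#' Empirical percentile of a score in a reference distribution
#'
#' Percentile = 100 x (number of reference scores <= score) / n, i.e. the
#' empirical CDF with ties counted as "less than or equal".
#'
#' @param score raw score value
#' @param ref_scores numeric vector of reference-cohort raw scores
#' @return percentile in `[0, 100]`
#' @export
percentile_of <- function(score, ref_scores) {
  if (length(ref_scores) == 0) stop("reference distribution is empty")
  100 * sum(ref_scores <= score) / length(ref_scores)
}

#' 90th-percentile threshold of a reference distribution (nearest rank)
#'
#' The threshold is a realized reference value: the nearest-rank 90th
#' percentile, `sort(ref)[ceiling(0.9 * n)]`. No interpolation is used, so
#' "greater than or equal to the threshold" is a well-defined, inclusive
#' rule.
#'
#' @param ref_scores numeric vector of reference-cohort raw scores
#'   (at least 10 values)
#' @param prob percentile level as a fraction (default 0.9)
#' @return the threshold score
#' @export
extreme_threshold <- function(ref_scores, prob = 0.9) {
  n <- length(ref_scores)
  if (n < 10) stop("reference distribution too small for percentile ",
                   "estimation (n = ", n, ", need >= 10)")
  sort(ref_scores)[ceiling(prob * n)]
}

#' Classify a score as extreme against a reference distribution
#'
#' A score is extreme when it is greater than or equal to the reference
#' cohort's 90th-percentile threshold (inclusive at the boundary).
#'
#' @inheritParams percentile_of
#' @param prob percentile level (default 0.9)
#' @return logical flag
#' @export
classify_extreme <- function(score, ref_scores, prob = 0.9) {
  score >= extreme_threshold(ref_scores, prob)
}

#' Score a cohort's genotype matrix for one trait
#'
#' @param geno matrix of trait-raising allele counts, samples x SNPs
#'   (column names are snp_ids); `NA` for missing genotypes
#' @param snps score-SNP rows for one trait
#' @param ref_scores reference-cohort raw scores for the same trait, used
#'   for percentiles and the extreme flag; `NULL` to skip classification
#' @return data frame with one row per sample: `sample_id`, `trait`,
#'   `raw_score`, `allele_tally`, `n_snps_used`, and (when a reference is
#'   given) `percentile` and `extreme`
#' @export
score_cohort <- function(geno, snps, ref_scores = NULL) {
  stopifnot(is.matrix(geno))
  trait <- unique(snps$trait)
  out <- data.frame(
    sample_id = rownames(geno),
    trait = trait,
    raw_score = NA_real_, allele_tally = NA_integer_,
    n_snps_used = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(geno))) {
    sc <- compute_score(geno[i, ], snps)
    out$raw_score[i] <- sc$raw_score
    out$allele_tally[i] <- as.integer(sum(geno[i, ], na.rm = TRUE))
    out$n_snps_used[i] <- sc$n_snps_used
  }
  if (!is.null(ref_scores)) {
    thr <- extreme_threshold(ref_scores)
    out$percentile <- vapply(out$raw_score, percentile_of, numeric(1),
                             ref_scores = ref_scores)
    out$extreme <- out$raw_score >= thr
  }
  out
}

#' Extract trait-raising allele counts for score SNPs from a VCF
#'
#' Matches score SNPs to VCF records by id (or by position when ids are
#' absent) and orients genotypes to the trait-raising allele: when the
#' raising allele is the ALT allele the alt-allele count is used, when it
#' is the REF allele the count is `2 - alt count`.
#'
#' @param vcf_path VCF 4.x path containing the score-SNP sites
#' @param snps score-SNP data frame (any mix of traits); needs columns
#'   `snp_id`, `trait_raising_allele`, `ref_allele`, `alt_allele`
#' @return matrix of counts, samples x SNPs (columns in `snps` order);
#'   `NA` where a site or genotype is missing
#' @export
score_genotypes_from_vcf <- function(vcf_path, snps) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  out <- matrix(NA_real_, nrow = length(samples), ncol = nrow(snps),
                dimnames = list(samples, snps$snp_id))
  row_of <- match(snps$snp_id, fix[, "ID"])
  for (j in seq_len(nrow(snps))) {
    i <- row_of[j]
    if (is.na(i)) next
    alleles <- strsplit(gsub("\\|", "/", gt[i, ]), "/")
    n_alt <- vapply(alleles, function(x) {
      if (any(is.na(x) | x == ".")) NA_real_ else sum(x == "1")
    }, numeric(1))
    raising <- snps$trait_raising_allele[j]
    if (raising == fix[i, "ALT"]) {
      out[, j] <- n_alt
    } else if (raising == fix[i, "REF"]) {
      out[, j] <- 2 - n_alt
    } else {
      stop("trait-raising allele ", raising, " for ", snps$snp_id[j],
           " matches neither REF nor ALT in ", vcf_path)
    }
  }
  out
}

#' Write/read a one-column reference score distribution
#' @param scores numeric vector of raw scores
#' @param path TSV path (single column `raw_score`)
#' @return invisibly, the path
#' @export
write_reference_scores <- function(scores, path) {
  utils::write.table(data.frame(raw_score = scores), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_scores
#' @export
read_reference_scores <- function(path) {
  utils::read.delim(path)$raw_score
}
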