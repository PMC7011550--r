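PROTEIN_ALTERING <- c("missense", "stop_gain", "stop_loss", "frameshift",
                      "inframe_indel", "splice_acceptor", "splice_donor")
LOF_ONTOLOGIES <- c("frameshift", "splice_acceptor", "splice_donor",
                    "stop_gain", "stop_loss")

#' Rare-variant flag
#'
#' A variant is rare when its population minor allele frequency is at or
#' below the threshold (default 1%), or when it is absent from the
#' population database (`population_maf` is `NA`). The boundary is
#' inclusive.
#'
#' @param v annotated-variant data frame
#' @param maf_threshold MAF cutoff (default 0.01)
#' @return logical vector, one per row
#' @export
is_rare <- function(v, maf_threshold = 0.01) {
  is.na(v$population_maf) | v$population_maf <= maf_threshold
}

#' Protein-altering flag
#'
#' True for consequences that change the encoded amino-acid sequence or a
#' canonical splice site: missense, stop gain/loss, frameshift and in-frame
#' indels, splice acceptor/donor. Synonymous and non-coding consequences
#' are excluded.
#'
#' @param v annotated-variant data frame
#' @return logical vector
#' @export
is_protein_altering <- function(v) {
  v$consequence %in% PROTEIN_ALTERING
}

#' Loss-of-function flag
#'
#' LOF ontologies: frameshift, splice acceptor, splice donor, stop gain
#' (nonsense), stop loss. In-frame indels and missense alter the protein
#' but are not LOF.
#'
#' @param v annotated-variant data frame
#' @return logical vector
#' @export
is_lof <- function(v) {
  v$consequence %in% LOF_ONTOLOGIES
}

#' Predicted-deleterious flag
#'
#' Combines the three in-silico missense predictors. Under the default
#' `any_tool` policy a variant passes when at least one of SIFT
#' (deleterious), PolyPhen2 (damaging) or MutationTaster (disease causing)
#' flags it; under `all_tools` all three must flag it. LOF ontologies
#' bypass the tools entirely (truncating variants are not scored by
#' missense-oriented predictors) and always pass.
#'
#' @param v annotated-variant data frame
#' @param policy `"any_tool"` (default) or `"all_tools"`
#' @return logical vector
#' @export
is_predicted_deleterious <- function(v, policy = c("any_tool", "all_tools")) {
  policy <- match.arg(policy)
  tool_hits <- cbind(v$sift == "deleterious",
                     v$polyphen2 == "damaging",
                     v$mutation_taster == "disease_causing")
  by_tools <- if (policy == "any_tool") {
    rowSums(tool_hits) >= 1
  } else {
    rowSums(tool_hits) == 3
  }
  is_lof(v) | by_tools
}

#' Run the staged rare-variant filter cascade
#'
#' Applies, in order: (1) rarity (MAF at or below threshold, or absent from
#' the population database); (2) protein-altering consequence; (3)
#' predicted deleterious/damaging. Reports the number of unique variants
#' entering and surviving each stage, plus two subsets of the final stage:
#' LOF-ontology variants, and variants with CADD PHRED at or above the
#' strict cutoff (default 20, boundary inclusive).
#'
#' Counts are of unique variants (cross-sample deduplication by
#' chrom:pos:ref:alt key), so recurrent variants count once.
#'
#' @param v annotated-variant data frame (sample-level records are fine;
#'   they are deduplicated internally)
#' @param maf_threshold rarity cutoff (default 0.01)
#' @param cadd_strict strict CADD PHRED cutoff for the clinical-interest
#'   tier (default 20)
#' @param policy prediction-tool policy, see [is_predicted_deleterious()]
#' @return an object of class `cascade_result`: list with `stage_counts`
#'   (named integer vector: `total`, `rare`, `protein_altering`,
#'   `predicted_deleterious`, `lof`, `cadd_strict`) and `surviving`
#'   (named list of unique-variant data frames per stage)
#' @export
run_cascade <- function(v, maf_threshold = 0.01, cadd_strict = 20,
                        policy = c("any_tool", "all_tools")) {
  policy <- match.arg(policy)
  u <- unique_variants(v)
  rare <- u[is_rare(u, maf_threshold), , drop = FALSE]
  pa <- rare[is_protein_altering(rare), , drop = FALSE]
  del <- pa[is_predicted_deleterious(pa, policy), , drop = FALSE]
  lof <- del[is_lof(del), , drop = FALSE]
  strict <- del[!is.na(del$cadd_phred) & del$cadd_phred >= cadd_strict,
                , drop = FALSE]
  surviving <- list(total = u, rare = rare, protein_altering = pa,
                    predicted_deleterious = del, lof = lof,
                    cadd_strict = strict)
  structure(list(
    stage_counts = vapply(surviving, nrow, integer(1)),
    surviving = surviving,
    params = list(maf_threshold = maf_threshold, cadd_strict = cadd_strict,
                  policy = policy)),
    class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  sc <- x$stage_counts
  cat("<cascade_result> unique variants per stage\n")
  cat(sprintf("  total                 %6d\n", sc[["total"]]))
  cat(sprintf("  rare (MAF <= %g)      %6d\n",
              x$params$maf_threshold, sc[["rare"]]))
  cat(sprintf("  protein-altering      %6d\n", sc[["protein_altering"]]))
  cat(sprintf("  predicted deleterious %6d  [policy: %s]\n",
              sc[["predicted_deleterious"]], x$params$policy))
  cat(sprintf("    of which LOF        %6d\n", sc[["lof"]]))
  cat(sprintf("    of which CADD >= %g %6d\n",
              x$params$cadd_strict, sc[["cadd_strict"]]))
  invisible(x)
}

#' Phenotype-relevance flag for prioritized variants
#'
#' A variant is relevant to a referral phenotype when it hits a gene in the
#' phenotype's causal gene set, is rare, alters the protein sequence, has
#' CADD PHRED at or above 10 (inclusive), and is either flagged by at least
#' one prediction tool or carries a LOF ontology.
#'
#' @param v annotated-variant data frame
#' @param phenotype phenotype key known to the panel
#' @param panel a `lipid_panel`
#' @param maf_threshold rarity cutoff (default 0.01)
#' @param cadd_min relevance CADD floor (default 10)
#' @return logical vector
#' @export
is_phenotype_relevant <- function(v, phenotype, panel, maf_threshold = 0.01,
                                  cadd_min = 10) {
  genes <- phenotype_gene_set(panel, phenotype)
  tool_any <- is_predicted_deleterious(v, policy = "any_tool")
  (v$gene %in% genes) &
    is_rare(v, maf_threshold) &
    is_protein_altering(v) &
    !is.na(v$cadd_phred) & v$cadd_phred >= cadd_min &
    tool_any
}
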