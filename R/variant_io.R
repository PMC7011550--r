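CONSEQUENCES <- c("missense", "stop_gain", "stop_loss", "frameshift",
                  "inframe_indel", "splice_acceptor", "splice_donor",
                  "synonymous", "other")
TOOL_LEVELS <- list(
  sift = c("deleterious", "tolerated", "unknown"),
  polyphen2 = c("damaging", "benign", "unknown"),
  mutation_taster = c("disease_causing", "polymorphism", "unknown"))

#' Read sample-level annotated variants from a VCF plus annotation TSV
#'
#' Genotypes come from the VCF; functional annotations (gene, consequence,
#' population MAF, CADD PHRED, SIFT/PolyPhen2/MutationTaster calls) come
#' from a sidecar TSV keyed by (chrom, pos, ref, alt), emulating the output
#' of external annotators. One record is emitted per carrier sample per
#' variant: genotype 0/1 maps to heterozygous, 1/1 to homozygous; 0/0 and
#' ./. emit nothing. Multi-allelic VCF rows are split into biallelic records
#' before matching.
#'
#' A population MAF of `NA` in the annotation table means the variant is
#' absent from the reference genotype database, which the rare-variant
#' filter treats as rare by definition (distinct from an observed frequency
#' of 0).
#'
#' @param vcf_path path to a VCF 4.x file with GT genotypes
#' @param annotation_path path to the annotation TSV (columns `chrom`,
#'   `pos`, `ref`, `alt`, `gene`, `consequence`, `maf`, `cadd_phred`,
#'   `sift`, `polyphen2`, `mutation_taster`)
#' @param on_missing what to do with a carried VCF variant that has no
#'   annotation row: `"error"` (default) or `"unknown"` (keep it with
#'   unknown predictions, gene `NA`, consequence `other`)
#' @return a data frame of annotated variants, one row per sample-variant,
#'   with columns `sample_id`, `gene`, `chromosome`, `position`,
#'   `ref_allele`, `alt_allele`, `zygosity`, `consequence`,
#'   `population_maf`, `cadd_phred`, `sift`, `polyphen2`, `mutation_taster`
#' @export
read_annotated_variants <- function(vcf_path, annotation_path,
                                    on_missing = c("error", "unknown")) {
  on_missing <- match.arg(on_missing)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  ann <- read_annotation_table(annotation_path)

  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF has no genotype (GT) data: ", vcf_path)
  samples <- colnames(gt)

  rows <- vector("list", nrow(fix) * 2L)
  k <- 0L
  for (i in seq_len(nrow(fix))) {
    frow <- stats::setNames(as.vector(fix[i, ]), colnames(fix))
    alts <- strsplit(unname(frow["ALT"]), ",", fixed = TRUE)[[1]]
    gts <- gt[i, ]
    alleles <- strsplit(gsub("\\|", "/", gts), "/", fixed = FALSE)
    for (a in seq_along(alts)) {
      n_alt <- vapply(alleles, function(x)
        sum(!is.na(x) & x == as.character(a)), integer(1))
      carriers <- which(n_alt > 0)
      if (length(carriers) == 0) next
      k <- k + 1L
      rows[[k]] <- data.frame(
        sample_id = unname(samples[carriers]),
        chromosome = unname(frow["CHROM"]),
        position = as.integer(unname(frow["POS"])),
        ref_allele = unname(frow["REF"]),
        alt_allele = alts[a],
        zygosity = unname(ifelse(n_alt[carriers] >= 2, "homozygous",
                                 "heterozygous")),
        stringsAsFactors = FALSE)
    }
  }
  if (k == 0L) {
    recs <- data.frame(sample_id = character(0), chromosome = character(0),
                       position = integer(0), ref_allele = character(0),
                       alt_allele = character(0), zygosity = character(0))
  } else {
    recs <- do.call(rbind, rows[seq_len(k)])
  }

  key <- variant_key(recs)
  akey <- paste(ann$chrom, ann$pos, ann$ref, ann$alt, sep = ":")
  idx <- match(key, akey)
  if (anyNA(idx) && nrow(recs) > 0) {
    missing_keys <- unique(key[is.na(idx)])
    if (on_missing == "error") {
      stop("no annotation row for variant(s): ",
           paste(utils::head(missing_keys, 5), collapse = ", "),
           if (length(missing_keys) > 5) " ...")
    }
  }
  out <- data.frame(
    sample_id = recs$sample_id,
    gene = ann$gene[idx],
    chromosome = recs$chromosome,
    position = recs$position,
    ref_allele = recs$ref_allele,
    alt_allele = recs$alt_allele,
    zygosity = recs$zygosity,
    consequence = ifelse(is.na(idx), "other", ann$consequence[idx]),
    population_maf = ann$maf[idx],
    cadd_phred = ifelse(is.na(idx), 0, ann$cadd_phred[idx]),
    sift = ifelse(is.na(idx), "unknown", ann$sift[idx]),
    polyphen2 = ifelse(is.na(idx), "unknown", ann$polyphen2[idx]),
    mutation_taster = ifelse(is.na(idx), "unknown", ann$mutation_taster[idx]),
    stringsAsFactors = FALSE)
  validate_annotated_variants(out)
}

#' Read an annotation TSV
#' @param path TSV path; `maf` may be numeric or the string `NA` for
#'   variants absent from the population database
#' @return data frame with normalized column order
#' @export
read_annotation_table <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  need <- c("chrom", "pos", "ref", "alt", "gene", "consequence", "maf",
            "cadd_phred", "sift", "polyphen2", "mutation_taster")
  miss <- setdiff(need, names(ann))
  if (length(miss) > 0) {
    stop("annotation table missing column(s): ", paste(miss, collapse = ", "))
  }
  ann$maf <- as.numeric(ann$maf)
  ann[, need]
}

#' Write an annotation TSV (row-for-row inverse of [read_annotation_table()])
#' @param ann annotation data frame
#' @param path output path
#' @return invisibly, the path
#' @export
write_annotation_table <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

validate_annotated_variants <- function(v) {
  if (nrow(v) == 0) return(v)
  if (any(v$position < 1)) stop("variant position must be >= 1")
  bad <- !is.na(v$population_maf) &
    (v$population_maf < 0 | v$population_maf > 1)
  if (any(bad)) stop("population_maf outside [0, 1]")
  if (any(v$cadd_phred < 0, na.rm = TRUE)) stop("cadd_phred must be >= 0")
  badc <- setdiff(unique(v$consequence), CONSEQUENCES)
  if (length(badc) > 0) {
    stop("unknown consequence term(s): ", paste(badc, collapse = ", "))
  }
  for (tool in names(TOOL_LEVELS)) {
    badt <- setdiff(unique(v[[tool]]), TOOL_LEVELS[[tool]])
    if (length(badt) > 0) {
      stop("unknown ", tool, " call(s): ", paste(badt, collapse = ", "))
    }
  }
  v
}

#' Variant keys (chrom:pos:ref:alt) for a set of records
#' @param v annotated-variant data frame
#' @return character vector, one key per row
#' @export
variant_key <- function(v) {
  if (nrow(v) == 0) return(character(0))
  cn <- if ("chromosome" %in% names(v)) {
    c("chromosome", "position", "ref_allele", "alt_allele")
  } else {
    c("chrom", "pos", "ref", "alt")
  }
  paste(v[[cn[1]]], v[[cn[2]]], v[[cn[3]]], v[[cn[4]]], sep = ":")
}

#' Collapse sample-level records to the set of unique variants
#'
#' A variant carried by several samples counts once; identity is the
#' (chromosome, position, ref, alt) key.
#'
#' @param v annotated-variant data frame
#' @return data frame with one row per unique variant (first occurrence's
#'   annotation columns retained, sample-specific columns dropped)
#' @export
unique_variants <- function(v) {
  keep <- setdiff(names(v), c("sample_id", "zygosity"))
  if (nrow(v) == 0) return(v[, keep, drop = FALSE])
  out <- v[!duplicated(variant_key(v)), keep, drop = FALSE]
  rownames(out) <- NULL
  out
}
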