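PANEL_CATEGORIES <- c("monogenic_dyslipidemia", "lipodystrophy",
                      "mody_diabetes", "candidate")
SCORE_TRAITS <- c("LDL", "TG", "HDL")
INHERITANCE_MODES <- c("dominant", "recessive", "either")

#' Load a panel definition from gene and score-SNP config files
#'
#' A panel couples two designs: a set of targeted genes (exons plus flanking
#' sequence, grouped into four categories: monogenic dyslipidemia genes,
#' lipodystrophy genes, MODY/inherited-diabetes genes and candidate genes)
#' and a set of common SNPs micro-sequenced to build small weighted polygenic
#' scores for LDL cholesterol, triglyceride and HDL cholesterol.
#'
#' The gene config is a TSV with columns `symbol`, `category`, `chromosome`,
#' `intervals` (semicolon-separated `start-end` pairs, 1-based inclusive),
#' `interval_labels` (optional; semicolon-separated labels such as `5'UTR`,
#' `Exon 1`, `3'UTR`), `phenotypes` (semicolon-separated phenotype keys this
#' gene is causal or relevant for) and `inheritance`
#' (`dominant`/`recessive`/`either`).
#'
#' The score-SNP config is a TSV with columns `snp_id`, `trait`
#' (`LDL`/`TG`/`HDL`), `trait_raising_allele`, `beta` (trait units per
#' allele, oriented so `beta > 0`), `ref_allele_freq`, and, for genotype
#' extraction from VCF, `chromosome`, `position`, `ref_allele`, `alt_allele`.
#'
#' @param gene_path path to the gene target TSV
#' @param snp_path path to the score-SNP TSV
#' @param micro_seq_snp_count number of micro-sequenced SNP assays on the
#'   panel design (default 185); the score SNPs are subsets of these
#' @return an object of class `lipid_panel`: a list with elements `genes`
#'   (data frame, one row per gene, list-columns `intervals` and
#'   `phenotypes`), `score_snps` (data frame) and `micro_seq_snp_count`
#' @export
load_panel <- function(gene_path, snp_path, micro_seq_snp_count = 185L) {
  for (p in c(gene_path, snp_path)) {
    if (!file.exists(p)) stop("panel config file not found: ", p)
  }
  graw <- utils::read.delim(gene_path, stringsAsFactors = FALSE,
                            check.names = FALSE)
  need <- c("symbol", "category", "chromosome", "intervals", "phenotypes",
            "inheritance")
  miss <- setdiff(need, names(graw))
  if (length(miss) > 0) {
    stop("gene config is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(graw) == 0) stop("gene config contains no genes")
  has_labels <- "interval_labels" %in% names(graw)

  genes <- data.frame(symbol = graw$symbol, category = graw$category,
                      chromosome = as.character(graw$chromosome),
                      inheritance = graw$inheritance,
                      stringsAsFactors = FALSE)
  genes$intervals <- lapply(seq_len(nrow(graw)), function(i) {
    iv <- parse_intervals(graw$intervals[i], graw$symbol[i])
    if (has_labels && nzchar(graw$interval_labels[i])) {
      labs <- strsplit(graw$interval_labels[i], ";", fixed = TRUE)[[1]]
      if (length(labs) != nrow(iv)) {
        stop("gene ", graw$symbol[i], ": interval_labels length (",
             length(labs), ") does not match intervals (", nrow(iv), ")")
      }
      iv$label <- trimws(labs)
    } else {
      iv$label <- paste("Exon", seq_len(nrow(iv)))
    }
    iv
  })
  genes$phenotypes <- lapply(graw$phenotypes, function(x) {
    if (is.na(x) || !nzchar(x)) character(0)
    else trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  })

  snps <- utils::read.delim(snp_path, stringsAsFactors = FALSE)
  sneed <- c("snp_id", "trait", "trait_raising_allele", "beta",
             "ref_allele_freq")
  smiss <- setdiff(sneed, names(snps))
  if (length(smiss) > 0) {
    stop("score-SNP config is missing column(s): ",
         paste(smiss, collapse = ", "))
  }

  panel <- structure(list(genes = genes, score_snps = snps,
                          micro_seq_snp_count = as.integer(micro_seq_snp_count)),
                     class = "lipid_panel")
  validate_panel(panel)
  panel
}

parse_intervals <- function(x, symbol) {
  if (is.na(x) || !nzchar(x)) {
    stop("gene ", symbol, ": empty intervals field")
  }
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  se <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^\\s*(\\d+)-(\\d+)\\s*$", p))[[1]]
    if (length(m) != 3) {
      stop("gene ", symbol, ": malformed interval '", p,
           "' (expected start-end)")
    }
    as.integer(m[2:3])
  })
  data.frame(start = vapply(se, `[`, integer(1), 1L),
             end = vapply(se, `[`, integer(1), 2L))
}

validate_panel <- function(panel) {
  genes <- panel$genes
  if (anyDuplicated(genes$symbol)) {
    stop("duplicate gene symbol(s) in panel: ",
         paste(unique(genes$symbol[duplicated(genes$symbol)]),
               collapse = ", "))
  }
  bad_cat <- setdiff(unique(genes$category), PANEL_CATEGORIES)
  if (length(bad_cat) > 0) {
    stop("unknown gene category: ", paste(bad_cat, collapse = ", "),
         " (valid: ", paste(PANEL_CATEGORIES, collapse = ", "), ")")
  }
  bad_inh <- setdiff(unique(genes$inheritance), INHERITANCE_MODES)
  if (length(bad_inh) > 0) {
    stop("unknown inheritance mode: ", paste(bad_inh, collapse = ", "))
  }
  for (i in seq_len(nrow(genes))) {
    iv <- genes$intervals[[i]]
    if (any(iv$start >= iv$end)) {
      stop("gene ", genes$symbol[i], ": interval with start >= end")
    }
  }
  snps <- panel$score_snps
  bad_trait <- setdiff(unique(snps$trait), SCORE_TRAITS)
  if (length(bad_trait) > 0) {
    stop("unknown score trait: ", paste(bad_trait, collapse = ", "))
  }
  if (any(snps$beta <= 0)) {
    stop("score SNP(s) with beta <= 0 (orient betas to the trait-raising ",
         "allele): ", paste(snps$snp_id[snps$beta <= 0], collapse = ", "))
  }
  if (any(snps$ref_allele_freq <= 0 | snps$ref_allele_freq >= 1)) {
    stop("score SNP allele frequencies must lie strictly in (0, 1): ",
         paste(snps$snp_id[snps$ref_allele_freq <= 0 |
                             snps$ref_allele_freq >= 1], collapse = ", "))
  }
  dup <- snps[duplicated(snps[, c("snp_id", "trait")]), "snp_id"]
  if (length(dup) > 0) {
    stop("duplicate snp_id within a trait score: ",
         paste(unique(dup), collapse = ", "))
  }
  invisible(panel)
}

#' Save a panel definition back to config files
#'
#' Inverse of [load_panel()]: `load_panel(save_panel(p))` reproduces `p`.
#'
#' @param panel a `lipid_panel`
#' @param gene_path,snp_path output TSV paths
#' @return invisibly, a list of the two paths
#' @export
save_panel <- function(panel, gene_path, snp_path) {
  stopifnot(inherits(panel, "lipid_panel"))
  g <- panel$genes
  out <- data.frame(
    symbol = g$symbol, category = g$category, chromosome = g$chromosome,
    intervals = vapply(g$intervals, function(iv)
      paste(sprintf("%d-%d", iv$start, iv$end), collapse = ";"), ""),
    interval_labels = vapply(g$intervals, function(iv)
      paste(iv$label, collapse = ";"), ""),
    phenotypes = vapply(g$phenotypes, paste, "", collapse = ";"),
    inheritance = g$inheritance, stringsAsFactors = FALSE)
  utils::write.table(out, gene_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(panel$score_snps, snp_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(gene_path = gene_path, snp_path = snp_path))
}

#' Load the synthetic default panel shipped with the package
#'
#' A 69-gene design split 25/16/13/15 across the four categories, with
#' 10 LDL, 16 TG and 9 HDL score SNPs. Gene symbols and phenotype links
#' follow the dyslipidemia literature; coordinates, rsIDs, betas and allele
#' frequencies are synthetic stand-ins (the real panel's GWAS-derived values
#' are not redistributable from public summaries alone).
#'
#' @return a `lipid_panel`
#' @export
default_panel <- function() {
  load_panel(
    system.file("extdata", "panel_genes_synthetic.tsv",
                package = "lipidpanel", mustWork = TRUE),
    system.file("extdata", "score_snps_synthetic.tsv",
                package = "lipidpanel", mustWork = TRUE))
}

#' Phenotype keys known to a panel
#' @param panel a `lipid_panel`
#' @return character vector of phenotype keys
#' @export
panel_phenotypes <- function(panel) {
  stopifnot(inherits(panel, "lipid_panel"))
  sort(unique(unlist(panel$genes$phenotypes)))
}

# Referral phenotypes that are scored/profiled but have no causal gene on a
# targeted lipid panel (e.g. Lp(a) is driven by the LPA locus, not targeted).
GENELESS_PHENOTYPES <- c("high_Lpa", "unclassified")

#' Causal/relevant gene set for a phenotype
#'
#' Returns the panel genes linked to a referral phenotype, e.g. for
#' familial hypercholesterolemia (`"FH"`) the LDL-receptor pathway genes
#' LDLR, APOB and PCSK9; for hypertriglyceridemia (`"HTG"`) the lipolysis
#' genes LPL, APOA5, LMF1, GPIHBP1 and APOC2.
#'
#' @param panel a `lipid_panel`
#' @param phenotype a phenotype key; keys `FH_suspected` and `severe_HTG`
#'   are aliases of `FH` and `HTG`
#' @return character vector of gene symbols (possibly empty for phenotypes
#'   with no causal gene on the panel, e.g. elevated Lp(a))
#' @export
phenotype_gene_set <- function(panel, phenotype) {
  stopifnot(inherits(panel, "lipid_panel"))
  key <- canonical_phenotype(phenotype)
  known <- union(panel_phenotypes(panel), GENELESS_PHENOTYPES)
  if (!key %in% known) {
    stop("unknown phenotype key '", phenotype, "'; valid keys: ",
         paste(sort(union(known, names(PHENOTYPE_ALIASES))), collapse = ", "))
  }
  hit <- vapply(panel$genes$phenotypes, function(ph) key %in% ph, logical(1))
  panel$genes$symbol[hit]
}

PHENOTYPE_ALIASES <- c(FH_suspected = "FH", severe_HTG = "HTG")

canonical_phenotype <- function(phenotype) {
  stopifnot(is.character(phenotype), length(phenotype) == 1)
  if (phenotype %in% names(PHENOTYPE_ALIASES)) {
    unname(PHENOTYPE_ALIASES[phenotype])
  } else {
    phenotype
  }
}

#' Per-target table of panel intervals (unmerged)
#'
#' One row per configured target interval (exon/UTR), in genomic order
#' within each gene. This is the row definition used by depth matrices and
#' the CNV caller's region vocabulary.
#'
#' @param panel a `lipid_panel`
#' @return data frame with columns `gene`, `label`, `chromosome`, `start`,
#'   `end`
#' @export
panel_targets <- function(panel) {
  stopifnot(inherits(panel, "lipid_panel"))
  g <- panel$genes
  rows <- lapply(seq_len(nrow(g)), function(i) {
    iv <- g$intervals[[i]]
    iv <- iv[order(iv$start), , drop = FALSE]
    data.frame(gene = g$symbol[i], label = iv$label,
               chromosome = g$chromosome[i], start = iv$start, end = iv$end,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(chromosome_rank(out$chromosome), out$start,
                   out$gene, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merged target regions of a panel
#'
#' Overlapping intervals within a gene are merged (union of covered bases);
#' output is sorted by (chromosome, start) with a deterministic order.
#'
#' @param panel a `lipid_panel`
#' @return data frame with columns `chromosome`, `start`, `end`, `gene`
#'   (1-based inclusive coordinates)
#' @export
target_regions <- function(panel) {
  stopifnot(inherits(panel, "lipid_panel"))
  g <- panel$genes
  rows <- lapply(seq_len(nrow(g)), function(i) {
    iv <- g$intervals[[i]]
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      seqnames = g$chromosome[i],
      ranges = IRanges::IRanges(start = iv$start, end = iv$end)))
    data.frame(chromosome = g$chromosome[i],
               start = GenomicRanges::start(gr),
               end = GenomicRanges::end(gr),
               gene = g$symbol[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(chromosome_rank(out$chromosome), out$start, out$end,
                   out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

chromosome_rank <- function(chrom) {
  x <- sub("^chr", "", chrom)
  n <- suppressWarnings(as.integer(x))
  n[x == "X"] <- 23L
  n[x == "Y"] <- 24L
  n[x %in% c("M", "MT")] <- 25L
  ifelse(is.na(n), 100L + as.integer(factor(x)), n)
}

#' Export merged target regions as BED
#'
#' Internal coordinates are 1-based inclusive; BED output is 0-based
#' half-open, with the gene symbol in the 4th column.
#'
#' @param panel a `lipid_panel`
#' @param path output BED path
#' @return invisibly, the path
#' @export
export_bed <- function(panel, path) {
  tr <- target_regions(panel)
  bed <- data.frame(chrom = tr$chromosome, start = tr$start - 1L,
                    end = tr$end, name = tr$gene)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.lipid_panel <- function(x, ...) {
  cat("<lipid_panel> ", nrow(x$genes), " genes (",
      paste(vapply(PANEL_CATEGORIES, function(cc)
        sum(x$genes$category == cc), integer(1)), collapse = "/"),
      " by category), ", nrow(x$score_snps), " score SNPs (",
      paste(vapply(SCORE_TRAITS, function(tt)
        sum(x$score_snps$trait == tt), integer(1)), collapse = "/"),
      " LDL/TG/HDL), ", x$micro_seq_snp_count,
      " micro-sequenced SNP assays\n", sep = "")
  invisible(x)
}
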