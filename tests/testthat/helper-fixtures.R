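# Shared in-code fixtures: a tiny panel, variant constructors, and a
# small depth-matrix builder. Everything is generated, nothing stored.

tiny_panel <- function() {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  genes <- data.frame(
    symbol = c("LDLR", "APOB", "PCSK9", "LPL", "APOA5", "LMNA"),
    category = c(rep("monogenic_dyslipidemia", 5), "lipodystrophy"),
    chromosome = c("chr19", "chr2", "chr1", "chr8", "chr11", "chr1"),
    intervals = c("100-200;300-400;500-600;700-800;900-1000",
                  "100-250;400-550", "1000-1100;1300-1400;1600-1700",
                  "200-300;500-600;800-900", "100-200;400-500",
                  "50-150;250-350"),
    interval_labels = c("5'UTR;Exon 1;Exon 2;Exon 3;3'UTR",
                        "Exon 1;Exon 2", "5'UTR;Exon 1;3'UTR",
                        "Exon 1;Exon 2;Exon 3", "Exon 1;Exon 2",
                        "Exon 1;Exon 2"),
    phenotypes = c("FH", "FH", "FH", "HTG", "HTG", "lipodystrophy"),
    inheritance = c("dominant", "dominant", "dominant", "recessive",
                    "recessive", "dominant"),
    stringsAsFactors = FALSE)
  snps <- data.frame(
    snp_id = c("rs_t1", "rs_t2", "rs_t3"),
    trait = c("LDL", "TG", "HDL"),
    trait_raising_allele = c("A", "G", "T"),
    beta = c(0.1, 0.2, 0.4),
    ref_allele_freq = c(0.3, 0.5, 0.2),
    chromosome = c("chr1", "chr2", "chr3"),
    position = c(1e6, 2e6, 3e6),
    ref_allele = c("A", "C", "T"),
    alt_allele = c("G", "G", "C"),
    stringsAsFactors = FALSE)
  gp <- file.path(dir, "genes.tsv")
  sp <- file.path(dir, "snps.tsv")
  write.table(genes, gp, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(snps, sp, sep = "\t", quote = FALSE, row.names = FALSE)
  load_panel(gp, sp, micro_seq_snp_count = 3L)
}

# one annotated-variant row with overridable fields
make_variant <- function(sample_id = "S1", gene = "LDLR",
                         chromosome = "chr19", position = 150L,
                         ref_allele = "A", alt_allele = "G",
                         zygosity = "heterozygous",
                         consequence = "missense",
                         population_maf = 0.001, cadd_phred = 25,
                         sift = "deleterious", polyphen2 = "unknown",
                         mutation_taster = "unknown") {
  data.frame(sample_id = sample_id, gene = gene, chromosome = chromosome,
             position = position, ref_allele = ref_allele,
             alt_allele = alt_allele, zygosity = zygosity,
             consequence = consequence, population_maf = population_maf,
             cadd_phred = cadd_phred, sift = sift, polyphen2 = polyphen2,
             mutation_taster = mutation_taster, stringsAsFactors = FALSE)
}

# random annotated-variant table for property tests
random_variants <- function(n, n_samples = 5) {
  data.frame(
    sample_id = sprintf("S%d", sample(n_samples, n, replace = TRUE)),
    gene = sample(c("LDLR", "APOB", "LPL", "LMNA"), n, replace = TRUE),
    chromosome = "chr1",
    position = sample(1000L, n, replace = TRUE),
    ref_allele = sample(c("A", "C"), n, replace = TRUE),
    alt_allele = sample(c("G", "T"), n, replace = TRUE),
    zygosity = sample(c("heterozygous", "homozygous"), n, replace = TRUE),
    consequence = sample(c("missense", "synonymous", "frameshift",
                           "stop_gain", "splice_donor", "inframe_indel",
                           "other"), n, replace = TRUE),
    population_maf = ifelse(runif(n) < 0.2, NA_real_, runif(n, 0, 0.2)),
    cadd_phred = runif(n, 0, 40),
    sift = sample(c("deleterious", "tolerated", "unknown"), n, TRUE),
    polyphen2 = sample(c("damaging", "benign", "unknown"), n, TRUE),
    mutation_taster = sample(c("disease_causing", "polymorphism",
                               "unknown"), n, TRUE),
    stringsAsFactors = FALSE)
}

# noisy depth matrix with one optional spiked event in the TEST sample
sim_depth_with_spike <- function(panel, n_ref = 20, spike_gene = NULL,
                                 spike_targets = NULL, ratio = 1,
                                 seed = 1, depth = 200) {
  set.seed(seed)
  tg <- panel_targets(panel)
  samples <- c("TEST", sprintf("R%02d", seq_len(n_ref)))
  eff <- exp(rnorm(nrow(tg), 0, 0.3))
  lib <- exp(rnorm(length(samples), 0, 0.15))
  mu <- outer(depth * eff, lib)
  if (!is.null(spike_gene)) {
    rows <- which(tg$gene == spike_gene)[spike_targets]
    mu[rows, 1] <- mu[rows, 1] * ratio
  }
  d <- matrix(rnbinom(length(mu), size = 1000, mu = mu), nrow(mu),
              ncol(mu), dimnames = list(NULL, samples))
  depth_matrix(tg, d)
}

# depth matrix on a panel with a flat expected profile
flat_depth <- function(panel, samples, depth = 200) {
  tg <- panel_targets(panel)
  d <- matrix(depth, nrow(tg), length(samples),
              dimnames = list(NULL, samples))
  depth_matrix(tg, d)
}
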