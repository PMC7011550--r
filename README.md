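# lipidpanel

Targeted-panel genetic characterization of dyslipidemias in R.

Clinical lipid genetics uses hybrid targeted sequencing panels that
capture, in one assay, (1) the exons of genes causing monogenic
dyslipidemias, lipodystrophies and monogenic diabetes, and (2) common
GWAS SNPs from which small weighted polygenic scores are built. This
package implements the analysis downstream of such a panel, for lipid
clinic laboratories and methods researchers:

* **Rare-variant prioritization** — the staged filter cascade over
  annotated variants: all unique variants → rare (MAF ≤ 1% or absent
  from the population database) → protein-altering → predicted
  deleterious (SIFT / PolyPhen2 / MutationTaster, with LOF ontologies
  bypassing the tools), plus the LOF and CADD ≥ 20 subsets.
* **Read-depth CNV calling** — normalized depth ratios of a test sample
  against a panel of CNV-free reference samples; per-target z-score
  detection, run-mean state typing (het deletion ≈ 0.5, hom deletion
  ≈ 0, duplication ≈ 1.5), and aggregation of calls into a unique-CNV
  catalogue keyed by lesion (gene, region, event type, breakpoint).
* **Polygenic scores** — per trait *t* ∈ {LDL-C, TG, HDL-C},
  PS_t = Σᵢ gᵢ βᵢ with gᵢ ∈ {0,1,2} trait-raising allele counts and βᵢ
  GWAS betas; a score is *extreme* when ≥ the nearest-rank 90th
  percentile of a normolipidemic reference cohort (inclusive).
* **Genetic profiles and reports** — per patient: phenotype (referral,
  or lipid thresholds: TG ≥ 10, LDL > 5.0, TG ≥ 1.8 mmol/L, Lp(a) ≥ 36
  mg/dL), phenotype-relevant rare findings (CADD ≥ 10 plus a damaging
  call, in the phenotype's gene set), the four-way profile category
  (rare only / rare + extreme / extreme only / none), gene/zygosity
  diagnosis rules (HeFH, HoFH, sitosterolemia, familial chylomicronemia
  syndrome, FPLD, MODY, ...), and report rendering (JSON and text) that
  discloses only the phenotype-matched score, as both a weighted score
  and a simple allele tally.
* **A synthetic cohort generator** with full ground truth (variants,
  CNV spike-ins, HWE score genotypes, lipids), so the whole pipeline is
  testable without patient data.

## Worked example

```r
library(lipidpanel)

panel <- default_panel()
panel
#> <lipid_panel> 69 genes (25/16/13/15 by category), 35 score SNPs
#> (10/16/9 LDL/TG/HDL), 185 micro-sequenced SNP assays

# aggregate a published CNV call catalogue into unique lesions
calls <- read_cnv_catalogue(system.file("extdata", "cnv_catalogue.tsv",
                                        package = "lipidpanel"))
u <- aggregate_unique(calls)
attr(u, "unique_count"); attr(u, "instance_count")
#> [1] 77
#> [1] 191

# score a heterozygote at all 10 LDL SNPs and classify against a reference
snps <- panel$score_snps[panel$score_snps$trait == "LDL", ]
sc <- compute_score(setNames(rep(1, nrow(snps)), snps$snp_id), snps)
sc$raw_score                       # mmol/L-scale weighted sum over 10 loci
#> [1] 1.013916
ref <- simulate_reference(sim_config(seed = 1), panel)
percentile_of(sc$raw_score, ref$ref_scores$LDL)
#> [1] 29.42346  — mid-distribution, not an extreme score

# cohort characterization from published category counts (FH, N = 924)
summarize_cohort(cohort_from_counts(354, 39, 76, 455), "FH")
#>             metric count percent
#>   any_rare_variant   393    42.5
#>     any_extreme_ps   115    12.4
#>          rare_only   354    38.3
#>  rare_plus_extreme    39     4.2
#>       extreme_only    76     8.2
#>               none   455    49.2
```

42.5% of this FH cohort carry a relevant rare variant and 49.2% have no
identifiable genetic determinant; the four categories partition the
cohort exactly.

## Analysis workflow

The `analysis/` scripts run the whole pathway on a simulated cohort,
writing tables under `results/` (raw simulated data goes to `scratch/`):

```sh
Rscript analysis/01_simulate_cohort.R     # panel + 200 patients + reference
Rscript analysis/02_prioritize_variants.R # filter cascade, stage counts
Rscript analysis/03_call_cnvs.R           # CNV calls + unique-CNV tables
Rscript analysis/04_polygenic_scores.R    # 3 trait scores + extreme flags
Rscript analysis/05_genetic_profiles.R    # profiles, diagnoses, reports
Rscript analysis/06_cohort_tables.R       # cohort characterization tables
```

## Layout

* `R/` — package code: panel model, variant IO, prioritization,
  CNV caller, polygenic scores, profiles, reports, synthetic data.
* `inst/extdata/` — shipped configs: synthetic 69-gene panel and score
  SNPs (labelled synthetic), diagnosis rules, the unique-CNV catalogue,
  report JSON schema.
* `vignettes/methods.Rmd` — the model, parameter and design rationale.
* `tests/testthat/` — unit, property and acceptance tests.
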