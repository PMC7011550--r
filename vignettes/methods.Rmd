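---
title: "Methods: targeted-panel genetic characterization of dyslipidemias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted-panel genetic characterization of dyslipidemias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidpanel)
```

# The problem

Dyslipidemias — extreme deviations of plasma lipids or lipoproteins — have
two broad genetic architectures. Monogenic forms are driven by rare
variants (single-nucleotide variants, small indels, or copy-number
variants) in established causal genes; polygenic forms reflect an
accumulation of common trait-raising alleles of individually small effect.
A hybrid targeted sequencing panel can interrogate both at once: deep
coverage of the exons (plus flanking intronic sequence and UTRs) of genes
for monogenic dyslipidemias, lipodystrophies and monogenic diabetes, and
micro-sequenced common SNPs from which small weighted polygenic scores are
built for LDL cholesterol, triglyceride and HDL cholesterol.

`lipidpanel` implements the analytic pathway downstream of such a panel:

1. **Rare-variant prioritization** — a staged filter cascade over
   annotated variants.
2. **CNV calling** — read-depth comparison of a test sample against a
   reference panel of CNV-free samples, and aggregation of calls into a
   unique-CNV catalogue.
3. **Polygenic scores** — weighted allele-count scores with
   percentile-based extreme classification against a normolipidemic
   reference.
4. **Genetic profiles and reports** — the per-patient synthesis of rare
   and polygenic findings into a four-way profile category, a diagnosis
   where gene/zygosity rules support one, and a patient report.
5. **A synthetic cohort generator** providing ground truth for every
   stage, since patient-level data from clinical cohorts of this kind
   cannot be shared.

# Panel model

The default panel configuration ships 69 genes split 25/16/13/15 across
four categories (monogenic dyslipidemia, lipodystrophy, MODY/inherited
diabetes, candidate genes) and 35 score SNPs (10 LDL, 16 TG, 9 HDL) out of
185 micro-sequenced assays. Gene symbols, category membership,
phenotype→gene links and inheritance modes follow the clinical literature
(e.g. FH → LDLR/APOB/PCSK9; hypertriglyceridemia → LPL/APOA5/LMF1/
GPIHBP1/APOC2; lipodystrophy → LMNA/PPARG; MODY → HNF1A/GCK;
hypoalphalipoproteinemia → LCAT/APOA1/ABCA1). Genomic coordinates, rsIDs,
beta weights and allele frequencies in the shipped files are **synthetic
stand-ins** — the real panel's GWAS-derived SNP lists and weights are not
reconstructible from public summaries — and the file names say so.
Coordinates are held 1-based inclusive internally (matching VCF) and
exported 0-based half-open in BED.

Score-SNP betas are stored at full precision. Coarsely rounded weights put
the small scores on a discrete grid, which manufactures exact score ties;
ties at the 90th-percentile threshold inflate the extreme-score rate above
its nearest-rank bound. Samples with identical genotypes at all of a
trait's SNPs still tie exactly — that is a real property of small SNP
scores, not an artifact.

# Rare-variant prioritization

The cascade applies, in order, to the cross-sample **unique** variant set
(identity = chromosome:position:ref:alt):

1. **Rare**: population MAF ≤ 1% *or absent* from the population
   database. Absence is encoded as a distinct marker (`NA`), not 0.0,
   because "not observed" is rare by definition while 0.0 is an observed
   frequency. The boundary is inclusive.
2. **Protein-altering**: missense, stop gain/loss, frameshift, in-frame
   indel, splice acceptor/donor. Synonymous and non-coding consequences
   drop out.
3. **Predicted deleterious**: under the default `any_tool` policy, at
   least one of SIFT (deleterious), PolyPhen2 (damaging), MutationTaster
   (disease causing); configurable to `all_tools` for sensitivity
   analysis. Loss-of-function ontologies (frameshift, splice
   acceptor/donor, stop gain/loss) bypass the tools entirely, since
   missense-oriented predictors do not score truncating variants.

Two subsets of the survivors are reported: the LOF-ontology subset, and a
stricter clinical-interest tier at CADD PHRED ≥ 20 (inclusive). A separate
*phenotype relevance* rule gates what reaches a patient's profile: gene in
the phenotype's causal set, rare, protein-altering, CADD ≥ 10, and at
least one damaging tool call or a LOF ontology.

# CNV calling

Depth matrices hold mean read depth per panel target (exon/UTR) per
sample. Normalization is two-step: columns are scaled to a common median
(library size), then each row is divided by its mean over the reference
samples (target capture efficiency), so a diploid target sits near ratio
1, a heterozygous deletion near 0.5, a duplication near 1.5.

Detection and typing are deliberately separated:

* **Detection**: a target is anomalous when the test ratio's z-score
  against the reference samples satisfies |z| ≥ 3. Maximal runs of
  consecutive same-direction anomalous targets within one gene are
  candidate events (`min_targets` defaults to 1 — single-exon events are
  clinically real). A combined run significance |mean z|·√n ≥ 5 is also
  required: per-target z-scores at low-coverage targets are noisy enough
  that, across hundreds of targets and many samples, single targets
  otherwise drift over a band edge.
* **Typing**: the run's **mean** ratio assigns the state — homozygous
  deletion < 0.15, heterozygous deletion 0.35–0.65, duplication
  1.35–1.75. Typing on per-target band membership would split true
  multi-exon duplications (at 200× depth a 1.5× target misses the
  duplication band ~18% of the time); the run mean shrinks that noise by
  √n. Runs whose mean ratio lands outside every band are discarded.

At these defaults, on the generator's default depth model, ≥90% of
embedded 2–6-target events are recovered with exact state and false calls
on null samples stay at or below about 1 per 50 samples. All bands and
thresholds are explicit configuration (`caller_params()`), since they are
method choices, not biological constants.

Aggregation groups calls by (gene, region, event type, breakpoint tag).
The identity of a unique CNV is the *lesion*: heterozygous and homozygous
carriers of the same deletion fall in one row (with a zygosity summary
such as `hom x2, het`), while same-span events with different breakpoints
remain distinct rows. Depth-only evidence cannot resolve breakpoints;
breakpoint tags must come from upstream evidence, and calls made by this
package carry an empty tag — a documented limitation.

# Polygenic scores

For each trait the raw score is Σᵢ gᵢβᵢ over the trait's SNPs, where gᵢ ∈
{0, 1, 2} counts trait-raising alleles and βᵢ is the GWAS effect size
oriented so βᵢ > 0. Missing genotypes contribute nothing, and the number
of loci actually used is recorded. An unweighted allele tally is computed
alongside for reporting: patients grasp "x of 2n trait-raising alleles"
more readily than a weighted statistic.

A score is **extreme** when it is at or above the 90th percentile of a
normolipidemic reference cohort (default size 503, the size of the
European subgroup of a public reference panel). The threshold is the
nearest-rank percentile — a realized reference value, no interpolation —
and the comparison is inclusive, so self-scoring a tie-free reference
flags a fraction in [0.10, 0.10 + 1/n]. Whether to interpolate is not
determined by the clinical rule as usually stated; nearest-rank keeps the
threshold interpretable as "the score of an actual reference individual".

# Phenotypes, profiles, diagnoses

When no referral phenotype accompanies a sample, lipid values assign one
by fixed precedence: severe hypertriglyceridemia (TG ≥ 10 mmol/L) >
familial combined hyperlipidemia (LDL > 5.0 **and** TG ≥ 1.8) > suspected
FH (LDL > 5.0, strict) > hypertriglyceridemia (TG ≥ 1.8, inclusive) >
elevated Lp(a) (≥ 36 mg/dL) > unclassified. Referral phenotype, when
present, overrides the computed assignment — in clinical practice
phenotype comes from referral, and the precedence order is this package's
own convention. Units are mmol/L (Lp(a) mg/dL); conversions ×38.67
(cholesterol) and ×88.57 (triglyceride) to mg/dL are provided.

The four-way profile category combines relevant rare findings (SNVs,
indels and CNVs all count) with the phenotype-matched extreme-score flag:
rare only / rare + extreme / extreme only / none. Each phenotype maps to
exactly one disclosed trait (FH-spectrum → LDL; HTG-spectrum → TG; HDL
phenotypes → HDL; phenotypes without a natural match, including elevated
Lp(a) and unclassified, disclose the LDL score — a package convention, as
one score must be disclosed and LDL is the default lipid axis).

Diagnosis rules are a shipped, ordered gene/zygosity table (first match
wins): e.g. biallelic LDLR/APOB/PCSK9/LDLRAP1 in an FH context → HoFH;
biallelic ABCG5/ABCG8 → sitosterolemia; heterozygous LDLR/APOB/PCSK9 →
HeFH; biallelic lipolysis genes in HTG → familial chylomicronemia
syndrome (biallelic APOC2 is labelled APOC2 deficiency). Biallelic status
from unphased genotypes treats two heterozygous variants in one gene as
in trans — an over-call risk that phased data would resolve. Report
categories follow clinical disclosure practice: (a) new genetically based
diagnosis, (b) confirmation of a prior diagnosis (an input flag carries
prior clinical suspicion), (c) relevant finding short of a diagnosis,
(d) negative, with the standard negative wording.

# The synthetic cohort generator

The generator emulates the *structure* of a large clinical panel cohort;
it does not emulate real sequence data. Defaults, chosen once:

* **Phenotype mix**: HTG 40.1%, FH 28.3%, the remainder split across HDL
  phenotypes, lipodystrophy, MODY, elevated Lp(a) and unclassified —
  matching the composition reported for the cohort the pipeline is
  modelled on.
* **Carrier rates**: FH 42.5%, HTG 23.9%, recessive phenotypes ~30–50% —
  the reported rare-variant carriage fractions. Causal variants are
  phenotype-concordant: gene drawn from the phenotype's set,
  protein-altering ontology, CADD ≥ 12, at least one damaging tool call,
  MAF ≤ 1% or absent; homozygous when the gene is recessive. Benign
  filter fodder (common missense, rare synonymous, rare tolerated
  missense) is drawn from a shared pool so unique-variant deduplication
  is exercised.
* **Score genotypes**: Hardy–Weinberg draws at each SNP's configured
  frequency; in affected patients the phenotype-matched trait's SNPs use
  odds multiplied by 1.3, which yields roughly the ~30% extreme-score
  prevalence reported for hypertriglyceridemia cohorts.
* **Depth**: negative-binomial counts with mean 200× scaled by a
  per-target lognormal capture-efficiency factor (σ = 0.3, removed by
  normalization) and a per-sample lognormal library factor (σ = 0.15).
  The NB size of 1000 leaves near-Poisson residual noise per target —
  the regime in which per-exon mean depth operates after averaging over
  a target. Embedded CNVs multiply depth by 0.5 (het deletion), 0.05
  (hom deletion) or 1.5 (duplication).
* **Lipids**: phenotype baseline + a polygenic contribution proportional
  to the standardized matched-trait score + a large rare-variant effect +
  Gaussian noise, calibrated so affected carriers typically cross the
  phenotype thresholds. The effect sizes are synthetic constants; no
  generative model of lipids is claimed.
* **Annotation noise** (default 2%): a causal variant's prediction-tool
  calls are flipped to benign, emulating annotator miscalls. With noise
  off, the pipeline recovers the generator's profile categories exactly;
  with default noise, recovery stays above 95%.

All randomness flows from a single seed; identical configurations
reproduce identical files byte for byte.

What passing tests on this generator do **not** show: robustness to
alignment artifacts, batch effects in capture efficiency, population
stratification of score SNPs, linkage disequilibrium between score SNPs,
annotation disagreement across database eras, or phasing errors. The
generator is a correctness harness, not a realism claim.

# Problem sizes and numerical choices

The shipped analyses and tests run at deliberately modest sizes — cohorts
of 100–200 patients, a 503-sample score reference (10,000 where a
law-of-large-numbers check needs it), 20-sample depth reference panels,
50-null-sample specificity checks — sizes a laptop handles in seconds
while still giving the binomial/Gaussian bounds quoted above.
Percentages in cohort tables round half away from zero to one decimal
(so 393/924 → 42.5%), matching how clinical tables are typeset.
Degenerate inputs fail loudly: empty panels, all-zero depth columns,
genotype counts outside {0, 1, 2}, all-null lipid profiles and unknown
phenotype keys are errors, not warnings.

# Known limitations

* Breakpoint-level CNV uniqueness requires external evidence.
* Unphased biallelic calls over-call compound heterozygotes.
* The percentile reference is synthetic by default; a real
  ancestry-matched reference should replace it in any real analysis.
* One prediction-tool policy (`any_tool`) is the default everywhere; the
  `all_tools` alternative is available but cohort numbers depend on the
  choice.
* Published cohort-level counts that depend on patient-level genotypes
  cannot be recomputed here; only their published arithmetic
  (percentages from counts, catalogue aggregation) is reproduced.
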