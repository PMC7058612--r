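---
title: "Methods: mitochondrial genome structure, imputation and PheWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitochondrial genome structure, imputation and PheWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`mitolandscape` implements the statistical toolkit used to characterize
the human mitochondrial genome (mtDNA) at population scale from
whole-genome sequencing: variant spectra, haplogroup assignment,
unsupervised sample classification, haploid linkage disequilibrium (LD)
with a distance-matched nuclear comparison, mtDNA copy number (mtCN)
from depth ratios, genome-wide mtDNA–nDNA and mtCN–nDNA association
scans, haploid genotype imputation with cross-validation, and a
mitochondrial phenome-wide association study (PheWAS). Upstream read
alignment and variant calling are out of scope: the package starts from
haploid VCF genotypes, depth summaries and phenotype tables.

Because population-scale WGS and biobank phenotypes are access
controlled, the package ships a synthetic-cohort generator that
reproduces the statistical structure every downstream stage relies on.
All tests and the reproduction script run on generated data only.

# Data model

mtDNA is a circular molecule of 16,569 bp (rCRS coordinates, 1-based)
present in many copies per cell and inherited without recombination.
The package treats homoplasmic variants as haploid genotypes: calls are
0 (reference), 1 (alternative) or missing. Heterozygous-style calls on
the mitochondrial contig — heteroplasmy-like mixtures — are set to
missing on input; the analyses model homoplasmy only. Multiallelic
sites are split into biallelic records sharing a position, and all
downstream LD and association work uses biallelic records.

# Haplogroup assignment

Haplogroups are named clades of mtDNA haplotypes on a rooted haplotree;
each edge carries defining variant alleles, and hierarchical names
alternate letters and digits (M, M7, M7a, ...), so name length equals
hierarchy depth ("D4b" is depth 3, counting digits). The expected
variant set of a node is the union of defining alleles on its root
path; a flagged back-mutation removes its target allele for the node
and its descendants.

A sample with observed allele set $O$ is scored against each node's
expected set $E$ with the symmetric Kulczynski similarity

$$s(O, E) = \tfrac{1}{2}\left(\frac{|O \cap E|}{|E|} +
\frac{|O \cap E|}{|O|}\right),$$

and assigned to the maximizing node, ties broken toward greater name
depth then lexicographic order. Published haplogroup classifiers use
tool-specific weighting schemes; the unweighted Kulczynski score
preserves the same decision structure while being fully specified and
testable. On noiseless simulated cohorts (no private mutations)
recovery is exact; private mutations only inflate $|O|$, and recovery
stays above 95% at the default mutation load.

# Unsupervised classification

Three complementary views of the same call matrix:

* **Phylogeny.** Pairwise Hamming distances (proportion of discordant
  calls over jointly observed sites, pairwise deletion) feed standard
  neighbor joining. Parsimony claims are quantified by Fitch scoring on
  the fixed NJ topology — the exact dynamic program, correct for binary
  trees including the unrooted trifurcation NJ produces. NJ replaces a
  heuristic parsimony tree search: it is deterministic, recovers
  additive topologies exactly, and serves the same downstream role
  (lineage visualization and clade checks).
* **PCA.** Mean-centered calls (missing imputed to the variant mean),
  top 20 components with explained-variance ratios.
* **UMAP.** Two components with `n_neighbors = 100` and
  `min_dist = 0.99`, the settings used for mtDNA variant patterns, and
  a fixed random state. The embedding is delegated to the
  `umap-learn` library through the `python` interpreter; its internals
  are outside the package's test surface beyond determinism and
  cluster quality.

Agreement between embedding-derived clusters and haplogroup labels is
quantified with the adjusted Rand index.

# Haploid LD structure

For two haploid variants, $D = p_{11} - p_x p_y$ over jointly observed
haplotypes,

$$r^2 = \frac{D^2}{p_x(1-p_x)\,p_y(1-p_y)}, \qquad
|D'| = \frac{|D|}{D_{\max}},$$

the original haplotype definitions; $r^2$ equals the squared Pearson
correlation of the 0/1 vectors, an identity the tests assert. Variants
monomorphic over the compared haplotypes are undefined and excluded.

The nuclear contrast is computed on phased haplotypes (2N gametes) from
random common-variant pairs restricted to ±8.3 kbp — the mtDNA molecule
scale — so the two decay analyses compare like with like. LD decay is
summarized by the Pearson correlation between pair distance and $r^2$:
clearly negative for recombining nuclear variants, indistinguishable
from zero for mtDNA.

Tag counting reports, per common variant (MAF ≥ 5%), the number of
other common variants with $r^2 \ge 0.5$ (nuclear search restricted to
±5 Mbp, mtDNA unrestricted) and the fraction with none. Spanning
haplotypes are connected components of the $r^2 \ge 0.8$ graph whose
positional extent covers at least 90% of the molecule; the extent is
the max–min member coordinate on the rCRS. Distances use linear rCRS
coordinates throughout, the conventional practice. Enrichment of
untagged variants in the control region (D-loop, 16,024–16,569 plus
1–576, wrapping the origin) is tested by Fisher's exact test on the
2×2 of untagged × in-region.

# mtCN and genome-wide scans

mtCN is estimated from mean depths as

$$\mathrm{mtCN}_c = \frac{\text{mean mtDNA depth}}
{\text{mean autosomal depth}_c} \times 2,$$

averaged over autosomes; the estimate is invariant to global depth
rescaling, and chromosomes with zero depth are excluded with a warning.

The mtDNA–nDNA scan fits, per (common mtDNA variant, nuclear variant)
pair, a logistic regression with the haploid mtDNA allele as the
response and nuclear dosage plus covariates (top PCs, run batches) as
predictors, reporting Wald p-values; separated or non-convergent fits
are flagged rather than dropped. The mtCN–nDNA scan is ordinary linear
regression, computed by covariate residualization
(Frisch–Waugh), numerically identical to `lm()` and verified as such.
Manhattan summaries use the per-nuclear-variant minimum p over mtDNA
variants. Significance thresholds are Bonferroni products, e.g.
$5\times10^{-8}/86$ mtDNA variants; QQ calibration uses the genomic
inflation factor $\lambda$ (median observed $\chi^2_1$ over 0.4549).
Nuclear variants enter after call rate ≥ 0.99, MAF ≥ 1% and exact-test
HWE $p \ge 10^{-6}$ filters; mitochondria-related gene annotations are
applied as ±10 kbp windows.

# Haploid imputation

Imputation uses a haploid Li–Stephens-style copying hidden Markov
model: the hidden state is which reference haplotype the target copies;
between adjacent typed sites the state switches to a uniformly chosen
haplotype with probability `switchRate`, and typed alleles are emitted
with mismatch probability `errorRate`. Defaults are
`switchRate = 1e-8` — effectively a single copying state, the
zero-recombination expectation for mtDNA (the analogue of running a
diploid imputer with a flat, zero recombination map) — and
`errorRate = 1e-3`. Posteriors come from the forward–backward
algorithm (normalized per step; implemented in C++); untyped variants
take the posterior-weighted average of reference alleles at the nearest
typed site (ties to the left — immaterial at the default switch rate).
The implementation is verified against brute-force enumeration over all
copying-state paths on small panels.

The per-variant info score is the haploid form of the standard
imputation quality metric,
$1 - \overline{d(1-d)}/(\hat p(1-\hat p))$ with $\hat p$ the mean
dose: 1 for hard calls, 0 at maximal uncertainty, undefined for
monomorphic estimated frequency. Post-imputation filters keep variants
with MAF ≥ 0.5% and info ≥ 0.7.

Reference-panel quality is measured by masking cross-validation: 50% of
calls are masked uniformly at random, each sample is imputed from all
other samples (leave-one-out copying states), doses are hard-called at
0.5 with ties to the reference allele, and concordance is reported
overall and — restricted to true minor-allele carriers — per MAF bin
(0–5, 5–10, 10–20, 20–30, 30–40, 40–50%). The minor-allele restriction
is used because overall concordance is dominated by easy
reference-allele calls. A fully masked sample has one call re-exposed
with a warning.

# PheWAS

Binary traits are tested by logistic regression of case status on the
imputed dosage with age, sex, top-20 PCs, geographic region and
genotyping platform as covariates; controls are all samples not
affected by the trait under scope. Quantitative traits are first
regressed on age, sex, PCs and trait-specific covariates, the
residuals rank-transformed through the normal quantile function with
the Blom offset $(r - 3/8)/(n + 1/4)$ (average ranks for ties), and
then tested by linear regression on the dosage with region and
platform additionally included. Rank normalization makes results
invariant under monotone (hence affine) transforms of the raw
phenotype. Dosages, not hard calls, enter the models. Two significance
levels are flagged: study-wide $0.05/(V \times P)$ and variant-wide
$0.05/V$, strict inequalities. Array genotypes pass three QC filters in
order — sample call rate ≥ 0.9, variant call rate ≥ 0.99, and ≥ 0.99
concordance with sequencing calls over overlapping samples.

# The synthetic cohort generator

The generator's defaults are the study conditions the analyses assume:

* **Cohort**: 1928 samples over 7 geographic regions (the scale of the
  motivating WGS panel).
* **Haplotree**: 11 single-letter macrohaplogroups, names up to 9
  characters, each node spawning 0–3 children (mean 1.5), giving a few
  hundred nine-letter lineages; each edge carries ≥ 1 defining variant
  at a position unique across the tree. Region-specific haplogroup
  frequencies are Dirichlet perturbations (concentration 20) of a
  global spectrum, emulating regional heterogeneity.
* **Haplotypes**: a sample's calls are its leaf's root-path union plus
  private mutations — no recombination anywhere. The mean private
  mutation rate is 2×10⁻⁵ per site per sample, calibrated so a cohort
  of ~2000 samples segregates on the order of 2000 variant sites, the
  scale reported for deep-WGS mtDNA panels. Per-site mutability is
  lognormal (sdlog 2, mean 1) to create recurrent hotspot sites, and
  D-loop sites mutate 10× faster; derived alleles are
  transition-biased (~16:1) to match the mitochondrial mutational
  spectrum. Recurrent hypermutable sites are what produce common,
  tree-independent — hence untagged — D-loop variants.
* **Nuclear contrast**: 2000 variants on a 2 Mbp region; 2N haplotypes
  copy 20 founders (allele frequencies U(0.05, 0.5)) with switches at
  an effective rate of 10⁻⁴ per bp. The rate is population-scaled:
  it stands in for per-meiosis recombination accumulated over
  coalescent history, so r² decays over kilobase distances as in real
  cohorts.
* **Depths and phenotypes**: true mtCN lognormal around 100
  copies/cell (sdlog 0.3); per-chromosome autosomal depth ~30×;
  `mt_depth = mtCN/2 × mean autosomal depth × lognormal noise`
  (sdlog 0.05). Quantitative phenotypes are covariate effects plus
  optional injected per-allele variant effects plus unit Gaussian
  noise; binary phenotypes use a logistic model on the same linear
  predictor.

One master seed fans out to fixed per-generator substreams, so the
whole pipeline is reproducible and adding one generator never perturbs
another.

What the generator does **not** emulate: heteroplasmy and its
read-level evidence, nuclear-embedded mitochondrial segments (nuMTs),
selection, coalescent-exact genealogies, realistic phenotype
correlation structure, and population-specific haplotree content.
Passing tests therefore demonstrate that the statistical machinery is
correct and calibrated under the assumed data-generating structure,
not that real-cohort point estimates are reproduced.

# Numerical choices and degenerate inputs

* LD values are clamped to [0, 1] against floating-point overshoot;
  monomorphic pairs are undefined (`NA`), never silently zero.
* The forward–backward recursions renormalize at every step; an
  all-mismatch emission with `errorRate = 0` raises an explicit
  underflow error rather than returning garbage.
* Logistic separation is detected via boundary fitted probabilities
  and blown-up standard errors; such fits are reported with a flag and
  no p-value. Firth-type corrections are not implemented.
* The HWE exact test enumerates the conditional distribution of the
  heterozygote count in log space (two-sided, summing probabilities no
  larger than the observed configuration's).
* Zero-variance inputs (constant mtCN, constant phenotype, constant
  r² vector) raise errors or warnings naming the condition.
* Assignment ties are broken deterministically (depth, then name);
  hard-call ties at dose 0.5 go to the reference allele.

# Problem sizes used in the shipped checks

The test suite and the reproduction script run at sizes chosen to
exercise the statistical behavior on a desktop: cohorts of 150–500
samples for unit properties; 20 seeds × 300 samples for the LD-decay
null; a 2000-haplotype cohort for imputation cross-validation; 10⁴
tests for null-scan calibration (λ within 1.00 ± 0.05); and n = 2000
to 9000 single-variant runs for power checks. The study-scale defaults
(n = 1928) are used in `scripts/acceptance.R`.

# Known limitations

* Haplogroup scoring is unweighted; tool-specific per-variant weights
  and quality ranks are not reproduced.
* The imputer is haploid-only: no diploid phasing, no chunking for
  nuclear-scale panels.
* Logistic scans at genome scale are loop-based R fits; they are
  intended for the mtDNA-sized problems the package targets.
* Circular coordinates are respected in region membership (the D-loop
  wraps the origin), but pair distances and spanning extents use
  linear rCRS coordinates.
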