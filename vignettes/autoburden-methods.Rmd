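---
title: "Recessive burden testing under autozygosity: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recessive burden testing under autozygosity: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(autoburden)
```

## The problem

In populations with a high rate of consanguineous unions, a substantial
fraction of each genome lies in runs of homozygosity. At a site with minor
allele frequency $q$, an individual with inbreeding coefficient $F$ is
homozygous for the minor allele with probability

$$P(\text{hom}) = q^2 + q(1-q)F,$$

instead of the Hardy–Weinberg $q^2$. For rare alleles ($q \ll 1$) the excess
term $q(1-q)F$ dominates, so autozygous cohorts harbor many more rare
biallelic genotypes — including complete "knockouts" of a gene by
loss-of-function variants — than outbred cohorts of the same size. That excess
is exactly what gives recessive association tests their power here, and what
this package models, detects and exploits.

The pipeline collapses biallelic genotypes (homozygous, or
compound-heterozygous: two distinct variants in trans) into per-gene 0/1
recessive burdens, tests them against quantitative and binary traits with
covariate adjustment, calibrates significance by genotype permutation,
meta-analyzes across cohorts, and catalogs knockout genes for drug-target
analyses. A synthetic cohort generator with the same statistical structure
validates every stage against known truth.

## The synthetic cohort generator

The generator is first-class, tested code, not a fixture. It emulates:

* **Rare variation in genes.** Per-site allele frequencies are drawn
  log-uniformly from a configurable spectrum (default $10^{-4}$–$5\times
  10^{-2}$), sites are grouped into genes (Poisson number of sites per gene,
  minimum one), and each site receives a consequence class
  (pLoF-HC / pLoF-LC / missense / synonymous) with damage-score surrogates for
  missense sites.
* **Autozygosity by gene-level IBD copying.** Each sample draws an inbreeding
  coefficient from a two-point mixture: with probability 0.33 it is
  "consanguineous" with $F = 0.05$, otherwise background with $F = 0.002$.
  For each gene, with probability $F_i$ the sample's second haplotype is
  copied identical-by-descent from the first; otherwise both are drawn
  independently from a founder haplotype pool. This reproduces the
  $q^2 + q(1-q)F$ homozygote excess by construction and depletes
  compound heterozygotes as $F$ grows (an IBD-copied gene cannot carry two
  distinct variants in trans). Autozygosity is modeled per gene rather than
  as per-base ROH tracts: the downstream statistics are all gene-collapsed,
  so recombination-map machinery would add realism the analyses never see.
* **Phasing noise.** Each heterozygous genotype's reported haplotype
  assignment is flipped with probability `phase_error_rate` (default 0.05),
  and a reported phasing probability is drawn from a Beta distribution whose
  shape differs between correct (default Beta(30, 1.5), mean ≈ 0.95) and
  flipped (Beta(6, 3), mean ≈ 0.67) genotypes, so the reported probability is
  informative about correctness, as the posterior of a statistical phaser is.
  A zero error rate models a perfect phaser and reports probability 1. Truth
  is retained separately for evaluation.
* **Phenotypes.** One trait per call of `simulate_phenotypes()`, generated
  from the joint model
  $y = \beta\, g_\mathrm{add} + \gamma\, g_\mathrm{domdev} +
  \beta_\mathrm{rec}\, \mathbf{1}[g = 2] + \text{covariates} + \varepsilon$,
  where $g \in \{0,1,2\}$ is the true gene genotype (0 = no qualifying
  allele, 1 = alleles on one haplotype only, 2 = biallelic),
  $g_\mathrm{domdev}$ its 0/1/0 recoding. A gene carries either an
  additive/dominance pair or a recessive effect, never both. Binary traits use
  a logistic model whose intercept is solved numerically (`uniroot`) so the
  expected prevalence hits the target — matching the logistic models used in
  testing. Covariates are age, sex, age², and standard-normal
  principal-component surrogates.

**Why $F = 0.05$ and 0.002?** The cohort the defaults describe has 33% of
participants genetically determined to be offspring of second cousins or
closer, and a cohort-wide mean autozygous genome fraction near 1.8%. The
mixture mean $0.33 \times 0.05 + 0.67 \times 0.002 \approx 0.018$ matches
that, with the consanguineous component sitting between second-cousin
(0.015625) and first-cousin (0.0625) offspring, weighted toward first cousins
as self-reported parental relatedness suggests. The per-individual $F$
distribution beyond these summaries is not identified by published figures;
the two-point mixture is a parsimonious stand-in, not an estimate.

What the generator does **not** emulate: linkage disequilibrium beyond IBD
copying, recombination within genes, mutation-rate heterogeneity, relatedness
between samples, population substructure, or the X chromosome. Tests passing
on synthetic cohorts therefore validate the statistical machinery under the
stated model, not robustness to confounding by fine-scale structure — in real
data that robustness is delegated to the genotype-permutation FDR and
genomic control.

## Biallelic calling and burdens

Homozygote calls are genotype-2 entries at sites qualifying under a
consequence mask and a strict MAF cutoff. The four masks are
A = pLoF-HC; B = pLoF-HC + predicted damaging missense (CADD > 20,
PolyPhen-2 > 0.445 **and** SIFT-deleterious); C = all pLoF + all missense;
D = synonymous (negative control). AF bins (singleton, <0.01%, <0.1%, <1%)
nest: a singleton belongs to all four. MAF is computed on the minor allele;
sites with alt frequency above 0.5 are flipped for binning only and flagged,
since the upstream convention is not fixed.

Compound heterozygotes require two **distinct** qualifying heterozygous
variants reported on opposite haplotypes with pair phasing probability
strictly above 0.9. The pair probability is defined as the minimum of the two
genotypes' reported probabilities — the conservative choice; the upstream
rule is stated per genotype only. Samples with three or more qualifying hets
contribute their best-supported trans pair once: the 0/1 recessive burden
needs at most one biallelic event per sample and gene. Cis pairs and
unphased hets never produce calls. A sample that is both homozygous and
compound-heterozygous in a gene is counted once, with homozygous provenance.

Recessive burdens are 0/1 per gene; genes with fewer than 4 carriers are
flagged untestable and skipped by the scan. Additive burdens collapse
qualifying genotypes by max (default) or by sum capped at 2.

**Hardy–Weinberg expectation.** For a gene with qualifying allele frequencies
$q_i$ and $Q = \sum_i q_i$ (assuming at most one qualifying allele per
haplotype; $Q > 0.5$ is an error), the expected biallelic-carrier count is
$n(Q^2 + Q(1-Q)F)$; $F = 0$ gives the reference for the enrichment ratio.
$Q^2$ covers homozygotes and compound heterozygotes together under random
mating, so the observed numerator includes both call classes. The headline
enrichment is the **ratio of sums** across genes (total observed over total
expected) rather than the mean of per-gene ratios, which explodes when
per-gene expectations are tiny; both aggregations are reported.

## Association models

Plain covariate-adjusted regression replaces whole-genome ridge/LOCO
mixed-model machinery: the synthetic cohort is generated unrelated, and in
real data relatedness control is delegated to the permutation FDR (genotypes
are permuted, phenotype–covariate structure held fixed). SKAT-type
variance-component tests are out of scope; the burden arm is what all
headline results use.

* **Quantitative traits**: exact OLS. The scan path residualizes the trait
  and the whole dosage matrix on the covariates once (Frisch–Waugh) and then
  performs per-unit slope t-tests; equality with per-unit `lm()` is asserted
  in the tests to machine precision. An optional rank-based inverse-normal
  transform (Blom) is off by default, as no transform is prescribed for the
  main scans.
* **Binary traits**: maximum-likelihood logistic regression first; when the
  Wald P on the dosage falls below 0.01 or the fit fails (non-convergence,
  separation), the model is refitted by Firth penalized likelihood (Jeffreys
  prior $\tfrac12 \log\det I(\beta)$) and the penalized estimate with its
  likelihood-ratio P is reported. The Firth fit uses Newton–Raphson on the
  modified score with step-halving on the penalized likelihood, tolerance
  $10^{-8}$ on the score norm, at most 100 iterations, and a step cap of 5 on
  the linear predictor scale. Its intercept-only fit equals the closed form
  $(k + \tfrac12)/(n+1)$ and its maximum is cross-checked against an
  independent Nelder–Mead maximizer in the tests.
* **Dominance deviation**: the joint fit
  $y \sim \beta g_\mathrm{add} + \gamma g_\mathrm{domdev} + \text{covariates}$
  reports $\hat\beta$, $\hat\gamma$, a 1-df P for $\gamma$ (both Wald and
  LRT, since the upstream convention is ambiguous), and the 2-df LRT for
  $(\beta, \gamma)$ jointly. Without heterozygotes $\gamma$ is flagged
  inestimable. The fit is intended for unrelated subsets; in simulation all
  samples are unrelated so no flag is needed.
* **Inflation**: $\lambda = \mathrm{median}(\chi^2_\mathrm{obs}) /
  \mathrm{median}(\chi^2_1)$, with P values converted through the $\chi^2_1$
  quantile function.

Single-variant tests require minor allele count ≥ 5. Trait inclusion defaults
are ≥ 5,000 measured values (quantitative) and ≥ 100 cases (additive binary;
120 for the recessive scan). Missing genotypes are excluded pairwise, never
imputed: rare-variant dosage imputation would distort carrier counts.

## Permutation FDR

At candidate threshold $t$,
$\widehat{\mathrm{FDR}}(t) = \frac{\frac1K \sum_k \#\{P^{(k)}_\mathrm{perm}
\le t\}}{\max(1, \#\{P_\mathrm{obs} \le t\})}$
over $K$ permutations (default 100) of whole genotype rows against fixed
phenotypes. The curve is made non-decreasing by isotonic regression before
thresholding — raw plug-in curves are non-monotone at sparse observed P
values — and $t^\*$ is the largest observed P with smoothed FDR at or below
the target (default 5%). When no threshold attains the target, that is
reported rather than forced. Thresholds are derived per test family, with a
pooled option.

## Meta-analysis

Fixed effects with inverse-variance weights $w_k = 1/\mathrm{se}_k^2$:
$\hat\beta = \sum w_k \beta_k / \sum w_k$, $\mathrm{se} = 1/\sqrt{\sum w_k}$,
Cochran's $Q = \sum w_k (\beta_k - \hat\beta)^2$ with $K-1$ df. Genomic
control inflates per-study standard errors by $\sqrt\lambda$ when
$\lambda > 1$ (per-study, the meta-analysis convention; never deflation).
Units with opposite effect directions are flagged and excluded from
significance claims; alleles are harmonized by exact
(chrom, pos, ref, alt) key match only — strand-ambiguous rescue is out of
scope. Default meta significance thresholds: binary 3.3e-8 (single-variant) /
3.5e-8 (gene-based); quantitative 7.5e-9 / 4.5e-7.

## Knockouts, carrier review, drug transitions

A human knockout is a biallelic carrier of pLoF-HC variants at cohort
MAF < 1% in a gene (mask A). Accrual curves repeatedly downsample individuals
without replacement; within a repeat the subsets are nested, so every
repeat's curve is monotone. Carrier phenotype review uses a z-test on the log
scale for a single carrier and the Wilcoxon rank-sum test on log-transformed
values for two or more, with window-matched noncarriers (age ±5 y, sex,
ancestry, BMI ±5) and a fallback to all noncarriers below 20 matches.

Drug phase-transition enrichment: outcome = maximal trial phase beyond
threshold $k$ (run for $k = 1..3$ as single dichotomous outcomes); exposure =
any (default) or all target genes in the knockout catalog; headline model is
logistic regression adjusting for the number of target genes, with the
unadjusted Fisher exact OR alongside, stratified by mode of action
(antagonistic/agonistic from the printed action-type lists) and oncology
indication (text match on cancer/neoplasia/neoplasm/leukemia/tumor or words
ending in "-oma"; the suffix rule is applied literally, so "glaucoma" matches
unless stop-listed).

## Power

With carrier fraction $p_c = Q^2 + Q(1-Q)F$, the analytic arm uses the 1-df
Wald non-centrality $\mathrm{ncp} = n\,p_c(1-p_c)\,\beta^2/\sigma^2$
(quantitative) or $n\,p_c(1-p_c)\,K(1-K)\,\beta^2$ (binary, prevalence $K$),
and power $\Phi(\sqrt{\mathrm{ncp}} - z_{1-\alpha/2}) +
\Phi(-\sqrt{\mathrm{ncp}} - z_{1-\alpha/2})$. The empirical arm simulates
single-gene cohorts through the generator and counts rejections of the
recessive test; replicates whose gene fails the ≥ 4-carrier filter count as
non-rejections, because that is what the pipeline run on real data would do.
The two arms are compared only where expected carrier counts are comfortably
above the filter; near the filter boundary the no-filter analytic
approximation is deliberately optimistic relative to the pipeline.

## Numerical choices and problem sizes

Ties on MAF-bin boundaries use strict `<` as printed. SIFT is a categorical
call, not a score. The phasing-probability threshold is strict (> 0.9).
Comp-het tie-breaks: highest pair probability, then smallest positions.
Seeds are explicit everywhere; a fixed seed makes the cohort, phenotypes and
every downstream artifact reproducible byte for byte.

The validation suites run at sizes chosen to give stable Monte Carlo
estimates on a single CPU: dominance-deviation calibration at n = 5,000 with
1,000 replicates; effect recovery on a 3×3 grid at n = 5,000 with 40
replicates per cell; enrichment ratios at n = 1,500 across 10 seeds per F
level; permutation FDR on 40-gene, 1,000-sample mixtures (5% causal genes)
with 100 permutations and 20 replicates; power on grids where expected
carriers exceed the testability minimum severalfold.

## Known limitations

The generator's independence assumptions (sites independent given IBD state,
samples unrelated) make the permutation-FDR validation easier than real data
would be; the dominance-deviation model is fit per gene without accounting
for multiple variants' phase uncertainty; the analytic power formula ignores
covariate adjustment loss (negligible for orthogonal covariates) and the
carrier-minimum filter; meta-analysis supports two studies operationally
(K > 2 structurally but untested); and the knockout catalog trusts the
annotation's loss-of-function confidence — no transcript-level curation is
attempted.
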