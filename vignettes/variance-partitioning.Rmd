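---
title: "Partitioning deregressed-proof variance by MAF and LD class"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning deregressed-proof variance by MAF and LD class}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grmpart)
```

## The problem

In dairy-cattle breeding, the phenotype available for a progeny-tested bull
is usually not a raw measurement but a *deregressed proof* (DRP): an
estimated breeding value with the parent-average shrinkage removed,
accompanied by a reliability $r \in (0, 1]$. A question of long standing is
how much of the variance in DRP can be recovered from genome-wide variants,
and how that recoverable variance is distributed across the allele-frequency
spectrum — in particular, how much rare variants (MAF $< 0.01$) contribute
relative to common ones, and how marker-based estimates compare with what
pedigree relationships capture.

`grmpart` implements the full analysis chain for this question: quality
control of genotype data, stratification of variants into MAF classes and
(optionally) LD groups, construction of genomic and pedigree relationship
matrices, multi-component REML estimation, and reporting of observed versus
expected variance partitions. A synthetic-data module generates cattle-like
genotypes, pedigrees and DRP phenotypes with *known* per-class genetic
variances, so that every stage can be validated end to end without any
external data.

## Models

### MAF-stratified GREML (GREML-MS)

Variants passing QC are assigned to seven MAF classes with boundaries
$(0.001, 0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5)$; intervals are
lower-inclusive, upper-exclusive, and the last class is closed at $0.5$.
For each class $i$ a genomic relationship matrix (GRM) $\mathbf G_i$ is
built and the model

$$
\mathbf y = \mathbf 1 \mu + \sum_{i=1}^{7} \mathbf g_i + \mathbf e,
\qquad
\mathbf g_i \sim N(\mathbf 0, \mathbf G_i \sigma_i^2),
\quad
\mathbf e \sim N(\mathbf 0, \mathbf I \sigma_e^2)
$$

is fitted by restricted maximum likelihood. The proportion of DRP variance
explained by class $i$ is
$\hat\sigma_i^2 / (\sum_k \hat\sigma_k^2 + \hat\sigma_e^2)$, with a
delta-method standard error that uses the full sampling covariance of the
estimates (the inverse average-information matrix). The intercept is the
only fixed effect. Reliabilities are read and stored but deliberately *not*
used as residual weights, matching the common practice of fitting DRP
unweighted in GREML software; a weighted mode is intentionally absent.

### LD stratification (GREML-LDMS)

Because heritability estimates are biased when causal variants sit in
regions of atypical LD, each MAF class can additionally be split by LD. The
LD score of a variant is the sum of $r^2$ (squared Pearson correlation of
dosages) with every other variant within a 20-Mb window centred on it
(±10 Mb, self excluded). Chromosomes are divided into consecutive segments
containing about twice the average number of variants per 100-kb window;
each variant carries its segment's mean LD score, and within each MAF class
variants are split into 3 or 4 equal-size groups of increasing segment-mean
LD (21 or 28 genetic components in total).

### Pedigree and single-GRM models

Three reference models complete the comparison: `reml-ped` (pedigree
numerator relationship matrix $\mathbf A$ only, built by the tabular
method), `reml-grm` (one VanRaden-method-1 GRM), and `reml-pedgrm` (both
jointly). Models are compared by AIC ($2k - 2\log L_R$, where $k$ counts
free variance components; boundary-fixed components are not counted because
they carry no sampling freedom at the optimum). Variances estimated under
different relationship matrices refer to different base populations; before
comparison they can be rescaled by $\bar{\mathrm{diag}}(\mathbf K) -
\bar{\mathbf K}$ (`rescale_to_base()`), which expresses each estimate as
genetic variance among the analysed individuals. This is one of several
rescaling conventions in the literature; the package documents it as its
interpretation and applies it symmetrically to all components.

### GRM scalings and expected partitions

Two classical GRM scalings are provided, plus their continuum:

* **VanRaden method 1** — $\mathbf G = \mathbf W \mathbf W' / 2\sum_j p_j(1-p_j)$
  with $\mathbf W$ the column-centred dosage matrix. A variant's expected
  contribution to genetic variance is proportional to its heterozygosity
  $2p(1-p)$, so the expected share of a class is the class sum of $2p(1-p)$
  over the total (`expected_partition_vr1()`).
* **VanRaden method 2 / GCTA scaling** — every variant is standardised
  before the cross-product ($\alpha = -1$ below), so every variant
  contributes equally in expectation and a class's expected share is its
  variant count share (`expected_partition_vr2()`). This weights rare
  variants relatively more.
* **$\alpha$-scaled family** — columns
  $(\mathbf S_j - 2f_j)\,(2f_j(1-f_j))^{\alpha/2}$ with $\mathbf G =
  \mathbf W\mathbf W'/m$; $\alpha = 0$ recovers method 1 up to a global
  factor, $\alpha = -1$ is method 2, and intermediate values such as
  $\alpha = -0.25$ (reported as optimal in human data) are accepted.

Per-class GRMs inside `greml-ms`/`greml-ldms` use the $\alpha = -1$
scaling, which is what mainstream GREML software computes; the single-GRM
models use method 1, which puts genomic and pedigree variances on a
comparable footing. Both choices can be overridden.

## The AI-REML engine

`ai_reml()` maximises the restricted log-likelihood

$$
\ell_R(\boldsymbol\theta) = -\tfrac12\left(\log|\mathbf V| +
\log|\mathbf 1'\mathbf V^{-1}\mathbf 1| + \mathbf y'\mathbf P\mathbf y\right),
\qquad
\mathbf V = \sum_k \theta_k \mathbf K_k + \theta_e \mathbf I,
$$

by average-information updates. Numerical policy, in order of application:

* the first two iterations use the EM update
  $\theta_k \leftarrow \theta_k + \theta_k^2\,(\mathbf y'\mathbf P\mathbf
  K_k\mathbf P\mathbf y - \mathrm{tr}(\mathbf P\mathbf K_k))/n$, which
  cannot decrease the likelihood and tolerates poor starting values
  (the default start splits $\mathrm{var}(y)$ equally);
* afterwards an AI step $\Delta = \mathrm{AI}^{-1}\nabla\ell_R$ is taken
  with step-halving (up to 20 halvings) until the likelihood does not
  decrease, falling back to EM if halving fails;
* variances are bounded below at $10^{-8}\,\mathrm{var}(y)$. Components
  pinned at the bound with a negative gradient form an *active set*: they
  are held fixed and the AI system is solved over the free components only.
  Without this, fits with several near-zero components crawl towards the
  boundary at an EM rate and can exhaust the iteration budget;
* convergence is declared when the likelihood changes by less than
  $10^{-8}$ (default) between accepted iterations; the iteration cap is
  200. Non-converged fits are returned with `converged = FALSE` — never
  silently dropped — and `aic()` refuses to summarise them;
* standard errors come from the inverse AI matrix at the optimum; a
  numerically singular AI matrix is ridged by $10^{-8}$ of its largest
  diagonal entry before inversion.

The engine is validated against an independent grid-refinement maximiser of
the same likelihood (agreement to $10^{-4}$ relative on single-component
problems) and against a naive dense evaluation of $\ell_R$ using explicit
matrix inverses.

## The synthetic-data generator

The generator is designed to emulate the features of imputed
whole-genome-sequence data in an intensively selected cattle population
that matter for this analysis, with every draw controlled by an explicit
integer seed (same seed, bit-identical output).

**LD by haplotype copying.** Every sampled haplotype is a mosaic of a small
pool of founder haplotypes, with Poisson-distributed switch points
(`switch_rate` per bp, default $10^{-8}$). The pool size is the LD dial:
a small pool (tens) produces the long-range LD and high LD scores typical
of cattle; a large pool (hundreds to thousands) approaches linkage
equilibrium. This is a deliberate simplification — it is seedable, fast and
dependency-free — and it couples LD strength to the lowest attainable MAF
(a pool of $H$ haplotypes cannot segregate below $1/H$), so scenarios that
need both very rare variants and very strong LD are approximated by
moderate pools.

**MAF spectrum.** Target frequencies come from a configurable spectrum:
`spectrum_uniform(lo, hi)`, the neutral-like density $\propto 1/x$
truncated to $[0.001, 0.5]$ (`spectrum_neutral()`, strongly enriched for
rare alleles), or a folded Beta. Realised frequencies are folded to
$[0, 0.5]$ at generation time; the minor allele is defined in the realised
sample.

**Pedigree and gene dropping.** `simulate_pedigree()` builds a
multi-generation pedigree with parents always preceding offspring;
`gene_drop()` gives founders pool-derived haplotypes and transmits one
recombinant gamete per parent (Poisson crossovers, default
$10^{-8}$/bp ≈ 1 cM/Mb), so offspring are Mendelian-consistent at every
locus by construction.

**DRP phenotypes.** Causal effects are drawn with variance
$\propto (2p(1-p))^\alpha$: $\alpha = 0$ is the animal-genetics convention
(common variants contribute more variance), $\alpha = -1$ the
human-genetics one (flat contribution per standardised variant). Effects
are rescaled so the *realised* genetic variance matches the request —
either a total (`target_h2`) or exact per-MAF-class variances
(`per_class_variance_fractions`); the truth record reports realised, not
target, quantities. Deregression noise uses the standard deregression-error
variance, $\mathrm{var}(\varepsilon_i) = \sigma^2_{TBV}(1-r_i)/r_i$. A
consequence worth stating plainly: with constant reliability $r$ the
expected DRP variance is $\sigma^2_{TBV}/r$, so the genetic fraction of DRP
variance equals $r$, and recovery studies that target a total explained
fraction $h^2$ do so by setting the reliability to $h^2$ (per-class
fractions are then expressed in DRP-variance units directly). An optional
planted QTL (e.g. MAF 0.29 explaining 15 % of the genetic variance, the
classic large milk-fat locus configuration) is orthogonalised against the
polygenic background so its marginal variance share is exact.

**What the generator does not emulate.** No selection, no coalescent
realism, no imputation-error model beyond the architecture knobs (imputed
rare variants in real data carry dosage error that *deflates* their
estimated contribution — a caveat for transferring simulated recovery rates
to real data), and no trait recording model behind the DRP. Passing the
packaged tests therefore demonstrates the correctness of the estimation
machinery under a known truth, not the field behaviour of any particular
real trait.

## QC and stratification conventions

* Filters run in a fixed order — individual call rate (≥ 0.85), locus call
  rate (≥ 0.95), monomorphic, Hardy–Weinberg ($P \ge 10^{-5}$, 1-df
  chi-square without continuity correction on rounded genotypes), MAF
  (≥ 0.001) — so locus statistics always use retained individuals. The
  chi-square (rather than exact) test is a documented choice.
* Missing dosages are mean-imputed per variant *inside* GRM and LD
  computations only; they are never written back.
* The segment rule uses chromosome span = (max − min position) in 100-kb
  units, minimum one window. Quantile splits use a stable sort with
  position as tie-break, and remainders go to the lowest-LD groups, so
  group sizes within a class differ by at most one and the split is
  reproducible.
* LD-score summation is performed in ascending variant order with a single
  BLAS kernel per variant; the packaged oracle test documents that the
  windowed implementation and an all-pairs double loop agree to
  $10^{-12}$, i.e. to the reordering tolerance of floating-point addition.

## Problem sizes used in the packaged checks

The validation suite runs at desk scale, chosen so the full battery
completes in minutes on one core while keeping every estimate's sampling
error well inside its tested tolerance: recovery of known per-class
fractions at $n = 1000$ individuals × 7000 variants ($h^2 = 0.6$ split
over seven classes, every estimate within 2 SE of truth); the AI-REML
versus grid oracle at $n = 500$; GRM-correlation structure at $n = 400$ ×
3500 variants; and model comparison by AIC over 20 replicates of a
400-member, three-generation pedigree with both marker-captured and
pedigree-only genetic variance, where the joint pedigree + GRM model is
expected to win in at least 80 % of replicates.

## Worked example

```{r example, eval = FALSE}
cfg <- system.file("extdata", "pipeline-config.yaml", package = "grmpart")
res <- run_pipeline(cfg, output_dir = tempfile("grmpart-report-"))
res$report          # per-class partition, aggregates, total explained
res$aic_table       # AIC differences against the pedigree-only model
```

## Known limitations

* Dense-matrix REML: cost is $O(n^3)$ per iteration with $n$ phenotyped
  individuals; the engine is comfortable to a few thousand individuals,
  which is the regime this analysis targets, but is not a sparse
  mixed-model solver.
* One record per individual (identity incidence), intercept-only fixed
  effects — the DRP design. Repeated records or covariates are out of
  scope.
* The binary relationship-matrix interchange format stores 4-byte floats;
  round-trips are exact at float32 precision.
* `greml-ldms` with 28 components on small samples frequently produces
  boundary estimates with large standard errors; this mirrors the
  identifiability limits of LD-and-MAF stratification at modest $n$ rather
  than a numerical failure, and such fits are flagged, not hidden.
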