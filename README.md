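# grmpart

Partitioning the variance of deregressed proofs (DRP) across
minor-allele-frequency (MAF) and linkage-disequilibrium (LD) classes of
genome-wide variants, and comparing the variance captured by sequence
variants, SNP-array variants and pedigree relationships.

`grmpart` is aimed at quantitative geneticists working with livestock
pseudo-phenotypes: DRP with per-animal reliabilities, imputed
whole-genome-sequence or array genotypes, and deep pedigrees. It
implements the full GREML-MS / GREML-LDMS analysis chain plus the
pedigree-based reference models, and ships a synthetic-data module that
generates cattle-like genotypes, pedigrees and DRP phenotypes with known
per-class genetic variances, so the whole pipeline is testable without any
external data.

## The model

Variants passing QC are grouped into seven MAF classes
(0.001–0.01, 0.01–0.05, 0.05–0.1, 0.1–0.2, 0.2–0.3, 0.3–0.4, 0.4–0.5),
optionally sub-stratified into 3 or 4 LD groups by segment-mean LD score
(LD score = Σ r² with all variants within ±10 Mb). With one genomic
relationship matrix **G**ᵢ per group, the multi-component model

    y = 1μ + Σᵢ gᵢ + e,   gᵢ ~ N(0, Gᵢ σᵢ²),   e ~ N(0, I σe²)

is fitted by average-information REML (EM fallback, step-halving,
active-set boundary handling). The proportion of DRP variance explained by
class *i* is σ̂ᵢ² / (Σₖ σ̂ₖ² + σ̂e²), with delta-method standard errors from
the full inverse-AI covariance. Reference models fit a pedigree numerator
matrix **A** (tabular method), a single VanRaden-method-1 GRM, or both
jointly; models are compared by AIC and variances can be put on a common
base via the mean-diagonal-minus-mean rescaling rule. Expected partitions
under VanRaden method 1 (share ∝ Σ 2p(1−p)) and method 2 (share ∝ variant
count) quantify what each GRM scaling *assumes* each class should explain;
an α-scaled GRM family spans both (α = 0 and α = −1 respectively).

## Worked example

The packaged configuration simulates 300 animals over a two-generation
pedigree with 1500 sequence-like variants, applies QC, stratifies by MAF,
and fits the four standard models:

```r
library(grmpart)
cfg <- system.file("extdata", "pipeline-config.yaml", package = "grmpart")
res <- run_pipeline(cfg, output_dir = "grmpart-report")
res$report
```

```
Partition of DRP variance by MAF class
  maf_class n_variants proportion     se exceeds_se expected_vr1 expected_vr2
 0.001-0.01         28   9.02e-03 0.0236      FALSE      0.00057       0.0188
  0.01-0.05        125   9.75e-09 0.0597      FALSE      0.01401       0.0839
   0.05-0.1        138   6.24e-02 0.0654      FALSE      0.03801       0.0926
    0.1-0.2        279   1.30e-01 0.0950       TRUE      0.14113       0.1872
    0.2-0.3        318   2.55e-01 0.1053       TRUE      0.23647       0.2134
    0.3-0.4        307   2.59e-01 0.0997       TRUE      0.27846       0.2060
    0.4-0.5        295   1.33e-01 0.0913       TRUE      0.29135       0.1980
total proportion explained: 0.849
     aggregate proportion relative_contribution
          rare   9.02e-03              1.06e-02
 low_frequency   9.75e-09              1.15e-08
        common   8.40e-01              9.89e-01
```

Reading this: each row is one MAF class — its variant count after QC, the
REML estimate of the share of DRP variance it explains (± SE, flagged when
the estimate exceeds one SE), and the share each GRM scaling would
*expect* it to explain. Here the simulated architecture was polygenic with
effect variance independent of MAF (the animal-genetics convention), so
common classes dominate and the rare class explains ~1 % — note the large
SEs on small estimates, the characteristic difficulty of MAF-partitioned
analyses at modest sample size. The model-comparison and AIC tables from
the same run:

```
       model total_proportion_explained converged
    greml-ms                  0.8486395      TRUE
    reml-grm                  0.8442453      TRUE
    reml-ped                  0.8150675      TRUE
 reml-pedgrm                  0.8442453      TRUE

       model       aic delta_aic converged
    greml-ms  5.837567 -50.94461      TRUE
    reml-grm -2.021987 -58.80416      TRUE
    reml-ped 56.782176   0.00000      TRUE
 reml-pedgrm -2.021987 -58.80416      TRUE
```

All genetic variance in this simulation is marker-captured, so the joint
pedigree+GRM fit collapses onto the GRM-only fit (the pedigree component
hits the boundary) and both beat the pedigree-only model by ~59 AIC
points.

A thin command-line front end over the same functions is installed at
`inst/cli/grmpart.R` (subcommands `run`, `simulate`, `qc`, `stratify`,
`grm`, `reml`).

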