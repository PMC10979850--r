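# locindex

Transcript nucleo-cytosolic localization from matched whole-cell, nuclear
and cytosolic RNA-seq.

## The problem

RNA-seq abundance estimates (FPKM) are relative to the total RNA of the
library, so nuclear and cytosolic FPKMs of the same transcript cannot be
compared directly: the two compartments hold unknown — and different —
total RNA volumes. `locindex` uses a matched whole-cell library to resolve
the missing scale. Molecule conservation, `m_w(i) = m_n(i) + m_c(i)`,
propagated through length-weighted read sampling, gives for every
transcript `i`:

    FPKM_w(i) = (1 − β)·FPKM_n(i) + β·FPKM_c(i)

where `β = Σ m_c(j)·l(j) / Σ m_w(j)·l(j)` is the fraction of total
cellular RNA volume in the cytosol. The package estimates `β` by Bayesian
robust linear regression with Student-t errors
(`ν ~ Γ(2, 0.1)`, `σ ~ Exp(mean = sd(FPKM_w))`, `β ~ Beta(2, 2)`;
4 chains × 6,000 MCMC iterations, 2,000 warm-up; MAP point estimate) and
then converts each transcript's fraction FPKMs into its **localization
index**, the estimated fraction of its molecules in the cytosol:

    LI(i) = β·FPKM_c(i) / ((1 − β)·FPKM_n(i) + β·FPKM_c(i))

The naive FPKM ratio `FPKM_c/(FPKM_n + FPKM_c)` is the special case
`β = 0.5` and is biased whenever the RNA volume is not equally split.

Intended users: transcriptomics groups with fractionated bulk or
pseudo-bulk single-cell RNA-seq who want per-transcript nuclear/cytosolic
distributions rather than compartment-enrichment calls.

Included: RSEM-style table readers, CPM filtering and mitochondrial
exclusion, replicate consensus, pseudo-bulk pooling, compartment
classification (LI < 0.4 nuclear, > 0.6 cytosolic), cross-condition
consistency and strong-localizer summaries, splicing-feature enrichment
(hypergeometric + Bonferroni), and a ground-truth simulator of
fractionated RNA-seq counts for parameter-recovery benchmarking.

## Worked example

```r
library(locindex)

cfg <- simConfig(nTranscripts = 3000, totalMolecules = 2e5,
                 targetBeta = 0.7, depthPerFraction = 5e5, seed = 11)
sim <- simulateDataset(cfg)
realizedBeta(sim$truth)
#> [1] 0.7018

fit <- runEstimateBeta(sim$samples$whole, sim$samples$nuclear,
                       sim$samples$cytosolic,
                       config = betaModelConfig(seed = 11))
fit$posterior
#> BetaPosterior: 16000 draws over 4 chains (2972 transcripts)
#>   beta MAP 0.6982 | mean 0.6993 | 90% CI [0.6989, 0.7010]
fit$qc
#> [1] "pass"
fit$locTable
#> LocalizationTable 'sample' (beta = 0.698): 2972 transcripts
#>      nuclear intermediate    cytosolic    undefined
#>          592          556         1824            0
```

The simulator split 70.2% of the RNA volume into the cytosol; the
regression recovers 0.698 from the three count tables alone (error 0.004),
and the localization table classifies each transcript by its estimated
cytosolic molecule fraction. Samples with an estimated `β > 0.95` are
flagged for exclusion (`qc = "flag_exclude"`) as likely fractionation or
regression artifacts.

Real data enter through the same function as file paths to RSEM-style
tab-separated tables (`transcript_id`, `length`, `effective_length`,
`expected_count`, aliases accepted):

```r
fit <- runEstimateBeta("whole.isoforms.results",
                       "nuclear.isoforms.results",
                       "cytosolic.isoforms.results",
                       excludedIds = mitochondrialIds(metadata),
                       outDir = "run1")
```

A thin command-line wrapper with `simulate`, `estimate-beta`, `localize`
and `benchmark` subcommands is installed at
`inst/scripts/locindex-cli.R`.

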