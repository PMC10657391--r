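# tadote

Toxin-antidote gamete-killer genetics for rice hybrid sterility.

Hybrid male sterility between cultivated rice (*Oryza sativa*) and its wild
relatives is driven by selfish toxin-antidote (TA) elements such as *qHMS1*
(toxin *HPT*, antidote *HPA*; functional haplotype from *O. meridionalis*)
and *qHMS7*. Each element is a pair of absolutely linked genes: a
**sporophytic toxin** — produced by the diploid plant and delivered to all
of its pollen — and a **gametophytic, cis-acting antidote** that rescues
only the pollen grains whose own haplotype carries it. In a heterozygote
the half of the pollen carrying the null haplotype is unprotected and dies;
the element thereby drives its own transmission.

`tadote` is for geneticists and breeders who want to compute with this
model rather than reason about it case by case: it predicts pollen
fertility and stage-resolved abortion for arbitrary genotypes (including
CRISPR knockouts and transgene constructs), progeny ratios for crosses and
pedigrees, fits killing efficiency and female-transmission bias to genotype
counts, runs forward population dynamics of TA haplotypes, and types
toxin/antidote alleles to predict cross compatibility.

## The model in one formula

For each male gamete class the survival probability is

    Pr(survive) = prod over loci l of
        1        if not exposed to the toxin at l, or protected in cis at l
        1 - k_l  otherwise

where exposure is sporophytic (any functional toxin copy in the parent, or
a toxin transgene), protection is strictly gametophytic-cis (the gamete's
own haplotype or a carried antidote transgene), and `k_l` in [0, 1] is the
killing efficiency. Pollen fertility is the prior-weighted sum of survival;
a grain doomed at several loci aborts at the earliest locus stage
(*qHMS1*: uninucleate; *qHMS7*: binucleate). Crosses combine the
unselected female gamete pool with the post-selection male pool.

## Worked example

The double heterozygote at the stacked loci (`1M1D;7D7M` in the field's
allele shorthand — one segment per locus, `M`/`D` for the *Mer*/DJY1
alleles):

```r
library(tadote)
p  <- qhms_panel()                       # qHMS1 + qHMS7, k = 1 at both
f1 <- ta_genotype("1M1D;7D7M", p)
male_gametes(f1, p)
#> Male gamete distribution  (viable fraction 25.0%)
#>  gamete prior survival       stage post
#>   1M/7D  0.25        1        <NA>    1
#>   1D/7D  0.25        0 uninucleate    0
#>   1M/7M  0.25        0  binucleate    0
#>   1D/7M  0.25        0 uninucleate    0
#> Aborted: uninucleate 50.0%, binucleate 25.0%
```

Only the pollen class carrying both functional haplotypes (`1M/7D`)
survives: 75% of pollen aborts, 50% at the uninucleate stage (killed by
*qHMS1*) and 25% at the binucleate stage (the *qHMS1*-survivors carrying
the *qHMS7* null, killed later). The grain doomed at both loci (`1D/7M`)
is counted at the earlier stage.

Estimating killing efficiency from a large heterozygote-self population in
which 1.08% of plants are homozygous for the null allele:

```r
cnt <- ta_counts(c(`1M1M` = 4940, `1D1M` = 4952, `1D1D` = 108),
                 design = "self_het")
fit_killing_efficiency(cnt)
#> Toxin-antidote model fit (profile ML, design: self_het, n = 10000)
#>   estimate  2.5 % 97.5 %
#> k   0.9781 0.9737  0.982
#> log-likelihood: -8.54171
```

A killing efficiency just below 1 accounts for the observed leak-through
of null homozygotes: at `k = 0.978` the model predicts a double-null
proportion of `0.5 (1-k)/(2-k) ≈ 1.1%`. The fitted object supports
`coef()`, `confint()`, `logLik()`, `predict()`, `residuals()` and
`simulate()`.

Other entry points: `cross()` / `self_progeny()` / `pedigree()` for
progeny distributions, `drive_trajectory()` / `wright_fisher_run()` /
`mutation_order_experiment()` for population dynamics,
`classify_fasta()` / `survey_summarize()` / `coupling_audit()` /
`predict_cross_sterility()` for allele typing, and the seeded
`gen_*()` generators for synthetic inputs.

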