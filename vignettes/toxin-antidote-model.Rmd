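---
title: "The toxin-antidote gamete-killing model behind tadote"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The toxin-antidote gamete-killing model behind tadote}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadote)
```

## The model

A toxin-antidote (TA) element is a pair of absolutely linked genes on one
haplotype: a *toxin* that poisons developing pollen and an *antidote* that
rescues it. The rice hybrid-sterility loci this package models, *qHMS1*
(toxin HPT, antidote HPA, functional haplotype from *O. meridionalis*) and
*qHMS7* (functional haplotype from the cultivated DJY1 background), combine
two action modes:

* **Sporophytic toxin.** The diploid plant produces the toxin and delivers
  it to *all* of its pollen. A single functional toxin copy anywhere in the
  genotype — either haplotype, or an unlinked toxin transgene — exposes the
  whole pollen population.
* **Gametophytic, cis-acting antidote.** Protection is decided inside each
  pollen grain: only a grain whose own haplotype (or a transgene copy it
  happens to carry) has a functional antidote survives. The antidote on the
  *other* parental haplotype never helps.

For a gamete class $g$ of a plant, the survival probability is

$$\Pr(\text{survive}) \;=\; \prod_{\ell}
  \begin{cases} 1 & \text{not exposed at } \ell \text{, or protected in cis}\\
  1 - k_\ell & \text{otherwise,}\end{cases}$$

where $k_\ell \in [0,1]$ is the *killing efficiency* of locus $\ell$. Loci
act independently; within a locus, toxin and antidote are treated as
absolutely linked (no recombination), while loci and transgenes segregate
freely. Pollen fertility is the prior-weighted sum of survival over all
gamete classes. This single rule reproduces the whole phenotype table: a
heterozygote at one locus loses exactly half its pollen; knocking out the
toxin restores full fertility; knocking out the antidote on a
toxin-carrying plant gives complete sterility; a hemizygous antidote
transgene rescues half of the otherwise-doomed half, 50% → 75% fertile.

Each locus kills at a characteristic developmental stage (*qHMS1* at the
uninucleate stage, *qHMS7* at the binucleate stage). A grain doomed at
several loci is counted once, at the earliest stage — implemented as
sequential per-stage hazards so the accounting also stays coherent when
$k<1$ at several loci. In the stacked double heterozygote with complete
killing this yields the 75% = 50% (uninucleate) + 25% (binucleate) split
and a single surviving pollen class carrying both functional haplotypes.

The package models *qHMS7*'s toxin as sporophytic and its antidote as
gametophytic-cis, identically to *qHMS1*. That symmetry is an assumption:
it is the simplest configuration from which both the stacked 75%
prediction and the single surviving pollen class follow, and both are what
the system shows.

## Crosses and inference

Progeny distributions combine the *unselected* female gamete pool with the
*post-selection* male pool (`cross()`, `self_progeny()`, `pedigree()`).
Single TA loci leave ovules untouched; the only female-side effect the
model admits is a joint reweighting of female gamete classes
(`female_weights()`), motivated by the biased F2 ratios of the stacked
heterozygote, where the four genotype classes map one-to-one onto the four
female gamete classes (the male gamete being fixed).

Killing efficiency is estimated from genotype count tables by multinomial
maximum likelihood (`fit_killing_efficiency()`). In the heterozygote self,
the heterozygote class has probability $1/2$ regardless of $k$, so the MLE
depends only on the homozygote split $1/(2-k) : (1-k)/(2-k)$ and has the
closed form $\hat k = (MM - DD)/MM$, clipped to $[0,1]$. Inverting the
expected double-null proportion $p = \tfrac{1}{2}(1-k)/(2-k)$ gives the
equivalent-in-expectation form $\hat k = (1-4p)/(1-2p)$; the two coincide
exactly when the heterozygote count equals half the sample. A double-null
proportion of 1.1% — the observed leak-through in a large self
population — inverts to $k \approx 0.978$, which is how incomplete killing
enters the model as a single free parameter rather than as genotyping
error. Intervals are 95% profile-likelihood intervals ($\chi^2_1$ cutoff
3.84); boundary estimates ($\hat k = 1$ when no double-null plant is seen)
are reported one-sided. Female transmission weights are the saturated
multinomial MLE (sample proportions), with a likelihood-ratio test against
1:1:1:1 (df = 3) and seeded nonparametric bootstrap intervals (1000
resamples). Segregation tests are plain Pearson chi-square without
continuity correction, with an exact multinomial tail probability by full
enumeration when $n \le 200$ — beyond that the chi-square approximation is
adequate and enumeration cost grows steeply.

## Population dynamics

`drive_trajectory()` iterates a deterministic single-locus recursion over
the four haplotype classes FA, fA, Fa, fa (toxin/antidote functional in
upper case). Parents form genotypes in Hardy-Weinberg proportions from the
current haplotype frequencies; the ovule pool equals the haplotype
frequencies (no female selection), while the pollen pool weights each
genotype by frequency × viable fraction and draws from its post-selection
gametes. A fraction $s$ of seed comes from selfing; fully male-sterile
genotypes mother no selfed seed, and the selfed pool is renormalised over
fertile mothers. The default selfing rate is $s = 0.95$ — rice is
predominantly selfing — with $s = 0$ used in tests where the clean
outcrossing algebra is wanted. Notably the drive is not slowed by selfing
here: heterozygous mothers self-fertilise exclusively with their own
surviving (all-protected) pollen.

The recursion makes the evolutionary ordering argument mechanical: a
toxin-only haplotype (Fa) can never pass through pollen in the presence of
any antidote-bearing competitor and is purged; an antidote-silenced
haplotype (fa) is eliminated while a functional toxin segregates, but is
exactly neutral once the toxin is dead (fA background). Hence promoter
silencing of the antidote can only establish *after* toxin loss, which is
also why surveys show FA, fA and fa but no Fa class — the coupling rule
audited by `coupling_audit()`.

`wright_fisher_run()` is the finite-population counterpart: each
generation draws $N$ offspring genotypes multinomially from the
deterministic offspring distribution. Mutant-fate experiments
(`mutation_order_experiment()`) introduce a haplotype at frequency 0.005
(deterministic) or one copy (Wright-Fisher).

## Allele typing

Typing is rule-based on engineered toy sequences (`gen_reference_toys()`),
not on real genomes: a 902-codon toxin CDS whose diagnostic G→T change at
CDS position 2011 (first base of codon 671) creates a premature stop and a
670-aa product; a 361-codon antidote CDS behind a 200-bp promoter; and a
1391-bp transposon whose insertion point has the base at coordinate −11
(ATG's A = +1, upstream negative) immediately 3′ of it. The classifier
calls `te_silenced` when an insertion of at least 50 bp (configurable; the
threshold separates the transposon from small indels) lands inside the
promoter window [−200, −1]; insertions are located by the longest common
prefix with the reference promoter, which is exact because the toy
transposon's first base is engineered to differ from the displaced
reference base. Coding variants are reported but never change the antidote
class: the known Asn→Thr substitution is benign (promoter-swap logic), so
expression, not protein sequence, decides functionality. The nucleotide
position of the toxin stop is configuration, not biology: only the protein
lengths 902/670 are anchored, so the toy reference pins the lesion to the
first base of codon 671.

## What the generators emulate — and what they do not

`gen_cross_counts()` draws multinomial genotype counts from the
model-predicted distribution of a named cross design; `gen_pollen_counts()`
draws microscope-style tallies (~200 grains) over viable/aborted-by-stage
classes; `gen_survey()` samples accessions over haplotype classes under
the coupling constraint and can emit toy FASTA records that round-trip
through the classifier. All randomness flows from one integer seed through
named substreams (a hash of generator name + seed), so adding a generator
never perturbs existing draws, and every generator is bit-reproducible.

The generators emulate the *statistical* structure the analysis assumes —
multinomial sampling, Mendelian priors, the killing rule — and nothing
else. They do not simulate genotyping error, residual background
heterozygosity of near-isogenic lines, linked markers, real transposon
sequence, or sequencing reads. Tests passing on these inputs therefore
validate the model arithmetic and the estimators' statistical behaviour,
not robustness to the messiness of real genotyping data.

## Numerical choices

* Probabilities are exact floating-point computations; nothing in the
  model layer is sampled. Distribution invariants are enforced to 1e-12.
* Progeny classes below 1e-15 are pruned after normalisation.
* Genotype keys canonicalise the unordered haplotype pair per locus
  (justified because free recombination makes phase across loci
  irrelevant), so `1M1D` and `1D1M` are the same class.
* Complete male sterility is a state (`viable_fraction = 0`), not an
  error, in the gamete layer; it becomes an error only where progeny are
  requested from a sterile father, and in the population layer only when
  *every* genotype is male-sterile.
* The likelihood optimiser confirms the closed-form MLE; profile roots are
  found by `uniroot` at tolerance 1e-9 within `[0, 1]`.

Simulation-based checks in the test suite use deliberately modest problem
sizes — 200–500 replicates and samples of 400–20,000 — chosen so the whole
suite exercises calibration, power, coverage and consistency while staying
quick to run; the Wright-Fisher concentration check uses the median across
20 replicates at $N = 10^4$ and the mean at $N = 10^5$, because takeoff
timing from ~1000 initial copies is drift-sensitive and single laggard
replicates would otherwise dominate a mean.

## Known limitations

* Two-locus interactions are modelled in the gamete/crossing layer only;
  the population recursion is single-locus, matching the single-locus
  evolutionary narrative it serves.
* The female-bias mechanism is descriptive (weights), not mechanistic; the
  data motivating it identify the bias only jointly across the two loci.
* `k` is a per-locus constant: no genotype-by-environment effects, no
  pollen-competition saturation, no overdispersion in count models.
* The typing rules are exact on the toy references; applying them to real
  sequence data would require alignment and variant normalisation that are
  out of scope here.
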