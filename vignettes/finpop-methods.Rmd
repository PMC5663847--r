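---
title: "Models and methods behind finpop"
author: "finpop authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind finpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

finpop implements the population-genetic workflow used to characterize
small, fragmented populations typed at microsatellite loci and a
maternally inherited control-region sequence — the design of the Yangtze
finless porpoise data set: ~150 diploids at 11 microsatellites, ~130
aligned 597-bp mtDNA haplotypes, and a partition of individuals into a
few genetic clusters produced by an external clustering analysis. This
document explains the models, the estimators, the tunable parameters and
their defaults, the numerical choices, and what the synthetic-data tests
do and do not demonstrate.

## Data model

Microsatellite genotypes are stored as unordered pairs of integer allele
sizes in *repeat units*; base-pair fragment lengths are divided by the
repeat-motif length on input, with a hard error if the division is not
integral. The M-ratio and the stepwise mutation models operate on repeat
counts, so this unit is load-bearing, not cosmetic. A genotype is either
fully typed or fully missing; a sentinel size of 0 never reaches a
computation. Alignment sites carrying non-ACGT symbols (gaps, ambiguity
codes) are recorded once per alignment and excluded listwise from every
sequence statistic and distance.

Individuals enter the analysis when at least half of their marker
information is present: at least 6 typed microsatellite loci, or at least
5 together with an mtDNA sequence. The filter is idempotent. Individuals
present only in the mtDNA alignment are legitimate and contribute only to
sequence statistics. The population partition is an *input*: cluster
inference (model-based clustering, DAPC, PCA) is deliberately out of
scope, so analyses condition on the published assignment.

## Diversity and differentiation statistics

Expected heterozygosity is the plain `1 - sum(p_i^2)` (the convention of
the desktop tools this workflow mirrors); an unbiased `n/(n-1)` variant
sits behind a flag. F-statistics use the Weir–Cockerham variance
components, summed over alleles and loci before taking ratios; the
per-population inbreeding coefficient F_IS uses the single-sample
reduction (components b and c only) and its significance comes from
permuting allele copies among individuals within the population
(two-sided, 10^4 permutations by default). Pairwise F_ST confidence
intervals bootstrap loci (the study does not state bootstrap vs
jackknife; bootstrap-over-loci was chosen and is declared here), and
p-values permute individuals between the two populations. Bonferroni
correction is applied across each family of pairwise tests.

Rarefied allelic richness standardizes allele counts to a common number
of *gene copies* `g` via hypergeometric absence probabilities; the
published table is rarefied to 26 individuals, i.e. `g = 52`. Private
allelic richness multiplies the probability that an allele appears in a
size-`g` subsample of the focal population by the probabilities that it
is absent from size-`g` subsamples of every other population. Both error
out, naming the offending locus, if `g` exceeds the typed copies
anywhere; the pipeline degrades gracefully (reports NA with a warning)
because rarefaction targets are configuration, not data.

The Garza–Williamson M-ratio is `k/(r+1)` per locus (`k` alleles, range
`r` in repeat units), averaged over loci; loci monomorphic within a
population contribute M = 1 by default (exclusion is a flag — the study
does not state which convention its table used). Significance is the
proportion of constant-size coalescent simulations, matched to sample
size and locus count with priors on the effective size and mutation
parameters, whose mean M falls below the observed value. The study ran
10^6 such simulations; the package default is 10^4, configurable, which
resolves p-values to ~10^-4 — ample for the table's significance stars.

Sequence diversity follows the classical estimators: segregating sites
S (split into singletons — sites where exactly one sequence departs from
the majority state — and shared polymorphisms), haplotype diversity
`Hd = n/(n-1) (1 - sum p_h^2)`, nucleotide diversity from per-site
pairwise differences, Watterson's `theta_W = S/(a_{n-1} L)`. Tajima's D
uses the standard variance normalization and is reported as 0 with a
degeneracy flag when S = 0 (the monomorphic cluster in the study prints
0); its significance conditions 10^4 constant-size coalescent replicates
on the sample size and the observed Watterson estimate, as the cited
sequence-analysis program does. Hudson's F_ST for mtDNA is
`1 - H_w/H_b` with `H_w` the unweighted mean of the two within-population
mean pairwise differences; significance comes from the Snn
nearest-neighbour permutation test (ties split equally among
equidistant neighbours).

## LD-based contemporary Ne

The linkage-disequilibrium method reads contemporary effective size from
inter-locus allele associations: in a closed random-mating population the
squared correlation `r^2` between unlinked loci equals the sampling
contribution `E[r^2_sample]` plus a drift term `~1/(3Ne)`. The package
computes the Burrows composite disequilibrium from unphased dosages with
the `S/(S-1)` correction, `r^2 = D^2/(p(1-p)q(1-q))`, screens alleles
whose frequency lies outside `(P_crit, 1 - P_crit)` (default
`P_crit = 0.02`, the study's setting; the screen is symmetric because a
near-fixed allele is the mirror image of a rare one), weights allele
pairs by their pair-specific sample size, subtracts the Waples
small-sample expectation (two regimes around harmonic-mean S = 30) and
inverts the published bias-corrected quadratic. A non-positive drift
component yields `Ne = Inf`, which is a legitimate outcome (the study's
TL cluster has an unbounded upper CI). Two interval flavours are
reported, since the study does not say which its table shows: a
chi-squared interval on the raw comparison count (anti-conservative when
allele pairs are correlated, as they are with multi-allelic loci) and a
jackknife-over-loci interval using the effective degrees of freedom
implied by the jackknife variance. The jackknife interval is the one
validated by the recovery experiments (~92% empirical coverage at
nominal 95% in the shipped check).

Validation uses a forward Wright–Fisher sampler rather than the
coalescent simulator: independent-locus genealogies carry *no* drift LD
by construction, so only a forward multilocus population produces the
signal this estimator measures.

## The coalescent engine

The simulator is a continuous-time Kingman coalescent over a set of
demes with piecewise-constant diploid sizes, merge events and admixture
events (backward in time, a lineage in an admixed deme picks a parent
deme with the admixture probability). Within a deme of diploid size N,
nuclear copy pairs coalesce at rate 1/(2N), mtDNA copies at rate 2/N:
the mitochondrial effective copy number is fixed at N/2 (haploid,
maternal, even sex ratio), i.e. one quarter of the 2N nuclear copies.
The continuous-time approximation (exponential waiting times rather than
generation-by-generation Bernoulli trials) is accurate for N of ~10 and
up and is what makes reference tables of 10^4–10^6 simulations feasible;
post-collapse remnant sizes are floored at 1 diploid. Times are
generations internally; priors are declared in years and divided by the
generation time (10 years, from the study's equation of 5 generations
with 50 years).

Microsatellites mutate under the generalized stepwise model: Poisson
mutations along branches, step magnitude `1 + Geometric(1 - P_GSM)`
(P_GSM = 0 gives the strict stepwise model), symmetric direction,
reflecting boundaries on a contiguous state space of 40 states by
default. The root allele sits mid-range; every statistic consumed
downstream is translation invariant, which the tests assert. The
control region mutates under a finite-sites model with
transition:transversion weighting kappa:1 and a uniform random root;
only mutated sites are materialized, which keeps a 597-bp locus cheap.

Mutation priors are not printed in the study (they live in inaccessible
supplementary tables); the defaults are the field-standard ranges:
per-locus microsatellite rate log-uniform on [1e-4, 1e-3], P_GSM uniform
on [0, 0.3], per-site control-region rate log-uniform on [1e-8, 1e-6],
kappa uniform on [5, 20]. All are configurable through the scenario-set
YAML.

## The scenario language and the three shipped sets

Scenarios are declarative: parameter declarations (uniform, log-uniform
or fixed priors with units), size and event templates whose fields are
expressions over the parameters, and inequality conditions enforced by
rejection resampling (an unsatisfiable condition set errors after 10^5
attempts rather than looping forever). Because a scenario is plain data,
scenario sets serialize losslessly to YAML and a saved set reproduces
draws bit-for-bit under the same seed.

Step 1 (branching order, 10 scenarios): the trichotomy, the three rooted
bifurcating orders, and six admixture variants — each population in turn
formed by admixture between the two others, with either choice of major
parent and the minor contribution uniform on [0, 0.5]. The exact
composition of the study's ten topologies is in its inaccessible
supplement; these templates are the natural three-population inventory
and are replaceable via YAML without touching code. Step 2 (size change,
6 nested scenarios): constant; daughter decline; ancestral founder
bottleneck (large ancestral size, a brief founder phase of 2–500
diploids lasting 10–500 years, expansion, then the split — equating the
three ancestral sizes recovers the constant scenario, which a
distribution-equality test asserts); daughter expansion; simple
ancestral decline; simple ancestral expansion. Step 3 (recent collapse,
2 scenarios): the step-2 winner unchanged, versus the same history with
an independent recent collapse in each daughter within the last 5
generations, per-population remnant fractions log-uniform on [0.001, 1].
The population-size prior is uniform [10, 20000] (the published
ancestral posterior reaches ~19,700, so 20,000 is the natural ceiling);
split times are uniform [100, 5000] years and the colonization time
uniform [1000, 50000] years, consistent with the published posteriors.

## The ABC engine

Reference tables simulate `n` prior draws per scenario, each row seeded
deterministically from the base seed and its index, and summarize each
dataset with a fixed-order statistic vector: per population the mean
allele count, mean expected heterozygosity, mean allele-size variance
and M-ratio, plus S, haplotype diversity, per-site nucleotide diversity
and Tajima's D for the mtDNA (D is imputed as 0 with a companion 0/1
degeneracy indicator, so monomorphism — the observed state of one
cluster — is itself information rather than a missing value); per pair
the Weir–Cockerham F_ST, the shared-allele distance
`1 - mean_l sum_a min(p1, p2)`, the `(delta mu)^2` distance and the
Hudson mtDNA F_ST. Any non-finite entry is imputed as 0.

Rejection standardizes statistics by the reference table's median
absolute deviation (falling back to the SD when the MAD vanishes,
dropping the statistic with a warning when both do) and keeps the
`tolerance` fraction nearest in Euclidean distance, ties broken by row
index so selection is reproducible.

Model choice runs along two routes. The LDA-logistic route fits a linear
discriminant projection on the selected PODs (variables standardized
first; those with near-zero pooled within-group variance dropped — they
would make the discriminant singular) and a multinomial logistic
regression of scenario on the discriminant axes, evaluated at the
observed point, with delta-method confidence intervals from the
regression's asymptotic covariance (the study does not say how its
probability CIs were obtained; this is the declared choice). The
random-forest route classifies on the raw statistics augmented with the
LDA axes, trained on the full table; the posterior probability of the
chosen scenario is a regression forest fitted to the out-of-bag success
indicator, and the prior error rate is the out-of-bag misclassification.
At desk-scale table sizes the forest is markedly the more robust
classifier, so the pipeline's step winner is the forest vote while the
logistic probabilities are reported alongside — at the study's 10^6-POD
scale the two routes agree, as the original analysis found.

Error calibration simulates fresh PODs per scenario (seed-offset so they
never reuse reference rows) and analyses each like an observed dataset:
type-I error for a scenario is the fraction of its own PODs not assigned
to it, type-II the fraction of other scenarios' PODs assigned to it, and
the prior error rate the overall misclassification under equal priors.

Parameter estimation follows the local-linear recipe: rejection
restricted to the winning scenario's rows, Epanechnikov weights in
distance, regression of each parameter on the deviation of the selected
statistics from the observed vector, and replacement of the fitted value
at the observed point. Two numerical guards matter at desk scale. First,
parameters are adjusted on a logit-transformed unit scale (log scale
first for log-uniform priors), so adjusted draws respect the prior box
by construction. Second, the regression uses the leading principal
components of the local statistic cloud (at most 10, and never more than
a tenth of the accepted count): with a few dozen accepted draws and ~40
statistics an unconstrained regression overfits catastrophically,
saturating the logit scale and collapsing the posterior onto the prior
bounds. Third, residuals are rescaled by `sqrt(n/(n - p - 1))` for the
degrees of freedom the regression absorbs; without this the adjusted
spread is biased narrow and credible intervals undercover. The recovery experiments show the package's intervals are
well-calibrated for parameters the statistics actually identify (the
post-founding expansion size in the shipped check) and that plain
rejection without adjustment is slightly conservative; weakly identified
parameters (founder size, founder duration) keep near-prior posteriors,
as they should.

Posterior predictive checks draw parameter vectors from the weighted
posterior (resampling until the scenario's inequality conditions hold),
simulate full datasets, and locate each observed statistic in its
simulated distribution with a two-tailed mid-p; statistics below 0.05
are flagged. Fitting the constant-size alternative to collapse-truth
data flags the per-population M-ratios — the same diagnostic that ranked
the study's models.

The three analysis steps run sequentially, each conditioning on the
previous winner, and winners are never revisited; joint selection over
all 18 scenarios is deliberately not offered, for fidelity to the nested
design.

## The synthetic generator and what the tests show

The generator emulates the study design: four clusters of 58/17/17/53
diploids at 11 loci (the three distinct populations plus the admixed
group; the published total of 148 additionally counts 3 individuals from
an unmodelled river-mouth locality, so the generator's total is 145),
597-bp mtDNA for a uniform random subset of 129 individuals, and 5%
uniformly random missing genotypes (the study's per-cluster missingness
spans 1.4–9.3%). The demographic truth is the fitted history: ancestral
size 18,700; founder phase of 50 diploids for 100 years at 3,400 years
BP; expansion to 5,660; trichotomous split 1,030 years BP into daughters
of 2,000; the admixed group joins the three populations by a two-stage
admixture event 100 years BP weighted toward the lake population; and a
collapse 50 years BP to 2% remnants. The control-region rate default is
4e-7 per site per generation, chosen because it reproduces the observed
scale of control-region diversity (a handful of segregating sites among
~130 sequences) under that history; the microsatellite defaults are
mid-prior.

Synthetic data validate the machinery, not the biology: they share the
study's dimensionality, missingness and demographic signal, but real
data additionally carry genotyping error, null alleles, locus-specific
mutation rates, non-uniform missingness and departures from the
isolation model (the study itself detects asymmetric recent gene flow
between the admixed group and the populations, which the ABC scenarios
deliberately omit, as the original analysis also did). Passing tests
therefore demonstrate correctness of the estimators and calibration of
the inference under the stated model, not robustness to those real-data
complications.

Problem sizes in the shipped tests and the acceptance script are desk
scale, chosen so the whole suite completes in minutes: reference tables
of 600–800 rows per scenario (the study used 10^6), 10-seed end-to-end
replications, 30–50-replicate recovery and calibration experiments,
coalescent analytics at 2,000–3,000 replicates against closed forms with
3-standard-error tolerances. Scaling the same calls up is a single
configuration change (`n_per_scenario`, `mgw_sims`, `n_pods`); nothing
in the code is specific to the reduced sizes.

## Known limitations

* No migration during divergence, no recombination, no selection in the
  coalescent engine; the scenario inventory is isolation-with-admixture
  only.
* The LD-Ne estimator inherits the known upward skew of `1/r^2`-type
  point estimates at small locus counts, and its parametric chi-squared
  interval undercovers with multi-allelic loci (use the jackknife
  interval; both are reported).
* Genotyping error and null alleles are not simulated.
* The exact composition of the study's step-1 topology set and its
  step-2 variants SC4–SC6, and all its priors, are in supplementary
  tables that are not redistributable; the shipped templates are
  documented stand-ins, configurable via YAML, and the full-scale
  published probabilities are treated as reference values rather than
  reproduction targets.
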