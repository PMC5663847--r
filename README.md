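# finpop

Population-genetic inference for small, fragmented populations typed at
microsatellite loci and a maternally inherited mtDNA control-region
fragment — the study design used for the critically endangered Yangtze
finless porpoise (*Neophocaena asiaeorientalis asiaeorientalis*): ~150
diploids at 11 microsatellites, ~130 aligned 597-bp haplotypes, and a
partition of individuals into a few genetic clusters. The package is for
conservation and population geneticists who want the full inference
chain — diversity tables, differentiation tests, contemporary effective
size, and model-based demographic history — as reproducible, scriptable,
tested code.

## What it computes

**Diversity and differentiation** (the classic "Table 1 / Table 2"
summaries): observed and expected heterozygosity (H_o, H_e = 1 − Σp²),
Weir–Cockerham F_IS and pairwise F_ST from variance components a, b, c
(multilocus θ = Σa / Σ(a+b+c)) with permutation tests and
bootstrap-over-loci CIs; rarefied allelic richness
A_r = Σ_i [1 − C(N−N_i, g)/C(N, g)] and private allelic richness at a
standardized number of gene copies g; the Garza–Williamson bottleneck
ratio M = k/(r+1) with significance from constant-size coalescent
simulation; S, haplotype diversity Hd, nucleotide diversity π,
Watterson's θ_W = S/(a_{n−1}L) and Tajima's D with a coalescent test;
Hudson's F_ST = 1 − H_w/H_b and the Snn nearest-neighbour permutation
test for the mtDNA.

**Contemporary Ne from linkage disequilibrium**: Burrows composite
disequilibrium Δ from unphased dosages, r² = Δ²/(p(1−p)q(1−q)), rare
alleles screened at P_crit, subtraction of the Waples sampling
expectation E[r²] and inversion of the bias-corrected random-mating
formula, with jackknife-over-loci and parametric confidence intervals.

**Demographic history by coalescent ABC**: a multi-population Kingman
coalescent (piecewise-constant sizes, splits, admixture; generalized
stepwise microsatellite mutation with reflecting boundaries; finite-sites
control-region mutation), a declarative YAML-serializable scenario
language with priors and inequality conditions, and the five-step
likelihood-free workflow — reference-table simulation, MAD-standardized
rejection, model choice by LDA-logistic regression *and* random forest,
type-I/type-II/prior error calibration on held-out simulations,
local-linear parameter-posterior estimation, and posterior predictive
goodness-of-fit. Three nested scenario sets ship with the package:
10 branching orders, 6 size-change scenarios (including the ancestral
founder bottleneck), and the 2-scenario recent-collapse test.

**Synthetic data with known truth**: a study-dimension generator under
the fitted demographic history (founder bottleneck → trichotomous
split → recent collapse to ~2% remnants) plus a forward Wright–Fisher
sampler for LD-Ne validation, so the whole pipeline is testable without
the original supplementary download.

## Worked example

```r
library(finpop)

truth <- truth_config()                     # fitted-history defaults
syn   <- generate_study_like(truth, seed = 1)
cfg   <- analysis_config(rarefaction_individuals = 10, n_perm = 1000,
                         n_boot = 1000, snn_perm = 500, mgw_sims = 1000,
                         tajima_sims = 2000, seed = 1)
rep   <- run_stats(syn$genotypes, syn$haplotypes, syn$partition, cfg)

rep$microsat[, c("population", "n_mean", "he_mean", "ho_mean", "fis",
                 "m_gw", "m_gw_p")]
#>   population n_mean he_mean ho_mean      fis  m_gw m_gw_p
#> 1         PY   55.5   0.718   0.718  0.00873 0.698  0.000
#> 2         TL   16.4   0.747   0.773 -0.00292 0.697  0.110
#> 3       XCSS   16.4   0.663   0.692 -0.01250 0.700  0.124
#> 4      Admix   50.1   0.736   0.738  0.00801 0.645  0.000
```

Heterozygosities sit near 0.7 with F_IS indistinguishable from zero
(random mating within clusters), and the M-ratio is depressed to ~0.65–
0.70 — in the two well-sampled clusters the constant-size coalescent
null already rejects (`m_gw_p` ≤ 0.001 resolution at 1000 simulations):
the genetic footprint of the simulated collapse.

```r
rep$mtdna[, c("population", "n", "S", "n_hap", "hd", "pi", "tajima_d")]
#>   population   n  S n_hap    hd       pi tajima_d
#> 1         PY  49  5     3 0.490 0.003641    2.283
#> 2         TL  17  1     2 0.118 0.000197   -1.164
#> 3       XCSS  17  5     2 0.485 0.004064    2.067
#> 4      Admix  46  6     4 0.595 0.002847    0.634
#> 5      Total 129 10     5 0.672 0.004869    1.429

rep$ldne[rep$ldne$population == "Total",
         c("ne", "ci_jack_low", "ci_jack_high", "harmonic_s")]
#>     ne ci_jack_low ci_jack_high harmonic_s
#> 5 74.2        43.6          148      132.1
```

A handful of control-region segregating sites among 129 sequences, and a
pooled LD-based contemporary Ne of ~74 breeders — two orders of
magnitude below the pre-collapse sizes in the generating truth. The
LD-Ne estimator itself validates against forward Wright–Fisher truth:

```r
est <- ldne_estimate(simulate_wright_fisher(50, 45, 18,
        n_generations = 40, init_alleles = 4, mu = 5e-4, seed = 3011))
est
#> LD-Ne estimate: 50
#>   parametric 95% CI: [ 36 - 75 ]
#>   jackknife 95% CI: [ 20 - 596 ]
#>   mean r2 = 0.03021 over 1476 allele pairs; harmonic S = 45.0
```

The three-step demographic analysis runs the same way
(`run_abc(syn$genotypes, syn$haplotypes, syn$partition, cfg)`) and
returns, per step, the model-choice probabilities from both routes, the
error calibration, and — for the final winner — parameter posteriors and
posterior predictive checks. A thin CLI (`inst/cli/finpop.R`) exposes
`stats`, `abc`, `simulate` and `ldne` subcommands for shell use.

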