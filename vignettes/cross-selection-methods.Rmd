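---
title: "Simulation-based cross selection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation-based cross selection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossrank)
```

## The problem

Recurrent genomic selection — phenotype a population, fit a marker model,
cross the best material, repeat — works well in outcrossing crops, where
large numbers of F1 seed are cheap. In selfing crops such as soybean every
F1 seed costs a hand-crossing event, so a cycle that needs dozens of crosses
is not practical. `crossrank` implements and benchmarks a strategy that
concentrates the crossing budget: instead of ranking *plants* by their own
predicted value, it ranks *crosses* by simulating the F2 progeny of every
possible parent pair in silico and scoring each pair by the predicted trait
values of its best simulated progeny. One or a few top crosses then carry
the whole cycle.

## The simulation model

**Genome and trait.** The simulated species is diploid with `n_groups = 20`
linkage groups of `length_cM = 150` cM. A quantitative trait is controlled
by `n_qtl` biallelic additive QTLs (30 or 100 in the benchmark) placed
uniformly at random on the map. Effect magnitudes are drawn from
Gamma(shape = 0.4, scale = 1.66) — a heavy-tailed architecture with many
small and a few large effects — and each locus's favorable allele is
assigned to founder A or B with probability 1/2 (`sign_mode = "random"`),
so both founders contribute favorable alleles as in a real biparental
cross; `sign_mode = "all_positive"` gives the symmetric textbook
architecture instead. There is no dominance, epistasis or mutation.

**Genotypes and genetic values.** Genotypes are coded founder-based:
+1 (AA), 0 (AB), −1 (BB). The genetic value of a plant is
$GV = \sum_j s_j\,\beta_j\,x_j$ with $s_j = \pm 1$ arranged so the
favorable homozygote contributes $+\beta_j$. After the initial population
is built, all effects are rescaled by one constant so that the variance of
GV in that population is exactly 1; this pins the trait scale.

**Phenotypes.** A phenotype is $y = GV + e$ with
$e \sim N(0, \sigma^2_e)$, $\sigma^2_e = \sigma^2_g (1 - h^2)/h^2$ and
$\sigma^2_g = 1$ the *initial* genetic variance. Heritability `h2` takes
values 0.3, 0.6 or 1.0 in the benchmark. $\sigma^2_e$ is held constant
across cycles even as genetic variance erodes — the measurement error of a
trait does not shrink because a breeding population became uniform — and
environmental deviations are redrawn at every phenotyping.

**Meiosis.** Crossing over follows the Haldane model (no interference):
recombination fraction $r = (1 - e^{-2d/100})/2$ at map distance $d$ cM.
Because haplotypes are stored only at the mapped loci, the package realises
this as a Markov phase walk: on each linkage group the starting parental
phase is drawn with probability 1/2 and the phase switches between
consecutive loci with the per-interval $r$. Under no interference,
crossover counts in disjoint intervals are independent Poisson, so this
walk is *exactly* the marginal law of the Poisson crossover process at the
loci — and it restricts exactly to any locus subset, which is what lets
the progeny engine simulate only at the prediction model's markers. The
walk is implemented in C++ (`src/meiosis.cpp`) and driven by R's global
RNG, so every result is reproducible from `set.seed()`.

**Initial population.** One F1, heterozygous at every locus, is selfed to
give `n_pop = 200` F2 plants; each is advanced by single-seed descent
through six further selfings to F8 (seven meioses total from the F1), so
residual per-locus heterozygosity is about $2^{-7} \approx 0.78\%$. These
200 F8 lines are the starting material of every benchmark run.

## The prediction model

The marker model is $y_i = \mu + \sum_j \beta_j x_{ij} + \varepsilon_i$
fitted by the LASSO (`glmnet`), with the penalty $\lambda$ chosen to
minimize 10-fold cross-validated error. Three conventions, each genuinely
open, were fixed as follows:

* **$\lambda$ rule:** minimum-CV-error $\lambda$ (`lambda.min`), not the
  1-SE rule — the plainer reading of "optimized by cross-validation".
* **No standardization:** genotype codes already share the scale
  $\{-1, 0, 1\}$, so predictors enter raw and the penalty treats loci
  symmetrically.
* **Predictors:** in simulation mode the QTL codes themselves (marker
  discovery is out of scope); in empirical mode whatever marker set the
  supplied model file names.

Zero coefficients are retained so a model always carries one coefficient
per training marker; a constant response degenerates, with a warning, to an
intercept-only model whose prediction accuracy is recorded as missing.

## The in-silico progeny engine

For a candidate pair, `simulate_cross_progeny()` draws `n_f1` F1 genotypes,
selfs each `n_f2_per_f1` times, and evaluates the model on all simulated F2.
`score_cross()` summarises the progeny distribution by the mean PV of the
`k` best progeny (the `k` smallest when selecting for a lower trait value),
and reports the variance of all progeny PVs. `rank_all_crosses()` applies
this to all $n(n-1)/2$ unordered pairs — 18,721 for a 194-line panel —
sorting by score with ties broken by ascending parent indices so rankings
are stable and byte-reproducible.

Two layouts matter:

* **Second-cycle empirical layout:** 5 F1 × 50 F2 = 250 progeny per cross,
  the default of `simulate_cross_progeny()`. With heterozygous parents the
  F1s genuinely differ, so `n_f1 > 1` matters.
* **Benchmark layout:** the per-cross progeny count used inside the
  S strategies is not pinned down by the study design, so the package
  defaults to 5 F1 × 40 F2 = 200 — the same size as the real F2 population
  each cycle produces — and exposes both numbers as arguments.

With fully homozygous (RIL) parents the F1 is unique, so the ranking is
invariant to `n_f1` and only Monte-Carlo noise depends on the progeny
count.

## Selection strategies and the cycle

Six strategies share one F1 budget of 10 per cycle:

| label | crosses | chosen by | F1 per cross |
|-------|---------|-----------|--------------|
| S1    | 1       | simulated-progeny score | 10 |
| S5    | 5       | simulated-progeny score | 2  |
| S10   | 10      | simulated-progeny score | 1  |
| P1    | 1 (top 2 plants) | own PV | 10 |
| P5    | 5 (round robin of top 5) | own PV | 2 |
| P10   | 10 (round robin of top 10) | own PV | 1 |

P5's pairing is not specified anywhere, so the round-robin chain is assumed
by analogy with P10. Each F1 is selfed equally to pool a 200-plant F2
population; five cycles are run, refitting the prediction model on the
current population at odd cycles (so the first model is trained on the
initial F8 lines) and reusing it at even cycles. Training is
non-cumulative: each refit sees only the current population, the simplest
reading of per-cycle model updates. Metrics — maximum genetic value,
proportions of fixed-favorable / fixed-unfavorable / unfixed QTLs, and
Pearson correlation between PV and GV — are recorded for each cycle's F2
population, with the initial population reported as cycle 0. Once every
QTL is fixed, crossing identical inbreds cannot create variation, so later
cycles carry the last record forward unchanged.

`run_experiment()` replicates this over conditions (QTL count ×
heritability). Within a replicate all strategies start from the *same*
genome, effects and initial population but consume independent downstream
random streams, so replicate pairs are matched and
`matched_pair_test()` / `compare_strategies()` can apply the paired t-test
with Bonferroni adjustment.

## Numerical and edge-case choices

* Ties in every ranking (plants or crosses) break by ascending population
  index via stable sorts; all outputs are byte-identical under a fixed
  seed.
* An intercept-only model gives constant PVs; selection then falls back to
  index order and accuracy is `NA`, excluded from replicate means.
* A paired t-test with all differences zero reports $t = 0$, $p = 1$; a
  constant nonzero difference reports $p = 0$ (the limit of the t
  statistic).
* `matched_pair_test` and effect scaling refuse inputs with fewer than two
  observations; scaling also refuses a population with zero genetic
  variance.
* Map positions are continuous cM values; coincident positions (measure
  zero) are tolerated and ordered by locus id.

## What the synthetic data does and does not emulate

The fixture generator (`generate_fixture()`) reproduces the *shape* of a
real selfing-crop panel: 194 RILs from a biparental cross, 513 mapped SNPs,
29 of them carrying effects and entering the model, phenotypes on a
percent scale around a baseline of 43 with `h2 = 0.6` (the middle of the
benchmark's heritability range). It does not emulate genotyping error,
missing data, segregation distortion, linkage-map estimation error,
genotype-by-environment interaction, or non-additive gene action. Passing
tests therefore demonstrate the machinery is correct under the stated
model, not that predictions for any particular real panel would be
accurate.

## Problem sizes used in the tests

The packaged checks run the distributional oracles at Monte-Carlo sizes
where the expected deviations are sharp (10^5 gametes for recombination
fractions, 10^4 lineages for inbreeding rates) and the replicated
benchmark at 10 replicates of the 30-QTL, `h2 = 1` condition with the
default 200-plant populations — large enough that the qualitative strategy
ordering (S10 ≥ P10 in cycle-5 gain; S1 loses segregating QTLs fastest) is
reproduced, while keeping a full run in minutes on one core. The full
50-replicate, six-strategy, six-condition experiment is a call away:

```{r, eval = FALSE}
res <- run_experiment(n_qtl = c(30, 100), h2 = c(0.3, 0.6, 1.0),
                      n_replicates = 50, seed = 1)
```

## Known limitations

* Only biparental founder populations: every locus is biallelic with
  founder-labelled alleles, which is what the coding +1/0/−1 presumes.
* No dominance or epistasis; selection on non-additive architectures will
  look better in these simulations than in the field.
* Self-crosses are excluded from candidate enumeration by design.
* The phase walk needs a genetic map; physical coordinates must be
  converted to cM upstream.
* `population_from_codes()` assigns arbitrary phase to residual
  heterozygotes; use haplotype files for populations with real
  heterozygosity.
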