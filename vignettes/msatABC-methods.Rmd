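---
title: "Demographic inference from microsatellites with msatABC: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demographic inference from microsatellites with msatABC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msatABC)
```

## The inference problem

msatABC estimates demographic history — the onset time of a population
expansion, or the branching order of three diverging populations — from
multi-locus microsatellite genotypes. Microsatellites mutate fast
(around $10^{-4}$–$10^{-3}$ per generation), so their allele-frequency
spectra carry information about events within the last few hundred
generations, a window where sequence polymorphism is nearly
uninformative. The motivating application is the expansion of
Bantu-speaking populations across sub-Saharan Africa: dating the onset
of growth in west African source populations, and asking whether the
southern populations descend from the eastern migration stream, the
western one, or an unresolved trichotomy.

Likelihoods for stepwise mutation models across hundreds of loci are
intractable, so the package uses approximate Bayesian computation
(ABC): simulate data under parameter draws from the prior, summarize
each simulated dataset by a fixed statistic vector, keep the draws whose
statistics come closest to the observed vector, and correct the kept
draws by a local regression. Every stage — simulator, statistics,
rejection, adjustment, model choice, posterior predictive checks — is a
separately exported and separately tested function.

## Demographic models

**Single-population expansion.** Backwards in time the population
shrinks exponentially from its present diploid size $N_0$ to the
pre-expansion size $N_p$, reached at the expansion onset $T_{\mathrm{EXP}}$
(generations); earlier than $T_{\mathrm{EXP}}$ the size is constant at
$N_p$. The growth rate is $\alpha = \ln(N_0/N_p)/T_{\mathrm{EXP}}$, so the
trajectory $N(t) = N_0 e^{-\alpha t}$ is continuous at the onset.
$N_0$ is treated as a nuisance parameter: recent sizes are poorly
constrained by this kind of data, and the quantities of interest are
$T_{\mathrm{EXP}}$ and $N_p$.

**Three-population divergence.** East, south and west populations
diverge under one of four topologies: ESW $=(\mathrm{E},(\mathrm{S},\mathrm{W}))$,
SEW $=(\mathrm{S},(\mathrm{E},\mathrm{W}))$, WES $=(\mathrm{W},(\mathrm{E},\mathrm{S}))$,
or a simultaneous three-way split (STAR). The designated pair merges
(backwards) at $T_1$ into a constant-size ancestral population, which
merges with the remaining population at $T_2 = T_1 + \Delta T$. Each
extant population may grow exponentially since its founding split, at
its own rate $\alpha$. Migration acts between every pair of coexisting
populations at scaled rate $M = 4N_0m$; the per-lineage backward
emigration rate from population $i$ is $M/(4N_i)$ with $N_i$ the
source's present (or constant ancestral) size, which keeps the migrant
*fraction* $m$ constant through time while the migrant *count* shrinks
with $N_e$ backwards in time. Migration remains active between
ancestral and extant populations after the first merge. The default
$M = 1500$ matches the regime in which the topology question was posed;
$M = 0$ gives clean isolation models.

## The coalescent simulator

The simulator draws exact structured-coalescent genealogies: within a
deme of current effective size $N(t)$, $k$ lineages coalesce at rate
$\binom{k}{2}/\bigl(2N(t)\bigr)$ per generation; the exponential-growth
hazard is integrated in closed form and inverted, so event times carry
no discretization error; migration is a constant-rate event per
lineage; split times move lineages deterministically. Everything is
implemented in compiled code (Rcpp) with the R RNG, so `set.seed()`
makes every dataset bit-reproducible and the single code path is shared
between the user-facing functions (`simulate_genealogy()`,
`mutate_genealogy()`, `simulate_dataset()`) and the batch
reference-table builder.

Mutations follow a symmetric generalized stepwise model (GSM): per
locus, a rate $\mu \sim U(2.5\times10^{-4},\,7.5\times10^{-4})$ per
generation; mutation counts Poisson in branch length; each mutation
changes the repeat count by $\pm k$ with sign equiprobable and
$k \sim \mathrm{Geometric}(p)$, $P(k) = p(1-p)^{k-1}$ with $p = 0.95$.
We read the geometric "parameter 0.95" as the probability of a
single-repeat step (mean step $1/0.95 \approx 1.05$ repeats); the
alternative reading (mean $1/(1-0.95) = 20$ repeats per mutation) is
biologically implausible for microsatellites. `p_step = 1` recovers the
strict single-step SMM. The ancestral state is 100 repeats and allele
sizes are unconstrained; all statistics are translation-invariant, so
the ancestral state is arbitrary.

Two equilibrium closed forms anchor the simulator's correctness and are
re-derived by simulation in the test suite: at $\theta = 4N\mu = 1$ and
constant size, strict-SMM expected pair identity is
$1/\sqrt{1+2\theta} = 1/\sqrt3 \approx 0.5774$ (Ohta–Kimura), and the
GSM expected repeat-number variance is
$(\theta/2)\,E[k^2] = (\theta/2)(2-p)/p^2 \approx 0.5817$ at $p = 0.95$.

## Summary statistics

Five per-locus statistics: Nei's unbiased expected heterozygosity
$\frac{n}{n-1}(1-\sum_i p_i^2)$; the sample variance (denominator
$n-1$) of repeat counts; the number of distinct alleles; the frequency
of the most frequent allele; and the number of singleton alleles. The
single-group vector is the mean and variance of each across loci (10
components). The three-population vector is the across-locus mean of
each statistic per population plus the across-locus mean of each
pairwise $F_{ST}$ (Weir–Cockerham multi-allelic $\theta$, computed from
allele frequencies without a within-individual component, as a ratio of
sums over alleles), 18 components in the fixed order east, south, west,
then pairs E–S, E–W, S–W. An 18-component total is arithmetically
incompatible with taking both means *and* variances per population
(that would give 33); we treat the printed total as authoritative and
expose the 33-component variant behind `include_variances = TRUE`.
Statistics undefined at a locus (e.g. $F_{ST}$ when both populations are
fixed for the same allele) are dropped from that statistic's
across-locus aggregation. Missingness is handled by counting only
non-missing allele copies per locus and population.

## ABC: rejection, adjustment, model choice

The reference table holds $R$ prior-predictive draws (parameters plus
summary vector). Distances to the observed vector are Euclidean after
dividing each statistic by its median absolute deviation across the
reference table — statistics live on wildly different scales, so some
standardization is required for the distance to be meaningful; it is
computed once from the table and applied identically to the observed
vector. An optional monotone transform (`log1p`, or per-column Box–Cox
with the exponent chosen by direct normal profile likelihood) can be
applied first. Rejection keeps exactly
$\lfloor \varepsilon R \rfloor$ rows (the empirical-scale setting is
$\varepsilon = 0.3\%$ of $R = 100{,}000$, i.e. 300 draws), breaking
boundary ties by row index so results are deterministic.

The local-linear adjustment regresses each accepted parameter on the
deviation of its statistics from the observed vector, weighting by the
Epanechnikov kernel $1-(d/d_{\max})^2$, and replaces each draw by the
fitted value at the observed statistics plus its residual. Parameters
with strictly positive prior support are regressed on the log scale and
back-transformed, which keeps adjusted sizes and times positive; note
the back-transformed upper tail can extend beyond the prior bound —
adjusted draws are clamped to the prior support before re-simulation in
the predictive check, but posterior summaries report them as produced.
A singular design falls back to the unadjusted draws with a warning.
Posterior summaries are weighted means and weighted 2.5%/97.5%
quantiles (linear interpolation of the weighted empirical CDF); time
parameters are also reported in calendar years at 25 years per
generation.

Model choice pools the per-model reference tables (equal $R$ per model
enforced), computes one shared standardization and one distance vector,
and counts how many globally accepted draws each model contributes at
each tolerance on a grid; ratios of per-model counts approximate Bayes
factors under equal prior model weights.

## Priors

The defaults are this package's choices, not values from any external
source, and everything is configurable per run: expansion
$T_{\mathrm{EXP}} \sim U(40, 1000)$ generations,
$N_p \sim U(500, 10^4)$, $N_0 \sim \log U(10^3, 10^5)$; three-population
$T_1 \sim U(40, 400)$, $\Delta T \sim U(0, 400)$ (dropped for STAR),
$\alpha \sim U(0, 0.05)$ per generation and population,
$N_{\mathrm{anc}} \sim U(500, 10^4)$; present sizes fixed at $10^4$ per
population and $M$ fixed at 1500 (not inferred). Sensible ranges for
recent human expansions: $U(40,1000)$ generations is 1,000–25,000 years.

## Posterior predictive checks

`run_ppc()` resamples parameter vectors from the weighted adjusted
posterior, re-simulates datasets of the observed shape, and reports the
marginal 2.5%/97.5% envelope per statistic together with the observed
value and an inside/outside flag, plus a two-dimensional PCA summary
(statistics centered and unit-scaled by the simulated moments, observed
vector projected with the same scaling). Marginal envelopes and the
PCA projection are complementary: a joint miss can hide in marginal
intervals, and both outputs are produced for that reason.

## The pseudo-observed-data generator and what it does (not) show

`make_expansion_pseudo_obs()` and `make_threepop_pseudo_obs()` generate
datasets of known truth with the structure of the motivating panel: 717
unlinked microsatellites; single groups of 661 or 940 diploids; or
east/south/west pools of 40/41/48 diploids. Defaults mirror the scale
of the application (expansion onset 226 generations ≈ 5,650 years from
a pre-expansion size of 2,200). `degrade()` adds i.i.d. missingness and
flags a fraction of loci as indels to exercise the 50%-missingness and
marker-class filters. The generator emulates unlinked neutral loci
under the fitted model classes; it does not emulate ascertainment bias,
genotyping error, allele binning, linkage, or admixture from unmodelled
populations — so passing recovery tests demonstrate the inference
machinery is self-consistent, not that real data satisfy the model.

**Problem sizes.** The package's reduced-scale preset (`ci_preset()`:
50 loci, 50 diploids, $R = 5000$, tolerance 1%) is the size at which a
full inference runs in seconds-to-tens-of-seconds, chosen so recovery
experiments with tens of replicates remain statistically meaningful:
at this scale the shipped acceptance checks re-verify that the 95%
posterior interval for $T_{\mathrm{EXP}}$ covers the truth in at least
16 of 20 seeded replicates.
Empirical-scale settings ($R = 10^5$, 717 loci) are reached by raising
the same arguments.

**Designing recovery scenarios.** For topology recovery, the truth
should be drawn from the prior's typical set. A truth with zero growth
sits on the boundary of the $\alpha \sim U(0, 0.05)$ prior: the
observed data then fall in the prior-predictive tail of *every* model,
and the comparison degenerates into rewarding whichever topology
implies the shortest growth durations (STAR) rather than the best
branching order — a confound of the experiment, not evidence about the
method. The shipped recovery scenario therefore uses prior-typical
growth ($\alpha = 0.02$ in all three populations) with well-separated
splits ($T_1 = 100$, $\Delta T = 350$) and $M = 0$; under these
conditions the generating WES topology wins the acceptance count
decisively and consistently.

## Numerical and interface choices

- Time is in generations and sizes are diploid individuals throughout;
  no ms-style rescaling, which avoids reference-size traps when $N_0$
  is itself a random draw.
- Haplotypes are paired into diploids consecutively within a deme,
  valid by exchangeability of the coalescent sample.
- Missing-data codes `-9`, `0` and `NA` are accepted on input and
  normalized to one internal sentinel; half-missing genotypes become
  fully missing. Alleles are stored as repeat counts, never fragment
  lengths.
- Marker missingness is computed over the individuals present in the
  dataset handed to the filter; scoping to a subset of populations is
  done by subsetting first (`d[d$pop %in% ..., ]`).
- Degenerate inputs: one haplotype gives a zero-length genealogy;
  monomorphic loci give zero heterozygosity and variance; zero-spread
  statistics are dropped from standardization with a warning;
  `tolerance * R < 1` is an error rather than an empty posterior.
- The package's interface is its exported functions plus the two
  end-to-end drivers (`run_expansion_analysis()`,
  `run_topology_analysis()`), which write every stage table, the
  resolved configuration and the seed when given an output directory —
  sufficient to re-run a result bit-identically. A shell wrapper would
  add nothing over `Rscript -e` on these functions, so none is shipped.

## Known limitations

- No recombination, selection, sequence mutation, allele-size bounds,
  or ascertainment modelling; the simulator covers exactly the model
  classes above.
- Model choice by acceptance ratios is a crude Bayes-factor
  approximation and inherits the usual sensitivity of ABC model choice
  to the statistic set.
- The regression adjustment assumes approximate local linearity; with
  very wide tolerances and strongly curved parameter–statistic
  relations the rejection-only posterior (`adjust = FALSE`) can be the
  safer choice.

## A worked micro-example

```{r example, eval = FALSE}
po <- make_expansion_pseudo_obs(t_exp = 226, np = 2200, n0 = 20000,
                                n_loci = 50, n_diploid = 50, seed = 1)
res <- run_expansion_analysis(po$data, R = 5000, tolerance = 0.01, seed = 2)
res$summary
res$ppc
```
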