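---
title: "Modelling public-goods cooperation in resource-heterogeneous metapopulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling public-goods cooperation in resource-heterogeneous metapopulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coopscape)
library(dplyr)
```

## The question

Siderophores are iron-chelating molecules that bacteria such as
*Pseudomonas aeruginosa* secrete under iron limitation. Because secreted
siderophores benefit every cell in a well-mixed culture, they are a textbook
public good: non-producing "cheats" share the benefit without paying the
production cost, and in mixed culture they reliably outgrow producers.
`coopscape` asks how *spatial heterogeneity in resource availability* — some
patches rich, some poor, with the same overall mean — changes the level of
cooperation a metapopulation can sustain, and provides three connected
layers to answer it:

1. an analytic kin-selection layer (selection gradients, ESS investment,
   hard vs soft selection),
2. a serial-transfer metapopulation simulator mirroring paired-microcosm
   competition and experimental-evolution designs, and
3. assay read-out computations (Malthusian relative fitness, per-capita CAS
   chelator activity, ANOVA/Tukey/t statistics) together with a
   synthetic-data generator with known ground truth.

## The growth model and its assumptions

A focal cell in a patch with resource availability $R$ grows at basic rate

$$\gamma = R^a\,y - x^2,$$

where $y$ is the siderophore availability the cell experiences (the mean
production of its neighbours), $x$ is the cell's own investment, and the
exponent $a>0$ sets how growth scales with resources ($a=1$ linear, $a<1$
diminishing returns, $a>1$ accelerating). Fitness is $w_R = e^{\gamma}$.
Two structural assumptions matter:

* **benefit is multiplicative in $R$ and $y$** — the *relative* cost of
  producing decreases as resources increase, and
* **cost is quadratic in $x$** — an accelerating production cost, which
  makes the equilibrium investment an interior point.

Relatedness $r = \mathrm{d}y/\mathrm{d}x$ enters as the regression slope of
neighbour production on focal production. It is treated as a free,
exogenous parameter in $[0,1]$ — it is *supplied*, not derived from
demography; deriving $r$ from migration or bottleneck structure is out of
scope.

Under vanishing trait variation, the marginal gradient of relative fitness
in a single patch is $R^a r - 2z$, which vanishes at the evolutionarily
stable investment $z^* = rR^a/2$:

```{r}
single_patch_ess(R = 1, r = 1)
```

## Metapopulations: hard versus soft selection

Across patches distributed as $p_R$, selection on investment integrates the
per-patch gradient with *ancestry weights* $c_R$ — the share of the next
generation's ancestry contributed by patches at resource level $R$:

* **soft selection**: every patch contributes equally, $c_R = p_R$. The
  gradient becomes $\bar{R^a}\,r - 2z$, so for $a = 1$ the ESS is
  $z^* = \bar{R}r/2$ — heterogeneity has *no* effect.
* **hard selection**: patches contribute in proportion to their
  productivity, $c_R = p_R \bar w_R / \bar w$ with
  $\bar w_R = e^{R^a z - z^2}$. Productive (resource-rich) patches — which
  are also the patches where cooperation is most favoured — dominate the
  ancestry, and the ESS rises. To second order in the resource variance
  $\sigma_R^2$ (at $a=1$): $z^* \approx (\bar R r/2)(1 + r\sigma_R^2/2)$.

```{r}
d <- resource_atoms(c(0.5, 1.5))      # two equal patches, mean 1, var 0.25
m <- trait_model(r = 1)
tidy(ess_solve(d, m, "soft"))
tidy(ess_solve(d, m, "hard"))
tidy(ess_approx(1, 0.25, m, "hard"))
```

With nonlinear returns the first-order expansions are
$z^*\approx(r\bar R^a/2)\,(1+\tfrac12 a(a-1)\bar R^{-2}\sigma_R^2)$ (soft)
and $z^*\approx(r\bar R^a/2)\,(1+\frac{a(a-1+ar\bar R^{2a})}{2\bar R^2}\sigma_R^2)$
(hard). Under soft selection the variance term is pure Jensen curvature:
$a<1$ makes heterogeneity *reduce* the ESS, $a>1$ raise it.

### Numerical choices

* Atomic supports are summed exactly; continuous densities are integrated
  by adaptive quadrature at absolute tolerance `1e-10`
  (`stats::integrate`).
* `ess_solve()` brackets the root on $[0,\,r\,R_{\max}^a]$: the gradient is
  positive at 0 whenever $r>0$ and negative at the upper end, where $2z$
  exceeds the largest possible benefit term; the root is found by
  `stats::uniroot` at tolerance `1e-10` and polished by bisection if
  needed. The boundary case ($r=0$, or a non-positive gradient at the
  origin) returns $z^*=0$ directly rather than failing the bracket.
* The hard-selection gradient is normalized by mean fitness $\bar w$; the
  normalization rescales but cannot move the root, and makes the returned
  gradient a per-capita quantity.
* Only monomorphic equilibria are sought; branching/dimorphism analysis is
  a non-goal.

### Trait substitution

`trait_substitution_run()` checks the analytic layer by a mutation-limited
walk: from resident $z$, mutants $z \pm \delta$ are proposed and the
direction with the larger positive ancestry-weighted *invasion exponent*
(log relative fitness, with the mutant's neighbourhood
$y = r z' + (1-r) z$) substitutes; the walk stops when neither direction
invades. The log form is deliberate: its derivative at $z'=z$ equals the
selection gradient exactly, whereas an arithmetic mean of relative fitness
across patches carries a $O(\delta^2)$ convexity bonus that can leave both
directions marginally invasive near the ESS and stall convergence at finite
step size. The walk lands within one mutation step of `ess_solve()` for
both regimes.

## The serial-transfer simulator

The simulator mirrors the paired-microcosm designs: pairs of 6-mL
microcosms are grown for 48-h "seasons", each pair is mixed, and 1% (by
volume, relative to the destination) of the mixture seeds two fresh
microcosms; this repeats for 20 transfers. The heterogeneous treatment
pairs a high- with a low-resource patch; the homogeneous treatment pairs
two intermediate patches of the same mean. Hard pooling mixes equal
volumes (contribution $\propto$ final density); soft pooling first rescales
each patch to the pair-average total density, equalizing contributions.

The theory above gives no within-season population dynamics, so the
simulator adopts the simplest law consistent with the growth model:

* strains grow exponentially at per-hour rates $\gamma_i = R^a y - x_i^2$,
  with $y$ the density-weighted mean investment of the patch (the public
  good is fully shared in a well-mixed microcosm; $r$ plays no role inside
  a patch),
* growth stops when the patch total reaches a carrying ceiling $K R$
  (capacity proportional to resource level, $K = 10^9$ cells/mL per unit
  $R$),
* integration is a fixed-step exponential-midpoint scheme on log densities
  (480 steps per season; halving the step moves end-of-season frequencies
  by $<10^{-6}$ at the default scales).

Two qualitative patterns of the biology fall out of this law: end-of-season
density increases with $R$ (the ceiling), and the cooperator's within-patch
relative fitness $W \approx 1 - x^2/(Ry)$ is below 1 everywhere but rises
with $R$ — richer patches cap earlier, shortening the season's effective
cheating window. Their combination is the *positive covariance* between
cooperation, productivity and resource level that makes hard selection
favour heterogeneous metapopulations.

Transfers are exact fractional dilutions by default: at the experimental
~$10^7$-cell bottlenecks, multinomial founder drift is negligible, and the
deterministic mode keeps trajectories exactly reproducible. Multinomial
founder sampling is available (`stochastic = TRUE`), with one child seed
per replicate drawn deterministically from the run seed. With all patches
at the same $R$, hard and soft pooling produce bitwise identical
trajectories.

### De-novo cheats

The evolution scenario starts from pure producers and lets non-producers
($x=0$) arise as a deterministic mutational flux: a fraction $\mu$ of each
producer's births joins the cheat class. The default
$\mu = 3\times10^{-4}$ per division is chosen on two grounds: complete
siderophore loss has a large mutational target (a single regulatory
knockout suffices), and the rate places the cheat sweep mid-course on the
20-transfer horizon — non-producers detectable and rising, cooperation
substantially but not completely eroded — which is the regime the
experimental evolution observed. The ranking of treatments is then an
output of the dynamics. At much lower $\mu$ the 20-transfer endpoint sits
in the rare-cheat regime, where arm differences are at the noise floor.

## Synthetic data

`synthetic_design()` fixes the study conditions for all generators. The
three media are the casamino-acid dilutions: high $=1$, low $=1/4$,
intermediate their 1:1 mix, scaled into model units by `resource_scale`
(default 6). The cooperator's investment is `coop_x = 0.19`. These two
defaults were set together, analytically, so that

* a pure producer culture saturates $KR$ within one season in every medium
  (density $\propto R$),
* co-culture relative fitness $W$ is below one in all media, increases
  with $R$, and sits near 0.9 in the intermediate medium — the operating
  point the competition assays report.

Twelve replicates per group, 48-h seasons, and 1% transfers follow the
experimental design. Measurement noise is multiplicative lognormal
(densities: $\sigma_{\log}=0.1$; absorbances: $0.05$) — counts and optical
densities are positive and right-skewed; no Poisson colony-count layer is
added because plate counts in this design are large. With noise switched
off, every downstream estimator recovers ground truth exactly; generators
are byte-identical under a fixed seed.

What the generator does **not** emulate: plate-reader artifacts and edge
effects, contamination, strain-marker costs, iron-chemistry kinetics,
spatially structured (biofilm) growth, and clone-level variance structure.
Passing tests therefore certify the pipeline's statistical machinery and
the model's qualitative directions, not quantitative agreement with any
particular wet-lab dataset — F and t statistics of the original
experiments depend on unpublished raw data and are not reproduction
targets.

## Assay read-outs

* `malthusian()` is $m=\ln(n_{\mathrm{end}}/n_{\mathrm{start}})$;
  `relative_fitness()` is $W = m_{\mathrm{coop}}/m_{\mathrm{cheat}}$.
  Zero colony counts are rejected with an error rather than pseudocounted
  (the assays never report extinctions; a zero would make $m$ undefined).
* `per_capita_cas()` reads the printed CAS formula
  "1 − (A_i/A_ref) / density" as $(1 - A_i/A_{\mathrm{ref}})/\text{density}$
  — the chelation *fraction* normalized per capita — because the quantity
  is described as per-capita activity; the alternative grouping
  ($1 - \frac{A_i/A_{\mathrm{ref}}}{\text{density}}$) would not be a
  per-capita measure. Density is the OD600 of the 1:10-diluted sample
  multiplied by the dilution factor (back-calculated undiluted density);
  set `dilution = 1` to normalise by the diluted reading instead, since
  the protocols do not pin this down.
* `one_way_anova()`, `tukey_hsd()` and `one_sample_t()` wrap `stats::aov`,
  `stats::TukeyHSD` and `stats::t.test`; tests verify them against
  explicit sums-of-squares, permutation-null and studentized-range oracles.
  All tests are two-sided at $\alpha=0.05$; no multiple-testing correction
  is applied beyond Tukey.

## A worked comparison

```{r}
des <- synthetic_design(replicates = 2L)
freqs <- lapply(c(heterogeneous = "heterogeneous",
                  homogeneous = "homogeneous"), function(trt) {
  cfg <- gen_metapop_config(des, trt, pooling = "hard", n_transfers = 2L)
  metapop_frequency(run_metapopulation_experiment(cfg))
})
sapply(freqs, function(f) f$frequency[f$transfer == 2][1])
```

After two transfers under hard pooling, the heterogeneous metapopulation
retains roughly four times the cooperator frequency of the homogeneous one
of equal mean resources.

## Known limitations

* **Soft pooling does not cancel the arm difference exactly.** In the
  weak-selection analytic layer, soft selection removes the effect of
  heterogeneity completely (and the package verifies this to $10^{-8}$).
  In the simulator it only attenuates it (about five-fold at the default
  operating point): the per-season frequency shift depends on $R$ through
  the effective growth window $\min(48\,\mathrm{h}, \text{time-to-ceiling})$,
  which is convex in $R$, saturates at the season length in weakly growing
  patches, and feeds back through the public good (patches losing
  producers grow ever more slowly). This Jensen-type residual survives
  contribution equalization. It is a property of the within-season growth
  law at experimentally realistic selection strengths, not of the pooling
  scheme.
* **$W$ is convex in $R$.** $1-W \propto 1/R$ at fixed composition, so the
  "intermediate equals the mean of high and low" linearity check holds
  only approximately in synthetic data (deviation ≈ 30% of the media
  spread at defaults).
* Frequencies are continuum quantities; there is no extinction threshold,
  so two-strain runs report astronomically small cooperator frequencies
  after long cheat sweeps rather than extinction.
* Generations are reported as doublings implied by the dilution factor
  ($\log_2 100 \approx 6.6$ per transfer), not forced to any nominal
  figure; the bottleneck is defined relative to the destination microcosm
  (1% by volume), not the pooled volume.

## Problem sizes

The shipped tests and the acceptance script run the theory checks at
1000 random parameter draws, the soft-invariance sweep over 50 random
distributions, trait substitution over 10 scenarios × 2 regimes,
single-metapopulation (12-pair) serial-transfer runs over 20 transfers,
noisy-plating comparisons over 100 seeds, and estimator-recovery sweeps
over 100 replicates — sizes at which every stochastic check is comfortably
inside its Monte-Carlo error while the whole suite remains quick on one
CPU.
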