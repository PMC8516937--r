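---
title: "Models and methods for dental-dietary macroevolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for dental-dietary macroevolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

cuspevol studies how a discrete measure of tooth complexity (cusp number:
1, 2, 3, or 4-plus cusps) and diet (carnivore, insectivore, omnivore,
herbivore — a gradient of increasing plant consumption) evolve together on
time-calibrated phylogenies that mix extant and fossil species. This
vignette records the models the package implements, the assumptions and
tunable parameters behind them, the numerical choices, and what the
synthetic-data generator does and does not emulate.

## Trees, ages, and polytomies

Trees are `ape` `phylo` objects with branch lengths in millions of years
(My). Node ages are computed from branch lengths with the deepest
root-to-tip path defining the present, so extant tips sit at age 0 and
extinct (fossil) tips at positive ages. Age/branch-length consistency is
revalidated after every tree operation.

The likelihood machinery needs strictly binary trees. `resolve_polytomies()`
resolves multifurcations into random dichotomies (via `ape::multi2di`,
seed-controlled) and then gives each inserted zero-length edge a small
positive length, `epsilon = 1e-3` My by default, *taken from the edges
immediately below* the inserted node. This keeps tip ages, total depth, and
the age ordering of nodes intact. The sources that motivate this workflow
do not state how large their adjusted branch lengths were, so epsilon is a
configuration knob; its default is small enough (a thousandth of a My) that
no downstream quantity we compute is sensitive to it.

`rescale_tree(tree, 0.1)` multiplies every branch by
`target / mean(branch length)`; the correlated-evolution machinery expects
trees on this mean-0.1 scale, where rates near 1 are "one expected change
per ten average branches".

## Mk models, model averaging, and reconstruction

A k-state character evolves by a continuous-time Markov chain with
generator Q (rows sum to zero, units 1/My). Six generator templates are
provided: `ER`, `SYM`, `ARD` (all transitions allowed with equal,
symmetric, or all-different rates) and their `ordered_*` variants, which
restrict transitions to adjacent states on the ordinal order. The ordered
templates encode the biological hypothesis that diet changes move along the
plant-consumption gradient one step at a time (carnivore to insectivore to
omnivore to herbivore), rather than jumping.

`mk_loglik()` is Felsenstein pruning with per-node scaling;
transition-probability matrices come from an eigendecomposition of Q with a
scaling-and-squaring fallback when the eigenbasis is ill-conditioned. The
root prior defaults to uniform over states (the convention under which the
up-down pass below equals the re-rooting construction); stationary or fixed
priors are available.

`fit_mk()` maximises the likelihood over log-rates with `nlminb`, bounds
1e-8 to 1e3 (1/My), and a fixed ladder of five starting values spanning
`10^-3` to `10` changes per tree height — fits are deterministic. For the
cusp character the `{ER, SYM, ARD}` fits are combined by Akaike weights
into a model-averaged generator (`mk_model_set(..., combine = "average")`);
for diet the six templates are compared and the single best-AIC generator
is used (`combine = "best"`). These two protocols mirror the two ways
discrete models are typically handled for these characters: averaging when
no template is clearly privileged, selection when a biological hypothesis
(the ordered gradient) is being tested against naive alternatives.

`marginal_asr()` computes the marginal posterior state probabilities of
every node in a single up-down (outside-inside) pass. For a time-reversible
generator this is algebraically identical to re-rooting the tree at each
node and reading the root state distribution — the up-down pass simply
computes all of them in one sweep. Correctness is checked against
brute-force enumeration over all internal state assignments on small trees.

`stochastic_maps()` samples complete character histories: node states by
backward sampling from the pruning partials, then each branch history
conditional on its endpoints by uniformisation (a rejection-free sampler:
the number of uniformised jumps is drawn from its exact conditional
distribution, jump states from the discrete bridge, jump times as sorted
uniforms, and self-transitions collapsed). The modal node state across maps
is the `simmap_modal` reconstruction; ties break toward the lower ordinal
state, deterministically. Downstream counting uses `simmap_modal` by
default; both reconstructions are available, and on decisive nodes they
agree (the test suite requires 97% agreement at 1000 maps where the
marginal is above 0.55).

## Transition counting

`enumerate_transitions()` emits one event per branch whose parent and child
states differ, with a signed ordinal magnitude; cusp events of magnitude at
least 2 are multi-cusp gains/losses. `count_originations()` classes each
gain of a derived condition (multicuspidness, or plant consumption) as a
`major_clade` when the subtended clade holds at least 3 derived terminal
species — the threshold is exposed because the underlying distinction
between "major clades" and "isolated lineages" is verbal, not formal — and
flags re-evolution when an ancestral branch carries a prior loss.

`pair_changes()` pairs same-direction changes of the two characters lying
on one root-to-descendant path. The pairing rule is: nearest same-direction
event of the other trait on the same path, no event reused, and no
opposite-direction event of either trait between the two (a reversal breaks
the causal reading of the pair). Order of pairing is by path separation,
nearest first. The verbal description this implements leaves reuse and
ordering open; our rule is deterministic and documented here.

`bin_lineages()` counts lineages per state in half-open 10-My bins anchored
at the present and counting backwards. A branch contributes one lineage to
every bin it overlaps; its state in a bin is its child-node state; change
events are dated at the branch midpoint. Whether such figures weight by
bin-residence time or date changes differently is typically not printed;
these defaults are exposed as arguments.

## Correlated evolution of two binary traits

The four cusp levels and four diets are recoded to binary traits under five
named schemes (`binarize()`); the headline pair is unicuspid-vs-multicuspid
against predator-vs-plant-consumer. The joint chain lives on
{00, 01, 10, 11} with dual transitions structurally zero. The independent
model has 4 rates (each trait's gain and loss, ignoring the other trait);
the dependent model has 8 (each single-trait rate in each context of the
other trait). Tied appropriately, the dependent model reproduces the
independent likelihood exactly, and the independent likelihood factorises
into the two single-trait pruning likelihoods — both are tested.

Rates get a uniform(0, 100) prior on the mean-0.1 rescaled tree, the
documented default of the standard software for this analysis. Sampling is
single-coordinate random-walk Metropolis-Hastings on log-rates, with the
proposal scale adapted toward 20-50% acceptance during burn-in only.

Marginal likelihoods use steppingstone sampling on a power-posterior ladder
with temperatures at quantiles of Beta(0.4, 1) — dense near the prior,
where the integrand changes fastest. The rungs are run from the posterior
end of the ladder down to the prior, with the first rung seeded at a cheap
maximum-likelihood mode and each rung handing its final state and adapted
proposal scales to the next. We adopted this direction after measuring, at
desk-scale iteration counts, that chains started at the prior end never
reached the posterior mass of the 8-parameter dependent model within the
per-rung budget: the resulting marginal-likelihood estimates were biased by
tens of log units against the larger model. Running downward from the
posterior removes that initialisation bias because every rung starts close
to its own stationary distribution; the estimator itself is unchanged.
Desk-scale defaults (30-100 stones of a few hundred to a few thousand
iterations) are configuration values; full-scale settings of the kind used
in published analyses are reached through the same arguments.

The log Bayes factor convention is `2 * (logZ_dependent - logZ_independent)`
— the scale on which 10 reads as very strong support. One behaviour worth
stating plainly: under the flat rate prior, data simulated *without*
dependence give systematically negative log Bayes factors (the marginal
likelihood penalises the four unused parameters), not values scattered
around zero. The calibration tests therefore check that independent data
never produce support *for* dependence (log BF below 2), which is the
substantive requirement.

## Open-outline morphometrics

Tooth profiles are ordered open polylines. The pipeline is: resample to 200
points at equal arc length along a natural cubic spline of each coordinate
against arc length; Bookstein-register the two endpoints to (-0.5, 0) and
(0.5, 0) (a similarity transform, so the pipeline is exactly invariant to
rotation, scale, and translation of the input); then take the orthonormal
DCT-II of each coordinate signal and keep orders 1-21 per axis (42
coefficients). Order 0 is the mean position, which registration has already
fixed, so it is dropped; the exact DCT dialect (normalisation, zeroth-term
handling) varies across software and is fixed and documented here. Energy
compaction is monotone: reconstructions from 5, 13, and 21 orders improve
strictly.

`morphospace_pca()` is ordinary PCA of the coefficient matrix.
`morphospace_ppca()` is phylogenetic PCA: eigenanalysis of the evolutionary
covariance estimated by GLS under the tree's Brownian covariance with the
GLS root state as mean; on a star phylogeny with equal depths it reduces
exactly to PCA.

`phylo_manova()` fits the score matrix on group by GLS under a Pagel's
lambda-scaled phylogenetic covariance (lambda estimated by ML on a profile
likelihood over [0, 1]), computes the Pillai trace of the group effect on
the whitened data, and permutes the whitened residuals of the
intercept-only model for the p-value. With lambda fixed at 0 this is an
ordinary permutation MANOVA. The regularised (penalised-likelihood) variant
used in some published analyses is deliberately not implemented: the
regularisation path is software-specific, so the printed Pillai trace of
such analyses is matched qualitatively, not numerically. Carnivores are
merged into a predatory group for shape tests when group sizes demand it.
Contrast matrices over group means are supported for targeted comparisons.
`dfa()` provides canonical discriminant axes (at most groups minus 1) and
leave-one-out nearest-centroid classification.

## Trait-dependent diversification

`bisse_loglik()` implements the binary-state speciation-extinction
likelihood on ultrametric, extant-only trees with a sampling fraction rho
(a global fraction near 0.05 is the reference configuration for
squamate-scale data; fossil-inclusive variants are out of scope so that the
core stays verifiable against closed forms). The extinction probabilities
E0(t), E1(t) depend only on time before present on such trees, so they are
integrated once (deSolve, relative tolerance 1e-8) on a global grid. The
linear D-system is then propagated along each branch using per-cell 2-by-2
propagator matrices precomputed on the same grid — each cell's propagator
is the exact exponential of the generator frozen at the cell midpoint
(local error O(h^3) in the cell width h, here tree height / 200) — with
partial cells at branch ends handled the same way. Node recombination
multiplies daughter likelihoods by the speciation rate of the node state;
the root uses likelihood-weighted (FitzJohn) averaging by default, with a
flat option, and optional conditioning on survival. Two independent checks
pin this machinery down: the state-independent case factorises exactly into
a closed-form constant-rate birth-death likelihood times a 2-state Mk
likelihood, and a 5-tip fixture matches a stiff adaptive integration of the
full joint system to 1e-5.

`fit_bisse()` optimises log-rates (bounds 1e-6 to 10/My) from a pure-birth
moment start, with constraint specs tying `lambda0 = lambda1` and/or
`mu0 = mu1` for the trait-independent null models compared by AIC.

## The synthetic-data generator

`simulate_study()` produces the package's test bed: a birth-death tree
(default birth 0.15/My, death 0.035/My, 40 My, extinct lineages kept as
fossil tips), two four-state ordinal characters simulated by exact Gillespie
CTMC along the branches with faster decreases than increases (the
asymmetry seen in real dental data), and parametric tooth outlines for the
multicuspid species. Expected scale is roughly 110-130 tips with about a
fifth fossil tips — about one-fifth the size of a full squamate study,
which keeps the complete pipeline within minutes on one CPU; the exact
sizes each analysis uses are stated with the respective tests. Because the
tip count of a single-founder birth-death clade is heavily dispersed, the
generator redraws (from derived seeds) until the tip count lands in a
workable band (default 60-200 tips); this conditioning is part of the study
design, not of any individual simulation's correctness, and the
unconditioned simulator is exercised directly by the pure-birth
expectation test.

Correlated binary data come from `simulate_binary_pair()`, which runs the
joint 4-state chain of the dependent model. The dependence used in power
checks is strong and asymmetric — the plant trait is rarely gained without
the complexity trait and decays quickly once complexity is lost — because
on phylogenies a single rare event can found a large clade, so mild
context ratios leave genuinely ambiguous histories at realistic tree sizes.

The outline model is deliberately simple: a flat-topped crown (constant
height across the cusp-bearing region, smooth falloff to the margins)
carrying k Gaussian cusps, with herbivory raising a protrusion parameter
(height over width, +50% at full herbivory by default) and an apical
flaring parameter (cusp width, +80%), plus additive coordinate noise (SD
0.02 crown widths). The flat base guarantees the k cusps are the only
local maxima of the noise-free profile. It spans the two axes real
multicuspid tooth morphospaces are dominated by — protrusion and apical
flaring — and nothing else: passing shape tests on these outlines shows
the pipeline recovers known, low-dimensional group structure, not that it
would capture the full geometry of real teeth.

Ground-truth node states are retained, so reconstruction accuracy is
scored exactly (`asr_accuracy()`), and every generator is a pure function
of (config, seed).

## Statistics

`kruskal_wallis()` wraps the tie-corrected H test and adds the
epsilon-squared effect size `H / (n - 1)` — the definition consistent with
published values for this kind of data (H = 144.27 on n = 548 giving 0.26)
— with a seed-fixed percentile bootstrap CI (default 10,000 resamples).
`pairwise_wmw()` runs all two-sided pairwise Wilcoxon-Mann-Whitney tests
with Holm correction by default (the correction used in the motivating
analyses is unstated; Holm is conservative without independence
assumptions, and the method is an argument).

## Orchestration

`run_pipeline()` executes the full graph — validation, Mk fitting and
averaging, reconstruction and mapping, transition analysis,
correlated-evolution testing, morphometrics, optional BiSSE, statistics —
on file inputs (Newick + CSV) or on a synthetic study, writing every
intermediate artifact as CSV/JSON plus a log and a checksum manifest; a
run is reproducible from its config and seed. The package is a library
rather than a shell tool, so the stage functions and `run_pipeline()` are
the interface; `scripts/acceptance.R` shows a complete scripted run.

## Known limitations

Hidden-rate and hidden-state models (covarion-style Mk, HiSSE), polymorphic
or missing tip states, fossil-aware diversification likelihoods,
regularised MANOVA, and closed-outline elliptic Fourier analysis are out of
scope. The steppingstone estimator's accuracy at very small per-rung
budgets depends on the ML pre-fit finding the posterior mode; multi-modal
posteriors would need longer rungs. The MANOVA permutes residuals under
the estimated lambda rather than re-estimating lambda per permutation — a
standard approximation that holds when lambda is well identified.
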