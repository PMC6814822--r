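---
title: "Modelling the macroevolution of sexual size dimorphism"
author: "ssdevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the macroevolution of sexual size dimorphism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question

Sexual size dimorphism (SSD) — a systematic body-size difference between
the sexes — is shaped by sexual selection (competition for mates favours
larger males) and by natural selection (intersexual niche divergence can
favour size differences that reduce competition between the sexes for
food). In carnivoran mammals both forces are plausible: social system is
the available proxy for the intensity of sexual selection, and diet for
the scope of niche divergence. `ssdevol` implements a complete
comparative pipeline for asking, on a time-calibrated phylogeny with
sex-specific body masses and social/dietary categories:

1. does SSD scale allometrically with body size (Rensch's rule), overall
   and within clades, and
2. do social system and/or diet predict the *optimum* SSD a lineage is
   attracted to over evolutionary time, and where on the tree did the
   optimum shift?

Every stage can be exercised on synthetic data generated by the package
itself, which is how the whole pipeline is validated.

## The dimorphism index and selective regimes

SSD is quantified by the size dimorphism index, in percent:

$$\mathrm{SDI} = \pm\left(\frac{S_L}{S_S} - 1\right)\times 100,$$

where $S_L$ and $S_S$ are the mean body masses of the larger and smaller
sex; the sign is positive when males are larger, negative when females
are, and exactly 0 for equal masses (the sign convention is then
immaterial). SDI is kept in percent throughout, so all OU optima
$\Theta$ below are in percent too. The index is antisymmetric in its
arguments and invariant to rescaling both masses, which the test suite
checks by property.

Species carry a social system (territorial solitary, pair-living,
group-living, variable) and a diet (carnivory, i.e. >70% terrestrial
vertebrate prey; omnivory; insectivory; herbivory; aquatic carnivory).
Because the full 4 × 5 interaction is far too fine for comparative
model fitting at ~166 species, the pipeline aggregates to six combined
regimes: {solitary, group} × {carnivory, omnivory, other}. Pair-living
and variable systems aggregate with group-living; insectivory,
herbivory and aquatic carnivory aggregate to "other". The loader takes
categories as given and never reclassifies a species — judgement calls
(e.g. treating lions as territorial solitary because males defend the
pride's territory) are data-entry decisions, not code.

## Rensch's rule: phylogenetic RMA with Pagel's λ

Rensch's rule predicts male-biased SSD increases with body size, i.e.
ln male mass is hyperallometric to ln female mass. Because the line is a
scaling relation with error in both variables, the slope is estimated by
reduced major axis (RMA): $b = \mathrm{sign}(s_{xy})\sqrt{s_{yy}/s_{xx}}$,
with $s$ the evolutionary (co)variances. These are GLS residual
cross-products under a bivariate Brownian model whose residual
covariance is the λ-transformed phylogenetic covariance
$C(\lambda)$ (off-diagonals multiplied by λ); λ is estimated
simultaneously by maximizing the bivariate log-likelihood on [0, 1],
with the endpoints checked explicitly because boundary optima are
common.

The package regresses **ln male mass (y) on ln female mass (x)**, so
that a slope above 1 reads directly as Rensch-positive hyperallometry.
The slope is tested against $b_0 = 1$ on the log-slope scale,

$$T = \frac{|\log b - \log b_0|}{\sqrt{(1 - r^2)/(n - 2)}},
\qquad df = 2 + \frac{n - 2}{1 + r^2/2},$$

the non-integer effective degrees of freedom being Clarke's correction
as used by the standard phylogenetic RMA software (about $0.68\,n$ at
$r^2 = 0.95$). Perfectly collinear data are handled explicitly
($T = 0$ at the null, $\infty$ otherwise). A clade-by-clade driver
prunes the tree per clade (retaining the stem above each clade's MRCA so
root-to-tip depths are preserved), skips clades with fewer than three
species with a warning, and classifies each fit as Rensch-positive,
Rensch-negative, or neither at α = 0.05. Type-I error of this test is
checked by simulation in the acceptance suite (nominal 0.05, accepted
band 0.03–0.07 over 1000 slope-1 data sets).

## Regime histories: Mk models and stochastic character maps

Discrete regimes evolve under a continuous-time Markov (Mk) model with
rate matrix $Q$ (transitions/Myr). The likelihood is Felsenstein
pruning with per-branch transition probabilities $P(t) = e^{Qt}$
(eigendecomposition, cached per unique branch length, with a
matrix-exponential fallback when the decomposition is ill-conditioned).
Defaults: equal-rates (ER) structure and an equal root prior, both
configurable (SYM/ARD available) — the source analyses this package
reproduces do not state these choices, so the defaults mirror the
common mapping software's defaults and are declared rather than
inferred.

Stochastic character maps are drawn by (i) sampling node states from
their joint conditional distribution given the tips (pruning followed
by preorder sampling), then (ii) sampling each branch history
conditional on its endpoints by **uniformization**. Uniformization was
chosen over rejection sampling because its work per branch is bounded
(the jump count is drawn from an explicitly truncated distribution), so
runtime is deterministic at desk scale; the truncation tail is below
$10^{-12}$ of the endpoint probability. $Q$ is fixed at its ML estimate
for mapping (empirical Bayes), mirroring the standard tool; full-Bayes
sampling of $Q$ is out of scope.

Maps are summarized as per-node state frequencies (the usual node-pie
posterior summary) and mean transition counts per ordered state pair; a
state regained after an excursion counts each event separately.
Correctness is validated against exact enumeration (node marginals on a
5-tip tree over 20 000 maps) and against exact conditional event-count
integrals.

The six-regime combined character is mapped directly, not assembled
from separate social and diet maps; the separate characters are also
mapped (for their own OUM models and for transition summaries).

## OU models of SDI evolution

Five models are compared: single-rate Brownian motion (BM1), a
single-optimum Ornstein–Uhlenbeck model (OU1), and multi-optimum OU
models (OUM) with one optimum per social regime, per diet regime, and
per combined regime. The OUM class has regime-specific optima
$\Theta_r$ but a single attraction $\alpha$ and diffusion $\sigma^2$;
multi-α / multi-σ² variants are out of scope. Under a mapped regime
history, tip $i$'s expected value is $\sum_r W_{ir}(\alpha)\Theta_r$
where the weight of regime $r$ telescopes over the tip's root-to-tip
segments $[t_1, t_2]$:

$$W_{ir} = \sum_{\text{segments in } r}
  \left(e^{-\alpha(T - t_2)} - e^{-\alpha(T - t_1)}\right),$$

and the covariance is the non-stationary-root OU form
$V_{ij} = \frac{\sigma^2}{2\alpha} e^{-\alpha d_{ij}}
(1 - e^{-2\alpha t_{ij}})$ ($d_{ij}$ patristic distance, $t_{ij}$
shared time), with the $\alpha \to 0$ limit handled analytically as
$\sigma^2 C$. The residual root weight $e^{-\alpha T}$ is merged into
the ancestral-most regime's optimum (the common "root station"
treatment; a stationary-root variant was considered and rejected
because published chronograms in this setting are ultrametric but the
non-stationary form degrades more gracefully near $\alpha = 0$). Rows
of $W$ sum to 1 exactly, which the suite asserts algebraically.

**Fitting.** Given $\alpha$, the optima are generalized least squares
and $\hat\sigma^2$ has a closed-form ML profile, so the whole fit is a
one-dimensional search over $\alpha$: a coarse log-grid spanning
half-lives from depth/100 to 10 × depth (12 points), then Brent
refinement in the bracketing interval, tolerance 1e-8 on
$\log\alpha$. This exact profiling replaces a joint quasi-Newton search
over $(\alpha, \sigma^2, \Theta)$: it cannot diverge in the profiled
directions, and it is roughly an order of magnitude faster, which is
what makes 200 × 200 bootstrap validation affordable. A Cholesky
failure triggers one retry with a 1e-10 relative diagonal jitter.
Regimes absent from a map's histories are dropped from that fit with a
warning. OUM with a single regime reproduces OU1 to 1e-6 in lnL, and
OU1 at $\alpha \to 0$ reproduces BM1 to 1e-4, both asserted in the
suite.

**Model comparison.** BM1 and OU1 do not depend on the maps and are fit
once; each OUM model is refit on every stochastic map to propagate
regime-history uncertainty. Per-map AICc
($-2\ln L + 2p + 2p(p+1)/(n-p-1)$) yields per-map Akaike weights, which
are then **averaged across maps**. Averaging per-map weights, rather
than recomputing weights from mean AICc, is deliberate: the two
disagree in general, and the per-map average is the quantity that
propagates mapping uncertainty; both are reported in the comparison
table. A map whose OUM fit fails is dropped with a warning; more than
10% failures aborts. The attraction strength is reported as the
phylogenetic half-life $\ln 2 / \alpha$ (Myr), the time to move halfway
to a new optimum; $\alpha = 0$ reports as infinite (Brownian-like).

**Uncertainty.** Parameter CIs come from a parametric bootstrap:
simulate trait vectors from the fitted Gaussian $(W\hat\Theta, \hat V)$,
refit the same model on the same map, and take percentile intervals of
the replicate estimates. Percentile intervals may exclude the point
estimate under skew; only lower ≤ upper is guaranteed. Coverage of the
true optima is validated at 200 data sets × 200 replicates (accepted
band 0.90–0.99 for nominal 95%).

## Shift detection without a-priori regimes: RJ-MCMC

A complementary, data-driven analysis asks where the SSD optimum
shifted, without using the social/diet regimes at all. The model is a
multi-peak OU process: a background optimum $\theta_0$ plus $K$ shifts,
each on a distinct branch at a sampled relative position (the
likelihood applies the regime change at that position, not at the
branch midpoint), each introducing a new optimum inherited tipward
until overridden. $K$ has a Poisson prior (mean 15) truncated at the
branch count and renormalized; occupied branch sets are uniform (at
most one shift per branch); optima are Normal(data mean, 2 × data SD);
$\alpha$ and $\sigma^2$ are log-normal (log-SD 1.5) centred on a
half-life of depth/3 and on the Brownian rate estimate respectively.
These hyperpriors are the package's own scale-aware defaults — the
analyses this mirrors do not state theirs, so posterior quantities that
depend on them cannot be compared across implementations.

The sampler is Metropolis–Hastings with birth / death / relocate /
optimum / $\alpha$ / $\sigma^2$ moves. Proposing a birth optimum from
its prior makes the dimension-matching acceptance ratio collapse to
$\lambda_{\text{shift}}/(K+1)$ (and $K/\lambda_{\text{shift}}$ for a
death), which is both simple and exactly balanced; impossible moves
(death at $K = 0$, birth at $K = B$) are proposed and rejected, which
preserves detailed balance. Correctness is validated by a
prior-recovery run: with the likelihood forced constant the sampled
$K$ marginal must match the truncated Poisson prior (χ² goodness of
fit), and a planted shift of 5 stationary SDs on a 100-tip tree must
attain the maximum posterior shift probability, above 0.5.

Likelihood evaluations cache the Cholesky factor of $V_0(\alpha)$, and
$\sigma^2$ enters analytically, so only $\alpha$ updates pay the
$O(n^3)$ cost; tip means under a shift configuration are accumulated by
a painting pass over shifts in age order. Chains are summarized after a
30% burn-in: per-branch posterior shift probability pp (the fraction of
retained samples with a shift on that branch; the sum of pp over
branches equals the posterior mean of $K$ by counting), optimum
summaries for branches above the pp threshold (default 0.5), and
convergence diagnostics — Gelman–Rubin potential scale reduction
(floored at 1, so identical chains read exactly 1) and an
autocorrelation ESS with initial-positive-sequence truncation, capped
at the trace length so anti-correlated traces cannot report more
samples than exist. Desk-scale defaults are 200 000 generations thinned
by 100 with two chains; the headline-analysis settings (10⁶
generations, sampling every 10⁴) remain available but note that they
retain only 100 samples per chain, too few for the ESS levels usually
demanded — the two knobs are exposed independently.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults define the
validation conditions. `paper_like_recipe()` freezes a study-shaped
data set: 166 species on a 60-Myr pure-birth chronogram; six combined
regimes evolving as a product chain (social flips at 0.008/Myr, diet at
0.012/Myr — rare transitions from a solitary-carnivory root, so social
and diet margins behave like slowly-evolving characters with few
reversals); OUM optima of (50, 33, 6, 15, 9, 17)% for solitary
carnivory/omnivory/other and group carnivory/omnivory/other; a
phylogenetic half-life of 3.16 Myr (short relative to tree depth, i.e.
strong attraction); and a stationary SD of 15%, giving mostly
male-biased SDI spanning roughly −30% to +110%. Female ln mass evolves
by Brownian motion (root 5000 g, rate 0.03/Myr), and male mass is
decoded from female mass and SDI so that `compute_sdi()` round-trips
exactly, including female-biased species
($\text{male} = \text{female}/(1 + |SDI|/100)$). Draws with SDI ≤ −100
are redrawn and logged (the decoding tolerates them, but they fall
outside the biologically interpretable range).

Pure-birth trees are used because tree-shape detail is immaterial to
the methods under test; fossil taxa, non-ultrametric trees and
intraspecific mass variation are deliberately not emulated. Passing
validation on these data therefore demonstrates correctness of the
estimators under their own assumptions — it does not demonstrate
robustness to model violations in real data (measurement error in
masses, regime misclassification, diversification-correlated traits).

## Numerical and design notes

- Simmap dialect: segments are stored and written rootward-to-tipward;
  the reader/writer round-trips to 1e-9 on durations and the validator
  enforces duration sums, alphabet membership and history continuity
  (including a common start state among the root's children).
  Zero-length branches carry exactly one zero-duration segment.
- Ultrametricity is checked at relative 1e-6 of depth; tip labels are
  matched between tree and table after underscore/space normalization,
  and all drops are logged.
- Pruning to a taxon set keeps the stem above the retained MRCA so
  depths (and hence covariances) are preserved.
- α is bounded below at 1e-10/Myr; V is jittered by 1e-10 relative on
  the diagonal only after a Cholesky failure.
- Every stochastic stage takes an explicit seed; the pipeline derives
  per-stage seeds deterministically from one master seed, so a rerun is
  byte-identical. Validation problem sizes (e.g. 50-tip bootstrap
  trees, 20 000-map node-frequency checks, 2 × 10⁶-generation
  prior-recovery runs thinned to near-independence) are the package's
  chosen balance of statistical resolution against desk-scale runtime.

## Interfaces

`run_pipeline()` orchestrates everything behind a validated config
(YAML or list; unknown keys are rejected with a spelling suggestion,
invalid values are reported together); defaults equal the
headline-analysis settings (500 maps, 1000 bootstrap replicates,
pp > 0.5, burn-in 0.30). Outputs are plain TSV/CSV/JSON plus a manifest
with seeds, runtimes and per-stage status; a stage failure preserves
earlier outputs. A thin Rscript wrapper lives in
`inst/scripts/ssd-pipeline.R`; the exported functions are the primary
interface. Figure rendering is out of scope — outputs are tables a
plotting layer can consume.
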