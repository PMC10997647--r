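---
title: "Variable-rates Bayesian PGLS: model, sampler, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variable-rates Bayesian PGLS: model, sampler, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vrpgls)
```

## The model

`vrpgls` fits the regression

$$ y = X\beta + \varepsilon, \qquad
   \varepsilon \sim \mathcal N\!\big(0,\; \sigma^2\, V(\lambda, r)\big), $$

where $y$ is a log10-scale body-size proxy (femur circumference in mm,
or body mass in g), $X$ a design matrix, and $V$ the Brownian-motion
phylogenetic covariance of the time-calibrated tree: $V_{ij}$ is the
root-to-MRCA shared path length of tips $i$ and $j$ (Myr),
$V_{ii}$ the root-to-tip length. Two transforms act on $V$:

* **Pagel's $\lambda \in [0,1]$** multiplies off-diagonal entries only.
  $\lambda = 1$ is full phylogenetic signal, $\lambda = 0$ a star
  phylogeny. Internally this is applied as the equivalent tree
  transform (every branch times $\lambda$, each terminal branch
  stretched by $(1-\lambda)\times$ tip depth), which keeps the
  likelihood computable by pruning in $O(n)$.
* **Rate scalars.** A configuration is a set of *placements*, each
  targeting a single branch or a clade (a node's subtree including its
  stem) with a multiplier $r \in [10^{-3}, 10^{3}]$. The effective
  scalar of a branch is the product of the placements covering it, and
  the branch contributes `length * scalar` to every path through it.
  This lets the tempo of evolution shift anywhere on the tree without
  pre-specifying where.

Assumptions worth stating: traits evolve by (possibly rate-rescaled)
Brownian motion; residual covariance follows the tree; branch lengths
are in consistent time units; predictors are measured at the tips
(latitude is a predictor here, not a mapped character — there is no
explicit dispersal process).

## Design matrices

`model_spec()` declares the fixed effects: a focal predictor
(`abslat`, absolute latitude in degrees; or `mat` / `cmmt` in &deg;C),
optional dummy-coded indicators and interactions, tip age (Ma,
Cope's-rule covariate), and the sampling-bias counts. Dummy coding is
fixed: northern hemisphere, Triassic, and Ornithischia are baselines
coded 0 (when those levels are present; otherwise the first sorted
level), and $k$-level factors use $k-1$ indicators. Latitudes are
stored *signed* and the absolute-value transform happens exactly once,
when the design row is built — so a species resampled to a southern
locality automatically flips its hemisphere indicator.

Species known from several localities carry one *occurrence record*
per locality (latitude, MAT, CMMT, age, linked). The deterministic
reduction used outside the sampler (`design_matrix()`) averages
record-level fields after transformation and takes the majority
hemisphere (ties resolve to the northern baseline); the stochastic
treatment lives in the sampler (below).

## Priors and the sampler

All priors are proper, vague and scale-free, fixed package-wide
because marginal likelihoods are compared across models:

| parameter | prior | default | why |
|---|---|---|---|
| $\beta_j$ (each coefficient) | Normal(0, 10^2) | sd 10 | slopes on log10 scales are $\ll 1$; effectively flat |
| $\log \sigma^2$ | Normal(0, 2^2) | — | spans rates from 10^-4 to 10^4 per Myr |
| $\lambda$ | Uniform(0, 1) | — | the standard vague choice |
| number of placements | Poisson(1), truncated at $2n-2$ | mean 1 | parsimony pressure toward few shifts |
| $\log r$ | Uniform on $[\log 10^{-3}, \log 10^{3}]$ | — | symmetric, spans the ten-fold shifts reported in comparative work |
| record assignment | uniform over a species' records | — | no locality is privileged |

`run_chain()` is Metropolis–Hastings with five move types:
per-coefficient Gaussian random walks (scales adapted in batches of 50
during burn-in toward 30% acceptance, frozen at the end of burn-in so
the post-burn-in chain is valid MCMC), a log-scale walk on $\sigma^2$,
a reflected walk on $\lambda$, reversible-jump moves on the scalar
configuration, and occurrence reassignment (one multi-occurrence
species, a uniformly proposed record, latitude and temperatures moved
jointly, accepted by likelihood ratio). The reversible-jump kinds
(add-branch, add-clade, delete, modify) are chosen uniformly; with
marks proposed from their priors the Green ratio reduces to
$\tfrac12/(k+1)$ for a birth and $2k$ for a death, and `modify`
perturbs $\log r$ by Normal(0, 0.3). Proposals that would push any
branch's *effective* scalar outside $[10^{-3}, 10^{3}]$ are rejected
outright rather than truncated, which keeps the stationary distribution
exactly the truncated prior — verified by a prior-recovery chi-square
test with the likelihood tempered away.

The likelihood is evaluated by Felsenstein pruning in compiled code,
returning the whitened data (standardised contrasts plus the scaled
root estimate) and $\log\det V$; coefficient and $\sigma^2$ moves reuse
the cached whitening, so only $\lambda$, scalar and occurrence moves
repay the $O(n)$ pass. Identical seeds and configurations reproduce
the sample stream bit-for-bit.

Chain presets mirror standard practice for these data scales
(`preset = "mesozoic"`: 12.5M iterations, 2.5M burn-in, thinning 1000;
`preset = "extant"`: 150M/100M/1000); everything is scalable down
through `chain_control()`.

## Model selection

`stepping_stone()` estimates $\log$ marginal likelihoods from a ladder
of power posteriors $p(D\mid\theta)^{b_k}\pi(\theta)$ with exponents at
Beta(0.4, 1) quantiles, $b_k = (k/K)^{1/0.4}$ — the standard spacing
that concentrates stones near the prior. Stones are chained (each
starts from the previous stone's final state) and the first 20% of
each stone's iterations are discarded, which removes most transient
bias. The estimator is the usual telescoped ratio with per-stone
max-shift for numerical stability; it reproduces a conjugate
closed-form marginal likelihood to better than 0.1 log units with 25–30
stones. Bayes factors are reported on the $2\,\Delta\log\mathrm{ML}$
scale with $\mathrm{BF} > 2$ read as positive evidence, matching the
convention and magnitudes used in this literature.

`model_ladder()` enumerates the comparison set: focal predictor only;
plus hemisphere; plus period; plus clade; plus indicator-by-predictor
interactions; plus tip age; plus formation count; plus occurrence
count — each in homogeneous-rate and variable-rates variants. The
mammaliaform preset drops the period and clade models: with only two
Triassic species, period contrasts are unidentifiable, and only a
hemisphere difference is testable.

## Sampling-bias covariates

`assign_zone()` partitions $[-90, 90]$ into nine 20-degree zones,
half-open $[-90+20k, -70+20k)$ with the top bin closed (so +90 maps to
zone 8); `build_counts()` tallies, per (zone, geologic period), unique
fossil-bearing formations and tetrapod occurrences after removing
taxonomically unidentifiable records and those not based on body
fossils; `attach_covariates()` assigns each species the counts of the
cell containing its mean signed palaeolatitude and mean age (explicit
period labels take precedence over age-derived periods; ICS bounds
251.9 / 201.4 / 145.0 / 66.0 Ma, configurable). Occurrence totals are
conserved by construction and the operation is idempotent.

## Branch-wise changes

For visualising coordinated shifts, `rate_scaled_tree()` multiplies
each branch by its across-samples consensus scalar from a univariate
(intercept-only) variable-rates run — with a fixed topology the
maximum-clade-credibility summary reduces to a per-branch statistic;
the arithmetic mean is the default and the median is available.
`branch_changes()` reconstructs ML ancestral states on that tree and
reports descendant-minus-ancestor changes per branch; changes
telescope exactly along root-to-tip paths. `change_scatter()` plots
the per-branch changes of two traits about origin crosshairs and
reports the origin-anchored least-squares trend; under a
Bergmann-type association the cloud runs from upper left to lower
right. Because published figures differ in whether points are coloured
by the *change* in temperature or by the ancestral temperature itself,
the colouring variable is an explicit argument rather than a guess.
Multi-occurrence species are reduced by their across-record means here:
a single reconstruction needs a single value per tip, while the
stochastic treatment stays in the sampler.

## The synthetic-data generators

`simulate_dataset()` supplies every structure the analyses assume, with
the generating truth returned for recovery testing:

* `independent-bm` — two uncorrelated Brownian traits (negative
  control; contrast correlations are centred on zero).
* `correlated-bm` — bivariate Brownian motion with rate matrix
  $\Sigma$ (positive control; default correlation 0.8).
* `regression` / `bergmann` — latitude evolves by Brownian motion
  (rate chosen so tip latitudes spread over roughly $\pm 35^\circ$ on a
  100-Myr tree) and the response is
  $\alpha + \beta\,|\mathrm{lat}|$ plus Brownian noise. The
  `bergmann` preset is the strong-effect small-clade
  parameterisation ($\beta = 0.0097$ log10 g per degree, $n = 8$),
  with the residual rate calibrated analytically so the expected
  whitened $R^2$ of the generating regression hits a stated target
  (0.75) — the calibration solves
  $R^2 = 1 - (n-2)\sigma^2 / (\mathrm{signal} + (n-1)\sigma^2)$ for
  $\sigma^2$, no tuning involved.
* `variable-rates` — Brownian response with one clade's branches
  multiplied by `mult` (default 10, matching the order of rate
  contrast reported for rapidly dispersing clades); the clade is
  chosen to hold about a quarter of the tips.

Trees are Yule (pure birth, unit rate) rescaled to a stated root
height — simple, standard, and irrelevant to the estimators under
test. Occurrence multiplicity: ~35% of species get extra records
(matching the multi-locality fraction typical of Mesozoic dinosaur
compilations), record latitudes are jittered with sd 2&deg; and
temperatures re-derived from the jittered latitude, so each record is
internally consistent (linked-record semantics). Temperature gradients
are deterministic monotone profiles anchored at a 30&nbsp;&deg;C
equator for the Mesozoic presets with polar MATs of 6.5–8&nbsp;&deg;C
and pole-ward-growing seasonality, and a steeper `modern` preset;
CMMT &le; MAT everywhere by construction.

What the generators deliberately do **not** emulate: spatial climate
fields (temperatures are a smooth function of latitude, not a GCM),
palaeogeography and plate rotation, fossil preservation processes,
non-Brownian trait models, and topological uncertainty. Passing tests
therefore demonstrate the correctness and calibration of the
estimators under the stated model, not robustness to model violations
in real data.

## Numerical choices and degenerate inputs

* Polytomies are kept at read time and resolved deterministically into
  zero-length bifurcations (via `ape`'s non-random resolution) only
  inside covariance/contrast computations; zero-length resolutions
  leave the covariance, and hence all likelihoods, unchanged.
* Singular covariances (e.g. duplicated zero-length tips) are handled
  by a ridge of $10^{-10}\times$ the mean diagonal, with a warning —
  never silently.
* $\lambda$ proposals reflect at 0 and 1; scalar `modify` proposals
  falling outside the prior support are rejected, not clamped.
* `p_mcmc` is one-tailed as defined (fraction of samples on the
  opposite side of zero from the posterior median, 0.5 if the median
  is exactly 0), so its maximum is 0.5.
* Two $R^2$ summaries are reported. The per-sample definition
  (whitened $1-\mathrm{SSE}/\mathrm{SST}$ with SST about the GLS
  phylogenetic mean, evaluated at each posterior sample's
  coefficients) can be negative and is the right object for
  "median $R^2$" posterior summaries. Because sampled coefficients are
  non-optimal, its median sits systematically below the maximum-
  likelihood $R^2$ at small $n$ (about 0.5 when the generating value
  is 0.75 at $n=8$), so the summary also exposes
  `r_squared_at_median`, the plug-in $R^2$ at the posterior medians,
  which is the comparable number when a fit is described as
  "explaining X% of variance".
* VIFs are computed by GLS-regressing each column on the rest after
  whitening; exact collinearity reports `Inf` rather than a large
  number.
* Effect-size conversions use
  $(10^{\beta\delta}-1)\times 100$ and are reported to one decimal
  place by convention.

## Problem sizes used by the test suite

The statistical acceptance checks run at desk scale, chosen as the
smallest sizes at which the phenomena are unambiguous: oracle
equivalence on 100 random trees of up to 10 taxa at $10^{-8}$;
credible-interval coverage on 20 independent 128-tip regressions with
50k-iteration chains (expecting $\ge 18$ of 20 to cover the generating
slope); ten-fold clade-shift detection on 10 replicates of 64 tips
(mean effective scalar in the fast clade more than three times
background in $\ge 8$); stepping-stone calibration within 0.1 log
units of a conjugate closed form, and nested-model Bayes factors
correctly favouring the simpler truth in $\ge 8$ of 10 replicates; and
positive/negative branch-change controls at 250 tips run through the
full univariate variable-rates pipeline.

## Known limitations

No Ornstein–Uhlenbeck or early-burst alternatives; no measurement-error
model beyond occurrence resampling; no tree inference, dating or
topology editing beyond pruning; no multi-chain convergence
orchestration (effective sample sizes are reported; run multiple seeds
yourself); posterior equality with other samplers is not a goal — their
reversible-jump proposal internals are unpublished, so only statistical
behaviour (calibration, coverage, detection) is comparable.
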