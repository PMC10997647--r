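# vrpgls

Variable-rates Bayesian phylogenetic regression for testing
macroecological rules on time-calibrated phylogenies.

## The problem

Bergmann's rule predicts that homeothermic animals (birds, mammals and
their extinct relatives) living in cooler, higher-latitude climates are
larger than close relatives from warmer climates. Testing such a rule
across hundreds of species requires a regression of body size on
latitude or local temperature that (i) treats species as
phylogenetically non-independent, (ii) lets the tempo of body-size
evolution vary across lineages, (iii) propagates the uncertainty of
species known from several localities, and (iv) controls for the uneven
geographic and temporal sampling of the fossil record. `vrpgls`
implements that full pipeline for comparative biologists and
palaeobiologists, together with seeded synthetic-data generators so
every stage can be validated without external downloads.

## The model

The core is a Bayesian phylogenetic generalised least squares (PGLS)
regression under Brownian-motion trait evolution,

y = X &beta; + &epsilon;, &nbsp;&nbsp; &epsilon; ~ N(0, &sigma;&sup2; V(&lambda;, r)),

where `y` is a log10 body-size proxy, `X` contains an intercept, a
focal predictor (absolute latitude in degrees, or MAT/CMMT in &deg;C)
and optional dummy-coded covariates (hemisphere, geologic period,
clade, their interactions with the focal predictor, tip age, and
fossil-sampling covariates), and `V` is the phylogenetic covariance:
shared root-to-MRCA path lengths, off-diagonals scaled by Pagel's
&lambda;, and each branch multiplied by the product of the rate-scalar
placements covering it. A reversible-jump MCMC sampler moves over
coefficients, &sigma;&sup2;, &lambda;, the set of branch/clade rate
scalars, and the occurrence-record assignment of species sampled at
several localities (latitude and temperatures proposed jointly from one
locality). Models are compared by stepping-stone marginal likelihoods
on the `BF = 2 (logML_A - logML_B)` scale with `BF > 2` read as
positive evidence, and slopes are summarised by posterior medians,
equal-tailed 95% credible intervals and `p_MCMC`, the proportion of
slope samples crossing zero. Branch-wise ancestral changes on
rate-scaled consensus trees visualise whether size and
latitude/temperature shift in a coordinated, Bergmann-consistent
direction.

## A worked example

An eight-species bear-like clade with a strong latitude effect (the
classic small-clade illustration of what Bergmann's rule looks like
when it does operate), generated by the built-in fixture registry:

```r
library(vrpgls)

dir    <- tempfile()
paths  <- make_fixture("ursid8", dir)          # synthetic, seeded
tree   <- read_tree(paths["tree"])
traits <- read_traits(paths["traits"], tree = tree)

fit <- run_chain(traits, tree, model_spec("abslat"),
                 chain_control(iterations = 50000, burnin = 10000, thin = 50),
                 seed = 1)
posterior_summary(fit)
```

```
Posterior summary (800 samples)
            median   2.5%  97.5%
(Intercept) 4.0824 3.5846 4.5566
abslat      0.0124 0.0053 0.0194
sigma2      0.0048 0.0013 0.0296
lambda      0.8051 0.0911 0.9925
p_MCMC:
abslat 
0.0025 
R^2 (median and CI):
median   2.5%  97.5% 
0.7740 0.0837 0.9019 
```

The posterior median slope (0.0124 log10 g per degree of absolute
latitude, 95% CI 0.0053--0.0194, `p_MCMC` = 0.0025) recovers the
generating value 0.0097: body mass rises by
`percent_change_per_unit(0.0124)` &asymp; 2.9% per degree of latitude,
and absolute latitude explains most of the mass variance across the
clade (plug-in R&sup2; at the posterior medians
`fit_summary$r_squared_at_median` &asymp; 0.86; the generating value is
0.75). Fitting the same model to data simulated under independent
evolution gives a slope CI spanning zero -- the package ships both
controls (`make_fixture("control_pos")`, `make_fixture("control_neg")`).

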