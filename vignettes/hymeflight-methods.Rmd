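---
title: "Methods: phylogenetic comparative analysis of flight morphology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic comparative analysis of flight morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hymeflight)
```

## The scientific question

Females of central-place foraging bees and wasps return to a nest with
food, over and over. Species differ in whether a forager can modulate the
load she carries per trip: bees pack as much or as little pollen as they
like, and social wasps chop large prey into portions ("able to
manipulate", AtM), whereas solitary wasps must lift each prey item whole
("unable to manipulate", UtM). If the whole-prey constraint matters, UtM
species should have evolved morphology that favours heavily loaded
take-off: a higher flight muscle ratio (FMR) and a lower wing loading
(WL). The package provides everything needed to test this hypothesis on a
species table and a phylogeny: trait computation, load-capacity
prediction, phylogenetic regression, ancestral-state reconstruction, and
seeded simulators to exercise each stage.

## Traits and load capacity

* **FMR** = 0.95 x thorax mass / wet body mass (dimensionless). The 0.95
  factor treats 95% of the thorax as flight muscle. `fmr()` enforces
  0 < M_t < M_b.
* **WL** = wet body mass / total wing area, in g/cm^2 (`wing_loading()`).
* **Load capacity**: maximum liftable total mass is predicted from flight
  muscle mass m = FMR x M_b through an empirical log-log lift regression,
  `log10(M_max) = a + b log10(m)`, with `Load_max = M_max - M_b` and
  `%load = 100 Load_max / M_b`. The coefficients (a, b) come from
  published load-lifting experiments and are **not** bundled: inventing
  them would manufacture ground truth, so `load_capacity()` refuses to
  run without an explicit `lift_params(a, b)` and the pipeline logs the
  stage as skipped. Lift is treated in mass-equivalent grams; converting
  a force in newtons is the caller's responsibility (divide by g).

Wet mass is the canonical body mass throughout: it is the mass that must
be lifted. Dry-mass or head-width columns are carried through the schema
but never silently substituted.

## PGLS with Pagel's lambda

Let V be the Brownian phylogenetic covariance matrix: V[i, j] is the
shared root-to-MRCA path length of species i and j (`phylo_covariance()`,
polytomies handled naturally by path sums). Pagel's lambda multiplies the
off-diagonal entries (`lambda_transform()`): lambda = 0 is phylogenetic
independence, lambda = 1 full Brownian structure. `pgls()` fits

> y = X beta + e, e ~ N(0, sigma^2 V_lambda)

by GLS. Numerical choices, all visible in `gls_fit()`:

* **ML, not REML**, throughout, so coefficient estimates, the lambda
  profile and likelihood-ratio tests all share one likelihood. sigma^2 is
  the ML estimate RSS_V / n; standard errors carry the n/(n - p)
  correction so that at lambda = 0 the fit reproduces `lm()` exactly,
  coefficient tests use Student's t with df = n - p.
* **Lambda is profiled over [0, 1]** by a 0.01-step grid scan followed by
  bounded refinement (`optimize()`, tolerance 1e-8) in the bracketing
  interval; the grid guards against local optima, and the boundary value
  is kept when refinement cannot beat it. No lambda > 1 extension is
  offered; the parameter is defined on [0, 1].
* **LR test of signal**: 2(logL(lambda-hat) - logL(0)) against
  chi-squared with 1 df. The null value lies on the parameter boundary
  only when lambda-hat = 0, in which case the statistic is 0 and p = 1;
  the plain chi-squared reference is used, a deliberate, conventional
  choice.
* **Listwise deletion** per model, with the species used stored in the
  fit; unmatched tip labels are an error, never a silent drop.
* **Heteroscedastic extension** (`var_group =`): the covariance becomes
  sigma^2 S V_lambda S with S diagonal, 1 for the first group level and a
  multiplier estimated jointly with lambda (L-BFGS-B on (lambda, log
  gamma)); an LR test with 1 df compares against the homoscedastic fit.
* Whitening uses the Cholesky factor of V_lambda; V_lambda is positive
  definite for any lambda in [0, 1] because it is a convex combination of
  a PSD matrix and a positive diagonal.
* A Kolmogorov-Smirnov statistic on the normalized residuals is reported
  in `summary()` as an advisory normality diagnostic only.

`pgls_profile()` exposes the profile likelihood so optimality can be
checked externally, and the test suite verifies `gls_fit()` against a
direct numerical maximization of the Gaussian likelihood and against the
`nlme::gls()` + `ape::corPagel()` route.

## Ancestral states under Mk1, and origin counting

The manipulation character is binary; the symmetric one-parameter Markov
model (Mk1) gives switch probability (1 - exp(-2qt))/2 over a branch of
length t. `mk1_loglik()` implements Felsenstein pruning with per-node
rescaling; `fit_q()` maximizes over log q on [1e-8, 1e3] (tolerance 1e-8,
boundary solutions flagged — an all-identical character always sits at
q = 0). `asr_mk1()` computes **marginal** reconstructions by an up-down
pass (equivalent to rerooting at each node), normalizes them to
proportional likelihoods, and applies the conventional 2-log-unit
rule-of-thumb on natural-log differences of the unnormalized marginals:
a node is called for a state only when its marginal likelihood exceeds
the alternative by more than 2 log units, otherwise "ambiguous". The
root prior is uniform (0.5, 0.5), the stationary distribution of the
symmetric model, and is configurable. Joint reconstruction is not
offered; marginal is what the proportional-likelihood convention
describes.

`count_origins()` is parsimony, not likelihood: the Fitch algorithm with
Hartigan's generalization at polytomies gives the minimum number of
state changes, and a root-to-tip assignment pass that keeps each node in
its parent's state whenever that state is most parsimonious (delayed
transformation) decomposes the changes into gains (0 to 1) and losses
(1 to 0). The root state defaults to the parsimony root set, with ties
reported and broken in favour of state 0 — consistent with the marginal
ML root call on the bundled data; forcing the other root state is
supported and simply shifts the decomposition.

On the bundled data the reconstruction places state 0 (unable) at the
deepest nodes and finds exactly two independent gains of manipulation
ability — one in the bee clade, one among the social vespids — and no
losses. At the ML rate on the bundled branch lengths the root's marginal
support for state 0 (proportional likelihood 0.61) does not clear the
2-log-unit bar, so the strict root call is "ambiguous" even though the
argmax state is 0; both facts are reported.

## The bundled dataset and tree

`hymeflight_table1()` holds the 28-species trait table (10 bees, 18
wasps; 14 AtM, 14 UtM; FMR missing for one species, WL for four). The
reference phylogeny `hymeflight_tree()` encodes the accepted topology for
these taxa: Vespidae sister to the Apoidea; Sphecidae basal to the other
apoid families; Crabronidae monophyletic; Apidae and Megachilidae
monophyletic sisters; congeners grouped; solitary vespids basal to the
social ones. True divergence times for this exact taxon set are not
available, so branch lengths are assigned by Grafen's method (node height
proportional to descendant tips minus one, root height 1;
`grafen_lengths()`), giving an ultrametric depth-1 tree. Consequences,
stated plainly:

* The FMR analyses are insensitive to this choice because the estimated
  lambda is at the zero boundary (the covariance collapses to a diagonal).
* The WL and WL-FMR covariation models do depend on branch lengths;
  their estimated lambdas (about 0.40 and 0.55 here) and exact
  coefficients would shift under another clock. The package treats their
  **signs and significance** as the robust product, and the pipeline can
  take any user-supplied Newick tree in their place.

## Synthetic data: what it emulates, what it does not

The generators (`simulate_tree()`, `simulate_traits()`,
`simulate_binary()`, `make_table1_like()`) are pure functions of their
seed; identical seeds give byte-identical output.

* Trees are pure-birth (Yule), rescaled to depth 1. Real trees have
  extinction and rate variation; none of that is modelled.
* `simulate_traits()` draws log10 body mass uniformly on [-2.1, -0.07]
  (about 0.008-0.85 g, the span of the bundled table), assigns a binary
  group either to two monophyletic clades (mirroring two evolutionary
  origins; the default) or at random, and adds multivariate-normal noise
  with covariance sigma^2 V_lambda via its Cholesky factor — the one
  stochastic primitive needing a matrix factorization. Defaults: lambda
  0.7 and coefficients (group 0.148, mass 0.278) at the wing-loading
  scale of the reference analysis, residual sd 0.1 on the log10 scale.
* `make_table1_like()` adds the dataset-specific texture: 28 species,
  AtM clades of about 10 and 4 tips (the smaller one labelled
  prey-feeding so wasp-only subsets keep both groups), FMR = 0.407 -
  0.06 x AtM + N(0, 0.035^2) iid — iid because FMR shows essentially no
  phylogenetic signal — and log10 WL = -0.45 + 0.394 log10 M_b +
  N(0, 0.158^2), the noise chosen so the allometric r^2 averages about
  0.68 given the uniform mass spread; one AtM species lacks FMR and four
  species (two per group) lack WL, mirroring the bundled table's
  missingness. Raw thorax masses and wing areas are back-computed so the
  schema validator's consistency checks pass exactly.

Passing tests on these data therefore demonstrate correctness of the
estimators under the stated generating model, not robustness to
measurement error, intraspecific variation, or tree misspecification —
none of which the generator produces.

## Problem sizes and tolerances used in the test suite

Brute-force oracles (exhaustive state enumeration, path-sum covariances,
direct likelihood maximization) run on trees of up to 12 tips; estimator
operating characteristics use 200 replicate datasets on 100-tip trees
for lambda and group-effect recovery, 100 replicates on 200-tip trees
for the Mk1 rate (median within a factor 1.6 of truth), and 40-replicate
batches for boundary-detection and heteroscedasticity power properties.
These sizes give stable Monte-Carlo summaries while keeping the full
suite under a couple of minutes of compute. Optimizer tolerances are
1e-8 throughout; exact identities (OLS equivalence, mass budgets,
transition-row sums) are asserted at 1e-10 or tighter.

## Known limitations

* The lift-regression coefficients are external input; without them the
  load-capacity stage only validates its own algebra.
* Lambda-dependent coefficients on the bundled tree are approximations,
  as discussed above.
* No independent-contrasts, Ornstein-Uhlenbeck, multivariate-response or
  asymmetric-rate (Mk2) models; no stochastic character mapping; no
  sequence-based tree inference. The tree is an input, not an estimate.
* The chi-squared reference for the lambda LR test ignores the boundary
  at lambda = 0, which makes that test mildly conservative there.
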