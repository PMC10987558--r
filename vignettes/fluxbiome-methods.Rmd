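---
title: "From genus tables to metabolite fluxes: methods and design choices"
author: "fluxbiome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From genus tables to metabolite fluxes: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxbiome)
```

## What the package computes

`fluxbiome` carries a genus-level 16S abundance table through three stages:

1. **Dysbiosis statistics** — alpha diversity (Shannon, richness),
   Bray–Curtis dissimilarity with PERMANOVA and PCoA, per-genus Wilcoxon
   tests with a permutation-based FDR, cross-compartment Spearman
   correlations, and shared-genus compartmentalization summaries for paired
   oral/faecal designs.
2. **Community flux balance analysis (FBA)** — for every individual, the
   genera above 1 % relative abundance with available metabolic
   reconstructions are merged into one abundance-weighted community model;
   parsimonious FBA yields a per-sample profile of net exchange
   (boundary) fluxes per extracellular metabolite, and a group comparison
   turns these into a per-metabolite *bioavailability index* (log2 fold
   change with Wilcoxon p and permutation FDR q).
3. **Discrimination** — a stepwise-AIC logistic classifier of disease
   status on the flux profiles, with ROC/AUC, a frozen-parameter external
   validation on an independent cohort, per-cohort mean-centering batch
   correction, and t-SNE embeddings for visualization.

A first-class synthetic-data module generates every input with planted
ground truth, which is how the whole chain is validated.

## The community model

Each taxon is described by a stoichiometric reconstruction: metabolites
tagged `internal` or `extracellular`, reactions with bounds and an
objective (a growth proxy), and exchange reactions that move one
extracellular metabolite across the boundary. Flux balance analysis solves

$$\max_v \; c^\top v \quad \text{s.t.} \quad S v = 0,\; lb \le v \le ub,$$

with fluxes in arbitrary units. For a community, member models are merged:

* every member metabolite and reaction is namespaced `taxon__id`;
* extracellular metabolites with the same id become one shared pool;
* each member's exchange reactions become *transfer* reactions between its
  own boundary node and the pool, keeping the member's bounds;
* one community exchange reaction per pooled metabolite connects the pool
  to the environment with medium bounds, `(-10, 1000)` by default;
* all member bounds and objective coefficients are scaled by the member's
  renormalized relative abundance $\hat w_t$, and the recorded *coverage*
  is the unrenormalized sum — the fraction of the sample's community the
  model explains.

Weight-scaling the bounds is what gives the algebra the package tests
against: a single taxon at weight 1 reproduces its solo optimum exactly
(provided the medium is no tighter than the member's own exchange bounds),
and non-interacting taxa contribute boundary fluxes additively,
weight-for-weight. Multiplying all abundances by a constant changes
nothing, because only renormalized weights enter the model.

### Degeneracy and determinism

FBA optima are routinely degenerate: many flux vectors attain the same
objective. Profiles must nevertheless be reproducible, so after the primary
solve the package minimizes total absolute flux at the fixed optimum (a
parsimonious step, implemented by splitting reversible fluxes into positive
and negative parts). Both linear programs are solved by the package's own
bounded-variable two-phase simplex with Bland's rule — deterministic and
cycle-free — and every optimal solution is checked against
$\lVert S v \rVert_\infty \le 10^{-6}$ and its bounds before it is
returned. Because all bounds are finite, no model is ever unbounded.
Reported fluxes follow the secretion-positive convention: positive means
net release into the environment.

### The bioavailability index

Per metabolite, per-individual community exchange fluxes are summarized per
group (mean by default, median by option). Because a ratio across a sign
change is meaningless, the fold change is computed on magnitudes with a
pseudo-flux $\varepsilon$ (default $10^{-6}$),

$$\log_2\mathrm{FC} = \log_2 \frac{|\bar v_{\text{case}}| + \varepsilon}
{|\bar v_{\text{control}}| + \varepsilon},$$

and a separate **switch flag** marks metabolites whose group summaries have
opposite signs (production in one group, consumption in the other).
Significance combines a two-sided Wilcoxon rank-sum p on the
per-individual fluxes with a permutation-FDR q; the default filter is
p < 0.05 **and** q < 0.1.

## Statistical components

**Wilcoxon tests** use the exact rank-sum distribution when the combined n
is at most 20 and the feature has no ties, otherwise the normal
approximation with tie and continuity corrections (matching
`stats::wilcox.test`).

**Permutation FDR.** For observed p-values $p_g$ and $B$ label
permutations, the estimate at threshold $p_g$ is the median across
permutations of the null count $\#\{p^{(b)} \le p_g\}$ divided by the
observed count $\#\{p \le p_g\}$, clipped to $[0,1]$ and monotonized so q
never decreases in p. This plug-in estimator is deliberately simple and
slightly conservative under the global null (verified by simulation in the
test suite: mean discovery fraction at q < 0.1 stays below 0.1).

**PERMANOVA** computes Anderson's pseudo-F from total and within-group sums
of squared Bray–Curtis distances and permutes labels freely (no strata);
$p = (1 + \#\{F^{(b)} \ge F_{\text{obs}}\})/(1 + B)$, so p can never be
exactly 0 and a seed is mandatory. On six-sample designs the permutation
null can be enumerated exhaustively and the test suite checks exact
agreement. Null calibration (rejection at $\alpha = 0.05$ within
[0.03, 0.07] over 500 exchangeable-label replicates) is asserted as well.

**PCoA** eigen-decomposes the double-centered $-D^2/2$ matrix; axes with
negative eigenvalues are reported by magnitude but never returned as
coordinates. A Cailliez correction is available behind a flag and off by
default.

**Shannon diversity** is reported in nats (natural log, the vegan
default); divide by `log(2)` for bits. Richness counts genera with nonzero
abundance; Shannon ≤ ln(richness) always, with equality exactly for a
uniform composition.

## The classifier

Features (metabolite fluxes) are z-scored; the standardization record is
frozen into the model. Selection starts from the intercept-only model and
proceeds bidirectionally, accepting at each step the single addition or
removal that most decreases AIC ($2k - 2\ell$), stopping when no move
improves it; the accepted-step AIC trace is strictly decreasing by
construction and kept in the result. Wald p-values of the selected
coefficients are reported without any post-selection adjustment — they are
descriptive, as the selection itself invalidates their nominal levels.
External validation never refits anything: training standardization,
coefficients and the training-chosen Youden-J threshold are applied as
frozen constants to the new cohort. Batch correction is per-feature,
per-cohort mean-centering; after it each cohort's feature means are zero to
within $10^{-12}$.

Two properties of stepwise-AIC worth stating plainly:

* With a **single** uninformative candidate, the null model is retained
  with probability $P(\chi^2_1 < 2) \approx 0.84$ — the AIC entry guard.
  With $k$ independent candidates that probability decays like $0.84^k$,
  so with many features greedy AIC selection **will** admit noise; this is
  a known anticonservatism of the procedure, not a defect of the
  implementation, and it is why the per-candidate guard is what the
  simulations quantify.
* At small sample sizes a few strong features can separate the training
  data completely, after which the likelihood saturates and remaining
  informative features can no longer improve AIC. The recovery simulations
  therefore use 40 cases and 40 controls with three informative features
  (per-feature standardized shift 1, joint AUC ≈ 0.9, chosen from that
  closed form, not fitted) among 17 noise features; recovery of the full
  planted set then exceeds 80 %. At 20 + 20 the saturation effect
  dominates at every effect size we examined, which is a real limitation
  of stepwise selection worth knowing before applying it to cohorts of
  that size.

## The synthetic-data generator

Counts are Dirichlet-multinomial: per-sample genus proportions are drawn
from a Dirichlet with concentration $\theta \cdot \pi$ around the group
mean $\pi$, then counts from a multinomial at a Poisson read depth. Base
mean proportions follow a geometric rank-abundance curve (a few dominant
genera, a long tail), which is the qualitative shape of genus-level 16S
tables. Planted effects multiply the mean proportion of chosen genera
before renormalization, so realized fold changes are attenuated by
compositional closure — the generator documents this rather than hiding
it, and recovery checks always compare against the planted *direction*.
Defaults: 20 samples per group, 40 genera, $\theta = 50$, depth $10^4$.
The flux-recovery studies use $\theta = 500$ (tight replication) so that a
2× planted shift on a 2–4 % genus is a ~2-sd effect at n = 20/20 —
a power calculation made from the Dirichlet variance formula, not from
test outcomes.

Paired oral/faecal cohorts share subjects; the fraction of the genus
universe resident in both compartments is controlled exactly (every genus
stays resident in at least one compartment), and requested
cross-compartment correlations are induced by scaling both genera's means
with a shared per-subject log-normal latent factor (reciprocal for
negative signs). Genera carrying a requested correlation are forced into
the shared-resident set.

Toy reconstructions couple each taxon's signature metabolite
stoichiometrically to its growth objective, so the optimal signature flux
is proportional to the taxon's community weight — that is what makes
planted abundance shifts imply known bioavailability shifts. Uptake
capacities are drawn in (4, 9), strictly below the default medium cap of
10, so that merging never tightens a member's own bounds and the
identity-merge property holds exactly. The generator solves every model it
emits and fails loudly on any infeasibility.

Validation cohorts re-use the training truth's planted signal under a
fresh seed and tilt all genus means by $\exp(\text{shift}\cdot\delta_g)$
with a fixed random unit direction $\delta$ — a coherent cohort-level
batch effect that propagates into the fluxes and that mean-centering
largely removes.

What the generator does **not** emulate: sequencing error, chimeras,
taxonomic misclassification, genuinely sparse zero-inflation beyond the
multinomial, realistic genome-scale reconstructions (thousands of
reactions), or diet-dependent media. Passing recovery tests therefore
demonstrates that the chain is implemented correctly and is well calibrated
under its stated model — not that the same effect sizes are detectable in
real cohorts.

## Numerical choices

* LP solver: dense bounded-variable two-phase simplex, Bland's rule,
  pivot tolerance $10^{-9}$; artificials are kept at fixed zero in phase 2
  so redundant steady-state rows are harmless. Solutions violating
  $\lVert Sv\rVert_\infty \le 10^{-6}$ raise an error rather than being
  returned.
* Seeds are mandatory everywhere randomness occurs; a master seed is split
  into named substreams per stage, so stages are independently
  reproducible and rerunning a pipeline with the same configuration is
  bit-identical for every deterministic output (the provenance file holds
  the only timestamps).
* Degenerate inputs fail fast with named context: all-zero samples,
  lb > ub, exchange reactions touching two metabolites, missing seeds,
  missing selected features at validation.
* Problem sizes in the shipped tests and acceptance script (cohorts of
  20–40 per group, 30-genus tables, 10-taxon libraries, 50–200
  permutations/replicates) were chosen so the whole suite completes in a
  few minutes while keeping every Monte-Carlo margin comfortable.

## Known limitations

* The bioavailability index inherits compositional closure: planting a 2×
  increase on several genera at once attenuates each realized fold change
  (the package reports ~0.6 log2 units instead of 1.0 in that regime).
  Sign and significance are unaffected; magnitudes should be read
  comparatively, not absolutely.
* Community models assume a shared well-mixed extracellular pool, no
  growth-rate coupling between members, and an open default medium; none
  of these is a statement about any particular real microbiome.
* Stepwise-AIC logistic selection is anticonservative with many candidate
  features and unstable near complete separation (see above); the package
  flags separation and reports the step trace so users can see what
  happened.
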