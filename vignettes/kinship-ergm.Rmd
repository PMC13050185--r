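---
title: "Modelling drivers of IBD kinship networks with dyad-independent ERGMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling drivers of IBD kinship networks with dyad-independent ERGMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinergm)
```

## The problem

Ancient-DNA studies increasingly produce *relatedness networks*: graphs in
which nodes are individuals (often from one or a few cemeteries) and edges
indicate that a pair shares enough identical-by-descent (IBD) genome to be
considered biological kin. The scientific questions are about the drivers of
the network's topology — are individuals buried at the same site, in the same
period, of the same sex or age class, or with similar grave goods more likely
to be related? — and about the *size* of those effects, not only their
existence.

`kinergm` treats this as a regression problem on dyads. It builds the network
by thresholding pairwise IBD sharing, expresses hypotheses as homophily and
mixing terms over node attributes, fits the resulting model by maximum
likelihood, selects among competing models with information criteria, and
provides the simulation machinery (confusion-matrix, power and
minimum-detectable-effect experiments) needed to know when such analyses are
reliable at archaeogenetic sample sizes.

## From IBD sharing to a network

For each unordered pair $(i,j)$ a connectedness measure $e_{ij} \ge 0$ is
observed — here, IBD sharing summaries. The adjacency is a hard threshold:
$Y_{ij} = 1$ iff $e_{ij} \ge c$, with the boundary inclusive. Two rule forms
are supported:

* a **scalar rule** on any numeric summary (typically total shared cM), and
* the **two-block rule** used for ancient-cemetery data: at least two IBD
  blocks of length $\ge 12$ cM *and* at least one block $\ge 16$ cM,
  corresponding to roughly seventh-degree or closer relatedness.

Pairs absent from the input are coded $e_{ij} = 0$ — *no sharing*, not
missing data. This matters: in a dyad regression the non-edges are
observations, so individuals with no qualifying partner stay in the network
as isolates, and the observed graph is treated as a noisy subsample of the
complete kinship network. Raising $c$ can only remove edges (monotonicity),
which the test suite checks as a property.

## The model

Conditional on node attributes, dyads are independent Bernoulli draws with a
logistic link:

$$\log\frac{p_{ij}}{1-p_{ij}} \;=\; \theta_0 \;+\; \sum_k \theta_k\, z_{ijk}
\;+\; \sum_\ell \lambda_\ell\, w_{ij\ell},$$

where the $z_{ijk}$ are indicator statistics built from the endpoints'
attributes and the $w_{ij\ell}$ are optional raw dyad covariates. This is
the dyad-independent subfamily of exponential-family random graph models.
Restricting to dyad independence is deliberate: it keeps the likelihood
exact and cheap for networks with tens of thousands of dyads, and it avoids
the degeneracy problems dyad-dependent terms (triangles, stars) are prone to
in sparse graphs. The trade-off is that transitivity ("my relatives'
relatives are my relatives") is not modelled; what the package estimates are
marginal attribute effects.

Three attribute-term shapes cover the hypotheses of interest for a
categorical attribute with $m$ levels:

| term | statistic | parameters |
|---|---|---|
| `term_nodematch` | $I(v_i = v_j)$ | 1 |
| `term_nodematch_diff` | $I(v_i = v_j = a)$ per level $a$ | $m$ |
| `term_nodemix` | one indicator per unordered level pair, minus a reference cell | up to $\binom{m}{2} + m - 1$ |

Simple match says sharing *any* level raises connection odds uniformly;
differential match lets the homophily strength differ by level (one
cemetery may be a single pedigree, another several); mixing additionally
allows *between*-level effects (two nearby sites may be connected to each
other more than to a third). The three are nested in expressiveness, which
is exactly why model selection is needed.

Conventions chosen where the design was open:

* **Reference cell for `nodemix`**: the lexicographically smallest unordered
  level pair, so designs are deterministic; it can be overridden (e.g. to
  make Adult F/Adult M the baseline, the natural choice when studying
  residence patterns).
* **Composite attributes** such as sex-by-age are built explicitly with
  `combine_attributes()`; nothing is crossed implicitly.
* **Missing attribute values** are a hard error by default, with
  `on_missing = "drop"` available to remove all dyads touching incomplete
  nodes. Dropping silently would bias the estimated density, so it is never
  the default.
* Column names follow `<kind>.<attribute>.<level(s)>` so fitted objects and
  exported tables are diffable.

## Estimation and inference

`fit_dyad_ergm()` maximises the Bernoulli likelihood by iteratively
reweighted least squares with step-halving (the log-likelihood is never
allowed to decrease). Convergence requires a gradient sup-norm below
$10^{-8}$ within 100 iterations. Before iterating, dyads with identical
design rows are pooled into binomial rows; this leaves the likelihood,
estimates and observed information untouched while making the per-iteration
cost independent of the dyad count — it is why the simulation experiments
below run in seconds. Standard errors come from the inverse observed
information, and p-values are two-sided Wald tests. No multiple-testing
correction is applied to the reported p-values; tables flag
non-significant rows instead, and users comparing many coefficients should
bear this in mind.

Two numerical edge cases are handled explicitly. *Rank-deficient designs*
(collinear columns) are rejected up front with the offending column names.
*Perfect separation* — a covariate cell whose dyads are all connected or all
unconnected — sends a coefficient to $\pm\infty$; estimates with
$|\hat\theta| > 15$ are flagged `separated`, reported with infinite standard
error and no p-value, and the remaining coefficients stay valid.

Effect sizes are reported as the **fold-increase in connection
probability**, $\mathrm{plogis}(\theta_0+\theta)/\mathrm{plogis}(\theta_0)$,
evaluated at the fitted baseline. In sparse networks this is close to the
odds ratio $e^\theta$ (both are emitted), but the probability ratio is the
quantity with a direct interpretation — "same-site pairs are 500× more
likely to be kin". At the simulation baseline $\theta_0 = -4$ used
throughout, coefficients of 0.25, 0.30 and 0.35 correspond to folds of
1.2775, 1.3414 and 1.4085.

## Model selection

Candidates are compared on the *same* dyad set by information criteria with
the observation count $N$ set to the number of dyads $n(n-1)/2$ — the
natural sample size here, since every potential edge is an observation:

$$\mathrm{BIC} = -2\ell + k\ln N, \qquad
  \mathrm{AIC} = -2\ell + 2k, \qquad
  \mathrm{AICc} = \mathrm{AIC} + \tfrac{2k(k+1)}{N-k-1}.$$

BIC is the default: with $N$ in the tens of thousands and $k$ in the teens,
its $\ln N$ penalty is what keeps the richer mixing models from winning on
noise. In this regime AICc is numerically indistinguishable from AIC. Ties
are broken toward the smaller model, then candidate order. A backward
elimination strategy (`criterion = "pvalue"`; iteratively drop the term
whose worst Wald p-value exceeds $\alpha$) is provided as the comparison
baseline; it is a reconstruction of the common practice BIC is meant to
replace, not a recommended procedure.

`confusion_experiment()` quantifies selection accuracy: simulate networks
from each model in a family, select on every realisation, tally truth
against selection. The default family spans the three term shapes over a
binary attribute (equal groups) and a three-level attribute (equal thirds):
edges-only, + sexmatch, + sitematch, + sitediff, + sitemix, and the two
sex+site combinations — seven models. The default truth coefficients are
$\theta_0 = -4$, 0.75 for simple match terms, and deliberately *distinct*
per-level values for differential match (0.5, 1.0, 1.5) and mixing (0.3,
0.6, 0.75, 1.0, 1.5). Equal per-level coefficients would make the
differential model observationally identical to the simple match model, and
no selection procedure can (or should) distinguish observationally
equivalent models — with distinct values each class is identifiable, and at
$n = 300$ nodes BIC assigns every realisation to its generating model.

## Power, sizing and sensitivity

`empirical_power()` estimates the probability of detecting a match effect:
simulate, refit the generating model, count Wald rejections at $\alpha$.
The fitted model is the data-generating one — the question asked is about
coefficient significance, not selection-then-testing. Degenerate replicates
(empty or complete graphs) are counted as non-rejections, which is the
conservative choice. At the canonical design ($n = 300$, equal groups,
$\theta_0 = -4$) the test is calibrated (5% rejections at zero effect) and
saturates by $\theta_1 = 0.35$; an unequal 25/75 split loses a little power
at small effects because the mismatched-dyad count shrinks.

`expected_edges()` computes $\sum_{i<j} p_{ij}$ exactly by grouping dyads
over endpoint attribute profiles (so it costs $O(\text{profiles}^2)$, not
$O(n^2)$), and `nodes_for_expected_edges()` inverts it by integer search.
Expected edge count — not node count — is the quantity that governs power,
so `min_detectable_effect()` works on a grid of expected edges: size the
network at the zero-effect baseline, then bisect the coefficient (to a
resolution of 0.01) for the smallest value reaching the target power. The
minimal detectable fold falls as networks grow: below 1.5-fold already at
500 expected edges, and approaching ~1.07-fold by 10,000.

`cutoff_sensitivity()` re-runs thresholding plus selection under a list of
rules and reports which variables stay significant — the standard check that
conclusions do not hinge on the exact cM cutoff. Rules yielding an empty
graph are flagged degenerate and excluded from the stability summary.

## The synthetic cemetery fixture

`make_avar_fixture()` generates a reproducible 237-individual cohort across
four sites (HNJ, KFJ, KUP, RK; 25/21/14/40%) with sex (50/50), age class
(70/30 adult/subadult), their composite, and burial orientation (60/40),
plus pairwise IBD summaries consistent with the simulated edges. Its
generating model — strong differential site homophily (baseline
$\theta_0 = -7.5$; within-site folds from roughly 200× at RK to 700× at
KFJ), sex/age mixing with adult-male homophily and an adult-female deficit
(0.26× to 12.8× across cells), and a 2.86× orientation-match effect — is
shaped like the published estimates for an Avar-period cohort, and the
generating coefficients are returned so parameter recovery can be asserted.
Background (non-kin) pairs receive sub-threshold sharing (< 12 cM totals, no
qualifying blocks) so thresholding and cutoff-sensitivity analyses exercise
the full path.

What the fixture does *not* emulate: genotype-level noise in IBD calling,
missingness correlated with preservation, pedigree-induced transitivity
(edges are sampled independently given attributes), or spatial/temporal
autocorrelation beyond the categorical attributes. Passing tests on the
fixture therefore demonstrate that the estimation and selection machinery is
correct under the model's own assumptions — not that the model is adequate
for any particular excavation.

## Problem sizes used in the checks

The packaged tests run the confusion study at 20 replicates per model
($n = 300$), calibration at 1000 replicates, power points at 100–200
replicates, the 500-edge and 10,000-edge minimum-detectable-effect searches
at 100 replicates per bisection step, and fixture parameter recovery over 50
draws. These sizes give Monte-Carlo errors comfortably inside the asserted
tolerances (e.g. ±1.4% on the calibration check) while keeping the whole
suite under two minutes; all experiment functions accept larger `reps` for
tighter estimates.

## Worked example

```{r example, eval = FALSE}
library(kinergm)

fx <- make_avar_fixture(seed = 1)
net <- threshold_network(fx$pairs, fx$nodes, two_block_rule())

candidates <- list(
  null        = model_spec(term_edges()),
  site        = model_spec(term_nodematch("site")),
  sitediff    = model_spec(term_nodematch_diff("site")),
  full        = fx$spec
)
sel <- select_model(net, candidates, criterion = "BIC")
summary_table(sel)

louvain_communities(net, use_weights = TRUE, seed = 1)$n_communities
```

## Known limitations

* Dyad-dependent structure (transitivity, degree heterogeneity beyond
  attributes) is out of scope by design; coefficients are marginal effects
  under independence.
* Separation is flagged, not resolved; penalised likelihoods are not
  implemented.
* Calibration of the IBD cutoff to a relatedness degree is not implemented;
  the two-block default encodes the conventional choice, and
  `cutoff_sensitivity()` is the tool for assessing its influence.
* Raw Wald p-values are reported without multiplicity correction, matching
  standard reporting for this model class.
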