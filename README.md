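# kinergm

Dyad-independent exponential-family random graph models (ERGMs) for
networks of biological kinship built from identity-by-descent (IBD)
sharing.

## What problem this solves

Archaeogenetic studies now routinely estimate pairwise IBD between dozens
or hundreds of ancient individuals, and summarise it as a *kinship
network*: an edge links two individuals who share enough IBD to be
biological kin. The interesting questions are about what drives that
network's topology — burial site, time period, sex, age class, funerary
customs, grave goods — and about the *magnitude* of each driver, with all
the others held fixed. `kinergm` answers both with a regression model on
dyads, aimed at population geneticists and archaeogeneticists who have
pairwise IBD calls plus per-individual metadata.

## The model

The network is formed by thresholding a pairwise connectedness measure
`e_ij` (IBD sharing): `Y_ij = 1` iff `e_ij >= c`, boundary inclusive. The
packaged two-block rule (≥ 2 blocks ≥ 12 cM and ≥ 1 block ≥ 16 cM) encodes
the convention for roughly seventh-degree-or-closer relatedness.

Conditional on node attributes, dyads are modelled as independent
Bernoulli draws with a logistic link:

    log( p_ij / (1 - p_ij) ) = θ0 + Σ_k θk z_ijk + Σ_l λl w_ijl

with indicator statistics `z_ijk` built from the endpoints' attributes:
simple homophily (`nodematch`, one parameter), differential homophily
(`nodematch_diff`, one per level), and attribute mixing (`nodemix`, one
per unordered level pair minus a reference cell). This dyad-independent
subfamily of ERGMs has an exact, fast likelihood and none of the
degeneracy of triangle/star terms in sparse graphs. Fitting is by IRLS
with step-halving; competing models are compared by BIC (with the dyad
count as sample size); effects are reported as fold-increases in
connection probability, `plogis(θ0 + θ) / plogis(θ0)`. Simulation
machinery — confusion-matrix, empirical-power, and
minimum-detectable-effect experiments — quantifies when such analyses are
reliable at archaeogenetic sample sizes.

## Worked example

The package ships a generator for a synthetic 237-individual,
four-cemetery cohort with site-structured kinship, patrilocal-style
sex/age mixing and an orientation effect, together with pairwise IBD
summaries (`make_avar_fixture()`; everything about it is synthetic):

```r
library(kinergm)

fx  <- make_avar_fixture(seed = 1)
net <- threshold_network(fx$pairs, fx$nodes, two_block_rule())
net
#> Kinship network: 237 nodes, 3871 edges (density 0.1384)
#> Attributes: site, sex, age, orientation, sexage

candidates <- list(
  null     = model_spec(term_edges()),
  site     = model_spec(term_nodematch("site")),
  sitediff = model_spec(term_nodematch_diff("site")),
  full     = fx$spec   # sitediff + sex/age nodemix + orientation match
)
select_model(net, candidates, criterion = "BIC")
#> Model selection by BIC
#>     model  k    logLik      BIC      AIC     AICc failed
#>      null  1 -11244.61 22499.46 22491.22 22491.22  FALSE
#>      site  2  -5999.18 12018.84 12002.37 12002.37  FALSE
#>  sitediff  5  -5800.85 11652.89 11611.69 11611.70  FALSE
#>      full 15  -4672.46  9498.49  9374.91  9374.93  FALSE
#> Chosen: full
```

BIC prefers the full model: differential site homophily plus sex/age
mixing plus orientation match. Its coefficient report (folds are
probability ratios against the baseline cell at the fitted intercept;
`ns` marks rows not significant at 0.05):

```r
summary_table(select_model(net, candidates))
#>   Variable              Level   Fold     P Type Significant
#> 1     site                HNJ 501.35 <1e-4 Diff
#> 2     site                KFJ 740.05 <1e-4 Diff
#> 3     site                KUP 738.27 <1e-4 Diff
#> 4     site                 RK 216.17 <1e-4 Diff
#> 5   sexage    Adult.F/Adult.F   0.25 <1e-4  Mix
#> 6   sexage Adult.F/Subadult.F   0.93 0.428  Mix          ns
#> 7   sexage Adult.F/Subadult.M   1.07 0.442  Mix          ns
#> 8   sexage    Adult.M/Adult.M   6.46 <1e-4  Mix
#> ...
```

Read: two individuals from the same site are hundreds of times more
likely to be kin than a cross-site pair (RK markedly less inter-related
than the others); relative to an adult-female/adult-male pair, two adult
males are ~6.5× *more* likely to be related and two adult females ~4×
*less* — the mixing signature of patrilocality with female exogamy. The
recovered folds match the fixture's generating values.

Community structure on the IBD-weighted graph:

```r
louvain_communities(net, use_weights = TRUE, seed = 1)
#> communities: 4, modularity: 0.662
```

Power planning uses the same machinery, e.g.
`empirical_power(seq(0, 1, 0.05), n = 300)` for a power curve, and
`min_detectable_effect(500)` for the smallest detectable fold at a given
expected network size.

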