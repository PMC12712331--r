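# cetempo

Numerical tools for the **covariant evolutionary tempo** model of
macroevolution: a birth–death process in which a single per-species
"tempo" variable multiplies *all* evolutionary rates — speciation,
extinction, and molecular change — and itself evolves by a self-scaled
Ornstein–Uhlenbeck diffusion. The package is aimed at researchers in
macroevolution and phylogenetic methods who want to explore how coupled
rate variation reshapes clade-size distributions, diversification curves,
ancestral-rate reconstructions and molecular branch lengths, without
committing to any particular empirical clade.

## The model

Each species carries a log-tempo $x = \log\tau$ evolving as

$$dx = -\theta e^{x} x\,dt + \sqrt{2\theta s^{2} e^{x}}\,dW,$$

and speciates/goes extinct at rates $e^{x}\lambda$ and $e^{x}\mu$; the
factor $e^{x}$ appears everywhere because tempo rescales time itself.
The clade-size probability generating function
$G_x(t,z)=\sum_n P_n(t,x)z^n$ obeys

$$\frac{\partial G_x}{\partial t} = e^{x}\Big((\lambda G_x-\mu)(G_x-1)
  -\theta x \frac{\partial G_x}{\partial x}
  +\theta s^{2}\frac{\partial^{2} G_x}{\partial x^{2}}\Big),
  \qquad G_x(0,z)=z,$$

from which the package derives, by linearisation, adjoints, Fourier
inversion and Bayes' rule:

* clade-size distributions and sister-group imbalance (`invert_gf()`,
  `sister_imbalance()`);
* expected species and lineage numbers through time (`mean_species()`,
  `second_moment()`, `experienced_size()`, `diversification_curves()`);
* the replicator–mutation dynamics and equilibrium of the tempo
  distribution (`evolve_tempo_density()`, `equilibrium_density()`);
* posterior historical tempos of ancestors and clade members
  (`ancestor_posterior()`, `historical_member_posterior()`,
  `tempo_trajectory()`);
* branch-duration and molecular branch-length densities
  (`branch_duration_density()`, `molecular_change_density()`);
* an exact-event Monte Carlo simulator producing annotated Newick trees
  (`simulate_clade()`, `simulate_ensemble()`, `tree_to_newick()`), used
  throughout the test suite as an independent oracle for the PDE solvers.

All user-facing functions take tidy inputs and return tibbles (with
`tidy()`/`glance()`/`autoplot()` methods), so results drop straight into
dplyr/ggplot2 pipelines. A thin command-line wrapper ships at
`inst/cli/cetempo`.

## A worked example

Reference parameters ($\lambda=0.51$, $\mu=0.5$ per species per myr,
$\theta=0.01$/myr, $s=1$) over 500 myr:

```r
library(cetempo)
params <- cet_params()        # lambda 0.51, mu 0.5, theta 0.01, s 1
grid   <- log_tempo_grid()    # x in [-10, 10], 201 nodes

# clade-size distribution of surviving clades
d <- invert_gf(500, 0, params, grid, M = 4096, dt = 0.5, conditional = TRUE)
sum(d$p[d$n < 1000])
#> [1] 0.3163173

# equilibrium tempo distribution and its mean
eq <- equilibrium_density(params, grid)
attr(eq, "mean"); attr(eq, "sd")
#> [1] -1.053897e-15
#> [1] 0.8330416

# expected log-tempo of the 300-myr-old ancestor of a random living species
post <- ancestor_posterior(300, 500, params, grid, prior = eq)
attr(post, "mean")
#> [1] 0.5464404
```

Read: about 32% of surviving clades stay below 1000 species even after
500 myr, the biota-wide tempo distribution equilibrates with mean
log-tempo 0 (a direct consequence of choosing $\theta = r$), and the
lineage leading to a typical modern species ran, 300 myr ago, at about
$e^{0.55}\approx 1.7$ times the baseline rate — the model's signature
"elevated ancestral tempo".

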