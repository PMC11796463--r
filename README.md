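# spmig — spatially explicit Bayesian estimation of recent seed and pollen migration rates

Plants exchange genes between populations through two distinct vectors:
seeds (whole zygotes) and pollen (single male gametes). Their rates, spatial
scales and environmental drivers differ, and both matter for the
connectivity, inbreeding and adaptive potential of fragmented populations.
`spmig` estimates *recent* (last-generation) migration for both vectors
jointly, from one temporal sample of multilocus codominant genotypes taken
across a set of discrete populations, and tests — separately for seed and
pollen — whether migration declines with geographic distance.

It is intended for population geneticists and conservation ecologists with
SSR or SNP genotypes from spatially structured plant (or plant-like, e.g.
sessile marine invertebrate) systems.

## The model

For individual $i$ sampled in population $s_i$, a latent origin pair
$o_i=(j,k)$ encodes a maternal seed source $j$ (probability
$\alpha_{s_i j}$) and a paternal pollen source $k$ (probability
$\beta_{jk}$). The genotype likelihood marginalizes over origins,

$$\Pr(G_i) \;=\; \sum_{j=1}^{K}\sum_{k=1}^{K} \alpha_{s_i j}\,\beta_{jk}
\prod_{l=1}^{L} \Pr_{jk}(G_{il}\mid p_l, F_i, \varepsilon_l),$$

where the single-locus term accounts for population allele frequencies
$p$ (an F-model correlated around ancestral frequencies $q$ with
population-specific divergence $F_{ST_j}$), individual inbreeding $F_i$
(identical-by-descent alleles must share a source), and per-locus allelic
dropout $\varepsilon_l$. Rows of $\alpha$ and $\beta$ carry Dirichlet priors
whose means encode isolation by distance through a competing-sources
weight $\rho_{ij} \propto e^{-b\log(1+d_{ij})}$; a reversible-jump MCMC
move selects between $b \equiv 0$ and $b$ free, per channel, and
$\Pr(b>0)$ is reported as the visit fraction of the distance model. The
same $b$ implies a fat-tailed migration-distance kernel
$f(d) \propto d\,(1+d)^{-b}$, truncated at `d_max`.

See the methods vignette (`vignettes/migration-model.Rmd`) for the full
prior structure, sampler design, numerical choices, and validation.

## Worked example

Simulate a nine-population system spanning 0.84–19.64 km (the packaged
`yew_layout()`), with strong divergence, no distance effect on seed
migration and a strong effect on pollen migration, then fit the model:

```r
library(spmig)
ly  <- yew_layout()
cfg <- scenario_config(K = 9, N = 270, assay = "SSR", mu_fst = 0.2,
                       b_seed = 0, b_pollen = 2.1274, layout = ly)
sim <- simulate_scenario(cfg, seed = 7)
fit <- spmig(sim$data, layout = ly,
             control = spmig_control(cycles = 3000, burnin = 1000, thin = 2,
                                     estimate_F = FALSE,
                                     estimate_dropout = FALSE),
             seed = 42)
print(fit)
#> Spatially explicit seed/pollen migration model
#> ...
#> spmig_trace: 1000 retained samples (3000 cycles, 1000 burn-in, thin 2)
#>   9 populations, 270 individuals, 20 loci
#> Pr(b_seed > 0) = 0.037, Pr(b_pollen > 0) = 1.000
```

The reversible jump gives the pollen distance effect posterior probability
1.000 and the (absent) seed effect only 0.037. Point estimates recover the
simulated parameters:

```r
cf <- coef(fit)
round(cf$b_pollen, 2)                    # 2.58  (simulated: 2.13)
round(kernel_median(cf$b_pollen, 20), 1) # 3.1 km median pollen migration
round(rbind(truth = sim$truth$alpha[1, ], estimate = cf$alpha[1, ]), 3)
#>              1     2     3     4     5    6     7     8     9
#> truth    0.976 0.000 0.001 0.002 0.001 0.00 0.000 0.020 0.001
#> estimate 0.902 0.013 0.009 0.010 0.010 0.01 0.009 0.028 0.010
```

`summary(fit)` adds SEs and 95% HPD intervals for every parameter;
`predict(fit, type = "maternal")` gives each individual's posterior origin
assignment; `write_summaries(fit, "out/")` writes the result tables. Real
data enter via `read_genotypes()` (a documented CSV layout;
`read_structure()` imports STRUCTURE files) plus `read_distances()` or
`read_coords()`. A command-line front-end with `simulate`, `estimate`,
`evaluate` and `summarize` subcommands is installed at `exec/spmig`; the
default estimation protocol is 10,000 burn-in cycles plus 20,000 sampling
cycles thinned to every 10th (2,000 retained samples).

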