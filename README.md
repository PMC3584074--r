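# bpnm: probabilistic niche models for bipartite ecological networks

Ecological interaction networks — plant–pollinator mutualisms, host–parasite
and plant–herbivore antagonisms — are binary bipartite graphs: `S_C`
consumers, `S_R` resources, and `L` observed links. `bpnm` asks how much of
that structure a one-dimensional niche explains. It fits the **bipartite
probabilistic niche model (BPNM)**, in which every resource has a position
`n_j` on a latent niche axis and every consumer a center `c_i` and width
`r_i`, with interaction probability

    p_ij = p_max * exp( - ( |n_j - c_i| / (r_i/2) )^g )

(`g = 2` is a Gaussian niche; `g`, `p_max` are community-wide). Parameters
are estimated by maximum likelihood over the Bernoulli cell likelihood
using simulated annealing (ordination-based starts, domain-wide and
collective affine moves, optional deterministic polish), and the BPNM is
compared against a constant-probability random model and a probabilistic
bipartite cascade model by AICc.

On top of the fits the package computes the structural metrics used to
judge whether a model reproduces *network structure* even where it fails at
*individual links*: consumer nestedness (NODF over columns, with
equal-degree pairs excluded from the average), the continuous niche-interval
overlap of fitted consumer ranges, three connectance estimators, the
expected fraction of observed links predicted (`f_L`), the
specialist-to-generalist ordering (Spearman correlation of degree vs fitted
width), and the dispersion of niche centers that separates clumped
("antagonistic-like") from uniform ("mutualistic-like") communities. A
seeded simulator draws network ensembles from any probability matrix, and a
synthetic generator produces networks with known ground truth so every
stage is testable without external data.

Intended users: ecologists modeling interaction-network structure and
methodologists studying link-prediction models on bipartite graphs.

## Worked example

```r
library(bpnm)

# a 12x12 niche-structured network with known ground truth
gen <- generate_synthetic_network(synthetic_spec(S_C = 12, S_R = 12), seed = 42)
net <- gen$network
print(net)
#> bipartite_network: 12 resources x 12 consumers, 31 links (connectance 0.215)

# fit all three models and rank by AICc
tab <- compare_models(net, config = anneal_config(seed = 7))
print(tab)
#>   model_kind       logL  k     aicc aicc_ratio_vs_bpnm
#> 1       bpnm  -4.796576 38 113.8217          1.0000000
#> 2     random -75.004688  1 152.0375          0.7486422
#> 3    cascade -47.471471 24 153.0270          0.7438017

# structural metrics for the niche-model fit
fit <- attr(tab, "fits")$bpnm
rep <- metrics_report(net, fit, ensemble_size = 100, seed = 7)
round(unlist(rep), 3)
#>               nodf_c         n_pairs_used      connectance_emp
#>               22.642               53.000                0.215
#>            overlap_r     connectance_prob        nodf_sim_mean
#>               29.457                0.217               25.063
#> connectance_sim_mean                  f_L    degree_r_spearman
#>                0.218                0.956                0.745
#>                 c_sd
#>                0.006
```

Reading the numbers: the niche model has the lowest AICc (the
`aicc_ratio_vs_bpnm` column shows each competitor's score relative to it).
The model reproduces structure closely — empirical consumer NODF 22.6
against a simulated-ensemble mean of 25.1, empirical connectance 0.215
against 0.217 (analytic) and 0.218 (ensemble) — while `f_L = 0.956` says
the fitted probabilities concentrate 95.6% of their link mass on the
observed links, and the degree-vs-width rank correlation 0.745 shows the
fitted widths recover the specialist-to-generalist ordering. When fitted
*parameters* are to be interpreted (rather than compared by AICc), fit with
`fix_g = 2` and `polish = TRUE`; see the methods vignette
(`vignettes/bpnm-methods.Rmd`) for why a free `g` overfits small networks.

Networks are read and written as labeled adjacency CSV (header row of
consumer labels, leading column of resource labels, 0/1 cells) or as
two-column tab-separated edge lists (`resource<TAB>consumer`, `#` comments)
via `read_network()` / `write_network()`; parameter sets round-trip through
JSON via `write_params()` / `read_params()`.

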