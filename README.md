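# hyperchron

Tools for characterizing **higher-order evolving networks** (temporal
hypergraphs): timestamped records of group interactions such as
face-to-face contacts among sets of people or multi-author collaborations.
The package answers three questions about such data, for whoever studies
interaction dynamics — network scientists, computational social
scientists, epidemiology modellers:

1. **Are events close in time also close in topology?** The topological
   distance between events $e_1 = (h_1, t)$ and $e_2 = (h_2, s)$ is 0 if
   $h_1 = h_2$ and otherwise
   $\eta(e_1, e_2) = \min_{u \in h_1,\, v \in h_2} \delta(u, v) + 1$,
   with $\delta$ the hop count on the unweighted pairwise aggregated graph
   $G$. The conditional curve
   $\mu_d(\Delta t) = \mathbb{E}[\eta \mid \mathcal{T} < \Delta t] /
   \mathbb{E}[\eta]$ (over pairs of an order-$d$ event and an event of any
   other order; $\nu_d$ for same-order pairs) rises with $\Delta t$ when
   temporally close events are topologically close, and its slope $m$ per
   decade of $\Delta t$ quantifies the correlation.
2. **Do nodes participate consistently across orders?** Per-node
   $d$-degree $k_d(v)$ and $d$-strength $s_d(v)$, their cross-order
   relation curves, and the linear law $s_d(v) \approx \omega_d\, k_d(v)$
   with $\omega_d$ the mean activations per order-$d$ hyperlink.
3. **Do local events cluster in time?** Egonetworks of order-$d$
   hyperlinks, their aggregated activity series, and the size distribution
   of center-active event trains (runs of events with inter-event times
   $\le \Delta t$).

Each statistic is read against three order-targeted null models that
randomize only order-$d$ events while preserving the aggregated
hypergraph: **H1** reshuffles timestamps, **H2** swaps whole activity
series between order-$d$ hyperlinks, **H3** swaps series only between
equal-weight hyperlinks. Seeded generators (`generate_coupled()`,
`generate_uncorrelated()`, `generate_contact_sequence()`) provide positive
and negative controls with planted ground truth.

Everything is tidyverse-shaped: networks are lists of tibbles, every
analysis returns a tibble, fitted slopes have `tidy()`/`glance()` methods,
and each result type has an `autoplot()`.

## Worked example

```r
library(hyperchron)

net <- generate_coupled(seed = 1)   # planted temporal-topological coupling
net
#> <temporal_hypergraph>
#>   nodes:      300
#>   hyperlinks: 592
#>   events:     1424
#>   horizon:    5000 steps of 1 s
#>   orders:     d=2 (532 links, 1124 events), d=3 (60 links, 300 events)

G  <- aggregate_pairwise(net)
cv <- distance_curve(net, d = 3, G = G)        # cross-order, exact estimator
fit_increasing_slope(cv)
#> <hg_slope_fit> m = 0.01034 per decade (r2 = 0.296, grid points 4..45)

h1 <- randomize_h1(net, d = 3, seed = 2)       # timestamp-reshuffle null
fit_increasing_slope(distance_curve(h1, 3, G = G))
#> <hg_slope_fit> m = 0.002175 per decade (r2 = 0.345, grid points 8..45)

mean_train_size(train_size_distribution(net, 3, delta_t = 60))
#> [1] 2.479167
mean_train_size(train_size_distribution(h1, 3, delta_t = 60))
#> [1] 1.775801
```

The observed network shows a positive distance–delay slope (events within
a short delay sit at roughly 1 hop from each other, pulling the normalized
curve below 1 before it returns to 1 at large delays) and center-active
trains half again as large as under the timestamp-reshuffle null — the two
signatures the planted coupling should produce. On the null realization
the slope collapses towards 0.

Reading real data:

```r
net <- read_contact_list("contacts.tij", dt = 20)   # "t i j" lines
net <- restrict_to_lcc(net)$network
net <- remove_inactivity_gaps(net)$network          # drop nights/weekends
hoi <- promote_cliques(net)                         # cliques -> group events
order_census(hoi)
```

A command-line front end over the same functions lives at
`inst/cli/hyperchron.R` (subcommands `convert`, `preprocess`, `promote`,
`complete-missing`, `census`, `distance-curve`, `nullmodel`, `degrees`,
`trains`, `synth`, `characterize`).

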