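# sprachbund

Bayesian inference of *language contact areas* — groups of geographically
proximate languages that share categorical traits beyond what universal
tendencies and family inheritance explain — from a languages x features
table of categorical data plus map locations.

## The problem and the model

When languages are similar, three processes may be responsible: a state can
be **universally preferred** (most languages have it), **inherited** inside a
language family, or spread by **contact** between neighbours. Naive
clustering happily groups languages that are similar for *any* of these
reasons. This package implements a mixture model that explains every
observed cell `X[l, f]` (language `l`, feature `f`) as a draw from

```
P(X[l, f] = s) = w_u[f] * alpha[f, s]            (universal preference)
               + w_i[f] * beta[family(l), f, s]  (inheritance)
               + w_c[f] * gamma[area(l), f, s]   (contact)
```

with per-feature weights `(w_u, w_i, w_c)` on the probability simplex,
renormalized per language (no family: inheritance drops; in no area: contact
drops). The contact areas `Z_1, ..., Z_K` are latent disjoint subsets of
languages, inferred jointly with all probability vectors by
Metropolis–Hastings sampling. A geographic prior keeps areas spatially
coherent: each area's log-prior is `-lambda` times the mean edge cost of the
minimum spanning tree over its members' locations. The number of areas is
chosen by scanning `K` and comparing the deviance information criterion
(DIC). A latent area is therefore evidence for contact only when its
members' features are mutually similar (low entropy) *and* poorly explained
by the confounders — similarity that inheritance already explains is
attributed to inheritance via the weights, not to contact.

Everything is estimated from the data: which languages form areas, how
strongly each feature loads on each of the three processes, and the
per-group categorical distributions.

## Quick start (R API)

Simulate a data set with one planted 15-member contact area and a 20-member
family among 100 languages, then recover the area:

```r
library(sprachbund)

spec <- scenario_spec(
  n_entities = 100, n_features = 25, n_states = rep(3L, 25),
  families = list(20), areas = list(15),
  weights = rbind(matrix(rep(c(0.25, 0.15, 0.6), each = 20), 20, 3),
                  matrix(1 / 3, 5, 3)),
  conc_alpha = 1, conc_beta = 0.05, conc_gamma = 0.1, seed = 1)
synth <- simulate_dataset(spec)
d <- synth$dataset
print(d)

# cost-based geo-prior: lambda = 2 / (mean nearest-neighbour distance)
cm <- build_cost_matrix(d, metric = "euclidean")
nn <- apply(cm + diag(Inf, nrow(cm)), 1, min)
pr <- prior_spec(d, geo = geo_prior_spec("cost_based", lambda = 2 / mean(nn),
                                         linkage = "mst", cost = cm))

cfg <- sampler_config(n_steps = 300000, n_retained = 1000, seed = 2,
                      anneal_T0 = 5, p_relocate = 0.25)
trace <- run_chain(d, pr, K = 1, config = cfg)
print(trace)

freq <- membership_frequencies(match_area_labels(trace))
planted <- synth$truth$areas[[1]]
range(freq[planted, 1])   # posterior membership of true members
max(freq[-planted, 1])    # ... and of everyone else
```

Output on this machine (the chain takes ~2–3 minutes):

```
<sb_dataset> 100 entities x 25 features (3-3 states, 0 missing cells), 1 families, planar coordinates
<sb_trace> K = 1, 1000 retained samples (300000 steps, burn-in 20%)
  acceptance: area 0.04, weights 0.61, alpha 0.36, beta 0.59, gamma 0.56 
  mean log-likelihood: -2081.695 
[1] 0.994 1.000
[1] 0.002
```

All 15 planted members have posterior membership frequency at least 0.994;
no other language exceeds 0.002.

Real data enter through delimited files: `read_feature_table()` (wide table,
`?` for missing), `read_locations()` (`id, x, y, family`; longitude/latitude
are auto-detected and distances then use great circles), combined by
`sb_dataset()`. `scan_k()` compares candidate numbers of areas by DIC;
`area_summary()`/`write_area_summary()` produce membership tables, ranked
areas, and a GeoJSON of Gabriel-graph edges weighted by posterior frequency
for mapping.

## Quick start (CLI)

The same pipeline is scriptable through YAML configs:

```sh
exec/sprachbund simulate --config sim.yaml   # writes features/locations/truth
exec/sprachbund run      --config run.yaml   # one chain + summaries
exec/sprachbund scan-k   --config scan.yaml  # DIC over a K list
```

A minimal run config:

```yaml
seed: 5
output: out/
data:
  features: features.csv
  locations: locations.csv
model:
  k: 1
priors:
  geo: {type: cost_based, lambda: 40}
  size: {min: 3, max: 50}
mcmc:
  steps: 300000
  retained: 1000
```

Outputs: `samples.tsv` (per-sample log-likelihood/prior/deviance),
`areas.txt` (memberships per retained sample), `summary.json`,
`membership.tsv`, `gabriel_edges.geojson`, `diagnostics.json` (acceptance
rates, effective sample sizes), and a `manifest.json` recording the exact
config and seed.

## Package map

| File | Contents |
| --- | --- |
| `R/dataset.R` | readers/writers, `sb_dataset`, cost matrices, validation |
| `R/likelihood.R` | mixture likelihood and effective weights |
| `R/priors.R` | Dirichlet pseudocounts, geo-prior, size prior |
| `R/sampler.R` | MH operators, incremental caches, `run_chain()` |
| `R/postprocess.R` | DIC, `scan_k()`, label matching, summaries, ESS |
| `R/geometry.R` | Gabriel graph, Delaunay edges |
| `R/simulate.R` | scenario generator and experiment presets |
| `R/config.R` | YAML configs and `cmd_*` entry points |
| `exec/sprachbund` | command-line interface |
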