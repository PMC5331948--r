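# httnet

Simulation and analysis of **horizontal transposon transfer (HTT) networks**.

Transposable element (TE) families cross species boundaries by horizontal
transfer, carried along ecological relationships by viruses and parasites.
If transfer follows ecological links, the structure of the ecological
network should leave a fingerprint in comparative genomics: species close in
the network share more TE families. `httnet` is a toolkit for studying that
fingerprint. It is aimed at researchers in genome evolution and community
ecology who want to explore, by simulation, how network topology shapes TE
sharing — and how much network structure can be recovered from TE content
alone.

The package provides:

* **Network generation** — complete, Erdos–Rényi, scale-free
  (preferential attachment), modular (stochastic block), and bipartite
  topologies, with per-species genome carrying capacities and weighted
  links (`generate_network()`), plus degree-preserving edge-shuffle
  perturbation (`shuffle_edges()`).
* **TE flow simulation** — a discrete-time stochastic model: each TE copy
  duplicates within its genome with probability *u* per iteration (blocked
  at the genome's carrying capacity *C*), attempts horizontal transfer with
  probability *u/ρ* towards a neighbour drawn by edge weight, and is lost
  with probability λ. Runs stop when a target number of successful HTTs has
  accumulated (`run_to_htt_count()`, `run_single_family()`).
* **Beta-diversity analysis** — presence/absence reduction and the Jaccard
  TE beta-diversity matrix, β(i,j) = 1 − |F_i ∩ F_j| / |F_i ∪ F_j|, with
  hierarchical clustering into blocks of species with similar TE content
  (`presence_matrix()`, `beta_matrix()`, `cluster_order()`).
* **Discrimination statistics** — Mantel correlation with permutation
  tests (`mantel_test()`), the edge-shuffle perturbation experiment
  (`shuffle_experiment()`, `htt_count_sensitivity()`), and single-family
  propagation dynamics (`propagation_experiment()`).
* **Network reconstruction** — similarity thresholding
  (`infer_by_threshold()`), mutual-information scores between TE profiles
  (`mutual_information_scores()`), and ABC-style candidate ranking by
  Mantel closeness of simulated beta-matrices (`abc_reconstruct()`).

Everything is reproducible from a single master seed via hierarchical seed
derivation (`derive_seed()`), and a `run_pipeline()` helper plus a thin CLI
(`inst/cli/httnet.R`) tie the stages together with a checksummed run
manifest.

## Worked example

Simulate TE flow on a scale-free network of 20 species and ask how specific
the resulting beta-matrix is to that network:

```r
library(httnet)

net <- generate_network("scale_free", n_species = 20, mean_degree = 4, seed = 1)
net
#> <htt_network> scale_free: 20 species, 37 links (mean degree 3.70, density 0.195)
#>   capacities: 100 copies/genome

res <- run_to_htt_count(net, sim_config(), seed = 1)
res
#> <sim_result> 1121 iterations, 150 successful HTTs, 2000 copies total
```

The run stopped at exactly 150 successful horizontal transfers after 1121
iterations; by then every genome had filled its 100-copy carrying capacity.
Reduce to presence/absence, compute the beta-matrix, and run the
edge-shuffle experiment (10 reference networks, 5 replicate simulations per
perturbation level):

```r
beta <- beta_matrix(presence_matrix(res))

ex <- shuffle_experiment(
  list(topology = "scale_free", n_species = 20, mean_degree = 4),
  sim_config(), shuffle_levels = c(0, 1, 2, 5, 10, 20),
  n_networks = 10, n_reps = 5, seed = 1)
ex
#> <shuffle_experiment> 10 networks x 5 reps, levels {0, 1, 2, 5, 10, 20}
#>  level    mean_r       sd_r  n
#>      0 0.6417126 0.06363076 50
#>      1 0.5752422 0.07966266 50
#>      2 0.5249564 0.09662546 50
#>      5 0.3580467 0.11267499 50
#>     10 0.2534231 0.09543306 50
#>     20 0.1492536 0.09795511 50
```

Read this as: re-simulating on the *unchanged* network gives beta-matrices
that correlate at Mantel r ≈ 0.64 with the reference (the stability
baseline, limited only by simulation stochasticity), and the correlation
decays monotonically — to r ≈ 0.15 after 20 edge shuffles — so the
beta-matrix genuinely fingerprints the wiring, not just the degree sequence
(shuffles preserve degrees). `plot(ex)` draws the mean ± SD curve.

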