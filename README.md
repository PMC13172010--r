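# micronet

Compositional co-occurrence networks, keystone taxa and percolation
robustness for gut microbiome profiles.

## The problem

Shotgun metagenomic profiles are compositional, and host phenotypes such as
metabolically healthy obesity (MHO) may differ less in *which* microbes are
present than in *how* the community is wired. `micronet` compares gut
microbial communities across metabolic-health/obesity phenotypes (MHNO,
MHO, MUNO, MUO) at the network level:

* **Phenotyping** — BioSHaRE-EU-style metabolic-health classification from
  clinical biomarkers (glucose ≤ 100 mg/dL, triglycerides ≤ 150 mg/dL, HDL
  > 40/50 mg/dL by sex, BP ≤ 130/85 mmHg, diagnosis/medication flags
  dominant) crossed with WHO obesity (BMI ≥ 30 kg/m²).
* **Network inference** — the SPIEC-EASI Meinshausen–Bühlmann core:
  prevalence/abundance filtering (> 0.1% in ≥ 10% of samples), centered
  log-ratio transform, per-taxon L1-penalized neighborhood regression, OR
  symmetrization with signed weights, and StARS penalty selection (100
  subsamples of size ⌊10√n⌋, instability threshold β = 0.05).
* **Topology** — global metrics, normalized betweenness/closeness on
  weighted distances d = 1 − w, k-core decomposition, Kruskal–Wallis
  comparison of node-metric distributions with Benjamini–Hochberg
  correction.
* **Keystone taxa** — nodes with degree *and* betweenness above the 90th
  percentile; ensemble presence/absence matrices, core sets, PCA.
* **Robustness** — random and targeted node-removal percolation on the
  positive-edge LCC, with the NR50 statistic (% of nodes removed until the
  LCC halves) and the percolation threshold p_c (steepest decay-curve
  slope, undefined when no phase transition is evident).
* **Ensembles** — repeated group subsampling → filter → infer → profile,
  with distribution summaries and ranking-consistency scores.
* **Synthetic data** — logistic-normal-multinomial generator over known
  sparse precision matrices (band / Erdős–Rényi / scale-free / modular),
  the offline ground truth for all of the above.

See `vignettes/microbiome-network-topology.Rmd` for the full methods
account.

## Worked example

```r
library(micronet)

# a two-group synthetic cohort with known conditional-dependence graphs:
# an evenly wired band community vs a hub-dominated scale-free one
ds <- make_group_dataset(list(
  healthy = synthetic_spec(n_taxa = 30, n_samples = 200, topology = "band",
                           band_width = 2, seed = 1),
  disease = synthetic_spec(n_taxa = 30, n_samples = 200,
                           topology = "scale_free",
                           target_edge_density = 0.12, seed = 2)))

# infer one network per group (filter -> CLR -> MB + StARS)
nets <- lapply(split(seq_len(400), ds$table$metadata$group), function(idx)
  infer_network(abundance_table(ds$table$values[idx, ],
                                metadata = ds$table$metadata[idx, ]),
                n_subsamples = 50, seed = 7))

global_metrics(nets$disease)
#>   order size pct_negative_edges edge_density n_components lcc_order
#> 1    30   28           57.14286   0.06436782           10        19
#>   mean_degree mean_shortest_path mean_betweenness mean_closeness
#> 1    2.736842           2.218394       0.07395941      0.4708822

detect_keystones(extract_lcc(nets$disease))
#> [1] "sp002" "sp003"   # the preferential-attachment hubs of the truth

suite <- run_attack_suite(nets$disease, strategies = c("degree", "random"),
                          n_reps = 200, seed = 1)
c(degree_nr50 = suite$degree$nr50, degree_pc = suite$degree$pc,
  random_nr50 = suite$random$nr50_mean)
#> degree_nr50   degree_pc random_nr50
#>   28.571429   28.571429   51.000000
```

Degree-targeted removal halves the hub-dominated community's largest
connected component after removing only ~29% of nodes, while random
failure needs ~51% — the hub-dependence signature that separates fragile
from robust communities. The recovered keystones are the planted
preferential-attachment hubs. (The high negative-edge share is a small-p
closure artifact of compositional inference; see the vignette.)

## Command line

```sh
Rscript inst/cli/micronet simulate --config cfg.json --out out/
Rscript inst/cli/micronet analyze  --config cfg.json
Rscript inst/cli/micronet attack   --config cfg.json --edge-lists net_MHNO.tsv
```

Subcommands: `simulate`, `classify`, `analyze`, `attack`, `ensemble`,
`paired-compare`. Configs are JSON (YAML when the `yaml` package is
installed); CLI flags override config values; every output carries a
provenance header (package version, config hash, seed).

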