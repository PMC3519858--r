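# ranetkit

Discovering disease-dominant gene sets and disease-perturbed interaction
networks from multiple expression studies.

## What it is for

When a disease such as rheumatoid arthritis is profiled against both
healthy tissue and a comparator disease (osteoarthritis) across several
independent microarray studies, the interesting biology splits into a
*shared* component (perturbed in both diseases) and a *disease-dominant*
component (perturbed predominantly in the primary disease). `ranetkit` is
for computational biologists who want to:

* pool per-study log2 fold-change matrices (normal-median reference,
  strongest-probe gene collapse, cross-study quantile normalization);
* soft-cluster the combined matrix by non-negative matrix factorization
  (NMF) into differential expression patterns (DEPs), `V ≈ WH` with
  multiplicative updates and NNDSVD initialization, gene membership by
  per-cluster z → upper-tail p → Benjamini–Hochberg at adjusted p < 0.05;
* keep only clusters that beat element-permutation null thresholds (the
  "N genes in M samples can show a DEP by chance" calibration) and
  classify them shared vs. dominant from the condition mix of their
  associated samples, yielding the **core** disease-dominant up-regulated
  gene set;
* score gene sets by empirical resampling enrichment, `p = (r+1)/(B+1)`
  against size-matched draws from the universe without replacement, with
  `Z = qnorm(1 − p)` and an exact hypergeometric oracle;
* rebuild the perturbed subnetwork (annotated core genes as seeds, their
  core interactors), assign process modules, and compute the module
  enrichment score for an overlay signature,
  `MES = (overlap/module size) / (network size/core size)`;
* find key transcription factors (target-count resampling, p < 0.01) and
  interaction hubs (first/second-neighbor count resampling, p < 0.01),
  ranked per module with smallest p first.

A synthetic-data generator with planted ground truth
(`simulate_ra_inputs()`) produces every input the pipeline consumes, so
all of the above is testable without any external download.

## Worked example

```r
library(ranetkit)

sim  <- simulate_ra_inputs(seed = 1)              # planted ground truth
comb <- preprocess_studies(sim$studies, sim$probe_to_gene)
comb
#> <combined_fc_matrix> 2000 genes x 30 samples from 3 studies

dep <- discover_deps(comb, n_clusters = 12, seed = 101)
dep
#> <dep_result> k = 12: 24 cluster entries, 4 significant (1u/shar, 1d/shar, 2u/domi, 2d/domi)
#>   135 core dominant-up genes
dep$thresholds
#> <perm_thresholds> 20 permutations, 95th percentile
#>   gene count > 70.0, sample count > 2.1; basis cutoff 0.03651, activation cutoff 27.06
```

Four cluster entries survive the permutation thresholds: a shared up/down
pair (active in both disease arms) and a dominant up/down pair (active in
the primary arm only). The 135 core genes recover the 140 planted
dominant-up genes at sensitivity 0.964 with zero false discoveries here.
Downstream, the perturbed network and module scores:

```r
net     <- reconstruct_perturbed_network(dep$core_genes, sim$annotations, sim$network)
modules <- assign_network_modules(net, sim$annotations)
mes     <- module_score_table(modules, sim$overlays,
                              igraph::vcount(net), length(dep$core_genes))
head(mes[order(-mes$score), ], 3)
#>    module_id overlay_label overlap_count module_size     score
#> 16        MR  cell_like_up            14          16 0.8881579
#> 8         CK  cell_like_up            13          15 0.8796992
#> 3         BC  cell_like_up            12          15 0.8120301
```

The `cell_like_up` overlay (which covers half of each module by
construction) scores high across modules, while the off-network
`blood_like_up` control scores 0 — the contrast the MES is designed to
expose. `identify_key_tfs()` and `test_hub_significance()` then rank
regulator candidates per module, and `run_full_pipeline(pipeline_config(...))`
chains every stage with a checksummed manifest; identical configuration
and seed reproduce all outputs byte for byte.

## Documentation

The methods vignette (`vignettes/disease-network-discovery.Rmd`) describes
the model, the statistical choices (folded signed matrix, NNDSVD
initialization, the joint permutation statistic, the column-relative
sample-association rule), the synthetic study conditions, and the known
limitations.
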