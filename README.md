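# cycleGRN

Recovering cell-cycle gene expression from gene-regulatory-network features
in budding yeast — and from synthetic data with the same statistical
structure.

## The scientific problem

The timing of transcription across the *Saccharomyces cerevisiae* cell
cycle is set by transcription factors (TFs), but the underlying gene
regulatory network (GRN) is only known through imperfect proxies: ChIP-chip
binding, deletion-mutant expression changes, position-weight-matrix scans
and protein-binding microarrays each yield a different TF→target edge list,
and the lists agree far less than one might expect. cycleGRN asks, for users
who work with such edge lists: how concordant are the networks, are
feed-forward loops (FFLs) over-represented in them, how well do network
features predict which genes cycle and in which of the five phases (G1, S,
S/G2, G2/M, M/G1), which TFs and TF–TF interactions carry that signal, and
do candidate FFLs behave like co-regulation kinetically?

The package provides, as plain R functions with S3 model objects at the two
estimator cores:

* **GRN comparison** — overlap coefficient |A∩B|/min(|A|,|B|), per-TF degree
  correlation, interaction uniqueness, and a degree-preserving randomization
  null (each TF redraws its targets uniformly from the pooled target
  universe, keeping its out-degree) with a two-tailed z-test.
* **Motif analysis** — FFL enumeration (primary→secondary, primary→target,
  secondary→target) and the mean-connectivity expectation: with
  λ = interactions / nodes, a random network carries ≈ λ³ FFLs
  (sd √λ³), giving z = (N_obs − λ³)/√λ³.
* **Classification** — `cc_classify()`: a balanced-ensemble linear SVM over
  binary gene × feature matrices (features are TFs or FFL TF-pairs, tagged
  by data set). For each grid cell (C, R), 100 training subsets of all
  positives plus R × n_pos sampled negatives are scored out-of-fold;
  per-gene scores are averaged and summarized as AUC-ROC. Returns a classed
  object with `print`/`summary`/`coef`/`predict` methods.
* **Importance** — `importance_table()` ranks SVM weights;
  `percentile_threshold()` applies the conservative tie rule (|top-X| never
  exceeds ⌊X%·n⌋); `build_importance_grn()` turns top-decile features into
  an annotated TF–TF subnetwork whose connected components are candidate
  modules.
* **FFL dynamics** — `ffl_fit()`: the linear ODE model
  dS/dt = α_S S + β_PS f(t), dT/dt = β_ST S + α_T T + β_PT f(t), solved in
  closed form for sinusoidal/constant forcing, fitted by Gaussian maximum
  likelihood, and filtered by the kinetic acceptance rule (α < 0, β > 0,
  converged, moved from init).
* **Enrichment** — one-sided Fisher exact tests with Benjamini-Hochberg
  correction.
* **Synthetic data** — `synth_config()` + generators for edge-list
  collections with tunable pairwise overlap, planted FFLs, phase labels,
  normalized two-cycle sinusoidal expression, and a planted TF→phase signal,
  so the full chain runs and is testable without external data.
* **Pipeline** — `run_pipeline()` sequences everything from a YAML config
  into an artifact directory with a checksum manifest; stages communicate
  only through serialized TSV/JSON artifacts.

## A worked example

```r
library(cycleGRN)

cfg <- synth_config(n_tfs = 25, n_genes = 450, out_degree_mean = 10,
                    n_datasets = 2, pairwise_overlap_target = 0.3,
                    planted_ffl_count = 10,
                    phase_sizes = c(G1 = 15, S = 12, "S-G2" = 11,
                                    "G2-M" = 12, "M-G1" = 10),
                    tf_phase_effect = 1, noise_sd = 0, seed = 5)
gen <- generate_grn_collection(cfg)
gen$grns[[1]]
#> GRN 'synth01': 255 interactions, 25 TFs, 197 target genes

pairwise_overlap(gen$grns[[1]], gen$grns[[2]])$coefficient
#> [1] 0.3764706

expected_ffl_stats(gen$grns[[1]])
#> FFLs: observed 18, expected 1.84 +/- 1.36 (lambda = 1.226), z = 11.90

labels  <- generate_phase_labels(cfg)
planted <- plant_tf_phase_signal(gen$grns, labels, cfg)
fm      <- build_feature_matrix(planted$grns, genes = names(labels))
fit <- cc_classify(fm, labels, positive_class = "cyclic",
                   config = svm_ensemble_config(c_grid = c(0.1, 1),
                                                r_grid = c(0.5, 1),
                                                n_balanced_sets = 10,
                                                seed = 1))
fit
#> Balanced-ensemble linear SVM ('cyclic'): 287 genes (60 positive), 50 features
#> Best grid cell: C = 0.1, R = 0.5, AUC-ROC = 1.000

head(importance_table(coef(fit))[, c("feature", "weight", "rank", "top10")], 4)
#>         feature    weight rank top10
#> 1 synth01:tf004 0.5552715    1  TRUE
#> 2 synth02:tf004 0.5352715    2  TRUE
#> 3 synth02:tf021 0.5117410    3  TRUE
#> 4 synth01:tf024 0.4867410    4  TRUE
```

Reading the numbers: the two generated edge lists overlap at coefficient
0.38 (target 0.3 plus the deliberately shared planted-FFL edges); the first
network holds 18 FFLs against a random expectation of 1.8, z ≈ 12, i.e. the
planted motif structure is detected as strong over-representation. With the
TF→phase signal planted at full strength and no noise, the ensemble
classifier separates cyclic from non-cyclic genes perfectly (AUC 1.0), and
the top-ranked features are precisely phase-linked TFs (tf004, tf021,
tf024 are among the ten planted regulators), in both data sets'
feature columns.

Running on real data instead: read each edge list with `read_edge_list()`,
labels with `read_phase_labels()`, expression with `read_expression()`, and
either call the module functions directly or point `run_pipeline()`'s
`paths` config block at the files.

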