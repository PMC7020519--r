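---
title: "Recovering cell-cycle expression from regulatory network features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering cell-cycle expression from regulatory network features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cycleGRN)
```

## The problem

In budding yeast, several hundred genes are transcribed in waves tied to the
five classical cell-cycle phases (G1, S, S/G2, G2/M, M/G1). Which
transcription factors (TFs), and which combinations of TFs, time those waves
is still only partly understood, in large part because the gene regulatory
network (GRN) itself is uncertain: in vivo binding assays (ChIP-chip),
deletion-mutant expression profiling, motif scans (position weight matrices)
and in vitro binding assays (protein-binding microarrays) each produce a
different TF→target edge list over the same genome, and those lists overlap
surprisingly little.

cycleGRN implements a complete analysis chain for this question:

1. **GRN comparison.** How concordant are the edge lists? Measured by the
   overlap coefficient (|A∩B| / min(|A|, |B|)), per-TF degree correlation,
   interaction uniqueness across data sets, and a degree-preserving
   randomization null with a two-tailed z-test.
2. **Motif analysis.** Enumeration of feed-forward loops (FFLs): ordered
   triplets (primary TF, secondary TF, target) with edges primary→secondary,
   primary→target, secondary→target. Observed counts are compared to the
   mean-connectivity expectation λ³ (λ = edges / nodes), with sd √λ³.
3. **Classification.** Can presence/absence of TF-target interactions (or of
   FFL membership) predict whether a gene is cyclically expressed, and in
   which phase? A balanced-ensemble linear-SVM protocol answers this with an
   averaged-score AUC-ROC.
4. **Importance.** Linear-SVM feature weights are ranked into importance
   tables; conservative top/bottom percentile subsets define reduced models
   and importance subnetworks whose connected components are candidate
   regulatory modules.
5. **Dynamics.** Candidate FFLs are validated against expression time
   courses by fitting a linear ODE model of transcription and applying a
   kinetic acceptance filter.
6. **Enrichment.** One-sided Fisher exact tests with Benjamini-Hochberg
   correction quantify over-representation of annotated regulators or
   functional terms among important TFs.

A synthetic-data generator reproduces the statistical structure all of this
assumes, so every stage can be exercised and tested end-to-end without
external data.

## The classification protocol

Each gene is a sample; each feature is binary: a TF column is 1 when that TF
targets the gene, an FFL-pair column is 1 when the gene is the target of
that (primary, secondary) pair's FFL. Genes with no feature at all are
excluded. Because only a small minority of the genome is cyclic, training on
the raw class ratio would reward the trivial "never cyclic" answer. The
protocol instead draws `n_balanced_sets` training subsets, each containing
every positive gene plus `round(R × n_pos)` randomly drawn negatives, where
the negative:positive ratio R is itself a tuned hyper-parameter
(R = 1 recovers the classic balanced construction).

Within a subset, genes are scored out-of-fold under `n_folds`-fold
cross-validation; genes outside the subset are scored by the model trained
on the whole subset. No gene is ever scored by a model that saw it in
training — this is asserted by a dedicated leakage test using one-hot gene
identity features, for which a memorizing model is perfect but honest
out-of-fold scores stay near chance. Per-gene scores are averaged across
subsets, and the AUC-ROC of those averaged scores against all genes is the
cell's performance. The grid spans C ∈ {0.01, 0.1, 0.5, 1, 1.5, 2} and
R ∈ {0.25, 0.5, …, 4}; the best cell (ties broken toward smaller C, then
smaller R, preferring the more regularized model) defines the representative
model. Its per-feature weights, averaged over the subsets' full-subset
models, feed the importance analysis. Scores are raw decision values: AUC is
rank-based, so calibration is irrelevant.

The SVM itself is the standard L2-regularized hinge-loss linear classifier
(libsvm via e1071, unscaled inputs so weights refer to the original binary
features, solver tolerance 1e-6 so the primal objective is optimal to about
1e-4). AUC uses the Mann-Whitney formulation with half-credit for ties.
Differences in performance across positive classes and data sources are
assessed with the two-way fixed-effects ANOVA S = C + D + C·D on AUC values
(type-I sums of squares on balanced designs, via `aov`).

## Importance percentiles and subnetworks

Weight ties are common with binary features, so percentile cutoffs are
conservative: the top-X% cutoff is the smallest weight above which X% *or
fewer* of all features lie, and only features strictly above it are kept
(the bottom side is the exact mirror). A tie straddling the cutoff therefore
shrinks the subset rather than inflating it, and |top-X| ≤ ⌊X%·n⌋ holds for
every weight vector — both properties are tested on thousands of tie-heavy
random vectors. The denominator is all features of the model (positive and
negative together).

Top-decile features of the general (cyclic vs non-cyclic) model span the
importance subnetwork: FFL-pair features contribute TF–TF edges, TF-target
features contribute nodes. Edges are annotated with the phases in whose
phase-specific models the same feature is also top-decile. A *module* is a
connected component of the undirected projection — the minimal formalization
of a visually clustered sub-GRN.

## The FFL dynamics model

For a candidate FFL, the secondary TF S and target T are modeled as a linear
chain driven by the primary TF's expression f(t):

$$\frac{dS}{dt} = \alpha_S S + \beta_{P,S}\, f(t), \qquad
  \frac{dT}{dt} = \beta_{S,T}\, S + \alpha_T T + \beta_{P,T}\, f(t)$$

with decay rates α (per minute) and production rates β. Because the system
is linear and first-order, constant or sinusoidal forcing admits an exact
solution by variation of parameters; the solver represents solutions as
finite sums of terms coef·t^k·e^{st} with complex exponents, which also
covers the degenerate cases (zero decay, equal rates) through secular
polynomial terms instead of dividing by zero. Arbitrary forcing falls back
to adaptive numeric integration (deSolve); both paths agree to better than
1e-6 where both apply, which is tested over random parameter draws.

Fitting is Gaussian maximum likelihood with a shared residual sd across the
two traces; profiling the variance reduces this to joint least squares, run
as a single deterministic local search (Nelder-Mead then a BFGS polish) from
one fixed initial vector (α = −0.1, β = 0.1). By default f(t) is a
four-parameter sinusoid least-squares-fitted to the primary trace — the
natural choice in a cyclic-expression context, and the one that keeps the
closed form available; piecewise-linear interpolation of the raw trace is
available via `forcing = "trace"`. Initial expression levels are taken from
the first observed time point.

A fit is **accepted** when the optimizer converged, at least one parameter
moved by more than 1e-6 relative from its initial value, both decay rates
are negative and all production rates are positive. Genuinely co-regulated
triplets simulated from accepted kinetics pass this filter almost always at
low noise, while white-noise triplets pass it markedly less often — the
package's tests require the paired contrast to hold in 10 of 10 seeds, and
acceptance to be monotone non-increasing in noise.

## Enrichment

Enrichment of annotated regulators (or of any gene→term annotation) among
important TFs uses the one-sided (greater) Fisher exact test — the
enrichment direction only, consistent with tables in which depleted cells
simply read p = 1 — with Benjamini-Hochberg step-up correction across
tested terms. Degenerate 2×2 tables with a zero margin (e.g. the whole
universe selected) are reported as p = 1 rather than an error, since no
enrichment is expressible. The TF universe is the feature set of the model
under test, the least-assuming choice. Annotations are flat gene→term
pairs; no ontology-graph propagation is performed.

## What the synthetic generator emulates

`synth_config()` fixes the study conditions; all downstream randomness
derives deterministically from its single seed via per-stage tags.

* **Degrees.** Per-TF out-degrees are geometric (minimum 1) with
  configurable mean — a one-parameter stand-in for the heavy-tailed degree
  spread of real regulatory data, where mean interactions per TF range from
  roughly one hundred to several hundred depending on the assay.
* **Overlap.** Each TF owns a shared "core" target set plus
  dataset-specific random targets. The core fraction is solved numerically
  (including the expected chance intersection of the random remainders) so
  that the expected pairwise overlap coefficient equals the configured
  target; a target below the chance level implied by the degrees is
  reported as unattainable. Monte-Carlo means over replicate generations
  sit within three standard errors of the target.
* **Phases and expression.** Phase clusters of configurable sizes — the
  defaults span the 71–300 gene range typical of yeast phase clusters over
  a 125-minute cycle — with two-period cosine traces peaking at each
  phase's offset (period/5 apart, i.e. 25 minutes), Gaussian noise, and
  min-max normalization to [0, 1]. Peak time is circular: a G1 peak at
  t = 0 reappears at the period boundary, which the tests unwrap before
  rank-correlating peak time with phase order.
* **Recoverable signal.** `plant_tf_phase_signal()` links a few TFs to
  each phase and adds TF→gene edges to in-phase genes with a configurable
  probability boost, creating the TF→phase association the classifier is
  supposed to find. At full effect and zero noise the best-grid AUC is
  essentially 1; with permuted labels it sits at chance.
* **Planted FFLs.** A configurable number of FFL triplets is wired into
  every data set and recorded as ground truth; enumeration recovers each of
  them by construction, which is asserted.

What it deliberately does **not** emulate: promoter sequence, binding-site
locations, assay-specific error structure, correlated noise between data
sets, or expression dynamics that actually follow the planted network
topology (planted FFL members get sinusoidal or constant traces by label,
not ODE-generated ones — ODE validation is exercised on
`simulate_ffl_timecourses()` output, where the truth is known). Passing
tests therefore demonstrate correctness and calibration of the methods
under their own assumptions, not biological fidelity of any particular real
data set.

## Numerical choices and problem sizes

* Randomization nulls default to 1000 permutations; p-values come from the
  normal approximation to the null (a permutation p at 1000 draws would be
  granular), flagged as undefined when the null is degenerate (sd = 0).
* Degree correlations use TFs shared between the two data sets by default;
  the union-with-zeros alternative (available via `mode = "union"`)
  inflates |r| and is therefore not the default.
* Grid cells whose R requests more negatives than exist are skipped with a
  warning; sampling is always without replacement.
* The test suite and the reproduction script run the ensemble protocol at
  reduced size — 20 balanced sets, worlds of a few hundred genes and a few
  dozen TFs, a reduced grid for the 20-fold permutation null — sizes chosen
  so the whole suite completes in minutes while leaving every Monte-Carlo
  band (3 standard errors; ±0.08 around chance AUC) comfortably resolvable.
* The exhaustive Fisher calibration covers every 2×2 table with N ≤ 30
  against explicit combinatorial tail sums.

## Known limitations

* The ODE acceptance filter tests kinetic plausibility, not causality;
  strongly autocorrelated noise can pass it, which is why the random-triplet
  contrast is reported alongside.
* The closed-form ODE path switches to numeric integration within 1e-8 of
  a resonance to avoid catastrophic cancellation; objective values are
  continuous across the switch only to the solver tolerance.
* Importance is a property of the fitted linear model, not of biology:
  correlated features share weight, and per-dataset tags deliberately keep
  the same TF's evidence from different assays as separate features.
* With `n_datasets = 1` the cross-dataset statistics (overlap, uniqueness)
  are undefined and the corresponding functions refuse to run, by design.
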