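---
title: "Cross-dataset co-expression meta-analysis: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-dataset co-expression meta-analysis: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`coexmeta` turns several phenotype-grouped expression matrices into
cross-dataset co-expression clusters with significance estimates,
annotation, and between-cluster similarity measures. This vignette is the
package's own account of the statistics it implements, the parameters
that matter, and the design decisions taken where more than one
reasonable choice existed.

## 1. The meta-analytic edge weight

Pearson correlation is computed per dataset for every unordered gene
pair. Absolute values are used for ranking because with tens of millions
of pairs, ranking *signed* correlations would hand high rank ratios even
to barely-positive pairs; ranking on `|r|` reserves the top of the scale
for strong co-expression of either sign (sign consistency is enforced
later by the pruning step, not by the ranking). Ties receive average
ranks, the standard convention.

For a pair with sorted rank ratios `r_1 <= ... <= r_n` across the `n`
datasets of a phenotype, the edge weight is the joint cumulative
probability that the order statistics of `n` independent Uniform(0,1)
draws fall below those ratios coordinate-wise:

$$P(r_1,\dots,r_n) = n!\int_0^{r_1}\!\!\int_{s_1}^{r_2}\!\!\cdots\!\!\int_{s_{n-1}}^{r_n} ds_n \cdots ds_1 .$$

Two conventions deserve a note:

* **Chained lower limits.** The inner integrals run from the previous
  integration variable (`s_1`, `s_2`, ...), not from the fixed `r_1`;
  only with chained limits is the expression the joint CDF of uniform
  order statistics it is meant to be.
* **Sorted arguments.** The integral is defined for ordered arguments,
  so `joint_cdf()` sorts its input ascending before evaluating.

Evaluation is exact: starting from the constant integrand 1, each
integral is applied symbolically to the polynomial coefficient vector
(antiderivative, evaluate at the upper limit, subtract the antiderivative
in the next variable). For `n <= 10` the coefficients stay tiny and
well-conditioned. The unit tests pin the closed forms `P(r) = r`,
`P(0.5, 0.5) = 0.25` and the hand-integrated `P(0.2, 0.5, 0.9) = 0.290`,
and cross-check 50 random inputs against a Monte-Carlo oracle.

**Pruning** retains a pair only when its *signed* correlation is strictly
greater than +0.50 in every dataset of the phenotype (`prune_pairs()`,
threshold configurable). This removes sign-conflicting pairs and weak
pairs in one rule; the boundary is exclusive because a pair *at* the
threshold is trimmed.

## 2. Consensus clustering and cluster significance

Networks are partitioned by the map equation (Infomap, via
`igraph::cluster_infomap`), which is stochastic; we therefore wrap it in
iterative consensus clustering: `runs_per_iter` partitions (default 500;
seeds derived as `master_seed + i` so runs are reproducible and
enumerable), a consensus matrix of co-assignment frequencies, entries
below `tau` (default 0.5) zeroed, and the thresholded matrix re-clustered
as a weighted graph until all partitions of an iteration agree. The
iteration count is surfaced because it is informative: an easy network
converges in one pass, noisier ones take two or three.

Significance uses two complementary null-model tests:

* **Node inclusion** (`node_inclusion_cleanup`): under the configuration
  model, a node of degree `k_v` reaches the cluster's stubs
  hypergeometrically; members whose tail probability of their observed
  internal degree exceeds `alpha_node` (default 0.05) are dropped. The
  pass is applied twice (drop, then re-test the pruned cluster), which in
  practice removes the occasional singly-attached hanger-on without
  eroding genuine modules.
* **Cluster score** (`cluster_significance`): the observed internal edge
  weight is compared with `n_null` degree-preserving rewirings of the
  whole network, edge weights shuffled with the edges. The p-value uses
  the `+1` correction, `p = (1 + #{null >= obs}) / (n_null + 1)`, so it
  is never zero and its resolution is explicit (`n_null = 199` gives a
  floor of 0.005; values below 99 are refused as too coarse).

One behaviour worth knowing: if a cluster *is* essentially the whole
connected network, the rewiring conserves total weight and the node test
sees nearly all stubs inside the cluster — such a "cluster" is correctly
judged non-significant. A meaningful analysis therefore needs a network
with more than one community, which real pruned co-expression networks
(and the synthetic defaults) have.

Retention is deliberately disjunctive: a cluster is kept only if it has
at least `min_size = 10` members **and** `p < 0.05`; failing either rule
excludes it. This is the reading consistent with result sets whose
smallest retained cluster has 11 nodes while all retained p-values are
below 0.05.

## 3. Enrichment

GO enrichment is restricted to the biological-process namespace,
annotations up-propagated by the true-path rule, and each term tested
with the one-sided Fisher exact test (the hypergeometric upper tail).
Two algorithms are provided: `classic` (independent tests) and `elim`
(default), which processes terms deepest-first (term id ascending within
a level for determinism) and, whenever a term scores below
`elim_alpha = 0.01`, removes its annotated cluster genes from all
ancestors before they are tested — so a parent is not dragged to
significance by one strong child. `elim` was chosen as the canonical
hierarchy-decorrelation method matching the "shares annotations between
parent and child" behaviour the analysis calls for; the variant and its
alpha are surfaced in the configuration.

Reported terms must satisfy `p < 0.05` and annotate at least 5 cluster
genes; no multiple-testing correction is applied, matching the raw-p
filter convention of the analysis this package operationalises. The
background universe defaults to the common-gene set (not the network's
nodes), because that is the universe from which clusters were drawn;
it is configurable. Pathway enrichment is the same test without a
hierarchy.

## 4. Cluster similarity

*Physical* similarity is the hypergeometric upper tail of the membership
overlap, tested for LA-versus-HA pairs only (clusters within one
partition are disjoint by construction). The universe defaults to the
common-gene set, consistent with the enrichment background.

*Functional* similarity compares the enriched GO term sets of two
clusters: pairwise Wang similarity (semantic contributions decay by 0.8
per `is_a` and 0.6 per `part_of` edge along the ancestor closure)
combined by best-match averaging. Because a BMA value has no analytic
null, significance is empirical: `N = 10,000` draws of two random term
sets from the pool of annotated BP terms, sizes drawn uniformly from the
observed enriched-set sizes, give `sim_RAND`; then
`p = #{sim_RAND > sim_CLUS} / N` with a *strict* inequality, so ties do
not count against significance. `sample_null()` precomputes the pairwise
similarity matrix over the term pool once, which makes the 10,000
repetitions cheap. Under its own null this p-value is uniform to within
Kolmogorov–Smirnov noise, which the acceptance suite verifies at 1,000
replicates.

## 5. The synthetic-data generator

`generate_datasets()` emulates the study shape the pipeline targets:
three datasets per phenotype group — one sequencing-style count dataset,
two array-style intensity datasets — with 29 + 29 samples by default, and
planted co-expression modules. Member genes of a module share a
per-sample latent factor:

* **Intensity:** `x = baseline + sd * (sqrt(rho) * L + sqrt(1 - rho) * e)`
  gives pairwise correlation exactly `rho` in expectation (verified to
  within 0.05 over 20 replicates in the tests).
* **Counts:** `mu = exp(b + beta * L)` with negative-binomial noise
  (dispersion 0.1) and `beta = sqrt(rho / (1 - rho) * (1/mu_0 + phi))` —
  a delta-method calibration that makes the post-log-CPM correlation
  approximately `rho`, slightly conservative at high `rho`, and monotone
  in `rho` (tested).

Phenotype-specific modules simply omit the latent factor outside their
phenotype. Each dataset consumes its own RNG stream (`seed + index`), so
adding a dataset never perturbs previously generated ones.

What the generator does **not** emulate: read-level sequencing noise,
probe effects, batch structure, and — importantly — realistic library
composition. With a small synthetic gene universe, a large planted
module is a noticeable fraction of each library, and CPM normalisation
then subtracts part of the module's own signal, attenuating
count-platform correlations below their target (at a 7,000-gene scale
the effect is negligible). Passing tests therefore demonstrate correct
mechanics and calibration of the method, not performance on any real
dataset.

The `log_cpm()` transform is the stated formula
`log2((count + prior) / (lib + 2 * prior) * 1e6)` with `prior = 0.5`;
voom-style precision weights are deliberately not reproduced, because
every downstream consumer is an unweighted per-gene Pearson correlation.
Probe collapse keeps the largest-variance probe per gene (unbiased
variance; ties broken by smallest probe id — both conventions chosen
here and documented, since either is defensible).

## 6. Problem sizes and determinism

The test and acceptance workloads run at deliberately desk-friendly
sizes chosen as representative for the mechanics under test: 300-gene
universes with three 30-gene modules at `rho = 0.85` and 20 + 20 samples
for pipeline recovery (100 partitions per consensus iteration), 199
rewirings for cluster p-values, 2,000-draw nulls for the similarity
calibration, and a 10^6-draw Monte-Carlo oracle for the joint CDF. Every
stochastic step takes an explicit seed, and an identical configuration
reproduces byte-identical outputs; the per-phenotype master seeds are
offset so LA and HA runs are independent streams.

## 7. Known limitations

* The joint CDF treats datasets as independent evidence; overlapping
  populations or shared samples would overstate edge weights.
* Only two-level (non-overlapping) partitions are produced; no
  hierarchical or overlapping community structure.
* The configuration-model node test and rewiring score are one concrete,
  testable instantiation of "significance against degree-preserving
  nulls"; other instantiations (e.g. score distributions over subgraph
  orders) would give numerically different p-values.
* Cluster counts and p-values on real data depend on annotation-database
  versions and are not reproduced by this package's fixtures.
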