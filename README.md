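# hmmbiclust

Bayesian biclustering of expression matrices with a hidden Markov prior on
biologically ordered features.

## The problem

In heterogeneous expression compendia (tumour collections, large cohorts),
genes that matter for a subgroup of samples are typically over- or
underexpressed only in that subgroup. `hmmbiclust` addresses this with an
interpretable model-based biclustering: samples are partitioned into `K`
clusters, and *within every cluster* each feature is latently classified as
**overexpressed**, **underexpressed** or **irrelevant** — so a fit defines
`3K` biclusters with a direct biological reading. Because genes can be
pre-ordered by functional similarity (e.g. Gene Ontology semantic
similarity), the prior on the per-cluster feature-state sequence is a
first-order hidden Markov chain along that ordering: neighbouring genes are
encouraged to share states, borrowing strength across functionally close
genes.

## The model

For sample *i* in cluster *z<sub>i</sub> = k* and feature *j* in state
*ρ<sub>jk</sub> = l*:

> y<sub>ij</sub> = μ<sub>jkl</sub> + ε<sub>ijkl</sub>,  ε<sub>ijkl</sub> ~ N(0, σ²<sub>jkl</sub>)

with hierarchical priors μ<sub>jk1</sub> ~ N(μ<sub>k1</sub>, σ²<sub>k1</sub>)
(μ<sub>k1</sub> > t), μ<sub>jk2</sub> ~ N(μ<sub>k2</sub>, σ²<sub>k2</sub>)
(μ<sub>k2</sub> < −t), μ<sub>jk3</sub> ≡ 0; Dirichlet priors on the cluster
probabilities Ω and on the rows of the state-transition matrix ξ;
inverse-gamma priors on all variances; and a truncated-normal prior on the
cluster-mean magnitudes. All full conditionals are conjugate and the model
is fitted by Gibbs sampling (compiled sampler, bit-reproducible given a
seed). The number of clusters is chosen by a DIC scan; recovered biclusters
are scored against a reference with a symmetrized best-match F1. Four
variants are available: with/without the Markov prior (`hmm`) and
with/without the sign constraint on cluster means (`constraint`).

## Worked example

```r
library(hmmbiclust)
sim <- simulate_expression(n = 100, K = 2, p = 1000, sigma2 = 1, seed = 1)
fit <- hmm_biclust(sim$Y, K = 2, n_iter = 2000, burn_in = 1000, seed = 2)
summary(fit)
f1_biclusters(biclusters(fit), truth_biclusters(sim$truth))
```

```
Bayesian HMM biclustering fit (HMMBi-C)
  100 samples x 1000 features, K = 2 clusters
  2000 iterations (1000 burn-in, thin 1): 1000 retained draws
  MAP draw 835, complete-data log-likelihood -142386.98
  MAP cluster sizes: 51, 49 

MAP cluster composition (feature states and cluster means):
 cluster size mu_over mu_under over under irrelevant
       1   51   1.488   -1.484  100   100        800
       2   49   0.962   -1.045  100   100        800

DIC (K = 2): 284458.23  [mean-deviance 569023.23 + MAP term -284565.00]

F1 vs truth: 0.989999
```

The simulated data has two balanced sample clusters whose first 100
features are overexpressed (true means 1.5 and 1) and next 100
underexpressed (−1.5 and −1), the rest irrelevant. The fit recovers the
50/50 partition (one sample misassigned), classifies exactly 100/100/800
features per cluster, and the estimated cluster means sit next to the
generating values; the symmetrized F1 of 0.99 says the six estimated
rectangles nearly coincide with the six true ones. `dic_scan(Y, 1:6)`
reproduces the elbow logic used to pick `K`, and `plot(fit)` shows the
log-likelihood trace with the MAP draw marked.

Other entry points: `standardize_features()` and `order_features()`
prepare a real matrix (per-feature standardization; greedy seriation from a
precomputed gene–gene similarity matrix), `read_expression()` /
`write_expression()` handle the TSV/CSV layout, `predict()` classifies new
samples, and `inst/cli/hmmbiclust.R` exposes
`simulate / fit / summarize / dic-scan / evaluate / order` subcommands for
shell pipelines.

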