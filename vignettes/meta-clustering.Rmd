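---
title: "Meta-clustering across expression datasets: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-clustering across expression datasets: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Unsupervised patient subtypes discovered in one expression cohort often fail
to reappear in the next. The usual remedy -- concatenating cohorts after
batch correction -- has two costs: batch correction can smooth away real
biology along with platform noise, and a single concatenated clustering says
nothing about how consistently each cohort supports each subtype.

crossclust takes the opposite route. Every dataset is normalized and
clustered *on its own*; subtypes are then defined as communities of
statistically similar clusters across datasets. A subtype that survives this
procedure is, by construction, replicable: it is supported by independently
produced clusters from at least three different cohorts, with no
between-dataset transformation at any point.

# The procedure

## Step 1 -- cluster each dataset independently

Each dataset (genes x samples, log scale) is clustered by consensus k-means:
`n_resamples` times (default 100), 90 % of samples are drawn without
replacement and partitioned by Hartigan--Wong k-means with a single random
start; the consensus matrix records, for every sample pair, the fraction of
co-draws in which the pair co-clustered. The proportion of ambiguous
clustering (PAC) is the fraction of off-diagonal consensus entries strictly
inside an ambiguity band (default 0.1--0.9). `select_k()` computes PAC for
each candidate `k` (default 2--6), rounds it to two decimals, and keeps the
smallest `k` attaining the minimum. Rounding before the argmin deliberately
coarsens the comparison: PAC differences below 0.005 are noise at these
sample sizes, and the tie then goes to the more parsimonious model. Final
labels cut an average-linkage dendrogram of `1 - consensus` at the chosen
`k`. With `allow_k1 = TRUE` a dataset whose rounded PAC at `k = 2` exceeds
0.5 is declared single-cluster, since collections can legitimately contain
one-subtype cohorts.

Pre-computed labels (e.g. centroid-classified subtypes) can be supplied as
`clustering()` objects, bypassing this step entirely.

## Step 2 -- bidirectional cluster similarity

For an ordered pair (reference dataset, query dataset), the reference
contributes per-cluster centroids (arithmetic means over its samples,
restricted to the genes the two datasets share; at least 10 shared genes are
required). Every query sample is assigned to the centroid with which it has
the highest Pearson correlation; ties break toward the lowest centroid
index. For each query cluster this yields

* the **best-fit** reference cluster (majority vote of assignments),
* the **nearest neighbor fraction** (NNF): the fraction of the query
  cluster's samples voting for the best fit,
* the **mean similarity**: the mean correlation between the query cluster's
  samples and the best-fit centroid.

The significance of a best-fit match is assessed against *null centroid
sets*: the centered centroid matrix `B = C - center` (with `center` the
reference data's per-gene mean) is re-embedded at a uniformly random
orientation, `center + V R`, where `B = QR` and `V` is a Haar-uniform
orthonormal frame. This preserves every pairwise centroid distance and every
centroid norm about the center exactly -- the null keeps the reference
geometry and randomizes only its orientation relative to the query. The
P value is the fraction of `n_null` draws (default 500) in which the null
best-fit mean similarity **and** the null NNF strictly exceed the observed
values; zero is reportable, with resolution `1/n_null`.

Both orderings are computed. A cluster pair is **reciprocal** when each
cluster is the other's best fit; only then are NNF and mean similarity
averaged across the two directions. The two P values are never averaged --
both must pass the threshold downstream.

## Step 3 -- thresholds and the similarity network

Reciprocal pairs receive an edge when `nnf_avg >= 0.7`, both P values are
`<= 0.01`, and `sim_avg` passes the minimum mean similarity threshold; all
comparisons are inclusive. The edge weight is `sim_avg`. The similarity
threshold is data-driven: `similarity_density()` fits a Gaussian kernel
density (Silverman bandwidth) to *all* directional mean similarities,
including non-best-fit ones, and `suggest_threshold()` returns the
smallest-similarity local maximum above a 0.1 baseline (both peak location
and height must exceed the baseline). The smallest qualifying peak is
preferred because pruning near similarity 1 discards clusters -- sometimes
whole datasets -- whose signal is real but noisy; when the curve is
multimodal all qualifying peaks are reported so alternates can be run.

## Step 4 -- meta-clusters

Girvan--Newman edge-betweenness community detection runs on the weighted
network. igraph's implementation treats weights as distances during
betweenness, so the removal sequence uses `1/weight`; the partition along
the dendrogram is then chosen to maximize modularity with weights as
*strengths*. Communities whose clusters span fewer than three unique
datasets are removed -- a meta-cluster supported by two cohorts is not
considered replicated. Community labels are canonicalized by each
community's lexicographically smallest node, so results do not depend on
input order.

## Marker genes

For each meta-cluster, `marker_table()` computes per-dataset Hedges' g
(exact small-sample bias correction; variance
`1/n1 + 1/n2 + g^2/(2(n1+n2))`) of each gene between the meta-cluster's
member samples and all other network-retained clustered samples of the same
dataset, then pools across datasets by fixed-effect inverse-variance
weighting (DerSimonian--Laird random effects optional). The conventional
filters are `>= 0.5` (enrichment-analysis input) and strictly `> 0.75`
(druggable-target shortlist).

# Feature selection

`rank_genes()` scores genes by mean absolute deviation about the
within-dataset mean; `meta_rank()` aggregates by mean rank across datasets
(a gene absent from a dataset receives that dataset's worst rank plus one,
so platform-sparse genes cannot win on a handful of observations), takes the
top `n_global`, and unions in any gene ranked in a dataset's top `n_intra`.
Mean-rank (Borda) aggregation is scale-free across platforms, which matters
when collections mix arrays with very different intensity distributions. An
`exclude` list is applied before ranking, for designs that must avoid a
known signature.

# The simulator

`simulate_collection()` generates collections with four ground-truth
"archetype" mean profiles in a 200-gene space, ten datasets, and additive
i.i.d. Gaussian noise. Seven scenario families vary cluster sizes (fixed 50
vs random 1--100), clusters per dataset (all 4, random 2--4, random 1--4),
and -- as a negative control -- replace half the clusters with "mixed"
clusters whose samples draw their archetype uniformly at random.

Archetypes are drawn i.i.d. Gaussian with per-gene standard deviation
`archetype_sd = 0.7` (mean pairwise archetype distance about
`sqrt(2 * 200) * 0.7 ~ 14` units). This calibration constant was chosen so
that the benchmark noise grid 0--2.4 traverses the full easy-to-hard regime:
the expected within-cluster sample-to-centroid correlation is
`0.7 / sqrt(0.49 + sd^2)`, i.e. about 0.66 at noise 0.8 (comfortably above a
0.3--0.5 similarity threshold) and about 0.28 at noise 2.4 (below it). A
much smaller separation would make every positive threshold empty the
network by moderate noise; a larger one would never stress the thresholds.
The constant is exposed, not hard-coded.

What the simulator emulates: multiple cohorts sharing latent sample classes,
class-specific mean profiles, cohort-specific class composition, and
per-sample noise. What it does not emulate: gene--gene correlation
structure, platform-specific dynamic ranges and missingness, cluster shape
beyond spherical Gaussians, and overlapping/hierarchical subtypes. Passing
benchmarks here therefore demonstrates the machinery's correctness and its
conservatism under noise -- not performance on any particular real
collection.

`score_edges()` evaluates edge-level recovery: over all cross-dataset
cluster pairs eligible for an edge (pairs whose parent datasets are not both
single-cluster, which the method cannot compare), a true positive is an edge
between same-archetype clusters; mixed clusters count as different from
everything. Scoring is applied after meta-cluster pruning, so it measures
the final output, not the raw edge stage.

# Benchmark scale and reproducibility

The shipped benchmark (`sweep_scenarios()` defaults scaled down in
`scripts/acceptance.R` and the acceptance tests) runs all seven scenarios
over noise sd {0, 0.4, ..., 2.4} and similarity thresholds
{0, 0.15, 0.3, 0.5, 0.7} with 10 replicates per cell and 100 null draws per
P value. Ten replicates estimate an averaged FPR bound comfortably when the
underlying rates are near zero, and 100 draws give P value resolution 0.01 --
exactly the decision threshold. Every replicate derives its RNG stream
deterministically from (seed, scenario, noise index, replicate), and each
ordered dataset pair inside a run derives its stream from the seed and the
two dataset ids, so results are independent of dataset ordering and
bit-reproducible.

Null draws are shared across the query clusters of one ordered dataset pair
(one rotation per draw, all query samples assigned once). Marginally each
P value has exactly the null defined above; sharing introduces only
dependence *between* P values of same-dataset query clusters, which no
downstream step exploits, and cuts the dominant cost of the pipeline by the
number of clusters per dataset.

# Numerical choices and degenerate inputs

* Ties: nearest-centroid ties and best-fit vote ties break toward the
  lowest index, deterministically; rounded-PAC ties break toward smaller k.
* Thresholds are inclusive (`>=` for NNF/similarity, `<=` for P).
* A constant sample or centroid on the shared genes has undefined
  correlation; it is treated as "never nearest" and reported. An
  all-constant comparison errors.
* Duplicate gene symbols within a dataset collapse to the row with the
  largest mean absolute deviation; rows with missing values are dropped at
  load.
* A rotation null is undefined on one shared gene; two or more are required.
* k-means initial centers are drawn from *distinct* sample profiles so
  noise-free duplicated samples cannot abort a consensus run.
* Consensus entries for sample pairs never co-drawn (rare at 100 resamples)
  are 0 and counted in `n_never_cosampled`.

# On the calibration of the P value

The reported P value requires the null draw to strictly exceed the observed
mean similarity *and* the observed NNF. Under a rotation-invariant
("isotropic") query cluster the observed statistics are exchangeable with
the null draws, and the exceedance fraction of the continuous mean
similarity alone is uniform -- the package's test suite verifies this, which
pins down the rotation sampler and the correlation bookkeeping end to end.
The *joint* exceedance fraction, however, is not a probability integral
transform: unless the two statistics are comonotone, requiring both to be
beaten inflates the mass at small values (for independent continuous
components, `P(p <= t) -> t(1 - log t)`), and the NNF is additionally
discrete with heavy ties. Measured under the isotropic null, the joint
P value has mean about 0.24 rather than 0.5. The joint rule is kept as the
package's definition -- it is the natural bivariate "at least as extreme"
event for this statistic pair, and its bias is toward *smaller* P values
only for matches that are already weak on one coordinate -- but users should
read the 0.01 default threshold as a conservative screen on strong matches,
not as a calibrated tail probability. The benchmark's near-zero false
positive rates are driven primarily by the reciprocity requirement and the
similarity magnitude threshold, with the P value as a backstop.

# Known limitations

* With the similarity threshold disabled (0.0), the spurious edges admitted
  at zero similarity can distort the community partition enough that a few
  nodes fall into sub-threshold communities and are pruned -- so the
  *post-pruning* TPR is not exactly monotone in the similarity threshold,
  even though the raw edge set is strictly nested. The benchmark asserts
  monotonicity at the edge stage, where it provably holds.
* A "mixed" cluster (a random blend of classes) is usually isolated by the
  NNF and reciprocity requirements, but when its random composition skews
  toward one class it can occasionally form a reciprocal borderline edge
  with a pure cluster of that class (observed once in 490 benchmark
  replicates, at noise sd 1.2 and threshold 0.3). Contamination-heavy
  collections deserve a higher similarity threshold.
* At exactly zero noise, samples within a cluster are identical, every
  nearest-neighbor vote is unanimous in every null draw, and the strict
  joint exceedance can never be attained on the NNF coordinate -- the
  P value degenerates to 0 for *every* reciprocal pair. Magnitude and NNF
  thresholds then do all the filtering (visible in the benchmark as the
  threshold-0.0 false positive rates at noise 0).
* Pearson correlation is the only shipped similarity; rank-based or
  absolute-distance alternatives would need a plug-in.
* Clusters from two single-cluster datasets cannot be compared at all, which
  lowers recall in collections dominated by one-subtype cohorts.
* Gene matching is exact string equality; symbol harmonization belongs to
  preprocessing.
* The fixed-effect marker summary assumes a common true effect across
  cohorts; use the random-effects option when cohorts are heterogeneous.
* Girvan--Newman is quadratic-ish in edges; collections with many hundreds
  of clusters may want a faster community detector behind the same
  interface.
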