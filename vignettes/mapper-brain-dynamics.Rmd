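---
title: "Mapper graphs of brain-state dynamics: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapper graphs of brain-state dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statemapper)
```

## The model

`statemapper` treats a subject's recording as a cloud of time points in
channel space and summarises it as a graph. The premise is that ongoing
cognition revisits a limited repertoire of whole-head activation states:
time points recorded in the same state are mutually similar under the
Euclidean metric, and a cognitively demanding task constrains the brain to
fewer, more mutually similar states than a less demanding one. The Mapper
summary makes that structure visible without collapsing time (no trial
averaging) or space (no prior channel reduction): nodes are clusters of
similar time points, edges record that two clusters share a time point,
and the paradigm label carried by each time point lets every node be
attributed to the paradigm dominating it.

Two mesoscale invariants carry the inference. Node centrality (degree,
eigenvector, betweenness, closeness, all in their standard normalized
forms) quantifies how central a paradigm's recurring states are in the
state-transition summary; Newman modularity quantifies how crisply the
graph decomposes into communities. Per subject, the mean centrality of the
nodes each paradigm dominates gives one number per paradigm; across
subjects these form a paired sample and the package's inference layer
(normality gate, paired *t* or sign-flip permutation test, Bonferroni
correction over the parameter sweep, direction check on the sample means)
decides whether one paradigm's centrality systematically exceeds the
other's.

### Assumptions

* The Euclidean metric on raw channel vectors is meaningful: channels are
  on comparable scales (true after standard upstream cleaning of
  magnetometer data, and true of the simulator by construction).
* Paradigm labels are piecewise constant and correct per time point; only
  `stimulus`-phase points enter the analysis.
* Graphs are connected or nearly so; analysis restricts to the largest
  connected component (below).

## Pipeline stages and their parameters

| Parameter | Default | Meaning |
|---|---|---|
| `n_intervals` | sweep `{10,15,20}` | cover intervals per filter dimension (bins = n²) |
| `overlap_pct` | sweep `{30,40,50,60}` | overlap between consecutive intervals, % of interval length |
| `n_clusters` | sweep `{5,10,15,20}` | single-linkage dendrogram cut per bin |
| `filter_method` | `"pca"` / `"tsne"` | 2-D lens |
| `filter_seed` | 1 | seed of the stochastic lens |
| `alpha` | 0.05 | significance level (gate and tests) |
| `satisfied_frac` | 0.95 | fraction of sweep rows that must individually satisfy a hypothesis |

**Preprocessing.** Sessions are optionally resampled (anti-aliased
polyphase resampling via `signal::resample`; upsampling refused), reduced
to fully finite `stimulus` rows, and two paradigm blocks are concatenated
over the intersection of their channel ids in lexicographic order — a
fixed canonical order so column layout is reproducible. Labels survive
resampling by the nearest-original-point rule, exact away from block
boundaries because labels are piecewise constant. Rows with missing
values are dropped, never imputed. Storage is time-major (time ×
channels) throughout; a single convention removes a whole class of
transpose bugs.

**Lens.** PCA (centered, unscaled, first two components) is deterministic
and exactly isometric on rank-2 data, which makes it the default for
simulation studies and tests. t-SNE is provided as the non-linear lens
for real data: an exact O(n²) implementation (perplexity calibrated per
point by bisection, early exaggeration 12 for 100 iterations, learning
rate 200, momentum 0.5 then 0.8, 500 iterations, seeded PCA-free random
init at scale 1e-4). Perplexity defaults to 30 and is reduced
automatically to `(n−1)/3` when the input is small. Exact t-SNE is
quadratic in the number of time points, so it is intended for
desk-scale inputs (a few thousand rows).

**Cover.** Per dimension the coordinate range `R` is covered by `n`
closed intervals of length `L = R/(n − (n−1)o)` starting at
`min + k·L·(1−o)`; consecutive intervals overlap by exactly `o·L` and the
union equals the range — an algebraically closed convention that is
testable to machine precision. Boundary membership uses closed intervals:
a point on a shared boundary belongs to both bins (and the bounding-box
center at `n = 2` to all four). The top interval's end is clamped to the
range maximum to guard the extreme point against round-off. A dimension
with zero range collapses to one interval with a warning. For
`o < 50 %` a point lies in at most 4 of the 2-D bins. Empty bins are
skipped silently.

**Per-bin clustering.** Single linkage under the Euclidean metric in the
*original channel space*, not the 2-D lens: Mapper clusters the preimage
of the filter, and the lens exists only to organise the cover. (Whether
the lens space would serve as well is a genuinely open choice; channel
space is fixed here and recorded.) The `n_clusters` parameter is read as
a dendrogram cut at `min(k, bin size)` clusters — single linkage itself
is parameter-free, and a fixed-count cut is the only reading under which
sweeping a "number of clusters" domain changes anything. Singleton bins
yield singleton clusters.

**Nerve.** One node per cluster; an unweighted, undirected, simple edge
whenever two clusters share a time index. Membership is conserved: every
time point sits in at least one bin, bins are partitioned by clustering,
so the union of node member sets is the whole time axis. Nerve edges are
computed by inverting the membership lists (per time index, all nodes
containing it), which matches the brute-force all-pairs intersection test
exactly and is tested against it.

**Connectivity.** Closeness and eigenvector centrality presuppose a
connected graph. The sweep domains in the full design are chosen so
graphs stay connected; when one is not, the default policy restricts all
node-level analysis to the largest connected component with a warning,
and `strict = TRUE` (or `on_disconnected = "error"`) raises instead —
`run_sweep` then records the run as skipped with its reason, mirroring
how infeasible parameter combinations are dropped from reported tables.

**Communities and modularity.** Deterministic fast-greedy agglomerative
modularity maximization (igraph), with the trivial one-community
partition always included as a candidate cut so the returned partition
never has negative modularity. Edgeless graphs take one community per
node and `Q = 0` by convention (logged). Modularity follows Newman's
formula on the unweighted nerve; tests check it against a literal
double-sum oracle on all small graphs and against the closed forms
`Q = 0` (one community), `Q = 0.5` (two disjoint triangles), `Q = −0.5`
(a split single edge).

## The inference layer

The statistic is always the mean of per-subject paired differences of
paradigm-mean centralities. The Shapiro–Wilk gate is applied to the
vector of differences — the quantity whose normality the paired *t*-test
actually assumes — not to the raw score columns. Below `alpha` the
sign-flip permutation test is used: under the null the two conditions
are exchangeable within subject, so each difference may be negated.
For `n ≤ 20` pairs all `2^n` sign patterns are enumerated (meet-in-the-
middle, so the worst case is two 2^10 half-sums combined by outer
addition); beyond that, seeded Monte Carlo patterns with add-one
smoothed tails `(count+1)/(B+1)`, which cannot produce a zero p-value.
Tails are inclusive, with a relative tolerance of 1e−12 at the observed
statistic so floating-point noise cannot reclassify exact ties. The
two-sided p-value is `2·min(p_l, p_g)` capped at 1. Constant differences
leave the *t*-statistic and the normality test undefined: the gate then
chooses the permutation test with a warning, and the degenerate
enumeration correctly returns `p = 1`.

Bonferroni's family size defaults to the number of parameter triples
present in the comparison, the natural family when one hypothesis is
re-tested across the sweep; it is configurable because captions of
corrected tables rarely pin the family down. A hypothesis is *satisfied*
when the corrected p-value is below `alpha` **and** the sample means are
ordered as hypothesised, in at least `satisfied_frac` (default 95 %) of
the sweep rows — an explicit operationalisation of "significant for the
large portion of parameter values". TIE nodes (exact label ties) are
excluded from every paradigm mean rather than arbitrarily assigned,
avoiding bias in the comparison; their count is reported. Correlation
between modularity and response times is Pearson by default (the
reported quantity is a signed fractional correlation with a separate
significance), with Spearman available.

## What the simulator emulates — and what it does not

`generate_subject_session` draws `S` state centroids from an isotropic
Gaussian (scale `centroid_sd`), a state sequence with geometric dwell
times (memoryless, the simplest law producing contiguous state blocks),
and observations centroid + isotropic noise (`noise_sd`). Cohorts derive
per-subject seeds from the cohort seed by a fixed integer hash, so
subjects are independent but the whole cohort is reproducible
bit-for-bit.

The canonical study conditions (`study_configs()`) encode task demand as
*higher mutual similarity of time points*: the demanding paradigm has 3
states at centroid scale 0.5, the relaxed paradigm 12 states at scale
1.0, with equal within-state noise 0.5 and mean dwell 10. Both levers
matter. Reducing the state count alone (at equal centroid scale) leaves
the mixture's total spread unchanged — the two paradigms then differ only
in lumpiness, node dominance is spatially unsystematic, and no centrality
ordering emerges; this was verified empirically during design. Pulling
the demanding centroids mutually closer is what makes its time points
genuinely more similar to one another, places its nodes in the dense core
of the nerve, and yields the expected closeness ordering in essentially
every simulated cohort.

The simulator does **not** emulate sensor geometry, 1/f spectra,
autocorrelated within-state dynamics, artifacts, or channel-count
variation between subjects. Consequently, passing end-to-end tests shows
that the pipeline recovers orderings *when the state-recurrence mechanism
is present*; it does not certify performance on real recordings. One
empirical trend of real magnetometer data is known not to transfer: on
synthetic sweeps the median modularity *rises* with the per-bin cluster
cut (more, smaller, still densely wired nodes), whereas on the original
recordings it falls; only the interval-direction trend (median modularity
non-decreasing in `n_intervals`) is asserted in tests.

## Problem sizes used by the test-suite and reproduction script

Chosen as the package's desk-scale design points: worked-example
statistics on the packaged 60-pair table; directed-hypothesis
satisfaction over 20 cohorts of 10 subjects (16 channels, 150 time points
per paradigm, triple 5-50-3, PCA lens); null rejection over 200 matched
cohorts (8 channels, 100 time points); one full-scale sweep of 8 triples
× 10 subjects at 32 channels and 2,000 time points per subject; sign
recovery of the modularity–response-time coupling over 100 seeds with
slope −0.5 and noise equal to the modularity spread. Monte Carlo
permutation tests use B = 10,000 throughout.

## Known limitations

* Exact t-SNE is quadratic; large recordings need the PCA lens or an
  external embedding passed through `run_mapper(..., embedding = )`.
* Nerve edges are unweighted; intersection sizes are discarded.
* Eigenvector centrality on a near-disconnected largest component can be
  concentrated on a few nodes; degree and closeness are more stable at
  small node counts.
* The `n_clusters`-direction modularity trend of real data is not
  reproduced by the simulator (above).
* Real-data ingestion expects the package's CSV container
  (`write_labeled_ts`/`read_labeled_ts`); adapters for acquisition
  formats are out of scope.
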