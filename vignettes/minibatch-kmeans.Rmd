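---
title: "Mini-batch k-means for matrices that do not fit in memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mini-batch k-means for matrices that do not fit in memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbcluster)
```

## The problem

Single-cell RNA-seq experiments now produce expression matrices with
millions of cells. The most common way to define putative cell types is
unsupervised clustering, and the workhorse partitional method is k-means:
partition the $N$ observations $\mathbf{Y} = \{y_1, \dots, y_N\}$,
$y_i \in \mathbb{R}^G$, into $k$ sets $S_1, \dots, S_k$ minimizing the
within-cluster sum of squares

$$\mathrm{WCSS} = \sum_{c=1}^{k} \sum_{y \in S_c} \lVert y - \mu_c \rVert^2,$$

where $\mu_c$ is the centroid (mean profile) of cluster $c$. Lloyd's
algorithm alternates assigning every observation to its nearest centroid
and replacing each centroid by its members' mean — which requires the whole
$N \times G$ matrix in RAM on every pass. At $10^6$ cells and $10^4$ genes
that is tens of gigabytes, so full k-means becomes slow or impossible on
ordinary hardware.

Mini-batch k-means replaces the full pass with a random subsample. At
iteration $t$ it draws, without replacement, a batch $\mathbf{M}$ of $b$
rows, assigns only those rows to the centroids $\hat\mu^{(t-1)}$, and
replaces each centroid that received batch rows by the mean of those rows.
Iteration stops when the centroid displacement
$\lVert \hat\mu^{(t)} - \hat\mu^{(t-1)} \rVert_2$ (Frobenius norm) falls
to a tolerance, after which the final centroids label all $N$ observations
in a block-wise sweep. The objective is still the *global* WCSS over all
observations; only the search uses subsamples. Because one iteration
touches just $b$ rows, the algorithm runs unchanged on a matrix stored on
disk — the package reads only the current batch, so memory is governed by
$b$, not $N$.

## What a fit does

`fit_minibatch()` executes, with a single seeded RNG driving every random
choice in a fixed order (so results are identical across storage
backends):

1. **Initialization.** k-means++ on a without-replacement subsample of
   `b_init` rows: the first centroid is a uniform draw from the subsample,
   and each later one is drawn with probability proportional to its squared
   distance to the nearest centroid chosen so far ($D^2$ sampling).
   Initializing on a subsample keeps the memory contract; defaulting
   `b_init` to the batch size gives the initialization the same sample size
   the iterations use.
2. **Iteration.** Sample a batch, assign it (ties to the lowest centroid
   index), update the receiving centroids by the batch means. A centroid
   that received no batch rows keeps its previous position — the update
   rule's mean is undefined for an empty set, and retaining the centroid
   preserves all $k$ clusters.
3. **Convergence.** Stop when the centroid shift is at most `tol`
   (default `1e-4`) or after `max_iter` (default 100) iterations. The first
   comparison is against the initialization. Note that with per-batch mean
   updates the shift fluctuates at the scale of batch sampling noise, so
   for `b` much smaller than `N` fits typically run to the iteration cap;
   the cap, not the tolerance, is the effective stopping rule there. The
   `converged` flag records which one fired.
4. **Prediction and evaluation.** `predict_blockwise()` labels all rows in
   blocks of `prediction_block` rows (identical to a single whole-matrix
   assignment, for every block size), and the WCSS is evaluated block-wise
   on the full data with the final centroids.

### Parameters that matter

* `k` — the number of clusters, user-supplied (no automatic selection).
* `b` (batch size) — default `min(10000, N)`. Batches of at least 500
  observations already match full k-means in accuracy on separable
  expression-like data; 10,000 adds robustness at negligible cost, and
  beyond that per-iteration cost and memory grow for no accuracy gain.
* `b_init` — default `b`, as above.
* `tol` — `1e-4` on the Frobenius shift; `max_iter` — 100. The convergence
  quantity is standard; the thresholds match common practice for in-memory
  mini-batch implementations.
* `prediction_block` — default `b`; affects memory only, never results.
* `restarts` — default 1; with more, seeds are derived from `seed` and the
  lowest-WCSS fit is kept.
* Labels are 1-based, matching `stats::kmeans()`; the command line can
  emit 0-based labels (`--labels-base 0`) for interoperability.

Distances are always computed in double precision regardless of the
storage type, so WCSS values are comparable across backends. The update
uses per-batch means only (no counts accumulated across batches, no
per-center learning rates): the batch mean is the literal update rule
stated above, and keeping iterations independent of batch history is what
makes the full-batch case collapse exactly to Lloyd's algorithm — a
property the test suite exploits by checking per-iteration equality with a
brute-force Lloyd implementation whenever `b = N`. Streaming variants with
decaying learning rates are deliberately out of scope.

## Storage backends and the memory contract

`open_matrix()` wraps dense matrices, sparse `Matrix` objects, delimited
text, MatrixMarket files, and dense 2-D HDF5 datasets behind one handle
whose logical shape is always observations × features; files that store
the transpose (the common layout for single-cell data) declare
`orientation = "feat_rows"`. All algorithm code reads through
`read_rows()`, which returns a dense block in request order — for HDF5 it
sorts indices internally for contiguous access and restores the order on
return, and it never reads the file at open time.

HDF5 handles are instrumented: `peak_rows_resident()` reports the largest
single row-read since the last reset. This is the package's testable
memory contract — a fit plus prediction never requests more than
`max(b_init, b, prediction_block)` rows at a time, independent of $N$ —
and is the hardware-independent surrogate for wall-clock RAM
measurements, which depend on the machine and the garbage collector. The
instrument counts rows per read, not allocator bytes.

## HDF5 chunk geometry

An HDF5 dataset is stored as a grid of rectangular chunks, and a read
decodes every chunk it touches, so layout determines the cost of reading
500 scattered rows. `default_chunk_geometry()` reproduces the
conventional automatic choice: a rectangle whose (i) area is below
1,000,000 elements, (ii) fits in the matrix, and (iii) matches the
matrix's aspect ratio. Those constraints do not pin down an algorithm, so
the package uses a deterministic one — scale both dimensions by
$\sqrt{(10^6 - 1)/(n_r n_c)}$, floor, clamp to ≥ 1, and shrink the larger
dimension if clamping pushed the area back over the bound.

For row-sampled access the aspect-matched default is not optimal: a batch
of scattered rows touches nearly every chunk. The best layout for this
algorithm is *indexing by cells* — each chunk spans the full feature
dimension for a slab of observations, so a row read decodes only the
slabs containing its rows. `rechunk_hdf5()` rewrites a dataset into that
layout (preset `"by_cell"`, slab depth defaulting to the value that puts
the chunk area just under 1,000,000), its transpose (`"by_gene"`), a
single whole-matrix chunk, or any explicit rectangle, streaming bounded
slabs so rechunking itself honours the memory contract.

## Evaluation metrics

`wcss()` evaluates the objective block-wise. `adjusted_rand_index()`
implements the Hubert–Arabie chance-corrected agreement from the label
contingency table; pair counts stay in exact double-precision integer
range well past $N = 10^6$. Two degenerate partitionings make the
adjustment denominator vanish — both sides one single cluster, or both all
singletons; the partitions are then identical up to relabeling and the
index is defined as 1.

## The synthetic-data generator

`generate_mixture()` draws component means i.i.d.
$\mathcal{N}(0, \texttt{centroid\_spread}^2)$ per coordinate, memberships
from the mixing proportions (uniform by default), and isotropic
$\mathcal{N}(0, \texttt{noise\_sd}^2)$ noise. It emulates the
Gaussian-mixture regime used to study clustering accuracy: known labels,
controllable separation, expression-like dimensions. It deliberately does
*not* emulate scRNA-seq counts — no discreteness, no dropout, no library
size variation, and values may be negative — so passing accuracy checks on
it demonstrates properties of the *algorithm* (batch-size dependence,
k-recovery, backend identity), not performance on real counts, which in
practice are normalized and often reduced to principal components before
clustering anyway.

**Choosing the separation.** The defaults are `centroid_spread = 1`,
`noise_sd = 1`. For experiments whose conclusions require the mixture to
be unambiguously recoverable, separation must be chosen with the
initialization in mind. During $D^2$ sampling, after $j$ of $k$ components
are covered, the odds that the next draw lands in an already-covered
component are roughly $j : (k - j)\,s^2$, where
$s = \texttt{centroid\_spread}/\texttt{noise\_sd}$ — so reliable coverage
of all components needs $s^2 \gg k$, not merely $s \gg 1$. At $s = 10$ and
$k = 15$ a component is missed in a substantial fraction of runs, which
confounds a k-recovery experiment; the package's simulation studies
therefore use $s = 100$ ($s^2 = 10^4 \gg 15$) for the "well-separated"
regime, and the k-means comparator in the accuracy study is given the same
k-means++ subsample initialization as the mini-batch fits, so the
comparison isolates the batch scheme rather than initialization luck.

## Problem sizes used in the checks

The package's self-checks run on one CPU in minutes, at sizes chosen to
exercise each claim rather than to benchmark: k-recovery on
$N = 25{,}000 \times G = 1{,}000$ with $k_{\text{true}} = 15$, $b = 500$,
a grid $k \in \{5, 10, 15, 20, 25\}$ and 10 replicates; batch-size
accuracy on $N = 5{,}000 \times G = 1{,}000$, $k_{\text{true}} = 3$,
$b \in \{75, 500, 1000\}$, 25 replicates; the memory contract on
HDF5-backed fits at $N = 5{,}000$ and $50{,}000$ with $b = 500$ and
prediction block 1,000; and Lloyd-equivalence on 50 random instances with
$N \le 200$. `scripts/acceptance.R` re-runs the chunk-constraint grid and
the k-recovery experiment from scratch for any seed.

## Known limitations

* Only dense 2-D HDF5 datasets are supported on disk; sparse on-disk
  layouts (e.g. 10x-style CSC groups) would need a further backend.
* The empty-cluster rule (retain the previous centroid) can leave a
  centroid stranded if it is initialized into a region the batches never
  revisit; restarts mitigate this.
* With $b < N$ the fit follows a different search path than Lloyd's
  algorithm and need not reach the same local optimum; no trajectory
  equivalence is claimed except at $b = N$.
* `peak_rows_resident()` counts requested rows, not bytes; transient
  copies made by the interpreter are outside its scope.

## A worked example

```{r example, eval = FALSE}
sim <- generate_mixture(mixture_spec(n_obs = 10000, n_feat = 200,
                                     k_true = 5, centroid_spread = 10,
                                     seed = 1))
h5 <- tempfile(fileext = ".h5")
write_fixture(sim, h5, format = "hdf5", geometry = "by_cell")

m <- open_matrix(h5, format = "hdf5")
fit <- fit_minibatch(m, k = 5, b = 500, seed = 1)
fit
adjusted_rand_index(fit$labels, sim$labels)
peak_rows_resident(m)   # never more than the batch/block bound
glance(fit)
tidy(fit)
plot_convergence(fit)
```
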