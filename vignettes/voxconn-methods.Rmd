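---
title: "Voxel-wise connectivity metrics: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise connectivity metrics: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxconn)
```

## The model

Resting-state fMRI connectomics treats each in-mask voxel as a node of an
undirected graph. The edge weight between voxels $i$ and $j$ is the
correlation $r_{ij}$ of their BOLD time series (Pearson, or Spearman =
Pearson on within-row ranks). Two per-voxel summaries of that graph are
computed here.

**Degree centrality.** A connection is *retained* either when
$r_{ij} > \theta$ (threshold mode, strict inequality, default
$\theta = 0$) or when it belongs to the top $P\%$ strongest of the
$M = N(N-1)/2$ unique pairs (sparsity mode). Binary DC of voxel $i$ is the
number of its retained connections; weighted DC is
$\sum_j r_{ij}$ over the same set, with no rescaling. Both maps satisfy
the handshake identity $\sum_i \mathrm{DC}^{bin}_i = 2\,k_{retained}$,
which the tests assert on every run.

**lFCD.** Local functional connectivity density replaces the global graph
with the spatially contiguous cluster around each target voxel: starting
at the target, 26-adjacent voxels (face-, edge- or corner-touching, in
index space) join iteratively while their correlation *with the target*
exceeds $\theta$. Binary lFCD is the cluster size, weighted lFCD the sum
of member correlations with the target (the seed contributes 1.0). The
admission test deliberately uses target correlation, not
neighbour-to-neighbour correlation — the second convention exists in the
lFCD literature, but growing on the target's correlation row is the
definition implemented here; it makes each cluster exactly the connected
component of the thresholded correlation row containing the seed, which
is also what the test-suite oracle recomputes independently.

**Concordance.** Agreement between two maps $a, b$ over the same mask is
the concordance correlation coefficient with population ($1/n$) moments,

$$\rho_c = \frac{2\,\mathrm{cov}(a,b)}
  {\mathrm{var}(a) + \mathrm{var}(b) + (\bar a - \bar b)^2},$$

which penalises location and scale shifts on top of decorrelation:
$\rho_c = 1$ only for identical maps and $|\rho_c| \le |r_{ab}|$. Several
published variants exist; the plain Lin form above is implemented and is
what `concordance()` documents.

## Streaming the correlation matrix

At voxel resolution the full $N \times N$ correlation matrix is the
bottleneck, so it is never formed. Time series are standardized once
(mean 0, unit $L_2$ norm) so Pearson $r$ is a dot product, then blocks of
`block_size` rows (default 1024) are multiplied against the full
standardized matrix and their upper-triangle entries are consumed
immediately, in deterministic i-major order. Peak additional memory is
$O(\mathrm{block\_size} \cdot N)$; accumulation is in double precision.
Correctness must not and does not depend on `block_size` — the suite
compares record streams across block sizes 1, 7, 40 and the default, and
an allocation-instrumented run over 5000 voxels (12.5 million pairs)
verifies that the largest single allocation stays ~10 MB, an order of
magnitude below what even the upper triangle would need.

## Top-k selection with a two-level adaptive histogram

Sparsity mode needs the top $k = \lceil P/100 \cdot M \rceil$
correlations without sorting $M$ values. Records with
$r$ above a moving admission threshold enter a 50-bin equal-width
histogram spanning $[\mathrm{floor}, 1]$ (floor 0 by default). After each
batch, while the bins strictly above the lowest retained bin already hold
at least $k$ records, the lowest bin is discarded and the admission
threshold rises by exactly one bin width — a record discarded this way can
never belong to the top $k$, a property the tests check against full-sort
oracles on randomized instances. At finalization whole bins are taken from
high to low; the first bin that would overshoot $k$ is re-histogrammed
into 100 equal-width sub-bins over its own range and consumed likewise,
and the final admitted sub-bin is taken whole.

Consequences, all tested:

- the retained count can exceed $k$, never undershoot it (short of a
  global shortfall, which warns);
- overshoot can come only from values within one sub-bin of each other,
  i.e. ties are broken with a precision of $1/(50 \cdot 100) = 2\times
  10^{-4}$ of the span — two values further apart can never be merged;
- a threshold-mode run at the sparsity run's realised `final_threshold`
  reproduces the sparsity maps up to boundary ties.

$\lceil \cdot \rceil$ for $k$ reads "top P%" as *at least* P%, consistent
with the overshoot-only tie behaviour; the histogram spans
$[\mathrm{floor}, 1]$ rather than $[-1, 1]$ because records at or below
the floor are inadmissible anyway. Setting `floor_threshold` below 0
widens the bins and degrades tie precision proportionally, which the
argument documentation states.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `threshold` | 0 | correlation cutoff (unitless r), strict `>` |
| `sparsity` | — | percent of M to retain; 0.1 means 0.1% |
| `primary_bins` / `secondary_bins` | 50 / 100 | histogram resolution; product sets tie precision |
| `floor_threshold` | 0 | lower edge of the primary span |
| `block_size` | 1024 rows | memory/speed trade-off only |
| `method` | pearson | or spearman (average ranks on ties) |
| `include_seed` | TRUE | count the seed voxel in its own lFCD cluster |

Thresholds are accepted anywhere below 1 (the value is compared strictly,
so a cutoff below −1 admits every pair, including pairs at exactly
$r = -1$ that no cutoff $\ge -1$ could admit).

## Conventions and degenerate inputs

- **Voxel order** is a fixed raster scan of the mask, x slowest,
  z fastest, 1-based rows; tests pin it so a change is caught.
- **Mask membership**: any nonzero mask value. No auto-masking is
  offered; masks come from the user or the fixture generator.
- **Constant time series** have undefined correlation; such voxels are
  removed with a warning and written as 0 in every output map.
- **Spearman ties** get average ranks.
- Fewer than 3 timepoints, empty masks, grid mismatches, and
  simultaneous `threshold`/`sparsity` requests are errors, not warnings.
- The seed voxel counts in binary lFCD (cluster-size semantics) and
  contributes weight 1.0; `include_seed = FALSE` toggles both.
- Adjacency ignores anisotropic voxel dimensions: "touching" is defined
  on the index grid.

## The synthetic generator

`synthetic_bold()` builds the only data the package's tests need: voxel
blocks sharing unit-variance latent Gaussian signals. A voxel in a block
with latent $g$ gets $w\,g + (1-w)\,\varepsilon$, $\varepsilon \sim
N(0, \sigma^2)$ i.i.d., so the expected within-block correlation is
analytically $w^2 / (w^2 + (1-w)^2\sigma^2)$ (returned as `expected_r`;
an empirical check at $T = 2000$ agrees within ±0.02). Cross-block
latents are independent, so cross-block correlations concentrate near 0
at rate $1/\sqrt{T}$. Optional `noise_voxels` are in-mask but carry pure
noise (unit variance when $\sigma = 0$, since a constant series would be
degenerate by construction). Defaults describe the noiseless limit
($w = 1, \sigma = 0$), where DC and lFCD are exactly predictable: binary
DC $= B - 1$ and binary lFCD $= B$ inside a contiguous block of size $B$.

What passing on these fixtures shows is that the graph metrics, the
selection algorithm and the I/O are correct on data whose correlation
structure is known exactly. What it does not show: behaviour under real
fMRI noise (temporal autocorrelation, drift, motion, physiological
signal), preprocessing choices, or registration — all out of scope; the
package starts at a cleaned 4D volume plus mask.

## Problem sizes and numerical choices

The test suite runs oracle comparisons at $N \le 200$ voxels and
$T = 50$ timepoints (100 randomized sparsity instances, exhaustive
double-loop threshold oracles at $N \le 100$, every-target flood-fill
checks on a $6^3$ grid) and one 5000-voxel allocation-instrumented
sparsity run; these sizes make the full-sort and double-loop oracles
cheap while exercising every code path. Integer maps are compared
exactly; weighted maps to $10^{-10}$ (ordered, double-precision
accumulation); oracle correlations from `stats::cor` agree with the
streamed dot products to ~$10^{-15}$, so cross-implementation scalar
comparisons use $10^{-12}$ slack. Ties *within* one secondary sub-bin are
resolved by taking the whole sub-bin — never by record order — so results
are independent of streaming order and block size.

## Known limitations

- `sparsity` percentages small enough that $k < 1$ record would be
  requested still retain one connection ($\lceil \cdot \rceil$).
- Memory in sparsity mode is bounded by the records that can still reach
  the top $k$; adversarial distributions (all correlations inside one
  primary bin) degrade to storing every admitted record.
- lFCD recomputes one correlation row per target ($O(N)$ memory,
  $O(N^2 T)$ work); no caching across targets is attempted.
- The concordance CLI compares maps over a mask's nonzero voxels only.
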