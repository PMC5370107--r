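---
title: "Information-based network classification of proteins: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information-based network classification of proteins: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protminet)
```

## The model

`protminet` classifies proteins by the statistical dependence of their
residue series, not by alignment. The chain of ideas:

1. A protein sequence over the 20 standard amino acids is a discrete time
   series with states 1..20 under a fixed encoding bijection (alphabetical:
   A→1 … Y→20). A 3D structure becomes a series the same way after its
   backbone (φ, ψ) torsion angles are computed and binned.
2. For two series the package computes the *plug-in mutual information*
   between the shorter series $X$ (length $M$) and every length-$M$ window
   $Y_i$ of the longer series $Y$:
   $$I(X; Y_i) = \sum_{\alpha,\beta} p(\alpha,\beta)
     \log \frac{p(\alpha,\beta)}{p(\alpha)\,p(\beta)},$$
   with $p(\alpha,\beta)$ the empirical frequency of the position-paired
   states. The pairwise similarity is $I_{XY,\max} = \max_i I(X; Y_i)$,
   which makes the comparison total for unequal lengths and corrects a net
   terminal offset between the two series.
3. Since $I(X; Y_i) \le \min(H(X), H(Y_i))$ and $X$ is always a full series
   of the dataset, dividing all pairwise values by
   $\max_q H_q$ (the largest per-protein entropy) lands every entry of the
   symmetric adjacency matrix in $[0, 1]$.
4. The *mutative threshold* $T_c = c \cdot \max_{ij} a_{ij}$ filters the
   network; connected components of the surviving graph are the classes at
   multiplicity $c$. Sweeping $c$ downward from 1 coarsens the partition
   monotonically, producing a nested merge hierarchy. The structure is that
   of single-linkage agglomeration on dissimilarity $\max(a) - a$: a pair's
   merge multiplicity equals its bottleneck similarity (best worst-edge
   over connecting paths) divided by $\max(a)$, floored to the grid. The
   package computes bottlenecks on a maximum spanning tree and cross-checks
   the sweep against `stats::hclust(..., "single")` in its tests.

The key modeling assumptions: dependence between aligned positions is what
makes related proteins similar; a single global offset is enough alignment
(interior insertions are *not* corrected — see Limitations); and the plug-in
estimator on one shared scale is adequate because only relative magnitudes
cross the threshold filter.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `base` (log base) | 2 | bits | Conventional; normalized results are provably base-invariant (tested to 1e-10). |
| `torsion_bins` | 20 | states | Matches the amino-acid alphabet so both branches share one scale; coarse enough that ~100-residue structures fill the histogram. |
| `torsion_layout` | interleaved | — | ψ₁, φ₂, ψ₂, …, φₙ in residue order (2n−2 values for an n-residue chain); φ-only and ψ-only available. |
| `alphabet_policy` | drop | — | Non-standard residues (X, B, Z, U, O, gaps, stops) are removed with a counted warning; `error` aborts instead. A "map to nearest" policy is not offered because X has no nearest standard residue. |
| grid (`threshold_grid()`) | 1.00 → 0.10, step 0.01 | multiplicity | Matches the two-decimal convention for reported merge values; step is configurable. |
| `exact_threshold_grid()` | data-induced | multiplicity | The partition can only change where $T_c$ crosses a distinct weight, so the descending distinct ratios $a_{ij}/\max(a)$ form the finest meaningful grid; any fixed step can alias two nearby hierarchy levels into one. Used wherever a test must see *every* level. |

## What the synthetic generator emulates — and what it does not

`generate_families()` draws one uniform-random ancestor per family and
derives members by i.i.d. substitutions (default rate 0.05/site, uniform
over the other 19 residues) and single-site indels (default 0.01/site,
insertion or deletion with equal probability, length 1 + Geometric(0.5)).
These defaults give within-family identity around 90% — a realistic
"clearly homologous" family — while indels perturb lengths by a few
residues, exercising the sliding-window path. It does **not** emulate
position-specific conservation, rate heterogeneity, phylogenetic tree
structure within a family, or compositional bias; passing tests therefore
show that the machinery separates families whose signal is distributed
i.i.d. across sites, not that it resolves fine phylogenetic structure in
real proteins.

`generate_torsion_structure()` builds N/CA/C backbones from ideal bond
geometry (N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å; ω fixed at 180°) with
φ/ψ at canonical helix (−60°, −45°) or sheet (−120°, +120°) values plus
optional Gaussian noise. Because the chain is built *from* the logged
angles, `compute_torsions()` recovering them validates generator and
torsion code against each other. Real structures add side-chain packing,
non-ideal geometry and chain breaks that this generator does not imitate.

## Numerical choices

- **Diagonal convention.** $a_{ii} = 0$. Self-similarity would otherwise
  dominate $\max_{ij} a_{ij}$ and distort every threshold; classification
  should be driven by inter-protein relations only.
- **Ties.** Among equally maximal window offsets the smallest is reported.
  Entries exactly equal to $T_c$ survive the filter. Three or more blocks
  uniting at one grid value are recorded as one multi-way merge node, not an
  arbitrary binary order.
- **Boundedness.** Plug-in entropy of a *window* can exceed the full-series
  entropy, but every windowed MI is still bounded by $H(X)$ of the full
  shorter series, so normalized entries cannot exceed 1. A clip-with-warning
  counter (`n_clipped`) guards float residue; it is asserted to be 0 in the
  pipeline tests.
- **Dihedrals.** Signed by the standard atan2 formulation
  ($y = |b_2|\, b_1 \cdot (b_2 \times b_3)$, $x = (b_1 \times b_2) \cdot
  (b_2 \times b_3)$), verified against an independent normal-vector
  construction and against `bio3d::torsion.xyz`. Range is half-open
  $[-180°, 180°)$: an exactly planar trans arrangement reports −180.
  Torsions spanning a chain break are excluded rather than computed across
  the gap.
- **Matrix-power components.** The summed-powers test includes the identity
  (path length 0) so singleton blocks are well defined; connected pairs are
  unaffected. Products of positive doubles cannot underflow at the matrix
  sizes involved.
- **Degenerate inputs.** All-constant datasets (zero entropy everywhere),
  all-zero filtered matrices, single-record datasets, sub-2-residue
  sequences and backbone-free PDB files abort with named errors rather than
  propagating NaN.
- **Determinism.** Blocks are numbered by smallest member index; the
  pipeline writes no timestamps; identical config + inputs reproduce every
  artifact byte for byte (tested).

## Design decisions that were genuinely open

- **Encoding bijection.** Any bijection yields identical MI (label
  invariance is a tested property); alphabetical order is frozen purely so
  encodings are reproducible across runs and machines.
- **Torsion estimator.** MI on torsions uses the same discrete engine after
  uniform binning rather than a kernel/continuous estimator: it keeps one
  code path, and bin count is exposed as a knob. Kernel estimation is out
  of scope.
- **Torsion series layout.** φ and ψ interleaved in residue order into one
  series, keeping a single series per structure; single-angle layouts are
  options rather than defaults.
- **Shorter-vs-longer.** The shorter series always slides along the longer,
  making the operation symmetric and total; with equal lengths there is
  exactly one window and the value reduces to plain MI.
- **Grid for recovery checks.** Tests that must certify "some hierarchy
  level equals the true partition" sweep the exact data-induced grid.
  At 18 nodes, 153 distinct weights span roughly 0.6 of the multiplicity
  range, so levels sit ~0.004 apart on average and any fixed-step grid
  (including the 0.01 default) provably aliases some of them.
- **Problem sizes in the test-suite.** Property tests run at the scale where
  the brute-force oracles are exact and fast: series of length 10–200 over
  K = 20, graphs of up to 15 nodes, 3×6 synthetic families of length ~200,
  hundreds of random replicates per property under fixed seeds.

## Known limitations

- **Estimator bias.** The plug-in MI of two *unrelated* 20-state series of
  length ~200 is far from zero (the classic $(|S_X|-1)(|S_Y|-1)/(2L\ln 2)$
  bias is on the order of 1.3 bits, ~0.3 after normalization). The method
  survives because thresholds are relative, but the dynamic range between
  "unrelated" and "related" is compressed, and short sequences make it
  worse. Bias-corrected estimators are deliberately out of scope.
- **Interior indels.** The sliding window corrects only a net offset. An
  insertion in the middle of one sequence misaligns everything on one side
  of it, so indel-rich pairs lose similarity faster than substitution-rich
  pairs. At the generator defaults this occasionally (roughly one
  realization in ten) leaves one family member bridging families more
  strongly than it links its own, and no threshold then yields the exact
  family partition — the acceptance script reports the honest recovery
  rate it measures.
- **Window entropy.** $H(Y_i) \le H(Y)$ holds for true distributions but
  not always for plug-in estimates; the package never relies on it,
  enforcing boundedness through $H(X)$ instead.
- **Scale.** The pairwise loop is $O(N^2)$ in proteins and the sweep
  recomputes components per grid value; the implementation is comfortable
  at the tens-to-hundreds-of-proteins scale the method is designed for,
  not for proteome-wide screens.
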