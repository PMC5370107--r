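# protminet

Unsupervised, alignment-free classification of protein sequences and 3D
structures from maximum mutual-information networks.

## The problem and the method

Classifying proteins usually means either aligning sequences and building a
phylogenetic tree (pairwise, alignment-dependent) or training a supervised
classifier (needs labels). `protminet` implements a third route: treat every
protein as a discrete time series, measure pairwise statistical dependence
with mutual information, and read the classification off the connected
components of the resulting similarity network as a filtering threshold is
swept. The method needs no alignment, no labels, and applies to sequences
and structures alike.

Concretely, for proteins *X* (length *M*) and *Y* (length *N*, *M* ≤ *N*):

1. **Encoding.** Each residue is mapped through a fixed bijection to a state
   in 1..20 (A→1, C→2, …, Y→20). For structures, backbone (φ, ψ) torsion
   angles are computed from PDB N/CA/C coordinates and binned uniformly on
   [−180°, 180°) into *K* states (default *K* = 20).
2. **Similarity.** The shorter series slides along the longer; for each
   window *Y<sub>i</sub>* the plug-in mutual information
   *I*(*X*; *Y<sub>i</sub>*) = Σ<sub>α,β</sub> *p*(α,β) log [*p*(α,β) /
   *p*(α)*p*(β)] is computed from position-paired state frequencies, and the
   pairwise similarity is the maximum over the *N* − *M* + 1 windows:
   *I*<sub>*XY*,max</sub>. Because *I*(*X*; *Y<sub>i</sub>*) ≤ min(*H*(*X*),
   *H*(*Y<sub>i</sub>*)), dividing the whole matrix by the largest
   per-protein entropy max<sub>q</sub> *H*<sub>q</sub> yields a symmetric
   adjacency matrix *a<sub>ij</sub>* ∈ [0, 1] with zero diagonal.
3. **Network and hierarchy.** For a multiplicity *c* ∈ (0, 1] the mutative
   threshold *T<sub>c</sub>* = *c* · max<sub>ij</sub> *a<sub>ij</sub>* zeroes
   all weaker edges; the connected components of what remains are the
   classes at level *c*. Sweeping *c* from 1 downward nests the components
   into a merge hierarchy (equivalent to single-linkage clustering on
   max(*a*) − *a*); the largest *c* at which two proteins share a component
   — their *merge multiplicity* — is the reported relatedness.

A matrix-power formulation is included as a cross-check: summing powers
*A*<sup>s</sup> (s = 0..N−1) of the filtered matrix gives a matrix that is
positive exactly on connected pairs, the block-diagonal reading of the
component structure. `connectivity_profile()` traces the per-pair quantity
ā(i,j) = (1/(N−1)) Σ<sub>n</sub> (A<sup>n</sup>)<sub>ij</sub><sup>1/n</sup>
across the sweep; it is positive precisely when the pair is connected.

## Worked example

Generate three synthetic families (point substitutions + indels from three
random ancestors), build the normalized network, and sweep:

```r
library(protminet)
library(dplyr)

fam <- generate_families(n_families = 3, members_per_family = 4,
                         ancestor_length = 150, seed = 11)
adj <- fam |> encode_proteins() |> build_adjacency() |> normalize_adjacency()
glance(adj)
#>       n normalized  base max_weight max_entropy n_clipped
#> 1    12 TRUE           2      0.925        4.26         0

tidy(adj) |> arrange(desc(weight)) |> head(3)
#>   id_i    id_j    weight
#> 1 fam3_m2 fam3_m3  0.925
#> 2 fam1_m1 fam1_m4  0.919
#> 3 fam1_m1 fam1_m2  0.755
```

`max_weight` 0.925 is the strongest normalized similarity (a within-family
pair, as it should be); `max_entropy` 4.26 bits is the normalizing constant,
close to the log₂ 20 ≈ 4.32 ceiling of a maximally diverse sequence.

```r
tree <- sweep_components(adj)
merge_tree_newick(tree)
#> ((((fam1_m1,fam1_m4)0.99,fam1_m2)0.81,fam1_m3)0.67,
#>  (((fam2_m1,fam2_m3)0.72,fam2_m2)0.62,fam2_m4)0.59,
#>  ((fam3_m1,fam3_m4)0.71,(fam3_m2,fam3_m3)1)0.53)0.45;

table(cut_merge_tree(tree, 0.5)$block)
#> 1 2 3
#> 4 4 4

merge_multiplicity(adj, "fam1_m1", "fam1_m2")  # 0.81 (same family)
merge_multiplicity(adj, "fam1_m1", "fam2_m1")  # 0.45 (whole network joins)
```

Internal-node labels in the Newick string are merge multiplicities: e.g.
`fam3_m2` and `fam3_m3` carry the maximal edge, so they merge at *c* = 1;
at *c* = 0.5 the partition has exactly the three true families (4 members
each); everything collapses into one component at *c* = 0.45.

`run_pipeline()` (or the `exec/protminet` command-line wrapper) runs the
same computation from a FASTA file, a set of PDB files, or a precomputed
similarity CSV, and writes the adjacency/entropy CSVs, per-threshold
partitions, filtered "colormap" matrices, merge tree (JSON + Newick) and a
run manifest. `autoplot()` methods draw the adjacency heatmap, connectivity
profiles and the component-count curve.

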