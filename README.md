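# paleohap

Damage spectra and weighted median-joining haplotype networks for ancient
mitochondrial DNA.

## The problem

Two questions dominate the analysis of mitochondrial amplicon sequences
recovered from archaeological material:

1. **Is the DNA ancient?** Post-mortem cytosine deamination systematically
   miscodes C→T (and, read on the complementary strand, G→A). Tabulating
   the twelve directed base changes between each amplicon's reads and their
   consensus, scaling for the fragment's base composition, and comparing the
   *type-2* transition class (C>T/G>A) against *type-1* (A>G/T>C) yields an
   authentication statistic: symmetric polymerase error alone gives a
   type2/type1 ratio ≈ 1, while authentic ancient templates show a clear
   excess (≈ 2:1).
2. **Where does the haplotype belong?** Aligned mitochondrial control-region
   or cytochrome-*b* haplotypes are collapsed to distinct "revised
   haplotypes" and connected by a **median-joining network**: a minimum
   spanning network augmented with inferred intermediate haplotypes (median
   vectors, the per-column majority of linked triples) that shorten the
   total connection length. Positions are weighted in inverse proportion to
   their mutation frequency (w = clamp(round(10/f), 1, 99)), so recurrent
   "hotspot" sites do not distort the topology. Branch labels identify the
   mutated positions; the minimal edge cut around a haplogroup gives its
   stem, and the stem positions mutating nowhere else in the network form
   the haplogroup's **diagnostic motif**.

`paleohap` implements both strands end to end for researchers working with
ancient mtDNA amplicon panels: a circular, insertion-aware coordinate system
(positions such as `15581.1` for an inserted column), per-clonal-group
consensus building and reference-anchored variant tables, the damage
spectrum with composition scaling, the median-joining builder with
quasi-median generation and exhaustive refinement at desk scale, network
annotation (frequencies, hotspots, motifs, placements), and synthetic-data
generators with analytic ground truth so every stage is testable offline.

## Worked example

Simulate a haplogroup-structured haplotype set with one recurrent hotspot,
build the two-pass weighted network, and read off hotspots and a
haplogroup's diagnostic motif:

```r
library(paleohap)

sim <- simulate_haplotypes(seed = 7, n_haplogroups = 3, star_size = 4,
                           stem_length = 3, n_hotspots = 1,
                           hotspot_recurrence = 3)
cl  <- collapse_haplotypes(sim$alignment)
two <- build_mj_network_weighted(cl)
glance(two$network)
#> # A tibble: 1 × 7
#>   n_nodes n_observed n_medians n_edges n_positions spanning_length epsilon
#>     <int>      <int>     <int>   <int>       <int>           <dbl>   <int>
#> 1      16         16         0      15          22             219       0

head(two$frequencies, 3)
#> # A tibble: 3 × 2
#>   position  freq
#>   <chr>    <int>
#> 1 15874        3
#> 2 15577        1
#> 3 15580        1
hotspots(two$frequencies)
#> [1] "15874"
```

The planted hotspot (15874) mutates on three independent branches and is
flagged as the frequency maximum; under the inverse-frequency map it is
down-weighted (10/3 → 3) while every single-origin position keeps weight 10.
The spanning length 219 is on the weighted scale: of the 22 variable
positions, 21 mutate once (21 × 10) and the hotspot recurs three times at
weight 3 (3 × 3), giving 210 + 9 = 219.

```r
lookup <- setNames(rep(cl$cluster_id, cl$n), unlist(cl$members))
labs   <- sim$truth$groups$label[sim$truth$groups$haplogroup == "HG2"]
infer_motif(two$network, unique(lookup[labs]), ft = two$frequencies,
            haplogroup = "HG2")
#> <motif_report> HG2: motif {15636, 15692, 15813}; stem of 3 position(s);
#>   ancestor candidate ROOT
```

The inferred motif is exactly the three stem mutations planted for that
haplogroup, and the node just outside the cut (the root haplotype) is
reported as the ancestor candidate.

Damage authentication on a simulated amplicon read pool whose lesion rate
equals its polymerase error rate (closed-form expected ratio 2):

```r
tmpl  <- paste(rep(c("A", "C", "G", "T"), 82), collapse = "")
reads <- simulate_clone_group(tmpl, n_reads = 500, delta_lesion = 0.005,
                              eps_error = 0.005, seed = 7)
glance(damage_spectrum(reads$group))
#> # A tibble: 1 × 8
#>   group_id n_reads type1 type2 ratio21 type1_raw type2_raw ratio21_raw
#>   <chr>      <int> <dbl> <dbl>   <dbl>     <int>     <int>       <dbl>
#> 1 sim1         500   422   831    1.97       422       831        1.97
```

`autoplot()` draws networks (observed clusters sized by membership, median
vectors as black dots, branches annotated with label counts) and spectra
(the twelve changes coloured by complementary pair). `run_damage()` and
`run_network()` drive both strands from a single YAML config and write
TSV/JSON/GraphML reports stamped with the config hash.

## Package layout

- `R/refcoords.R` — circular coordinates, column maps, gap policy
- `R/consensus_variants.R` — clonal groups, consensus, variant tables
- `R/damage.R` — misincorporation spectra, scaling, type ratio
- `R/mjnet.R` — collapsing, weighted distances, median-joining builder
- `R/netstats.R` — frequencies, weights, motifs, placements
- `R/synthdata.R` — generators with ground truth
- `R/pipeline.R` — YAML-configured end-to-end drivers
- `vignettes/paleohap-methods.Rmd` — the methods vignette (model,
  assumptions, parameter choices, limitations)
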