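---
title: "Methods: damage spectra and weighted median-joining networks for ancient mtDNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: damage spectra and weighted median-joining networks for ancient mtDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleohap)
```

## Scope

`paleohap` implements the two analytical strands used to authenticate and
place ancient mitochondrial amplicon sequences:

1. **Damage-spectrum authentication.** Reads from each PCR amplicon (a
   *clonal group*) are condensed into a majority consensus; the residual
   read-versus-consensus differences are tabulated as the twelve directed
   base changes, scaled for fragment composition, folded into six
   complementary pairs, and classified into type-1 (A>G/T>C) versus type-2
   (C>T/G>A) transitions. Authentic ancient templates show a marked excess
   of type 2, the signature of post-mortem cytosine deamination.
2. **Haplotype-network placement.** Pre-aligned haplotypes over a
   mitochondrial control-region or cytochrome-*b* window are collapsed into
   "revised haplotypes", connected by a position-weighted median-joining
   network, and annotated with per-position mutation frequencies, hotspot
   candidates, and haplogroup-diagnostic motifs.

Everything operates on small tabular objects (tibbles in, tibbles out), so
the stages compose with ordinary tidyverse tooling; `tidy()`/`glance()`
methods summarise fitted objects and `autoplot()` draws them.

## Coordinates on a circular reference

Mitochondrial coordinates are 1-based and closed-interval, and the genome is
circular: an amplified region may wrap through the origin, and a wrapping
interval is written `start > end` (e.g. `ref_interval(15308, 109)`).
`interval_length()` computes exact closed-interval counts; for the wrapping
region above that is `(L - 15308 + 1) + 109 = 1159` positions on the
16,357-bp reference. A published figure for this stretch rounds differently;
the package always reports the arithmetic value and never hard-codes a
printed length.

Alignment columns map to reference positions through a *column map*:
`anchor` (the reference base) plus an insertion sub-index `ins`, rendered as
keys such as `"15581"` and `"15581.1"` (first inserted column after base
15581). Insertions are anchored to the *preceding* reference base. This is a
documented convention, not something an alignment can tell you; the sidecar
TSV input (`column_index`, `anchor`, `ins_index`) makes the numbering of any
other insertion columns explicit rather than guessed.

**Gap policy.** Alignment columns containing `-` in any row are removed
before network analysis — indel-rich columns in multi-source alignments are
dominated by alignment artefacts — *except* for positions explicitly
declared as genuine indel characters (for red deer control-region data, the
insertion after 15581). An excepted column is retained as a single
multistate character with states {absent, A, C, G, T}, so an insertion
carrying T in one lineage and G in another counts as two distinct derived
states. `N` is missing data, never grounds for column removal, and never
contributes to distances.

## Consensus and variant tabulation

`build_consensus()` takes the per-column majority among non-N read states;
sequencing depth is the non-N count. Ties between bases default to the IUPAC
ambiguity code (`tie_rule = "ambiguity"`) — deliberately *not* the reference
base, which would bias ancient consensus sequences toward the modern
reference; `tie_rule = "reference"` is available where comparability with
reference-guided callers matters. A tie between a base and a gap resolves to
the base (an observed base is positive evidence; a gap is absence).

`call_variants()` emits one record per consensus/reference difference —
substitution, insertion (`anchor.k`), or deletion — in reference numbering
even across the origin wrap, so position 108 can sit in the same table as
position 16,263. Ambiguity codes compatible with the reference produce no
record; incompatible ones are *reported separately*, never coerced into a
substitution call. `apply_variants()` inverts the tabulation, which gives the
suite its round-trip invariant: reference + records reconstructs the
consensus exactly.

## The damage model

For a clonal group with consensus fixed, every read cell that is a base
differing from the consensus base increments one of the 12 directed changes;
cells that are `N` or `-`, and columns whose consensus is not an unambiguous
base, are excluded (indels are not part of the spectrum).

**Composition scaling.** A fragment with few G/C sites offers fewer
opportunities for C>T/G>A changes. With `r = (A+T)/(G+C)` computed from the
consensus over the analysed columns, counts whose *origin* base belongs to
the underrepresented class are multiplied up: C/G-origin changes by `r` when
G+C < A+T, A/T-origin changes by `1/r` when A+T < G+C, and nothing otherwise.
Only the underrepresented origin class is ever scaled.

**Type ratio.** `type1 = A>G + T>C`, `type2 = C>T + G>A` (scaled), and the
pooled `type2/type1` ratio across groups is the authentication statistic; a
ratio near 2 is typical of ancient templates while symmetric polymerase error
alone gives 1. Whether published ratios are computed on scaled or raw counts
is often unstated, so `type_ratio()` reports both (`ratio21`,
`ratio21_raw`); with the read simulator's uniform per-site model the two
coincide in expectation on a balanced template. The ratio is undefined when
the pooled type-1 class is zero; it is then flagged (`ratio_defined =
FALSE`), never imputed.

The simulator (`simulate_clone_group()`) draws reads independently: per site,
each wrong base with the symmetric polymerase rate ε, plus δ added to C>T
and G>A (deamination lesions on both strands), plus an optional N-masking
rate. The lesion is uniform along the read — the analysis is
position-agnostic, so end-enrichment would add realism without changing what
is being estimated; consequently the package neither models nor tests 5'/3'
damage curves. The closed-form expectation `expected_ratio21()` applies the
same composition scaling to the expected counts, and `δ = ε` on a balanced
template gives exactly 2. Estimator checks in the test suite use 20
replicates of 300–500 reads over ~330-bp templates; the acceptance script
uses 20 × 500.

## Median-joining networks

Distinct haplotypes are first collapsed over the variable columns of the
analysed window (`collapse_haplotypes()`). Under the default *permissive*
missing-data mode an `N` matches any base and clusters are formed greedily in
input order, back-filling representatives — matching common network-software
practice; *strict* mode requires byte-identical vectors. Greedy permissive
merging is order-dependent in principle (N-compatibility is not transitive),
which is why the mode is explicit and the strict alternative exists.

`build_mj_network()` implements the median-joining scheme over the weighted
Hamming distance (missing contributes 0; the indel character is an ordinary
fifth state; weight 0 silences a column):

1. **Feasible links.** The ε-relaxed minimum spanning network: a pair is
   linked iff its distance is within ε of the level at which single-linkage
   agglomeration first joins their components. ε = 0 gives exactly the union
   of all minimum spanning trees; raising ε only ever adds links.
2. **Median generation.** For every triple with at least two feasible links,
   the per-column majority vector; columns with three distinct states expand
   into all *quasi-medians* (bounded, deterministic), which is what lets the
   three-state indel character resolve correctly. Minimal-connection-cost
   candidates (within ε) are added and the loop repeats to a fixed point.
3. **Pruning.** Synthetic nodes whose removal does not lengthen the minimum
   spanning tree over the node set are deleted; survivors are load-bearing,
   with degree ≥ 3.
4. **Refinement (small node sets).** While the node set stays within
   `refine_limit` (default 15) nodes, a deterministic deepening phase runs:
   strict-improvement greedy over the quasi-medians of *all* triples,
   alternated with pruning, escaping plateaus by provisionally adding one or
   two near-neutral medians and keeping the result only if it strictly
   shortens the network. On genealogy-structured instances with ≤ 5
   haplotypes and ≤ 8 variable sites this reaches the exact Steiner minimum
   (verified against a Dreyfus–Wagner enumeration in the test suite and the
   acceptance script).

The output is deterministic for a given input ordering: candidate medians
are processed in lexicographic state order and surviving medians renumbered
canonically. Edges are labelled with exactly the positions at which their
endpoints differ. `spanning_length` — the minimum spanning tree total over
the final node set — is the scalar the oracle comparisons use.

**What is guaranteed and what is not.** Median joining is a heuristic. The
refinement phase makes it exact on the small, genealogy-structured instances
the oracle tests draw (copy-and-diverge with recurrent-site toggles, the
regime real haplotype samples live in), but uniform-random haplotype sets —
mutation at up to every site independently — can require chains of mutually
dependent median vectors that stepwise search will not assemble; the
maximum-parsimony post-processing offered by the Network software for such
cases is deliberately out of scope here. Epsilon defaults to 0, the minimal
reproducible network.

**Weights.** Positions are weighted in inverse proportion to their mutation
frequency, on the conventional integer scale: `w = clamp(round(scale / f),
1, 99)` with `scale = 10`; unobserved positions keep the full scale. Because
frequencies require a network and the weights require frequencies,
`build_mj_network_weighted()` runs the minimal consistent procedure: a
unit-weight pass, frequency extraction, then the weighted pass. Frequencies
are computed on the unweighted first pass by default; both passes are
returned so the choice is inspectable.

## Network annotation

*Mutation frequency* of a position is the number of branches (edges,
including median-incident ones) whose label set contains it; the maxima are
hotspot candidates. The table total always equals the total label count over
edges (a test invariant).

*Motif inference* (`infer_motif()`): the stem of a haplogroup is the minimal
edge cut separating its nodes from the rest (unit edge capacities; median
vectors fall on whichever side the cut dictates); stem positions carry their
network-wide frequencies, and the *motif* is the frequency-1 subset — the
positions unique enough to be diagnostic. The observed node just outside the
cut, nearest to the haplogroup, is reported as the ancestor candidate.
Haplogroup membership is an *input* (labels or node ids): assigning
haplogroups is prior knowledge, not something this package infers. When the
minimal cut strands foreign observed nodes with the haplogroup or leaves the
haplogroup side disconnected — the signature of a reticulate region — the
function raises a topology error instead of guessing, because diagnostic
mutations cannot be read off an unresolved reticulation.

*Placement* (`cluster_distance_report()`) reports the shortest weighted
path, its branch labels and the total label count between two nodes, the
quantity used to describe how far apart two haplotypes sit (e.g. counting
the differences separating two deeply diverged haplogroup representatives).

## Synthetic data and what passing tests show

`simulate_haplotypes()` emulates the structure the network analysis
consumes: star-shaped haplogroups (founder + single-mutation tips) joined to
a root by multi-mutation stems, optional hotspots recurring on one tip
branch in each of several haplogroups, and an optional three-state insertion
column carried by one haplogroup. Defaults (3 haplogroups × 4 tips, stem
length 3, 327-column alignments starting at anchor 15,573) mirror the shape
and scale of control-region haplotype sets in the red deer literature while
staying desk-sized. The default is a perfect phylogeny — every mutated
position unique — so collapse counts, network length (= planted mutation
events), hotspot frequencies and motifs are exactly predictable; hotspots
are opt-in homoplasy. `simulate_genealogy_matrix()` generates the small
random instances for oracle comparisons (random copy-and-mutate genealogies
with an 80% biallelic-toggle rule, ≤ 5 haplotypes, ≤ 8 sites).

What the generators do *not* emulate — and therefore what green tests do not
certify about real data: alignment error, 454 homopolymer indels,
contamination, position-dependent damage, rate heterogeneity beyond the
planted hotspots, and sampling bias across haplogroups. The pipeline's
behaviour on real alignments still depends on the quality of the input
alignment and of the prior haplogroup assignments.

## Numerical and design choices

- Consensus ties: IUPAC by default; reference-tie and base-over-gap rules as
  stated above. Median ties: full quasi-median expansion, capped at 64
  combinations per triple (beyond the cap, first-listed states are taken
  deterministically).
- Integer weights on a 1–99 scale; `scale/f` rounding uses R's default
  half-to-even.
- Determinism: all generators take seeds and restore RNG state
  (`withr`); pipeline reports embed a config hash (`rlang::hash`) and
  re-running a config reproduces reports byte for byte.
- Degenerate inputs raise typed errors rather than returning empties:
  empty read groups, < 2 clusters, non-covering weights, out-of-range
  anchors, non-separable haplogroups.
- Problem sizes in the shipped tests and acceptance script (100 oracle
  instances, 20-replicate damage recovery at 500 reads, ~16-node synthetic
  networks) were chosen as the smallest sizes at which the estimators'
  sampling error is clearly below the effects being tested.

## Interfaces

FASTA in (aligned haplotypes, per-group reads; column maps from an in-file
reference row or a sidecar TSV), TSV/JSON/GraphML out. `run_damage()` and
`run_network()` drive the two strands end to end from a single YAML or list
config; `write_fixture_bundle()` emits a self-contained synthetic dataset
with machine-readable ground truth. These functions, rather than a shell
executable, are the package's pipeline interface — the natural shape for an
R analysis library.

## Known limitations

- Median joining is exact here only at desk scale; large reticulate datasets
  get the heuristic network, and motif inference will (correctly) refuse
  reticulate haplogroups such as a densely sampled western-lineage cluster.
- No read mapping, no quality scores, no UDG-treatment or end-curve damage
  modelling, no statistical test on the type ratio or the motifs beyond the
  frequency-1 rule.
- Permissive collapsing is greedy; pathological N patterns can depend on
  input order (use strict mode when that matters).
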