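---
title: "Methods: from MAGs to wild-plant key species, exclusive features, and strain sharing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from MAGs to wild-plant key species, exclusive features, and strain sharing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wildgut)
```

wildgut implements the analysis chain used to compare gut microbiomes of
populations along a forager-to-farmer lifestyle gradient — for example a
forest-camp foraging group, a settled group of the same community, and a
neighboring farming village — and to isolate the subset of microbial
species tied to wild-plant food degradation. This vignette explains each
stage's model, its assumptions, the tunable parameters, and the design
choices made where conventions genuinely diverge.

## From MAGs to species-level genome bins

Metagenome-assembled genomes (MAGs) arrive as a quality table
(CheckM-style completeness and contamination percentages) plus pairwise
genome distances. `qc_filter()` retains genomes with completeness
strictly above 50% and contamination strictly below 5%; the bounds are
strict because the conventional phrasing of the rule ("above", "lower
than") excludes the boundary, and a genome at exactly 50% completeness is
removed.

`dereplicate()` clusters the survivors by single linkage at a distance
threshold of 0.05 — clusters of MAGs spanning 5% genetic diversity, the
conventional operational species boundary — which is exactly the
connected components of the graph joining genome pairs at distance
≤ 0.05. Within a cluster the representative maximizes the quality score

$$Q = \text{completeness} - 5 \times \text{contamination},$$

the standard dereplication scoring family, with ties broken by larger
genome size and then lexicographically smaller MAG id so that results are
deterministic. The distance backend is pluggable: a precomputed matrix,
or the built-in `sketch_distance()`, a Mash-style k-mer sketch estimate
$d = -\tfrac{1}{k}\ln\frac{2j}{1+j}$ (Jaccard index $j$, default
$k = 21$), capped at 1. Alignment-coverage filters used by two-stage
dereplication pipelines have no analogue in a sketch-only backend and are
intentionally out of scope.

## Community structure

`unifrac()` computes phylogeny-aware sample dissimilarities over a rooted
SGB tree. The unweighted variant is the branch length unique to one
sample's presence set divided by the branch length covered by either
sample — a Jaccard distance on the branch-length measure, and a true
metric. The weighted variant is the *normalized* form
$\sum_b \ell_b\,|p_A(b)-p_B(b)| \;/\; \sum_b \ell_b\,(p_A(b)+p_B(b))$
with $p$ the branch-subtended relative abundance. Normalization bounds
it by 1 and makes it comparable to the unweighted variant, but the
normalizer depends on the sample pair, so the weighted form is a
dissimilarity, not a strict metric: small triangle-inequality violations
are possible and the test suite asserts metric axioms only for the
unweighted variant. Proportional samples always have weighted distance
exactly 0.

`pcoa()` is classical scaling of the double-centered squared-distance
matrix; axes with negative eigenvalues (a normal occurrence for
non-Euclidean dissimilarities) are reported in the eigenvalue vector but
dropped from the coordinates.

`permanova()` implements the distance-based pseudo-F ratio
(one-way, Anderson's formulation): $SS_{total}$ from all squared
pairwise distances divided by $n$, $SS_{within}$ from within-group
pairs, and significance by label permutation with the add-one correction
$p = (1 + \#\{F^\pi \ge F\})/(1 + n_{perm})$, so a permutation p-value
is never exactly zero and the smallest attainable value at the default
$n_{perm} = 999$ is 0.001. The permutation count is a configuration
parameter because no universal convention exists; 999 is the common
default of the R ecosystem's distance-based tests. When within-group
distances are all zero the pseudo-F ratio is undefined and the function
stops rather than reporting an arbitrary number. An explicit permutation
matrix can be supplied for exact tests by full enumeration; in that mode
the p-value is the plain fraction of permutations (identity included)
reaching the observed statistic.

`kruskal_wallis_per_sgb()` applies the tie-corrected Kruskal-Wallis test
per SGB with Benjamini-Hochberg q-values over all tested SGBs. An SGB
constant across samples carries no rank information and is assigned
p = 1 by convention. For exactly two groups the Kruskal-Wallis ranking
is equivalent to a Wilcoxon rank-sum test up to the tie convention, so
two-group comparisons (cluster abundance, module abundance) reuse the
same machinery with the convention fixed to KW-with-ties; where the
package reports "rank-sum" p-values for group pairs it uses the
Wilcoxon form directly.

## Co-abundance network

Network construction starts from `abundance_filter()` (default: at least
10 gcpm in at least 2 samples, the usual gate before correlation
estimation), then `kendall_tau_matrix()` computes tie-corrected Kendall
tau-b for every SGB pair; the rank basis makes the network robust to the
heavy-tailed abundance scale. Constant SGBs have undefined tau and are
recorded as 0 with a warning rather than dropped, keeping the matrix
complete.

`cluster_sgbs()` cuts an average-linkage dendrogram on `1 - tau`
(default: 7 clusters, the granularity at which such cohort networks are
usually summarized); SGBs are sorted lexicographically before clustering
so the partition is invariant to input order. `build_graph()` keeps
edges with $|\tau| \ge$ `abs_tau_min` (default 0.3) and records their
sign; signs are reporting metadata only — `centralities()` treats the
graph as undirected and unweighted because no signed-path semantics is
standard for connectivity metrics, and computes centralities on the full
graph rather than per cluster. Closeness uses the per-component form
with the Wasserman-Faust component-size correction
$\frac{n_c-1}{\sum d}\cdot\frac{n_c-1}{n-1}$ (isolated nodes score 0),
and betweenness is normalized by $(n-1)(n-2)/2$, so both lie in [0, 1].

`keystone_call()` labels a taxon keystone when closeness, betweenness,
and degree all reach their thresholds *and* mean abundance exceeds
50 gcpm. Only the abundance gate has a stated field convention (">50
normalized genome copies per million reads"); the centrality cut-offs
(defaults 0.45, 0.02, 20) are configuration parameters chosen to sit
just below the centrality profiles typical of keystone taxa in cohorts
of this structure, and every threshold is tunable.

## Metabolic key species

Genome-scale metabolic models are consumed as boolean reaction networks:
a reaction fires when all substrates are reachable, adding its products.
This topological ("network expansion" / scope) semantics matches the
reachability formalism of microbiome-scale metabolic complementarity
tools, avoids stoichiometric assumptions the input cannot support, and
is exactly testable. Reversible reactions are encoded by listing both
directions. `scope()` iterates to the fixpoint; it is monotone in both
seeds and community, and idempotent.

For each plant substrate profile (seed compounds → target degradation
products), `minimal_communities()` first determines which targets the
*full* community can produce, then enumerates the inclusion-minimal
species subsets (up to `max_size = 8`) whose scope still covers them.
Species in every minimal community are *essential*; species in some but
not all are *alternative*. Two exactness devices matter here:

* **Relevance pre-filter.** Only species with at least one reaction
  firing during the full-community expansion can affect any subset's
  scope (expansion is monotone in the community, so a reaction that
  never fires under the full community never fires under a subset).
  Candidates are restricted accordingly, which keeps the enumeration
  exact and small even in cohorts with hundreds of species, because the
  degraders of any one substrate are few.
* **Exhaustive cutoff.** When more than 20 candidates survive the
  filter, a greedy deletion heuristic (with single-species replacement
  probes) stands in for the enumeration and the result is flagged
  non-exhaustive with a warning.

`wp_module()` unions the per-plant key species. "Involved in the
metabolism of at least one plant" is read as essential ∪ alternative —
an interchangeable degrader is still involved — with
`essential_only = TRUE` available for the stricter reading.
`module_abundance_test()` then compares the module's cumulative
abundance between groups with rank-sum tests.

## Exclusive features and prevalence

`exclusive_genes()` returns genes present in at least one module SGB,
absent from *every* SGB outside the module, and annotated in a
screen-relevant category (defaults: carbohydrate-active and
xenobiotic-degradation annotations, the categories relevant to
degradation of plant polysaccharides and phytochemicals).
`rpkm()` normalizes read-mapping counts by feature length and
sequencing depth (reads per kilobase per million mapped reads), and
`prevalence()` averages presence per population panel. The presence
threshold defaults to 0 RPKM — any aligned read counts as presence —
because no cut-off convention is stated for such screens; the threshold
is configurable and the raw RPKM matrix is always emitted alongside the
binary calls, so users can apply their own. `bgc_prevalence()` is the
identical computation for biosynthetic gene cluster panels with an
additional per-product-class summary.

## Strain sharing

Strain-level analysis runs on eligible SGBs
(`select_eligible_wpsgbs()`: at least 5 MAGs, and abundance strictly
above 5 gcpm in at least one sample of *each* of the two groups being
compared). Marker genes (`select_markers()`) are core genes exclusive to
the SGB for which at least 90% of the SGB's MAGs map with coverage
strictly above 50% of the gene length — the inclusive/strict mix follows
the phrasing of the rule ("at least 90%", "covering >50%").

The normalized phylogenetic distance `ngd()` is the leaf-to-leaf path
length divided by the total branch length of the marker tree, a
pseudometric bounded by 1. `calibrate_threshold()` scans the midpoints
of the sorted pooled related/unrelated nGD values and picks the
threshold maximizing Youden's J = sensitivity + specificity − 1 subject
to at most 5% of unrelated pairs falling at or below it; the bound is
applied as a constraint on the unrelated-pair acceptance fraction (the
"false-sharing rate"), which is how the 5%-of-unrelated rule functions
as a false-discovery bound. Ties favor the smaller threshold (the more
conservative call), and the false-sharing fraction is computed by direct
counting rather than `1 - specificity` so that thresholds sitting
exactly at the bound are kept. `call_sharing()` declares sharing at
nGD ≤ threshold — inclusive, since the threshold is defined as the
maximal accepted distance. The unrelated background is supplied as
data (or synthesized); no external cohort is downloaded.

## The synthetic cohort generator

`gen_cohort()` and its companions generate data with the statistical
structure the pipeline assumes, plus the ground truth to score it:

* **Abundances** are log-normal with multiplicative group effects — the
  simplest model producing the rank-based signals the nonparametric
  tests consume. Defaults mirror the field-cohort scale: 161 SGBs over
  16 + 10 + 18 samples in three ordered groups. The between-species
  spread (`species_sd = 3` on the log scale) and the detection floor
  (`detection_limit = 5` gcpm, below which values are recorded as 0)
  are set so the table shows the heavy-tailed rank-abundance and
  presence/absence structure of real SGB tables, with roughly a tenth
  of SGBs too rare to pass the 10-gcpm network gate. Samples are closed
  to a constant total (1e6) to mimic per-million normalization.
* **Planted signals**: six gradient SGBs change monotonically across
  the ordered groups (half increasing toward the forest end, half
  decreasing; default log(3) per group step), and a 26-SGB module is
  shifted up toward the forest end (log(2) per step). Planted SGBs
  draw their baselines from a moderately abundant stratum because the
  differential taxa reported in such cohorts are detectable taxa; a
  planted signal carried by an SGB absent from most samples would be
  ground truth in name only.
* **Pangenomes** (`gen_pangenome()`) plant module-exclusive annotated
  genes (default 29); any *background* gene that happens to carry a
  screen-relevant annotation is forced to appear outside the module, so
  the planted set is exactly the screen's ground truth.
* **Metabolic networks** (`gen_networks()`) plant one cross-feeding
  degrader guild per plant profile; distractor reactions live in a
  disjoint metabolite namespace whose substrates are never reachable,
  and generation *audits* both properties (guild completes its chain;
  community minus guild does not) before returning. Default guild
  sizes in the full pipeline total 26 species over five plant profiles,
  with one redundant step giving an essential/alternative mix.
* **Strain pairs** (`gen_strain_pairs()`) draw related and unrelated
  nGD values from truncated normals (defaults 0.01 ± 0.005 and
  0.5 ± 0.1) and build, per pair, a three-leaf marker tree realizing
  the drawn value exactly: a cherry $(a{:}x, b{:}x)$ with
  $x = g/(2(1-g))$ beside one unit of outgroup branch gives
  $\mathrm{nGD}(a,b) = g$. Reported nGDs are recomputed from the trees.

Every generator is a pure function of its spec, including the seed.

What passing tests on these data do **not** show: the generator has no
phylogenetic signal in abundances (the tree is an independent
coalescent), no compositional correlation structure beyond closure, no
read-level noise, and its group effects are clean multiplicative shifts.
Recovery results on synthetic cohorts therefore demonstrate the
correctness of the machinery, not the effect sizes or p-values to be
expected from field data — community-level separation (the pseudo-F
p-value) in particular varies freely across seeds because the planted
module is placed on random tree branches.

## Problem sizes and numerical choices in the test suite

The test suite checks every statistic against an independent
brute-force oracle (pair counting for tau-b, the rank formula for the
Kruskal-Wallis H, the step-up definition for Benjamini-Hochberg,
exhaustive permutation enumeration for the pseudo-F test on 4–6
samples, powerset enumeration for minimal communities up to 8 species,
BFS shortest paths for centralities, a naive repeat-until-stable
expansion for scope, and a full midpoint scan for the Youden
threshold). Property tests run on 100–200 randomized instances per
invariant; the null-calibration check uses 100 cohorts of 40 SGBs ×
24 samples; the end-to-end determinism check runs a reduced pipeline
(50 SGBs, 17 samples) twice and compares outputs byte for byte. These
sizes were chosen so each oracle remains exact while the whole suite
runs in well under a minute per file.

## Known limitations

* Dereplication is single-linkage on one distance source; the two-stage
  (sketch-then-alignment) pipelines with coverage filters are out of
  scope, so chaining across borderline pairs can merge clusters that an
  alignment-coverage filter would split.
* The weighted UniFrac variant is the normalized dissimilarity (see
  above); users needing a strict metric should use the unweighted
  variant or the raw (unnormalized) weighted form of other toolkits.
* The boolean expansion ignores stoichiometry, cofactor balance, and
  flux feasibility; a reachable target is necessary, not sufficient,
  evidence of degradation capacity.
* Above 20 relevant species per profile the minimal-community search is
  heuristic and may miss alternative communities (always flagged).
* The permutational test is one-way; no strata or covariates.
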