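---
title: "Two-phase consensus mapping: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-phase consensus mapping: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syncmap)
```

## The problem

Different labs map the same chromosome with different crosses and partly
different marker panels. Markers genotyped in two or more populations
(*shared* markers) tie the maps together; markers genotyped in one
population (*unique* markers) can only be placed relative to the shared
anchors. Because recombination rates differ between populations and all
estimates are noisy, the per-population maps typically disagree about the
order of some shared markers. `syncmap` re-analyzes the *raw genotype
data* of all populations jointly and returns per-population maps that all
embed a single consensus order of the shared markers.

## Criterion

For each population $i$ with weight $w_i$, let $S_i$ be the sum of
recombination fractions between adjacent markers along its map. A
consensus order $g$ of the shared markers is scored by

$$S(g) \;=\; \sum_i w_i \min_{u_i} S_i\bigl(g(i), u_i\bigr),$$

where the inner minimum is over placements $u_i$ of population $i$'s
unique markers around the anchors $g(i)$ (the projection of $g$ onto the
markers of population $i$). Minimizing $S$ subject to "shared order for
shared markers" is an anchor-constrained, multi-map generalization of the
traveling-salesperson formulation of single-population marker ordering —
a *synchronized TSP*. The cheap *skeleton criterion*
$S_\mathrm{shared}(g) = \sum_i w_i S_i(g(i))$ scores $g$ on shared
markers alone and is used as a pre-screen.

Units: the criterion is a plain sum of recombination fractions (no
mapping function); reported lengths are $100 \times \sum r$ cM. This is
consistent with how per-population map lengths behave additively in the
worked examples, and avoids committing to Haldane or Kosambi for a
quantity that is only ever compared, never interpreted as physical
distance. A map and its reversal are the same solution; all comparisons
orientation-align first (maximize concordant shared pairs; ties keep the
first map's orientation).

## Phase 1 — per-population ordering

Pairwise recombination fractions come from cross-specific two-point
estimators: direct counts for BC, numerical maximum likelihood on the
3×3 joint genotype table for codominant F2 (golden-section search on
[0, 0.5]; the double-heterozygote class mixes the two phases), and the
inversion $r = R/(2(1-R))$ of the selfing-RIL discordance expansion.
Pairs with fewer than `min_informative` (default 10) informative
individuals are flagged unreliable and imputed by the smallest two-hop
sum so the criterion always sees a complete matrix.

Ordering is an open-path TSP over that matrix: exact Held–Karp dynamic
programming up to 16 markers, otherwise an evolution-strategy heuristic
(greedy construction, 2-opt + Or-opt local search, iterated
segment-reversal/translocation perturbations). Jackknife resampling
(default 20% of individuals dropped, 100 replicates, neighbor-match
scoring, instability threshold 0.7 — the resampling protocol is our
declared concrete choice, exposed in the configuration) scores order
stability. The skeleton filter then removes markers that are absolutely
linked (rf 0) to a retained marker, violate monotone growth of
recombination with up to four subsequent neighbors (tolerance twice the
binomial standard error — window and tolerance are our choices, the rule
itself is standard skeleton-mapping practice), or are unstable. In
consensus mode only unique markers are removed under these rules; a
shared marker is dropped only when absolutely linked to another shared
marker, keeping as many anchors as possible. After filtering, the map is
re-optimized on the retained markers so the reported individual length
is the skeleton's own optimum.

## Phase 2 — conflicts and synchronized ordering

Pairwise conflicts are shared-marker pairs appearing in opposite order
in two (orientation-aligned) maps; higher-order conflicts are cycles in
the union precedence graph and are absorbed into the same regions.
Before conflict resolution, a pre-correction pass handles gross
artifacts: a map segment sitting beyond a large interval (adjacent rf at
or above 0.3, matching the magnitude where such artifacts were observed)
is tentatively reversed (inversion) or relocated (transposition); the
move is kept only if it strictly reduces the total conflict count while
inflating that map by at most 0.02 (criterion units). Both thresholds
are configuration parameters.

Conflicts are merged transitively into *conflict regions*: a region's
window in each map sweeps in every marker lying between its conflicting
markers, and its boundaries extend outward to the nearest
*non-conflicting* shared marker (conflict markers encountered on the way
join the region, merging regions that would otherwise abut — boundaries
are always conflict-free, except that a region reaching the end of the
linkage group has a free end there). We prefer shared markers as flanks,
absorbing intervening unique markers into the region, so the frozen
boundary is the same marker in every population. Flanks stay frozen
while the region is solved, and the flank edges are included in the
region cost so candidate orders are comparable.

### Exact region solver

For a region with $k$ shared markers and $n_i$ unique markers in
population $i$, stage 1 tabulates, per population, the optimal path
$a \to T \to b$ for every anchor pair and every subset $T$ of unique
markers ($2^{n}((k+2)(k+1)/2-1)$ entries), by a subset dynamic program
over (subset, last marker) states. Stage 2 enumerates the $k!$ shared
orders; for each, the best assignment of unique markers to the $k+1$
intervals is a subset-partition dynamic program over the stage-1 table —
equivalent to, and tested against, enumerating all $(k+1)^n$
assignments. The result is the global constrained optimum. Feasibility
follows the $k+n<15$ (and $k,n<11$) caps; additionally the pipeline
hands a region to the heuristic when the stage-2 combination count
exceeds `exact_budget` (default $2\times10^5$), a computational budget
chosen so a single region solves in well under a second. Ties between
equal-cost shared orders go to the order closest to the phase-1 maps
(fewest discordant pairs), then lexicographic — determinism matters for
reproducibility.

### Guided evolution strategy

Oversized regions, and the optional whole-chromosome polish, use a
guided evolution strategy. A multi-parametric generator mutates the
incumbent shared order with segment reversal, segment translocation and
point exchange; rates and (geometric) segment-length laws are the six
generator parameters, and mutation sites can be biased toward positions
flanked by long intervals, where order confidence is lowest. Each mutant
is screened by $S_\mathrm{shared}$ against a learned threshold $q$; only
survivors are evaluated fully, by placing each population's unique
markers around the anchors — optimally (subset-partition DP) when a
population has at most 6 unique markers, otherwise by cheapest insertion
followed by three anchor-preserving moves (reinsert, reinsert-reversed
run, exchange of two unique markers). After every accepted improvement
$q$ is recomputed as the largest $S_\mathrm{shared}$ among the five best
recorded $(S_\mathrm{shared}, S)$ pairs, inflated by a 2% margin; the
update rule is our concrete instantiation of threshold learning and is
isolated behind the threshold state so it can be swapped. The incumbent
criterion is non-increasing by construction, and every returned solution
embeds one shared order everywhere, hence is conflict-free.

## Weights, cost of consensus, and diagnostics

Weights default to 1. The `inverse_length` mode sets $w_i = 1/L_i$ from
the phase-1 lengths, down-weighting noise-inflated populations — useful
as a second round once individual lengths are known. The *cost of
consensus* report compares each population's individual (phase-1) length
with its post-consensus length; the difference is attributed per marker
as half of each incident adjacent-interval change, so attributions sum
to the total. Datasets inflated beyond `high_cost_cM` (default 10 cM;
single-digit differences are routine, tens of cM are not) are flagged,
and `suggest_removals()` re-solves the affected regions with each
candidate marker removed (pairs of top candidates when no single removal
suffices), ranking proposals by the inflation they recover — proposals
are never applied automatically.

The *integral map* is a directed graph over all markers: each population
contributes its consensus chain with per-population distances. Unique
markers from different populations falling between the same pair of
shared flanks have no cross-population order information; they stay as
parallel branches (a *loop*) rather than being forced into a linear
order, and distances are never averaged across populations. Export is
GraphML/DOT via igraph.

## The simulator

`make_problem()` generates the study conditions the method was described
under: single-chromosome panels of F2/BC/RIL populations; 50 markers
with interval lengths drawn 75% from U[1, 4] cM and 25% from U[4, 20] cM;
meiosis without crossover interference (per-interval recombination
probability from the Haldane function; RIL genotypes drawn directly from
the fixed-line distribution with $r_\mathrm{RIL} = 2r/(1+2r)$, which is
marginally equivalent to iterated selfing and far cheaper); independent
per-cell missingness; and misclassification restricted to a
locus-by-individual stratum with the standard transitions (H scored as
either homozygote with 5% each; each homozygote scored H with 10%).
Shared markers are named `mar<k>`, unique markers `mar<k>_<i>` with the
population index, and the generator emits the true order for recovery
scoring. What it does not emulate: crossover interference (a hook exists
but no interference model is implemented, since the reference conditions
state none), segregation distortion, dominant markers, and
non-independent missingness — so green tests say nothing about those
features of real data.

## Numerical choices and degenerate inputs

Recombination fractions are clamped to [0, 0.5]; RIL discordance at or
above 2/3 clamps to 0.5 with a warning. Markers with no scores are
excluded with a warning; a dataset with fewer than two shared markers is
excluded from consensus with a warning. Absolute ties in ordering are
broken by orientation normalization (first marker name sorts before the
last) and lexicographic order, purely for determinism. All randomized
components take explicit seeds.

## Problem sizes used in the tests

The test-suite simulations use 8 populations × 50 markers × N = 100 for
the mixed clean/noisy panels (10 seeds), 50 smaller panels
(4 × 15 × 80) for the conflict-free guarantee, 200 random constrained
regions (against exhaustive enumeration) for the exact solver, and 50
seeded GES runs against the exact optimum — sizes we consider
representative while keeping a full run at desk scale.

## Known limitations

* Two-point estimates bound what ordering can resolve: in clean F2
  panels of 50 markers at N = 100, the criterion optimum differs from
  the true order by one or two local swaps of 1–4 cM neighbors in
  roughly a third of populations. These are genuine optima of the
  two-point criterion, not solver failures (the heuristic matches the
  exact dynamic program on such instances); multipoint likelihood
  distances, which would sharpen local order, are deliberately out of
  scope. Consensus over several populations corrects most of these
  local deviations — that is, in fact, the method's selling point.
* The exact solver's guarantees hold per region; the stitched whole
  chromosome is globally optimal only when regions are truly
  independent, which the frozen-flank construction enforces by design.
* GES is a heuristic: on exactly solvable instances it attains the
  optimum in ≥90% of seeded runs and never undercuts it, but no
  worst-case guarantee exists.

## A short example

```{r example, eval = FALSE}
noisy <- noise_spec(missing_rate = 0.2, error_locus_fraction = 0.75,
                    error_individual_fraction = 1)
prob <- make_problem(n_markers = 50, n_datasets = 8, n_individuals = 100,
                     noise = c(rep(list(noise_spec()), 4),
                               rep(list(noisy), 4)),
                     shared_fraction = 0.7, rng_seed = 11)
fit <- consensus_map(prob, control = syncmap_control(seed = 5))
summary(fit)
recovery_coefficient(fit, attr(prob, "ground_truth"))
plot(fit)
```
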