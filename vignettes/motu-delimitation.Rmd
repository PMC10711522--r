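---
title: "Validating DNA barcode reference libraries with motuforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating DNA barcode reference libraries with motuforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motuforge)
```

## The problem

A DNA barcode reference library couples short standardized marker
sequences (here, ~652 bp of mitochondrial COI) with expert species
identifications, so that later specimens can be identified by sequence
alone. Before a library can be trusted it has to be validated: do the
named species form tight, mutually separated sequence clusters (a
"barcode gap"), and do data-driven cluster definitions (molecular
operational taxonomic units, MOTUs) agree with the morphological
species? Disagreements are themselves informative - a species whose
sequences fall into two deep clusters is a candidate cryptic-diversity
case, while two species sharing one cluster flag either recent
divergence or misidentification.

motuforge implements this validation workflow end to end: distance
computation, barcode-gap records, four independent MOTU delimitation
algorithms, a majority-rule consensus with a conflict report, sequence
accumulation curves, and a sequence simulator with known truth against
which every stage of the pipeline is benchmarked.

## Distances

Pairwise divergences use the Kimura 2-parameter model,
$$d = -\tfrac{1}{2}\,\ln\!\big((1-2P-Q)\sqrt{1-2Q}\big),$$
with $P$ and $Q$ the proportions of transition and transversion
differences over the jointly resolved sites. Sites where either
sequence carries a gap, an `N` or any other IUPAC ambiguity code are
excluded pair by pair (pairwise deletion), which maximises the usable
sites per comparison and is the standard choice for barcode data. When
the logarithm's argument is non-positive (saturation) the cell is
undefined: such cells are excluded from all summaries (with a count
kept in the matrix attributes) and imputed with the matrix maximum
before tree building, where a complete matrix is required.

Per species, `speciesGapTable()` records the maximum intraspecific
distance (undefined for singletons), the nearest-neighbour distance to
any other labelled species, their ratio (only when the denominator is
positive), and whether a barcode gap is present on an individual
basis. Rank-level pools (`rankSummaries()`) are mutually exclusive by
default - conspecific pairs, heterospecific congeneric pairs,
heterogeneric confamilial pairs - because published summary tables are
ambiguous on this point, an inclusive variant (each level containing
the ones below) is emitted side by side.

## Delimitation algorithms

Four algorithms with quite different assumptions delimit MOTUs; their
disagreements are the interesting output, which is why the consensus
stage exists.

**Threshold single-linkage (`slcCluster()`).** Connected components of
the graph joining sequences at distance <= 2.2%, the seed threshold
used by BIN-style barcode registries. The registry algorithm itself is
proprietary, so this is an explicit stand-in labelled `SLC`. An
optional refinement pass cuts each component at its widest internal
single-linkage gap and keeps the split when the mean silhouette width
reaches 0.5; it is off by default because coalescent clusters have
genuine internal structure and a permissive silhouette bar would shred
true species.

**Hierarchical distance partitioning (`asapPartitions()`).** Candidate
partitions are the single-linkage merge levels. Each candidate gets
(i) a hazard-type panmixia probability for the first merge it
declines: within panmictic groups, single-linkage join heights
accumulate without large multiplicative jumps, so under a memoryless
null whose scale is the deepest accepted join (floored at the smallest
positive pairwise distance, the data's resolution) the probability of
the groups staying separate until the next merge height is
$\exp(-(h_{next}-h_{ref})/h_{ref})$. A barcode gap makes this jump
ten-fold or more and the probability collapses, while within-species
and deep-backbone merges jump by factors of two to three and score
moderately. Depending only on two order statistics, the score is
immune to group sizes and to the heavy distance ties that
haplotype-identical sequences create - the failure modes that sink
sample-size-dependent spacing tests here; (ii) a relative gap width:
the distance gap just above the partition's largest intra-group
distance, divided by that intra-group distance (same resolution
floor), so a 4% gap above 0.4% intra-group divergence outweighs an
equally wide gap between deep backbone clades. Candidates are ranked
on each criterion and the final score is the mean of the two ranks,
lowest first; the jump statistics stay in the candidate table so the
ranking can be audited.

**Poisson tree process (`ptpFit()`).** On a metric tree, branches are
classified into speciation-class and coalescent-class events, each
with an exponential rate (multi-rate mode: one rate per multi-sequence
species). The boundary set is searched greedily from the one-species
partition with simulated-annealing restarts; by default both the
single- and multi-rate models are fitted and AIC decides. Branches
shorter than `minBr` (default 1e-4 substitutions/site, below the
resolution of a ~650 bp marker) carry no information about branching
rates and are excluded from both classes - without this floor a rate
estimate can diverge on zero-length cherries. Because the maximised
improvement over the one-rate null is inflated by the search itself, a
naive likelihood-ratio test would be anticonservative; significance is
instead assessed by a parametric bootstrap that redraws branch lengths
from the fitted null and re-runs the identical search. When the null
is not rejected the returned partition has k = 1.

**General mixed Yule-coalescent (`gmycFit()`).** On an ultrametric
tree, a threshold height $T$ separates diversification (Yule) events
from within-species coalescent events. Within each inter-event
interval the total branching rate is
$$b = \lambda_y\,(n_y^{p_y}-1) +
     \lambda_c \sum_k n_k\,(n_k-1)^{p_c},$$
where $n_y$ counts diversification lineages and $n_k$ the lineages of
species $k$; each interval contributes $b\,e^{-b x}$. All
between-event thresholds are scanned exhaustively (the one-species
null, $T$ above the root, included, so the fitted maximum can never
fall below the null) and the rate/exponent parameters are re-optimised
at each. The likelihood-ratio test against the null uses a chi-square
mixture with 2 and 3 degrees of freedom in equal weights - the
boundary-case convention for this comparison. Because the threshold is
itself chosen by maximising over every candidate height, that
reference distribution runs mildly anticonservative; the
parametric-bootstrap test (re-simulate single-population coalescent
trees from the fitted null, re-run the full scan on each) is
calibrated by construction and is the one to use when type-I control
matters, at the cost of `nBoot` extra scans. Two guards keep the likelihood
proper on distance-derived (UPGMA) trees: clades of identical leaves
are collapsed to one representative before fitting and re-expanded
afterwards (a zero-length coalescence has unbounded density under any
continuous model), and exactly tied node heights are merged into one
simultaneous-event level rather than jittered apart, which keeps the
scan deterministic and leaves no infinitesimal interval for a runaway
rate estimate to exploit. Multiple-threshold mode greedily gives
individual clusters their own deeper threshold while AIC (one extra
parameter per threshold) improves.

## Consensus and conflict

`consensusPartition()` places an edge between two sequences when they
share a MOTU in strictly more than a fraction $m$ (default 0.5) of the
voting schemes; consensus MOTUs are the connected components. A tie at
exactly $m$ creates no edge: splitting is the conservative direction
when the purpose is flagging candidate cryptic lineages. With an odd
number of voters the rule is decisive. Components can contain pairs
that did not themselves reach a majority (intransitivity); they are
not re-split, only counted and reported per MOTU. Morphological
species labels can vote alongside the four molecular methods (the
default in `runPipeline()`), and a flag excludes them for a strictly
molecular consensus.

`conflictReport()` then classifies every labelled species as a match,
a split (more than one consensus MOTU) or a lump (its MOTU shared with
another species); a species that is both is counted as a split and
flagged. The classification carries the barcode-gap distances so the
report reads like the mismatch tables of reference-library papers.

## Accumulation curves

`accumulationCurve()` randomises the sequence order (delegating the
permutations to `vegan::specaccum()`), and reports the mean and
empirical 2.5/97.5 percentiles of cumulative richness. Plateau
judgement in the literature is visual; for programmatic use the curve
is declared flat when the mean gain over the last 10% of sequences
falls below 0.01 labels per sequence (computed with the discrete
denominator $n - \lceil 0.9 n\rceil$).

## The simulator and what it does (not) emulate

`simulateReferenceLibrary()` draws a Yule tree over species, rescales
its node heights so that the shallowest species split sits at
`stemScale` (default 0.025, i.e. a minimum between-species divergence
of 5%) and the crown at `crownDepth` (default 0.15, giving congeneric
divergences around 7% and family-level divergences up to ~30%, the
shape typical of a regional fish COI library). Within each species a
Kingman coalescent genealogy is grafted whose scale makes the expected
conspecific pairwise divergence exactly `theta` (default 0.0036).
Sequences then evolve along the combined genealogy under a strict
clock and the K80 model (`kappa` = 4) - deliberately the same model
family the distance estimator assumes, so divergence targets are
analytic and estimator consistency can be tested to Monte-Carlo
precision. Sample sizes per species are truncated-geometric on 1..23
with mean 4, matching the skewed effort of real survey libraries.
Genera and families are defined by cutting the species tree at fixed
heights (20% and 60% of the crown above the stem floor), which yields
a consistent taxonomy for the rank summaries.

`injectFeature()` plants the edge cases that matter for validation:
a cryptic split (one nominal species re-labelled over two clades whose
height is set so the *realized maximum* intraspecific K2P estimate,
the observable the mismatch tables report, lands on the requested
depth - the maximum of the noisy cross-clade estimates sits ~8-10%
above the true path length, and the injected height is shrunk
accordingly); a shallow sister pair grafted at a requested divergence;
and a singleton pruned to one sequence. The first two edit the node
heights of the true genealogy (raising ancestors where needed so it
stays ultrametric) and re-simulate the alignment from the modified
genealogy, keeping sequences and recorded truth exactly consistent.

What passing the simulation-based tests does *not* show: the generator
has no rate heterogeneity across sites or lineages, no alignment gaps,
no sequencing error, no selection, and its sequences are not readable
open reading frames (the stop-codon screen will flag them - it is
validated on constructed coding sequences instead). Real libraries
violate the K80 clock in all of these ways, so recovery rates here are
an upper bound on real-data performance, not an estimate of it.

## Numerical choices and problem sizes

Distances are reported to 4 decimals in files; saturated cells are
counted and excluded; NJ's negative branch lengths are clamped to zero
with the deficit moved to the sibling so path lengths are preserved;
ultrametricity is checked to 1e-6 of tree height and UPGMA satisfies
it to 1e-9. The PTP search uses 10 annealing restarts and a 20-draw
bootstrap by default; GMYC bounds its exponents to [0.01, 3] and its
log-rates to +/-25. The test suite exercises recovery at 20 species
(~80 sequences, 652 bp) over 50 seeds and calibration over 100 null
trees of 15-20 leaves - sizes at which the full suite completes in
minutes on one core while keeping the Monte-Carlo error of every rate
estimate well inside the asserted margins.

## Known limitations

The SLC stand-in is not the proprietary registry algorithm and its
MOTU counts on real data should be read as approximate. The
distance-partitioning scorer follows the published method's *shape*
(ranked gap width and panmixia criteria over single-linkage levels)
but its probability model is this package's own. GMYC results are only
as good as the ultrametric tree supplied; the built-in UPGMA fallback
is a crude stand-in for a properly dated tree, and externally inferred
trees can be passed to `runPipeline()` whenever available. A strict
clock conversion (1.2% pairwise divergence per Myr) is provided for
reporting only and plays no role in any analysis.
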