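---
title: "Sequence features of FG nucleoporins: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence features of FG nucleoporins: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgseq)
```

FG nucleoporins (FG Nups) are the intrinsically disordered,
phenylalanine-glycine-repeat proteins that line the nuclear pore complex
and form its permeability barrier. Their behavior is thought to be encoded
not in a folded structure but in the composition and the along-sequence
layout of a few residue classes: the FG dimers themselves, charged residues
(R/K positive, D/E negative), and polar residues (S/N/T/Q). `fgseq`
implements a complete analysis of that layout for a cohort of sequences:
composition metrics, FG-linker statistics, like-charge-region detection,
one-dimensional density clustering of feature positions, cluster-overlap
statistics, and a three-zone localization profile. A synthetic-sequence
generator with exact planted ground truth makes every stage testable
without any database download.

This vignette records the methods, the tunable parameters and their units,
and the design decisions taken where the problem statement was genuinely
open.

## Residue scheme and coordinates

The default classification is R/K positive, D/E negative, S/N/T/Q polar,
and F/I/L/V/W/Y hydrophobic; all charged residues carry unit charge.
Histidine is deliberately *not* charged — the analysis follows the strict
four-letter charge alphabet — and ambiguity codes (X, B, Z, U) are retained
in sequences but classify as "other" and take the mid-scale normalized
hydrophobicity 0.5 when averaged, so that a rare ambiguous residue never
discards a record. Hydrophobicity uses the Kyte–Doolittle scale normalized
per residue to $h' = (h + 4.5)/9 \in [0, 1]$, averaged with no sliding
window (a plain length-normalized total).

All coordinates — internal, in region files, and in every output TSV — are
1-based inclusive, the R/Bioconductor interval convention. Keeping a single
convention end to end removes the half-open/closed translation layer that a
0-based internal representation would need, at the cost of one subtraction
when porting formulas stated in 0-based terms.

Analyses of FG Nup cohorts operate on the disordered regions of each
protein (supplied as an annotation file; disorder prediction itself is out
of scope). Like-charge regions and linkers never bridge two disordered
regions. Clustering and zoning use whole-sequence coordinates: feature
positions are found inside disordered regions but mapped back to the full
sequence before clustering, because the zonal analysis divides the *whole*
sequence into thirds.

## Cohort filter

A record enters the FG Nup cohort when its disorder fraction exceeds 0.30
and its FG-dimer density exceeds 0.15 FG/AA (occurrences of the exact dimer
"FG" divided by full sequence length). The filter counts "FG" only by
default — it reflects the database-construction rule, which predates the
clustering motif definition — while linker extraction and clustering count
both "FG" and "GF". Both choices are flags (`include_gf`).

## FG linkers and the polar–charge relationship

A linker is the run of residues strictly between two consecutive motif
anchors, kept when 10–30 residues long; gaps between overlapping anchors
are never linkers, and a linker interior is motif-free by construction.
Each linker carries its signed net charge and charged/polar/hydrophobic
number densities. Two cohort summaries follow: the fraction of linkers with
$|\mathrm{net\ charge}| \le 1$ (characteristically high, about 93%, in
published FG Nup cohorts), and the mean polar density binned by charged
density. Binning uses width 0.05 charged-density units (the bin width is
not prescribed anywhere, so it is a package default with a sensitivity
check in the test suite), drops linkers with charged density above 0.7, and
reports only bins holding at least 50 linkers. A control curve can be built
from random 10–30-mer windows drawn uniformly from a control cohort's
disordered regions, count-matched to the linkers under a fixed seed.

## Like-charge regions

A like-charge region (LCR) is a maximal run of $\ge 2$ same-sign charged
residues uninterrupted by an opposite charge. "Multiple" is read as at
least two, so isolated charges are never LCRs. The span is inclusive —
first to last charged residue, so an adjacent pair has span 2 — which keeps
the charge content (count/span) a proper density bounded by 1; an exclusive
variant would allow infinite content for adjacent pairs. Per protein the
*largest* LCR (most charges; ties to the larger span, then the smaller
start) summarizes the record. The charge-count rule for localization
(fewer than eight charges central-channel-like, seven or more
periphery-like) leaves a count of exactly seven satisfying both published
conditions; the package reports it as "ambiguous" rather than silently
picking a side.

## Density clustering in one dimension

Positions of the three feature types — FG/GF anchor starts, charged
residues (both signs pooled), polar residues — are clustered with DBSCAN
semantics on the 1-D line: a core point has at least `min_points` points
(itself included) within `epsilon` residues; clusters are chains of core
points linked at distance $\le \epsilon$ plus border points, each border
point assigned deterministically to its leftmost core neighbor's cluster.
The subspace-preference generalization of DBSCAN used in the original
analysis degenerates to exactly DBSCAN in one dimension — every point's
preference vector is the single axis — so this package states and tests
DBSCAN semantics directly; a brute-force reachability oracle over the
$\epsilon$-neighborhood graph verifies the implementation exhaustively on
random inputs.

Defaults are the Dunn-index-tuned values for FG Nup cohorts:
$\epsilon = 35/8/2$ residues for FG/charged/polar with minimum points
2/2/4. `tune_epsilon()` re-tunes on any cohort by maximizing the mean Dunn
index (minimum inter-cluster distance over maximum intra-cluster diameter)
across proteins, skipping proteins with fewer than two clusters and
breaking ties toward the smaller epsilon; a singleton-member cluster takes
a diameter floor of one residue to avoid division by zero.

A cluster's footprint runs from its first member residue to the last
residue of its last member — anchors contribute both dimer residues, so a
cluster of FG anchors ending at position $p$ has footprint end $p + 1$.
Overlap between cluster types X and Y is the number of residues in the
intersection of X footprints with the union of Y footprints, divided by the
summed X footprint sizes; the denominator makes overlap deliberately
asymmetric. "Shared residues" means footprint-interval intersection, not
shared feature positions, consistent with cluster sizes being quoted in
amino acids spanned.

One invariant worth noting: growing $\epsilon$ *merges* clusters (the core
members of any cluster at $\epsilon_1$ stay together at
$\epsilon_2 > \epsilon_1$) but can also promote former noise into new
clusters, so the cluster *count* is not monotone in $\epsilon$ — two lone
points at distance 10 form zero clusters at $\epsilon = 5$ and one at
$\epsilon = 10$. The property suite asserts the refinement form, which is
the true statement.

## Zones and groups

Each whole sequence is divided into three contiguous zones of near-equal
length (remainder residues to the earliest zones; at protein lengths the
N-terminal bias is immaterial), zone 1 at the N-terminus. For each feature
type the per-zone proportion is that zone's cluster-footprint residues over
the type's total — a cluster straddling a boundary contributes to both
zones, and proportions sum to one. Ten of fifty cluster residues in zone 1
give exactly 0.2. Proteins with strictly more than half of their
polar-cluster residues in zone 1 form group A, the rest group B (exactly
one half is B — "more than" is strict); proteins without polar clusters are
unassigned and excluded from group aggregates.

## Synthetic cohorts and what they do (not) show

`synth_fg_cohort()` emulates the architecture the analysis is designed to
detect: an N-terminal FG segment (motifs at a whole-sequence target density
of 0.16 FG/AA by default, polar fraction 0.35, background charge 0.02) and
a C-terminal stalk (charged fraction 0.30 mixed signs, polar 0.12), lengths
400–1200, disorder fraction 0.8 from the N-terminus. Inter-motif spacing is
bimodal, as in real repeat regions: most gaps are short (a uniform random
composition, mean ≈ 2 residues at the default density), but a small
fraction (`linker_gap_fraction`, default 0.05, capped by the density
budget) is drawn from the 10–30-residue linker range so the linker stage
sees realistic input; at 0.15+ FG/AA the motif budget simply leaves no room
for many long gaps, which is why the fraction is small. The defaults were
chosen once to sit just above the cohort filter (0.15 FG/AA, mirroring the
~29–30% of residues in FG repeats reported for real FG Nups) and to
reproduce the bimodal charge layout described for Nsp1-like proteins; the
control generator `synth_disprot()` defaults to roughly twice the charge
density (0.17–0.30), the contrast reported between real FG Nup and
disordered-protein databases.

Generation is exact-count rather than per-position Bernoulli: each segment
receives `round(density * segment_length)` charged/polar residues at
random non-motif positions, so cohort densities match the specification up
to rounding and determinism under a seed is byte-exact. Motif ground truth
is kept exact by construction: background fill excludes F entirely and a
fill G immediately preceding a planted F is rewritten to A, so the planted
anchor list *is* the motif content of the emitted sequence. A planted
like-charge region claims its window before motif layout (motifs avoid the
window), which guarantees feasibility even for dense, short plants; with
the FG-segment background charge density set to zero and disorder
restricted to the FG segment, planted LCRs are recovered exactly.

What passing these tests shows is that every operator does what it claims
on sequences whose ground truth is known. What it does not show is anything
about real FG Nups: synthetic sequences have no evolutionary correlation
structure, no length–composition covariance, no species structure, and
their background composition is a configured default (G/A/P-rich,
F excluded), not an empirical profile. Cohort-level statements about real
proteins require real cohorts; the published headline statistics were
computed on database snapshots that are not redistributable, so the package
reproduces the *mechanisms* (worked examples, planted contrasts,
recoveries) rather than those numbers.

## Numerical and degenerate-input choices

* Problem sizes in the test suite (cohorts of 5–60 synthetic proteins,
  500 planted-LCR recoveries, 1000 random position sets for the clustering
  oracle) keep the full suite under a minute while leaving sampling error
  far below the asserted tolerances.
* Neighborhood tests use a $10^{-9}$ tolerance on the integer line so that
  positions exactly `epsilon` apart count as neighbors regardless of
  floating-point representation of `epsilon`.
* Empty inputs are errors where a statistic is undefined on them
  (composition of an empty string, net-charge summary of zero linkers),
  empty results where emptiness is meaningful (no motifs, no LCRs, no
  qualifying linkers), and `NA` where a per-protein value is undefined but
  the protein must remain in the cohort (overlap with no X clusters, zone
  proportions with no clusters); cohort aggregates drop `NA`s.
* The pipeline orders every output by protein id and writes plain TSVs with
  a comment line naming units and the coordinate convention, so repeated
  runs on identical inputs are byte-identical.

## Limitations

Disorder annotation quality bounds everything downstream — the package
consumes regions, it does not predict them. The localization rule from LCR
charge counts was derived from a small set of proteins with known pore
positions and is exposed as a label, not a claim. Clustering parameters
were tuned on FG Nup cohorts; for other protein families `tune_epsilon()`
should be re-run rather than trusting the defaults.
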