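---
title: "Methods: intron-size distributions, PRDM9 domain scans and loss inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intron-size distributions, PRDM9 domain scans and loss inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introntd)
```

## The scientific question

Most vertebrates share a remarkably constant shape of the log-transformed
intron-size distribution: a minor peak of near-minimal introns separated
from a dominant peak of long introns by an antimode near $2^{7.25}$ bp
(~150 bp).  Most teleost fish instead show a "teleost distribution" (TD):
still log-bimodal, but with the antimode shifted to $2^{8}$ bp (~256 bp) or
beyond and a *dominant* short-intron peak.  The TD occurs in several
mutually distant teleost lineages, and its presence coincides with lineages
whose PRDM9 orthologues have lost the ancestral KRAB (aKRAB) domain —
PRDM9 being the zinc-finger protein that positions meiotic recombination
hotspots in mammals via its PR-SET methyltransferase domain, a function
that requires aKRAB.

`introntd` implements the full chain of analyses behind this observation as
reusable, tested components: intron extraction and distribution
classification, domain-architecture scanning, PR-SET sequence distances and
trees, and parsimony-style counting of independent domain losses and trait
origins.  A synthetic-data module supplies inputs with known ground truth,
so the whole chain is testable without downloading a single genome.

## Synthetic intron-size distributions

Intron sizes are modelled as $2^x$ for $x$ drawn from a two-component
normal mixture in $\log_2$ space.  This family is a stand-in: it is
constrained only by the antimode positions the analysis cares about, not by
any claim that real intron-size distributions are normal mixtures.  The
mixture's free weight is *solved* so that the analytic density minimum sits
exactly at a requested antimode (`solve_mixture_weight()`, 1-D root finding
on the density derivative, rejected unless the stationary point is an
interior minimum).  Defaults:

* `td_mixture()`: components at 6.5 and 10.0 $\log_2$ bp (sd 0.35, 1.2),
  antimode solved at 8.0.  The solved weight (~0.99 on the short
  component) yields the TD's dominant short-intron peak.
* `vertebrate_mixture()`: components at 6.5 and 9.75 (sd 0.3, 1.25),
  antimode solved at 7.25.  The solved weight (~0.12) yields the
  vertebrate-typical dominant long-intron peak.

Draws below a 60 bp floor — a typical vertebrate minimal intron size — are
rejected and redrawn rather than clipped, which truncates the distribution
without creating a spurious spike at the floor.

What the generator does **not** emulate: per-gene correlation of intron
sizes, GC/repeat structure, chromosome-scale heterogeneity, or the
indel-process evolution of intron size over a tree.  Passing tests
therefore demonstrate correctness of the measurement chain, not realism of
teleost genomes.

`generate_annotation()` lays sampled exon/intron structures onto synthetic
chromosomes and emits GFF3 + FASTA such that re-extracting introns recovers
the sampled multiset exactly; this round-trip identity anchors the
intron-extraction tests.

## Intron extraction and the histogram

Coordinates are GFF3 semantics throughout (1-based, inclusive): the intron
between consecutive exons is $[e_i^{end}+1,\, e_{i+1}^{start}-1]$, size
$e_{i+1}^{start}-e_i^{end}-1$.  Abutting exons yield no intron and are
tallied; transcripts with overlapping exons are skipped and tallied.
Whether isoform-shared introns should count once or once per transcript is
not a settled convention, so it is a flag (`dedupe`, default once per
unique coordinate set).

`log2_histogram()` uses half-open bins anchored at integer $\log_2$ values,
width 0.25 by default — fine enough to separate antimodes at 7.25 from
8.0 — with densities normalised to unit mass.  `interval_density()` refuses
unaligned intervals rather than interpolating.

## Antimode detection and the TD call

`find_antimode()` smooths the binned density with a 3-bin moving average,
finds the two highest local maxima in the search window (default
$(6.5, 10.5)$, spanning both canonical antimode positions; boundary bins
count as candidate maxima because the short-intron mode can sit at the
window edge), and takes the argmin strictly between them.  Two numerical
choices matter:

* The sub-bin position is refined by quadratic interpolation through the
  three **unsmoothed** bins around the minimum.  Smoothing is kept for
  *locating* the dip (it suppresses noise wiggles) but biases the minimum
  towards the flatter flank by about half a bin; refining on raw densities
  removes that bias (empirically ~8.07 and ~7.30 on $2\times10^5$ draws
  from the two default mixtures, against analytic antimodes 8.0 and 7.25).
* A dip-prominence guard: the smoothed minimum must be below 0.8 of the
  lower of the two chosen peaks.  Without it, sampling noise on a unimodal
  distribution fabricates shallow "antimodes".  The 0.8 factor was chosen
  once from the analytic dip ratios of the default mixtures (~0.3) versus
  noise-level wiggles (~1.0) and is exposed as a parameter.

The TD call uses two interval densities: $d_8$ over $(2^8, 2^{8.5})$ and
$d_{11}$ over $(2^{11}, 2^{11.5})$.  A species is TD iff
$d_8 < a + b\,d_{11}$ (strictly below; a point on the line is non-TD).
The dividing line is configuration, not a constant.  The packaged default
($a = 0.02$, $b = 0.5$) was calibrated once, analytically, from the
interval densities of the two default mixtures — TD at
$(d_{11}, d_8) \approx (0.0024, 0.0014)$, non-TD at $\approx (0.136,
0.136)$ — and then frozen; it separates both synthetic ensembles with wide
margins relative to sampling noise at $5\times10^4$ introns per species.
A steeper line through the origin region (e.g. intercept 0.08, slope 1)
would *not* separate them, because the vertebrate-typical point has
$d_8 \approx d_{11}$.  Species with fewer than 1000 introns are called
ambiguous rather than forced.

One known edge case is deliberate: a distribution with a TD-position
antimode but an *inverted* peak ratio (higher long-intron peak) lands near
the line, and its call legitimately depends on the line parameters; the
package does not hard-code a resolution.

## Domain scanning

The scanning stack reproduces a profile-scan *decision contract* — windowed
score, calibrated thresholds, presence call — with a transparent
position-specific log-odds matrix (PSSM) rather than an HMM:

1. `consensus_scores()`: the score of an aligned row is the sum over
   columns of how many rows share its residue there (gaps contribute 0).
   `filter_alignment()` drops rows under a threshold (default 250) in a
   single pass; survivors are *not* re-aligned, as no aligner is in scope.
2. `build_profile()`: per-column log-odds
   $\log_2\frac{(c + \kappa\,p_r)/(n+\kappa)}{p_r}$ with pseudocount
   $\kappa = 1$ and uniform background by default; columns over 50% gaps
   are dropped.
3. `scan_peptides()`: all windows are scored; hits above threshold are
   selected greedily, non-overlapping, by descending score.  The best
   window is always reported even when sub-threshold, so score
   distributions can be inspected for calibration.
4. `six_frame_translate()` splits each of the six frames at stop codons
   into segments carrying source-strand and genomic coordinates, and
   `scan_genome()` scans within segments — mirroring the fact that a
   single-exon domain can be found in unannotated assemblies without gene
   prediction.

Presence thresholds are configuration with calibrated defaults: aKRAB
against six-frame genome translations, present at score ≥ 30; aKRAB
against annotated proteins, absent ≤ 20 / uncertain in (20, 50) / present
≥ 50 (the empirical score regions 0–20, 38–45 and >50 motivate the
uncertain band); extended PR-SET ("ePR-SET"), present ≥ 180 (true
orthologue scores sit above a 180–250 gap).  Because the scoring engine
here is a PSSM and not the original HMMs, these printed values are the
*contract defaults*, and synthetic-data tests calibrate that the planted
architecture is recovered perfectly at substitution rates ≤ 0.05.

C2H2 zinc fingers are matched with the simplified Prosite-style pattern
`C-x(2,4)-C-x(11,13)-H-x(3,5)-H`, non-overlapping left-to-right;
consecutive fingers at most 15 residues apart form one array.  Canonical
transcript selection: most distinct domain models, then largest summed hit
length, then smallest transcript id.

## PR-SET distances, trees and classes

The residue distance is derived from a BLOSUM-style matrix $B$ as
$$D_{x,y} = -B_{x,y} + \tfrac{1}{2}\,(B_{x,x} + B_{y,y}),$$ which is zero
on the diagonal, symmetric, and non-negative for BLOSUM62 (verified over
all 210 pairs).  The distance between two aligned sequences is the mean of
$D$ over the columns where **both** carry a standard residue — gaps and
unknowns (X) are excluded, following the reading that only positions
aligned in both sequences are informative.  A pair with no such columns is
an error (or `NA` inside the all-pairs matrix, with a warning).

Trees are built with classic Saitou–Nei neighbour joining, implemented
directly: Q-criterion selection, standard branch lengths, ties broken by
the lexicographically smallest label pair for determinism, negative branch
lengths clamped to zero with the deficit reported.  Classic NJ was chosen
over BioNJ's variance weighting because the downstream use is topology and
coarse class structure, and the two are topology-equivalent on additive
inputs; `ape`'s NJ implementations serve as independent cross-checks in the
test suite, never as the implementation.  Rooting places the root at the
midpoint of the outgroup's pendant branch (the outgroup being, in the
motivating analysis, the mouse PR-SET sequence).

The four PR-SET classes were originally drawn by eye on a distance heat
map; the codified stand-in is average-linkage hierarchical clustering cut
at $k = 4$ ($k$ is a parameter), with classes labelled I…IV by increasing
mean distance to a designated reference row so that class I is the most
reference-similar (the PRDM9-$\alpha$-like class, the only one whose
members may carry aKRAB; classes II–IV correspond to the $\beta$ type).

## Counting independent losses and origins

Given a rooted tree and binary leaf labels, a *maximal uniform clade* is a
node all of whose labelled descendant leaves carry the target state, while
its parent's clade does not.  The number of such clades is the inferred
number of independent events.  Three properties are deliberate:

* Unknown-state leaves are transparent — they neither break a clade nor
  found one — because absences caused by poor assemblies should not split
  a genuine absence clade.  They are reported per clade.
* The same operation counts aKRAB *losses* (target "absent") and TD
  *origins* (target "present"): the monophyly logic is identical.
* The count is a lower bound: losses planted on sister branches merge into
  one clade.  The tests assert both the bound and exactness under the
  non-adjacency condition over 100 simulated scenarios.

The packaged fixture (`teleost_fixtures()`) is an order-level tree with one
representative leaf per lineage relevant to the counts, topology assembled
from the accepted order-level teleost phylogeny, branch lengths arbitrary
(the inference is topological).  Its aKRAB labels mark ten leaves absent in
eight maximal clades — Osteoglossidae; *Denticeps clupeoides*;
Cypriniformes; Characiformes + Siluriformes; Lampriformes +
Euacanthomorphacea; Zeiformes; *Guentherus altivela*; *Coryphaenoides
rupestris* — and its TD labels mark four origin clades (*D. clupeoides*;
Cypriniformes; Characiformes + Siluriformes; Lampriformes +
Euacanthomorphacea).  Two fixture choices to be aware of:

* Gymnotiformes is included as an aKRAB-retaining, non-TD leaf.  In the
  order-level phylogeny it sits between Cypriniformes and Characiformes +
  Siluriformes; without such a lineage the two absence clades would merge
  and the counts would be 7 and 3.
* Zeiformes and *G. altivela* carry TD-negative labels even though their
  estimated distributions are TD-like, because the "at least 4" origin
  count is defined over the annotated-genome species set that predates
  those estimates; the origin count is explicitly a lower bound.

```{r fixture}
fx <- teleost_fixtures()
count_independent_events(fx$tree, fx$akrab, "absent")
count_independent_events(fx$tree, fx$td, "present")
```

## Problem sizes and determinism

The packaged defaults are the analysis conditions: antimode checks use
$2\times10^5$ sampled sizes per distribution; classifier calibration tests
use 100 synthetic species at $5\times10^4$ introns each; loss-recovery
properties use 100 random 24-leaf trees.  All generators funnel randomness
through explicit integer seeds and are bit-reproducible; the pipeline
writes a manifest of seeds and output digests, and a fixed-seed run is
byte-identical.

## Limitations

* The PSSM scanner is not an HMM: no position-specific gap states, no
  local/glocal alignment.  Score scales differ from hmmer's; only the
  decision structure is shared.  An external hit table can be substituted
  where hmmer fidelity matters.
* The monophyly count is a lower bound by construction and performs no
  probabilistic ancestral-state reconstruction.
* Alignments are consumed, never produced; filtering does not re-align.
* The classifier's dividing line is calibrated on the synthetic ensemble;
  applying it to real species tables should start from a recalibration on
  the (d11, d8) scatter of those species.
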