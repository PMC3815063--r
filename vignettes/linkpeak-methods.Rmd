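---
title: "Methods: pseudomolecule construction from maps and link peaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pseudomolecule construction from maps and link peaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linkpeak)
```

This vignette is the package's own account of what it computes, the
assumptions behind each stage, the defaults and why they were chosen,
and what the simulation-based tests do and do not demonstrate.

## The problem

A whole-genome shotgun assembly of a plant-sized genome delivers
scaffolds without chromosomal coordinates or orientation. Building
chromosome-scale pseudomolecules (PMs) requires external evidence:
genetic maps tie scaffolds to linkage-group positions through markers;
maps of related genotypes or species extend coverage through proxy
anchors; and mate-pair libraries (clone ends, long-insert reads) supply
short-range order and orientation signal. `linkpeak` combines these in
two stages — a map-driven backbone (Stage I) and mate-pair-driven
orientation, insertion and error correction (Stage II) — ending in an
AGP layout with fixed gaps.

## Stage I: anchoring and the backbone

### Marker placement cascade

STS markers are located on scaffolds through four filters, in order:

1. **Repeat-depth filter.** An alignment is removed when a fraction
   `frac` (default 0.20, inclusive) or more of its length is covered by
   at least `max_competitors` (default 5) other alignments of the same
   query. Crucially, an alignment merely *spanning* a short repeat is
   kept: removal always requires the fractional condition. Competition
   is evaluated in query space by default, with a target-space mode
   available, since repeats manifest in both.
2. **Hit grouping.** Alignment blocks of one query on the same scaffold
   and strand chain into a single hit when target gaps stay within
   `max_gap_bp` (default 1 kb), tolerating indels. Hit score = sum of
   block scores; span = union.
3. **Pair consistency.** For markers assayed as forward/reverse read
   pairs, hits must lie on one scaffold, converge, and be separated by a
   plausible amplicon length (default 50 bp – 5 kb, the PCR scale;
   configurable per marker class). Single-read markers skip this stage.
4. **Unique placement.** A marker is placed only when its best hit beats
   the runner-up by a factor `min_ratio` (default 1.2; not dictated by
   any external source, recorded in the run report). Otherwise it is
   ambiguous and contributes nothing.

Markers designed directly against the assembly (here, the SNP class)
carry a priori coordinates and skip the cascade. Markers collapsed as
co-segregating during map construction are genetically redundant but
physically distinct, so they re-enter anchoring with their group
representative's map position. The anchor coordinate is the hit-span
midpoint — a choice, since nothing canonical defines "the" position of a
multi-block hit.

### Genotype-matrix QC

Loci, then individuals, with ≥ 20% missing calls are removed, then loci
re-checked once (individual removal only lowers locus missingness, so a
single re-check reaches a fixpoint for the surviving set). Segregation
distortion is scanned by a χ² test against the 1:1 backcross
expectation (df = 1, missing excluded per locus) and *reported only*:
distorted markers map fine and are kept. No α or multiplicity correction
is imposed; thresholds belong to the caller. Genotypes use two-state
backcross coding; full outbred four-allele coding is out of scope
because every preprocessing rule here is coding-agnostic.

Map distances use the Kosambi function, d = 25 ln((1+2r)/(1−2r)) cM,
with exact inverse r = tanh(d/50)/2; the pair round-trips to machine
precision (~1e−16, asserted at 1e−12).

### Backbone and hierarchical insertion

Each scaffold is assigned to the chromosome holding the majority of its
anchors, requiring a 2/3 supermajority; below that the scaffold is
routed to chimera screening instead of being placed whole (a conflict a
human curator would resolve by hand). Its position is the median anchor
cM; scaffolds sort by position, and exact ties share a bin flagged as
internally unordered.

Foreign-map anchors are first re-expressed on the backbone cM scale:
scaffolds anchored in both maps give (foreign, backbone) reference
pairs per linkage group, through which a monotone piecewise-linear
transform is fitted (isotonic adjustment, then interpolation; linear
extrapolation beyond terminal pairs, flagged). Declared inversion
intervals have their content order-reversed (reflected) on the foreign
axis before transformation; the inversion catalogue is configuration
input, expressed in foreign-map cM because that is the axis the reversal
operates on. Detection of novel inversions is out of scope.

A scaffold carried only by foreign maps is inserted where its projected
position falls; when two foreign maps both carry it, they must agree on
the chromosome and on the pair of backbone neighbours, otherwise the
scaffold stays unplaced with the conflict counted. Priority is
reference map > first foreign > second foreign.

### Chimera detection

Anchors along a scaffold, ordered by bp, are segmented into runs
consistent in chromosome and local cM (a jump > 10 cM breaks a run).
Runs with fewer than 3 supporting anchors are set aside as logged
candidates; surviving adjacent runs that still disagree yield a
breakpoint at the midpoint between their flanking anchors, at most 3
per scaffold. Screening pools *all* anchor sources — reference plus
projected foreign — because misjoins in regions the reference map
covers thinly are exactly where proxy anchors earn their keep. The
midpoint placement means breakpoint error is bounded by half the local
anchor spacing; with the default marker densities that stays well below
the largest library insert, which is the scale at which a misplaced
breakpoint would corrupt link evidence.

## Stage II: link peaks

### Scores

Pairs with both ends reliably mapped are classified against the working
layout: same-scaffold pairs, and pairs on layout-adjacent scaffolds
whose summed end-to-edge distances fit within insert mean + 3 sd, are
satisfied; the rest are unsatisfied and become evidence. The gap
between adjacent scaffolds is a fixed convention, not an estimate, so
the plausibility check discounts it entirely.

Windows (default 10 kb, stepping 5 kb — unconstrained externally, chosen
to resolve structure at the scale of the smallest library insert while
keeping per-window pair counts stable) group unsatisfied ends by target
scaffold; group score is the sum of library weights; the window's peak
is the top group and the noise score the sum of the rest. Ties go to
the lexicographically smallest target and are flagged for curation
rather than silently resolved. Peak direction is the majority strand of
the peak group's source ends (`+` reads point right). Each window also
records the top group *per direction*: a scaffold shorter than the
largest insert has both ends' evidence in the same windows, and the
single overall peak would otherwise mask the weaker end's partner —
this was visible in testing as missed adjacencies confined to
sub-300-kb scaffolds. The headline peak and noise definitions, and the
conservation identity peak + noise = total window weight, are unchanged
by the extra columns.

Default library weights are 3 (reference clone ends), 2 (20-kb
long-insert), 1.5 (8-kb long-insert), 1 (related-genotype), 0.5
(related-species): a monotone encoding of "prefer the reference
genotype and longer, better-aligned inserts". They are configurable and
all scores are linear in them, so doubling every weight doubles every
score and leaves calls invariant when thresholds double (asserted).

### Calls, orientation, tracks

For each scaffold end, only the terminal ⌈max insert / step⌉ windows
are examined — evidence farther from an end than any insert can span is
unreachable. The dominant target becomes a candidate when its best
window peak ≥ 4.0 and noise/peak ≤ 0.5 (both thresholds are package
defaults surfaced in the run report; the noise ratio implements the
stated purpose of exposing multi-target repeat links). Only reciprocal
candidates become links; one-way candidates are reported as
suggestions. R–L/L–R end pairing implies the same strand, R–R/L–L
opposite; orientations propagate by breadth-first traversal per
component, and a parity-conflicting cycle voids the whole component's
orientation (conflicts counted) — an automated stand-in for what would
otherwise be manual review. Components acquire an absolute sign by
majority vote of members' map-slope orientations.

The map-slope fallback uses the Theil–Sen median slope of anchor cM
against bp, requiring ≥ 2 anchors and |slope| ≥ 0.1 cM/Mb; the floor
prevents orienting inside zero-recombination regions where the map
carries no directional information.

Within the full pipeline, link evidence is scored against the
*pre-scaffolding* state (only same-scaffold pairs satisfied): junction
evidence between scaffolds the map has already ordered is precisely
what orients them, so it must not be discarded as satisfied-adjacent.
The layout-aware classification is still computed and reported as QC.
Unanchored segments with a reciprocal link to a placed segment are
inserted beside their partner, on the side of the linked end.

### AGP and statistics

Components and 50,000-N gaps alternate (gap type `contig`, linkage
`no`; no gap-size estimation is attempted — the AGP vocabulary is a
package default, configurable). Unplaced segments collect into a
"chromosome 0" object. Statistics are size-based: oriented percentage =
100·oriented Mb / anchored Mb rounded half-up to 1 decimal; N50 by
descending cumulation; the Total row sums counts and sizes but
*averages* N50 and the oriented percentage across chromosomes,
following assembly-table convention. Any non-`?` orientation counts as
oriented, including link-derived relative orientations. Scaffolds
emitted with `?` are rendered as `+` in sequence output and listed in a
sidecar attribute.

Independent validation uses clone assemblies: filtered contig-to-segment
matches (> 1 kb, > 97% identity; clone-end hits at ≥ 400 bp and > 700
bits, strictness following the stated wording) build a tripartite
graph, and an AGP join is validated when a cycle through a clone label
connects its two segments; clones bridging non-adjacent segments are
contradictions.

## The synthetic-data generator

The generator defines the study conditions; its defaults are fixed, not
tuning knobs. It emulates, at desk scale, the statistical structure the
pipeline assumes:

* 3 chromosomes × 10 Mb, cut into lognormal scaffolds (median ~0.42 Mb,
  ~56 scaffolds), each randomly oriented and identified by shuffled ids;
  2 chimeric scaffolds planted by fusing pieces from different
  chromosomes. Fusion partners are ≥ 300 kb and ≥ 60% euchromatic, where
  anchor support makes a misjoin detectable — mirroring where curated
  assemblies actually catch them.
* A three-piece recombination landscape per chromosome: 10 cM/Mb on the
  arms, zero across the central 25% (the pericentromeric block), giving
  ~75 cM maps — the per-chromosome scale of real diploid potato-family
  maps, so that crossover counts per meiosis are realistic.
* Marker densities 10/Mb (euchromatin) and 1.5/Mb (pericentromere),
  reflecting the strong euchromatic bias of STS marker systems; classes
  SNP (a priori), DArT (single-read), SSR (read-pair) at 2:6:2. Five
  percent of aligned markers receive six-fold decoy alignment stacks on
  every read (repeat mimics, which the depth filter must remove) and 3%
  a consistent near-score (0.9×) decoy placement (a paralogous locus,
  which unique placement must refuse).
* A 180-individual backcross genotyped by simulated meioses: crossover
  count Poisson in map length, positions uniform on the cM axis — the
  no-interference simplification beyond the Kosambi model's implicit
  one. Distortion loci bias transmission by rejection sampling
  (default: one locus at 2:1), and 3% of calls are masked missing.
* Three mate-pair libraries: clone ends at 100 kb ± 10 kb (the BAC-end
  scale; 6,000 pairs = 20× physical coverage), 20 kb ± 2 kb (12,000
  pairs) and 8 kb ± 0.8 kb (20,000 pairs), weights 3/2/1.5; 2% of pairs
  are noise with random ends. The largest insert mean (100 kb) is also
  the scale against which chimera breakpoint error is judged.
* Foreign maps as affine distortions (×0.8–1.2, + 0–5 cM) of the true
  cM axis with 0.2-cM anchor noise, per-segment proxy anchors, 10%
  segment dropout, and optionally a planted inversion.

Everything derives deterministically from one master seed through
per-stream offsets, so generators can be called in any order.

What the simulation does *not* model: nucleotide-level alignment error
(alignments are emitted directly, so the depth filter sees idealized
decoys), segmental duplication, read chimerism beyond uniform noise
pairs, insert-size asymmetry, genotyping error other than missingness,
and real map-construction error (the consumed map is truth). Passing
the recovery tests therefore shows the algorithms are correct and
well-calibrated under their stated assumptions, not that those
assumptions hold for any particular real assembly.

## Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open everywhere; AGP, GFF3 and
  wiggle convert at the I/O boundary only. One convention internally
  eliminates off-by-one drift; conversion is tested by span-invariance
  over random alignments.
* Printed-table reproduction uses round-half-up at the table's
  precision; full precision is kept internally.
* Marey profiles isotonically regularize genetic positions before
  windowed differencing (window 5 Mb, step 1 Mb): mapping noise creates
  local inversions that would otherwise yield negative rates. Rates are
  slopes of the regularized curve between window edges. Pericentromere
  calling takes the longest run of windows below 0.1 cM/Mb spanning
  ≥ 2 Mb; ties go to the smaller start coordinate (real pipelines
  resolve such ties with auxiliary bin-density evidence; that manual
  step is not automated here).
* Ultra-high-density bin positions convert to pseudo-cM at 0.8 cM/bin;
  clones whose map interval spans ≥ 5 bins are down-weighted 0.5 as
  inaccurately mapped. How a bin interval collapses to a point is
  unstated in any source; the midpoint is used.
* Degenerate inputs fail loudly: empty genotype matrices, anchors at a
  single physical position, breakpoints on scaffold edges, unknown
  library ids, NaN wiggle values, AGP tiling violations.

## Problem sizes

Tests and the acceptance script run the full pipeline on the ~30-Mb,
~56-scaffold default configuration (about 38,000 pairs and 250
markers), a size chosen so an end-to-end run with truth scoring
completes in a couple of minutes while every per-scaffold quantity
(anchors, junction-crossing pairs, link scores) stays at the same order
of magnitude per scaffold as in a real assembly campaign.

## Known limitations

* Orientation of a link component with no map-slope-oriented member
  stays relative (`?` in the AGP) rather than being arbitrarily signed.
* The insertion of unanchored scaffolds via links places them beside
  their partner without re-checking downstream neighbours; heavily
  nested insertions may need curation, which is why non-reciprocal
  links are emitted as suggestions rather than acted on.
* `detect_chimeras` calls at most 3 breakpoints per scaffold and cannot
  see misjoins whose flanks lack 3 anchors on either side; such runs
  are logged as candidates for manual review.
* The CLI reads YAML configuration only.
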