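---
title: "Optical map assembly and sequence-discordance auditing with omtk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optical map assembly and sequence-discordance auditing with omtk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omtk)
```

## The data and the problem

Optical mapping images single, randomly sheared genomic DNA molecules
(~400 kb) digested on a surface by one restriction enzyme (here BamHI,
GGATCC).  Each molecule yields an *Rmap*: an ordered list of measured
fragment lengths — the map-space analogue of a sequencing read.  At
genome scale, millions of Rmaps are assembled into consensus maps
("optical contigs"), stitched into chromosome-wide maps, and compared
with *in silico* restriction maps computed from a sequence assembly.
Places where map and sequence disagree — extra or missing cuts,
extraneous or missing sequence, compound misassemblies, inverted or
translocated blocks — are *discordances*, and cataloguing them is the
point of the exercise: the optical map audits the sequence assembly.

omtk implements this workflow end to end at desk scale, driven entirely
by a synthetic-data generator with a truth ledger, so that every stage is
testable without any external dataset.

## The error model the simulator encodes

`errorModel()` fixes the study conditions:

* molecules shear at ~400 kb (normal, SD 60 kb) and are discarded below
  300 kb, matching the conventional single-molecule size filter;
* each true site is cut with probability `pDigest = 0.8` (partial
  digestion);
* false cuts arrive as a Poisson process at 0.005 per kb;
* measured fragment lengths carry Gaussian sizing error with variance
  proportional to true length, calibrated to SD ≈ 1.3 kb on a 9-kb
  fragment (the pooled-SD scale reported for real BamHI maps);
* fragments below 800 bp merge into their left neighbour (the first
  fragment, having none, merges right — a tie-break we fix, not a law of
  nature);
* molecule orientation is unobservable, so each Rmap is flipped with
  probability 1/2.

Truth genomes are drawn in map space: fragment lengths are
`500 + Exp(meanFrag − 500)` so the mean is exactly the 8.91-kb site
density of the bovine BamHI map while respecting a 500-bp floor.  (A
literal truncation of an Exp(8910) at 500 bp would have mean 9.41 kb by
memorylessness and miss the stated density by 5%.)  The generator's
defaults *are* the study conditions; they are configurable but not tuned
per experiment.

What the simulator does **not** model: chimeric molecules, surface
stretching gradients, diploid heterozygosity (beyond the allele-pair
rule at merge time), or sequence-composition biases.  Passing tests
therefore demonstrate algorithmic correctness under the stated error
channels, not performance on any particular real dataset.

## Alignment

`alignRmap()` computes a fitting alignment of a molecule to a reference
map by dynamic programming over *blocks*: a block matches up to
`delta = 5` consecutive fragments on each side and scores

    matchBonus − (x − y)² / (2 · sizingVarPerBp · max(x, sizingFloor))
              − cutPenalty · interiorSites,

with `x` the reference-side and `y` the query-side block length.  The
whole molecule interior must be consumed; end blocks are shear artifacts
and pay no sizing penalty when the broken side is the shorter one, with
the freedom restricted to blocks of at most two fragments on the longer
side (a sheared end lies within one reference fragment, or two when a
site was missed).  Fragments overhanging a reference end are clipped
free — this is how consensus contigs grow.  The DP is exact; an
exhaustive decomposition search reproduces its optimum on every tested
case.

Acceptance is deliberately stricter than the score alone:

* `minScore = 25` and `minAlignedFragments = 10` (so a ~45-fragment
  molecule must anchor substantially);
* a per-fragment score floor (`minScorePerFragment = 1.9`): a correctly
  placed molecule earns ≈ 2.1 per fragment against an in silico map,
  while placements straddling a structural difference are systematically
  depressed.  Against consensus references the floor relaxes by 0.12
  (they carry their own measurement noise), and against low-depth seed
  maps (mean depth < 35) by 0.45;
* windowed cumulative-deviation bounds (`maxDevSigma = 4` SDs over any
  run of interior blocks, and over the whole molecule): a structural
  difference smeared thinly across many blocks escapes per-block tests
  but not the cumulative one.  The bounds are skipped against low-depth
  references, whose own sizing error would dominate the budget.

These acceptance rules are what make discordant regions *visible*: a
molecule spanning a planted insertion or deletion cannot place, the
local molecule recruitment collapses, and the assembly honestly refuses
to assert the region.

`alignMapPair()` extracts maximal local alignments between two maps,
best-first with overlap masking, optionally restricted to one
orientation.  Spacer fragments of chromosome maps are masked and can
never align.

## Consensus assembly

Iterative assembly follows the reference-seeded design: cycle 1 aligns
every Rmap to the seeding build's in silico map, bins the posed
molecules (1-Mb bins, 500-kb overlap), and assembles each bin at a
minimum depth of 20 molecules; from cycle 2 onward the previous cycle's
contigs are the reference and sequence information is no longer used.
Within a cycle, overlapping bin contigs in the same frame are
consolidated by pooling their member poses, and contigs are merged
transitively when their overlap alignment is corroborated by the
molecules themselves (at least three shared members whose implied
offsets agree; a pure pattern match between the facing ends of two
contigs split at a discordance shares no molecules and is rejected).
Pairs whose overlap evidence contains two well-supported placements
differing by ≥ 40 kb are kept apart and cross-tagged as an allele pair.
Contigs with a fragment-pattern autocorrelation above 0.9 at a non-zero
lag are flagged as long tandem repeats and excluded from merging.

Consensus construction works on *poses*: each accepted alignment
projects the molecule's cut positions into the reference frame
piecewise — matched cuts take the frame coordinate of their partner,
unmatched cuts (false cuts, overhangs) anchor to the nearest matched
boundary plus the measured distance, and the alignment's outermost
boundaries never snap (end blocks may be free/partial).  Projected cuts
are grouped against the frame's own cut grid (radius 2 kb, about 1.5
sizing SDs); off-grid cuts chain-cluster at a tighter radius.  A cluster
becomes a consensus cut when at least half the spanning molecules carry
it — which is also what deletes a seeding build's spurious cuts and
restores its missing ones.  Fragment lengths are re-estimated as the
median of member-measured inter-cut distances, so the consensus reports
measurements, not the seed's geometry; per-fragment depth and the pooled
SD of those measurements are recorded.  Regions below the depth minimum
— or below 55% of the contig's own median recruitment (`relDepth`),
which is how an un-sizeable structural disagreement manifests — are
trimmed at the ends and split in the interior.

Two cuts closer than the 2-kb clustering radius cannot be represented
separately; this is the effective resolution limit of the consensus (on
top of the 800-bp detection limit of single molecules) and the reason
cut-level discordance calling ignores sites with a flanking fragment
under 2.2 kb.

Cycling stops when the total span stops growing (with two flat cycles of
grace, since merging can restructure before extension shows); the
best-span cycle is returned.  With a truth-grade seed the assembly
converges by cycle 2–3; growth-limited stopping matters for seed-map
growth and for healing across discordant regions.

## Germinate-and-Grow

De novo assembly quantizes fragment lengths geometrically
(`code(f) = floor(log(f/f0)/log(1+ε))`) and builds a de Bruijn graph
over canonicalized k-mers of codes (k = 5, lexicographic min over
orientation).  Nodes with multiplicity ≥ 5 are confident.  The
`QuantizationScheme` default is ε = 0.25, but graph construction uses
ε = 0.75: under the stated sizing noise (SD 1.3 kb at 9 kb), 0.25-wide
bins are narrower than the measurement error, exact k-window agreement
between molecules almost never happens, and no confident node forms;
0.75 restores multiplicities ≈ coverage · pDigest^(k+1) while keeping
random 5-mer collisions rare.

Each confident node (in decreasing multiplicity, skipping consumed
nodes) germinates a seed map: the Rmaps containing the node are posed
against the node's longest member by pairwise alignment and assembled at
`seedMinDepth = 3` — node-sharing subsets are much smaller than full
piles, which is why seeds use their own depth floor.  Redundant seeds
(sharing more than half their members) are thinned, and the survivors
grow through the iterative engine at full depth.  A gap-fill round
repeats everything at k = 4 using only Rmaps absent from prior contigs.

## Chromosome maps and discordance calling

Contigs are ordered and oriented by their best local alignment to the
per-chromosome in silico maps and stitched with 500-kb gap-flagged
spacer fragments.  Stitching also records, per junction, the placement
delta on the build: overlapping placements (trimmed at stitch time) mean
the optical maps carry more material than the build; a placement gap
means extraneous build sequence.  Map segments — maximal runs of
fragments aligned between the chromosome map and the build — give
Table-2-style statistics; inverted blocks hidden inside forward
alignments are resolved by comparing orientation-restricted score
densities per reference fragment.

`callDiscordances()` walks the colinear alignment chain: unmatched
sequence cuts are ECs and unmatched optical cuts MCs (skipping sites
below the consensus resolution); matched blocks or windows of blocks
whose cumulative deviation clears `max(10 kb, 4σ)` are DEL/INS (the σ
uses the consensus-depth-scaled error); unaligned regions between
anchors classify by their mass difference, with the junction placement
delta overriding when a contig junction lies inside; point events
chained within 100 kb collapse into one COMPLEX, and indels absorb point
events inside their own interval.  Interior regions whose consensus
depth collapses below 65% of the contig background while recovering on
both sides are flagged COMPLEX (`depth_dip`): the molecules voted
against the region but left no sizing signature.  `callITs()` reports
non-colinear blocks ≥ 100 kb — other chromosome, out of order, or
reverse orientation — as IT with a subtype, suppressing reverse calls
whose optical footprint is already claimed by a stronger forward
alignment.

One identifiability limit is worth stating plainly: when a planted
insertion or deletion splits the assembly and contig extension has not
fully healed the recruitment dead zone around it, the junction geometry
measures the event size *plus* the unhealed width, and the sign no
longer identifies the direction.  Such events are recovered reliably
(the recall criterion) but a fraction are reported as DEL or COMPLEX
rather than INS; this is the same regime for which the original
six-category scheme keeps a compound class and which required manual
curation at full scale.

Direction conventions follow the assembly-judged-against-the-map
reading: DEL means extraneous sequence in the assembly (signed size
difference sequence − optical > 0), INS missing sequence (< 0).  The
methods-style bracket wording that swaps these glosses is treated as a
misprint and not followed.

## Planted-variant validation

`plantAssemblyErrors()` corrupts a truth map with EC/MC cut edits,
DEL/INS mass edits, INV/TRANS block moves and clustered COMPLEX triples,
recording a ledger in both coordinate systems.  Cut edits are planted
≥ 3 kb from other sites so they are optically resolvable; structural
events keep ≥ 650 kb from each other and from the genome ends so their
flanks can assemble independently — a molecule that crosses such an
event cannot align, so an event without assemblable flanks is not
interpretable by any map-based caller.  `scoreAgainstLedger()` reports
recall, category accuracy and precision at a 5-kb matching tolerance.

## Problem sizes and determinism

The test-suite and acceptance computations run at the package's chosen
desk scales: 2 Mb scenes for unit properties, 10 Mb at 60× for assembly
recovery and seed-bias, 5 Mb at 60× for Germinate-and-Grow, and the
20 Mb / 60× end-to-end demo with five planted events per category.  The
bovine scale (2.8 Gb at 439×) is configuration-reachable but not a
validation target.  All stochastic entry points take explicit seeds and
restore the caller's RNG state; identical seeds give identical outputs.

## Evaluating maps against a truth

`mapAgreement()` is the evaluation used throughout: it aligns a map to a
reference, registers matched cut pairs with a rolling local offset
(100-kb window), and reports per-cut deviations.  Local registration is
deliberate: consensus coordinates drift slowly relative to a truth frame
(a random walk of per-fragment measurement medians), and cut recovery is
a local property; crediting or penalizing frame drift would measure the
wrong thing.  Truth-cut recovery is assessed over cuts inside the
assembled footprint — at 60× with a depth-20 floor and a ≥ 300-kb
molecule filter, roughly 1% of truth cuts sit in sub-threshold end ramps
that no honest consensus can contain.
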