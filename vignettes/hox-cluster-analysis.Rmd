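---
title: "Comparative Hox cluster analysis with hoxatlas: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative Hox cluster analysis with hoxatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hoxatlas)
```

## The problem

The insect Hox cluster ancestrally holds ten genes in a fixed order — lab,
pb, zen, Dfd, Scr, ftz, Antp, Ubx, abdA, AbdB — co-oriented on one
chromosome. Across insect lineages this arrangement is reshaped by cluster
splits, inversions, translocations of anterior genes (most often paralogy
groups 1-4), tandem duplication of the derived genes zen and ftz (including
the fast-evolving lepidopteran Shx genes and the dipteran bcd), and rare
losses. Surveying these changes across hundreds of assemblies requires the
same small set of operations again and again: find homeoboxes, decide which
paralogy class each one is, reconstruct the per-species arrangement, compare
it to the ancestral one, and aggregate.

hoxatlas packages those operations with one design constraint throughout:
**every stage must be verifiable at desk scale**, without downloading
assemblies. That is what the synthetic-genome generator is for — it plants a
cluster with known coordinates and known structural events and emits a truth
table, so recovery can be asserted exactly.

## The unit of measurement: the homeobox

All coordinates in the package refer to the 180 bp homeobox (the 60-residue
homeodomain), not to transcripts: assembly sequence alone does not delimit
transcription units reliably, so intergenic distances are measured
homeobox edge to homeobox edge, and a "locus" is a scored 60-codon window.
Internal coordinates are 0-based half-open everywhere; conversion to the
1-based inclusive convention happens only when writing GFF3.

## Detection: PSSM scan over six frames

`build_profiles()` turns per-class seed alignments into 20 x 60 log-odds
matrices (bits):

$$S_c(a,p) = \log_2 \frac{(n_{a,p} + \beta b_a)/(N_c + \beta)}{b_a}$$

with pseudocount $\beta$ (default 1) and background $b$ (default uniform).
`scan_genome()` slides a 60-codon window over all six frames, rejects
windows containing a stop codon or an ambiguous (N-containing) codon, keeps
windows whose best class score reaches `min_bits`, and resolves overlapping
windows greedily by score (ties: leftmost, then plus strand). For speed the
scan prefilters windows with the elementwise maximum over all class
matrices — an upper bound on every class score, evaluated in compiled code
with a branch-and-bound early exit — so the accepted hit set is provably
identical to exhaustive enumeration (the test suite asserts this equality
against an independent brute-force oracle).

### The packaged seed alignments are synthetic

The seed sequences behind the default profiles are not curated biological
alignments. They are package-designed stand-ins: an Antp-like homeodomain
backbone with deterministic class-specific substitutions at non-critical
positions, keeping the invariant helix-3 core so every canonical class
carries the ancestral Q50 and M54 while bcd alone carries K50/R54. Classes
differ pairwise at 14 or more positions (6 or more within the zen clade).
This choice makes the whole system self-consistent and testable: the
generator plants exactly these consensi, and classification margins are
predictable. The corollary is stated plainly: green tests establish that the
*machinery* (scanning, classification, reconstruction, event calling) is
correct on its stated world; they do not validate the seed alignments as
biology. A user applying hoxatlas to real assemblies should swap in curated
per-class homeodomain alignments via `build_profiles(seed_alignments = ...)`.

### Calibrated threshold

`min_bits` defaults to 104 bits, computed by `calibrate_min_bits()` as the
largest integer threshold retaining 100% recall of planted loci at per-site
divergence 0.2 across 100 generator seeds. It is stored in
`hox_run_config()`, not hard-coded in the scanner. Random 60-codon windows
score far below this (mean around -100 bits under a single profile), so
false positives are effectively impossible at genome scale, while true
homeoboxes at 20% divergence still clear it comfortably.

## Classification

`classify_hits()` assigns the arg-max class over the ten canonical classes,
with all zen-clade profiles (zen, bcd, zen2, ShxA-D) rolled up into the zen
score so that highly derived duplicates are still recognised as zen-clade at
this stage. The margin over the runner-up must reach `min_margin` (default
5 bits, chosen so that no misassignment occurs at divergence 0.2 on the
generator — class consensi differ by at least 6 positions, each worth about
6 bits of margin); below it the call is flagged ambiguous with both labels
retained. `assign_zen_subtypes()` then resolves zen-labelled loci: a subtype
profile must beat the plain zen profile by `zen_divergence_cutoff` (default
10 bits, i.e. roughly three diagnostic residues) — the biological divergence
separating "Shx" from "zen" is not a settled quantity, so the cutoff is a
configuration parameter, not an asserted fact. The bicoid diagnostic
(`detect_bcd()`) requires **both** K50 and R54; single-residue matches are
only flagged, never called, because the two substitutions jointly define the
derived DNA-binding specificity.

Putative duplicates of canonical (non-zen) genes are always reported with a
`needs-verification` flag: a duplicate seen in a single assembly may be an
assembly artefact, and losses carry the same caution.

## Cluster reconstruction and event calling

`build_cluster_model()` orders loci per scaffold and derives adjacent
intergenic distances, per-scaffold spans, and the core span (AbdB to Scr,
defined only when all six core genes share one scaffold). An exact identity
ties these together — per scaffold, span = sum of gaps + 180 bp per locus —
and is asserted on every synthetic genome.

Split calling uses `max(abs_threshold, rel_multiplier * species median)`
with defaults 9 Mb and 5. The survey literature gives no formal numeric
criterion for drawing a split, so this operationalisation is an explicit
package decision, anchored on two boundary cases: the 9.6 Mb ANT-C/BX-C
separation in *Drosophila melanogaster* must be called a split, while
*Schistocerca* clusters with a 10.8-12.2 Mb core spread over six intervals
must not. Both thresholds are configurable and recorded in run metadata.

Event calls are deliberately simple, order-free operationalisations:

* **inversions** — maximal runs of loci opposing the majority strand of
  their scaffold group (ties resolved to AbdB's strand);
* **translocations** — a terminal block, ancestrally contiguous within the
  group's own labels, sitting at the wrong end relative to the remaining
  genes, with its flanking observed adjacency broken. The broken-flank
  condition excludes reversed-in-place blocks (whose inner boundary keeps an
  ancestral adjacency), and when a block at one end is equivalently "the
  complement at the other end", the smaller description wins;
* **scaffold translocations** — a gene alone on a scaffold whose ancestral
  neighbours are observed adjacent elsewhere (the gene left a closed gap
  behind). A lone terminal gene without a closed gap is indistinguishable
  from a plain split and is reported as a split instead;
* **tandem duplications** — two or more same-label loci within 1 Mb on one
  scaffold with no other Hox gene intervening (wide enough for the large
  Shx arrays, narrow enough to exclude dispersed copies, which are reported
  as low-confidence dispersed duplications);
* **losses** — any ancestral label with zero loci, always flagged tentative.

Orientation evidence is reported independently of positional evidence: one
physical block may yield both an inversion and a translocation call, which
matches how combined events are described in comparative work. Splits whose
flanking gene belongs to a called translocation are suppressed — the
displacement is already explained by the positional event.

`breakpoint_distance()` summarises any arrangement as the number of
ancestral adjacencies (unordered, restricted to present labels) missing from
it; a full reversal scores zero.

## The synthetic world

`simulation_config()` states the generator's world; its defaults are the
package's reference conditions and were chosen once:

| parameter | default | rationale |
|---|---|---|
| background_length_bp | 1 Mb | chromosome-arm scale at desk cost |
| spacer (ANT-C-like) | log-normal, median 20 kb, sdlog 0.6 | tens of kb, matching the "tightly linked" central genes |
| spacer (posterior: Antp-Ubx, Ubx-abdA, abdA-AbdB) | log-normal, median 120 kb, sdlog 0.6 | posterior intervals are consistently several-fold larger |
| array spacer | log-normal, median 3 kb | tandem arrays are tight |
| gc_content | 0.35 | typical insect genome GC |
| divergence | 0 | truth-recovery baseline; tests also exercise 0.2 |
| event probabilities | loss 0.02, tandem 0.2, inversion 0.1, translocation 0.15, scaffold translocation 0.05, split 0.3 | splits are common across the survey cohort, losses are rare |
| zen_expansion_geometric_p | 0.35 | a few extra copies typically, occasionally many |

Events are applied in the fixed order loss, duplication, inversion,
translocation, scaffold translocation, split, and placements are constrained
so that events do not obscure one another: inversion blocks are drawn from
the central genes and stay a strict minority of their final scaffold group,
translocated blocks keep at least as many unmoved genes beside them (so the
block-at-wrong-end call is unambiguous), and a split never cuts beside
another event's footprint. This is what makes truth tables unambiguous and
perfect recovery a fair requirement; it also means the generator does not
emulate pathological event stacks (for instance a split straight through an
inverted block), and no claim is made about detector behaviour there.

Layout draws (events, spacers, divergence) are staged before sequence draws
(codon choice, background), so `emit_sequence = FALSE` yields an identical
truth table at a fraction of the cost — summary-level tests use this. ORFs
are emitted as ATG + 60 codons + TAA with codons drawn uniformly among
synonymous codons; there is no model of splicing, codon bias, indels,
repeats or assembly error, all of which are out of scope of the analyses the
package reproduces. If a spacer draw would overrun the configured scaffold
length the scaffold is lengthened, never truncated.

What the generator does **not** emulate, hence what a green test does not
establish: real homeodomain sequence evolution (site-heterogeneous rates,
indels at domain edges), spliced homeoboxes (an intron inside the homeobox
would defeat a six-frame scan), fragmented or erroneous assemblies, and
non-Hox homeobox genes that a real genome contains in large numbers (a real
scan will report them too; classification margins, not the scan, are what
separate Hox from non-Hox matches in practice).

## Numerical choices

* Quartiles use linear interpolation between closest ranks (R type 7, the
  ggplot2 boxplot convention), whiskers reach the most extreme values within
  1.5 x IQR; the convention is recorded in output metadata.
* Correlations (core span vs genome size, per order) are Pearson on raw
  scale; the scale choice is recorded in metadata rather than asserted.
  Degenerate input (zero variance, fewer than 3 pairs) yields an explicit
  reason, never NaN.
* Neighbor joining is implemented in full (Saitou-Nei agglomeration,
  lowest-index tie-break, no clamping of negative branch lengths, exact on
  additive inputs) and cross-checked in the tests against the independent
  ape implementation; distances are plain p-distances over the fixed
  60-column frame — adequate for duplicate-clade grouping at desk scale,
  not a substitute for model-based phylogenetics.
* Genome size is the total assembly span of the input FASTA; no other
  definition is available from sequence alone.

## Known limitations

The scan assumes an intact 60-codon homeobox in one frame; the package
classifies only homeodomain content (no non-coding RNAs, no regulatory
landscape); event calls are per-species operationalisations, not
ancestral-state reconstructions over a tree; and the packaged manifest
records assembly labels verbatim in heterogeneous styles — normalising them
for download is deliberately left outside the tested path.
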