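---
title: "Fusion calling from Cas9-enriched long reads: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusion calling from Cas9-enriched long reads: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longfuse)
```

## The problem and the assay

A fusion gene joins parts of two genes through a genomic rearrangement.
One partner is often recurrent and known (the targeted gene); the other
partner and the breakpoint position are not. The enrichment assay
`longfuse` supports cuts the genome with Cas9 next to the known partner.
Because Cas9 stays bound to the PAM-distal side of its cut, only the
PAM-proximal end is available for adapter ligation, so sequencing
proceeds from the cut *into* the flank on the PAM-proximal side — by
choosing the guide strand, reads are directed across the suspected
breakpoint region and into the unknown partner. The result is
low genome-wide coverage (well below 1×) with a sharp on-target pile-up
of ~10 kb reads, some of which split-align across the fusion junction.

`longfuse` turns those alignments into fusion calls. This vignette
records the models, parameters and design decisions; the README shows
the user-facing workflow.

## Coordinates and breakend encoding

All internal coordinates are 0-based half-open; GTF (1-based inclusive)
and VCF (1-based) are converted at the I/O boundary. A breakpoint is a
*junction coordinate* between bases. Each breakend records its retained
side: L means the genomic-left flank of the junction is the piece joined
into the derivative chromosome, R the genomic-right flank. In VCF
output, POS anchors on the retained base (POS = pos for side L,
pos + 1 for side R) and the four bracket orientations of the VCF 4.2
breakend ALT encode the retained sides of the record and its mate.
This single encoding is used everywhere: the breakend extractor, the
clustering, the VCF writer/parser, the simulator's truth junctions and
the continuity rule, which is what makes exact round-trip tests
possible.

## Breakend extraction and clustering

One aligned segment per primary/supplementary record (secondary
alignments dropped); read-coordinate intervals are recovered from CIGAR
clips and flipped to original-read orientation for minus-strand
records. Adjacent segments in read order each contribute one breakend
pair; ends are stored in canonical (chromosome, position, side) order so
reads traversing a junction in either direction produce the same pair.

Clustering is single linkage: pairs merge iff retained sides match at
both ends and both positions are within `cluster_distance` (100 bp
default). The defaults mirror the established long-read SV-calling
practice for this assay: `min_mapq` 12 applied to the lower of a pair's
two segment MAPQs before clustering, support counted as distinct read
IDs with a minimum of 2 (1 allowed for targeted re-queries when a known
fusion locus produced a single spanning read), no depth-based support,
insertions never emitted. The per-end confidence interval is the width
(max − min) of member positions; widths above `ci_flag` (300 bp) set a
flag on the call but never remove it, matching the flag-like semantics
of that threshold upstream. Single linkage with per-end medians was
chosen over more elaborate cluster models because it is exactly
testable: the suite checks it against a brute-force connected-components
computation over the pairwise merge predicate.

The reference pipeline this reimplements re-maps candidate reads with a
local aligner and re-calls breakpoints on the remapped subset.
`longfuse` extracts breakends from the already-split alignments in a
single pass and keeps `refine_breakpoints()` as a no-op hook where a
re-mapping engine could be slotted in; with truth-derived or
modern-aligner input the second pass has nothing to correct.

## The continuous-transcript rule

A fusion candidate is an SV whose breakends lie in two *different*
genes; events with an intergenic end (promoter hijacking, UTR breaks)
deliberately stay out of the fusion overview but remain in the SV VCF
for manual review. A gene is a valid 5' partner iff its retained flank
is transcript-upstream of the junction — retained side L for a '+' gene,
R for a '−' gene — and a valid 3' partner iff the retained flank is
transcript-downstream. Both role assignments are tried; each valid one
becomes a fusion call and candidates valid in neither orientation are
rejected (of the 16 side × strand combinations, exactly the 8 pairing
one upstream-retained with one downstream-retained end yield a call, and
the suite asserts this exhaustively). When a breakend falls in
overlapping genes, every gene pair is evaluated and all valid fusions
are reported without ranking — the partner-agnostic philosophy of the
assay argues against guessing.

## Exon/intron context and CDS composition

Each gene uses one canonical transcript: the isoform with the longest
total CDS, ties broken by lexicographically smallest transcript ID.
The annotation source does not dictate an isoform choice for CDS
accounting, so the package fixes this deterministic, common convention;
any transcript can be requested explicitly. Exons and introns are
numbered in transcript orientation from 1; half-open intervals make
boundary assignment deterministic (the base at an exon start belongs to
the exon). `cds5_len` counts canonical CDS bases on the retained flank
of the 5' gene, `cds3_len` on the retained flank of the 3' gene, and
their sum is the fused CDS length, with OUT_OF_FRAME flagged when the
sum is not a multiple of 3 *and both genes code* — a frame statement
about a non-coding partner would be meaningless, so NO_CDS is raised
instead. A coding 5' partner broken upstream of its CDS start yields
`cds5_len` 0 with a PROMOTER_5 flag rather than rejection: DNA-level
detection intentionally keeps promoter-fusion-like events. The flag
vocabulary (OUT_OF_FRAME, NO_CDS, PROMOTER_5, WIDE_CI, CHAIN,
RECIPROCAL_OF) is the package's own, machine-readable and extensible;
flags annotate, they never filter.

Reciprocal fusions — same two genes with 5'/3' roles exchanged — are
linked by mutual RECIPROCAL_OF flags with no constraint on breakpoint
proximity, since reciprocal products of balanced rearrangements are
observed at independent positions. Complex events are handled
best-effort: SV calls sharing supporting reads with breakends within
1 kb receive CHAIN annotations naming each other, flagging multi-step
rearrangements (deletion + inversion + translocation) for inspection
while each component stays individually reported. Full automatic
reconstruction of such chains into one biological event is out of
scope; the component calls carry all the breakpoint information.

## Enrichment statistics

Genome coverage is total aligned bases over genome length, on- and
off-target alike. On-target coverage is mean depth over the
cut-to-breakpoint region. The breakpoint-spanning count is the depth at
the breakpoint base: distinct reads whose alignment covers the base
immediately left of the junction coordinate, which includes split reads
clipped exactly at the junction. This choice (rather than requiring a
single segment to continue across the position) is what makes the
signal triad nested — fusion-spanning reads ⊆ breakpoint-spanning reads
⊆ on-target signal — so the corresponding fold enrichments over genome
coverage are provably ordered on clean data, and the suite asserts the
ordering. Fold enrichment is a plain ratio with a guarded denominator.

A read "starts at the cut" when the genomic position of its outermost
read start lies within ±50 bp of the cut site; the window absorbs cut
jitter and adapter trimming, and no value is dictated by the assay
itself. Directionality is the fraction of starters extending in the
guide-dictated direction. The time course bins cumulative
fusion-spanning reads at 1–6, 12, 18, …, 48 h after the earliest read
of the run and reports the first bin reaching a threshold (default 2
reads). The cutoff sweep counts fusions retained at minimum support 1,
2, 3, 4, 5+ from a support-1 run; equality with per-threshold recalling
is asserted as an oracle test.

## Panel design

PAM scanning finds 20-nt protospacers with NGG immediately 3' on the
requested strand; minus-strand sites are plus-strand CCN motifs, and the
blunt cut sits 3 bp 5' of the PAM. Role fixes the design strand: unknown
3' partner → the known gene's sense strand, unknown 5' partner → its
antisense strand; the expected read direction then follows from the
PAM-proximal ligation mechanism (plus-strand guide → genomic-downstream
reads). Tiling is greedy left-to-right, choosing the leftmost valid PAM
within `max_spacing` of the previous cut, which bounds every gap by
construction; `max_spacing` defaults to 6 kb, the scale of a typical
read length, consistent with three sequential guides spanning an 18 kb
breakpoint window. Guide scoring against off-target activity is out of
scope (vendor scorers are proprietary); within a stride the leftmost
valid PAM wins, which keeps the design deterministic.

Primer design is a self-contained emulation of a standard primer-design
run honoring the 200–400 bp product window: exhaustive search over
18–27-nt candidates flanking the junction, 30–70% GC, nearest-neighbor
Tm (unified duplex parameters, 50 nM primer, 50 mM Na⁺ with the
0.368·(N−1)·ln[Na⁺] entropy correction) in 57–63 °C, pair ΔTm ≤ 3 °C,
scored by |Tm − 60| per primer plus |product − 300|/50, ties to the
leftmost forward primer then the shortest product. No randomness is
involved; the Tm model is pinned to independently computed reference
values in the tests. The function is a drop-in surface: an external
design engine can replace it wholesale since only the returned fields
are consumed.

## The simulator: what it emulates, and what it does not

The simulator provides the study conditions in miniature. Defaults:
lognormal read lengths with 9.9 kb mean (σ_log 0.5), 50 capture reads
per guide cut starting within ±5 bp of the cut and extending only in
the guide direction, uniform background at 0.2× (the assay's observed
genome-wide coverage lies in the 0.015–0.57× range), a 48 h run with
exponentially decaying start times at rate 0.1 h⁻¹ — chosen so ~70% of
reads fall in the first 12 h, echoing the observed accumulation — plus
optional i.i.d. substitution errors (default 0, 5% for robustness
scenarios) and amplification-chimera reads (default 0) that join two
uniform loci as whole-genome amplification artifacts do.

Derivative haplotypes are built by literal sequence surgery (DEL, INV,
JOIN with retained-side semantics), and truth junctions are enumerated
from the observable adjacencies of the derivative's segment map, so a
deletion directly abutting an inverted segment yields the single merged
junction a spanning read would actually produce. Truth alignments are
emitted as SAM with exact CIGARs and SA tags, standing in for an
aligner so tests are hermetic; externally aligned SAM enters the same
reader. Error draws happen after all structural draws, so a fixed seed
yields identical coordinates with errors on or off.

Deliberate simplifications: substitution-only errors (no indels or
homopolymer structure — alignments are truth-derived, so errors only
exercise sequence-dependent paths like primer design); no pore-level
signal, basecalling spectra, or adapter sequence; uniform background
rather than chromatin-biased. Consequently, passing tests demonstrate
the correctness of the calling logic on structurally faithful input,
not robustness to real basecaller error profiles or alignment ambiguity
in repetitive regions — on real data those are the aligner's problem,
and MAPQ filtering is the hook where its uncertainty enters.

## Numerical and degenerate-input choices

Cluster positions use `floor(median(...))` for an integer, deterministic
tie-break. Directionality with no starters is NA, not an error; an
empty alignment file yields empty outputs and exit status 0; an empty
region for coverage is an error (the mean is undefined). Unknown
chromosomes in gene queries return an empty list (targeted panels
routinely query contigs absent from the annotation). Capture reads
running off a haplotype end are truncated, not errors. VCF output
suppresses the file-date header line by default so replays are
byte-identical.

## Problem sizes in the test suite

The suite runs entirely on synthetic data at desk scale: 120 kb
two-chromosome genomes, 5 genes, tens of reads per scenario (up to 1000
for the read-length law-of-large-numbers check and 300 for the
directionality interval check), brute-force oracles over ≤ 3 kb of
positions and ≤ 50 breakend pairs. These sizes were chosen as the
smallest at which each property is non-trivially exercised; every
number printed in the README was produced by running the code shown
there.
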