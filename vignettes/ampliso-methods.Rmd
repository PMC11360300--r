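---
title: "ampliso: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ampliso: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliso)
```

## The scientific problem

The human *NRG1* locus produces dozens of isoforms by combining alternative
transcription start sites (defining isoform classes I--VII), cassette
exons, alternative EGF-like domains (α/β), alternative linkers, and
alternative transmembrane/cytoplasmic-tail arrangements. The myeloid class
VII is defined by a novel TSS that extends a 51-nt internal exon into a
190-nt first exon carrying a 139-nt class-specific 5′ region, with the
initiating methionine at transcript positions 115--117. Class VII
transcripts were characterised by targeted nanopore amplicon sequencing:
one forward primer in the unique 5′ UTR, two reverse primers defining a
"short" amplicon (ending in the linker-3 terminal exon) and a "long"
amplicon (ending in the a-tail exon). Reads were filtered for identity,
full-length structure and splice-junction accuracy, clustered into exon
chains, thresholded at 5% of a sample's reads, translated, and classified
as coding or nonsense-mediated-decay (NMD) candidates; a 111-nt poison
exon introduces an amber (TAG) stop that truncates the open reading frame
at 67 residues. Class-specific expression was quantified by qRT-PCR with
the efficiency-corrected Pfaffl method.

`ampliso` re-implements this workflow as a tested, seeded, desk-scale
pipeline: a synthetic locus with the published geometry, a nanopore-like
read simulator, a bespoke splice-aware chain caller, the QC and
high-confidence filters, ORF/NMD/domain annotation, and the Pfaffl
formulas. Everything runs from explicit seeds with no downloads.

## The locus model

Coordinates are 0-based half-open internally, so the published poison-exon
pair chr8:32,676,084--32,676,195 spans exactly `end - start = 111` bases;
GTF output converts to 1-based closed coordinates. All fixture work is on
the transcribed (+) strand of a synthetic contig; real genomic strandedness
is out of scope.

Exons carry domain roles (class-VII N-terminal, shared first-exon portion,
spacer, poison, EGF common/α/β, transmembrane, a/b tails, linker-3
terminal) and an annotated *entering codon phase*: the number of
nucleotides of the pending codon carried in from upstream exons when the
exon is read in its canonical context. The canonical frame itself is
anchored on a codon start inside the shared portion of the first exon
(transcript position 142, codon 10), which operationalises "in frame with
the other isoform classes" with a single source of truth.

Isoform names follow the locus grammar
`class - [P] egf terminal` (`VII-ab3`, `VII-Pb3`, `VII-a2a`, ...). Greek
letters are stored as ASCII tokens and rendered as α/β only in display
output; files always use ASCII. `nameIsoform()` and `chainFromName()` are
mutually inverse on all role-resolvable names. The published isoform
"Pαca" has a terminal whose exact exon composition is not resolvable from
roles; it is realised as poison + α ending at the linker-3 terminal exon,
registered in a per-locus name-override table and flagged
`nonstandard-terminal`. On loci without such an override the `ca` terminal
raises an unsupported-name error rather than guessing.

## Fixture construction: the coding arithmetic

The printed peptide segmentation fixes all upstream exon lengths; the
fixture builder treats the following as locus architecture (validated, not
tunable):

* first exon = 139-nt unique 5′ region + 51-nt shared portion = 190 nt,
  ATG at 115--117, so the first exon carries 76 coding nt = 25 codons plus
  one carry nucleotide;
* codons 1--8 (`MSYHLFFS`) lie entirely within the unique region
  (nt 115--138); codon 9 bridges the unique/shared boundary at nt 139/140,
  so the shared first-exon segment is codons 9--25 (17 residues);
* the 59-nt spacer exon completes codon 26 and adds codons 27--45, putting
  the cumulative coding length at 135 nt (45 codons, phase 0) at the
  poison-exon 5′ edge;
* the 111-nt poison exon encodes 22 further residues with a TAG at its
  nt 67--69, reproducing the printed 67-residue ORF (8 + 17 + 20 + 22).

This is the only small-integer solution consistent with every printed
dimension, and the builder *asserts* each dimension by an independent scan
of the built sequence (first-ATG position, primer placement, TAG position)
rather than trusting the constructor.

The nucleotides that encode the printed peptide are fixed by a
deterministic back-translation table (one codon per residue) and shipped
as constants; the 5′ UTR and all remaining exon content are seeded random
sequence generated under explicit constraints (no ATG anywhere in the
114-nt UTR; no stop codons in frames that must read through; forced stop
codons where a frame must terminate). Because every stop codon begins with
T, constraining the final bases of carry-out exons to A/C/G guarantees
that no junction-bridging codon can ever terminate, independent of the
downstream exon.

The EGF cassettes implement the α+β frame shift with one congruence pair:
`len(α) ≡ len(β) (mod 3)` and `len(α) mod 3 ≠ 0` (defaults 76 and 64 nt).
Single-EGF chains therefore place all downstream exons in one consistent
frame (their annotated phase), while chains containing both α and β read
β — and everything after it — shifted. Consequences, all asserted in
tests: `VII-ab3` reads through β to a distinct stop inside the linker-3
terminal exon (coding, unique C-terminus); `VII-ab2a` meets an early stop
inside the shifted transmembrane exon, far upstream of the tail junction
(NMD candidate); β-only chains are unaffected. EGF/TM/tail/linker lengths
are configurable under these congruences, and the classification outcome
is invariant to such changes (tested with an alternative geometry).

The poison exon is 111 nt ≡ 0 (mod 3), so its inclusion does not disturb
downstream phases — translation has already terminated inside it.

Two annotated boundary-variant exons (β shifted −3 at its 5′ boundary,
a-tail shifted −4) model junction-wobble decoys; their genomic intervals
overlap their parents, which is the one sanctioned exception to the
non-overlap rule.

## The read simulator

Each read is the amplicon subsequence of one isoform drawn by its planted
fraction, then optionally junction-wobbled (per-read probability 0.02, one
junction, shift uniform on 1..6 nt, insertion- or deletion-type),
optionally truncated (probability 0.05, 10--60% removed from a random
end), mutated per base (substitution 0.02, insertion 0.01, deletion 0.01),
reverse-complemented with probability 0.5, and given Gaussian Phred
qualities around Q14. These rates are deliberately pessimistic
nanopore-amplicon-like values; they are configuration, not constants. All
randomness flows from explicit seeds; a fixed seed gives byte-identical
FASTQ.

The default three-library design mirrors the study's presence/absence
layout: the two secreted short isoforms in every library; the poison-exon
isoforms and the single long isoform in monocytes (with `P-a2a` planted at
2%); the full long-isoform complement in the iPSC-derived progenitors and
macrophages (with `b2b` at 2%); one single-library wobble decoy per
amplicon at 2%. Planted fractions sum to exactly 1 per (library, amplicon)
cell, with decoys and sub-threshold isoforms as explicit entries — an
implicit "remainder" would make the simulated truth unauditable. Depth
defaults to 2,000 reads per library per amplicon.

What the simulator does *not* emulate: raw signal and basecalling,
homopolymer-biased errors, barcode chemistry, PCR chimeras and template
switching, or abundance-dependent amplification bias. Passing tests
therefore demonstrate correctness of the discovery logic under a
homogeneous error model, not robustness to every real-world artifact.

## Discovery

**Amplicon assignment.** A read is oriented by the shared forward primer
at its start (up to 2 substitutions, none in the primer's 3′-terminal
5 nt, small end offsets) and assigned to the short or long amplicon by the
reverse-primer site at its end under the same rule; matching both is an
ambiguity rejection. The rule is substitution-only, so roughly a third of
reads with an indel inside a primer are rejected at the default error
rates — a loss that is independent of isoform identity and therefore does
not bias fractions, which are always computed over assigned, QC-passing
reads.

**Chain calling.** Exact 15-mer seeds on the primary exon sequences
(k-mers occurring in more than one exon are dropped) identify which exons
a read covers and in what order; an exon needs at least two seeds. For
each junction, the seed diagonals nearest the boundary on either side give
a signed offset — the deviation in nt of the read's junction from the
annotated exon boundary (0 for exact reads, ±w for wobble, ±1--2 of indel
noise). Overall identity is `matches / alignment columns` from a
global-local alignment of the read against the spliced chain reference
trimmed to the amplicon; per-exon identities come from the same alignment.
Full-length means both primer sites within 10 nt of the read ends. The
caller is deterministic and needs no external aligner or SAM intermediate.

**QC gates** (defaults, all configurable): identity strictly > 0.95;
full length required; fraction of junctions placed within 6 nt strictly
> 0.90; mean base quality ≥ 10 applied only when qualities are present.
Miscalled chains (a dropped exon) produce one junction offset equal to the
missing exon's length and fail the junction gate.

**Clustering and wobble collapse.** Reads group by exon chain after each
junction offset is snapped to the nearest annotated boundary within the
6-nt tolerance: the primary boundary (offset 0) or an annotated
boundary-variant exon, in which case the chain is rewritten to that
variant. Read-level random wobble thus merges into the majority chain,
while systematically shifted chains survive as distinct candidates. A
candidate that differs from a better-supported one only by such
boundary-variant substitutions is a *minor wobble chain*: detected in
exactly one library it is flagged `artifact` (the study's
manual-removal rule); detected in several it is retained and judged by
fraction alone. A +3 wobble at the variant's own junction is
indistinguishable from the variant by construction, so occasional
multi-library wobble noise can keep a variant chain unflagged — it is
still excluded from the high-confidence set by the fraction filter.

**Quantification and the 5% filter.** Fractions are per (library,
amplicon) cell over that cell's QC-passing reads; empty cells are absent,
not zero. A candidate is `high_confidence` when it reaches 5%
(inclusive) in at least one cell of either amplicon and is not
artifact-flagged; the reported set is the union over cells. Raising the
threshold can only shrink the set (tested). Counts are conserved: the
candidate counts of a cell sum exactly to its QC-passing reads.

## ORF, NMD and domain annotation

`findInitiatingAtg()` returns the first ATG whose frame matches the
canonical frame propagated from the locus anchor; the 114-nt UTR is
ATG-free by construction, so the fixture answer is 115. Translation uses
the standard nuclear code to the first stop; the translation path is
cross-checked in the tests against an independent character-level codon
table. Exons whose actual entering phase differs from their annotated
phase are recorded as frame-shifted.

The NMD rule is the standard 50-nt rule — a stop ending more than 50 nt
upstream of the final exon-exon junction is premature — with the distance
configurable; the study only theorises NMD, and this is the field's
operationalisation. A transcript with no in-frame ATG is `noncoding`
(none among the fixtures); a stop in the last exon, or within 50 nt of the
final junction (the b-tail stop), is `coding`.

Domains map residues to exon roles by the codon's centre nucleotide, so
junction-bridging codons belong to the downstream exon; this single rule
yields the 8-residue class-specific segment and the 17-residue shared
segment without special-casing. A transmembrane call requires the TM exon
fully translated in its annotated frame; coding isoforms without one are
secreted forms. The catalogue arithmetic appends accepted coding isoforms
to the 28 reference isoforms (28 + 5 = 33 on the fixture set), with
duplicate names rejected.

## Pfaffl quantification

Primer efficiency is fitted by least squares of CT against log10
concentration; `E = 10^(-1/slope)` (slope −3.32 cycles per decade for
E = 2), with an error for non-negative slopes. The printed single-sample
formula has the housekeeping gene's efficiency raised to the *sample's*
CT in a way that would make the ratio grow with the target's CT;
`relativeExpression()` therefore uses the standard Pfaffl convention,
`E_hkg^CT_hkg / E_goi^CT_goi`, which is strictly decreasing in the target
CT. Between samples, `comparativeExpression()` uses
`E_goi^(-ΔCT_goi) / E_hkg^(-ΔCT_hkg)` with `ΔCT = CT(sample1) −
CT(sample2)`, which reduces algebraically to `2^-ΔΔCT` at equal
efficiencies (tested numerically). Undetected targets (classes IV--VI in
the study) are missing values with an `undetected` flag, never CT 40 or
ratio 0. Technical replicates are summarised by mean CT.

## Numerical choices and problem sizes

* Junction tolerance 6 nt ("a few bases" is unquantified in the source
  material); it is both the QC junction-accuracy tolerance and the wobble
  snap radius, so a read judged junction-accurate is also snappable.
* Read-assignment ties cannot arise: a read maps to exactly one chain
  group, and candidate ordering in reports is by total support then chain
  id.
* The `fixtureConfig()` seed (1150) fixes the golden fixture sequences;
  the pipeline's top-level seed drives simulation only, so the locus is
  identical across runs by default.
* The end-to-end recovery checks run the full study design (3 libraries ×
  2 amplicons × 2,000 reads) over three seeds; the seed-stability property
  test uses 600 reads per cell over five seeds, and the remaining unit
  tests use 25--250 reads — sizes chosen so the whole suite exercises
  every code path at desk scale.
* Monte-Carlo efficiency recovery uses 100 seeds at CT noise 0.1 cycles
  and checks the mean against a 2-standard-error band.

## Known limitations

* The chain caller assumes the amplicon structure of the fixture (forward
  primer in the first exon); it is not a general-purpose spliced aligner.
* Junction offsets are estimated from seed diagonals and carry ±1--2 nt
  of indel noise; offsets are interpreted only relative to the 6-nt
  tolerance.
* Boundary-variant exons model 5′-boundary wobble only.
* The artifact rule flags but never promotes: a sub-threshold
  multi-library isoform stays `low_abundance`, exactly as the study left
  β2b and P-α2a.
* qPCR modelling covers dilution series and ratio arithmetic; no
  thermal-cycler file parsing and no donor-level statistics.
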