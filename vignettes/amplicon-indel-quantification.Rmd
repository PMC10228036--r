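---
title: "Methods: quantifying editing outcomes from amplicon reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying editing outcomes from amplicon reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliquant)
```

This vignette documents the statistical and algorithmic model behind
ampliquant: what each stage computes, why the defaults are what they
are, how the built-in simulator is constructed, and where the
approach's limits lie. The worked sizes below (200-bp amplicons,
hundreds to thousands of reads) are the package's own choices for
illustration; nothing in the implementation depends on them.

## Problem statement

A CRISPR editing experiment produces reads from an amplicon spanning
the target site. Each read is either unedited or carries a small set of
edits — insertions and deletions from end-joining repair, substitutions
from base editors or from sequencing error. The quantities of interest
are: the fraction of reads that are *modified* near the cut site, the
table of distinct editing outcomes with their frequencies, and
per-position edit profiles. All coordinates in the package are 0-based
half-open; qualities are Phred scores stored as integers.

## Preprocessing

**Trimming.** The 3' tail of a read is trimmed with a sliding-window
rule: the longest 3' suffix in which every trailing window (up to
`window_size` = 4 bases ending at each suffix position, clipped at the
suffix start) has mean quality below `window_quality` = 20 is dropped,
iterated to a fixpoint. Clipping windows at the suffix start matters:
a window reaching back into the kept prefix would dilute a genuinely
bad tail with good bases and under-trim. The fixpoint iteration makes
the operation idempotent — removing one bad suffix can expose another
once the good bases just past the cut no longer prop up its windows.

**Filtering** applies three ordered checks — length < 15, more than
5 N bases, more than 40% of bases below Q15 — and reports the first
failure, so every dropped read has exactly one reason and the counts
satisfy the conservation identity
`reads_in == reads_out + dropped_quality + dropped_n + dropped_length`.
These thresholds are the documented defaults of the widely used fastp
tool, chosen so behaviour on typical amplicon data is familiar rather
than novel.

**Paired-end merging** reverse-complements the second mate and scans
every "innie" overlap of length at least 10, scoring each by mismatch
fraction (N counts as a match). The lowest-fraction candidate wins,
ties going to the longer overlap; candidates above a 25% mismatch
fraction are rejected. Consensus bases that agree keep quality
`min(60, max(q1, q2))`; disagreements keep the higher-quality base at
quality `|q1 - q2|` — the standard posterior-style deflation used by
overlap mergers: a disagreement is evidence against both calls.

## Alignment model

Reads are aligned to each reference with a semi-global
(*glocal*) dynamic program: global in the read (every read base must be
explained — reads may not be clipped, since a clipped indel would
silently vanish from the counts), with free end gaps in the reference
(an amplicon read may start anywhere inside a longer reference). The
affine gap model scores match +1, mismatch −4, gap of length L at
−(6 + L); an N in the read scores 0 against anything. The scoring is
the classic three-matrix Gotoh formulation, compiled in C++ (the
only compiled code in the package); the traceback prefers
match/mismatch, then deletion, then insertion, which can never produce
a leading or trailing deletion run (free end gaps dominate them).

The mismatch/gap ratio encodes a prior: with mismatch −4 and 1-base gap
−7, two adjacent substitutions (−8) are *just* more expensive than a
1-base indel plus nothing — so isolated sequencing errors stay
substitutions, while genuine short indels, which desynchronize the
entire downstream alignment, are recovered as gaps. A read whose best
score falls below 30% of its maximum attainable score (its length) is
`unmapped`; if the forward strand falls below this threshold the
reverse complement is tried. When two references tie for the best
score the read is `ambiguous` rather than arbitrarily assigned — on
identical alleles this is the only honest answer.

## Indel left-alignment

On repetitive sequence an indel's placement is ambiguous: deleting any
`A` of `AAAA` yields the same read. Alignments are therefore
normalized by shifting every gap run to the smallest reference
coordinate that still explains the read — the variant-normalization
convention. A deletion moves left past an aligned column as long as the
read base that hops over the gap matches the reference base it lands
on; insertions move analogously. The operation preserves the implied
read, is idempotent, and preserves the score of optimal alignments.
Left-alignment is what makes signature counting well-defined: all
co-optimal placements of the same physical edit collapse to one key.

## Quantification

Edit events are transcribed from the left-aligned CIGAR: one deletion
per D run, one insertion per I run (anchored at the count of reference
bases to its left), one single-base substitution per mismatched M
column. Adjacent mismatches are deliberately *not* merged into
multi-base substitution blocks — base-editor analysis needs single-base
resolution.

The *quantification window* defaults to ±10 bases around the declared
cut site (the whole reference when no cut site is given). In `indel`
mode a read is modified iff a deletion footprint intersects the window
or an insertion anchor touches it; substitutions never count, so
sequencing errors cannot inflate editing estimates. In `base_editor`
mode window substitutions also count. The window governs
*classification* only; a read's *signature* keeps all of its indels
wherever they fall, so distant co-occurring edits are not silently
merged into the cut-site tally.

Signatures are serialized as `position:code:length[:bases]` tokens
(`8:D:3`, `6:I:2:GG`, `10:S:1:A`) joined by `;`, with `WT` for the
empty signature. Tallying asserts two conservation identities on every
run — `total == mapped + unmapped + ambiguous` and, per reference,
`assigned == modified + unmodified == sum of signature counts` — as
hard errors, not warnings.

## The simulator as the package's oracle

The simulator draws, per read and in a fixed order (outcome, fragment
coordinates, qualities, errors) from one seeded RNG stream, so a
specification reproduces its sample byte for byte. Outcomes are drawn
from a user spectrum of signatures with fractions; the remainder is
unedited. Qualities follow a truncated normal (mean 35, sd 3, clamped
to [2, 41] — a caricature of modern Illumina quality strings);
substitution errors are uniform at a configurable per-base rate.

The design rationale: every pipeline claim in the test suite is checked
against a *truth table* the pipeline never sees. Error-free simulations
must be recovered read for read with zero tolerance; noisy simulations
must be recovered within binomial expectation. One subtlety is
deliberate: the simulator writes truth keys in the coordinates the user
specified, while the pipeline reports *left-aligned* coordinates — on a
repeat these can differ, and the verification studies canonicalize the
truth key (with an independent implementation of the shift rule) before
comparing.

## Whole-genome regions mode

For targeted analysis of whole-genome input, BED regions (±100 bp of
genomic flank, so reads overhanging the region edges still align
end-to-end) are extracted as references. A hash-set prefilter over all
k-mers (default k = 15) of the regions and their reverse complements
skips reads sharing no k-mer with any region; such reads cannot reach
the 30% score threshold, so skipping them before dynamic programming
changes no result while removing almost all of the cost on off-target
reads. At error rate 0 a read from a region with at most
`floor((read_length − k)/k)` edits always shares a k-mer, so no true
read is lost; at realistic error rates the guarantee is statistical.

## Numerical choices, in one place

| Quantity | Default | Rationale |
|---|---|---|
| match / mismatch / gap open / extend | +1 / −4 / 6 / 1 | errors stay substitutions; real indels become gaps |
| min mapped score fraction | 0.30 | rejects unrelated reads, tolerates dense edits |
| trim window / quality | 4 / Q20 | fastp-like sliding window |
| qualified quality / max fraction / max N / min length | Q15 / 40% / 5 / 15 | fastp documented defaults |
| min overlap / max mismatch fraction | 10 / 0.25 | FLASH-like merging |
| quantification window | cut ± 10 | conservative, overridable |
| prefilter k | 15 | specific (4^15 ≫ genome) yet error-tolerant |

## Limitations

- Substitution-only sequencing error model in the simulator; no indel
  sequencing errors, quality-correlated errors, or chimeric reads.
- No adapter trimming: amplicon reads are primer-defined; data with
  read-through adapters should be trimmed upstream.
- Large structural outcomes (inversions, big deletions beyond the
  amplicon) are out of scope; a read not explainable within the
  reference simply goes `unmapped`.
- The aligner is exact but quadratic; it is built for amplicon-scale
  references (hundreds of bases), not chromosomes — which is precisely
  why the regions mode extracts references instead of aligning
  genome-wide.
- One best reference per read: co-amplified paralogs more similar than
  the score threshold can separate will surface as `ambiguous`.
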