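---
title: "Annotating small RNA libraries with srnannot: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating small RNA libraries with srnannot: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnannot)
```

# Scope

`srnannot` annotates small RNA sequencing libraries (miRNAs and their
isomiRs, rRNA/tRNA/sn/snoRNA degradation fragments, tRNA-derived fragments,
piRNA candidates, phased siRNAs) against **user-supplied local reference
collections**. Nothing is downloaded: mature/hairpin miRNA collections,
class-tagged ncRNA/cDNA FASTA files, flanked tRNAs and piRNA cluster
sequences are provided as plain FASTA in a small header dialect
(`?read_reference_fasta`), and genome mappings for the phasing and
ping-pong analyses are consumed as SAM or ELAND3 map files produced by any
external mapper.

Reads are processed in a fixed hierarchy so that **every read is counted in
exactly one category**: adapter trimming (optional), low-complexity
filtering, miRNA annotation, ncRNA/cDNA annotation with tRF classification,
piRNA-cluster candidate calling, remainder unannotated. The summary table
of `run_pipeline()` always sums to the input read count; this conservation
is asserted by the test suite.

# Adapter inference and trimming

Raw reads of dominant (modal) length $n$ are scanned for the most frequent
$m$-mer, ignoring positions 1..22 (a typical miRNA length, so abundant
small RNAs do not masquerade as adapters), with

$$m = n - 22, \qquad 6 \le m \le 12.$$

Counting is weighted by read count; ties break lexicographically, making
inference deterministic. Matching tolerates 2 mismatches for 12-nt motifs,
1 for 9–11 nt and 0 for 6–8 nt. Trimming first searches for the leftmost
occurrence of the full motif anywhere in the read (adapters may begin
before position 23 when inserts are short); reads without a full-motif hit
are tested against 3'-truncations of the motif, down to 6 nt, as read
suffixes only, with the allowance re-derived from the truncated length.

Because the inferred motif need not start at the adapter's first base,
a constant residue of up to a few adapter bases can survive motif trimming.
The positional-bias step removes it: while the count-weighted most frequent
3'-terminal base exceeds the bias threshold (default 0.8), that base is
stripped from the reads ending in it, and the check repeats inward, at most
5 positions. A *universal* terminal base (fraction 1.0) is treated as bias
even at threshold 1.0, so the threshold's upper boundary stays meaningful.

# Low-complexity filter

A read is rejected when a fraction $f > 0.75$ of its length is covered by
non-overlapping copies of a single 1–5-nt motif, or when a fraction
$f' > f + (1-f)\,f$ (0.9375 at the default $f$) of its positions is drawn
from only two nucleotides. Both inequalities are strict. Motif coverage is
counted greedily left-to-right anywhere in the read — tandem arrangement is
not required, which is the more sensitive reading of repetitive
composition. Periodic motifs are canonicalized to their primitive root
(`"ACAC"` counts as `"AC"`) to avoid double counting. The implementation is
checked against an independently coded exhaustive oracle on all sequences
up to length 6 and on seeded random samples up to length 12: full
enumeration of all 4^1..4^12 sequences (≈ 2.2·10^7) is not a practical test
size, and the sampled lengths exercise every code path.

# The mapper and non-template 3' tails

All annotation stages use one ungapped alignment core: every placement of a
read (or its reverse complement) on a reference with at most `max_mismatch`
substitutions is enumerated. References are concatenated into a single
subject separated by `N` runs — `N` never matches, and hits crossing a
separator are discarded — so each read costs one vectorized position scan
(`Biostrings::neditStartingAt` machinery) instead of a loop over
references. Reads containing `N` never align. Equivalence with a
brute-force position scan is tested exhaustively for short reads and on
random instances.

**Tail semantics.** The non-template 3' tail of an aligned read is the
*maximal trailing run* of bases that disagree with the templated
continuation of the reference at that locus (positions beyond the reference
end always disagree). A templated base therefore always belongs to the
aligned core, and a disagreeing terminal base is always tail, never an
"internal modification" — the two are indistinguishable in sequence data,
and resolving the ambiguity toward tailing keeps tail statistics faithful
for the overwhelmingly more common case of genuine post-transcriptional
additions. If the run exceeds `max_tail` (default 2 nt), the read is not
annotated at that locus; if the remaining core exceeds `max_mismatch`, the
locus is likewise rejected. A direct consequence, reflected in the
synthetic generators: a substitution at a read's terminal position is
reported as a 1-nt tail, so the generators never plant mutations there
(the truth label would be ill-defined).

# miRNA annotation

Reads are annotated against hairpin references, sense strand only, in four
tiers per species scope: (i) canonical miRNAs, (ii) 3'-tailed canonical
miRNAs, (iii) offset miRNAs (moRs), (iv) 3'-tailed offset miRNAs — first
for the library's own species, then for all other species in the
collection, with the source species reported per hit. A read is assigned to
the **first** tier in which it has at least one hit; equal hits to several
genes within that tier split the read count uniformly per gene. Defaults:
at most 2 non-template 3' nt, at most 1 internal modification.

A hit is canonical when the read's 5' end coincides with a mature 5' end on
the hairpin; it is an offset miRNA when the 5' end falls within ±5 nt of a
mature 5' end without coinciding. The ±5 window follows the moR literature
and is configurable (`offset_window`); reads elsewhere on the hairpin are
not miRNAs — de novo discovery is out of scope. Offset reads may carry
internal modifications and tails, mirroring the tier names.

Internal modifications are recorded at mature-relative positions (read
position + offset) with their `from>to` base change and aggregated into a
position × substitution matrix; tails are summarized as
mono-/di-nucleotide A/C/G/T/mixed composition
(`modification_matrix()`).

# ncRNA/cDNA annotation and count apportioning

Reads left over from the miRNA stage map to the class-tagged collection
with a default of 1 mismatch — the package's own default, chosen because
fragment annotation must tolerate the single mismatches that dominate real
sequencing error and modification patterns (the synthetic tRF benchmark
plants exactly one mismatch in half of its reads). The *best hits* of a
read are those with the minimal mismatch count (tail length does not enter
this comparison); the number of distinct classes among them, $h_i$, defines
the fractional assignment

$$c_{class} = \sum_i \frac{r_i}{h_i},$$

where $r_i$ is the read count of sequence $i$. Conservation
$\sum_{class} c_{class} = \sum_i r_i$ holds exactly and is verified against
an integer-arithmetic oracle. Protein-coding (cDNA) references participate
on equal footing with ncRNA classes.

## tRNA fragments

tRNA references carry genomic 5'/3' flanks declared in their headers
(`pad5`/`pad3`). Since secondary-structure prediction is out of scope, the
cloverleaf landmarks of a mature tRNA of length $L$ are projected
proportionally from the canonical 76-nt tRNA:
D-loop end $\mathrm{round}(25L/76)$, anticodon loop
$\mathrm{round}(31L/76)$–$\mathrm{round}(39L/76)$, TψC-loop start
$\mathrm{round}(52L/76)$, each compared with ±2 nt tolerance
(configurable). Eight classes are assigned from the aligned coordinates:
5' tRF (5' end to D-loop), 5' tR-half (5' end to anticodon loop), 3' tRF
(TψC-loop to 3' end), 3' CCA-tRF (same, ending in the CCA), 3' tR-half
(anticodon loop to 3' end), tRF-1 (from just after the mature 3' end to the
first oligo-T ≥ 4 in the trailer), tRNA-leader (ending within tolerance
upstream of the mature 5' end), and misc-tRF for anything else on the tRNA,
including antisense and full-length reads.

Because mature tRNAs carry a post-transcriptional CCA, mapping to tRNA
references additionally allows a 3' tail of up to 3 nt that spells the CCA
end; a read reaching the mature 3' end with CCA — templated or not — is a
3' CCA-tRF. A read's tRNA share ($r_i/h_i$) is divided equally among the
tRNA genes it hits best and classified per gene.

# piRNA candidates and the ping-pong signature

Reads not annotated as any other class map to piRNA cluster sequences,
exactly by default (0 mismatches): piRNA sequences are diverse, and exact
cluster mapping limits false positives while any position in a cluster can
legitimately be a piRNA 5' end. Hits become "piRNA candidates"; their
length distribution and positional nucleotide composition (e.g. the
1U bias) are reported like for every class (`summarize_class()`).

Given a genome/cluster map file, the ping-pong signature is computed from
all opposite-strand read pairs whose 5' ends overlap by $d \in 1..20$ nt:
bin $d$ accumulates the product of the two read counts. The Z-score
compares the 10-nt bin against the 19 background bins (1..9, 11..20) using
the sample standard deviation; a constant background yields `NA`. The 1..20
range with the 10-nt bin excluded from the background is the declared
convention of the package.

# phasiRNA detection

Reads of the phase length $i$ (user-supplied, e.g. 21 or 24) are
*consolidated*: plus-strand reads by their 5' coordinate, minus-strand
reads by their leftmost coordinate minus 2, so both partners of the 2-nt
3'-overhang duplex fall into the same register. Windows of 1 kb (default)
slide with step `window/2` across the read-covered span of each target;
within a window the register (position mod $i$) with the largest weighted
read count defines $j$, and $n$ counts all length-$i$ reads. The
probability of observing more than $j$ phased reads by chance is the
binomial tail

$$p = 1 - \sum_{k=0}^{j} \binom{n}{k} q^k (1-q)^{n-k}, \qquad q = 1/i,$$

evaluated as the exact upper tail (`stats::pbinom`, stable for
$n$ up to at least $10^5$) and verified against brute-force summation to
1e-12 for all $j \le n \le 60$. The formula counts *more than* $j$; because
the verbal definition ("a defined number or more") suggests $\ge j$, an
`inclusive` flag provides that variant, with the printed formula as the
default. The legacy eight-cycle phase score
$P = (n-2)\ln(1+\sum k)$ is available for comparison (`phase_score()`) but
is not used for calling; its exponent is undefined below two occupied
cycle positions, where 0 is returned with a `degenerate` attribute.

A window is called phased when all of the following hold: $p$ is below
$\alpha / N$ with $\alpha = 0.05$ and $N$ the number of windows actually
analyzed (containing ≥ 1 length-$i$ read — strict Bonferroni; overlapping
windows each count); phased reads make up ≥ 50% of *all* mapped reads in
the window; they occupy ≥ 5 distinct consolidated positions; and no strand
contributes more than 90% of them. The strand-bias default is 0.9, with the
threshold exposed (`max_strand_frac`) since values up to 0.95 are
defensible. Overlapping called windows merge into maximal runs for
reporting and the phased sequences are reported deduplicated. Because the
statistic is windowed, background reads outside the window do not affect
the call — sensitivity to a planted locus is flat under genome-wide
background, which the acceptance checks sweep explicitly; the Bonferroni
divisor grows with the covered span, which the planted loci survive easily
(their $p$ is astronomically small).

# Synthetic data generators

All fixtures are generated in code, deterministically under a seed
(`with_seed()` leaves the caller's RNG untouched). They emulate the
*structure* of real inputs, not their full statistics: uniform base
composition, no sequencing-quality errors beyond single substitutions, no
hairpin secondary structure, no codon or modification biases. Passing tests
therefore demonstrate algorithmic correctness on well-posed inputs, not
performance on real libraries.

* `gen_hairpins()` / `gen_mirna_testset()`: random hairpins with planted
  matures placed so the full ±5 offset grid fits; the read grid enumerates
  every offset × tail × mismatch combination per mature (tails: none, 4
  mono-, 16 di-nucleotide). Tail bases that would coincide with the
  templated continuation are deterministically replaced — every emitted
  tail is genuinely non-template — and internal mutations avoid the
  terminal position, where tailing and substitution are indistinguishable.
  `count_range = 1:10` attaches per-scenario counts so per-gene correlation
  with truth is well-defined.
* `gen_trnas()` / `gen_trf_testset()`: tRNA bodies of 70–80 nt (never
  ending in CCA) with 20-nt flanks; the trailer starts `GTT` — disjoint
  from CCA at each position, so a non-template CCA always splits cleanly —
  and carries an oligo-T at trailer positions 15–18. One read per class per
  tRNA, random counts 1–100, one internal substitution planted in half of
  the sequences (never in a CCA end or the base before it).
* `gen_phased_testset()`: phased registers spaced $i$ nt on alternating
  strands (minus reads shifted +2 per duplex geometry), optional uniform
  background placed *outside* the planted locus, emulating genome-wide
  background away from the source region.
* `gen_pingpong_testset()`: opposite-strand pairs with exact 5' overlap
  $d$, or random $d$ for signature-free nulls.
* `gen_adapter_testset()`: insert + adapter + random fill at fixed read
  length; inserts are redrawn if the read would contain a ≤ 2-mismatch
  copy of any 12-nt adapter window upstream of the true junction, because
  no trimmer can define a unique insert for such a read.

# Problem sizes and numerical choices

The shipped verification runs use desk-scale instances chosen to exercise
every code path with comfortable margins: 50 synthetic hairpins
(≈ 1.3·10^5 grid reads) for miRNA recovery, 20 tRNAs × 8 classes for tRF
assignment, 1,000 random hit tables for apportioning, all $j \le n \le 60$
for the binomial tail, 100 null maps for the phasing false-positive rate
and 200 for the ping-pong null. Ties anywhere (motif counts, register
choice) break lexicographically or by coordinate so all outputs are
deterministic; result tables are written with sorted keys and byte-identical
across reruns. Thresholds are compared strictly where the defining
inequality is strict ($f$, $f'$, bias, $p$); boundary cases are pinned by
unit tests.

# Known limitations

* Ungapped alignment only; indels in reads are not modeled (consistent
  with fragment annotation practice, but divergent loci will be missed).
* The cloverleaf projection is proportional, not structure-based; unusual
  tRNAs (long variable arms) may shift true loop boundaries by more than
  the 2-nt tolerance.
* Cross-species miRNA annotation unions all non-self records; it does not
  rank species by phylogenetic distance.
* SAM input is restricted to ungapped primary records (pure-match CIGAR);
  BAM is not read — convert externally.
* The low-complexity filter's motif scan is quadratic in read length; it
  is intended for small RNA read lengths (< 100 nt), not long reads.
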