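---
title: "Anchor-guided assembly of B-cell receptor chains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchor-guided assembly of B-cell receptor chains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcrasm)
```

## The problem

A B cell's receptor (BCR) is encoded by somatically rearranged loci: one V,
(for the heavy chain) one D, and one J gene segment are recombined with
junctional trimming and untemplated insertions, the transcript continues
into a constant (C) region, and affinity maturation adds somatic
hypermutation (SHM) — point mutations concentrated in the V(D)J region.
Short-read single-cell RNA-seq of a B cell therefore contains reads from two
transcripts (heavy and light chain) that match no reference exactly:
reference-guided assembly breaks on the rearrangement and the mutations,
while a fully de novo assembler must solve a much harder general problem and
often loses the junction. `bcrasm` takes the middle road: *semi-de novo*
assembly, in two stages.

**Stage 1 — anchors.** Reads are mapped to four germline component sets —
heavy variable (IGHV), heavy constant (IGHC), pooled kappa+lambda light
variable (IGK/LV) and pooled light constant (IGK/LC). For each component the
fixed-length window with the highest number of overlapping read placements
becomes that component's *anchor*: a germline-derived sequence that is close
enough to the cell's transcript to recruit its reads. Pooling kappa and
lambda means the cell's light-chain locus is decided by which genes win the
read-support competition, not by a prior choice.

**Stage 2 — greedy extension.** Each anchor is extended 3' and then 5', one
read at a time, through exact suffix–prefix overlaps (a read may join in
either orientation). Extension stops when no read overlaps the contig end,
when the chosen read has already been used in this pass (a repeat has been
re-entered), or at a length cap. Per chain, if the variable-anchored and
constant-anchored contigs agree they are reported as a single merged
sequence; otherwise both contigs are reported separately.

Mapping uses an internal exact k-mer seed index with Hamming verification
rather than an external aligner, which keeps the package self-contained and
byte-deterministic; the mapping layer is written against the index
interface, so a wrapper around an external aligner could be substituted
without touching anchor selection.

## Parameters that matter

| parameter | default | meaning and rationale |
|---|---|---|
| `k` | 16 bp | seed k-mer for germline mapping; exact 16-mers are specific against ~300 bp references while leaving room for mismatches in a 50 bp read |
| `w` | 50 bp | anchor window length — one read length; the window only needs to seed extension, not span the gene |
| `max_mismatches` | 3 | per-placement substitution budget (50 bp reads): absorbs SHM plus sequencing error |
| `min_anchor_support` | 3 reads | guards against spurious single-read anchors |
| `m` | 20 bp | minimum read overlap during extension; under half a read, so adjacent read starts may be up to `read_len - m` apart |
| `max_len` | 1500 bp | contig cap, roughly a full-length chain transcript |
| `min_score` | 30 | annotation call threshold on the local-alignment score (match +1, mismatch −1, gap −2); random 300 bp sequence pairs score below ~20 under this scheme, genuine segment hits score in the hundreds |

All tunables are function arguments and are echoed to the log by the
command-line wrapper.

## Resolved ambiguities and numerical choices

Several points of the two-stage scheme admit more than one reading; the
package fixes them as follows and reports them here rather than applying
them silently.

* **Candidate choice per extension step.** Among reads overlapping the
  contig end, the read with the *longest* exact overlap wins — the most
  conservative extension. Ties break by shortest appended suffix, then
  lexicographic oriented sequence, then read id, making assembly fully
  deterministic.
* **Contained reads.** A read whose overlap equals its whole length adds no
  sequence. Such reads are not extension candidates: at high coverage a
  greedy longest-overlap rule would otherwise consume duplicates of already
  incorporated reads and trip the repeat rule before extending at all. The
  overlap relation is therefore *proper* suffix–prefix overlap.
* **The repeat rule.** "A repeat is found" is made concrete as: the winning
  candidate at this step was already incorporated in the current extension
  pass. In linear sequence each step's terminal context is fresh, so a
  previously used read can win again only when extension has cycled back
  into the same context — exactly the signature of a repeat longer than a
  read. The winner is judged among *all* matching reads, used or not;
  duplicated reads have distinct ids, so coverage-level duplication does not
  trigger the stop.
* **Overlap exactness.** Overlaps must match with 0 mismatches. Greedy
  extension with inexact overlaps compounds errors into the contig; the
  anchor stage already absorbs germline divergence, and at 100x coverage an
  error-free path through the transcript almost always exists.
* **Finding overlaps longer than `m`.** The prefix map is keyed on each
  read's first `m` bases, but a read overlapping the contig by `ov > m`
  bases has its prefix aligned `ov` bases before the contig end. The
  extender therefore probes the map at every candidate overlap length from
  the longest down to `m`, verifying the full overlap exactly; stopping at
  the first verified length yields the longest-overlap candidate set
  directly.
* **The merge test.** Two extended contigs "being equal" is relaxed to:
  one contains the other, or they share an exact suffix(V)–prefix(C)
  overlap of at least `m` bases (the variable region lies 5' of the
  constant region). The 5'/3' extents of the two extensions rarely coincide
  exactly, so literal equality would split almost every chain.
* **5' extension** is implemented as reverse-complement, 3'-extend,
  re-complement. The test suite checks it against an independent naive
  extender (no index, direct scan over all reads) rather than against that
  identity, so the check is not vacuous.
* **Anchor ties** break to the lexicographically smallest germline name,
  then smallest window start.
* **Gene calls** use `Biostrings::pairwiseAlignment` local alignment with
  match +1, mismatch −1, gap −2; the best-scoring candidate is called, ties
  break lexicographically. D segments (~16 bp) are too short for reliable
  best-hit calling at this granularity and are deliberately not called.
  Reads or contigs containing `N` are handled by the alignment's ambiguity
  scoring.

## The simulator: what it emulates, and what it does not

`sim_germline_db()` builds a fully synthetic germline set (uniform-random
sequences, IMGT-like names suffixed `-syn`, ~300 bp V, ~16 bp D, ~50 bp J,
constant regions truncated to 300 bp — assembly only ever needs the
constant-region prefix adjacent to the junction). `sim_receptor()` emulates
V(D)J recombination: uniform gene choice (light-chain V/J/C drawn coherently
from one locus), 0–3 bp junctional trimming, junctional inserts of 0–10 bp,
and i.i.d. substitution SHM over the V(D)J span. `sim_reads()` produces
uniform-coverage 50 bp reads on uniform strands with i.i.d. substitution
errors, optionally paired, optionally with a masked interval to create a
controlled coverage gap.

Deliberate simplifications, and what they mean for interpreting green
tests:

* **Random germline genes are unrelated to each other**, whereas real IGHV
  genes share 70–95% identity. Anchor competition and V-gene calling are
  therefore easier here than on real data; the tests demonstrate the
  machinery is correct, not that gene-level accuracy on real repertoires
  will match the simulated rates.
* **Uniform coverage** rather than the 3'-biased coverage of oligo-dT
  protocols; a 3'-bias stress mode is not a default condition.
* **Substitution-only SHM and sequencing error** (no indels), which keeps
  the exact-overlap recovery property well defined. The mapper verifies by
  Hamming distance, so indel-bearing reads would simply fail to place.
* Gene-usage frequencies, clonal structure and expression levels are not
  modelled.

## Problem sizes and acceptance-level checks

The cohort-level tests and `scripts/acceptance.R` run the full pipeline at
the package's design conditions: 50 simulated cells per regime, both
chains, 50 bp reads at 100x coverage, `m = 20`. The noise-free regime must
reach 100% merged assemblies containing the full true transcript with 100%
correct V/J/C calls; the realistic regime (3% SHM, 0.5% sequencing error)
must reach at least 90% correct V-gene identification. Anchor selection is
compared against exhaustive window enumeration on 200 random instances, and
extension against the naive no-index extender. Split-fallback behaviour is
forced with a masked inter-anchor interval of `read_len − m` bases.

For the simulator calibration checks, each of 100 seeded replicates is
compared with the closed-form central 99% binomial interval for its own
trial count; the acceptance bound allows up to four replicates outside the
interval, since with 100 draws from a correctly calibrated generator the
probability of more than four misses is under 0.5% — demanding all 100
inside would reject a correct simulator more than a third of the time.

## Known limitations

* Greedy extension takes no consensus: a sequencing error carried on the
  read chosen at a step enters the contig verbatim. At realistic error
  rates this typically truncates extension rather than corrupting calls
  (the next true read no longer overlaps exactly), which is why the
  realistic-regime criterion is about gene identification rather than
  full-length recovery. Pileup-based polishing is out of scope.
* Placement is substitution-only (no indel-tolerant mapping, no
  Smith–Waterman in the mapper).
* A single chain per locus is assumed; a doublet (two cells) would produce
  competing anchors of which only the strongest is pursued.
* Expression quantification, CDR3 delineation and clonotype grouping are
  out of scope.
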