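---
title: "Methods: rolling-circle 16S-ITS consensus and rrn resolution"
author: "rcaits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rolling-circle 16S-ITS consensus and rrn resolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Bacterial genomes carry one to ten-plus copies of the ribosomal RNA operon
(rrn). The 16S gene resolves taxa to roughly the species level; the internally
transcribed spacer (ITS) between the 16S and 23S genes evolves much faster and
distinguishes strains and even individual rrn copies within one genome — but
only if 16S and ITS are read together, on one molecule. Rolling-circle
amplification of a circularized 16S-ITS amplicon produces a long nanopore read
containing the same insert repeated `k` times, separated by copies of a splint
sequence. Each repeat is an independent observation of one molecule, so a
per-read consensus removes most of the ~2% single-pass error.

`rcaits` implements the full computational path from raw concatemer reads to
per-rrn consensus sequences and community statistics, plus a seeded simulator
so every stage is testable at desk scale without external data.

## Pipeline overview

1. **Segmentation** (`findJunctions`, `splitRead`): the junction cassette
   (reverse-complemented unique primer tail, splint, forward unique tail) is
   located on both strands by iterated local affine-gap alignment in
   overlapping windows; the intervals between junctions become candidate
   sub-reads. Only sub-reads of 1500–3500 bp are valid.
2. **Barcode validation** (`barcodeConsensus`, `validateAndClip`): each insert
   carries a 5-bp random barcode at both ends. Per side, the observations are
   multiply aligned and a gapped consensus taken: a column's plurality
   character is emitted when its frequency reaches the cutoff (default 0.6),
   otherwise `N`; gaps are removed. A consensus longer than 5, or mostly
   ambiguous, marks a mixed read, which is discarded. Barcodes are clipped
   before any further analysis.
3. **Per-read consensus** (`alignSubreads`, `pruneOutliers`,
   `buildConsensus`): sub-reads are aligned center-star against an evolving
   column profile (banded affine DP, in C++). Each sub-read is scored against
   the plurality column consensus — 1 point per matching column, 0.5 where the
   sub-read has a gap under a consensus base, 0 otherwise — and sub-reads
   under 65% of the alignment width are removed iteratively, re-aligning after
   every removal, until nothing is removed or three or fewer remain. Gap-free
   consensi with at least 5 surviving sub-reads continue.
4. **Genus clustering** (`extract16S`, `rescue16S`, `greedyCluster`,
   `assignTaxonomy`): the 16S gene is cut out between the 27F and 1492R
   motifs (strict IUPAC matching, with similarity rescue against
   high-confidence seeds for primer-mutated sequences) and clustered greedily
   at 95% identity — roughly genus level. Clusters under 5 members are
   excluded. Labels come from the modal best-hit of members' V4 regions
   against labeled references.
5. **Correction and trimming** (`buildGenusMsa`, `correctMsa`, `trimMsa`):
   per-genus MSAs are repaired locally where progressive alignment gapped
   inconsistently, then corrected in two passes: pass 1 only counts would-be
   corrections per sequence (a column with a ≥98% dominant character corrects
   its minorities to it; otherwise characters under 2% become `N`) and
   excludes sequences with more counted corrections than 0.05% of their
   length; pass 2 recomputes the tallies on survivors and applies them. Ends
   are trimmed to the first/last column with ≥98% non-gap characters.
6. **rrn resolution** (`variableColumns`, `extractSubsequences`,
   `sweepCluster`): columns whose majority character (over non-`N` rows)
   falls below 95% are variable; each is extracted with 4 flanking columns,
   overlapping windows merged. These slices concentrate the discriminating
   signal. They are re-clustered over an identity ladder (default 0.90–0.99
   in 0.005 steps, then 0.9925/0.995/0.9975/0.999 — the finer top matters
   because an insertion among the variable columns inflates the window
   denominator, pushing one-SNP operon pairs above 0.995 window identity;
   column-wise identity with `N` as a wildcard); clusters
   under 5% of the input are excluded as putative chimeras; survivors map
   back to full-length clusters whose plurality consensus is the rrn call.
7. **Chimera screening** (`detectChimera`): against vetted references, a
   candidate is compared to its best single reference (global edit distance)
   and to the best ordered reference pair under a one-breakpoint model
   (prefix-distance array to parent A plus suffix-distance array to parent B,
   minimized over the breakpoint). It is chimeric when the two-parent model
   saves ≥4 edits *and* ≥1.5% of the candidate length.
8. **Statistics** (`estimateError`, `chisqUniform`, `correlationStats`,
   `informativeSites`, `survivalTable`): error rates against references use
   the aligned-region length plus unaligned reference bases as denominator;
   rrn-abundance uniformity is a goodness-of-fit chi-square; cross-platform
   agreement uses Pearson/Spearman on raw counts and the least-squares
   R-squared; stage survival tables carry largest-cluster share and percent
   surviving.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `minSubLen`, `maxSubLen` | 1500, 3500 bp | valid sub-read size window |
| `barcodeCutoff` | 0.6 | column frequency to call a barcode consensus base; majority plus a margin (the value itself is a package choice, exposed in config) |
| `junctionMaxError` | 0.35 | maximum junction alignment error, tuned on the simulator's indel-rich noise |
| `outlierScoreFraction` | 0.65 | sub-read score floor, as a fraction of alignment width |
| `minFinalSubreads` | 5 | support needed to keep a per-read consensus |
| `hiConfSubreads` | 15 | support marking high-confidence seeds for 16S rescue |
| `genusIdentity` | 0.95 | greedy clustering threshold, ~genus level |
| `dominantFraction` / `minorityToN` | 0.98 / 0.02 | the two column-correction branches |
| `maxCorrectionFraction` | 5e-4 | exclusion threshold: counted corrections over 0.05% of the *ungapped* sequence length |
| `trimNongapFraction` | 0.98 | non-gap fraction defining the kept end columns |
| `variableMajorityFraction` | 0.95 | variable-column rule for rrn resolution |
| `flankColumns` | 4 | context kept around each variable column |
| `minClusterInputFraction` | 0.05 | small-cluster (putative chimera) exclusion at the rrn stage; `rescueMinMembers` replaces it with an absolute floor when rare isolates must be kept |
| `chimeraMinEditsSaved` / `chimeraMinIdentityGain` | 4 / 0.015 | two-parent model must beat the single parent by both margins |

Alignment scores default to match +2, mismatch −3, gap open −5, gap extend −1
— a BLAST-like regime scaled to small integers — with the DP band set to the
length difference plus 100 columns.

## What the simulator emulates — and what it does not

`simulateCommunity` emulates: the construct geometry (splint — unique tail —
5-bp barcode — insert — barcode — reverse-complemented tail, repeated `k`
times with `k+1` splints, starting at the priming site next to the splint);
multi-copy rrn sets diverging by single SNPs up to tRNA-sized (80–100 bp) ITS
insertions, including exact duplicates; taxon abundances spread over orders of
magnitude; a ~2% indel-rich error process with a homopolymer indel multiplier
and per-read rate jitter (sub-read identity ≈ 98% ± 1%); a shifted-geometric
repeat count so that most reads fail the ≥5 sub-read filter, which is the
dominant loss in practice; and single-breakpoint template-swap chimeras with a
uniform breakpoint.

It does **not** emulate signal-level artifacts, base-caller-specific error
motifs, realistic quality strings (a flat Phred 20 is written), PCR-cycle
amplification bias, or multi-breakpoint chimeras. Passing tests therefore
demonstrate the pipeline's logic and its behavior under a calibrated
indel-rich error regime — not performance on any particular flow cell. The
default splint is a fixed 386-bp pseudo-random sequence shipped as a fixture
(`extdata/splint_synthetic.fa`): the real splint is a lambda-phage subsequence
that is not public in full, and segmentation takes the splint as an input
either way.

## Numerical choices and tie-breaks

- **Plurality tie-break** (consensus columns, everywhere): bases before `N`
  before gap, bases alphabetically. Fixed so all consensi are deterministic;
  it slightly favors retaining sequence over deleting it.
- **Center-star order**: per-read MSAs seed on the sub-read of median length
  and add the rest in input order; genus MSAs are guided by decreasing
  length. Deterministic for fixed input order; shuffling sub-reads leaves
  clean consensi identical and noisy ones within a couple of edits.
- **Re-alignment between pruning iterations**: removing a divergent sub-read
  can shift columns, so the MSA is rebuilt after every removal — the
  conservative reading of the iterative procedure.
- **Scoring gap-gap columns**: a column where both the sub-read and the
  consensus have a gap counts as a match (character equality), which favors
  retention.
- **Identity definitions**: greedy clustering uses matches over alignment
  columns with end gaps excluded (overlap alignment, the cd-hit-like
  convention); the full-length prefilter includes end gaps (global
  alignment, the "global identity" convention). Both are exposed; each is
  used where the corresponding convention applies.
- **Window identity at the rrn stage** is column-wise on the already-aligned
  MSA slices (no re-alignment, which would erase the signal in 9-column
  windows); gaps count as characters, so operons differing only by a 1–2 bp
  deletion remain distinct; `N` is a wildcard so correction-introduced
  uncertainty never splits a cluster.
- **Correction accounting**: the 0.05% exclusion bound is taken over the
  ungapped sequence length; gap cells participate in column tallies like
  bases (a ≥98% dominant gap may overwrite a minority base, i.e. correct a
  spurious insertion); `N` never counts as dominant. Corrections are applied
  to MSA cells and the ungapped sequences regenerated, keeping the column
  arithmetic aligned.
- **Mixed-barcode rule**: the length test (consensus > 5 after gap removal)
  catches offset mixtures; conflicting *same-length* tags align without gaps
  under a substitution-friendly aligner and instead surface as mostly
  ambiguous columns, so a consensus with more than 2 `N`s is also rejected.
- **Reporting rule for the identity sweep**: when the rrn count is known a
  priori the lowest identity reaching it is used (the threshold is adjusted
  upward, as one does with a reference genome in hand). Unsupervised runs
  default to the modal count across the ladder (`"plateau"`); for corrected,
  trimmed inputs the count curve is a non-decreasing staircase whose top step
  is the finest resolvable structure, so `"terminal"` — the count at the top
  of the ladder — is the choice used in the package's own acceptance runs.
- **Degenerate inputs**: a single sub-read cannot form a consensus (it is
  discarded for insufficient support); a read with zero junctions is
  discarded with its own ledger reason; an alignment whose columns all fail
  the trim rule raises an error rather than returning an empty alignment.

## Problem sizes used in the test and acceptance runs

The packaged runs are desk-scale by design. The read-level acceptance run
uses ~2.0 kb amplicons (1250 bp 16S, 750 bp ITS — inside the 2000–3500 bp
product range the protocol targets; note that at 2 kb the 0.05% correction
bound allows one counted correction, the same regime as a full-length
amplicon) and 450 simulated concatemer reads with a shifted-geometric repeat
count (minimum 2), so roughly a third of reads pass the ≥5 sub-read filter
and ~150 consensus sequences survive. That coverage keeps every operon's
expected share (1/7 ≈ 14%) more than three binomial standard deviations
above the method's intrinsic 5% resolution floor (the variable-column
majority rule and the small-cluster exclusion both blind the sweep to
variants below ~5% of the survivors — a variant that scarce is
indistinguishable from a chimera by design). Module tests use 10–14
consensus-level sequences per operon and 30–40-candidate chimera panels.
These sizes give stable statistics for every check while keeping a full run
in minutes on one CPU.

## Known limitations

- Progressive center-star alignment is adequate for dozens of ~98%-identical
  sequences (its intended substrate) but is not a general-purpose aligner;
  strongly divergent inputs rely on the outlier-pruning and window-repair
  steps to stay consistent.
- The similarity rescue for 16S extraction requires a seed from the same
  genus among the high-confidence sequences; a genus whose every member has
  mutated primer motifs would be lost; this is inherent to seed-based rescue.
- Reference-free chimera detection is limited to the small-cluster exclusion
  heuristic; the two-parent detector needs vetted references.
- Qualities are carried through I/O but never used by the consensus — the
  consensus is purely count-based by design.
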