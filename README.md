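# rcaits

High-resolution profiling of microbial communities from rolling-circle
16S-ITS amplicon long reads.

## The problem

The bacterial ribosomal operon (rrn) couples the taxonomically informative
16S gene to the fast-evolving internally transcribed spacer (ITS). Read
together on one molecule, they resolve not just species but strains and even
the individual rrn copies within one genome. Rolling-circle amplification of
a circularized 16S-ITS amplicon yields a long nanopore read in which the same
insert appears `k` times, separated by splint copies; the repeats are
independent observations of one molecule, so a per-read consensus cancels
most of the ~2% single-pass error.

`rcaits` turns such concatemer reads into high-accuracy consensus sequences
and resolves them into genera and individual rrn copies:

- **segment**: locate splint junctions by local affine-gap alignment, split
  reads into sub-reads (valid size 1500–3500 bp), validate the 5-bp molecular
  barcodes on both flanks by gapped consensus, discard mixed reads, clip
  barcodes;
- **consensus**: center-star profile alignment of the sub-reads (banded
  affine DP in C++), iterative outlier pruning by column scoring (1 point per
  matching column, 0.5 for a gap under a consensus base, drop below 65% of
  the width), plurality consensus; sequences need ≥ 5 surviving sub-reads;
- **cluster**: extract the 16S between the 27F/1492R motifs (with similarity
  rescue for primer-mutated sequences), greedy identity clustering at 95%
  (~genus level), small-cluster exclusion, V4-based taxonomy labels;
- **refine**: per-genus MSA with local window repair, two-pass column
  correction (≥98% dominant characters overwrite minorities; sub-2%
  characters become `N`; sequences with more counted corrections than 0.05%
  of their length are excluded before anything is applied), trim ends to the
  98% non-gap span;
- **resolve**: extract variable columns (majority < 95%) with 4-column
  flanks, re-cluster the slices over an identity ladder (0.90–0.999), exclude
  sub-5% clusters as putative chimeras, emit per-rrn consensus sequences;
  reference-based two-parent chimera detection via prefix/suffix edit-distance
  arrays;
- **stats**: error rates vs references (identities over HSP length plus
  unaligned reference bases), rrn-abundance chi-square, Pearson/Spearman/R²
  agreement between platforms, informative-site counts, stage-survival
  tables;
- **simulate**: a seeded generator for rrn template sets (SNPs, indels,
  tRNA-sized ITS insertions, exact duplicates), stratified communities,
  concatemer reads with an indel-rich ~2% error process, and template-swap
  chimeras — with truth tables, so the whole pipeline is testable offline.

## Worked example

```r
library(rcaits)

con <- defaultConstruct()                  # universal primers + splint fixture
tpl <- makeTaxonTemplate(seed = 7)         # one synthetic 16S-ITS, ~1.7 kb
rrns <- makeRrnSet(tpl, 3, seed = 8)       # 3 rrn copies, 1-2 SNPs apart

spec <- communitySpec("demo", 1, list(rrns))
run <- simulateCommunity(spec, nReads = 30, kMin = 4, kGeomP = 0.4, seed = 9)

res <- consensusFromReads(run$reads, con)
ledgerTable(res$ledger)
#>       stage input retained discarded            reasons
#> 1   segment    30       30         0
#> 2 consensus    30       21         9 too_few_subreads=9

call <- resolveGenus(res$sequences, construct = con, genus = "demo",
                     reportRule = "terminal")
call$call
#> RrnCall demo: 3 clusters at identity 0.999 (0 excluded)

ee <- estimateError(res$sequences, setNames(rrns, paste0("rrn", 1:3)))
round(ee$meanErrorPct, 3)
#> [1] 0.025
```

Thirty simulated concatemer reads (2% per-base error) yield 21 consensus
sequences with ≥ 5 supporting sub-reads; nine reads are discarded for
insufficient repeats — short reads are the dominant loss, as in real runs.
The identity sweep resolves the three rrn copies exactly, and the surviving
consensus sequences average 0.025% error against the truth templates, two
orders of magnitude below the raw sub-read error.

A thin command-line wrapper over the same functions ships in
`inst/scripts/rca-pipeline.R` (subcommands `simulate`, `consensus`,
`cluster`, `resolve`, `report`).

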