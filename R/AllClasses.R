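#' @import methods
NULL

# ---------------------------------------------------------------------------
# Core data containers
# ---------------------------------------------------------------------------

#' Gapped DNA multiple sequence alignment
#'
#' A rectangular alignment over the alphabet `{A,C,G,T,N,-}`. Rows are stored
#' as gapped strings; [ungap()] recovers each source sequence. `DnaMsa` is the
#' substrate for per-read consensus building, column correction, end trimming,
#' and variable-column extraction.
#'
#' @slot ids character vector of unique, non-empty row identifiers.
#' @slot rows character vector of gapped strings, all the same width.
#' @export
setClass("DnaMsa",
  representation(ids = "character", rows = "character"))

setValidity("DnaMsa", function(object) {
  if (length(object@ids) != length(object@rows))
    return("ids and rows must have the same length")
  if (length(object@rows) == 0L) return("an alignment needs at least one row")
  if (anyDuplicated(object@ids)) return("row ids must be unique")
  if (any(!nzchar(object@ids))) return("row ids must be non-empty")
  w <- nchar(object@rows)
  if (length(unique(w)) != 1L) return("alignment rows must be rectangular")
  if (any(grepl("[^ACGTN-]", object@rows)))
    return("rows must be over {A,C,G,T,N,-}")
  TRUE
})

#' Construct model for the circularized amplicon
#'
#' Describes the repeated unit of the rolling-circle product:
#' `splint - [fwdUnique - barcode5 - <insert> - barcode3 - revUniqueRc] - splint ...`
#' where the insert is one 16S-ITS amplicon whose ends carry the annealing
#' portions of the two PCR primers. The splint plus its flanking unique primer
#' sequences form the junction cassette that segmentation searches for.
#'
#' @slot splint concrete DNA, >= 50 bp (default fixture is 386 bp).
#' @slot fwdUnique,revUnique concrete unique 5' primer tails.
#' @slot fwdAnneal,revAnneal annealing primer portions; IUPAC codes allowed.
#' @slot barcodeLen molecular barcode length on each side (default 5).
#' @export
setClass("ConstructModel",
  representation(splint = "character", fwdUnique = "character",
                 revUnique = "character", fwdAnneal = "character",
                 revAnneal = "character", barcodeLen = "integer"))

setValidity("ConstructModel", function(object) {
  if (object@barcodeLen < 1L) return("barcodeLen must be >= 1")
  if (nchar(object@splint) < 50L) return("splint must be at least 50 bp")
  TRUE
})

#' One segmented concatemer read
#'
#' The extracted insert copies (sub-reads) of a single long read, in canonical
#' orientation, together with the per-repeat barcode observations and the two
#' barcode consensus calls. Sub-reads are barcode-clipped once the read passes
#' barcode validation.
#'
#' @slot readId source read identifier.
#' @slot subReads character vector of sub-read sequences.
#' @slot bc5Obs,bc3Obs per-repeat barcode observations.
#' @slot bc5,bc3 barcode consensus, `NA` before validation, `"REJECTED"` when
#'   the gapped consensus exceeds the barcode length (mixed barcodes).
#' @slot orientation `"+"` or `"-"` (strand of the junction hits on the read).
#' @slot discardReason `NA` while the read is live, otherwise the ledger reason.
#' @export
setClass("SubReadSet",
  representation(readId = "character", subReads = "character",
                 bc5Obs = "character", bc3Obs = "character",
                 bc5 = "character", bc3 = "character",
                 orientation = "character", discardReason = "character"),
  prototype(bc5 = NA_character_, bc3 = NA_character_,
            orientation = "+", discardReason = NA_character_))

#' Per-read rolling-circle consensus sequence
#'
#' The gap-free consensus of the surviving sub-reads of one concatemer read,
#' with its support counts. Downstream stages only use consensus sequences
#' whose final support reaches the configured minimum (default 5 sub-reads).
#'
#' @slot id consensus identifier.
#' @slot seq ungapped consensus DNA.
#' @slot nSubreadsInitial,nSubreadsFinal sub-read counts before/after pruning.
#' @slot readId source read identifier.
#' @slot discardReason `NA` when retained, otherwise e.g. `"too_few_subreads"`.
#' @export
setClass("RcaConsensus",
  representation(id = "character", seq = "character",
                 nSubreadsInitial = "integer", nSubreadsFinal = "integer",
                 readId = "character", discardReason = "character"),
  prototype(discardReason = NA_character_))

setValidity("RcaConsensus", function(object) {
  if (object@nSubreadsFinal > object@nSubreadsInitial)
    return("final sub-read count cannot exceed the initial count")
  TRUE
})

#' A sequence cluster at a stated identity threshold
#'
#' Used at both the genus level (greedy identity clustering of 16S portions)
#' and the rrn level (variable-column sub-sequence clustering).
#'
#' @slot clusterId,level,identityThreshold cluster identity and provenance.
#' @slot memberIds,representativeId membership; the representative is a member.
#' @slot consensus optional ungapped consensus of the members.
#' @slot taxonomy optional label with its supporting modal fraction.
#' @slot modalFraction fraction of members carrying the modal label.
#' @export
setClass("SeqCluster",
  representation(clusterId = "character", level = "character",
                 identityThreshold = "numeric", memberIds = "character",
                 representativeId = "character", consensus = "character",
                 taxonomy = "character", modalFraction = "numeric"),
  prototype(consensus = NA_character_, taxonomy = NA_character_,
            modalFraction = NA_real_))

setValidity("SeqCluster", function(object) {
  if (length(object@memberIds) < 1L) return("a cluster needs >= 1 member")
  if (!object@representativeId %in% object@memberIds)
    return("representative must be a member")
  TRUE
})

#' Per-stage read accounting
#'
#' Conservation ledger: at every stage, `input == retained + sum(discarded)`,
#' with discards broken down by named reason. Enforced on construction so stage
#' survival tables always add up.
#'
#' @slot stages list of per-stage records.
#' @export
setClass("StageLedger", representation(stages = "list"),
         prototype(stages = list()))

setValidity("StageLedger", function(object) {
  for (st in object@stages) {
    if (st$input != st$retained + sum(st$discarded))
      return(sprintf("stage '%s' violates conservation", st$stage))
  }
  TRUE
})

#' Result of the rrn-level identity sweep for one genus
#'
#' @slot genus genus label.
#' @slot identityUsed the reported clustering identity.
#' @slot clusters list of [SeqCluster-class] at that identity.
#' @slot curve data.frame with columns `identity` and `count` (cluster-count
#'   curve across the sweep).
#' @slot excludedIds sequences excluded as putative chimeras (small clusters).
#' @export
setClass("RrnCall",
  representation(genus = "character", identityUsed = "numeric",
                 clusters = "list", curve = "data.frame",
                 excludedIds = "character"))

# ---------------------------------------------------------------------------
# Stage parameter classes (all thresholds carry their documented defaults)
# ---------------------------------------------------------------------------

#' Segmentation parameters
#'
#' @slot minSubLen,maxSubLen valid sub-read size range (default 1500-3500 bp).
#' @slot junctionMinScoreFrac junction hits must score at least this fraction
#'   of a perfect cassette alignment.
#' @slot junctionMaxError maximum junction alignment error fraction.
#' @slot barcodeCutoff column frequency required to call a barcode consensus
#'   character (default 0.6).
#' @slot maxBarcodeLen barcode consensus longer than this is rejected as mixed.
#' @export
setClass("SegmentParam",
  representation(minSubLen = "integer", maxSubLen = "integer",
                 junctionMinScoreFrac = "numeric", junctionMaxError = "numeric",
                 barcodeCutoff = "numeric", maxBarcodeLen = "integer"),
  prototype(minSubLen = 1500L, maxSubLen = 3500L, junctionMinScoreFrac = 0.3,
            junctionMaxError = 0.35, barcodeCutoff = 0.6, maxBarcodeLen = 5L))

setValidity("SegmentParam", function(object) {
  if (object@minSubLen >= object@maxSubLen)
    return("minSubLen must be < maxSubLen")
  if (object@barcodeCutoff <= 0.5 || object@barcodeCutoff > 1)
    return("barcodeCutoff must be in (0.5, 1]")
  TRUE
})

#' Per-read consensus parameters
#'
#' @slot minFinalSubreads consensus sequences need at least this many surviving
#'   sub-reads to be retained (default 5).
#' @slot outlierScoreFraction sub-reads scoring below this fraction of the
#'   alignment width are pruned (default 0.65).
#' @slot stopAtSubreads pruning stops once this few sub-reads remain (default 3).
#' @slot bandWidth extra band half-width for the profile aligner, on top of the
#'   length difference.
#' @slot hiConfSubreads support count that marks a high-confidence consensus
#'   (default 15), used to seed similarity-based 16S extraction.
#' @slot match,mismatch,gapOpen,gapExtend affine alignment scores.
#' @export
setClass("ConsensusParam",
  representation(minFinalSubreads = "integer", outlierScoreFraction = "numeric",
                 stopAtSubreads = "integer", bandWidth = "integer",
                 hiConfSubreads = "integer", match = "numeric",
                 mismatch = "numeric", gapOpen = "numeric",
                 gapExtend = "numeric"),
  prototype(minFinalSubreads = 5L, outlierScoreFraction = 0.65,
            stopAtSubreads = 3L, bandWidth = 100L, hiConfSubreads = 15L,
            match = 2, mismatch = -3, gapOpen = -5, gapExtend = -1))

setValidity("ConsensusParam", function(object) {
  if (object@stopAtSubreads >= object@minFinalSubreads)
    return("stopAtSubreads must be < minFinalSubreads")
  if (object@gapOpen > 0 || object@gapExtend > 0)
    return("gap penalties must be <= 0")
  TRUE
})

#' Genus-level clustering parameters
#'
#' @slot genusIdentity greedy clustering identity (default 0.95, ~genus level).
#' @slot minClusterMembers genus clusters below this size are excluded
#'   (default 5).
#' @slot kmerSize,prefilterMinFrac k-mer prefilter: a candidate representative
#'   must share at least `prefilterMinFrac * identity * <query k-mers>` k-mers.
#' @slot rescueMinMembers optional absolute member floor replacing the
#'   5-percent rule at the rrn stage (default `NA`, off).
#' @slot prefilterIdentity full-length global-identity prefilter threshold
#'   (default 0.95).
#' @slot max16sMismatch,maxV4Mismatch primer-motif mismatch allowances.
#' @export
setClass("ClusterParam",
  representation(genusIdentity = "numeric", minClusterMembers = "integer",
                 kmerSize = "integer", prefilterMinFrac = "numeric",
                 rescueMinMembers = "integer", prefilterIdentity = "numeric",
                 max16sMismatch = "integer", maxV4Mismatch = "integer"),
  prototype(genusIdentity = 0.95, minClusterMembers = 5L, kmerSize = 12L,
            prefilterMinFrac = 0.3, rescueMinMembers = NA_integer_,
            prefilterIdentity = 0.95, max16sMismatch = 1L, maxV4Mismatch = 2L))

setValidity("ClusterParam", function(object) {
  if (object@genusIdentity <= 0 || object@genusIdentity > 1)
    return("genusIdentity must be in (0, 1]")
  TRUE
})

#' Genus-MSA correction and trimming parameters
#'
#' @slot dominantFraction a column with one character at or above this
#'   frequency has its minority characters corrected to it (default 0.98).
#' @slot minorityToN with two or more abundant characters, characters below
#'   this frequency are corrected to `N` (default 0.02).
#' @slot maxCorrectionFraction sequences with more prospective corrections than
#'   this fraction of their ungapped length are excluded as outliers
#'   (default 5e-4, i.e. 0.05 percent).
#' @slot trimNongapFraction end columns are trimmed until the first/last column
#'   whose non-gap fraction reaches this value (default 0.98).
#' @slot correctionPasses two-pass scheme: pass 1 counts only, pass 2 applies.
#' @slot realignMinDisagreement column disagreement above which a window is
#'   re-aligned during MSA repair.
#' @export
setClass("RefineParam",
  representation(dominantFraction = "numeric", minorityToN = "numeric",
                 maxCorrectionFraction = "numeric",
                 trimNongapFraction = "numeric", correctionPasses = "integer",
                 realignMinDisagreement = "numeric"),
  prototype(dominantFraction = 0.98, minorityToN = 0.02,
            maxCorrectionFraction = 5e-4, trimNongapFraction = 0.98,
            correctionPasses = 2L, realignMinDisagreement = 0.3))

setValidity("RefineParam", function(object) {
  if (object@minorityToN >= object@dominantFraction)
    return("minorityToN must be < dominantFraction")
  if (object@correctionPasses < 2L) return("correctionPasses must be >= 2")
  TRUE
})

#' rrn-resolution parameters
#'
#' @slot variableMajorityFraction a column is variable when its plurality
#'   character (over non-N rows) is below this frequency (default 0.95).
#' @slot flankColumns columns kept on each side of a variable column
#'   (default 4).
#' @slot sweepIdentities ascending identity ladder for the sweep.
#' @slot minClusterInputFraction sub-sequence clusters below this fraction of
#'   the input are excluded as putative chimeras (default 0.05).
#' @slot rescueMinMembers optional absolute floor replacing the fraction rule.
#' @slot chimeraMinEditsSaved,chimeraMinIdentityGain a candidate is chimeric
#'   when the best two-parent model saves at least this many edits AND this
#'   identity fraction over the best single parent.
#' @export
setClass("ResolveParam",
  representation(variableMajorityFraction = "numeric", flankColumns = "integer",
                 sweepIdentities = "numeric",
                 minClusterInputFraction = "numeric",
                 rescueMinMembers = "integer",
                 chimeraMinEditsSaved = "integer",
                 chimeraMinIdentityGain = "numeric"),
  prototype(variableMajorityFraction = 0.95, flankColumns = 4L,
            sweepIdentities = c(seq(0.90, 0.99, by = 0.005),
                                0.9925, 0.995, 0.9975, 0.999),
            minClusterInputFraction = 0.05, rescueMinMembers = NA_integer_,
            chimeraMinEditsSaved = 4L, chimeraMinIdentityGain = 0.015))

setValidity("ResolveParam", function(object) {
  if (is.unsorted(object@sweepIdentities, strictly = FALSE))
    return("sweepIdentities must be sorted ascending")
  if (any(object@sweepIdentities < 0.5 | object@sweepIdentities > 1))
    return("sweepIdentities must be identities in (0.5, 1]")
  TRUE
})

#' Full pipeline configuration
#'
#' Aggregates the construct model and every stage parameter set, plus the seed
#' driving all randomness. Serializable to a flat `key = value` text file via
#' [writePipelineParam()] / [readPipelineParam()].
#'
#' @slot construct,segment,consensus,cluster,refine,resolve stage parameters.
#' @slot seed integer seed for every stochastic operation.
#' @export
setClass("PipelineParam",
  representation(construct = "ConstructModel", segment = "SegmentParam",
                 consensus = "ConsensusParam", cluster = "ClusterParam",
                 refine = "RefineParam", resolve = "ResolveParam",
                 seed = "integer"),
  prototype(seed = 1L))
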