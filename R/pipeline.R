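# End-to-end drivers composing the stage functions, with ledger accounting.

#' Segment reads and build per-read consensus sequences
#'
#' Runs [segmentReads()] then [buildConsensus()] on every surviving read,
#' recording both stages in a conservation ledger.
#'
#' @param reads named character vector (or `QualityScaledDNAStringSet`).
#' @param construct a [ConstructModel-class].
#' @param segParam a [SegmentParam-class].
#' @param consParam a [ConsensusParam-class].
#' @return `list(sequences = <named character, retained consensi>,
#'   support = <named integer, final sub-read counts>,
#'   consensus = <list of RcaConsensus for every segmented read>,
#'   sets = <list of SubReadSet>, ledger = <StageLedger>)`.
#' @export
consensusFromReads <- function(reads, construct = defaultConstruct(),
                               segParam = SegmentParam(),
                               consParam = ConsensusParam()) {
  seg <- segmentReads(reads, construct, segParam)
  live <- Filter(isRetained, seg$sets)
  cons <- lapply(live, buildConsensus, param = consParam)
  reasons <- vapply(cons, function(x) x@discardReason, "")
  disc <- table(reasons[!is.na(reasons)])
  ledger <- addStage(seg$ledger, "consensus", length(live),
                     sum(is.na(reasons)),
                     stats::setNames(as.integer(disc), names(disc)))
  keep <- Filter(isRetained, cons)
  sequences <- vapply(keep, function(x) x@seq, "")
  names(sequences) <- vapply(keep, function(x) x@id, "")
  support <- vapply(keep, function(x) x@nSubreadsFinal, 0L)
  names(support) <- names(sequences)
  list(sequences = sequences, support = support, consensus = cons,
       sets = seg$sets, ledger = ledger)
}

#' Resolve one genus into rrn clusters
#'
#' The full per-genus analysis: genus MSA ([buildGenusMsa()]), two-pass column
#' correction ([correctMsa()]), end trimming ([trimMsa()]), variable-column
#' extraction, and the identity sweep ([sweepCluster()]). A genus with no
#' variable column is reported as a single rrn cluster.
#'
#' @param seqs named character vector of the genus' consensus sequences (>= 2).
#' @param refineParam a [RefineParam-class].
#' @param resolveParam a [ResolveParam-class].
#' @param alnParam a [ConsensusParam-class].
#' @param construct optional [ConstructModel-class] for primer-remnant
#'   trimming.
#' @param genus label for the call.
#' @param targetCount,reportRule forwarded to [sweepCluster()].
#' @return `list(call = <RrnCall>, msa = <trimmed corrected DnaMsa>,
#'   report = <correction report>, excludedIds)`.
#' @export
resolveGenus <- function(seqs, refineParam = RefineParam(),
                         resolveParam = ResolveParam(),
                         alnParam = ConsensusParam(), construct = NULL,
                         genus = "genus", targetCount = NULL,
                         reportRule = "plateau") {
  msa <- buildGenusMsa(seqs, refineParam, alnParam)
  corr <- correctMsa(msa, refineParam)
  trimmed <- trimMsa(corr$msa, refineParam, construct)
  fullSeqs <- stats::setNames(ungap(trimmed$msa), msaIds(trimmed$msa))
  vc <- variableColumns(trimmed$msa, resolveParam)
  if (!length(vc)) {
    cl <- new("SeqCluster", clusterId = paste0(genus, "_rrn001"),
              level = "rrn", identityThreshold = NA_real_,
              memberIds = msaIds(trimmed$msa),
              representativeId = msaIds(trimmed$msa)[1L],
              consensus = clusterConsensus(fullSeqs, alnParam))
    call <- new("RrnCall", genus = genus, identityUsed = NA_real_,
                clusters = list(cl),
                curve = data.frame(identity = resolveParam@sweepIdentities,
                                   count = 1L),
                excludedIds = character(0))
    return(list(call = call, msa = trimmed$msa, report = corr$report,
                excludedIds = corr$excludedIds))
  }
  subseqs <- extractSubsequences(trimmed$msa, vc, resolveParam)
  call <- sweepCluster(subseqs, fullSeqs, resolveParam, genus = genus,
                       targetCount = targetCount,
                       reportRule = match.arg(reportRule,
                                              c("plateau", "terminal")),
                       alnParam = alnParam)
  list(call = call, msa = trimmed$msa, report = corr$report,
       excludedIds = corr$excludedIds)
}
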