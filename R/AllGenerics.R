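#' Strip gap characters from an alignment row or gapped string
#'
#' @param x a [DnaMsa-class] or a gapped character string.
#' @param row for a `DnaMsa`, the row index or id to extract; omit to get all
#'   rows as a character vector.
#' @return ungapped character string(s).
#' @export
setGeneric("ungap", function(x, row) standardGeneric("ungap"))

#' Number of alignment columns
#' @param x a [DnaMsa-class].
#' @return integer width.
#' @export
setGeneric("msaWidth", function(x) standardGeneric("msaWidth"))

#' Row identifiers of an alignment
#' @param x a [DnaMsa-class].
#' @export
setGeneric("msaIds", function(x) standardGeneric("msaIds"))

#' Gapped rows of an alignment
#' @param x a [DnaMsa-class].
#' @export
setGeneric("msaRows", function(x) standardGeneric("msaRows"))

#' Cluster membership
#' @param x a [SeqCluster-class].
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' Whether an object survived its filtering stage
#' @param x a [RcaConsensus-class] or [SubReadSet-class].
#' @export
setGeneric("isRetained", function(x) standardGeneric("isRetained"))

#' Record one stage in a conservation ledger
#'
#' @param ledger a [StageLedger-class].
#' @param stage stage name.
#' @param input,retained counts entering and surviving the stage.
#' @param discarded named integer vector of discard counts by reason.
#' @return the updated ledger; errors if `input != retained + sum(discarded)`.
#' @export
setGeneric("addStage", function(ledger, stage, input, retained,
                                discarded = integer(0))
  standardGeneric("addStage"))

#' Ledger as a data.frame
#' @param ledger a [StageLedger-class].
#' @export
setGeneric("ledgerTable", function(ledger) standardGeneric("ledgerTable"))
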