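# Constructors, accessors, and show methods for the core classes.

#' Build a gapped DNA alignment from rows
#'
#' @param ids unique row identifiers.
#' @param rows gapped strings over `{A,C,G,T,N,-}`, all the same width.
#' @return a [DnaMsa-class].
#' @examples
#' m <- DnaMsa(c("a", "b"), c("AC-T", "A-GT"))
#' msaWidth(m)   # 4
#' ungap(m, "a") # "ACT"
#' @export
DnaMsa <- function(ids, rows) {
  new("DnaMsa", ids = as.character(ids), rows = toupper(as.character(rows)))
}

#' @rdname ungap
#' @export
setMethod("ungap", "character", function(x, row) {
  if (!missing(row)) stop("'row' only applies to DnaMsa objects")
  gsub("-", "", x, fixed = TRUE)
})

#' @rdname ungap
#' @export
setMethod("ungap", "DnaMsa", function(x, row) {
  if (missing(row)) return(gsub("-", "", x@rows, fixed = TRUE))
  if (is.character(row)) row <- match(row, x@ids)
  if (is.na(row) || row < 1L || row > length(x@rows))
    stop("row not found in alignment")
  gsub("-", "", x@rows[row], fixed = TRUE)
})

#' @rdname msaWidth
#' @export
setMethod("msaWidth", "DnaMsa", function(x) nchar(x@rows[1L]))

#' @rdname msaIds
#' @export
setMethod("msaIds", "DnaMsa", function(x) x@ids)

#' @rdname msaRows
#' @export
setMethod("msaRows", "DnaMsa", function(x) stats::setNames(x@rows, x@ids))

setMethod("show", "DnaMsa", function(object) {
  cat(sprintf("DnaMsa: %d rows x %d columns\n",
              length(object@rows), msaWidth(object)))
  n <- min(5L, length(object@rows))
  for (i in seq_len(n)) {
    r <- object@rows[i]
    cat(sprintf("  %-12s %s%s\n", object@ids[i], substr(r, 1, 60),
                if (nchar(r) > 60) "..." else ""))
  }
  if (length(object@rows) > n) cat(sprintf("  ... %d more rows\n",
                                           length(object@rows) - n))
})

# internal: alignment as a character matrix (rows x columns)
.msaMatrix <- function(msa) {
  do.call(rbind, strsplit(msa@rows, "", fixed = TRUE))
}

.msaFromMatrix <- function(ids, mat) {
  DnaMsa(ids, apply(mat, 1L, paste, collapse = ""))
}

#' @rdname members
#' @export
setMethod("members", "SeqCluster", function(x) x@memberIds)

#' @rdname isRetained
#' @export
setMethod("isRetained", "RcaConsensus",
          function(x) is.na(x@discardReason))

#' @rdname isRetained
#' @export
setMethod("isRetained", "SubReadSet",
          function(x) is.na(x@discardReason))

setMethod("show", "RcaConsensus", function(object) {
  cat(sprintf("RcaConsensus %s (read %s): %d bp, sub-reads %d -> %d%s\n",
              object@id, object@readId, nchar(object@seq),
              object@nSubreadsInitial, object@nSubreadsFinal,
              if (isRetained(object)) ""
              else sprintf(" [discarded: %s]", object@discardReason)))
})

setMethod("show", "SeqCluster", function(object) {
  cat(sprintf("SeqCluster %s (%s, identity %.4g): %d members, rep %s%s\n",
              object@clusterId, object@level, object@identityThreshold,
              length(object@memberIds), object@representativeId,
              if (is.na(object@taxonomy)) ""
              else sprintf(", taxonomy %s (%.2f)", object@taxonomy,
                           object@modalFraction)))
})

setMethod("show", "StageLedger", function(object) {
  print(ledgerTable(object))
})

setMethod("show", "RrnCall", function(object) {
  cat(sprintf("RrnCall %s: %d clusters at identity %.4g (%d excluded)\n",
              object@genus, length(object@clusters), object@identityUsed,
              length(object@excludedIds)))
})

# ---------------------------------------------------------------------------
# StageLedger
# ---------------------------------------------------------------------------

#' Create an empty stage ledger
#' @return a [StageLedger-class] with no stages.
#' @export
StageLedger <- function() new("StageLedger")

#' @rdname addStage
#' @export
setMethod("addStage", "StageLedger",
  function(ledger, stage, input, retained, discarded = integer(0)) {
    nm <- names(discarded)
    discarded <- stats::setNames(as.integer(discarded), nm)
    if (length(discarded) && is.null(names(discarded)))
      stop("discard counts must be named by reason")
    st <- list(stage = as.character(stage), input = as.integer(input),
               retained = as.integer(retained), discarded = discarded)
    ledger@stages <- c(ledger@stages, list(st))
    validObject(ledger)
    ledger
  })

#' @rdname ledgerTable
#' @export
setMethod("ledgerTable", "StageLedger", function(ledger) {
  if (!length(ledger@stages)) {
    return(data.frame(stage = character(0), input = integer(0),
                      retained = integer(0), discarded = integer(0),
                      reasons = character(0)))
  }
  do.call(rbind, lapply(ledger@stages, function(st) {
    data.frame(stage = st$stage, input = st$input, retained = st$retained,
               discarded = sum(st$discarded),
               reasons = if (length(st$discarded))
                 paste(sprintf("%s=%d", names(st$discarded), st$discarded),
                       collapse = ",") else "",
               stringsAsFactors = FALSE)
  }))
})

# ---------------------------------------------------------------------------
# Parameter constructors (thin wrappers over the class prototypes)
# ---------------------------------------------------------------------------

.newParam <- function(class, ...) {
  args <- list(...)
  proto <- new(class)
  for (nm in names(args)) {
    slot(proto, nm) <- if (is(slot(proto, nm), "integer"))
      as.integer(args[[nm]]) else args[[nm]]
  }
  validObject(proto)
  proto
}

#' @rdname SegmentParam-class
#' @param ... named slot overrides; see the class documentation for defaults.
#' @export
SegmentParam <- function(...) .newParam("SegmentParam", ...)

#' @rdname ConsensusParam-class
#' @param ... named slot overrides.
#' @export
ConsensusParam <- function(...) .newParam("ConsensusParam", ...)

#' @rdname ClusterParam-class
#' @param ... named slot overrides.
#' @export
ClusterParam <- function(...) .newParam("ClusterParam", ...)

#' @rdname RefineParam-class
#' @param ... named slot overrides.
#' @export
RefineParam <- function(...) .newParam("RefineParam", ...)

#' @rdname ResolveParam-class
#' @param ... named slot overrides.
#' @export
ResolveParam <- function(...) .newParam("ResolveParam", ...)

#' Construct model constructor
#'
#' @param splint concrete splint DNA (>= 50 bp).
#' @param fwdUnique,revUnique unique primer tails (concrete DNA).
#' @param fwdAnneal,revAnneal annealing primer portions (IUPAC allowed).
#' @param barcodeLen barcode length (default 5).
#' @return a [ConstructModel-class].
#' @export
ConstructModel <- function(splint, fwdUnique, revUnique, fwdAnneal, revAnneal,
                           barcodeLen = 5L) {
  new("ConstructModel",
      splint = .normalizeDna(splint, "splint"),
      fwdUnique = .normalizeDna(fwdUnique, "fwdUnique"),
      revUnique = .normalizeDna(revUnique, "revUnique"),
      fwdAnneal = .normalizeIupac(fwdAnneal, "fwdAnneal"),
      revAnneal = .normalizeIupac(revAnneal, "revAnneal"),
      barcodeLen = as.integer(barcodeLen))
}

#' Full pipeline parameter set
#'
#' @param construct a [ConstructModel-class]; defaults to [defaultConstruct()].
#' @param segment,consensus,cluster,refine,resolve stage parameter objects.
#' @param seed integer seed.
#' @return a [PipelineParam-class].
#' @export
PipelineParam <- function(construct = defaultConstruct(),
                          segment = SegmentParam(),
                          consensus = ConsensusParam(),
                          cluster = ClusterParam(),
                          refine = RefineParam(),
                          resolve = ResolveParam(),
                          seed = 1L) {
  new("PipelineParam", construct = construct, segment = segment,
      consensus = consensus, cluster = cluster, refine = refine,
      resolve = resolve, seed = as.integer(seed))
}
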