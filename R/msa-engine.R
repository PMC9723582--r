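# Progressive center-star alignment against an evolving column profile.
# Each incoming sequence is aligned to the current profile with banded affine
# DP (src/align.cpp); the band is the row/profile length difference plus a
# configurable pad. Deterministic for a fixed input order.

.profFromMatrix <- function(mat) {
  prof <- matrix(0L, nrow = 6L, ncol = ncol(mat))
  for (a in seq_along(.ALPHABET)) prof[a, ] <- colSums(mat == .ALPHABET[a])
  prof
}

# Align one new sequence into (mat, prof); returns updated list(mat, prof).
.profileAdd <- function(mat, prof, seq, param) {
  sc <- .chars(seq)
  band <- abs(ncol(mat) - length(sc)) + param@bandWidth
  ops <- .cpp_profile_align(prof, match(sc, .ALPHABET) - 1L,
                            param@match, param@mismatch,
                            param@gapOpen, param@gapExtend, as.integer(band))
  newW <- length(ops)
  colMap <- ifelse(ops == 2L, 0L, cumsum(ops != 2L))
  em <- matrix("-", nrow(mat), newW)
  keep <- colMap > 0L
  em[, keep] <- mat[, colMap[keep], drop = FALSE]
  seqPos <- cumsum(ops != 1L)
  newRow <- rep("-", newW)
  consumes <- ops != 1L            # seqPos is 0 before the first consuming op
  newRow[consumes] <- sc[seqPos[consumes]]
  pf <- matrix(0L, 6L, newW)
  pf[, keep] <- prof[, colMap[keep], drop = FALSE]
  pf[6L, !keep] <- nrow(mat)
  enc <- match(newRow, .ALPHABET)
  pf[cbind(enc, seq_len(newW))] <- pf[cbind(enc, seq_len(newW))] + 1L
  list(mat = rbind(em, newRow, deparse.level = 0), prof = pf)
}

# orderBy = "median": seed is the sequence of median length (ties: earliest),
# remaining sequences joined in input order (per-read sub-read alignment).
# orderBy = "length": guide order by decreasing length (genus-level MSAs).
.progressiveAlign <- function(seqs, ids, param, orderBy = c("median", "length")) {
  orderBy <- match.arg(orderBy)
  n <- length(seqs)
  if (n < 2L) stop("progressive alignment needs at least 2 sequences")
  if (orderBy == "median") {
    seed <- order(nchar(seqs))[ceiling(n / 2)]
    ord <- c(seed, setdiff(seq_len(n), seed))
  } else {
    ord <- order(-nchar(seqs), seq_len(n))
  }
  mat <- matrix(.chars(seqs[[ord[1L]]]), nrow = 1L)
  prof <- .profFromMatrix(mat)
  for (i in ord[-1L]) {
    st <- .profileAdd(mat, prof, seqs[[i]], param)
    mat <- st$mat
    prof <- st$prof
  }
  # restore input row order
  mat <- mat[order(ord), , drop = FALSE]
  .msaFromMatrix(ids, mat)
}

#' Multiply align the sub-reads of one concatemer read
#'
#' Center-star progressive alignment: the sub-read of median length seeds the
#' profile and the remaining sub-reads are added in input order with banded
#' affine-gap DP. Deterministic for a fixed input order.
#'
#' @param subReads character vector of >= 2 sub-read sequences; names are used
#'   as row ids (default `sr1..srk`).
#' @param param a [ConsensusParam-class].
#' @return a [DnaMsa-class] with one row per sub-read, in input order.
#' @examples
#' m <- alignSubreads(c("ACGT", "AGT"))
#' msaWidth(m)  # 4
#' @export
alignSubreads <- function(subReads, param = ConsensusParam()) {
  if (length(subReads) < 2L)
    stop("a single sub-read cannot form a consensus alignment")
  ids <- names(subReads)
  if (is.null(ids)) ids <- sprintf("sr%d", seq_along(subReads))
  seqs <- vapply(unname(subReads), .normalizeDna, "", what = "sub-read")
  .progressiveAlign(seqs, ids, param, orderBy = "median")
}

#' Plurality consensus of alignment columns
#'
#' Per column, the most common character over `{A,C,G,T,N,-}` (a gap can win).
#' Ties are broken by a fixed rank: bases before N before gap, bases in
#' alphabetical order, so e.g. a 2:2 tie between `A` and `-` yields `A`.
#'
#' @param msa a [DnaMsa-class].
#' @return gapped consensus string of width `msaWidth(msa)`.
#' @export
columnConsensus <- function(msa) {
  mat <- .msaMatrix(msa)
  counts <- .profFromMatrix(mat)
  score <- counts - .CHAR_RANK[.ALPHABET] * 1e-3
  .collapse(.ALPHABET[max.col(t(score), ties.method = "first")])
}

#' Score one alignment row against the column consensus
#'
#' A row receives 1 point per column where it matches the consensus character,
#' 0.5 points per column where the row has a gap but the consensus called a
#' base, and 0 otherwise. Rows scoring below a fraction of the alignment width
#' are pruned as outliers.
#'
#' @param row,consensus gapped strings of equal length.
#' @return numeric score.
#' @export
scoreSubread <- function(row, consensus) {
  rc <- .chars(row)
  cc <- .chars(consensus)
  if (length(rc) != length(cc))
    stop("row and consensus must have the same width")
  sum(rc == cc) + 0.5 * sum(rc == "-" & cc %in% .BASES)
}

#' Iteratively prune outlier sub-reads from a read alignment
#'
#' Loop: build the plurality column consensus, score every row, remove all rows
#' scoring below `outlierScoreFraction * width`, and re-align the survivors.
#' Stops when no row is removed or when `stopAtSubreads` or fewer rows remain.
#' The alignment is rebuilt after every removal because dropping a divergent
#' row can shift the remaining columns.
#'
#' @param msa a [DnaMsa-class] of sub-reads.
#' @param param a [ConsensusParam-class].
#' @return `list(msa = <pruned DnaMsa>, removed = <character ids>)`.
#' @export
pruneOutliers <- function(msa, param = ConsensusParam()) {
  removed <- character(0)
  repeat {
    cons <- columnConsensus(msa)
    w <- msaWidth(msa)
    scores <- vapply(msa@rows, scoreSubread, 0, consensus = cons,
                     USE.NAMES = FALSE)
    drop <- scores < param@outlierScoreFraction * w
    if (!any(drop) || all(drop)) break
    removed <- c(removed, msa@ids[drop])
    keepIds <- msa@ids[!drop]
    keepSeqs <- ungap(msa)[!drop]
    if (length(keepIds) < 2L) {
      msa <- DnaMsa(keepIds, keepSeqs)
      break
    }
    msa <- .progressiveAlign(keepSeqs, keepIds, param, orderBy = "median")
    if (length(keepIds) <= param@stopAtSubreads) break
  }
  list(msa = msa, removed = removed)
}

#' Build the per-read consensus sequence
#'
#' Align the validated sub-reads, prune outliers, take the plurality column
#' consensus, and strip gaps. The result is discarded (reason
#' `"too_few_subreads"`) when fewer than `minFinalSubreads` sub-reads survive.
#'
#' @param set a validated [SubReadSet-class].
#' @param param a [ConsensusParam-class].
#' @return a [RcaConsensus-class]; check [isRetained()] for the filter outcome.
#' @export
buildConsensus <- function(set, param = ConsensusParam()) {
  nInit <- length(set@subReads)
  mk <- function(seq, nFinal, reason = NA_character_) {
    new("RcaConsensus", id = paste0(set@readId, "_cons"), seq = seq,
        nSubreadsInitial = nInit, nSubreadsFinal = as.integer(nFinal),
        readId = set@readId, discardReason = reason)
  }
  if (nInit == 0L) return(mk("", 0L, "no_subreads"))
  if (nInit == 1L) {
    reason <- if (param@minFinalSubreads > 1L) "too_few_subreads"
              else NA_character_
    return(mk(set@subReads[[1L]], 1L, reason))
  }
  msa <- alignSubreads(set@subReads, param)
  pruned <- pruneOutliers(msa, param)
  nFinal <- length(pruned$msa@rows)
  seq <- ungap(columnConsensus(pruned$msa))
  reason <- if (nFinal < param@minFinalSubreads) "too_few_subreads"
            else NA_character_
  mk(seq, nFinal, reason)
}
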