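# Concatemer segmentation. The junction cassette (splint plus its flanking
# unique primer tails) is located by iterated local alignment on both strands;
# every inter-junction interval becomes a candidate sub-read carrying a 5-bp
# barcode at each end.

.junctionCassette <- function(construct) {
  paste0(.revcomp(construct@revUnique), construct@splint, construct@fwdUnique)
}

# substitution matrix for junction search: N is the masking character and
# scores worse than a mismatch so masked regions are never re-hit
.junctionSubMat <- function(match = 2, mismatch = -3, maskPenalty = -6) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5L, 5L, dimnames = list(letters, letters))
  diag(m) <- match
  m["N", ] <- maskPenalty
  m[, "N"] <- maskPenalty
  m
}

#' Locate junction cassettes on a concatemer read
#'
#' Scans both strands by iterated local affine-gap alignment of the junction
#' cassette (reverse-complemented unique tail, splint, forward unique tail):
#' the best local hit is recorded and masked, and the search repeats until the
#' score drops below `junctionMinScoreFrac` of a perfect hit. Hits with error
#' fraction above `junctionMaxError` are dropped; overlapping hits are resolved
#' greedily by score (ties: leftmost).
#'
#' @param read read sequence (character string).
#' @param construct a [ConstructModel-class].
#' @param param a [SegmentParam-class].
#' @param readId id used in the output.
#' @return data.frame with columns `read_id`, `start`, `end` (1-based,
#'   inclusive), `strand`, `score`, `identity`, sorted by `start`. Zero rows
#'   when nothing is found.
#' @export
#' @importFrom Biostrings pairwiseAlignment nmatch nchar
findJunctions <- function(read, construct, param = SegmentParam(),
                          readId = "read") {
  read <- .normalizeDna(as.character(read), "read")
  cassette <- .junctionCassette(construct)
  perfect <- 2 * base::nchar(cassette)
  minScore <- param@junctionMinScoreFrac * perfect
  subMat <- .junctionSubMat()
  casLen <- base::nchar(cassette)
  L <- base::nchar(read)
  # a concatemer read lies on one strand; probe a prefix once per strand and
  # iterate on the better one (the other is still tried if < 2 hits turn up)
  probeSubj <- substr(read, 1L, min(L, 8000L))
  probe <- vapply(c(cassette, .revcomp(cassette)), function(p)
    BiocGenerics::score(pairwiseAlignment(p, probeSubj, type = "local",
                                          substitutionMatrix = subMat,
                                          gapOpening = 5, gapExtension = 2)),
    0, USE.NAMES = FALSE)
  strands <- if (probe[1L] >= probe[2L]) c("+", "-") else c("-", "+")
  # scan in overlapping windows so cost stays one pass over the read
  winSize <- max(4L * casLen, 3000L)
  overlap <- casLen + 200L
  winStarts <- unique(pmin(seq(1L, max(1L, L - 1L), by = winSize - overlap),
                           max(1L, L - winSize + 1L)))
  hits <- list()
  for (strand in strands) {
    if (strand == strands[2L] && length(hits) >= 2L) break
    pat <- if (strand == "+") cassette else .revcomp(cassette)
    for (ws in winStarts) {
      we <- min(L, ws + winSize - 1L)
      subjChars <- .chars(substr(read, ws, we))
      for (iter in seq_len(20L)) {
        aln <- pairwiseAlignment(pat, .collapse(subjChars), type = "local",
                                 substitutionMatrix = subMat,
                                 gapOpening = 5, gapExtension = 2)
        sc <- BiocGenerics::score(aln)
        if (sc < minScore) break
        sv <- Biostrings::subject(aln)
        s <- BiocGenerics::start(sv)
        e <- BiocGenerics::end(sv)
        err <- 1 - nmatch(aln) / Biostrings::nchar(aln)
        if (err <= param@junctionMaxError) {
          hits[[length(hits) + 1L]] <-
            data.frame(read_id = readId, start = ws + s - 1L,
                       end = ws + e - 1L, strand = strand,
                       score = sc, identity = 1 - err,
                       stringsAsFactors = FALSE)
        }
        subjChars[s:e] <- "N"
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(read_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      score = numeric(0), identity = numeric(0)))
  }
  df <- do.call(rbind, hits)
  # greedy overlap resolution: best score first, ties by leftmost start
  df <- df[order(-df$score, df$start), , drop = FALSE]
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    ok <- TRUE
    for (j in which(keep)) {
      if (df$start[i] <= df$end[j] && df$end[i] >= df$start[j]) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  df <- df[keep, , drop = FALSE]
  df[order(df$start), , drop = FALSE]
}

#' Split a read into candidate sub-reads at its junctions
#'
#' Each interval between consecutive junction hits becomes a candidate
#' sub-read; intervals outside `[minSubLen, maxSubLen]` are dropped (reason
#' `size`). Sub-reads are reverse-complemented into canonical orientation when
#' the junctions sit on the minus strand, and the barcode fields (the
#' `barcodeLen` bases adjacent to each junction, on the insert side) are
#' recorded as observations. Barcodes are still attached at this point; they
#' are clipped by [validateAndClip()].
#'
#' @param read read sequence.
#' @param junctions data.frame from [findJunctions()].
#' @param construct a [ConstructModel-class].
#' @param param a [SegmentParam-class].
#' @param readId read identifier.
#' @return a [SubReadSet-class] (possibly already discarded: `no_junction`
#'   when no junction was found, `no_valid_subread` when all intervals failed
#'   the size filter).
#' @export
splitRead <- function(read, junctions, construct, param = SegmentParam(),
                      readId = "read") {
  read <- .normalizeDna(as.character(read), "read")
  empty <- function(reason) new("SubReadSet", readId = readId,
                                subReads = character(0),
                                bc5Obs = character(0), bc3Obs = character(0),
                                discardReason = reason)
  if (nrow(junctions) == 0L) return(empty("no_junction"))
  strand <- names(sort(table(junctions$strand), decreasing = TRUE))[1L]
  j <- junctions[junctions$strand == strand, , drop = FALSE]
  j <- j[order(j$start), , drop = FALSE]
  if (nrow(j) < 2L) return(empty("no_valid_subread"))
  bl <- construct@barcodeLen
  subs <- character(0); bc5 <- character(0); bc3 <- character(0)
  for (i in seq_len(nrow(j) - 1L)) {
    s <- j$end[i] + 1L
    e <- j$start[i + 1L] - 1L
    len <- e - s + 1L
    if (len < param@minSubLen || len > param@maxSubLen) next
    canon <- substr(read, s, e)
    if (strand == "-") canon <- .revcomp(canon)
    subs <- c(subs, canon)
    bc5 <- c(bc5, substr(canon, 1L, bl))
    bc3 <- c(bc3, substr(canon, len - bl + 1L, len))
  }
  if (!length(subs)) return(empty("no_valid_subread"))
  new("SubReadSet", readId = readId, subReads = subs,
      bc5Obs = bc5, bc3Obs = bc3, orientation = strand,
      discardReason = NA_character_)
}

#' Gapped consensus of barcode observations
#'
#' The observations are multiply aligned; per column the most frequent
#' character (base or gap) is emitted when its frequency reaches `cutoff`,
#' otherwise an `N`. Gaps are then removed (ambiguity characters are kept).
#' Observations from more than one molecule surface either as extra gapped
#' columns (a consensus longer than `maxLen`) or, for equal-length conflicting
#' tags, as mostly-ambiguous columns (more than `maxLen %/% 2` `N`s); both
#' yield `"REJECTED"` (mixed barcodes).
#'
#' @param observations character vector of barcode fields (>= 1).
#' @param cutoff column frequency threshold (default 0.6).
#' @param maxLen maximum accepted consensus length (default 5).
#' @return consensus string, or `"REJECTED"`.
#' @export
barcodeConsensus <- function(observations, cutoff = 0.6, maxLen = 5L) {
  if (!length(observations)) stop("need at least one barcode observation")
  obs <- toupper(observations)
  obs <- obs[nzchar(obs)]
  if (!length(obs)) return("REJECTED")
  if (length(unique(obs)) == 1L) {
    cons <- obs[1L]
    return(if (base::nchar(cons) > maxLen) "REJECTED" else cons)
  }
  msa <- .progressiveAlign(obs, sprintf("o%d", seq_along(obs)),
                           ConsensusParam(bandWidth = 10L), orderBy = "median")
  mat <- .msaMatrix(msa)
  counts <- .profFromMatrix(mat)
  freq <- counts / nrow(mat)
  top <- apply(freq, 2L, max)
  ch <- .ALPHABET[max.col(t(counts - .CHAR_RANK[.ALPHABET] * 1e-3),
                          ties.method = "first")]
  cons <- ifelse(top >= cutoff, ch, "N")
  cons <- .collapse(cons[cons != "-"])
  nAmbig <- sum(.chars(cons) == "N")
  if (base::nchar(cons) > maxLen || nAmbig > maxLen %/% 2L) "REJECTED"
  else cons
}

#' Validate barcode consistency and clip barcodes
#'
#' Both barcode consensuses are computed; if either is rejected the whole read
#' is discarded (`mixed_barcode`). Otherwise the barcodes are recorded and
#' clipped from the sub-read sequences, which are excluded from all further
#' analysis.
#'
#' @param set a [SubReadSet-class] from [splitRead()].
#' @param param a [SegmentParam-class].
#' @param barcodeLen number of bases clipped at each end (default
#'   `param@maxBarcodeLen`).
#' @return the updated [SubReadSet-class].
#' @export
validateAndClip <- function(set, param = SegmentParam(),
                            barcodeLen = param@maxBarcodeLen) {
  if (!isRetained(set)) return(set)
  bc5 <- barcodeConsensus(set@bc5Obs, param@barcodeCutoff, param@maxBarcodeLen)
  bc3 <- barcodeConsensus(set@bc3Obs, param@barcodeCutoff, param@maxBarcodeLen)
  set@bc5 <- bc5
  set@bc3 <- bc3
  if (identical(bc5, "REJECTED") || identical(bc3, "REJECTED")) {
    set@discardReason <- "mixed_barcode"
    return(set)
  }
  set@subReads <- vapply(set@subReads, function(s) {
    substr(s, barcodeLen + 1L, base::nchar(s) - barcodeLen)
  }, "", USE.NAMES = FALSE)
  set
}

#' Segment one read end to end
#'
#' [findJunctions()], [splitRead()], then [validateAndClip()].
#'
#' @param read read sequence.
#' @param construct a [ConstructModel-class].
#' @param param a [SegmentParam-class].
#' @param readId read identifier.
#' @return a [SubReadSet-class].
#' @export
segmentRead <- function(read, construct, param = SegmentParam(),
                        readId = "read") {
  j <- findJunctions(read, construct, param, readId)
  validateAndClip(splitRead(read, j, construct, param, readId), param,
                  barcodeLen = construct@barcodeLen)
}

#' Segment a set of reads with ledger accounting
#'
#' @param reads named character vector (or any object coercible with
#'   `as.character`, e.g. a `QualityScaledDNAStringSet`).
#' @param construct a [ConstructModel-class].
#' @param param a [SegmentParam-class].
#' @param ledger optional [StageLedger-class] to append to.
#' @return `list(sets = <list of SubReadSet>, ledger = <StageLedger>)`;
#'   `sets` keeps one entry per input read, discarded or not.
#' @export
segmentReads <- function(reads, construct, param = SegmentParam(),
                         ledger = StageLedger()) {
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%05d", seq_along(reads))
  reads <- as.character(reads)
  sets <- lapply(seq_along(reads), function(i)
    segmentRead(reads[[i]], construct, param, readId = ids[i]))
  names(sets) <- ids
  reasons <- vapply(sets, function(s) s@discardReason, "")
  disc <- table(reasons[!is.na(reasons)])
  ledger <- addStage(ledger, "segment", length(reads),
                     sum(is.na(reasons)),
                     stats::setNames(as.integer(disc), names(disc)))
  list(sets = sets, ledger = ledger)
}
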