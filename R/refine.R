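# Genus-level MSA refinement: progressive alignment with local window repair,
# the two-pass column-correction procedure (count first, exclude outliers,
# then apply), and ragged-end trimming.

# column disagreement = 1 - plurality fraction (all characters, gaps included)
.colDisagreement <- function(mat) {
  prof <- .profFromMatrix(mat)
  1 - apply(prof, 2L, max) / nrow(mat)
}

#' Align the consensus sequences of one genus cluster
#'
#' Progressive profile alignment (guide order by decreasing length) followed by
#' local repair: windows whose column disagreement exceeds
#' `realignMinDisagreement` are extracted with 10-column flanks, re-aligned,
#' and spliced back when the re-alignment reduces disagreement. This repairs
#' the inconsistent gap placements progressive alignment can produce in
#' repetitive stretches. Deterministic.
#'
#' @param seqs named character vector of >= 2 sequences from one genus.
#' @param param a [RefineParam-class].
#' @param alnParam a [ConsensusParam-class] (alignment scores and band).
#' @return a [DnaMsa-class] in input row order.
#' @export
buildGenusMsa <- function(seqs, param = RefineParam(),
                          alnParam = ConsensusParam()) {
  if (length(seqs) < 2L) stop("a genus alignment needs at least 2 sequences")
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("seq%04d", seq_along(seqs))
  msa <- .progressiveAlign(unname(seqs), ids, alnParam, orderBy = "length")
  mat <- .msaMatrix(msa)
  dis <- .colDisagreement(mat)
  bad <- which(dis > param@realignMinDisagreement)
  if (!length(bad)) return(msa)
  # group disagreeing columns into windows (merge gaps <= 5), widest first
  runs <- split(bad, cumsum(c(1L, diff(bad) > 5L)))
  windows <- lapply(runs, function(r) {
    c(max(1L, min(r) - 10L), min(ncol(mat), max(r) + 10L))
  })
  windows <- windows[order(-vapply(windows, `[`, 0, 1L))]  # right to left
  for (w in windows) {
    block <- mat[, w[1L]:w[2L], drop = FALSE]
    ung <- apply(block, 1L, function(r) .collapse(r[r != "-"]))
    if (length(unique(ung[nzchar(ung)])) < 2L) next
    reblock <- tryCatch({
      sub <- .progressiveAlign(ung, rownames(block, do.NULL = FALSE),
                               alnParam, orderBy = "length")
      .msaMatrix(sub)
    }, error = function(e) NULL)
    if (is.null(reblock)) next
    if (sum(.colDisagreement(reblock)) < sum(.colDisagreement(block))) {
      mat <- cbind(mat[, seq_len(w[1L] - 1L), drop = FALSE], reblock,
                   if (w[2L] < ncol(mat))
                     mat[, (w[2L] + 1L):ncol(mat), drop = FALSE])
    }
  }
  .msaFromMatrix(ids, mat)
}

#' Classify one alignment column for correction
#'
#' If one character (gaps participate; `N` can never be dominant) reaches the
#' dominant frequency, all minority characters are corrected to it. Otherwise,
#' if two or more characters are each at or above the minority threshold, any
#' character below that threshold is corrected to `N`. Otherwise no action.
#'
#' @param column character vector (one alignment column).
#' @param param a [RefineParam-class].
#' @return `list(action, replacement, change)` where `change` is a logical
#'   vector marking the cells that would be modified.
#' @export
analyzeColumn <- function(column, param = RefineParam()) {
  n <- length(column)
  if (!n) stop("empty column")
  counts <- table(factor(column, levels = .ALPHABET))
  freq <- as.numeric(counts) / n
  names(freq) <- .ALPHABET
  cand <- setdiff(.ALPHABET, "N")          # N never counts as dominant
  top <- cand[order(-freq[cand], .CHAR_RANK[cand])][1L]
  if (freq[[top]] >= param@dominantFraction && freq[[top]] < 1) {
    return(list(action = "corrected_to_dominant", replacement = top,
                change = column != top))
  }
  abundant <- .ALPHABET[freq >= param@minorityToN & as.numeric(counts) > 0]
  low <- .ALPHABET[freq < param@minorityToN & as.numeric(counts) > 0]
  low <- setdiff(low, "N")
  if (length(abundant) >= 2L && length(low)) {
    return(list(action = "minority_to_N", replacement = "N",
                change = column %in% low))
  }
  list(action = "none", replacement = NA_character_, change = rep(FALSE, n))
}

#' Two-pass column correction of a genus alignment
#'
#' Pass 1 counts the prospective corrections of every sequence without
#' applying any; sequences whose count exceeds
#' `maxCorrectionFraction * <ungapped length>` are excluded as outliers
#' (in practice large-indel or chimeric sequences). Pass 2 recomputes the
#' column statistics on the survivors only — so the outliers never influence
#' the final corrections — and applies them. Corrected cells are modified in
#' the alignment; ungapped sequences are regenerated from it.
#'
#' @param msa a [DnaMsa-class] from [buildGenusMsa()].
#' @param param a [RefineParam-class].
#' @return `list(msa = <corrected DnaMsa of survivors>, report = <data.frame
#'   with counted/applied corrections per sequence>, excludedIds)`.
#' @export
correctMsa <- function(msa, param = RefineParam()) {
  mat <- .msaMatrix(msa)
  countPass <- function(m) {
    cnt <- integer(nrow(m))
    for (j in seq_len(ncol(m))) {
      a <- analyzeColumn(m[, j], param)
      cnt <- cnt + a$change
    }
    cnt
  }
  counted <- countPass(mat)
  ungLen <- base::nchar(ungap(msa))
  excluded <- counted > param@maxCorrectionFraction * ungLen
  excludedIds <- msa@ids[excluded]
  keep <- which(!excluded)
  if (!length(keep)) stop("all sequences excluded by the correction filter")
  m2 <- mat[keep, , drop = FALSE]
  applied <- integer(length(keep))
  for (j in seq_len(ncol(m2))) {
    a <- analyzeColumn(m2[, j], param)
    if (a$action != "none" && any(a$change)) {
      applied <- applied + a$change
      m2[a$change, j] <- a$replacement
    }
  }
  report <- data.frame(id = msa@ids,
                       corrections_counted = counted,
                       corrections_applied = 0L,
                       excluded = excluded,
                       stringsAsFactors = FALSE)
  report$corrections_applied[keep] <- applied
  # drop columns that became all-gap after correction
  m2 <- m2[, colSums(m2 != "-") > 0L, drop = FALSE]
  list(msa = .msaFromMatrix(msa@ids[keep], m2), report = report,
       excludedIds = excludedIds)
}

#' Trim ragged alignment ends
#'
#' Keeps columns from the first to the last column whose non-gap fraction
#' reaches `trimNongapFraction`, removing ragged ends and, when a construct is
#' given, any residual primer-motif columns at the boundaries.
#'
#' @param msa a [DnaMsa-class] (after correction).
#' @param param a [RefineParam-class].
#' @param construct optional [ConstructModel-class]; when supplied, primer
#'   motifs still visible in the boundary consensus are trimmed as well.
#' @return `list(msa = <trimmed DnaMsa>, left, right)` with 1-based kept
#'   column bounds on the input alignment.
#' @export
trimMsa <- function(msa, param = RefineParam(), construct = NULL) {
  mat <- .msaMatrix(msa)
  nonGap <- colSums(mat != "-") / nrow(mat)
  ok <- which(nonGap >= param@trimNongapFraction)
  if (!length(ok)) stop("empty_after_trim: no column passes the non-gap rule")
  left <- min(ok); right <- max(ok)
  if (!is.null(construct)) {
    sl <- .msaFromMatrix(msa@ids, mat[, left:right, drop = FALSE])
    consG <- .chars(columnConsensus(sl))
    baseCols <- which(consG != "-")       # slice columns carrying a consensus base
    cons <- .collapse(consG[baseCols])
    n <- base::nchar(cons)
    f <- .motifHit(substr(cons, 1L, min(40L, n)), construct@fwdAnneal, 2L)
    if (!is.null(f) && f[1L] <= 5L) {
      left <- (min(ok) - 1L) + baseCols[f[2L]] + 1L
    }
    roff <- max(1L, n - 39L)
    r <- .motifHit(substr(cons, roff, n), .revcomp(construct@revAnneal), 2L)
    if (!is.null(r)) {
      p <- roff + r[1L] - 1L              # ungapped start of the motif
      if (n - (p + r[2L] - r[1L]) <= 5L)
        right <- (min(ok) - 1L) + baseCols[p] - 1L
    }
    if (left > right) stop("empty_after_trim: primer masking removed all columns")
  }
  list(msa = .msaFromMatrix(msa@ids, mat[, left:right, drop = FALSE]),
       left = left, right = right)
}
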