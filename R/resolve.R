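# Resolving a genus alignment into individual rrn copies. The discriminating
# signal is concentrated by slicing out the variable columns (plus flanks);
# the slices are re-clustered over an identity ladder and surviving clusters
# are mapped back to full-length sequences.

#' Variable columns of a corrected genus alignment
#'
#' A column is variable when the frequency of its plurality character, over
#' non-N rows (gaps count as characters), is below
#' `variableMajorityFraction`. Columns that are entirely N are skipped.
#'
#' @param msa a corrected, trimmed [DnaMsa-class].
#' @param param a [ResolveParam-class].
#' @return 1-based column indices.
#' @export
variableColumns <- function(msa, param = ResolveParam()) {
  mat <- .msaMatrix(msa)
  out <- integer(0)
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    col <- col[col != "N"]
    if (!length(col)) next
    if (max(table(col)) / length(col) < param@variableMajorityFraction)
      out <- c(out, j)
  }
  out
}

#' Extract variable-column sub-sequences
#'
#' Per row, concatenates the characters of every variable column plus
#' `flankColumns` columns on each side; overlapping windows are merged and
#' clipped at the alignment bounds. Gaps are retained as characters, so rrns
#' that differ only by a deletion stay distinguishable.
#'
#' @param msa a [DnaMsa-class].
#' @param columns variable column indices from [variableColumns()].
#' @param param a [ResolveParam-class].
#' @return named character vector of equal-width sub-sequences (one per row).
#' @export
extractSubsequences <- function(msa, columns, param = ResolveParam()) {
  if (!length(columns))
    stop("no_variable_columns: genus appears to carry a single rrn")
  w <- msaWidth(msa)
  fl <- param@flankColumns
  starts <- pmax(1L, columns - fl)
  ends <- pmin(w, columns + fl)
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1L]; me <- ends[1L]
  wins <- list()
  for (i in seq_along(starts)[-1L]) {
    if (starts[i] <= me + 1L) me <- max(me, ends[i])
    else { wins[[length(wins) + 1L]] <- c(ms, me); ms <- starts[i]; me <- ends[i] }
  }
  wins[[length(wins) + 1L]] <- c(ms, me)
  mat <- .msaMatrix(msa)
  idx <- unlist(lapply(wins, function(wn) seq.int(wn[1L], wn[2L])))
  stats::setNames(apply(mat[, idx, drop = FALSE], 1L, paste, collapse = ""),
                  msa@ids)
}

# Hamming identity between equal-width window strings; N is a wildcard so
# correction-introduced uncertainty never splits a cluster.
.hammingIdentity <- function(a, b) {
  ca <- .chars(a); cb <- .chars(b)
  mean(ca == cb | ca == "N" | cb == "N")
}

# greedy clustering of aligned window strings: identical strings are grouped,
# groups processed by decreasing abundance (ties lexicographic), each joining
# the first representative within the identity threshold
.greedyHamming <- function(strs, identity) {
  grp <- split(names(strs), unname(strs))
  grp <- grp[order(-lengths(grp), names(grp))]
  reps <- character(0)
  assign <- integer(length(grp))
  for (g in seq_along(grp)) {
    s <- names(grp)[g]
    hit <- 0L
    for (r in seq_along(reps)) {
      if (.hammingIdentity(s, reps[r]) >= identity) { hit <- r; break }
    }
    if (hit == 0L) { reps <- c(reps, s); hit <- length(reps) }
    assign[g] <- hit
  }
  lapply(seq_along(reps), function(r) {
    mem <- unlist(grp[assign == r], use.names = FALSE)
    new("SeqCluster", clusterId = sprintf("rrn%03d", r), level = "rrn",
        identityThreshold = identity, memberIds = mem,
        representativeId = grp[[which(assign == r)[1L]]][1L])
  })
}

#' Consensus sequence of a full-length cluster
#'
#' Members are multiply aligned (same engine as the genus MSA), the plurality
#' column consensus taken, and gaps stripped.
#'
#' @param seqs named character vector of cluster members (>= 1).
#' @param alnParam a [ConsensusParam-class].
#' @return ungapped consensus string.
#' @export
clusterConsensus <- function(seqs, alnParam = ConsensusParam()) {
  if (!length(seqs)) stop("empty cluster")
  if (length(seqs) == 1L) return(unname(seqs[[1L]]))
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("m%d", seq_along(seqs))
  msa <- .progressiveAlign(unname(seqs), ids, alnParam, orderBy = "length")
  ungap(columnConsensus(msa))
}

#' Identity sweep over variable-column sub-sequences
#'
#' For each identity on the ladder, the sub-sequences are greedily clustered
#' (column-wise identity on the aligned windows, N as wildcard), clusters
#' below `minClusterInputFraction` of the input (or `rescueMinMembers`, when
#' set) are excluded as putative chimeras, and the surviving count recorded.
#' Surviving sub-sequence clusters are mapped back to clusters of the
#' full-length sequences, whose plurality consensus is attached.
#'
#' The reported call uses, in order of preference: the lowest identity
#' reaching `targetCount` (when a target is known a priori, mirroring upward
#' adjustment of the threshold); the terminal count at the top of the ladder
#' (`reportRule = "terminal"`, the finest resolvable structure); or the modal
#' count across the ladder (`reportRule = "plateau"`, the default).
#'
#' @param subseqs named character vector from [extractSubsequences()].
#' @param fullSeqs named character vector of the corresponding full-length
#'   corrected sequences (same ids).
#' @param param a [ResolveParam-class].
#' @param genus label for the call.
#' @param targetCount optional known rrn count.
#' @param reportRule `"plateau"` or `"terminal"` (ignored when `targetCount`
#'   is given).
#' @param alnParam alignment parameters for the cluster consensus.
#' @return an [RrnCall-class].
#' @export
sweepCluster <- function(subseqs, fullSeqs, param = ResolveParam(),
                         genus = "genus", targetCount = NULL,
                         reportRule = c("plateau", "terminal"),
                         alnParam = ConsensusParam()) {
  reportRule <- match.arg(reportRule)
  stopifnot(all(names(subseqs) %in% names(fullSeqs)))
  ladder <- param@sweepIdentities
  counts <- integer(length(ladder))
  for (i in seq_along(ladder)) {
    cl <- .greedyHamming(subseqs, ladder[i])
    filt <- filterSmallClusters(cl, inputN = length(subseqs),
                                minFraction = param@minClusterInputFraction,
                                rescueMinMembers = param@rescueMinMembers)
    counts[i] <- length(filt$kept)
  }
  curve <- data.frame(identity = ladder, count = counts)
  chosen <- if (!is.null(targetCount)) {
    hit <- which(counts == targetCount)
    if (length(hit)) ladder[hit[1L]]
    else ladder[which.max(counts)]
  } else if (reportRule == "terminal") {
    ladder[length(ladder)]
  } else {
    tab <- table(counts)
    modal <- max(as.integer(names(tab)[tab == max(tab)]))
    ladder[which(counts == modal)[1L]]
  }
  cl <- .greedyHamming(subseqs, chosen)
  filt <- filterSmallClusters(cl, inputN = length(subseqs),
                              minFraction = param@minClusterInputFraction,
                              rescueMinMembers = param@rescueMinMembers)
  clusters <- lapply(seq_along(filt$kept), function(r) {
    k <- filt$kept[[r]]
    k@clusterId <- sprintf("%s_rrn%03d", genus, r)
    k@consensus <- clusterConsensus(fullSeqs[k@memberIds], alnParam)
    k
  })
  new("RrnCall", genus = genus, identityUsed = chosen, clusters = clusters,
      curve = curve, excludedIds = filt$excludedIds)
}

#' Reference-based two-parent chimera detection
#'
#' The candidate is compared to every single reference (full global edit
#' distance) and to every ordered reference pair under a single-breakpoint
#' model: prefix edit distance to parent A plus suffix edit distance to parent
#' B, minimized over the breakpoint via prefix/suffix DP arrays. The candidate
#' is called chimeric when the best two-parent model saves at least
#' `chimeraMinEditsSaved` edits AND `chimeraMinIdentityGain` of the candidate
#' length over the best single parent.
#'
#' @param candidate sequence to test.
#' @param refs named character vector of >= 2 vetted references.
#' @param param a [ResolveParam-class].
#' @return `list(isChimera, bestRef, parents, breakpoint, editsSaved,
#'   identityGain)`; breakpoint is the 1-based candidate position after which
#'   the second parent takes over.
#' @export
detectChimera <- function(candidate, refs, param = ResolveParam()) {
  if (length(refs) < 2L) stop("need at least 2 references")
  if (is.null(names(refs))) names(refs) <- sprintf("ref%d", seq_along(refs))
  enc <- .encodeSeq(candidate)
  n <- length(enc)
  rev1 <- rev(enc)
  pref <- list(); sufs <- list(); full <- numeric(length(refs))
  for (r in seq_along(refs)) {
    er <- .encodeSeq(refs[[r]])
    fa <- .cpp_edit_arrays(enc, er)
    pref[[r]] <- fa$prefix_min
    full[r] <- fa$full
    sufs[[r]] <- rev(.cpp_edit_arrays(rev1, rev(er))$prefix_min)
  }
  bestSingle <- min(full)
  bestRef <- names(refs)[which.min(full)]
  lo <- min(20L, n); hiI <- max(1L, n - 20L)
  span <- seq.int(lo, hiI)
  bestTwo <- Inf; bestPair <- c(NA_character_, NA_character_); bestBp <- NA_integer_
  for (a in seq_along(refs)) for (b in seq_along(refs)) {
    if (a == b) next
    tot <- pref[[a]][span + 1L] + sufs[[b]][span + 1L]
    i <- which.min(tot)
    if (tot[i] < bestTwo) {
      bestTwo <- tot[i]
      bestPair <- c(names(refs)[a], names(refs)[b])
      bestBp <- span[i]
    }
  }
  saved <- bestSingle - bestTwo
  gain <- saved / n
  list(isChimera = saved >= param@chimeraMinEditsSaved &&
         gain >= param@chimeraMinIdentityGain,
       bestRef = bestRef, parents = bestPair, breakpoint = bestBp,
       editsSaved = saved, identityGain = gain)
}
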