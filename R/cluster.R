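# Genus-level organisation of consensus sequences: extract the 16S portion,
# cluster greedily at ~genus identity, exclude small clusters, and label
# clusters from V4 references.

#' @importFrom Biostrings DNAString matchPattern nucleotideSubstitutionMatrix
NULL

.NUC_MAT <- NULL
.nucMat <- function() {
  if (is.null(.NUC_MAT)) {
    m <- nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                      baseOnly = FALSE, type = "DNA")
    utils::assignInMyNamespace(".NUC_MAT", m)
  }
  .NUC_MAT
}

# identity = matches / alignment columns. type = "overlap" excludes end gaps
# (clustering convention); type = "global" includes them (full-length
# global-identity convention).
.pairIdentity <- function(a, b, type = c("overlap", "global")) {
  type <- match.arg(type)
  aln <- pairwiseAlignment(a, b, type = type,
                           substitutionMatrix = .nucMat(),
                           gapOpening = 5, gapExtension = 1)
  nmatch(aln) / Biostrings::nchar(aln)
}

# first/last IUPAC motif hit (mismatches allowed, no indels); NULL if absent
.motifHit <- function(seq, motif, maxMismatch, last = FALSE) {
  h <- matchPattern(DNAString(motif), DNAString(seq),
                    max.mismatch = maxMismatch, with.indels = FALSE,
                    fixed = c(pattern = FALSE, subject = TRUE))
  if (!length(h)) return(NULL)
  i <- if (last) length(h) else 1L
  c(BiocGenerics::start(h)[i], BiocGenerics::end(h)[i])
}

#' Extract the 16S gene by strict primer matching
#'
#' Returns the bases between the forward (27F-type) and reverse (1492R-type)
#' universal primer sites, inclusive, located by IUPAC-aware motif matching
#' with at most `maxMismatch` mismatches and no indels, in canonical
#' orientation. `NA` when either motif is absent.
#'
#' @param seq consensus sequence (character).
#' @param fwdPrimer forward primer motif (default the 27F core).
#' @param revPrimer reverse primer as written 5'->3' on the antisense strand
#'   (default 1492R); its reverse complement is searched on the sense strand.
#' @param maxMismatch mismatches tolerated per motif (default 1).
#' @return the 16S span as a character string, or `NA_character_`.
#' @export
extract16S <- function(seq, fwdPrimer = .PRIMER_27F,
                       revPrimer = .PRIMER_1492R, maxMismatch = 1L) {
  f <- .motifHit(seq, fwdPrimer, maxMismatch)
  if (is.null(f)) return(NA_character_)
  r <- .motifHit(seq, .revcomp(revPrimer), maxMismatch, last = TRUE)
  if (is.null(r) || r[2L] <= f[1L]) return(NA_character_)
  substr(seq, f[1L], r[2L])
}

#' Similarity-based 16S extraction for primer-mutated sequences
#'
#' Sequences whose primer motifs failed strict matching are rescued by local
#' alignment against a seed set of 16S genes (built from high-confidence
#' consensus sequences with strict primer hits): the best hit's footprint on
#' the query is taken as its 16S. Queries below the identity or coverage
#' threshold stay unextracted.
#'
#' @param unmatched named character vector of full-length sequences.
#' @param seeds character vector of seed 16S sequences (non-empty).
#' @param minIdentity minimum alignment identity (default 0.85).
#' @param minCoverage minimum fraction of the seed covered (default 0.8).
#' @return named character vector aligned with `unmatched`; `NA` where not
#'   extracted.
#' @export
rescue16S <- function(unmatched, seeds, minIdentity = 0.85,
                      minCoverage = 0.8) {
  if (!length(seeds)) stop("seed 16S set is empty")
  vapply(unmatched, function(q) {
    best <- NULL; bestScore <- -Inf
    for (s in seeds) {
      aln <- pairwiseAlignment(q, s, type = "local",
                               substitutionMatrix = .nucMat(),
                               gapOpening = 5, gapExtension = 1)
      if (BiocGenerics::score(aln) > bestScore) {
        bestScore <- BiocGenerics::score(aln); best <- list(aln = aln, seed = s)
      }
    }
    aln <- best$aln
    cov <- (BiocGenerics::end(Biostrings::subject(aln)) -
              BiocGenerics::start(Biostrings::subject(aln)) + 1L) /
      base::nchar(best$seed)
    ident <- nmatch(aln) / Biostrings::nchar(aln)
    if (ident >= minIdentity && cov >= minCoverage) {
      substr(q, BiocGenerics::start(Biostrings::pattern(aln)),
             BiocGenerics::end(Biostrings::pattern(aln)))
    } else NA_character_
  }, "")
}

#' Greedy identity clustering
#'
#' Sequences are sorted by decreasing length and compared to existing cluster
#' representatives (k-mer count prefilter, then banded overlap alignment); a
#' sequence joins the first representative reaching the identity threshold
#' (identity = matches / alignment columns, end gaps excluded) or founds a new
#' cluster. Deterministic.
#'
#' @param seqs named character vector (>= 1).
#' @param identity clustering identity threshold.
#' @param param a [ClusterParam-class] (k-mer prefilter settings).
#' @param level label stored on the clusters (`"genus"` or `"rrn"`).
#' @return list of [SeqCluster-class].
#' @export
greedyCluster <- function(seqs, identity = 0.95, param = ClusterParam(),
                          level = "genus") {
  if (!length(seqs)) stop("no sequences to cluster")
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%05d", seq_along(seqs))
  ord <- order(-base::nchar(seqs), seq_along(seqs))
  k <- param@kmerSize
  reps <- list()
  membership <- integer(length(seqs))
  for (i in ord) {
    q <- seqs[[i]]
    qk <- .kmerSet(q, k)
    minShared <- ceiling(param@prefilterMinFrac * identity * length(qk))
    joined <- 0L
    for (r in seq_along(reps)) {
      if (length(qk) &&
          sum(qk %in% reps[[r]]$kmers) < minShared) next
      if (.pairIdentity(q, reps[[r]]$seq, "overlap") >= identity) {
        joined <- r; break
      }
    }
    if (joined == 0L) {
      reps[[length(reps) + 1L]] <- list(id = names(seqs)[i], seq = q,
                                        kmers = .kmerSet(q, k))
      joined <- length(reps)
    }
    membership[i] <- joined
  }
  lapply(seq_along(reps), function(r) {
    new("SeqCluster", clusterId = sprintf("%s%03d", level, r), level = level,
        identityThreshold = identity,
        memberIds = names(seqs)[membership == r],
        representativeId = reps[[r]]$id)
  })
}

#' Exclude small clusters
#'
#' Genus level: clusters need at least `minMembers` members. rrn level:
#' clusters below `ceiling(minFraction * inputN)` members are excluded as
#' putative chimeras, unless `rescueMinMembers` is set, in which case that
#' absolute floor applies instead (the rescue used for genera whose isolates
#' are individually rare).
#'
#' @param clusters list of [SeqCluster-class].
#' @param minMembers absolute member floor (genus level).
#' @param inputN,minFraction fraction rule inputs (rrn level).
#' @param rescueMinMembers optional absolute floor overriding the fraction
#'   rule.
#' @return `list(kept = <clusters>, excludedIds = <character>)`.
#' @export
filterSmallClusters <- function(clusters, minMembers = NA, inputN = NA,
                                minFraction = NA, rescueMinMembers = NA) {
  thr <- if (!is.na(rescueMinMembers)) rescueMinMembers
         else if (!is.na(minMembers)) minMembers
         else if (!is.na(inputN) && !is.na(minFraction))
           ceiling(minFraction * inputN)
         else stop("no size rule given")
  sizes <- vapply(clusters, function(cl) length(cl@memberIds), 0L)
  kept <- clusters[sizes >= thr]
  excluded <- unlist(lapply(clusters[sizes < thr], members))
  list(kept = kept, excludedIds = as.character(excluded))
}

# V4 span via the Earth-Microbiome motifs
.extractV4 <- function(seq, maxMismatch = 2L) {
  f <- .motifHit(seq, .PRIMER_515F, maxMismatch)
  if (is.null(f)) return(NA_character_)
  r <- .motifHit(seq, .revcomp(.PRIMER_806R), maxMismatch, last = TRUE)
  if (is.null(r) || r[2L] <= f[1L]) return(NA_character_)
  substr(seq, f[1L], r[2L])
}

#' Assign a taxonomy label to a cluster from labeled V4 references
#'
#' Each member's V4 span (515F/806R motifs, <= `maxMismatch` mismatches each)
#' is labeled by its best-identity reference; the cluster label is the modal
#' member label, reported with the modal fraction. `"unassigned"` when no
#' member yields a V4 span.
#'
#' @param cluster a [SeqCluster-class].
#' @param seqs named character vector holding the member sequences.
#' @param v4Refs named character vector of labeled V4 reference sequences
#'   (names are taxon labels); must be non-empty.
#' @param maxMismatch per-motif mismatch allowance (default 2).
#' @return the cluster with `taxonomy` and `modalFraction` filled in.
#' @export
assignTaxonomy <- function(cluster, seqs, v4Refs, maxMismatch = 2L) {
  if (!length(v4Refs)) stop("V4 reference set is empty")
  labels <- character(0)
  for (m in cluster@memberIds) {
    v4 <- .extractV4(seqs[[m]], maxMismatch)
    if (is.na(v4)) next
    ident <- vapply(v4Refs, function(r) .pairIdentity(v4, r, "overlap"), 0)
    labels <- c(labels, names(v4Refs)[which.max(ident)])
  }
  if (!length(labels)) {
    cluster@taxonomy <- "unassigned"
    cluster@modalFraction <- NA_real_
    return(cluster)
  }
  tab <- sort(table(labels), decreasing = TRUE)
  cluster@taxonomy <- names(tab)[1L]
  cluster@modalFraction <- as.numeric(tab[1L]) / length(cluster@memberIds)
  cluster
}

#' Full-length global-identity prefilter
#'
#' Keeps a sequence iff its best full-length global identity against any
#' reference reaches `minIdentity` (end gaps count as alignment columns).
#' Used to drop truncated or artifactual sequences when trusted 16S-ITS
#' references exist for the sample. Note this does not remove chimeras of two
#' references: a 50/50 crossover keeps ~97% identity to either parent.
#'
#' @param seqs named character vector.
#' @param refs character vector of reference 16S-ITS sequences (non-empty).
#' @param minIdentity threshold (default 0.95).
#' @return `list(kept = <named character>, discardedIds = <character>)`.
#' @export
globalIdentityPrefilter <- function(seqs, refs, minIdentity = 0.95) {
  if (!length(refs)) stop("reference set is empty")
  ok <- vapply(seqs, function(q) {
    for (r in refs) {
      if (.pairIdentity(q, r, "global") >= minIdentity) return(TRUE)
    }
    FALSE
  }, TRUE)
  list(kept = seqs[ok], discardedIds = names(seqs)[!ok])
}

#' Cluster summaries as a data.frame
#'
#' @param clusters list of [SeqCluster-class].
#' @return data.frame with id, level, threshold, size, representative,
#'   taxonomy, and modal fraction.
#' @export
clusterTable <- function(clusters) {
  do.call(rbind, lapply(clusters, function(cl) {
    data.frame(cluster_id = cl@clusterId, level = cl@level,
               identity = cl@identityThreshold,
               size = length(cl@memberIds),
               representative = cl@representativeId,
               taxonomy = cl@taxonomy, modal_fraction = cl@modalFraction,
               stringsAsFactors = FALSE)
  }))
}
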