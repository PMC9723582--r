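# Quantitative summaries: error rates against references, uniformity tests on
# rrn abundances, cross-platform agreement statistics, informative-site
# counts, and stage-survival tables.

#' Estimate per-sequence error against reference sequences
#'
#' Each sequence is locally aligned to every reference; the best-scoring match
#' is assumed correct. The alignment length is the aligned region (HSP) plus
#' any unaligned bases of the reference, and percent identity is identities
#' divided by that length, so truncated queries are penalized for the
#' reference they fail to cover.
#'
#' @param seqs named character vector (sub-reads, consensus sequences, or
#'   extracted 16S portions).
#' @param refs named character vector of references (non-empty).
#' @return `list(perSequence = <data.frame>, meanIdentity, sdIdentity,
#'   meanErrorPct)`.
#' @export
estimateError <- function(seqs, refs) {
  if (!length(refs)) stop("reference set is empty")
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%05d", seq_along(seqs))
  rows <- lapply(names(seqs), function(id) {
    q <- seqs[[id]]
    best <- NULL; bestScore <- -Inf; bestRef <- NA_character_
    for (r in names(refs)) {
      aln <- pairwiseAlignment(q, refs[[r]], type = "local",
                               substitutionMatrix = .nucMat(),
                               gapOpening = 5, gapExtension = 1)
      if (BiocGenerics::score(aln) > bestScore) {
        bestScore <- BiocGenerics::score(aln); best <- aln; bestRef <- r
      }
    }
    refLen <- base::nchar(refs[[bestRef]])
    covered <- BiocGenerics::end(Biostrings::subject(best)) -
      BiocGenerics::start(Biostrings::subject(best)) + 1L
    alnLen <- Biostrings::nchar(best) + (refLen - covered)
    ident <- nmatch(best)
    data.frame(id = id, best_ref = bestRef, identities = ident,
               alignment_length = alnLen,
               percent_identity = 100 * ident / alnLen,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  list(perSequence = per,
       meanIdentity = mean(per$percent_identity),
       sdIdentity = stats::sd(per$percent_identity),
       meanErrorPct = 100 - mean(per$percent_identity))
}

#' Chi-square test against a uniform distribution
#'
#' Goodness-of-fit of observed category counts to equal expected counts;
#' upper-tail p-value. Used to ask whether reads distribute evenly over the
#' rrn copies of a genome.
#'
#' @param counts integer vector of >= 2 category counts, total > 0.
#' @return `list(statistic, df, p.value)`.
#' @export
chisqUniform <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) < 2L) stop("need at least 2 categories")
  total <- sum(counts)
  if (total <= 0) stop("zero total count")
  expd <- total / length(counts)
  stat <- sum((counts - expd)^2 / expd)
  df <- length(counts) - 1L
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Pearson correlation
#' @param x,y numeric vectors of equal length >= 3 with non-zero variance.
#' @export
pearsonR <- function(x, y) {
  .checkXY(x, y)
  stats::cor(x, y)
}

#' Spearman rank correlation (mid-ranks for ties)
#' @param x,y numeric vectors of equal length >= 3 with non-zero variance.
#' @export
spearmanRho <- function(x, y) {
  .checkXY(x, y)
  stats::cor(x, y, method = "spearman")
}

#' Least-squares R-squared of y on x
#' @param x,y numeric vectors of equal length >= 3 with non-zero variance.
#' @export
rSquared <- function(x, y) {
  .checkXY(x, y)
  summary(stats::lm(y ~ x))$r.squared
}

.checkXY <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance")
  invisible(TRUE)
}

#' All three agreement statistics at once
#' @param x,y paired abundance counts.
#' @return `list(pearson, spearman, r_squared)`.
#' @export
correlationStats <- function(x, y) {
  list(pearson = pearsonR(x, y), spearman = spearmanRho(x, y),
       r_squared = rSquared(x, y))
}

#' Informative alignment columns
#'
#' `variable`: columns with at least two distinct non-N characters (a gap is a
#' character). `parsimony`: columns where at least two non-N characters each
#' occur at least twice. Both are reported because "informative" is used
#' loosely in the field.
#'
#' @param msa a [DnaMsa-class] with >= 2 rows.
#' @return named integer vector `c(variable = , parsimony = )`.
#' @export
informativeSites <- function(msa) {
  mat <- .msaMatrix(msa)
  if (nrow(mat) < 2L) stop("need >= 2 rows")
  variable <- 0L; parsimony <- 0L
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    col <- col[col != "N"]
    if (!length(col)) next
    tab <- table(col)
    if (length(tab) >= 2L) {
      variable <- variable + 1L
      if (sum(tab >= 2L) >= 2L) parsimony <- parsimony + 1L
    }
  }
  c(variable = variable, parsimony = parsimony)
}

#' Stage survival table
#'
#' Per genus: the largest-cluster share (largest cluster over the count at
#' initial clustering, as a percent) and processing survival (final count over
#' the count at initial clustering, as a percent), plus a totals row. Both
#' percentages are reported to one decimal, the precision used in community
#' summaries.
#'
#' @param counts data.frame with columns `genus`, `initial` (sequences at
#'   initial clustering), `largest` (largest cluster size), `final` (sequences
#'   after full analysis); further count columns are carried through.
#' @return the table with `largest_cluster_pct` and `survival_pct` columns and
#'   a `Total` row.
#' @export
survivalTable <- function(counts) {
  req <- c("genus", "initial", "largest", "final")
  if (!all(req %in% names(counts))) stop("missing columns: ",
                                         paste(setdiff(req, names(counts)),
                                               collapse = ", "))
  if (any(counts$largest > counts$initial) || any(counts$final < 0))
    stop("largest cluster cannot exceed the initial count")
  out <- counts
  out$largest_cluster_pct <- round(100 * out$largest / out$initial, 1)
  out$survival_pct <- round(100 * out$final / out$initial, 1)
  total <- out[1L, , drop = FALSE]
  total$genus <- "Total"
  for (cn in setdiff(names(out), "genus")) {
    total[[cn]] <- if (cn %in% c("largest_cluster_pct", "survival_pct"))
      NA_real_ else sum(out[[cn]])
  }
  rbind(out, total)
}
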