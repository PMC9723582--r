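# Synthetic community and rolling-circle read simulator. The generator's
# defaults are the study conditions: ~2% indel-rich per-base error on
# sub-reads (98% +/- 1% identity), taxon abundances spread over orders of
# magnitude, a shifted-geometric repeat count so most reads fail the
# >= 5 sub-read filter, and single-breakpoint template-swap chimeras.

# Published universal primer motifs (IUPAC) used by the construct and by 16S/V4
# extraction downstream.
.PRIMER_27F   <- "AGAGTTTGATCMTGGCTCAG"
.PRIMER_1492R <- "TACGGYTACCTTGTTACGACTT"
.PRIMER_515F  <- "GTGYCAGCMGCCGCGGTAA"
.PRIMER_806R  <- "GGACTACNVGGGTWTCTAAT"
# Unique 5' tails of the two construct primers and the 23S-side annealing
# portion (the 16S-side annealing portion is the 27F motif above).
.FWD_UNIQUE <- "AATGATACGGCGACCACCGAGAT"
.REV_UNIQUE <- "ATGGAAGACGCCAAAAACATAAAGGCTGC"
.REV_ANNEAL <- "TACTDAGATGTTTCASTTC"

#' Default construct model
#'
#' The standard construct primer layout with a fixed 386-bp synthetic splint shipped as
#' a plain-text fixture (`extdata/splint_synthetic.fa`); the true splint is a
#' lambda-phage subsequence that is not public in full, and segmentation takes
#' the splint as an input either way.
#'
#' @return a [ConstructModel-class].
#' @export
defaultConstruct <- function() {
  splintFa <- system.file("extdata", "splint_synthetic.fa", package = "rcaits")
  ConstructModel(splint = unname(readFasta(splintFa)[1L]),
                 fwdUnique = .FWD_UNIQUE, revUnique = .REV_UNIQUE,
                 fwdAnneal = .PRIMER_27F, revAnneal = .REV_ANNEAL,
                 barcodeLen = 5L)
}

.defaultConstructRaw <- function() defaultConstruct()

#' Nanopore-like error model
#'
#' @slot mismatch,ins,del per-base rates; defaults total 0.02 so sub-read
#'   identity is ~98%.
#' @slot hpMult multiplier applied to indel rates inside homopolymer runs.
#' @slot jitter relative sd of the per-read rate multiplier (gives the ~1% sd
#'   of sub-read identity between reads).
#' @export
setClass("ErrorModel",
  representation(mismatch = "numeric", ins = "numeric", del = "numeric",
                 hpMult = "numeric", jitter = "numeric"),
  prototype(mismatch = 0.008, ins = 0.006, del = 0.006, hpMult = 2,
            jitter = 0.4))

setValidity("ErrorModel", function(object) {
  if (any(c(object@mismatch, object@ins, object@del) < 0) ||
      any(c(object@mismatch, object@ins, object@del) > 1))
    return("rates must be fractions in [0, 1]")
  if (object@hpMult < 1) return("hpMult must be >= 1")
  TRUE
})

#' @rdname ErrorModel-class
#' @param ... named slot overrides (`mismatch`, `ins`, `del`, `hpMult`,
#'   `jitter`).
#' @export
errorModel <- function(...) .newParam("ErrorModel", ...)

#' A zero-error model (for exact round-trip fixtures)
#' @export
noError <- function() errorModel(mismatch = 0, ins = 0, del = 0, jitter = 0)

# Apply the error process to one sequence. Uses the session RNG.
.mutateSeq <- function(seq, em, rateFactor = 1) {
  if (em@mismatch + em@ins + em@del == 0 || rateFactor == 0) return(seq)
  cc <- .chars(seq)
  n <- length(cc)
  hp <- c(FALSE, cc[-1L] == cc[-n])              # inside a homopolymer run
  indelMult <- ifelse(hp, em@hpMult, 1) * rateFactor
  delP <- pmin(1, em@del * indelMult)
  insP <- pmin(1, em@ins * indelMult)
  misP <- min(1, em@mismatch * rateFactor)
  keep <- stats::runif(n) >= delP
  out <- cc[keep]
  m <- length(out)
  if (m == 0L) return("")
  sub <- stats::runif(m) < misP
  if (any(sub)) {
    out[sub] <- vapply(out[sub],
                       function(b) sample(setdiff(.BASES, b), 1L), "")
  }
  insAt <- which(stats::runif(m) < insP[keep])
  if (length(insAt)) {
    pieces <- character(m)
    pieces[insAt] <- sample(.BASES, length(insAt), replace = TRUE)
    out <- paste0(out, pieces)
  }
  .collapse(out)
}

#' Generate one synthetic 16S-ITS template
#'
#' Layout (5' to 3', sense strand): 27F annealing site, conserved 16S stretch,
#' V4 region flanked by the 515F/806R sites, conserved 16S stretch, 1492R site
#' (16S end), ITS of the requested length, and the reverse-complemented
#' 23S-side annealing site. The ITS start is recorded in attribute
#' `itsStart` (0-based) so rrn edits can be targeted to the ITS.
#'
#' @param coreLen total 16S length between the 27F and 1492R sites (bp).
#' @param itsLen ITS length (bp).
#' @param v4Len length of the variable V4 stretch inside the core.
#' @param seed optional seed (otherwise the session RNG is used).
#' @return template string with attribute `itsStart`.
#' @export
makeTaxonTemplate <- function(coreLen = 1250L, itsLen = 450L, v4Len = 250L,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p27 <- .resolveIupac(.PRIMER_27F)
  p1492 <- .revcomp(.resolveIupac(.PRIMER_1492R))
  v4f <- .resolveIupac(.PRIMER_515F)
  v4r <- .revcomp(.resolveIupac(.PRIMER_806R))
  endSite <- .revcomp(.resolveIupac(.REV_ANNEAL))
  fixed <- nchar(p27) + nchar(v4f) + nchar(v4r) + nchar(p1492) + v4Len
  inner <- coreLen - fixed
  if (inner < 100L) stop("coreLen too short for the primer layout")
  cons1 <- .randDna(round(inner * 0.25))
  cons2 <- .randDna(inner - nchar(cons1))
  seq <- paste0(p27, cons1, v4f, .randDna(v4Len), v4r, cons2, p1492,
                .randDna(itsLen), endSite)
  attr(seq, "itsStart") <- nchar(seq) - itsLen - nchar(endSite)
  seq
}

# one edit specification applied to a template
.applyEdits <- function(base, spec, itsStart) {
  seq <- base
  n0 <- nchar(seq)
  lo <- 30L                       # keep primer sites intact
  hi <- n0 - 30L
  if (hi <= lo) stop("template too short to edit")
  if (!is.null(spec$del) && spec$del > 0L) {
    if (spec$del >= hi - lo) stop("edit spec exceeds sequence length")
    at <- sample(seq.int(lo, hi - spec$del), 1L)
    seq <- paste0(substr(seq, 1L, at - 1L), substr(seq, at + spec$del, n0))
  }
  if (!is.null(spec$ins) && spec$ins > 0L) {
    at <- sample(seq.int(lo, nchar(seq) - 30L), 1L)
    seq <- paste0(substr(seq, 1L, at), .randDna(spec$ins),
                  substr(seq, at + 1L, nchar(seq)))
  }
  if (isTRUE(spec$trna)) {
    # tRNA-sized insertion into the ITS portion
    len <- sample(80:100, 1L)
    at <- sample(seq.int(itsStart + 5L, nchar(seq) - 25L), 1L)
    seq <- paste0(substr(seq, 1L, at), .randDna(len),
                  substr(seq, at + 1L, nchar(seq)))
  }
  nsnp <- if (is.null(spec$snps)) 0L else spec$snps
  if (nsnp > 0L) {
    if (nsnp >= nchar(seq)) stop("edit spec exceeds sequence length")
    cc <- .chars(seq)
    at <- sample(seq.int(lo, nchar(seq) - 30L), nsnp)
    cc[at] <- vapply(cc[at], function(b) sample(setdiff(.BASES, b), 1L), "")
    seq <- .collapse(cc)
  }
  seq
}

#' Derive a multi-copy rrn set from one base template
#'
#' Copy 1 is the base template; each further copy carries its requested edits
#' (SNPs, small indels, an optional tRNA-sized 80-100 bp ITS insertion) or is
#' an exact duplicate of an earlier copy (`copyOf`), emulating intragenomic
#' rrn heterogeneity such as near-identical operons that differ by one or two
#' bases, or by the presence of a tRNA in the ITS.
#'
#' @param base template string (attribute `itsStart` honored if present).
#' @param nCopies number of rrn copies (>= 1).
#' @param edits optional list of length `nCopies`; element `i` is a list with
#'   any of `snps` (count), `del`/`ins` (lengths), `trna` (logical),
#'   `copyOf` (earlier copy index). Element 1 is ignored. Default: 1-2 SNPs
#'   per copy.
#' @param seed optional seed.
#' @return character vector of `nCopies` templates.
#' @export
makeRrnSet <- function(base, nCopies, edits = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nCopies < 1L) stop("nCopies must be >= 1")
  itsStart <- attr(base, "itsStart")
  if (is.null(itsStart)) itsStart <- as.integer(nchar(base) * 0.75)
  out <- character(nCopies)
  out[1L] <- as.character(base)
  if (nCopies == 1L) return(out)
  if (is.null(edits)) {
    edits <- c(list(NULL),
               lapply(seq_len(nCopies - 1L),
                      function(i) list(snps = sample(1:2, 1L))))
  }
  if (length(edits) != nCopies) stop("edits must have one element per copy")
  for (i in 2:nCopies) {
    sp <- edits[[i]]
    out[i] <- if (!is.null(sp$copyOf)) {
      if (sp$copyOf >= i) stop("copyOf must point at an earlier copy")
      out[sp$copyOf]
    } else {
      .applyEdits(out[1L], sp, itsStart)
    }
  }
  out
}

#' Simulate one rolling-circle concatemer read
#'
#' The clean read is `kRepeats` insert copies delimited by `kRepeats + 1`
#' splint copies (the linear product begins at the priming site adjacent to
#' the splint): `splint [fwdUnique bc5 template bc3 revUniqueRc] splint ...`,
#' with the same barcodes in every repeat. The read is then corrupted by the
#' error model and reverse-complemented with probability 1/2.
#'
#' @param template insert template (16S-ITS with primer-site ends).
#' @param construct a [ConstructModel-class].
#' @param kRepeats number of insert copies (`k = 0` gives a splint-only read).
#' @param barcodes optional `c(bc5, bc3)`; random barcodes by default.
#' @param error an [ErrorModel-class].
#' @param readId read identifier.
#' @param seed optional seed.
#' @return `list(seq = <named read string>, truth = <one-row data.frame>)`.
#' @export
simulateConcatemerRead <- function(template, construct = defaultConstruct(),
                                   kRepeats = 5L, barcodes = NULL,
                                   error = errorModel(), readId = "read1",
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (kRepeats < 0L) stop("kRepeats must be >= 0")
  bl <- construct@barcodeLen
  if (is.null(barcodes)) barcodes <- c(.randDna(bl), .randDna(bl))
  unit <- paste0(construct@fwdUnique, barcodes[1L], as.character(template),
                 barcodes[2L], .revcomp(construct@revUnique))
  clean <- paste0(construct@splint,
                  strrep(paste0(unit, construct@splint), kRepeats))
  rateFactor <- if (error@jitter > 0) max(0.05, stats::rnorm(1L, 1, error@jitter))
                else 1
  seq <- .mutateSeq(clean, error, rateFactor)
  flipped <- stats::runif(1L) < 0.5
  if (flipped) seq <- .revcomp(seq)
  truth <- data.frame(read_id = readId, k = kRepeats,
                      bc5 = barcodes[1L], bc3 = barcodes[2L],
                      flipped = flipped, chimera = FALSE,
                      breakpoint = NA_real_, stringsAsFactors = FALSE)
  list(seq = stats::setNames(seq, readId), truth = truth)
}

#' Assemble a community specification
#'
#' @param taxonIds taxon labels.
#' @param weights positive abundance weights (one per taxon).
#' @param templates list of character vectors: the rrn templates of each taxon.
#' @return a `list` of per-taxon entries (`taxonId`, `weight`, `templates`).
#' @export
communitySpec <- function(taxonIds, weights, templates) {
  if (length(taxonIds) != length(weights) ||
      length(taxonIds) != length(templates))
    stop("taxonIds, weights and templates must align")
  if (any(weights <= 0)) stop("abundance weights must be > 0")
  if (any(lengths(templates) < 1L)) stop("every taxon needs >= 1 rrn template")
  mapply(function(id, w, tt) list(taxonId = id, weight = w,
                                  templates = as.character(tt)),
         taxonIds, weights, templates, SIMPLIFY = FALSE)
}

#' Generate a random stratified community
#'
#' Taxa diverge from a shared ancestral 16S-ITS by `taxonDivergence`
#' substitutions per base plus a taxon-specific V4 stretch; each taxon carries
#' an rrn set with 1-3 SNPs per copy. Default weights span three orders of
#' magnitude, matching a deliberately stratified mock community.
#'
#' @param nTaxa number of taxa.
#' @param rrnCounts rrn copies per taxon (recycled).
#' @param weights abundance weights; default `10^seq(3, 0, length.out = nTaxa)`.
#' @param coreLen,itsLen template geometry (see [makeTaxonTemplate()]).
#' @param taxonDivergence per-base substitution divergence between taxa.
#' @param seed seed.
#' @return a community spec as from [communitySpec()].
#' @export
randomCommunity <- function(nTaxa = 8L, rrnCounts = 3L, weights = NULL,
                            coreLen = 1250L, itsLen = 450L,
                            taxonDivergence = 0.08, seed = 1L) {
  set.seed(seed)
  if (is.null(weights)) weights <- 10^seq(3, 0, length.out = nTaxa)
  rrnCounts <- rep_len(as.integer(rrnCounts), nTaxa)
  ancestor <- makeTaxonTemplate(coreLen, itsLen)
  itsStart <- attr(ancestor, "itsStart")
  v4f <- .resolveIupac(.PRIMER_515F)
  v4r <- .revcomp(.resolveIupac(.PRIMER_806R))
  p1492 <- .revcomp(.resolveIupac(.PRIMER_1492R))
  templates <- lapply(seq_len(nTaxa), function(i) {
    cc <- .chars(ancestor)
    n <- length(cc)
    # substitutions outside the universal primer motifs
    protected <- c(seq_len(30L), seq.int(n - 30L, n))
    r1492 <- regexpr(p1492, ancestor, fixed = TRUE)
    protected <- union(protected, seq.int(r1492, r1492 + nchar(p1492) - 1L))
    v4span <- (regexpr(v4f, ancestor, fixed = TRUE) + nchar(v4f)):
      (regexpr(v4r, ancestor, fixed = TRUE) - 1L)
    protected <- union(protected,
                       c(seq.int(v4span[1L] - nchar(v4f), v4span[1L] - 1L),
                         max(v4span) + seq_len(nchar(v4r))))
    at <- sample(setdiff(seq_len(n), protected),
                 round(n * taxonDivergence))
    cc[at] <- vapply(cc[at], function(b) sample(setdiff(.BASES, b), 1L), "")
    # taxon-specific V4 stretch
    cc[v4span] <- .chars(.randDna(length(v4span)))
    tpl <- .collapse(cc)
    attr(tpl, "itsStart") <- itsStart
    makeRrnSet(tpl, rrnCounts[i],
               edits = c(list(NULL),
                         lapply(seq_len(rrnCounts[i] - 1L),
                                function(j) list(snps = sample(1:3, 1L)))))
  })
  communitySpec(sprintf("taxon%02d", seq_len(nTaxa)), weights, templates)
}

#' Simulate a community sequencing run
#'
#' Molecules are sampled proportional to taxon weight times rrn copy number
#' (rrns uniform within a taxon). Repeat counts follow a shifted geometric,
#' `k = kMin + Geom(kGeomP)`, so short reads dominate and most reads fail the
#' downstream >= 5 sub-read filter. Chimeric inserts are single-breakpoint
#' crossovers between the sampled template and a second template drawn from
#' the whole pool, at `chimeraRate`. Deterministic for a fixed seed.
#'
#' @param spec community spec from [communitySpec()] / [randomCommunity()].
#' @param nReads number of reads (>= 1).
#' @param construct a [ConstructModel-class].
#' @param kGeomP,kMin repeat-count distribution parameters.
#' @param chimeraRate fraction of molecules that are chimeric.
#' @param error an [ErrorModel-class].
#' @param seed seed.
#' @return `list(reads = <named character>, truth = <data.frame>,
#'   templates = <named character>)`; truth has one row per read with source
#'   taxon/rrn, repeat count, barcodes, and chimera flag/breakpoint.
#' @export
simulateCommunity <- function(spec, nReads, construct = defaultConstruct(),
                              kGeomP = 0.25, kMin = 1L, chimeraRate = 0,
                              error = errorModel(), seed = 1L) {
  if (!length(spec)) stop("community spec is empty")
  if (nReads < 1L) stop("nReads must be >= 1")
  set.seed(seed)
  taxW <- vapply(spec, function(t) t$weight * length(t$templates), 0)
  tmplNames <- unlist(lapply(spec, function(t)
    sprintf("%s_rrn%d", t$taxonId, seq_along(t$templates))))
  tmplPool <- stats::setNames(
    unlist(lapply(spec, function(t) as.character(t$templates))), tmplNames)
  reads <- character(nReads)
  ids <- sprintf("read%05d", seq_len(nReads))
  rows <- vector("list", nReads)
  for (i in seq_len(nReads)) {
    ti <- sample.int(length(spec), 1L, prob = taxW)
    ri <- sample.int(length(spec[[ti]]$templates), 1L)
    tpl <- spec[[ti]]$templates[[ri]]
    isChim <- stats::runif(1L) < chimeraRate
    partner <- NA_character_
    bp <- NA_real_
    if (isChim) {
      own <- sprintf("%s_rrn%d", spec[[ti]]$taxonId, ri)
      others <- setdiff(tmplNames, own)
      partner <- sample(others, 1L)
      bp <- stats::runif(1L)
      n1 <- nchar(tpl); n2 <- nchar(tmplPool[[partner]])
      tpl <- paste0(substr(tpl, 1L, round(bp * n1)),
                    substr(tmplPool[[partner]], round(bp * n2) + 1L, n2))
    }
    k <- kMin + stats::rgeom(1L, kGeomP)
    r <- simulateConcatemerRead(tpl, construct, k, barcodes = NULL,
                                error = error, readId = ids[i])
    reads[i] <- r$seq
    rows[[i]] <- cbind(r$truth,
                       data.frame(taxon = spec[[ti]]$taxonId, rrn = ri,
                                  chimera_partner = partner,
                                  stringsAsFactors = FALSE))
    rows[[i]]$chimera <- isChim
    rows[[i]]$breakpoint <- bp
  }
  truth <- do.call(rbind, rows)
  list(reads = stats::setNames(reads, ids), truth = truth,
       templates = tmplPool)
}

#' Write a simulated run to disk
#'
#' Emits `reads.fastq` (flat Phred 20), `templates.fa`, and `truth.tsv`.
#'
#' @param run result of [simulateCommunity()].
#' @param dir output directory (created if needed).
#' @export
writeCommunityRun <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeFastq(run$reads, file.path(dir, "reads.fastq"))
  writeFasta(run$templates, file.path(dir, "templates.fa"))
  utils::write.table(run$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
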