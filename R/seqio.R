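# Sequence I/O. Heavy lifting (containers, FASTA serialization) is done by
# Biostrings; FASTQ records pass through a light structural validation first so
# malformed files fail with the offending line number.

#' Read a FASTQ file
#'
#' Reads 4-line FASTQ records (Phred+33 qualities) into a
#' [Biostrings::QualityScaledDNAStringSet]. Sequences are uppercase-folded;
#' characters outside `{A,C,G,T,N}` (including `U`) are rejected. Gzipped
#' input is handled transparently.
#'
#' @param path path to a FASTQ (or FASTQ.gz) file.
#' @return a `QualityScaledDNAStringSet`; empty file gives an empty set.
#' @export
#' @importFrom Biostrings DNAStringSet QualityScaledDNAStringSet PhredQuality
readFastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (!length(lines)) {
    return(QualityScaledDNAStringSet(DNAStringSet(), PhredQuality(character(0))))
  }
  if (length(lines) %% 4L != 0L)
    stop(sprintf("truncated FASTQ record near line %d", length(lines)))
  idx <- seq(1L, length(lines), by = 4L)
  for (i in idx) {
    if (!startsWith(lines[i], "@"))
      stop(sprintf("malformed FASTQ: line %d must start with '@'", i))
    if (!startsWith(lines[i + 2L], "+"))
      stop(sprintf("malformed FASTQ: line %d must start with '+'", i + 2L))
    if (nchar(lines[i + 1L]) != nchar(lines[i + 3L]))
      stop(sprintf(
        "malformed FASTQ: quality length differs from sequence length at line %d",
        i + 3L))
  }
  ids <- sub("^@", "", sub("\\s.*$", "", lines[idx]))
  if (anyDuplicated(ids)) stop("duplicate read ids in FASTQ")
  seqs <- vapply(lines[idx + 1L], .normalizeDna, "", what = "FASTQ sequence",
                 USE.NAMES = FALSE)
  QualityScaledDNAStringSet(
    DNAStringSet(stats::setNames(seqs, ids)),
    PhredQuality(lines[idx + 3L]))
}

#' Write FASTQ
#'
#' Records are written directly (4 lines per record): concatemer reads run to
#' tens of kilobases, beyond the line-buffer limit of the usual XStringSet
#' FASTQ writer.
#'
#' @param seqs a `QualityScaledDNAStringSet`, or a named character vector (a
#'   flat quality of Phred 20 is written in that case).
#' @param path output path.
#' @export
#' @importFrom Biostrings quality
writeFastq <- function(seqs, path) {
  if (is.character(seqs)) {
    ids <- names(seqs)
    quals <- vapply(nchar(seqs), function(n) strrep("5", n), "",
                    USE.NAMES = FALSE)
    seqs <- unname(seqs)
  } else {
    ids <- names(seqs)
    quals <- as.character(quality(seqs))
    seqs <- as.character(seqs)
  }
  if (is.null(ids) || any(!nzchar(ids))) stop("all records need ids")
  if (anyDuplicated(ids)) stop("duplicate record ids")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), con)
  invisible(path)
}

#' Write FASTA
#'
#' Deterministic byte output for fixed input. Gapped strings are allowed, so
#' alignments can be exported as gapped FASTA.
#'
#' @param seqs named character vector (or `DNAStringSet`); ids must be unique
#'   and non-empty.
#' @param path output path.
#' @param wrap sequence line width (default 60).
#' @export
#' @importFrom Biostrings writeXStringSet
writeFasta <- function(seqs, path, wrap = 60L) {
  if (is.character(seqs)) {
    if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
      stop("all records need non-empty ids")
    if (anyDuplicated(names(seqs))) stop("duplicate record ids")
    seqs <- vapply(seqs, function(s) {
      s <- toupper(s)
      if (grepl("[^ACGTN-]", s))
        stop("sequence contains characters outside {A,C,G,T,N,-}")
      s
    }, "")
    seqs <- DNAStringSet(seqs)
  }
  if (anyDuplicated(names(seqs))) stop("duplicate record ids")
  writeXStringSet(seqs, path, width = as.integer(wrap))
  invisible(path)
}

#' Read FASTA
#'
#' @param path FASTA path.
#' @return named character vector of uppercase sequences (gaps preserved).
#' @export
#' @importFrom Biostrings readBStringSet
readFasta <- function(path) {
  x <- readBStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Export an alignment as gapped FASTA
#' @param msa a [DnaMsa-class].
#' @param path output path.
#' @export
writeMsaFasta <- function(msa, path) {
  writeFasta(stats::setNames(msa@rows, msa@ids), path)
}

#' Read a gapped FASTA into an alignment
#' @param path gapped FASTA path.
#' @return a [DnaMsa-class].
#' @export
readMsaFasta <- function(path) {
  x <- readFasta(path)
  DnaMsa(names(x), unname(x))
}
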