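# Internal helpers shared across modules. Internal coordinates are 0-based
# half-open; anything user-facing is converted to 1-based inclusive at the edge.

.ALPHABET <- c("A", "C", "G", "T", "N", "-")
.BASES <- c("A", "C", "G", "T")
.IUPAC <- c("A","C","G","T","N","M","R","W","S","Y","K","V","H","D","B","U")

.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

.collapse <- function(v) paste(v, collapse = "")

#' @importFrom Biostrings DNAString reverseComplement
.revcomp <- function(x) {
  as.character(reverseComplement(DNAString(x)))
}

# Uppercase-fold and validate a DNA string over {A,C,G,T,N}. 'U' is rejected:
# this is a DNA-only pipeline.
.normalizeDna <- function(x, what = "sequence") {
  x <- toupper(x)
  bad <- gsub("[ACGTN]", "", x)
  if (nzchar(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T,N}: '%s'",
                 what, substr(bad, 1, 10)), call. = FALSE)
  }
  x
}

# Degenerate primers keep their IUPAC codes.
.normalizeIupac <- function(x, what = "primer") {
  x <- toupper(x)
  cc <- .chars(x)
  if (!all(cc %in% setdiff(.IUPAC, "U"))) {
    stop(sprintf("%s contains non-IUPAC characters", what), call. = FALSE)
  }
  x
}

# Encode to the integer alphabet used by the C++ core (0..5; see src/align.cpp).
.encodeSeq <- function(x) {
  v <- match(.chars(x), .ALPHABET) - 1L
  if (anyNA(v)) stop("sequence contains characters outside {A,C,G,T,N,-}",
                     call. = FALSE)
  v
}

# Resolve IUPAC degeneracies to a concrete base (first listed option), used when
# a degenerate primer becomes part of a simulated molecule.
.IUPAC_FIRST <- c(A="A", C="C", G="G", T="T", N="A", M="A", R="A", W="A",
                  S="C", Y="C", K="G", V="A", H="A", D="A", B="C")
.resolveIupac <- function(x) {
  .collapse(unname(.IUPAC_FIRST[.chars(toupper(x))]))
}

.randDna <- function(n) .collapse(sample(.BASES, n, replace = TRUE))

# Character ranking used by every plurality tie-break: bases before N before gap,
# bases alphabetical. Fixed so all consensus operations are deterministic.
.CHAR_RANK <- stats::setNames(seq_along(.ALPHABET), .ALPHABET)

# Plurality character of a character vector under the shared tie-break.
.plurality <- function(v) {
  tab <- table(factor(v, levels = .ALPHABET))
  score <- as.numeric(tab) - .CHAR_RANK[.ALPHABET] * 1e-3
  .ALPHABET[which.max(score)]
}

# k-mer set of a sequence (unique k-mers), for the clustering prefilter.
.kmerSet <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, seq_len(n - k + 1), k:n))
}
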