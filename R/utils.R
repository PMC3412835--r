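# Internal helpers shared across modules.

.BASES <- c("A", "C", "G", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# split a string into a character vector of single bases (upper case)
.chars <- function(x) strsplit(toupper(x), "", fixed = TRUE)[[1L]]

.collapse <- function(v) paste(v, collapse = "")

#' Reverse complement of a nucleotide string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] that accepts and
#' returns plain character strings over A/C/G/T/N.
#'
#' @param x Single nucleotide string.
#' @return The reverse complement as a character string.
#' @export
#' @examples
#' reverseComplementSeq("ATGC")
reverseComplementSeq <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) == 0L) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# fast reverse complement on a character vector of bases
.revcompChars <- function(v) unname(rev(.COMP[v]))

# round half away from zero (printed-value convention)
.roundHalfAway <- function(x, digits = 3L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# 1-based inclusive positions covered by a (possibly wrapping) circular feature
.featurePositions <- function(start, end, genomeLength) {
  if (end <= genomeLength && end >= start) return(start:end)
  c(start:genomeLength, 1:(end %% genomeLength))
}

# check a seed-bearing integer argument
.checkSeed <- function(seed) {
  if (is.null(seed) || length(seed) != 1L || is.na(seed)) {
    stop("a single integer 'seed' is required", call. = FALSE)
  }
  as.integer(seed)
}

# normalise unicode dash dialects and thousands separators in a numeric field
.normNum <- function(x) gsub(",", "", gsub("[–—−]", "-", x))

.isBlank <- function(x) {
  is.na(x) | trimws(x) %in% c("", "-", "–", "—")
}
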