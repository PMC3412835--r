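# Nucleotide composition, codon-position composition, AT/GC skew statistics
# and sign-based skew classification.

#' Nucleotide composition of a sequence
#'
#' Exact A/C/G/T counts (case-insensitive).  The ambiguity code N is accepted
#' but excluded from all counts and fractions; any other character is an
#' error naming its position.
#'
#' @param x Nucleotide string, or a character vector of single bases.
#' @return A list of class `CompositionProfile`: `counts` (named integer),
#'   `fractions` (named numeric, sums to 1 when any base counted),
#'   `at_content` ((A+T)/(A+C+G+T); `NA` when no base counted) and `n`
#'   (number of counted bases).
#' @export
#' @examples
#' baseComposition("AATT")$at_content   # 1
baseComposition <- function(x) {
  v <- if (length(x) > 1L) toupper(x) else .chars(x)
  bad <- which(!(v %in% c(.BASES, "N")))
  if (length(bad)) {
    stop(sprintf("non-IUPAC character '%s' at position %d", v[bad[1L]], bad[1L]),
         call. = FALSE)
  }
  counts <- stats::setNames(tabulate(match(v, .BASES), nbins = 4L), .BASES)
  n <- sum(counts)
  fractions <- if (n > 0L) counts / n else stats::setNames(rep(NA_real_, 4L), .BASES)
  structure(list(counts = counts, fractions = fractions,
                 at_content = if (n > 0L) (counts[["A"]] + counts[["T"]]) / n else NA_real_,
                 n = n),
            class = "CompositionProfile")
}

#' @export
print.CompositionProfile <- function(x, ...) {
  cat(sprintf("CompositionProfile: %d bases; A %d, C %d, G %d, T %d; A+T %.1f%%\n",
              x$n, x$counts[["A"]], x$counts[["C"]], x$counts[["G"]], x$counts[["T"]],
              100 * x$at_content))
  invisible(x)
}

#' AT and GC strand skew
#'
#' AT-skew = (A - T)/(A + T) and GC-skew = (G - C)/(G + C), the standard
#' descriptive statistics of strand nucleotide asymmetry.  A component is
#' `NA` ("undefined") exactly when its denominator is zero; no NaN ever
#' propagates.
#'
#' @param x A nucleotide string or a `CompositionProfile`.
#' @return A list of class `SkewPair` with `at_skew` and `gc_skew`.
#' @export
#' @examples
#' atGcSkew("AAGGGTC")   # at = 1/3, gc = 1/2
atGcSkew <- function(x) {
  p <- if (inherits(x, "CompositionProfile")) x else baseComposition(x)
  cA <- p$counts[["A"]]; cT <- p$counts[["T"]]
  cG <- p$counts[["G"]]; cC <- p$counts[["C"]]
  at <- if (cA + cT > 0L) (cA - cT) / (cA + cT) else NA_real_
  gc <- if (cG + cC > 0L) (cG - cC) / (cG + cC) else NA_real_
  structure(list(at_skew = at, gc_skew = gc), class = "SkewPair")
}

#' @export
print.SkewPair <- function(x, ...) {
  cat(sprintf("SkewPair: AT-skew = %s, GC-skew = %s (%s)\n",
              format(x$at_skew, digits = 4), format(x$gc_skew, digits = 4),
              classifySkew(x)))
  invisible(x)
}

#' Skew class from the signs of the two skews
#'
#' Maps a skew pair to the categories used in strand-asymmetry surveys:
#' positive AT-skew reads "A", negative "T"; positive GC-skew reads "G",
#' negative "C"; a zero or undefined GC-skew yields the `*_only_gc_zero`
#' categories; zero or undefined AT-skew is flagged `undefined`.
#'
#' @param x A `SkewPair` (or anything [atGcSkew()] accepts).
#' @param gc_skew Optional; give `x` and `gc_skew` as two numbers instead.
#' @return One of `"A_and_C"`, `"A_and_G"`, `"T_and_C"`, `"T_and_G"`,
#'   `"A_only_gc_zero"`, `"T_only_gc_zero"`, `"undefined"`.
#' @export
#' @examples
#' classifySkew(-0.327, 0.383)   # "T_and_G"
classifySkew <- function(x, gc_skew = NULL) {
  if (is.numeric(x) && !is.null(gc_skew)) {
    at <- x; gc <- gc_skew
  } else {
    p <- if (inherits(x, "SkewPair")) x else atGcSkew(x)
    at <- p$at_skew; gc <- p$gc_skew
  }
  if (is.na(at) || at == 0) return("undefined")
  a <- if (at > 0) "A" else "T"
  if (is.na(gc) || gc == 0) return(paste0(a, "_only_gc_zero"))
  paste0(a, "_and_", if (gc > 0) "G" else "C")
}

#' Nucleotide composition at each codon position of the protein genes
#'
#' Concatenates the coding-strand sequences of all protein-coding features,
#' reads them as codons anchored at the annotated start, drops any trailing
#' incomplete codon (1-2 nt, as left by incomplete stop codons) and tallies
#' the composition at codon positions 1, 2 and 3.
#'
#' @param g An [AnnotatedGenome-class] carrying a sequence.
#' @return A list of class `CodonPositionComposition`: `position1`,
#'   `position2`, `position3` (each a `CompositionProfile`) and `at_content`
#'   (numeric length 3).
#' @export
codonPositionComposition <- function(g) {
  ft <- featureTable(g)
  pcg <- ft$name[ft$klass == "PCG"]
  if (!length(pcg)) stop("no protein-coding features", call. = FALSE)
  pos <- list(character(0), character(0), character(0))
  for (nm in pcg) {
    v <- .chars(extractFeatureSequence(g, nm))
    if (!length(v)) stop(sprintf("zero-length protein gene %s", nm), call. = FALSE)
    nFull <- (length(v) %/% 3L) * 3L
    v <- v[seq_len(nFull)]
    idx <- rep_len(1:3, nFull)
    for (k in 1:3) pos[[k]] <- c(pos[[k]], v[idx == k])
  }
  prof <- lapply(pos, baseComposition)
  structure(list(position1 = prof[[1L]], position2 = prof[[2L]], position3 = prof[[3L]],
                 at_content = vapply(prof, `[[`, numeric(1), "at_content")),
            class = "CodonPositionComposition")
}

#' Strand-partitioned skew report
#'
#' Computes skew pairs and classes for: the whole genome (entire major
#' strand, non-coding regions included), all protein-coding genes
#' concatenated, and the major-strand and minor-strand protein-coding genes
#' separately.  Each protein-gene partition is computed on the concatenation
#' of coding-strand (sense) sequences of its members, so a minor-strand gene
#' contributes its own sense composition rather than a re-read of the major
#' strand.  An empty partition is returned as `defined = FALSE`.
#'
#' @param g An [AnnotatedGenome-class] carrying a sequence.
#' @return A list of class `StrandSkewReport` with entries `whole_genome`,
#'   `all_PCGs`, `major_strand_PCGs`, `minor_strand_PCGs`; each entry holds
#'   `defined`, `genes`, `composition`, `skew` and `class`.
#' @export
strandPartitionSkew <- function(g) {
  if (is.null(genomeSequence(g))) stop("sequence-free genome", call. = FALSE)
  ft <- featureTable(g)
  pcg <- ft[ft$klass == "PCG", , drop = FALSE]
  entry <- function(genes, seqs) {
    if (!length(genes)) {
      return(list(defined = FALSE, genes = character(0)))
    }
    p <- baseComposition(paste(seqs, collapse = ""))
    s <- atGcSkew(p)
    list(defined = TRUE, genes = genes, composition = p, skew = s,
         class = classifySkew(s))
  }
  senseSeqs <- vapply(pcg$name, function(nm) extractFeatureSequence(g, nm), character(1))
  structure(list(
    whole_genome = entry("(whole major strand)", genomeSequence(g)),
    all_PCGs = entry(pcg$name, senseSeqs),
    major_strand_PCGs = entry(pcg$name[pcg$strand == "+"], senseSeqs[pcg$strand == "+"]),
    minor_strand_PCGs = entry(pcg$name[pcg$strand == "-"], senseSeqs[pcg$strand == "-"])
  ), class = "StrandSkewReport")
}

#' @export
print.StrandSkewReport <- function(x, ...) {
  cat("Strand-partitioned skew:\n")
  for (nm in names(x)) {
    e <- x[[nm]]
    if (!isTRUE(e$defined)) {
      cat(sprintf("  %-18s undefined (no genes)\n", nm))
    } else {
      cat(sprintf("  %-18s AT %6.3f  GC %6.3f  %s\n", nm,
                  .roundHalfAway(e$skew$at_skew), .roundHalfAway(e$skew$gc_skew), e$class))
    }
  }
  invisible(x)
}
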