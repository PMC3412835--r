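#' @import methods
NULL

.FEATURE_CLASSES <- c("PCG", "tRNA", "rRNA", "control_region", "repeat_region", "other")

.FEATURE_COLUMNS <- c(
  "name", "klass", "strand", "start", "end",
  "anticodon", "anticodon_start", "anticodon_end", "start_codon", "stop_codon"
)

#' AnnotatedGenome: a circular annotated mitochondrial genome
#'
#' Holds the genome length, circularity flag, an optional major-strand
#' nucleotide sequence (5'->3'), and an ordered table of strand-aware gene
#' features using 1-based inclusive coordinates (GenBank convention).  A
#' feature may wrap past the origin of a circular genome by at most one
#' revolution, in which case `end` exceeds the genome length.
#'
#' The feature table has columns `name`, `klass` (one of PCG, tRNA, rRNA,
#' control_region, repeat_region, other), `strand` (`+` major, `-` minor, `NA`
#' for non-genes), `start`, `end`, and optional `anticodon`,
#' `anticodon_start`, `anticodon_end`, `start_codon`, `stop_codon`.
#'
#' @slot genomeLength Integer genome length in bp.
#' @slot circular Logical; is the molecule circular?
#' @slot sequence Character; the major-strand sequence (length-0 when absent).
#' @slot features data.frame of features, sorted by start.
#'
#' @seealso [annotatedGenome()], [parseFeatureTable()], [featureTable()]
#' @export
setClass("AnnotatedGenome",
  representation(
    genomeLength = "integer",
    circular = "logical",
    sequence = "character",
    features = "data.frame"
  )
)

setValidity("AnnotatedGenome", function(object) {
  msg <- character()
  L <- object@genomeLength
  if (length(L) != 1L || is.na(L) || L < 1L) msg <- c(msg, "genomeLength must be a single integer >= 1")
  if (length(object@circular) != 1L) msg <- c(msg, "circular must be a single logical")
  if (length(object@sequence) > 1L) msg <- c(msg, "sequence must be absent or a single string")
  if (length(object@sequence) == 1L && length(L) == 1L && !is.na(L) &&
      nchar(object@sequence) != L) {
    msg <- c(msg, sprintf("sequence length (%d) differs from genomeLength (%d)",
                          nchar(object@sequence), L))
  }
  ft <- object@features
  if (!all(.FEATURE_COLUMNS %in% names(ft))) {
    msg <- c(msg, "feature table is missing required columns")
  } else if (nrow(ft) > 0L) {
    if (anyNA(ft$name) || any(ft$name == "")) msg <- c(msg, "feature names must be non-empty")
    if (!all(ft$klass %in% .FEATURE_CLASSES)) msg <- c(msg, "unknown feature klass")
    if (!all(ft$strand %in% c("+", "-") | is.na(ft$strand))) msg <- c(msg, "strand must be '+', '-' or NA")
    if (any(ft$start < 1L)) msg <- c(msg, "feature start must be >= 1")
    if (length(L) == 1L && !is.na(L) && any(ft$end > 2L * L)) {
      msg <- c(msg, "feature end may wrap a circular genome at most once")
    }
    if (is.unsorted(ft$start)) msg <- c(msg, "features must be sorted by start")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AnnotatedGenome
#'
#' @param features data.frame with at least `name`, `start`, `end` columns;
#'   `klass` is inferred from the gene name when missing and `strand` defaults
#'   to `NA` for non-genes.
#' @param genomeLength Genome length in bp; inferred as the maximum feature
#'   end when `NULL`.
#' @param sequence Optional major-strand nucleotide string (A/C/G/T/N).
#' @param circular Logical, default `TRUE`.
#' @return An [AnnotatedGenome-class] object.
#' @export
#' @examples
#' g <- annotatedGenome(data.frame(name = "trnM", strand = "+", start = 1, end = 68))
#' genomeLength(g)
annotatedGenome <- function(features, genomeLength = NULL, sequence = NULL, circular = TRUE) {
  ft <- as.data.frame(features, stringsAsFactors = FALSE)
  if (is.null(ft$klass)) ft$klass <- vapply(ft$name, .inferKlass, character(1))
  if (is.null(ft$strand)) ft$strand <- NA_character_
  for (col in c("anticodon", "start_codon", "stop_codon")) {
    if (is.null(ft[[col]])) ft[[col]] <- NA_character_
  }
  for (col in c("anticodon_start", "anticodon_end")) {
    if (is.null(ft[[col]])) ft[[col]] <- NA_integer_ else ft[[col]] <- as.integer(ft[[col]])
  }
  ft$start <- as.integer(ft$start)
  ft$end <- as.integer(ft$end)
  ft <- ft[order(ft$start, ft$end), .FEATURE_COLUMNS, drop = FALSE]
  rownames(ft) <- NULL
  if (is.null(genomeLength)) genomeLength <- max(ft$end)
  seq <- if (is.null(sequence)) character(0) else toupper(sequence)
  new("AnnotatedGenome",
      genomeLength = as.integer(genomeLength),
      circular = isTRUE(circular),
      sequence = seq,
      features = ft)
}

#' @describeIn annotatedGenome Genome length accessor.
#' @param x,object An `AnnotatedGenome`.
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))

#' @rdname annotatedGenome
#' @export
setMethod("genomeLength", "AnnotatedGenome", function(x) x@genomeLength)

#' @describeIn annotatedGenome Circularity accessor.
#' @export
setGeneric("isCircular", function(x) standardGeneric("isCircular"))

#' @rdname annotatedGenome
#' @export
setMethod("isCircular", "AnnotatedGenome", function(x) x@circular)

#' @describeIn annotatedGenome Major-strand sequence accessor (`NULL` when absent).
#' @export
setGeneric("genomeSequence", function(x) standardGeneric("genomeSequence"))

#' @rdname annotatedGenome
#' @export
setMethod("genomeSequence", "AnnotatedGenome", function(x) {
  if (length(x@sequence)) x@sequence else NULL
})

#' @describeIn annotatedGenome Feature table accessor.
#' @export
setGeneric("featureTable", function(x) standardGeneric("featureTable"))

#' @rdname annotatedGenome
#' @export
setMethod("featureTable", "AnnotatedGenome", function(x) x@features)

#' @rdname annotatedGenome
#' @export
setMethod("show", "AnnotatedGenome", function(object) {
  ft <- object@features
  cat(sprintf("AnnotatedGenome: %s, %d bp, %s\n",
              if (object@circular) "circular" else "linear",
              object@genomeLength,
              if (length(object@sequence)) "with sequence" else "annotation only"))
  tab <- table(factor(ft$klass, levels = .FEATURE_CLASSES))
  cat(sprintf("  %d features (%s)\n", nrow(ft),
              paste(sprintf("%s: %d", names(tab)[tab > 0], tab[tab > 0]), collapse = ", ")))
  invisible(object)
})

#' GeneOrder: a signed circular gene order
#'
#' A circular, orientation-aware list of unique gene labels (the 37 canonical
#' mitochondrial genes and the control region "CR", or a subset).  Equality is
#' invariant under rotation of the origin.
#'
#' @slot genes Character vector of gene labels, unique.
#' @slot orientation Character vector of "+"/"-" matching `genes`.
#' @seealso [geneOrder()], [ancestralInsectOrder()], [compareOrders()]
#' @export
setClass("GeneOrder",
  representation(genes = "character", orientation = "character")
)

setValidity("GeneOrder", function(object) {
  msg <- character()
  if (length(object@genes) != length(object@orientation)) {
    msg <- c(msg, "genes and orientation must have equal length")
  }
  if (anyDuplicated(object@genes)) msg <- c(msg, "gene labels must be unique")
  if (!all(object@orientation %in% c("+", "-"))) msg <- c(msg, "orientation must be '+' or '-'")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneOrder
#'
#' @param genes Character vector of unique gene labels.
#' @param orientation Character vector of "+"/"-" (coding strand), recycled if
#'   length 1.
#' @return A [GeneOrder-class] object.
#' @export
#' @examples
#' geneOrder(c("trnK", "trnD"), c("+", "+"))
geneOrder <- function(genes, orientation = "+") {
  if (length(orientation) == 1L) orientation <- rep(orientation, length(genes))
  new("GeneOrder", genes = as.character(genes), orientation = as.character(orientation))
}

#' @describeIn geneOrder Gene labels in circular order.
#' @param x,object A `GeneOrder`.
#' @export
setGeneric("orderGenes", function(x) standardGeneric("orderGenes"))

#' @rdname geneOrder
#' @export
setMethod("orderGenes", "GeneOrder", function(x) x@genes)

#' @describeIn geneOrder Orientations ("+"/"-") matching [orderGenes()].
#' @export
setGeneric("orientations", function(x) standardGeneric("orientations"))

#' @rdname geneOrder
#' @export
setMethod("orientations", "GeneOrder", function(x) x@orientation)

#' @rdname geneOrder
#' @export
setMethod("length", "GeneOrder", function(x) length(x@genes))

#' @rdname geneOrder
#' @export
setMethod("show", "GeneOrder", function(object) {
  lab <- ifelse(object@orientation == "-", paste0("-", object@genes), object@genes)
  cat(sprintf("GeneOrder (circular, %d elements):\n  %s\n",
              length(object@genes), paste(lab, collapse = " ")))
  invisible(object)
})

#' Rotation-invariant equality of circular gene orders
#'
#' Two orders are equal when one can be rotated so that gene labels and
#' orientations coincide position by position.
#'
#' @param a,b [GeneOrder-class] objects.
#' @return Logical.
#' @export
#' @examples
#' a <- geneOrder(c("x", "y", "z"))
#' b <- geneOrder(c("z", "x", "y"))
#' sameGeneOrder(a, b)
sameGeneOrder <- function(a, b) {
  ga <- orderGenes(a); gb <- orderGenes(b)
  if (length(ga) != length(gb) || !setequal(ga, gb)) return(FALSE)
  i <- match(ga[1L], gb)
  rot <- c(i:length(gb), if (i > 1L) 1:(i - 1L))
  all(gb[rot] == ga) && all(orientations(b)[rot] == orientations(a))
}
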