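# Circular annotated-genome model: feature-table parsing, length/spacer
# accounting, sequence extraction and annotation validation.

.PCG_NAMES <- c("nad2", "cox1", "cox2", "atp8", "atp6", "cox3", "nad3",
                "nad5", "nad4", "nad4L", "nad6", "cytb", "nad1")

# infer a feature class from its label
.inferKlass <- function(name) {
  n <- tolower(name)
  if (grepl("^trn", n)) return("tRNA")
  if (grepl("^rrn", n)) return("rRNA")
  if (name %in% .PCG_NAMES) return("PCG")
  if (grepl("a\\+?t[- ]rich", n) || n %in% c("cr", "control region", "control_region", "d-loop")) {
    return("control_region")
  }
  if (grepl("^tru", n) || grepl("repeat", n)) return("repeat_region")
  "other"
}

# parse "start-end" under any dash dialect; returns c(start, end) or NULL
.parseCoordPair <- function(x) {
  x <- .normNum(trimws(x))
  m <- regmatches(x, regexec("^([0-9]+)-([0-9]+)$", x))[[1L]]
  if (length(m) != 3L) return(NULL)
  as.integer(m[2:3])
}

#' Parse an annotated-genome feature table
#'
#' Reads a tab-separated feature table in either of two dialects:
#' \describe{
#'   \item{summary dialect}{columns `gene`, `direction` (F/R, empty for
#'     non-genes), a combined coordinate column (`coordinates` or
#'     `nucleotide_number`) formatted `start-end` (hyphen, en- or em-dash),
#'     optional `anticodon` (`"31-33 CAT"` or a bare triplet), `start_codon`,
#'     `stop_codon`.}
#'   \item{plain dialect}{columns `gene`, `class`, `direction`, `start`,
#'     `end`, `anticodon`, `anticodon_start`, `anticodon_end`, `start_codon`,
#'     `stop_codon`.}
#' }
#' Thousands separators and dash variants are normalised.  Feature classes are
#' inferred from gene labels when no `class` column is present (trn* -> tRNA,
#' rrn* -> rRNA, TRU -> repeat_region, A+T-rich region/CR -> control_region,
#' known protein genes -> PCG).  The genome length is inferred as the maximum
#' feature end unless given.
#'
#' @param file Path to a TSV file, or a character vector of TSV lines when
#'   `text = TRUE`.
#' @param genomeLength Optional known genome length (bp).
#' @param circular Logical, default `TRUE`.
#' @param text Logical; treat `file` as literal TSV text.
#' @return An [AnnotatedGenome-class] object (no sequence).
#' @export
#' @examples
#' tsv <- c("gene\tdirection\tcoordinates\tanticodon",
#'          "trnM\tF\t1-68\t31-33 CAT")
#' g <- parseFeatureTable(tsv, text = TRUE)
#' featureTable(g)
parseFeatureTable <- function(file, genomeLength = NULL, circular = TRUE, text = FALSE) {
  tab <- if (text) {
    utils::read.delim(text = paste(file, collapse = "\n"), stringsAsFactors = FALSE,
                      check.names = FALSE, colClasses = "character")
  } else {
    utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE,
                      colClasses = "character", fileEncoding = "UTF-8")
  }
  names(tab) <- tolower(trimws(names(tab)))
  if (nrow(tab) == 0L) stop("no features in table", call. = FALSE)
  geneCol <- intersect(c("gene", "name", "feature"), names(tab))[1L]
  if (is.na(geneCol)) stop("feature table has no 'gene' column", call. = FALSE)

  n <- nrow(tab)
  name <- trimws(tab[[geneCol]])
  dir <- if ("direction" %in% names(tab)) trimws(tab$direction) else rep("", n)
  strand <- ifelse(toupper(dir) == "F", "+", ifelse(toupper(dir) == "R", "-", NA_character_))

  if (all(c("start", "end") %in% names(tab))) {
    start <- as.integer(.normNum(tab$start))
    end <- as.integer(.normNum(tab$end))
  } else {
    coordCol <- intersect(c("coordinates", "nucleotide_number", "nucleotide number",
                            "position", "range"), names(tab))[1L]
    if (is.na(coordCol)) stop("feature table has no coordinate columns", call. = FALSE)
    start <- end <- integer(n)
    for (i in seq_len(n)) {
      pr <- .parseCoordPair(tab[[coordCol]][i])
      if (is.null(pr)) {
        stop(sprintf("malformed coordinate '%s' on line %d (gene %s)",
                     tab[[coordCol]][i], i + 1L, name[i]), call. = FALSE)
      }
      start[i] <- pr[1L]; end[i] <- pr[2L]
    }
  }

  anticodon <- rep(NA_character_, n)
  acStart <- acEnd <- rep(NA_integer_, n)
  if ("anticodon" %in% names(tab)) {
    for (i in seq_len(n)) {
      a <- trimws(tab$anticodon[i])
      if (.isBlank(a)) next
      m <- regmatches(.normNum(a), regexec("^([0-9]+)-([0-9]+)[[:space:]]+([ACGTUacgtu]{3})$",
                                           .normNum(a)))[[1L]]
      if (length(m) == 4L) {
        acStart[i] <- as.integer(m[2L]); acEnd[i] <- as.integer(m[3L])
        anticodon[i] <- toupper(m[4L])
      } else if (grepl("^[ACGTUacgtu]{3}$", a)) {
        anticodon[i] <- toupper(a)
      } else {
        stop(sprintf("malformed anticodon '%s' on line %d (gene %s)", a, i + 1L, name[i]),
             call. = FALSE)
      }
    }
  }
  for (col in c("anticodon_start", "anticodon_end")) {
    if (col %in% names(tab)) {
      val <- suppressWarnings(as.integer(.normNum(tab[[col]])))
      if (col == "anticodon_start") acStart <- ifelse(is.na(val), acStart, val)
      else acEnd <- ifelse(is.na(val), acEnd, val)
    }
  }
  codon <- function(col) {
    if (col %in% names(tab)) ifelse(.isBlank(tab[[col]]), NA_character_, toupper(trimws(tab[[col]]))) else rep(NA_character_, n)
  }
  klass <- if ("class" %in% names(tab)) {
    trimws(tab$class)
  } else {
    vapply(name, .inferKlass, character(1))
  }
  dup <- name[duplicated(name)]
  if (length(dup)) {
    stop(sprintf("duplicate gene name(s): %s", paste(unique(dup), collapse = ", ")),
         call. = FALSE)
  }
  annotatedGenome(
    data.frame(name = name, klass = klass, strand = strand, start = start, end = end,
               anticodon = anticodon, anticodon_start = acStart, anticodon_end = acEnd,
               start_codon = codon("start_codon"), stop_codon = codon("stop_codon"),
               stringsAsFactors = FALSE),
    genomeLength = genomeLength, circular = circular)
}

#' Length of a (possibly origin-wrapping) feature
#'
#' Under 1-based inclusive coordinates the length is `end - start + 1`; a
#' feature with `end < start` on a circular genome wraps the origin and has
#' length `genomeLength - start + 1 + end`.
#'
#' @param start,end 1-based inclusive coordinates.
#' @param genomeLength Genome length (needed only for wrapping features).
#' @param circular Logical; wrapping is an error on a linear genome.
#' @return Integer length in bp.
#' @export
#' @examples
#' featureLength(16455, 17788)          # 1334
#' featureLength(20450, 10, 20456)      # wraps the origin: 17
featureLength <- function(start, end, genomeLength = NA_integer_, circular = TRUE) {
  if (end >= start) return(as.integer(end - start + 1L))
  if (!circular) stop("end < start on a non-circular genome", call. = FALSE)
  if (is.na(genomeLength)) stop("genomeLength required for a wrapping feature", call. = FALSE)
  as.integer(genomeLength - start + 1L + end)
}

#' Feature lengths for a whole genome
#'
#' @param g An [AnnotatedGenome-class].
#' @return Named integer vector of feature lengths (bp).
#' @export
featureLengths <- function(g) {
  ft <- featureTable(g)
  L <- genomeLength(g)
  out <- mapply(function(s, e) {
    e2 <- if (e > L) e - L else e
    featureLength(s, e2, L, isCircular(g))
  }, ft$start, ft$end)
  stats::setNames(as.integer(out), ft$name)
}

#' Intergenic spacers and overlaps of the circular gene chain
#'
#' Walks consecutive gene pairs (PCG, tRNA and rRNA features only; repeat and
#' control regions are excluded from the adjacency chain because they lie
#' inside, or are reported separately from, intergenic spacers) in circular
#' order, including the wrap-around pair.  The signed length of each record is
#' `start(downstream) - end(upstream) - 1`: positive values are intergenic
#' spacers, negative values gene overlaps.
#'
#' Records whose span is occupied by a control-region feature (the A+T-rich
#' region, conventionally reported separately from the intergenic spacers) are
#' flagged `is_control_region` and excluded from the positive-spacer summary;
#' repeat regions contained in a spacer are listed in `contains`.
#'
#' @param g An [AnnotatedGenome-class] with at least two gene features.
#' @return A list with `spacers` (data.frame: `upstream`, `downstream`,
#'   `length`, `contains`, `is_control_region`) and `summary` (list:
#'   `n_positive`, `total_positive`, `min_positive`, `max_positive`, computed
#'   over positive, non-control-region records).
#' @export
#' @examples
#' g <- earwigGenome()
#' ir <- intergenicRegions(g)
#' ir$summary$max_positive   # the 2888-bp trnI-trnW spacer
intergenicRegions <- function(g) {
  ft <- featureTable(g)
  chain <- ft[ft$klass %in% c("PCG", "tRNA", "rRNA"), , drop = FALSE]
  if (nrow(chain) < 2L) stop("need at least two gene features", call. = FALSE)
  L <- genomeLength(g)
  if (sum(pmin(featureLengths(g)[chain$name], L)) > 2L * L) {
    stop("overlapping gene chain longer than genome", call. = FALSE)
  }
  n <- nrow(chain)
  upstream <- chain$name
  downstream <- c(chain$name[-1L], chain$name[1L])
  gap <- integer(n)
  for (i in seq_len(n)) {
    e <- chain$end[i]
    s <- if (i < n) chain$start[i + 1L] else chain$start[1L] + L
    gap[i] <- s - e - 1L
  }
  nonGene <- ft[ft$klass %in% c("control_region", "repeat_region"), , drop = FALSE]
  contains <- character(n)
  isCR <- logical(n)
  for (i in seq_len(n)) {
    if (gap[i] <= 0L) next
    a <- chain$end[i] + 1L
    b <- a + gap[i] - 1L            # may exceed L on the wrap record
    hit <- character(0)
    for (j in seq_len(nrow(nonGene))) {
      fs <- nonGene$start[j]; fe <- nonGene$end[j]
      # also consider the feature shifted by L for the wrap interval
      if ((fs >= a && fe <= b) || (fs + L >= a && fe + L <= b)) {
        hit <- c(hit, nonGene$name[j])
        if (nonGene$klass[j] == "control_region") isCR[i] <- TRUE
      }
    }
    contains[i] <- paste(hit, collapse = ",")
  }
  sp <- data.frame(upstream = upstream, downstream = downstream, length = gap,
                   contains = contains, is_control_region = isCR,
                   stringsAsFactors = FALSE)
  pos <- sp$length[sp$length > 0L & !sp$is_control_region]
  list(
    spacers = sp,
    summary = list(
      n_positive = length(pos),
      total_positive = sum(pos),
      min_positive = if (length(pos)) min(pos) else NA_integer_,
      max_positive = if (length(pos)) max(pos) else NA_integer_
    )
  )
}

#' Extract a region of the genome sequence
#'
#' Returns the major-strand subsequence for `strand = "+"` and its reverse
#' complement for `strand = "-"`; circular wrap (`end` past the genome length,
#' or `end < start`) is supported.
#'
#' @param g An [AnnotatedGenome-class] carrying a sequence.
#' @param start,end 1-based inclusive coordinates.
#' @param strand `"+"` or `"-"`.
#' @return Nucleotide string.
#' @export
extractRegion <- function(g, start, end, strand = "+") {
  s <- genomeSequence(g)
  if (is.null(s)) stop("sequence-free genome", call. = FALSE)
  L <- genomeLength(g)
  if (end > L) end <- end - L
  out <- if (end >= start) {
    substr(s, start, end)
  } else {
    if (!isCircular(g)) stop("end < start on a non-circular genome", call. = FALSE)
    paste0(substr(s, start, L), substr(s, 1L, end))
  }
  if (identical(strand, "-")) reverseComplementSeq(out) else out
}

#' Extract the coding-strand (sense) sequence of a feature
#'
#' @param g An [AnnotatedGenome-class] carrying a sequence.
#' @param feature Feature name (or row index into [featureTable()]).
#' @return Nucleotide string, 5'->3' on the coding strand.
#' @export
extractFeatureSequence <- function(g, feature) {
  ft <- featureTable(g)
  i <- if (is.character(feature)) match(feature, ft$name) else as.integer(feature)
  if (is.na(i) || i < 1L || i > nrow(ft)) {
    stop(sprintf("unknown feature '%s'", as.character(feature)), call. = FALSE)
  }
  strand <- ft$strand[i]
  if (is.na(strand)) strand <- "+"
  extractRegion(g, ft$start[i], ft$end[i], strand)
}

.START_CODONS <- c("ATA", "ATT", "ATC", "ATG", "TTG", "GTG")
.STOP_CODONS_FULL <- c("TAA", "TAG")
.STOP_CODONS <- c(.STOP_CODONS_FULL, "T", "TA")

#' Validate a genome annotation
#'
#' Non-fatal consistency checks: anticodon positions inside the tRNA span;
#' anticodon (and annotated start/stop codons) agreeing with the sequence when
#' one is present; protein start codons drawn from the mitochondrial set
#' (ATA/ATT/ATC/ATG/TTG/GTG); stop codons complete (TAA/TAG) or incomplete
#' (T/TA, reported as a warning); coordinates within bounds.  Published
#' feature tables occasionally carry typos (e.g. an anticodon coordinate
#' inconsistent with its gene span), so findings are returned, never thrown.
#'
#' @param g An [AnnotatedGenome-class].
#' @return data.frame with columns `feature`, `rule`, `severity`
#'   ("error"/"warning"), `message`; zero rows when the annotation is clean.
#' @export
validateAnnotation <- function(g) {
  ft <- featureTable(g)
  L <- genomeLength(g)
  hasSeq <- !is.null(genomeSequence(g))
  out <- list()
  add <- function(feature, rule, severity, message) {
    out[[length(out) + 1L]] <<- data.frame(feature = feature, rule = rule,
                                           severity = severity, message = message,
                                           stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(ft))) {
    f <- ft[i, ]
    if (f$start < 1L || f$end > 2L * L) {
      add(f$name, "coordinate_bounds", "error",
          sprintf("coordinates %d-%d outside [1, 2x genome length]", f$start, f$end))
    }
    if (!is.na(f$anticodon_start)) {
      span <- .featurePositions(f$start, f$end, L)
      acSpan <- tryCatch(.featurePositions(f$anticodon_start, f$anticodon_end, L),
                         error = function(e) integer(0))
      if (!all(acSpan %in% span) || length(acSpan) == 0L) {
        add(f$name, "anticodon_span", "error",
            sprintf("anticodon positions %d-%d outside feature span %d-%d",
                    f$anticodon_start, f$anticodon_end, f$start, f$end))
      } else if (hasSeq && !is.na(f$anticodon)) {
        obs <- extractRegion(g, f$anticodon_start, f$anticodon_end,
                             if (is.na(f$strand)) "+" else f$strand)
        if (!identical(obs, f$anticodon)) {
          add(f$name, "anticodon_sequence", "error",
              sprintf("anticodon in sequence is %s, annotation says %s", obs, f$anticodon))
        }
      }
    }
    if (f$klass == "PCG") {
      if (!is.na(f$start_codon) && !(f$start_codon %in% .START_CODONS)) {
        add(f$name, "start_codon", "warning",
            sprintf("unusual start codon %s", f$start_codon))
      }
      if (!is.na(f$stop_codon)) {
        if (f$stop_codon %in% c("T", "TA")) {
          add(f$name, "stop_codon", "warning",
              sprintf("incomplete stop codon %s", f$stop_codon))
        } else if (!(f$stop_codon %in% .STOP_CODONS_FULL)) {
          add(f$name, "stop_codon", "error",
              sprintf("invalid stop codon %s", f$stop_codon))
        }
      }
      if (hasSeq && !is.na(f$start_codon)) {
        sense <- extractFeatureSequence(g, f$name)
        if (substr(sense, 1L, 3L) != f$start_codon) {
          add(f$name, "start_codon_sequence", "error",
              sprintf("sequence starts %s, annotation says %s",
                      substr(sense, 1L, 3L), f$start_codon))
        }
      }
    }
  }
  if (length(out)) do.call(rbind, out) else {
    data.frame(feature = character(0), rule = character(0),
               severity = character(0), message = character(0))
  }
}

#' The published earwig mitogenome annotation
#'
#' Parses the feature table of the Challia fletcheri (Dermaptera) mitochondrial
#' genome (GenBank JN651407) shipped with the package: 13 protein-coding
#' genes, 22 tRNAs, 2 rRNAs, the 2856-bp tandem-repeat unit and the 1816-bp
#' A+T-rich region on a 20,456-bp circle.  The table is annotation only (no
#' nucleotide sequence) and reproduces the published coordinates verbatim,
#' including a known anticodon-coordinate typo in trnL(CUN) that
#' [validateAnnotation()] flags.
#'
#' @return An [AnnotatedGenome-class].
#' @export
#' @examples
#' g <- earwigGenome()
#' genomeLength(g)   # 20456
earwigGenome <- function() {
  parseFeatureTable(system.file("extdata", "challia_fletcheri_mtgenome_features.tsv",
                                package = "mitoarch"))
}
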