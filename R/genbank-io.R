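# Minimal GenBank flat-file and FASTA input/output for annotated circular
# genomes.  GenBank 1-based inclusive locations are the native coordinate
# convention of AnnotatedGenome; "complement(...)" maps to the minor strand
# and "join(a..L,1..b)" to an origin-wrapping feature.

.GB_KEY_FOR_KLASS <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                       control_region = "D-loop", repeat_region = "repeat_region",
                       other = "misc_feature")
.KLASS_FOR_GB_KEY <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                       "D-loop" = "control_region", repeat_region = "repeat_region",
                       misc_feature = "other")

.gbLocation <- function(start, end, strand, L) {
  loc <- if (end > L) {
    sprintf("join(%d..%d,%d..%d)", start, L, 1L, end - L)
  } else {
    sprintf("%d..%d", start, end)
  }
  if (identical(strand, "-")) sprintf("complement(%s)", loc) else loc
}

#' Write an annotated genome as a GenBank flat file
#'
#' Emits LOCUS, FEATURES and ORIGIN sections sufficient for a lossless
#' round-trip of coordinates, strand, gene names, feature classes, anticodons
#' and start/stop codons through [readGenBank()].
#'
#' @param g An [AnnotatedGenome-class].
#' @param path Output file path.
#' @param locus Locus name written to the header.
#' @return `path`, invisibly.
#' @export
writeGenBank <- function(g, path, locus = "genome") {
  L <- genomeLength(g)
  ft <- featureTable(g)
  lines <- c(
    sprintf("LOCUS       %-16s %d bp    DNA     %s       UNK",
            locus, L, if (isCircular(g)) "circular" else "linear"),
    sprintf("DEFINITION  %s.", locus),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", L))
  qual <- function(txt) sprintf("                     %s", txt)
  for (i in seq_len(nrow(ft))) {
    f <- ft[i, ]
    key <- .GB_KEY_FOR_KLASS[[f$klass]]
    lines <- c(lines,
               sprintf("     %-15s %s", key, .gbLocation(f$start, f$end, f$strand, L)),
               qual(sprintf('/gene="%s"', f$name)))
    if (f$klass == "other") lines <- c(lines, qual('/note="klass:other"'))
    if (!is.na(f$anticodon)) {
      lines <- c(lines, if (!is.na(f$anticodon_start)) {
        qual(sprintf('/anticodon=(pos:%d..%d,seq:%s)',
                     f$anticodon_start, f$anticodon_end, tolower(f$anticodon)))
      } else {
        qual(sprintf('/anticodon=(seq:%s)', tolower(f$anticodon)))
      })
    }
    if (!is.na(f$start_codon) || !is.na(f$stop_codon)) {
      lines <- c(lines, qual(sprintf('/note="start_codon:%s;stop_codon:%s"',
                                     f$start_codon, f$stop_codon)))
    }
  }
  s <- genomeSequence(g)
  if (!is.null(s)) {
    lines <- c(lines, "ORIGIN")
    s <- tolower(s)
    for (off in seq(1L, nchar(s), by = 60L)) {
      blk <- substr(s, off, min(nchar(s), off + 59L))
      grp <- substring(blk, seq(1L, nchar(blk), by = 10L),
                       pmin(nchar(blk), seq(10L, nchar(blk) + 9L, by = 10L)))
      lines <- c(lines, sprintf("%9d %s", off, paste(grp, collapse = " ")))
    }
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}

.parseGbLocation <- function(loc) {
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  wrap <- FALSE
  if (grepl("^join\\(", loc)) {
    loc <- sub("^join\\((.*)\\)$", "\\1", loc)
    pieces <- strsplit(loc, ",")[[1L]]
    a <- as.integer(strsplit(pieces[1L], "\\.\\.")[[1L]])
    b <- as.integer(strsplit(pieces[2L], "\\.\\.")[[1L]])
    return(list(start = a[1L], end = b[2L], strand = strand, wrapEnd = a[2L]))
  }
  p <- as.integer(strsplit(loc, "\\.\\.")[[1L]])
  list(start = p[1L], end = p[2L], strand = strand, wrapEnd = NA_integer_)
}

#' Read a GenBank flat file into an AnnotatedGenome
#'
#' Parses the LOCUS length/topology, the FEATURES table (gene, tRNA, rRNA,
#' CDS, D-loop, repeat_region, misc_feature keys; unknown keys are retained
#' as class "other" with a warning) and the ORIGIN sequence when present.
#'
#' @param path GenBank file path.
#' @return An [AnnotatedGenome-class].
#' @export
readGenBank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("not a GenBank file: no LOCUS line", call. = FALSE)
  L <- as.integer(sub(".* (\\d+) bp.*", "\\1", locus[1L]))
  circular <- grepl("circular", locus[1L])
  featStart <- grep("^FEATURES", lines)
  originAt <- grep("^ORIGIN", lines)
  endAt <- grep("^//", lines)
  featEnd <- if (length(originAt)) originAt[1L] - 1L else
    if (length(endAt)) endAt[1L] - 1L else length(lines)
  rows <- list()
  cur <- NULL
  flush <- function() {
    if (is.null(cur)) return()
    rows[[length(rows) + 1L]] <<- cur
  }
  if (length(featStart)) {
    for (ln in lines[(featStart[1L] + 1L):featEnd]) {
      if (grepl("^     \\S", ln)) {                      # new feature
        key <- trimws(substr(ln, 1L, 20L))
        loc <- trimws(substr(ln, 21L, nchar(ln)))
        if (key == "source") { flush(); cur <- NULL; next }
        klass <- .KLASS_FOR_GB_KEY[key]
        if (is.na(klass)) {
          warning(sprintf("unknown feature key '%s' retained as class 'other'", key))
          klass <- "other"
        }
        flush()
        p <- .parseGbLocation(loc)
        cur <- data.frame(name = NA_character_, klass = unname(klass),
                          strand = p$strand, start = p$start, end = p$end,
                          anticodon = NA_character_, anticodon_start = NA_integer_,
                          anticodon_end = NA_integer_, start_codon = NA_character_,
                          stop_codon = NA_character_, stringsAsFactors = FALSE)
        if (!is.na(p$wrapEnd) && p$wrapEnd == L) cur$end <- cur$end + L
      } else if (!is.null(cur) && grepl("^\\s+/", ln)) { # qualifier
        q <- trimws(ln)
        if (grepl("^/gene=", q)) {
          cur$name <- gsub('"', "", sub("^/gene=", "", q))
        } else if (grepl("^/anticodon=", q)) {
          m <- regmatches(q, regexec("pos:(\\d+)\\.\\.(\\d+)", q))[[1L]]
          if (length(m) == 3L) {
            cur$anticodon_start <- as.integer(m[2L])
            cur$anticodon_end <- as.integer(m[3L])
          }
          ms <- regmatches(q, regexec("seq:([acgtu]+)", q))[[1L]]
          if (length(ms) == 2L) cur$anticodon <- toupper(ms[2L])
        } else if (grepl("^/note=\"start_codon:", q)) {
          m <- regmatches(q, regexec('start_codon:([A-Z]+|NA);stop_codon:([A-Z]+|NA)', q))[[1L]]
          if (length(m) == 3L) {
            if (m[2L] != "NA") cur$start_codon <- m[2L]
            if (m[3L] != "NA") cur$stop_codon <- m[3L]
          }
        }
      }
    }
    flush()
  }
  seq <- NULL
  if (length(originAt)) {
    body <- lines[(originAt[1L] + 1L):(if (length(endAt)) endAt[1L] - 1L else length(lines))]
    seq <- toupper(gsub("[^acgtnACGTN]", "", paste(body, collapse = "")))
    if (!is.na(L) && nchar(seq) != L) {
      stop(sprintf("ORIGIN sequence length (%d) differs from LOCUS length (%d)",
                   nchar(seq), L), call. = FALSE)
    }
  }
  if (!length(rows)) stop("no features in GenBank file", call. = FALSE)
  ftab <- do.call(rbind, rows)
  ftab$name[is.na(ftab$name)] <- sprintf("feature_%d", which(is.na(ftab$name)))
  # control and repeat regions are strandless in the genome model
  ftab$strand[ftab$klass %in% c("control_region", "repeat_region")] <- NA_character_
  annotatedGenome(ftab, genomeLength = L, sequence = seq, circular = circular)
}

#' Read a genome FASTA (optionally attaching a feature table)
#'
#' @param path FASTA path (single record).
#' @param featureTable Optional feature-table TSV path parsed with
#'   [parseFeatureTable()]; the FASTA length must equal the table's genome
#'   length.
#' @param circular Logical, default `TRUE`.
#' @return An [AnnotatedGenome-class].
#' @export
readFastaGenome <- function(path, featureTable = NULL, circular = TRUE) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L) stop("expected a single-record FASTA", call. = FALSE)
  seq <- toupper(as.character(ss[[1L]]))
  if (!is.null(featureTable)) {
    g <- parseFeatureTable(featureTable, circular = circular)
    return(attachSequence(g, seq))
  }
  annotatedGenome(
    data.frame(name = names(ss)[1L], klass = "other", strand = NA_character_,
               start = 1L, end = nchar(seq), stringsAsFactors = FALSE),
    genomeLength = nchar(seq), sequence = seq, circular = circular)
}

#' Attach a sequence to an annotation-only genome
#'
#' @param g An [AnnotatedGenome-class].
#' @param sequence Nucleotide string whose length must equal the genome length.
#' @return The genome with sequence attached.
#' @export
attachSequence <- function(g, sequence) {
  if (nchar(sequence) != genomeLength(g)) {
    stop(sprintf("sequence length (%d) differs from declared genome length (%d)",
                 nchar(sequence), genomeLength(g)), call. = FALSE)
  }
  annotatedGenome(featureTable(g), genomeLength = genomeLength(g),
                  sequence = sequence, circular = isCircular(g))
}

#' Write the genome sequence as FASTA
#'
#' @param g An [AnnotatedGenome-class] carrying a sequence.
#' @param path Output path.
#' @param name Record name.
#' @return `path`, invisibly.
#' @export
writeFastaGenome <- function(g, path, name = "genome") {
  s <- genomeSequence(g)
  if (is.null(s)) stop("sequence-free genome", call. = FALSE)
  ss <- Biostrings::DNAStringSet(s)
  names(ss) <- name
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write a feature table TSV (plain dialect)
#'
#' Writes the columns of [featureTable()] as tab-separated text that
#' [parseFeatureTable()] reads back losslessly.
#'
#' @param g An [AnnotatedGenome-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(g, path) {
  ft <- featureTable(g)
  out <- data.frame(gene = ft$name, class = ft$klass,
                    direction = ifelse(is.na(ft$strand), "",
                                       ifelse(ft$strand == "+", "F", "R")),
                    start = ft$start, end = ft$end,
                    anticodon = ifelse(is.na(ft$anticodon), "", ft$anticodon),
                    anticodon_start = ifelse(is.na(ft$anticodon_start), "", ft$anticodon_start),
                    anticodon_end = ifelse(is.na(ft$anticodon_end), "", ft$anticodon_end),
                    start_codon = ifelse(is.na(ft$start_codon), "", ft$start_codon),
                    stop_codon = ifelse(is.na(ft$stop_codon), "", ft$stop_codon),
                    stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
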