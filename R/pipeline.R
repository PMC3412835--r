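# Orchestration: one genome in, one comparative report out (JSON and text).
# Every section is either populated or explicitly marked skipped, and the
# report is deterministic for identical inputs and options.

.skipped <- function(reason) list(skipped = TRUE, reason = reason)

#' Run the full comparative report on one genome
#'
#' Computes, with the respective modules: annotation validation; genome
#' architecture (length, feature census, intergenic spacers and overlaps);
#' strand-partitioned composition and skew with codon-position A+T content;
#' tandem repeat units in non-coding regions; control-region motifs
#' (stem-loops with conserved flanks, poly-T stretches, ORFs) and tRNA-like
#' cloverleaves in the repeat-bearing spacer; and rearrangement
#' classification against an ancestral order.  Sequence-level sections are
#' marked skipped for annotation-only input; the rearrangement section is
#' skipped when the gene sets differ.
#'
#' @param g An [AnnotatedGenome-class], or a path to a feature-table TSV or
#'   GenBank file.
#' @param ancestral Reference [GeneOrder-class]; default
#'   [ancestralInsectOrder()].
#' @param scanMotifs Scan control-region motifs and tRNA-like repeats
#'   (sequence-bearing input only); default `TRUE`.
#' @param maxTrnaScan Longest region (bp) submitted to the cloverleaf
#'   scanner; default 4000.
#' @return A list of class `GenomeReport` with sections `provenance`,
#'   `validation`, `architecture`, `skew`, `tru`, `motifs`, `rearrangement`.
#' @export
runReport <- function(g, ancestral = ancestralInsectOrder(), scanMotifs = TRUE,
                      maxTrnaScan = 4000L) {
  input <- "AnnotatedGenome object"
  if (is.character(g)) {
    input <- g
    g <- if (grepl("\\.(gb|gbk|genbank)$", g, ignore.case = TRUE)) {
      readGenBank(g)
    } else {
      parseFeatureTable(g)
    }
  }
  stopifnot(is(g, "AnnotatedGenome"))
  hasSeq <- !is.null(genomeSequence(g))
  ft <- featureTable(g)

  findings <- validateAnnotation(g)
  ir <- intergenicRegions(g)
  lens <- featureLengths(g)
  census <- as.list(table(factor(ft$klass, levels = .FEATURE_CLASSES)))
  architecture <- list(
    genome_length = genomeLength(g),
    circular = isCircular(g),
    feature_census = census,
    feature_lengths = as.list(lens),
    spacers = ir$spacers,
    spacer_summary = ir$summary,
    control_region_length = {
      cr <- which(ft$klass == "control_region")
      if (length(cr)) unname(lens[ft$name[cr[1L]]]) else NA_integer_
    },
    stop_codon_census = as.list(table(ft$stop_codon[ft$klass == "PCG" &
                                                      !is.na(ft$stop_codon)]))
  )

  skew <- if (!hasSeq) .skipped("no sequence") else {
    sp <- strandPartitionSkew(g)
    fmt <- function(e) {
      if (!isTRUE(e$defined)) return(list(defined = FALSE))
      list(defined = TRUE, genes = e$genes,
           at_skew = .roundHalfAway(e$skew$at_skew),
           gc_skew = .roundHalfAway(e$skew$gc_skew),
           class = e$class,
           at_content_percent = .roundHalfAway(100 * e$composition$at_content, 1L))
    }
    out <- lapply(sp, fmt)
    if (any(ft$klass == "PCG")) {
      cp <- codonPositionComposition(g)
      out$codon_position_at_percent <- as.list(stats::setNames(
        .roundHalfAway(100 * cp$at_content, 1L), c("pos1", "pos2", "pos3")))
    }
    out
  }

  tru <- if (!hasSeq) .skipped("no sequence") else characterizeTRU(g)

  motifs <- if (!hasSeq) {
    .skipped("no sequence")
  } else if (!scanMotifs) {
    .skipped("motif scan disabled")
  } else {
    out <- list()
    cr <- which(ft$klass == "control_region")
    if (length(cr)) {
      crSeq <- extractRegion(g, ft$start[cr[1L]], ft$end[cr[1L]], "+")
      out$control_region_stem_loops <- findStemLoops(crSeq)
      out$control_region_poly_t <- findPolyT(crSeq)
      out$control_region_orfs <- findOrfs(crSeq)
    }
    rr <- which(ft$klass == "repeat_region")
    if (length(rr) && (ft$end[rr[1L]] - ft$start[rr[1L]] + 1L) <= maxTrnaScan) {
      out$repeat_region_trna_like <- scanRegionForTrnaLike(
        g, c(ft$start[rr[1L]], ft$end[rr[1L]]))
    }
    if (!length(out)) out <- .skipped("no non-coding regions to scan")
    out
  }

  rearrangement <- tryCatch({
    obs <- orderFromGenome(g)
    rep <- compareOrders(obs, ancestral)
    list(summary = rep$summary,
         breakpoints = rep$breakpoints,
         events = rep$events,
         moved = rep$table[rep$table$class != "in_place",
                           c("gene", "class", "orientation_ancestral",
                             "orientation_observed")])
  }, error = function(e) .skipped(conditionMessage(e)))

  structure(list(
    provenance = list(package = "mitoarch",
                      version = as.character(utils::packageVersion("mitoarch")),
                      input = input,
                      options = list(scanMotifs = scanMotifs, maxTrnaScan = maxTrnaScan)),
    validation = findings,
    architecture = architecture,
    skew = skew,
    tru = tru,
    motifs = motifs,
    rearrangement = rearrangement
  ), class = "GenomeReport")
}

#' Write a GenomeReport as JSON (and optionally human-readable text)
#'
#' @param report A `GenomeReport` from [runReport()].
#' @param jsonPath Output JSON path.
#' @param textPath Optional plain-text summary path.
#' @return `jsonPath`, invisibly.
#' @export
writeGenomeReport <- function(report, jsonPath, textPath = NULL) {
  jsonlite::write_json(report, jsonPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
  if (!is.null(textPath)) writeLines(formatGenomeReport(report), textPath)
  invisible(jsonPath)
}

#' Format a GenomeReport as readable text
#'
#' @param report A `GenomeReport`.
#' @return Character vector of lines.
#' @export
formatGenomeReport <- function(report) {
  out <- c(sprintf("mitoarch report (package %s)", report$provenance$version),
           sprintf("input: %s", report$provenance$input), "")
  a <- report$architecture
  out <- c(out,
           sprintf("genome length: %d bp (%s)", a$genome_length,
                   if (a$circular) "circular" else "linear"),
           sprintf("features: %s",
                   paste(sprintf("%s %d", names(a$feature_census), unlist(a$feature_census)),
                         collapse = ", ")),
           sprintf("positive intergenic spacers: %d (total %d bp, range %s-%s bp)",
                   a$spacer_summary$n_positive, a$spacer_summary$total_positive,
                   a$spacer_summary$min_positive, a$spacer_summary$max_positive))
  secLine <- function(name, s) {
    if (isTRUE(s$skipped)) sprintf("%s: skipped (%s)", name, s$reason) else NULL
  }
  sk <- report$skew
  if (isTRUE(sk$skipped)) {
    out <- c(out, secLine("skew", sk))
  } else {
    for (nm in intersect(c("whole_genome", "all_PCGs", "major_strand_PCGs",
                           "minor_strand_PCGs"), names(sk))) {
      e <- sk[[nm]]
      out <- c(out, if (isTRUE(e$defined)) {
        sprintf("skew %s: AT %.3f GC %.3f (%s)", nm, e$at_skew, e$gc_skew, e$class)
      } else {
        sprintf("skew %s: undefined", nm)
      })
    }
    if (!is.null(sk$codon_position_at_percent)) {
      cp <- sk$codon_position_at_percent
      out <- c(out, sprintf("codon-position A+T%%: %.1f / %.1f / %.1f",
                            cp$pos1, cp$pos2, cp$pos3))
    }
  }
  tr <- report$tru
  out <- c(out, if (isTRUE(tr$skipped)) {
    secLine("tandem repeats", tr)
  } else if (nrow(tr) == 0L) {
    "tandem repeats: none detected"
  } else {
    sprintf("tandem repeat in %s: unit %d bp x %d copies + %d bp partial (span %d bp)",
            tr$region, tr$unit_length, tr$full_copies, tr$partial_length, tr$span)
  })
  re <- report$rearrangement
  out <- c(out, if (isTRUE(re$skipped)) {
    secLine("rearrangement", re)
  } else {
    sprintf("rearrangement vs ancestral order: %d translocated, %d local inversions, %d shuffles with remote inversion, %d in place (%d breakpoints)",
            re$summary$translocated, re$summary$local_inversion,
            re$summary$shuffle_with_remote_inversion, re$summary$in_place,
            re$breakpoints)
  })
  nerr <- sum(report$validation$severity == "error")
  nwarn <- sum(report$validation$severity == "warning")
  out <- c(out, sprintf("validation: %d error(s), %d warning(s)", nerr, nwarn))
  out
}
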