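# Seeded synthetic genomes and gene orders with planted, recoverable
# structure: per-strand base composition, tandem repeat units, cloverleaf
# motifs, and scripted rearrangement events with known ground truth.

.TRNA_ANTICODONS <- c(
  "trnM" = "CAT", "trnI" = "GAT", "trnW" = "TCA", "trnL(UUR)" = "TAA",
  "trnK" = "CTT", "trnD" = "GTC", "trnG" = "TCC", "trnA" = "TGC",
  "trnN" = "GTT", "trnR" = "TCG", "trnS(AGN)" = "GCT", "trnY" = "GTA",
  "trnC" = "GCA", "trnQ" = "TTG", "trnE" = "TTC", "trnF" = "GAA",
  "trnH" = "GTG", "trnT" = "TGT", "trnP" = "TGG", "trnS(UCN)" = "TGA",
  "trnV" = "TAC", "trnL(CUN)" = "TAG")

.sampleBases <- function(n, probs) {
  if (n <= 0L) return(character(0))
  sample(.BASES, n, replace = TRUE, prob = probs[.BASES])
}

#' Build a cloverleaf-folding tRNA-like sequence
#'
#' Constructs a sequence satisfying the structural grammar of
#' [findCloverleaves()] (7-bp acceptor stem, DHU arm or 12-nt DHU loop, 5-bp
#' anticodon stem with the anticodon at loop positions 3-5, 4-nt variable
#' loop, 5-bp T-psi-C stem) with perfectly Watson-Crick-paired stems, so the
#' construct is detectable by definition.
#'
#' @param anticodon 3-mer placed at anticodon-loop positions 3-5.
#' @param dhuLess Build the DHU-stem-less (serine-AGN-like) variant.
#' @param probs Base probabilities for unpaired positions.
#' @return A list: `seq` (nucleotide string), `anticodon_start`,
#'   `anticodon_end` (1-based offsets within `seq`).
#' @export
buildCloverleaf <- function(anticodon, dhuLess = FALSE,
                            probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  stopifnot(grepl("^[ACGT]{3}$", anticodon))
  stem <- function(len) .sampleBases(len, probs)
  acc <- stem(7L)
  conn1 <- .sampleBases(2L, probs)
  dhu <- if (dhuLess) {
    .sampleBases(12L, probs)
  } else {
    d5 <- stem(4L)
    c(d5, .sampleBases(8L, probs), .revcompChars(d5))
  }
  conn2 <- .sampleBases(1L, probs)
  ac5 <- stem(5L)
  loop <- c(.sampleBases(2L, probs), .chars(anticodon), .sampleBases(2L, probs))
  var <- .sampleBases(4L, probs)
  t5 <- stem(5L)
  tloop <- .sampleBases(7L, probs)
  pre <- c(acc, conn1, dhu, conn2, ac5, loop[1:2])
  seq <- c(pre, .chars(anticodon), loop[6:7], .revcompChars(ac5), var,
           t5, tloop, .revcompChars(t5), .revcompChars(acc))
  list(seq = .collapse(seq),
       anticodon_start = length(pre) + 1L,
       anticodon_end = length(pre) + 3L)
}

#' Simulation configuration for synthetic genomes
#'
#' Bundles the planted structure of a synthetic circular mitogenome.  All
#' randomness flows from the single mandatory `seed`, so outputs are
#' byte-identical across runs.
#'
#' @param seed Integer seed (mandatory).
#' @param skeleton `"ancestral"` (the full 37-gene + CR insect arrangement,
#'   with protein/rRNA gene lengths taken from the published earwig
#'   annotation so synthetic genomes are realistic in scale) or `"minimal"`
#'   (a 6-feature toy skeleton).
#' @param genomeLength Optional target length; the pre-control-region spacer
#'   is padded with background sequence to reach it.
#' @param baseProbs Major-strand background base probabilities (named A/C/G/T,
#'   summing to 1).  The default mirrors the published earwig composition
#'   (A 28.2%, C 13.9%, G 17.6%, T 40.3%), i.e. a T- and G-skewed major strand.
#' @param tru `NULL`, or a list with `unit` (bp), `copies`, `partial` (bp),
#'   `divergence` (per-copy mutation rate), and optionally
#'   `cloverleafAnticodon` (plant one cloverleaf inside every repeat copy).
#' @param truHost Gene after which the repeat region is inserted.
#' @param crLength Control-region length (bp).
#' @param crMotifs Plant a stem-loop with TATA/G(A)nT flanks and a poly-T
#'   stretch in the control region.
#' @param spacerLength Background spacer length between features (bp).
#' @param events Optional rearrangement script applied to the skeleton order
#'   (see [generateOrder()]).
#' @return A list of class `SimulationConfig`.
#' @export
simulationConfig <- function(seed, skeleton = c("ancestral", "minimal"),
                             genomeLength = NULL,
                             baseProbs = c(A = 0.282, C = 0.139, G = 0.176, T = 0.403),
                             tru = list(unit = 135L, copies = 21L, partial = 21L,
                                        divergence = 0),
                             truHost = "trnI", crLength = 1816L, crMotifs = FALSE,
                             spacerLength = 2L, events = NULL) {
  seed <- .checkSeed(seed)
  skeleton <- match.arg(skeleton)
  if (abs(sum(baseProbs) - 1) > 1e-9) stop("baseProbs must sum to 1", call. = FALSE)
  if (!is.null(tru)) {
    stopifnot(tru$unit >= 2L, tru$copies >= 2L, tru$partial >= 0L, tru$partial < tru$unit)
  }
  structure(list(seed = seed, skeleton = skeleton, genomeLength = genomeLength,
                 baseProbs = baseProbs, tru = tru, truHost = truHost,
                 crLength = as.integer(crLength), crMotifs = isTRUE(crMotifs),
                 spacerLength = as.integer(spacerLength), events = events),
            class = "SimulationConfig")
}

# sample a protein gene: valid start codon, stop-free interior, valid stop
.samplePCG <- function(len, probs) {
  stopifnot(len %% 3L == 0L, len >= 9L)
  startCodon <- sample(c("ATA", "ATT", "ATC", "ATG"), 1L)
  stopCodon <- sample(c("TAA", "TAG"), 1L)
  nInner <- len %/% 3L - 2L
  inner <- character(nInner)
  for (k in seq_len(nInner)) {
    repeat {
      cd <- .collapse(.sampleBases(3L, probs))
      if (!(cd %in% c("TAA", "TAG"))) break
    }
    inner[k] <- cd
  }
  list(seq = paste0(startCodon, .collapse(inner), stopCodon),
       start_codon = startCodon, stop_codon = stopCodon)
}

.buildTruSequence <- function(tru, probs) {
  unit <- if (!is.null(tru$cloverleafAnticodon)) {
    cl <- buildCloverleaf(tru$cloverleafAnticodon, probs = probs)
    clv <- .chars(cl$seq)
    if (tru$unit < length(clv) + 4L) {
      stop("repeat unit too short to host a cloverleaf", call. = FALSE)
    }
    pad <- tru$unit - length(clv)
    pre <- pad %/% 2L
    c(.sampleBases(pre, probs), clv, .sampleBases(pad - pre, probs))
  } else {
    .sampleBases(tru$unit, probs)
  }
  copies <- character(tru$copies)
  for (k in seq_len(tru$copies)) {
    cp <- unit
    if (tru$divergence > 0) {
      nm <- stats::rbinom(1L, tru$unit, tru$divergence)
      if (nm > 0L) {
        at <- sample.int(tru$unit, nm)
        for (p in at) cp[p] <- sample(setdiff(.BASES, cp[p]), 1L)
      }
    }
    copies[k] <- .collapse(cp)
  }
  paste0(paste(copies, collapse = ""),
         .collapse(unit[seq_len(tru$partial)]))
}

.minimalSkeleton <- function() {
  data.frame(
    name = c("trnM", "nad2", "cox1", "trnV", "rrnS", "CR"),
    klass = c("tRNA", "PCG", "PCG", "tRNA", "rRNA", "control_region"),
    strand = c("+", "+", "+", "-", "-", NA),
    len = c(NA, 300L, 300L, NA, 400L, NA),
    stringsAsFactors = FALSE)
}

.ancestralSkeleton <- function() {
  lens <- featureLengths(earwigGenome())
  ord <- ancestralInsectOrder()
  data.frame(
    name = orderGenes(ord),
    klass = vapply(orderGenes(ord), .klassOfLabel, character(1)),
    strand = ifelse(orderGenes(ord) == "CR", NA, orientations(ord)),
    len = unname(lens[ifelse(orderGenes(ord) == "CR", "A+T-rich region",
                             orderGenes(ord))]),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic annotated circular genome
#'
#' Builds a circular genome from a [simulationConfig()]: protein genes carry
#' valid mitochondrial start/stop codons and a stop-free interior; tRNAs are
#' constructed cloverleaves with the correct anticodon for their label (the
#' serine-AGN tRNA is built DHU-less); a tandem repeat unit with the
#' configured (unit, copies, partial, divergence) is planted in the spacer
#' downstream of `truHost`; background sequence is sampled i.i.d. from the
#' per-strand base probabilities.  Deterministic given the seed.  Generated
#' annotations pass [validateAnnotation()] with zero errors.
#'
#' @param cfg A `SimulationConfig`.
#' @return An [AnnotatedGenome-class] with sequence.
#' @export
#' @examples
#' g <- generateGenome(simulationConfig(seed = 1, skeleton = "minimal",
#'                                      tru = NULL, crLength = 200))
#' validateAnnotation(g)
generateGenome <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  probs <- cfg$baseProbs
  skel <- if (cfg$skeleton == "ancestral") .ancestralSkeleton() else .minimalSkeleton()
  if (!is.null(cfg$events)) {
    ord <- geneOrder(skel$name, ifelse(is.na(skel$strand), "+", skel$strand))
    ord <- .applyScript(ord, cfg$events)
    skel <- skel[match(orderGenes(ord), skel$name), , drop = FALSE]
    skel$strand <- ifelse(skel$klass == "control_region", NA, orientations(ord))
  }
  parts <- list()   # each: list(kind, name, klass, strand, seq(genome strand), meta)
  addSpacer <- function(n) {
    if (n > 0L) parts[[length(parts) + 1L]] <<- list(kind = "spacer",
                                                     seq = .collapse(.sampleBases(n, probs)))
  }
  for (i in seq_len(nrow(skel))) {
    f <- skel[i, ]
    meta <- list(anticodon = NA_character_, acs = NA_integer_, ace = NA_integer_,
                 start_codon = NA_character_, stop_codon = NA_character_)
    if (f$klass == "tRNA") {
      cl <- buildCloverleaf(.TRNA_ANTICODONS[[f$name]],
                            dhuLess = f$name == "trnS(AGN)", probs = probs)
      sense <- cl$seq
      meta$anticodon <- .TRNA_ANTICODONS[[f$name]]
      meta$acs <- cl$anticodon_start; meta$ace <- cl$anticodon_end
    } else if (f$klass == "PCG") {
      p <- .samplePCG(f$len, probs)
      sense <- p$seq
      meta$start_codon <- p$start_codon; meta$stop_codon <- p$stop_codon
    } else if (f$klass == "control_region") {
      n <- cfg$crLength
      if (cfg$crMotifs) {
        stemArm <- .sampleBases(7L, probs)
        planted <- paste0("TATA", .collapse(stemArm), .collapse(.sampleBases(6L, probs)),
                          .collapse(.revcompChars(stemArm)), "GAAAT",
                          "TTTTATTTTT")
        rest <- n - nchar(planted)
        if (rest < 0L) stop("control region too short for planted motifs", call. = FALSE)
        pre <- rest %/% 2L
        sense <- paste0(.collapse(.sampleBases(pre, probs)), planted,
                        .collapse(.sampleBases(rest - pre, probs)))
      } else {
        sense <- .collapse(.sampleBases(n, probs))
      }
    } else {
      sense <- .collapse(.sampleBases(f$len, probs))
    }
    strand <- if (is.na(f$strand)) NA_character_ else f$strand
    gseq <- if (identical(strand, "-")) reverseComplementSeq(sense) else sense
    parts[[length(parts) + 1L]] <- list(kind = "feature", name = f$name,
                                        klass = f$klass, strand = strand,
                                        seq = gseq, meta = meta)
    if (!is.null(cfg$tru) && identical(f$name, cfg$truHost)) {
      addSpacer(cfg$spacerLength)
      parts[[length(parts) + 1L]] <- list(
        kind = "feature", name = "TRU", klass = "repeat_region",
        strand = NA_character_, seq = .buildTruSequence(cfg$tru, probs),
        meta = list(anticodon = NA_character_, acs = NA_integer_, ace = NA_integer_,
                    start_codon = NA_character_, stop_codon = NA_character_))
    }
    if (i < nrow(skel)) addSpacer(cfg$spacerLength)
  }
  total <- sum(vapply(parts, function(p) nchar(p$seq), numeric(1)))
  if (!is.null(cfg$genomeLength)) {
    pad <- cfg$genomeLength - total
    if (pad < 0L) {
      stop(sprintf("features (%d bp) exceed requested genome length (%d bp)",
                   total, cfg$genomeLength), call. = FALSE)
    }
    if (pad > 0L) {
      crAt <- which(vapply(parts, function(p) identical(p$kind, "feature") &&
                             identical(p$klass, "control_region"), logical(1)))
      at <- if (length(crAt)) crAt[1L] else length(parts) + 1L
      parts <- append(parts, list(list(kind = "spacer",
                                       seq = .collapse(.sampleBases(pad, probs)))),
                      after = at - 1L)
    }
  }
  pos <- 1L
  rows <- list()
  seqs <- character(length(parts))
  for (k in seq_along(parts)) {
    p <- parts[[k]]
    seqs[k] <- p$seq
    len <- nchar(p$seq)
    if (identical(p$kind, "feature")) {
      acs <- ace <- NA_integer_
      if (!is.na(p$meta$acs)) {
        if (identical(p$strand, "-")) {
          e <- pos + len - 1L
          acs <- e - p$meta$ace + 1L
          ace <- e - p$meta$acs + 1L
        } else {
          acs <- pos + p$meta$acs - 1L
          ace <- pos + p$meta$ace - 1L
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        name = p$name, klass = p$klass, strand = p$strand,
        start = pos, end = pos + len - 1L,
        anticodon = p$meta$anticodon, anticodon_start = acs, anticodon_end = ace,
        start_codon = p$meta$start_codon, stop_codon = p$meta$stop_codon,
        stringsAsFactors = FALSE)
    }
    pos <- pos + len
  }
  annotatedGenome(do.call(rbind, rows), genomeLength = pos - 1L,
                  sequence = paste(seqs, collapse = ""), circular = TRUE)
}

# --- rearrangement scripts ---------------------------------------------------

.EVENT_TYPES <- c("invert", "translocate", "translocate_invert", "dup_loss_swap")

# indices (ancestral coordinates) a script event influences, with a guard zone
.eventZone <- function(ev, refGenes) {
  n <- length(refGenes)
  around <- function(i) unique(((i - 1L + c(-2L, -1L, 0L, 1L, 2L)) %% n) + 1L)
  z <- unlist(lapply(match(ev$genes, refGenes), around))
  if (!is.null(ev$after)) z <- c(z, around(match(ev$after, refGenes)))
  unique(z)
}

.applyScript <- function(order, script) {
  for (ev in script) {
    order <- switch(ev$type,
      invert = applyInversion(order, ev$genes),
      translocate = applyTranslocation(order, ev$genes, ev$after),
      translocate_invert = applyTranslocation(order, ev$genes, ev$after, invert = TRUE),
      dup_loss_swap = applyDupLoss(order, ev$genes, loseFirst = ev$genes[1L],
                                   loseSecond = ev$genes[2L]),
      stop(sprintf("unknown event type '%s'", ev$type), call. = FALSE))
  }
  order
}

.scriptTruth <- function(script, refGenes) {
  cls <- stats::setNames(rep("in_place", length(refGenes)), refGenes)
  for (ev in script) {
    cls[ev$genes] <- switch(ev$type,
      invert = "local_inversion",
      translocate = "translocated",
      translocate_invert = "shuffle_with_remote_inversion",
      dup_loss_swap = "translocated")
  }
  data.frame(gene = refGenes, class = unname(cls[refGenes]), stringsAsFactors = FALSE)
}

#' Generate a rearranged gene order with known ground truth
#'
#' Applies a rearrangement script to the ancestral insect order and emits the
#' per-gene event classes the script implies.  Events must be
#' non-interacting: the genes each event touches (with a two-gene guard zone
#' and the insertion target) may not overlap another event's zone, otherwise
#' the ground truth would be ambiguous and an error is thrown.
#'
#' Script events are lists with a `type` and parameters:
#' \describe{
#'   \item{`invert`}{`genes` = single gene flipped in place (local inversion);}
#'   \item{`translocate`}{contiguous `genes` moved after gene `after`
#'     (translocation, orientation kept);}
#'   \item{`translocate_invert`}{moved and inverted (shuffle with remote
#'     inversion);}
#'   \item{`dup_loss_swap`}{adjacent pair duplicated and randomly pruned to a
#'     swap; both genes translocated, one event.}
#' }
#'
#' @param script List of events, or `NULL` to sample one.
#' @param nEvents Number of events to sample when `script` is `NULL` (1-3).
#' @param seed Seed used when sampling a script (ignored for explicit scripts).
#' @return A list: `order` ([GeneOrder-class]), `truth` (data.frame of
#'   per-gene classes), `script`.
#' @export
#' @examples
#' gt <- generateOrder(list(list(type = "invert", genes = "trnE")))
#' subset(gt$truth, class != "in_place")
generateOrder <- function(script = NULL, nEvents = 1L, seed = NULL) {
  ref <- ancestralInsectOrder()
  refGenes <- orderGenes(ref)
  if (is.null(script)) {
    if (!is.null(seed)) set.seed(.checkSeed(seed))
    script <- .randomScript(nEvents, ref)
  }
  zones <- lapply(script, .eventZone, refGenes = refGenes)
  if (length(zones) > 1L) {
    for (i in seq_along(zones)) {
      for (j in seq_len(i - 1L)) {
        if (length(intersect(zones[[i]], zones[[j]]))) {
          stop("interacting events: ambiguous ground truth", call. = FALSE)
        }
      }
    }
  }
  if (any(vapply(script, function(e) "CR" %in% c(e$genes, e$after), logical(1)))) {
    stop("events may not involve the control region", call. = FALSE)
  }
  list(order = .applyScript(ref, script), truth = .scriptTruth(script, refGenes),
       script = script)
}

# sample a non-interacting random script over the ancestral order
.randomScript <- function(nEvents, ref) {
  refGenes <- orderGenes(ref)
  n <- length(refGenes)
  used <- integer(0)
  script <- list()
  tries <- 0L
  while (length(script) < nEvents && tries < 500L) {
    tries <- tries + 1L
    type <- sample(.EVENT_TYPES, 1L)
    i <- sample.int(n - 1L, 1L)             # never the control region (index n)
    ev <- switch(type,
      invert = list(type = type, genes = refGenes[i]),
      dup_loss_swap = {
        if (i >= n - 1L) next
        list(type = type, genes = refGenes[c(i, i + 1L)])
      },
      {
        blockLen <- sample(1:2, 1L)
        if (i + blockLen - 1L >= n) next
        target <- sample.int(n - 1L, 1L)
        dist <- min(abs(target - i), n - abs(target - i))
        if (dist < blockLen + 3L) next
        list(type = type, genes = refGenes[i:(i + blockLen - 1L)],
             after = refGenes[target])
      })
    zone <- .eventZone(ev, refGenes)
    if (length(intersect(zone, used))) next
    used <- c(used, zone)
    script[[length(script) + 1L]] <- ev
  }
  if (length(script) < nEvents) {
    stop("could not place non-interacting events", call. = FALSE)
  }
  script
}
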