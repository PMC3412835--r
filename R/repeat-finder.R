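# Tandem repeat unit (TRU) detection: self-alignment at candidate periods,
# maximal sliding-window identity runs, score-trimmed boundaries, consensus
# and partial-copy arithmetic.

# column-wise majority consensus over full copies (ties broken alphabetically)
.majorityConsensus <- function(v, start, unit, copies) {
  cons <- character(unit)
  for (k in seq_len(unit)) {
    col <- v[start + k - 1L + (seq_len(copies) - 1L) * unit]
    tab <- table(factor(col, levels = .BASES))
    cons[k] <- names(tab)[which.max(tab)]
  }
  cons
}

# maximum-scoring subarray (Kadane), leftmost maximal segment on ties;
# returns c(start, end, score) or NULL when every element is negative
.maxScoreSegment <- function(sc) {
  best <- 0; bi <- 0L; bj <- -1L
  cur <- 0; ci <- 1L
  for (t in seq_along(sc)) {
    if (cur < 0) { cur <- 0; ci <- t }
    cur <- cur + sc[t]
    if (cur > best || (cur == best && ci == bi && t > bj)) {
      best <- cur; bi <- ci; bj <- t
    }
  }
  if (bj < bi) return(NULL)
  c(bi, bj, best)
}

#' Detect tandem repeat units in a sequence
#'
#' For each candidate period \eqn{\ell} in `[minUnit, maxUnit]` the sequence
#' is aligned against itself at lag \eqn{\ell}.  A tandem-repeat candidate is
#' a maximal stretch over which every sliding \eqn{\ell}-window of that
#' self-alignment (equivalently, every adjacent-copy comparison) has identity
#' at least `minIdentity`.  Because a plain identity threshold would let a
#' boundary copy absorb up to `1 - minIdentity` of flanking noise, candidate
#' boundaries are then trimmed to the maximum-scoring segment of the
#' self-alignment (match +1, mismatch \eqn{-}`mismatchPenalty`), which pins
#' them to the true repeat edges.  The trimmed stretch of length \eqn{s}
#' contains \eqn{c = \lfloor s/\ell \rfloor} full copies plus a partial copy
#' of \eqn{p = s \bmod \ell} bp (the leftover lag-matched repeat content at
#' the boundary, i.e. a prefix of the repeat unit); the consensus is the
#' column-wise majority over the full copies.  Overlapping candidates are
#' resolved deterministically: periods that merely re-describe an overlapping
#' shorter-period repeat (span advantage less than one unit of the shorter
#' period) are suppressed as harmonics, then candidates are accepted
#' greedily by longest span, smallest unit, leftmost start.
#'
#' @param seq Nucleotide string (length at least `2 * minUnit`).
#' @param minUnit,maxUnit Period range searched (bp).  Defaults 10-600 span
#'   the repeat units reported in insect mitogenomes (135-, 189-, 297- and
#'   554-bp units) while excluding homopolymer noise.
#' @param minCopies Minimum number of full copies (>= 2).
#' @param minIdentity Minimum adjacent-copy identity fraction.
#' @param mismatchPenalty Boundary-trimming penalty per mismatching
#'   self-alignment column (default 3; matches score +1).
#' @param resolve When `FALSE`, return all qualifying per-period runs without
#'   overlap resolution (used for oracle comparisons).
#' @return data.frame with one row per repeat: `region_start`, `region_end`
#'   (1-based inclusive, including the partial copy), `unit_length`,
#'   `full_copies`, `partial_length`, `span` (= copies x unit + partial),
#'   `consensus`, `mean_copy_identity` (mean identity of adjacent full-copy
#'   comparisons).
#' @export
#' @examples
#' findTandemRepeats("ACACACACAC", minUnit = 2)
findTandemRepeats <- function(seq, minUnit = 10L, maxUnit = 600L, minCopies = 2L,
                              minIdentity = 0.85, mismatchPenalty = 3,
                              resolve = TRUE) {
  if (minUnit > maxUnit) stop("minUnit > maxUnit", call. = FALSE)
  if (minCopies < 2L) stop("minCopies must be >= 2", call. = FALSE)
  v <- .chars(seq)
  n <- length(v)
  empty <- data.frame(region_start = integer(0), region_end = integer(0),
                      unit_length = integer(0), full_copies = integer(0),
                      partial_length = integer(0), span = integer(0),
                      consensus = character(0), mean_copy_identity = numeric(0))
  if (n < 2L * minUnit) return(empty)
  thr <- minIdentity - 1e-12
  rows <- list()
  for (ell in minUnit:min(maxUnit, n %/% 2L)) {
    m <- v[seq_len(n - ell)] == v[(ell + 1L):n]
    nb <- n - 2L * ell + 1L
    if (nb < 1L) next
    cs <- c(0L, cumsum(m))
    bm <- (cs[seq_len(nb) + ell] - cs[seq_len(nb)]) / ell
    good <- bm >= thr
    r <- rle(good)
    rEnds <- cumsum(r$lengths)
    rStarts <- rEnds - r$lengths + 1L
    for (k in which(r$values)) {
      g1 <- rStarts[k]; g2 <- rEnds[k]
      if (g2 - g1 + 2L * ell < minCopies * ell) next
      seg <- m[g1:(g2 + ell - 1L)]
      sq <- .maxScoreSegment(ifelse(seg, 1, -mismatchPenalty))
      if (is.null(sq)) next
      a <- g1 + sq[1L] - 1L
      b <- g1 + sq[2L] - 1L
      span <- b + ell - a + 1L
      copies <- span %/% ell
      p <- span %% ell
      if (copies < minCopies) next
      anchors <- a + (seq_len(copies - 1L) - 1L) * ell
      meanId <- mean((cs[anchors + ell] - cs[anchors]) / ell)
      cons <- .majorityConsensus(v, a, ell, copies)
      rows[[length(rows) + 1L]] <- data.frame(
        region_start = as.integer(a), region_end = as.integer(a + span - 1L),
        unit_length = as.integer(ell), full_copies = as.integer(copies),
        partial_length = as.integer(p), span = as.integer(span),
        consensus = .collapse(cons), mean_copy_identity = meanId,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-out$span, out$unit_length, out$region_start), , drop = FALSE]
  rownames(out) <- NULL
  if (!resolve) return(out)
  # harmonic suppression: a repeat of period l is re-detected at overlapping
  # multiples of l whose span can differ only by boundary effects; keep the
  # fundamental (smaller) period unless the larger one explains at least one
  # extra unit of sequence
  drop <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    if (drop[i]) next
    for (j in seq_len(nrow(out))) {
      if (i == j || drop[j]) next
      if (out$unit_length[j] <= out$unit_length[i]) next
      overlap <- out$region_start[j] <= out$region_end[i] &&
        out$region_start[i] <= out$region_end[j]
      if (overlap && out$span[j] - out$span[i] < out$unit_length[i]) drop[j] <- TRUE
    }
  }
  out <- out[!drop, , drop = FALSE]
  keep <- logical(nrow(out))
  occ <- matrix(numeric(0), ncol = 2L)
  for (i in seq_len(nrow(out))) {
    a <- out$region_start[i]; b <- out$region_end[i]
    if (nrow(occ) == 0L || all(b < occ[, 1L] | a > occ[, 2L])) {
      keep[i] <- TRUE
      occ <- rbind(occ, c(a, b))
    }
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Characterise tandem repeats in the non-coding regions of a genome
#'
#' Runs [findTandemRepeats()] on every positive intergenic spacer long enough
#' to host a repeat and on each control-region feature, and reports detected
#' units in genome coordinates alongside the host region.  Regions are
#' extracted on the major strand with circular wrap, so results are invariant
#' under rotation of the sequence origin.
#'
#' @param g An [AnnotatedGenome-class] carrying a sequence.
#' @param minUnit,maxUnit,minCopies,minIdentity Passed to [findTandemRepeats()].
#' @return data.frame with `region` (label: "upstream-downstream" spacer or
#'   feature name), `region_start`, `region_end`, plus the columns of
#'   [findTandemRepeats()] mapped to genome coordinates (`start`, `end`
#'   normalised to `[1, genomeLength]`).
#' @export
characterizeTRU <- function(g, minUnit = 10L, maxUnit = 600L, minCopies = 2L,
                            minIdentity = 0.85) {
  if (is.null(genomeSequence(g))) stop("sequence-free genome", call. = FALSE)
  L <- genomeLength(g)
  ft <- featureTable(g)
  chain <- ft[ft$klass %in% c("PCG", "tRNA", "rRNA"), , drop = FALSE]
  regions <- list()
  if (nrow(chain) >= 2L) {
    ir <- intergenicRegions(g)$spacers
    for (i in seq_len(nrow(ir))) {
      if (ir$length[i] < 2L * minUnit) next
      up <- chain[chain$name == ir$upstream[i], ]
      a <- up$end + 1L
      b <- a + ir$length[i] - 1L
      regions[[length(regions) + 1L]] <- list(
        label = paste0(ir$upstream[i], "-", ir$downstream[i]), start = a, end = b)
    }
  }
  for (i in which(ft$klass == "control_region")) {
    regions[[length(regions) + 1L]] <- list(label = ft$name[i],
                                            start = ft$start[i], end = ft$end[i])
  }
  rows <- list()
  for (r in regions) {
    s <- extractRegion(g, r$start, r$end, "+")
    hits <- findTandemRepeats(s, minUnit, maxUnit, minCopies, minIdentity)
    if (!nrow(hits)) next
    norm <- function(p) ((r$start + p - 2L) %% L) + 1L
    hits$start <- vapply(hits$region_start, norm, numeric(1))
    hits$end <- vapply(hits$region_end, norm, numeric(1))
    hits$region <- r$label
    hits$region_start <- ((r$start - 1L) %% L) + 1L
    hits$region_end <- ((r$end - 1L) %% L) + 1L
    rows[[length(rows) + 1L]] <- hits
  }
  if (!length(rows)) {
    return(data.frame(region = character(0), region_start = integer(0),
                      region_end = integer(0), start = integer(0), end = integer(0),
                      unit_length = integer(0), full_copies = integer(0),
                      partial_length = integer(0), span = integer(0),
                      consensus = character(0), mean_copy_identity = numeric(0)))
  }
  out <- do.call(rbind, rows)
  cols <- c("region", "region_start", "region_end", "start", "end", "unit_length",
            "full_copies", "partial_length", "span", "consensus", "mean_copy_identity")
  out <- out[, cols, drop = FALSE]
  rownames(out) <- NULL
  out
}
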