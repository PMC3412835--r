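# Combinatorial motif scanning of non-coding sequence: tRNA-like cloverleaf
# candidates, stem-loops with conserved flanks, poly-T stretches, open
# reading frames, and global-alignment percent identity.
#
# Secondary structure is treated combinatorially (base-pairing constraints on
# arm lengths), not thermodynamically: the scanners assert what can fold, not
# how stably.

# base-pairing lookup over integer-coded bases (A=1, C=2, G=3, T=4)
.pairMatrix <- function(allowGU = TRUE) {
  P <- matrix(FALSE, 4L, 4L, dimnames = list(.BASES, .BASES))
  P["A", "T"] <- P["T", "A"] <- P["G", "C"] <- P["C", "G"] <- TRUE
  if (allowGU) P["G", "T"] <- P["T", "G"] <- TRUE
  P
}

# row-major flattening of the pair matrix for fast 1-D lookups
.pairVector <- function(allowGU = TRUE) as.vector(t(.pairMatrix(allowGU)))

# mismatches in a stem: 5' side starts at i5, 3' side *ends* at e3, length len;
# Pv is the flattened pair matrix and N bases count as mismatches
.stemMismatches <- function(si, i5, e3, len, Pv) {
  ok <- Pv[(si[i5 + 0:(len - 1L)] - 1L) * 4L + si[e3 - 0:(len - 1L)]]
  sum(is.na(ok) | !ok)
}

.pkgCache <- new.env(parent = emptyenv())

.geneticCode5 <- function() {
  if (is.null(.pkgCache$code5)) {
    .pkgCache$code5 <- Biostrings::getGeneticCode("5")   # invertebrate mitochondrial
  }
  .pkgCache$code5
}

# amino-acid letter inferred from an anticodon (5'->3')
.isotypeFromAnticodon <- function(anticodon) {
  codon <- .collapse(.revcompChars(.chars(anticodon)))
  aa <- unname(.geneticCode5()[codon])
  if (is.na(aa)) "?" else aa
}

# offset templates for the arms that flank the anticodon arm, relative to an
# anchor i (the first base of the anticodon 5' stem); computed once per
# parameter set
.cloverleafTemplates <- function(params) {
  key <- paste0("tpl_", params$varLoopMax, "_", isTRUE(params$dhuOptional))
  tpl <- .pkgCache[[key]]
  if (!is.null(tpl)) return(tpl)
  # downstream: variable loop (vlen), T-psi-C arm (stem t, loop tl)
  dnTab <- expand.grid(tl = 4:9, t = 3:5, vlen = 3:params$varLoopMax)
  dnTab <- as.matrix(dnTab[, c("vlen", "t", "tl")])
  relJ <- 17L + dnTab[, "vlen"]
  relAcc3 <- relJ + 2L * dnTab[, "t"] + dnTab[, "tl"]  # acceptor 3' side start
  dnTab <- cbind(dnTab, relAcc3 = relAcc3, relEnd = relAcc3 + 6L)
  nd <- nrow(dnTab)
  d5 <- unlist(lapply(seq_len(nd), function(k) relJ[k] + 0:(dnTab[k, "t"] - 1L)))
  d3 <- unlist(lapply(seq_len(nd), function(k) relAcc3[k] - 1L - 0:(dnTab[k, "t"] - 1L)))
  dId <- rep(seq_len(nd), dnTab[, "t"])
  # upstream: connector c2, DHU arm (stem d, loop dl) or bare loop (d = -1)
  upl <- list()
  for (c2 in 0:1) {
    for (d in 3:4) for (dl in 4:12) {
      upl[[length(upl) + 1L]] <- c(c2 = c2, d = d, dl = dl, block = 2L * d + dl)
    }
    if (isTRUE(params$dhuOptional)) {
      for (dlo in 7:14) {
        upl[[length(upl) + 1L]] <- c(c2 = c2, d = -1L, dl = dlo, block = dlo)
      }
    }
  }
  upTab <- do.call(rbind, upl)
  upTab <- cbind(upTab, relX = -(upTab[, "c2"] + upTab[, "block"]))  # x - i
  nu <- nrow(upTab)
  hasArm <- upTab[, "d"] > 0L
  u5 <- u3 <- integer(0)
  uId <- integer(0)
  for (k in which(hasArm)) {
    dd <- upTab[k, "d"]
    u5 <- c(u5, upTab[k, "relX"] + 0:(dd - 1L))
    u3 <- c(u3, -upTab[k, "c2"] - 1L - 0:(dd - 1L))
    uId <- c(uId, rep(k, dd))
  }
  tpl <- list(dnTab = dnTab, d5 = d5, d3 = d3, dId = dId,
              upTab = upTab, u5 = u5, u3 = u3, uId = uId)
  .pkgCache[[key]] <- tpl
  tpl
}

# core cloverleaf scan on one strand; returns, per (start, end), the
# best-scoring folding (fewest mismatches, then most paired bases);
# DHU-less foldings are coded dhu_stem = -1 internally
.scanCloverleafStrand <- function(v, params) {
  P <- .pairVector(params$allowGU)
  mm <- params$maxStemMismatch
  si <- match(v, .BASES)
  n <- length(v)
  if (n < 40L) return(NULL)
  tpl <- .cloverleafTemplates(params)
  nd <- nrow(tpl$dnTab)
  nu <- nrow(tpl$upTab)
  # vectorised anticodon-arm screen: stem 5 bp at [i, i+4] / [i+12, i+16]
  nA <- n - 16L
  acMM <- integer(nA)
  for (k in 0:4) {
    ok <- P[(si[(1L + k):(nA + k)] - 1L) * 4L + si[(17L - k):(nA + 16L - k)]]
    acMM <- acMM + (is.na(ok) | !ok)
  }
  acc <- vector("list", 64L)
  nacc <- 0L
  for (i in which(acMM <= mm)) {
    am <- acMM[i]
    # downstream arms, all combos at once
    validDn <- i + tpl$dnTab[, "relEnd"] <= n
    if (!any(validDn)) next
    okd <- P[(si[i + tpl$d5] - 1L) * 4L + si[pmin(i + tpl$d3, n)]]
    miss <- is.na(okd) | !okd
    tm <- tabulate(tpl$dId[miss], nbins = nd)
    dnOK <- which(validDn & tm <= mm)
    if (!length(dnOK)) next
    dnM <- cbind(tpl$dnTab[dnOK, , drop = FALSE],
                 acc3 = i + tpl$dnTab[dnOK, "relAcc3"], tm = tm[dnOK])
    # upstream arms
    validUp <- i + tpl$upTab[, "relX"] >= 2L
    if (!any(validUp)) next
    iu5 <- i + tpl$u5; iu5[iu5 < 1L] <- NA_integer_
    iu3 <- i + tpl$u3; iu3[iu3 < 1L] <- NA_integer_
    oku <- P[(si[iu5] - 1L) * 4L + si[iu3]]
    um <- tabulate(tpl$uId[is.na(oku) | !oku], nbins = nu)
    upOK <- which(validUp & (tpl$upTab[, "d"] < 0L | um <= mm))
    if (!length(upOK)) next
    upM <- cbind(tpl$upTab[upOK, , drop = FALSE],
                 x = i + tpl$upTab[upOK, "relX"],
                 dm = ifelse(tpl$upTab[upOK, "d"] < 0L, 0L, um[upOK]))
    # acceptor mismatches for the distinct (5' start, 3' start) pairs
    bs <- sort(unique(c(outer(upM[, "x"], 7L + 0:2, "-"))))
    bs <- bs[bs >= 1L]
    if (!length(bs)) next
    a3s <- sort(unique(dnM[, "acc3"]))
    # columns: the 3' acceptor side of each candidate end, read inward
    a3mat <- matrix(si[rep(a3s + 6L, each = 7L) - rep(0:6, length(a3s))],
                    nrow = 7L)
    accM <- matrix(NA_integer_, length(bs), length(a3s))
    for (bi in seq_along(bs)) {
      ok <- P[(si[bs[bi] + 0:6] - 1L) * 4L + a3mat]
      accM[bi, ] <- colSums(matrix(is.na(ok) | !ok, nrow = 7L))
    }
    a3idx <- match(dnM[, "acc3"], a3s)
    for (ui in seq_len(nrow(upM))) {
      u <- upM[ui, ]
      for (c1 in 0L:2L) {
        b <- u[["x"]] - c1 - 7L
        if (b < 1L) next
        accRow <- accM[match(b, bs), a3idx]
        ok <- accRow <= mm
        if (!any(ok)) next
        total <- accRow[ok] + am + dnM[ok, "tm"] + u[["dm"]]
        paired <- 12L + dnM[ok, "t"] + max(u[["d"]], 0L)
        nacc <- nacc + 1L
        if (nacc > length(acc)) acc <- c(acc, vector("list", length(acc)))
        acc[[nacc]] <- cbind(b, dnM[ok, "acc3"] + 6L, accRow[ok], u[["d"]], u[["dl"]],
                             i, dnM[ok, "vlen"], dnM[ok, "t"], dnM[ok, "tl"],
                             total, paired)
      }
    }
  }
  if (nacc == 0L) return(NULL)
  M <- do.call(rbind, acc[seq_len(nacc)])
  colnames(M) <- c("start", "end", "accmm", "dhu_stem", "dhu_loop", "anchor",
                   "vlen", "t", "tl", "mism", "paired")
  # keep the best folding per (start, end)
  o <- order(M[, "start"], M[, "end"], M[, "mism"], -M[, "paired"], -M[, "dhu_stem"])
  M <- M[o, , drop = FALSE]
  M <- M[!duplicated(M[, c("start", "end")]), , drop = FALSE]
  anticodon <- vapply(M[, "anchor"], function(i) .collapse(v[(i + 7L):(i + 9L)]),
                      character(1))
  data.frame(start = as.integer(M[, "start"]), end = as.integer(M[, "end"]),
             acceptor_stem = 7L,
             acceptor_mismatches = as.integer(M[, "accmm"]),
             dhu_stem = as.integer(ifelse(M[, "dhu_stem"] < 0L, NA, M[, "dhu_stem"])),
             dhu_loop = as.integer(M[, "dhu_loop"]), anticodon = anticodon,
             isotype = NA_character_, variable_loop = as.integer(M[, "vlen"]),
             tpsic_stem = as.integer(M[, "t"]), tpsic_loop = as.integer(M[, "tl"]),
             mismatches = as.integer(M[, "mism"]), paired = as.integer(M[, "paired"]),
             stringsAsFactors = FALSE)
}

#' Scan for tRNA-like cloverleaf structures
#'
#' Exhaustive arm-length-constrained search of both strands for sequences
#' foldable into a tRNA cloverleaf: a 7-bp acceptor stem, a DHU arm with a
#' 3-4-bp stem and 4-12-nt loop (or, when `dhuOptional`, a bare 7-14-nt DHU
#' loop, the form taken by serine-AGN tRNAs), a 5-bp anticodon stem with an
#' exactly 7-nt loop, a variable loop of 3 to `varLoopMax` nt (default 21,
#' accommodating the unusually long 19-20-nt variable loops seen in some
#' insect tRNAs), and a T-psi-C arm (3-5-bp stem, 4-9-nt loop).
#' Watson-Crick pairs, plus G-U wobble when `allowGU`, with at most
#' `maxStemMismatch` mismatches per stem.  The anticodon is read at loop
#' positions 3-5 (5'->3' on the coding strand) and its isotype inferred under
#' the invertebrate mitochondrial genetic code.
#'
#' @param seq Nucleotide string (>= 50 nt recommended).
#' @param allowGU Allow G-U wobble pairs (default `TRUE`).
#' @param maxStemMismatch Maximum mismatches tolerated per stem (default 1).
#' @param dhuOptional Also accept DHU-stem-less foldings (default `TRUE`).
#' @param varLoopMax Maximum variable-loop length (default 21 nt).
#' @return data.frame of candidates, deduplicated by (start, end, strand)
#'   keeping the fewest-mismatch folding, ranked by total mismatches then
#'   total paired bases: `start`, `end`, `strand`, stems/loops, `anticodon`,
#'   `isotype`, `mismatches`, `paired`.  `dhu_stem` is `NA` for DHU-less
#'   foldings.
#' @export
findCloverleaves <- function(seq, allowGU = TRUE, maxStemMismatch = 1L,
                             dhuOptional = TRUE, varLoopMax = 21L) {
  params <- list(allowGU = allowGU, maxStemMismatch = maxStemMismatch,
                 dhuOptional = dhuOptional, varLoopMax = varLoopMax)
  v <- .chars(seq)
  n <- length(v)
  res <- list()
  plus <- .scanCloverleafStrand(v, params)
  if (!is.null(plus)) {
    plus$strand <- "+"
    res[[length(res) + 1L]] <- plus
  }
  minus <- .scanCloverleafStrand(.revcompChars(v), params)
  if (!is.null(minus)) {
    s <- minus$start; e <- minus$end
    minus$start <- n - e + 1L
    minus$end <- n - s + 1L
    minus$strand <- "-"
    res[[length(res) + 1L]] <- minus
  }
  if (!length(res)) {
    return(data.frame(start = integer(0), end = integer(0), strand = character(0),
                      acceptor_stem = integer(0), acceptor_mismatches = integer(0),
                      dhu_stem = integer(0), dhu_loop = integer(0),
                      anticodon = character(0), isotype = character(0),
                      variable_loop = integer(0), tpsic_stem = integer(0),
                      tpsic_loop = integer(0), mismatches = integer(0),
                      paired = integer(0)))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$mismatches, -out$paired, is.na(out$dhu_stem)), , drop = FALSE]
  out <- out[!duplicated(out[, c("start", "end", "strand")]), , drop = FALSE]
  out$isotype <- vapply(out$anticodon, .isotypeFromAnticodon, character(1))
  out <- out[order(out$mismatches, -out$paired, out$start), , drop = FALSE]
  cols <- c("start", "end", "strand", "acceptor_stem", "acceptor_mismatches",
            "dhu_stem", "dhu_loop", "anticodon", "isotype", "variable_loop",
            "tpsic_stem", "tpsic_loop", "mismatches", "paired")
  out <- out[, cols, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percent identity under global alignment
#'
#' Needleman-Wunsch global alignment with match = 1, mismatch = 0 and linear
#' gap penalty -1; identity is the number of matched columns divided by the
#' alignment length.  Among score-optimal alignments the one with the most
#' matched columns (and, among those, the shortest alignment) is scored, a
#' deterministic and symmetric tie-break.
#'
#' @param a,b Non-empty nucleotide strings.
#' @return Identity fraction in `[0, 1]`.
#' @export
#' @examples
#' percentIdentity("AAAA", "AATA")   # 0.75
percentIdentity <- function(a, b) {
  va <- .chars(a); vb <- .chars(b)
  n <- length(va); m <- length(vb)
  if (n == 0L || m == 0L) stop("empty sequence", call. = FALSE)
  # per cell: best score; among optimal paths, max matches; then min length
  S <- matrix(0L, n + 1L, m + 1L)   # score
  Tm <- matrix(0L, n + 1L, m + 1L)  # matches
  Ln <- matrix(0L, n + 1L, m + 1L)  # alignment length
  S[, 1L] <- -(0:n); Ln[, 1L] <- 0:n
  S[1L, ] <- -(0:m); Ln[1L, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      eq <- va[i] == vb[j]
      cs <- c(S[i, j] + eq, S[i, j + 1L] - 1L, S[i + 1L, j] - 1L)
      ct <- c(Tm[i, j] + eq, Tm[i, j + 1L], Tm[i + 1L, j])
      cl <- c(Ln[i, j], Ln[i, j + 1L], Ln[i + 1L, j]) + 1L
      best <- which(cs == max(cs))
      best <- best[ct[best] == max(ct[best])]
      best <- best[which.min(cl[best])]
      S[i + 1L, j + 1L] <- cs[best]
      Tm[i + 1L, j + 1L] <- ct[best]
      Ln[i + 1L, j + 1L] <- cl[best]
    }
  }
  Tm[n + 1L, m + 1L] / Ln[n + 1L, m + 1L]
}

#' Scan a region for tRNA-like sequences and score them against real tRNAs
#'
#' Finds cloverleaf candidates in a genome region and pairs each with the
#' genome's own annotated tRNA sharing its inferred anticodon (falling back
#' to the highest-identity reference when no anticodon matches), reporting
#' the global-alignment identity between candidate and reference.  Repeated
#' candidates (one per tandem-repeat copy) are each reported.
#'
#' @param g An [AnnotatedGenome-class] carrying a sequence.
#' @param region Integer pair `c(start, end)` in genome coordinates, or a
#'   feature name.
#' @param references Optional named character vector of reference tRNA sense
#'   sequences; defaults to the genome's annotated tRNAs.
#' @param nonOverlapping Report only the best folding (fewest mismatches,
#'   most paired bases) among mutually overlapping candidates, so one hit is
#'   reported per locus (and hence per repeat copy); default `TRUE`.
#' @param ... Passed to [findCloverleaves()].
#' @return data.frame: candidate coordinates (genome scale), `anticodon`,
#'   `isotype`, `reference`, `identity`.
#' @export
scanRegionForTrnaLike <- function(g, region, references = NULL,
                                  nonOverlapping = TRUE, ...) {
  if (is.character(region) && length(region) == 1L) {
    ft <- featureTable(g)
    i <- match(region, ft$name)
    if (is.na(i)) stop(sprintf("unknown feature '%s'", region), call. = FALSE)
    region <- c(ft$start[i], ft$end[i])
  }
  if (is.null(references)) {
    ft <- featureTable(g)
    trn <- ft[ft$klass == "tRNA", , drop = FALSE]
    references <- stats::setNames(
      vapply(trn$name, function(nm) extractFeatureSequence(g, nm), character(1)),
      trn$name)
    names(references) <- trn$name
    attr(references, "anticodon") <- stats::setNames(trn$anticodon, trn$name)
  }
  refAnticodon <- attr(references, "anticodon")
  s <- extractRegion(g, region[1L], region[2L], "+")
  cand <- findCloverleaves(s, ...)
  if (!nrow(cand)) {
    return(data.frame(start = integer(0), end = integer(0), strand = character(0),
                      anticodon = character(0), isotype = character(0),
                      reference = character(0), identity = numeric(0)))
  }
  if (nonOverlapping) {
    cand <- cand[order(cand$mismatches, -cand$paired, cand$start), , drop = FALSE]
    keep <- logical(nrow(cand))
    occ <- matrix(numeric(0), ncol = 2L)
    for (k in seq_len(nrow(cand))) {
      a <- cand$start[k]; b <- cand$end[k]
      if (nrow(occ) == 0L || all(b < occ[, 1L] | a > occ[, 2L])) {
        keep[k] <- TRUE
        occ <- rbind(occ, c(a, b))
      }
    }
    cand <- cand[keep, , drop = FALSE]
    cand <- cand[order(cand$start), , drop = FALSE]
  }
  L <- genomeLength(g)
  off <- region[1L] - 1L
  cand$start <- ((cand$start + off - 1L) %% L) + 1L
  cand$end <- ((cand$end + off - 1L) %% L) + 1L
  ref <- character(nrow(cand)); ident <- numeric(nrow(cand))
  candSeq <- function(k) {
    a <- cand$start[k]; b <- cand$end[k]
    extractRegion(g, a, b, cand$strand[k])
  }
  for (k in seq_len(nrow(cand))) {
    hit <- if (!is.null(refAnticodon)) names(refAnticodon)[match(cand$anticodon[k], refAnticodon)] else NA_character_
    cs <- candSeq(k)
    if (!is.na(hit)) {
      ref[k] <- hit
      ident[k] <- percentIdentity(cs, references[[hit]])
    } else {
      ids <- vapply(references, function(r) percentIdentity(cs, r), numeric(1))
      ref[k] <- names(references)[which.max(ids)]
      ident[k] <- max(ids)
    }
  }
  data.frame(start = cand$start, end = cand$end, strand = cand$strand,
             anticodon = cand$anticodon, isotype = cand$isotype,
             reference = ref, identity = ident, stringsAsFactors = FALSE)
}

#' Scan for stem-loop (hairpin) structures
#'
#' Exhaustive inverted-repeat scan: for every possible loop interval of 3 to
#' `maxLoop` nt, the flanking stem is extended outwards pair by pair
#' (Watson-Crick plus G-U) for as long as at most `maxMismatch` mismatches
#' have accumulated and the outermost position is a true pair; loop intervals
#' whose maximal stem reaches `minStem` become candidates.  Each candidate is
#' annotated with the conserved control-region flanking motifs: `TATA`
#' ending within 10 nt upstream of the stem, and `G(A)nT` (n >= 2) starting
#' within 10 nt downstream.
#'
#' @param seq Nucleotide string.
#' @param minStem Minimum stem length (bp), default 5.
#' @param maxLoop Maximum loop length (nt), default 20 (minimum 3).
#' @param maxMismatch Mismatches tolerated in the stem, default 0.
#' @param allowGU Allow G-U pairs, default `TRUE`.
#' @return data.frame: `start`, `end`, `stem_length`, `loop_length`,
#'   `mismatches`, `flank_tata`, `flank_gant`, `gant_n`.
#' @export
#' @examples
#' findStemLoops("GGGGGAAATTCCCCC")   # stem 5, loop 5
findStemLoops <- function(seq, minStem = 5L, maxLoop = 20L, maxMismatch = 0L,
                          allowGU = TRUE) {
  v <- .chars(seq)
  n <- length(v)
  P <- .pairMatrix(allowGU)
  si <- match(v, .BASES)
  out <- list()
  for (lp in 3L:maxLoop) {
    for (ls in seq_len(max(0L, n - lp + 1L))) {
      le <- ls + lp - 1L
      k <- 0L; mism <- 0L; stem <- 0L; stemMism <- 0L
      while (ls - k - 1L >= 1L && le + k + 1L <= n) {
        k <- k + 1L
        a <- si[ls - k]; b <- si[le + k]
        ok <- if (is.na(a) || is.na(b)) FALSE else P[a, b]
        if (!ok) mism <- mism + 1L
        if (mism > maxMismatch) break
        if (ok) { stem <- k; stemMism <- mism }
      }
      if (stem < minStem) next
      hs <- ls - stem; he <- le + stem
      upw <- if (hs > 1L) .collapse(v[max(1L, hs - 13L):(hs - 1L)]) else ""
      tata <- grepl("TATA", upw, fixed = TRUE)
      dnw <- if (he < n) .collapse(v[(he + 1L):min(n, he + 14L)]) else ""
      m <- regmatches(dnw, regexec("G(A{2,})T", dnw))[[1L]]
      gant <- length(m) == 2L
      out[[length(out) + 1L]] <- data.frame(
        start = hs, end = he, stem_length = stem, loop_length = lp,
        mismatches = stemMism, flank_tata = tata, flank_gant = gant,
        gant_n = if (gant) nchar(m[2L]) else NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0), stem_length = integer(0),
                      loop_length = integer(0), mismatches = integer(0),
                      flank_tata = logical(0), flank_gant = logical(0),
                      gant_n = integer(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$loop_length), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Find poly-T stretches
#'
#' Maximal runs of T containing at most `maxInterruptions` non-T bases
#' (counted inclusively in the run length); runs start and end on a T.
#'
#' @param seq Nucleotide string.
#' @param minLen Minimum run length (>= 2), default 10.
#' @param maxInterruptions Maximum interrupting bases, default 1.
#' @return data.frame: `start`, `end`, `length`, `interruptions`.
#' @export
#' @examples
#' findPolyT("TTTTATTTTT", minLen = 10)   # one 10-bp run with one insertion
findPolyT <- function(seq, minLen = 10L, maxInterruptions = 1L) {
  if (minLen < 2L) stop("minLen must be >= 2", call. = FALSE)
  v <- .chars(seq)
  r <- rle(v == "T")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tIdx <- which(r$values)
  empty <- data.frame(start = integer(0), end = integer(0), length = integer(0),
                      interruptions = integer(0))
  if (!length(tIdx)) return(empty)
  cand <- list()
  for (ii in seq_along(tIdx)) {
    i <- tIdx[ii]
    gaps <- 0L
    jj <- ii
    while (jj < length(tIdx)) {
      between <- sum(r$lengths[(tIdx[jj] + 1L):(tIdx[jj + 1L] - 1L)])
      if (gaps + between > maxInterruptions) break
      gaps <- gaps + between
      jj <- jj + 1L
    }
    cand[[ii]] <- c(starts[i], ends[tIdx[jj]], gaps)
  }
  m <- do.call(rbind, cand)
  keep <- rep(TRUE, nrow(m))
  for (i in seq_len(nrow(m))) {
    contained <- m[, 1L] <= m[i, 1L] & m[, 2L] >= m[i, 2L]
    contained[i] <- FALSE
    if (any(contained)) keep[i] <- FALSE
  }
  m <- m[keep, , drop = FALSE]
  res <- data.frame(start = m[, 1L], end = m[, 2L],
                    length = m[, 2L] - m[, 1L] + 1L, interruptions = m[, 3L])
  res <- res[res$length >= minLen, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Find open reading frames
#'
#' Scans each frame of one or both strands for ORFs beginning at a
#' mitochondrial start codon and ending at a complete stop (TAA/TAG under
#' the invertebrate mitochondrial code) or, when `allowIncompleteStop`, at a
#' trailing incomplete stop `T`/`TA` flush with the region boundary (such
#' stops are completed by polyadenylation of the transcript).  `aa_length`
#' counts codons from the start codon inclusive up to the last full codon
#' before the stop.
#'
#' @param seq Nucleotide string (>= 6 nt).
#' @param strandBoth Scan the reverse complement too, default `TRUE`.
#' @param starts Allowed start codons.
#' @param allowIncompleteStop Accept boundary `T`/`TA` stops, default `TRUE`.
#' @return data.frame: `start`, `end` (coordinates on the input sequence,
#'   forward numbering), `strand`, `frame`, `start_codon`, `stop_codon`,
#'   `aa_length`.
#' @export
#' @examples
#' findOrfs("ATGAAATAA", strandBoth = FALSE)   # 2 aa, stop TAA
findOrfs <- function(seq, strandBoth = TRUE,
                     starts = c("ATG", "ATA", "ATT", "ATC", "TTG", "GTG"),
                     allowIncompleteStop = TRUE) {
  v0 <- .chars(seq)
  n <- length(v0)
  if (n < 6L) stop("sequence too short", call. = FALSE)
  scan1 <- function(v, strand) {
    res <- list()
    for (fr in 0L:2L) {
      nc <- (length(v) - fr) %/% 3L
      if (nc < 2L) next
      cod <- vapply(seq_len(nc), function(k) .collapse(v[fr + (3L * k - 2L):(3L * k)]),
                    character(1))
      tailRem <- if (fr + 3L * nc < length(v)) {
        .collapse(v[(fr + 3L * nc + 1L):length(v)])
      } else ""
      k <- 1L
      while (k <= nc) {
        if (cod[k] %in% starts) {
          stopAt <- k
          found <- FALSE
          for (q in (k + 1L):nc) {
            if (q > nc) break
            if (cod[q] %in% c("TAA", "TAG")) { stopAt <- q; found <- TRUE; break }
          }
          if (found) {
            res[[length(res) + 1L]] <- data.frame(
              s = fr + 3L * k - 2L, e = fr + 3L * stopAt, strand = strand, frame = fr + 1L,
              start_codon = cod[k], stop_codon = cod[stopAt], aa_length = stopAt - k,
              stringsAsFactors = FALSE)
            k <- stopAt + 1L
            next
          } else if (allowIncompleteStop && tailRem %in% c("T", "TA")) {
            res[[length(res) + 1L]] <- data.frame(
              s = fr + 3L * k - 2L, e = length(v), strand = strand, frame = fr + 1L,
              start_codon = cod[k], stop_codon = tailRem, aa_length = nc - k + 1L,
              stringsAsFactors = FALSE)
            k <- nc + 1L
            next
          }
        }
        k <- k + 1L
      }
    }
    if (length(res)) do.call(rbind, res) else NULL
  }
  out <- list(scan1(v0, "+"))
  if (strandBoth) {
    rc <- scan1(.revcompChars(v0), "-")
    if (!is.null(rc)) {
      s <- rc$s; e <- rc$e
      rc$s <- n - e + 1L
      rc$e <- n - s + 1L
      out[[2L]] <- rc
    }
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    return(data.frame(start = integer(0), end = integer(0), strand = character(0),
                      frame = integer(0), start_codon = character(0),
                      stop_codon = character(0), aa_length = integer(0)))
  }
  names(out)[names(out) == "s"] <- "start"
  names(out)[names(out) == "e"] <- "end"
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
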