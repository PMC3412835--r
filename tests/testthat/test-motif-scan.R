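# Motif scanning: cloverleaves, alignment identity, stem-loops, poly-T, ORFs.

test_that("a constructed cloverleaf is detected with its anticodon and isotype", {
  set.seed(3)
  cl <- buildCloverleaf("CAT")
  s <- paste0(randSeq(40), cl$seq, randSeq(40))
  hits <- findCloverleaves(s)
  expect_gt(nrow(hits), 0L)
  # the planted construct itself is among the zero-mismatch foldings
  planted <- hits[hits$start == 41L & hits$end == 40L + nchar(cl$seq) &
                    hits$strand == "+", ]
  expect_identical(nrow(planted), 1L)
  expect_identical(planted$anticodon, "CAT")
  expect_identical(planted$isotype, "M")
  expect_identical(planted$mismatches, 0L)
  # and the top-ranked candidate is a perfect CAT folding
  expect_identical(hits$anticodon[1], "CAT")
  expect_identical(hits$mismatches[1], 0L)
})

test_that("DHU-stem-less cloverleaves are detected when permitted", {
  set.seed(4)
  cl <- buildCloverleaf("GCT", dhuLess = TRUE)
  s <- paste0(randSeq(30), cl$seq, randSeq(30))
  hits <- findCloverleaves(s)
  top <- hits[hits$anticodon == "GCT" & hits$strand == "+", ][1, ]
  expect_identical(top$isotype, "S")
  expect_true(is.na(top$dhu_stem))
  # with dhuOptional off, no zero-mismatch folding of this construct exists
  strict <- findCloverleaves(s, dhuOptional = FALSE)
  expect_false(any(strict$strand == "+" & strict$anticodon == "GCT" &
                     strict$mismatches == 0))
})

test_that("every motif found on one strand mirrors onto the reverse complement", {
  set.seed(5)
  cl <- buildCloverleaf("TTC")
  s <- paste0(randSeq(35), cl$seq, randSeq(35))
  n <- nchar(s)
  fw <- findCloverleaves(s)
  rv <- findCloverleaves(reverseComplementSeq(s))
  mirror <- data.frame(start = n - rv$end + 1L, end = n - rv$start + 1L,
                       strand = ifelse(rv$strand == "+", "-", "+"),
                       anticodon = rv$anticodon)
  key <- function(d) sort(paste(d$start, d$end, d$strand, d$anticodon))
  expect_identical(key(fw), key(mirror))
})

test_that("randomised cloverleaf constructions are always detected", {
  set.seed(6)
  bases <- c("A", "C", "G", "T")
  for (k in 1:50) {
    ac <- paste(sample(bases, 3, replace = TRUE), collapse = "")
    cl <- buildCloverleaf(ac, dhuLess = k %% 7 == 0)
    s <- paste0(randSeq(25), cl$seq, randSeq(25))
    hits <- findCloverleaves(s)
    hit <- hits[hits$strand == "+" & hits$start == 26L &
                  hits$end == 25L + nchar(cl$seq), ]
    expect_identical(nrow(hit), 1L)
    expect_identical(hit$anticodon, ac)
  }
})

test_that("percent identity follows the global-alignment contract", {
  expect_identical(percentIdentity(strrep("ACGT", 18), strrep("ACGT", 18)), 1)
  expect_identical(percentIdentity("AAAA", "AATA"), 0.75)
  expect_error(percentIdentity("", "ACGT"), "empty")
  set.seed(7)
  for (k in 1:20) {
    a <- randSeq(sample(4:30, 1)); b <- randSeq(sample(4:30, 1))
    expect_equal(percentIdentity(a, b), percentIdentity(b, a))
    expect_identical(percentIdentity(a, a), 1)
    if (a != b && nchar(a) == nchar(b)) expect_lt(percentIdentity(a, b), 1)
  }
})

test_that("alignment score matches exhaustive enumeration on short sequences", {
  # brute force over all alignments (edit paths) with match 1 / mismatch 0 /
  # gap -1: best score, and the identity set of score-optimal paths
  bruteAlign <- function(a, b) {
    va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
    best <- new.env(parent = emptyenv()); best$score <- -Inf; best$ids <- numeric(0)
    rec <- function(i, j, score, matches, len) {
      if (i > length(va) && j > length(vb)) {
        if (score > best$score) { best$score <- score; best$ids <- matches / len }
        else if (score == best$score) best$ids <- c(best$ids, matches / len)
        return(invisible())
      }
      if (i <= length(va) && j <= length(vb)) {
        rec(i + 1, j + 1, score + (va[i] == vb[j]), matches + (va[i] == vb[j]), len + 1)
      }
      if (i <= length(va)) rec(i + 1, j, score - 1, matches, len + 1)
      if (j <= length(vb)) rec(i, j + 1, score - 1, matches, len + 1)
    }
    rec(1, 1, 0, 0, 0)
    list(score = best$score, identities = unique(best$ids))
  }
  set.seed(8)
  for (k in 1:25) {
    a <- randSeq(4); b <- randSeq(sample(3:5, 1))
    want <- bruteAlign(a, b)
    got <- percentIdentity(a, b)
    expect_true(any(abs(want$identities - got) < 1e-12))
  }
  expect_true(any(abs(bruteAlign("ACGT", "TGCA")$identities -
                        percentIdentity("ACGT", "TGCA")) < 1e-12))
})

test_that("hairpins are found with their conserved flanking motifs", {
  h <- findStemLoops("GGGGGAAATTCCCCC")
  expect_true(any(h$stem_length == 5L & h$loop_length == 5L &
                    h$start == 1L & h$end == 15L & h$mismatches == 0L))
  s <- paste0("CC", "TATA", "GGGGG", "CAACA", "CCCCC", "GAAAT", "CC")
  h2 <- findStemLoops(s, allowGU = FALSE)
  hit <- h2[h2$stem_length == 5L & h2$loop_length == 5L, ]
  expect_true(any(hit$flank_tata & hit$flank_gant))
  expect_identical(hit$gant_n[hit$flank_gant][1], 3L)
})

test_that("stem-loop candidates equal a brute-force enumeration", {
  # independent definition: for every loop interval, the maximal stem under
  # the mismatch budget whose outermost position pairs
  naiveStemLoops <- function(seq, minStem, maxLoop, maxMismatch) {
    v <- strsplit(seq, "")[[1]]
    n <- length(v)
    pair <- function(x, y) {
      (x == "A" && y == "T") || (x == "T" && y == "A") ||
        (x == "G" && y == "C") || (x == "C" && y == "G") ||
        (x == "G" && y == "T") || (x == "T" && y == "G")
    }
    out <- list()
    for (lp in 3:maxLoop) {
      for (ls in seq_len(max(0, n - lp + 1))) {
        le <- ls + lp - 1
        stem <- 0; mism <- 0; kept <- 0
        k <- 0
        while (ls - k - 1 >= 1 && le + k + 1 <= n) {
          k <- k + 1
          ok <- pair(v[ls - k], v[le + k])
          if (!ok) mism <- mism + 1
          if (mism > maxMismatch) break
          if (ok) { stem <- k; kept <- mism }
        }
        if (stem >= minStem) {
          out[[length(out) + 1]] <- c(ls - stem, le + stem, stem, lp, kept)
        }
      }
    }
    if (length(out)) do.call(rbind, out) else matrix(numeric(0), ncol = 5)
  }
  set.seed(9)
  s <- randSeq(120)
  got <- findStemLoops(s, minStem = 4, maxLoop = 12, maxMismatch = 1)
  want <- naiveStemLoops(s, 4, 12, 1)
  key <- function(m) sort(apply(m, 1, paste, collapse = "/"))
  expect_identical(key(as.matrix(got[, c("start", "end", "stem_length",
                                         "loop_length", "mismatches")])),
                   key(want))
})

test_that("poly-T stretches tolerate the configured interruptions", {
  r1 <- findPolyT(strrep("T", 10), minLen = 10, maxInterruptions = 0)
  expect_identical(nrow(r1), 1L)
  expect_identical(r1$length, 10L)
  r2 <- findPolyT("TTTTATTTTT", minLen = 10, maxInterruptions = 1)
  expect_identical(nrow(r2), 1L)
  expect_identical(c(r2$start, r2$end, r2$length, r2$interruptions),
                   c(1L, 10L, 10L, 1L))
  expect_identical(nrow(findPolyT("TTTTT", minLen = 10)), 0L)
  # runs start and end on a T and are maximal
  r3 <- findPolyT("AATTTTTTTTTTGG", minLen = 10, maxInterruptions = 1)
  expect_identical(c(r3$start, r3$end), c(3L, 12L))
})

test_that("open reading frames honour start sets and incomplete stops", {
  expect_identical(findOrfs("ATGAAATAA", strandBoth = FALSE)$aa_length, 2L)
  expect_identical(findOrfs("ATGAAATAA", strandBoth = FALSE)$stop_codon, "TAA")
  # TTG start + 42 sense codons + incomplete TA stop: 131 nt encoding 43 aa
  set.seed(10)
  sense <- character(0)
  while (length(sense) < 42) {
    cd <- randSeq(3)
    if (!(cd %in% c("TAA", "TAG", "ATG", "ATA", "ATT", "ATC", "TTG", "GTG"))) {
      sense <- c(sense, cd)
    }
  }
  region <- paste0("TTG", paste(sense, collapse = ""), "TA")
  expect_identical(nchar(region), 131L)
  orfs <- findOrfs(region, strandBoth = FALSE)
  uorf <- orfs[orfs$start == 1L, ]
  expect_identical(uorf$start_codon, "TTG")
  expect_identical(uorf$stop_codon, "TA")
  expect_identical(uorf$aa_length, 43L)
  expect_identical(uorf$end, 131L)
  # the incomplete-stop reading disappears when disallowed
  strict <- findOrfs(region, strandBoth = FALSE, allowIncompleteStop = FALSE)
  expect_identical(nrow(strict[strict$start == 1L, ]), 0L)
  expect_identical(nrow(findOrfs(strrep("CCC", 10), strandBoth = FALSE)), 0L)
})

test_that("tRNA-like scanning pairs candidates to references by anticodon", {
  cfg <- simulationConfig(seed = 5, tru = list(unit = 135, copies = 21, partial = 21,
                                               divergence = 0,
                                               cloverleafAnticodon = "TGC"))
  g <- generateGenome(cfg)
  rr <- featureTable(g)
  rr <- rr[rr$klass == "repeat_region", ]
  hits <- scanRegionForTrnaLike(g, c(rr$start, rr$end))
  planted <- hits[hits$anticodon == "TGC", ]
  expect_identical(nrow(planted), 21L)                # one per repeat copy
  expect_identical(unique(planted$reference), "trnA")
  expect_true(all(planted$identity > 0 & planted$identity <= 1))
  # anticodon GTA pairs to the tyrosine tRNA reference
  refs <- c(trnY = "ACGTACGT")
  attr(refs, "anticodon") <- c(trnY = "GTA")
  set.seed(12)
  cl <- buildCloverleaf("GTA")
  g2 <- tinyGenome(paste0(randSeq(20), cl$seq, randSeq(20)),
                   data.frame(name = "spacer", klass = "other", strand = NA,
                              start = 1L, end = 40L + nchar(cl$seq)))
  h2 <- scanRegionForTrnaLike(g2, c(1L, genomeLength(g2)), references = refs)
  expect_true(all(h2$reference[h2$anticodon == "GTA"] == "trnY"))
  # a region that cannot base-pair yields no candidates
  g3 <- tinyGenome(strrep("A", 120),
                   data.frame(name = "x", klass = "other", strand = NA,
                              start = 1L, end = 120L))
  expect_identical(nrow(scanRegionForTrnaLike(g3, c(1L, 120L), references = refs)), 0L)
})
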