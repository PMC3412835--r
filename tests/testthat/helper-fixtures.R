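# Shared fixture builders. All randomness is seeded inside each test.

randSeq <- function(n, probs = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs), collapse = "")
}

mutateSeq <- function(x, rate) {
  v <- strsplit(x, "")[[1]]
  k <- stats::rbinom(1L, length(v), rate)
  if (k > 0L) {
    at <- sample(length(v), k)
    for (p in at) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
  }
  paste(v, collapse = "")
}

# the canonical planted-repeat construction: copies of a unit plus a partial
# leading prefix of the unit, embedded in random flanks
plantedRepeat <- function(unitLen, copies, partial, flank = 500L, divergence = 0) {
  unit <- randSeq(unitLen)
  cps <- vapply(seq_len(copies), function(i) {
    if (divergence > 0) mutateSeq(unit, divergence) else unit
  }, character(1))
  list(unit = unit,
       seq = paste0(randSeq(flank), paste(cps, collapse = ""),
                    substr(unit, 1L, partial), randSeq(flank)),
       region_start = flank + 1L,
       span = copies * unitLen + partial)
}

# a tiny sequence-bearing genome wrapping the given features
tinyGenome <- function(seq, features) {
  annotatedGenome(features, genomeLength = nchar(seq), sequence = seq)
}

# rotate the origin of a circular annotated genome by r bases
rotateGenome <- function(g, r) {
  L <- genomeLength(g)
  s <- genomeSequence(g)
  newSeq <- paste0(substr(s, r + 1L, L), substr(s, 1L, r))
  ft <- featureTable(g)
  shift <- function(p) ((p - r - 1L) %% L) + 1L
  ft$start <- shift(ft$start)
  end0 <- ifelse(ft$end > L, ft$end - L, ft$end)
  ft$end <- shift(end0)
  wraps <- ft$end < ft$start
  ft$end[wraps] <- ft$end[wraps] + L
  if (any(!is.na(ft$anticodon_start))) {
    i <- !is.na(ft$anticodon_start)
    ft$anticodon_start[i] <- shift(ft$anticodon_start[i])
    ft$anticodon_end[i] <- shift(ft$anticodon_end[i])
    w <- i & ft$anticodon_end < ft$anticodon_start
    ft$anticodon_end[w] <- ft$anticodon_end[w] + L
  }
  annotatedGenome(ft, genomeLength = L, sequence = newSeq)
}

# published gene order of the earwig mitogenome, for rearrangement tests
earwigOrder <- function() orderFromGenome(earwigGenome())

# the k genes circularly following `gene` in a GeneOrder
nextGenes <- function(ord, gene, k) {
  g <- orderGenes(ord)
  n <- length(g)
  i <- match(gene, g)
  g[((i - 1L + seq_len(k)) %% n) + 1L]
}
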