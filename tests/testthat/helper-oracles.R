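# Independent brute-force re-derivation of the repeat-detector contract with
# plain loops: for one period, maximal stretches of adjacent-copy identity
# >= thr, trimmed to the maximum-scoring self-alignment segment.
naiveRepeatRuns <- function(seq, ell, minCopies, thr, penalty = 3) {
  v <- strsplit(seq, "")[[1]]
  n <- length(v)
  nb <- n - 2 * ell + 1
  if (nb < 1) return(NULL)
  good <- logical(nb)
  for (i in seq_len(nb)) {
    good[i] <- mean(v[i:(i + ell - 1)] == v[(i + ell):(i + 2 * ell - 1)]) >= thr - 1e-12
  }
  res <- list()
  i <- 1
  while (i <= nb) {
    if (!good[i]) { i <- i + 1; next }
    j <- i
    while (j < nb && good[j + 1]) j <- j + 1
    # score every subsegment of the matched stretch, pick the best
    seg <- v[i:(j + ell - 1)] == v[(i + ell):(j + 2 * ell - 1)]
    sc <- ifelse(seg, 1, -penalty)
    best <- 0; ba <- 0; bb <- -1
    for (a in seq_along(sc)) {
      tot <- 0
      for (b in a:length(sc)) {
        tot <- tot + sc[b]
        if (tot > best || (tot == best && a == ba && b > bb)) {
          best <- tot; ba <- a; bb <- b
        }
      }
    }
    if (bb >= ba) {
      span <- bb + ell - ba + 1
      copies <- span %/% ell
      if (copies >= minCopies) {
        res[[length(res) + 1]] <- c(start = i + ba - 1, span = span,
                                    copies = copies, partial = span %% ell)
      }
    }
    i <- j + 1
  }
  if (length(res)) do.call(rbind, res) else NULL
}
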