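# Signed circular gene-order model: the ancestral insect arrangement,
# per-gene rearrangement classification against it, duplication/random-loss
# and inversion/translocation operators, and breakpoint counting.

.ANCESTRAL_GENES <- c(
  "trnI", "trnQ", "trnM", "nad2", "trnW", "trnC", "trnY", "cox1", "trnL(UUR)",
  "cox2", "trnK", "trnD", "atp8", "atp6", "cox3", "trnG", "nad3", "trnA",
  "trnR", "trnN", "trnS(AGN)", "trnE", "trnF", "nad5", "trnH", "nad4",
  "nad4L", "trnT", "trnP", "nad6", "cytb", "trnS(UCN)", "nad1", "trnL(CUN)",
  "rrnL", "trnV", "rrnS", "CR")
.ANCESTRAL_ORI <- c(
  "+", "-", "+", "+", "+", "-", "-", "+", "+",
  "+", "+", "+", "+", "+", "+", "+", "+", "+",
  "+", "+", "+", "+", "-", "-", "-", "-",
  "-", "+", "-", "+", "+", "+", "-", "-",
  "-", "-", "-", "+")

#' The ancestral insect mitochondrial gene order
#'
#' The arrangement shared by most insects (identical to that of Drosophila):
#' 37 genes plus the control region ("CR"), with coding-strand orientations
#' on the major-strand convention.
#'
#' @return A [GeneOrder-class] of 38 elements.
#' @export
#' @examples
#' head(orderGenes(ancestralInsectOrder()))
ancestralInsectOrder <- function() {
  geneOrder(.ANCESTRAL_GENES, .ANCESTRAL_ORI)
}

#' Gene order of an annotated genome
#'
#' Elements in ascending start order with orientation taken from the coding
#' strand; the control region is kept (as "CR"), repeat regions and
#' unclassified features are dropped.
#'
#' @param g An [AnnotatedGenome-class].
#' @return A [GeneOrder-class].
#' @export
orderFromGenome <- function(g) {
  ft <- featureTable(g)
  keep <- ft[ft$klass %in% c("PCG", "tRNA", "rRNA", "control_region"), , drop = FALSE]
  nm <- ifelse(keep$klass == "control_region", "CR", keep$name)
  if (anyDuplicated(nm)) {
    stop(sprintf("duplicate gene name(s) in order: %s",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")), call. = FALSE)
  }
  ori <- ifelse(is.na(keep$strand), "+", keep$strand)
  geneOrder(nm, ori)
}

# canonical signed adjacency labels of a circular order (reading-direction
# independent: x>y is identified with -y>-x)
.adjacencies <- function(genes, ori) {
  n <- length(genes)
  nxt <- c(2:n, 1L)
  flip <- function(o) ifelse(o == "+", "-", "+")
  a1 <- paste0(ori, genes, ">", ori[nxt], genes[nxt])
  a2 <- paste0(flip(ori[nxt]), genes[nxt], ">", flip(ori), genes)
  pmin(a1, a2)
}

#' Breakpoint count between two signed circular gene orders
#'
#' The number of signed circular adjacencies of `a` absent from `b` (an
#' adjacency and its reverse-complement reading are identified).
#'
#' @param a,b [GeneOrder-class] objects over the same gene set.
#' @return Integer breakpoint count.
#' @export
#' @examples
#' breakpointCount(ancestralInsectOrder(), ancestralInsectOrder())   # 0
breakpointCount <- function(a, b) {
  ga <- orderGenes(a); gb <- orderGenes(b)
  if (!setequal(ga, gb) || length(ga) != length(gb)) {
    stop(sprintf("gene sets differ: only in first: %s; only in second: %s",
                 paste(setdiff(ga, gb), collapse = ","),
                 paste(setdiff(gb, ga), collapse = ",")), call. = FALSE)
  }
  sum(!(.adjacencies(ga, orientations(a)) %in% .adjacencies(gb, orientations(b))))
}

# restrict a circular order to a gene subset, preserving cyclic order
.restrict <- function(genes, ori, keep) {
  i <- which(genes %in% keep)
  list(genes = genes[i], ori = ori[i])
}

# cyclic equality of two (gene, orientation) sequences over the same set
.cyclicEqual <- function(a, b) {
  n <- length(a$genes)
  if (n != length(b$genes)) return(FALSE)
  if (n == 0L) return(TRUE)
  i <- match(a$genes[1L], b$genes)
  if (is.na(i)) return(FALSE)
  rot <- c(i:n, if (i > 1L) 1:(i - 1L))
  all(b$genes[rot] == a$genes) && all(b$ori[rot] == a$ori)
}

.klassOfLabel <- function(name) {
  if (name == "CR") "control_region" else .inferKlass(name)
}

# nearest backbone neighbours (prev, next) of gene g in a circular order
.backboneInterval <- function(genes, g, backbone) {
  n <- length(genes)
  i <- match(g, genes)
  prv <- i
  repeat {
    prv <- if (prv == 1L) n else prv - 1L
    if (genes[prv] %in% backbone) break
  }
  nxt <- i
  repeat {
    nxt <- if (nxt == n) 1L else nxt + 1L
    if (genes[nxt] %in% backbone) break
  }
  c(genes[prv], genes[nxt])
}

#' Classify gene-order rearrangements against a reference order
#'
#' Finds the largest "in place" backbone: the maximal gene set whose
#' restriction of the observed circular order (gene labels and orientations)
#' equals the restriction of the ancestral order.  The backbone is computed
#' exactly by exhaustive search over flag sets seeded by broken adjacencies
#' and orientation changes, with deterministic tie-breaking (prefer keeping
#' protein-coding/rRNA genes as anchors, then the lexicographically smallest
#' flagged set).  Every flagged gene is then classified by how it moved:
#' \describe{
#'   \item{translocated}{orientation unchanged, adjacency context changed;}
#'   \item{local_inversion}{orientation flipped within the same
#'     inter-backbone interval (same nearest backbone neighbours);}
#'   \item{shuffle_with_remote_inversion}{orientation flipped and moved to a
#'     different interval.}
#' }
#' When a flagged gene and a backbone neighbour form an adjacent swap (either
#' one could equally have been flagged), both genes are reported as
#' translocated but the swap counts as a single translocation event, so gene
#' counts follow the convention of rearrangement maps (both members of a
#' swapped pair are marked) while event counts match mechanism bookkeeping
#' (one duplication/random-loss event per swap).  The control region anchors
#' the backbone and is never classified as rearranged.
#'
#' @param observed,ancestral [GeneOrder-class] objects over the same gene set.
#' @return A list of class `rearrangementReport`: `table` (per-gene classes
#'   and neighbour context), `summary` (counts per class), `events`
#'   (data.frame of grouped events), `backbone` (in-place gene labels).
#' @export
#' @examples
#' rep <- compareOrders(ancestralInsectOrder(), ancestralInsectOrder())
#' rep$summary
compareOrders <- function(observed, ancestral) {
  gO <- orderGenes(observed); oO <- orientations(observed)
  gA <- orderGenes(ancestral); oA <- orientations(ancestral)
  if (!setequal(gO, gA) || length(gO) != length(gA)) {
    stop(sprintf("gene sets differ: only in observed: %s; only in ancestral: %s",
                 paste(setdiff(gO, gA), collapse = ","),
                 paste(setdiff(gA, gO), collapse = ",")), call. = FALSE)
  }
  oriA <- stats::setNames(oA, gA)
  oriO <- stats::setNames(oO, gO)
  flipped <- gA[oriO[gA] != oriA[gA]]
  if ("CR" %in% flipped) stop("control region orientation change is unsupported", call. = FALSE)

  adjA <- .adjacencies(gA, oA)
  adjO <- .adjacencies(gO, oO)
  brokenO <- which(!(adjO %in% adjA))
  brokenA <- which(!(adjA %in% adjO))
  nO <- length(gO); nA <- length(gA)
  incident <- unique(c(
    gO[brokenO], gO[ifelse(brokenO == nO, 1L, brokenO + 1L)],
    gA[brokenA], gA[ifelse(brokenA == nA, 1L, brokenA + 1L)]))
  pool <- setdiff(unique(c(flipped, incident)), "CR")
  mandatory <- setdiff(flipped, "CR")
  free <- setdiff(pool, mandatory)

  validFlag <- function(F) {
    keep <- setdiff(gA, F)
    .cyclicEqual(.restrict(gA, oA, keep),
                 .restrict(gO, oO, keep))
  }
  chooseBest <- function(cands) {
    if (length(cands) == 1L) return(cands[[1L]])
    anchorCost <- vapply(cands, function(F) {
      sum(vapply(F, function(g) .klassOfLabel(g) %in% c("PCG", "rRNA"), logical(1)))
    }, numeric(1))
    cands <- cands[anchorCost == min(anchorCost)]
    keys <- vapply(cands, function(F) paste(sort(F), collapse = "|"), character(1))
    cands[[order(keys)[1L]]]
  }
  flagSet <- NULL
  for (k in length(mandatory):(length(mandatory) + length(free))) {
    extra <- k - length(mandatory)
    subsets <- if (extra == 0L) list(character(0)) else {
      if (length(free) < extra) break
      asplit(utils::combn(sort(free), extra), 2L)
    }
    valid <- Filter(function(s) validFlag(c(mandatory, s)), subsets)
    if (length(valid)) {
      flagSet <- c(mandatory, chooseBest(valid))
      break
    }
  }
  if (is.null(flagSet)) {
    stop("could not resolve a consistent in-place backbone", call. = FALSE)
  }

  # adjacent-swap expansion: if a backbone neighbour could equally have been
  # flagged in place of g, both belong to one swap event
  swapPartner <- stats::setNames(rep(NA_character_, length(flagSet)), flagSet)
  partners <- character(0)
  for (g in flagSet) {
    if (oriO[g] != oriA[g]) next
    iO <- match(g, gO); iA <- match(g, gA)
    nbrs <- unique(c(gO[c(ifelse(iO == 1L, nO, iO - 1L), ifelse(iO == nO, 1L, iO + 1L))],
                     gA[c(ifelse(iA == 1L, nA, iA - 1L), ifelse(iA == nA, 1L, iA + 1L))]))
    nbrs <- setdiff(nbrs, c(flagSet, partners, "CR"))
    for (h in nbrs) {
      if (oriO[h] != oriA[h]) next
      if (validFlag(c(setdiff(flagSet, g), h))) {
        swapPartner[g] <- h
        partners <- c(partners, h)
        break
      }
    }
  }

  moved <- c(flagSet, partners)
  backbone <- setdiff(gA, moved)
  cls <- stats::setNames(rep("in_place", length(gA)), gA)
  intA <- intO <- stats::setNames(rep(NA_character_, length(gA)), gA)
  for (g in moved) {
    ia <- .backboneInterval(gA, g, backbone)
    io <- .backboneInterval(gO, g, backbone)
    intA[g] <- paste(ia, collapse = "..")
    intO[g] <- paste(io, collapse = "..")
    if (oriO[g] == oriA[g]) {
      cls[g] <- "translocated"
    } else if (identical(ia, io)) {
      cls[g] <- "local_inversion"
    } else {
      cls[g] <- "shuffle_with_remote_inversion"
    }
  }

  events <- list()
  done <- character(0)
  for (g in names(swapPartner)) {
    if (!is.na(swapPartner[g])) {
      events[[length(events) + 1L]] <- data.frame(
        type = "translocation_swap", genes = paste(g, swapPartner[g], sep = ","),
        stringsAsFactors = FALSE)
      done <- c(done, g, swapPartner[g])
    }
  }
  for (g in setdiff(moved, done)) {
    events[[length(events) + 1L]] <- data.frame(
      type = switch(cls[g],
                    translocated = "translocation",
                    local_inversion = "inversion",
                    shuffle_with_remote_inversion = "shuffle_with_remote_inversion"),
      genes = g, stringsAsFactors = FALSE)
  }
  events <- if (length(events)) do.call(rbind, events) else {
    data.frame(type = character(0), genes = character(0))
  }

  tab <- data.frame(
    gene = gA,
    klass = vapply(gA, .klassOfLabel, character(1)),
    orientation_ancestral = unname(oriA[gA]),
    orientation_observed = unname(oriO[gA]),
    class = unname(cls[gA]),
    interval_ancestral = unname(intA[gA]),
    interval_observed = unname(intO[gA]),
    stringsAsFactors = FALSE)
  lev <- c("in_place", "translocated", "local_inversion", "shuffle_with_remote_inversion")
  structure(list(
    table = tab,
    summary = as.list(table(factor(tab$class, levels = lev))),
    events = events,
    backbone = backbone,
    breakpoints = breakpointCount(observed, ancestral)
  ), class = "rearrangementReport")
}

#' @export
print.rearrangementReport <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Rearrangement report: %d in place, %d translocated, %d local inversions, %d shuffles with remote inversion (%d breakpoints)\n",
              s$in_place, s$translocated, s$local_inversion,
              s$shuffle_with_remote_inversion, x$breakpoints))
  mv <- x$table[x$table$class != "in_place", ]
  for (i in seq_len(nrow(mv))) {
    cat(sprintf("  %-28s %-10s %s -> %s\n", mv$class[i], mv$gene[i],
                mv$interval_ancestral[i], mv$interval_observed[i]))
  }
  invisible(x)
}

# contiguous run of genes in circular order; returns start index or NULL
.segmentStart <- function(genes, segment) {
  n <- length(genes)
  i <- match(segment[1L], genes)
  if (is.na(i)) return(NULL)
  idx <- ((i - 1L + seq_along(segment) - 1L) %% n) + 1L
  if (all(genes[idx] == segment)) i else NULL
}

#' Tandem duplication followed by random loss
#'
#' Duplicates a contiguous gene block in tandem and deletes the named genes
#' from each copy; the deletion pattern must leave exactly one surviving copy
#' of every gene in the block.  Orientations are carried through unchanged.
#'
#' @param order A [GeneOrder-class].
#' @param block Character vector, contiguous in `order`.
#' @param loseFirst,loseSecond Genes deleted from the first and second copy;
#'   together they must partition `block`.
#' @return The resulting [GeneOrder-class].
#' @export
#' @examples
#' o <- applyDupLoss(ancestralInsectOrder(), c("trnR", "trnN"),
#'                   loseFirst = "trnR", loseSecond = "trnN")
applyDupLoss <- function(order, block, loseFirst, loseSecond) {
  genes <- orderGenes(order); ori <- orientations(order)
  i <- .segmentStart(genes, block)
  if (is.null(i)) stop("block is not contiguous in the order", call. = FALSE)
  if (length(intersect(loseFirst, loseSecond)) ||
      !setequal(c(loseFirst, loseSecond), block)) {
    stop("deletions must partition the block so each gene survives exactly once",
         call. = FALSE)
  }
  n <- length(genes)
  idx <- ((i - 1L + seq_along(block) - 1L) %% n) + 1L
  keep1 <- idx[!(genes[idx] %in% loseFirst)]
  keep2 <- idx[!(genes[idx] %in% loseSecond)]
  rest <- setdiff(seq_len(n), idx)
  # rebuild starting just after the block, then append both surviving copies
  after <- idx[length(idx)]
  ordRest <- integer(0)
  p <- after
  repeat {
    p <- if (p == n) 1L else p + 1L
    if (p %in% idx) break
    ordRest <- c(ordRest, p)
    if (length(ordRest) == length(rest)) break
  }
  newIdx <- c(keep1, keep2, ordRest)
  outG <- genes[newIdx]; outO <- ori[newIdx]
  # keep the caller's origin so linear indexing stays comparable
  o <- match(genes[1L], outG)
  rot <- c(o:length(outG), if (o > 1L) 1:(o - 1L))
  geneOrder(outG[rot], outO[rot])
}

#' Invert a contiguous segment
#'
#' Reverses the segment's order and flips every orientation (one
#' intramitochondrial recombination).  Applying the same inversion twice is
#' the identity.
#'
#' @param order A [GeneOrder-class].
#' @param segment Character vector contiguous in `order`.
#' @return The resulting [GeneOrder-class].
#' @export
applyInversion <- function(order, segment) {
  genes <- orderGenes(order); ori <- orientations(order)
  i <- .segmentStart(genes, segment)
  if (is.null(i)) stop("segment is not contiguous in the order", call. = FALSE)
  n <- length(genes)
  idx <- ((i - 1L + seq_along(segment) - 1L) %% n) + 1L
  genes[idx] <- rev(genes[idx])
  ori[idx] <- rev(ifelse(ori[idx] == "+", "-", "+"))
  geneOrder(genes, ori)
}

#' Translocate a contiguous segment
#'
#' Moves the segment intact to follow gene `after` (optionally inverting it
#' in transit, i.e. a shuffle with remote inversion).
#'
#' @param order A [GeneOrder-class].
#' @param segment Character vector contiguous in `order`.
#' @param after Gene label the segment is inserted after (not in segment).
#' @param invert Also invert the segment, default `FALSE`.
#' @return The resulting [GeneOrder-class].
#' @export
applyTranslocation <- function(order, segment, after, invert = FALSE) {
  genes <- orderGenes(order); ori <- orientations(order)
  i <- .segmentStart(genes, segment)
  if (is.null(i)) stop("segment is not contiguous in the order", call. = FALSE)
  if (after %in% segment) stop("'after' must lie outside the segment", call. = FALSE)
  n <- length(genes)
  idx <- ((i - 1L + seq_along(segment) - 1L) %% n) + 1L
  segG <- genes[idx]; segO <- ori[idx]
  if (invert) {
    segG <- rev(segG)
    segO <- rev(ifelse(segO == "+", "-", "+"))
  }
  gR <- genes[-idx]; oR <- ori[-idx]
  j <- match(after, gR)
  geneOrder(append(gR, segG, after = j), append(oR, segO, after = j))
}
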