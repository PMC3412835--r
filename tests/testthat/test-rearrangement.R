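# Gene-order model, event classification, operators, breakpoint counting.

test_that("the built-in ancestral order has the canonical structure", {
  anc <- ancestralInsectOrder()
  g <- orderGenes(anc)
  expect_identical(length(anc), 38L)
  expect_identical(anyDuplicated(g), 0L)
  # trnK immediately precedes trnD; trnA-trnR-trnN run as a block
  expect_identical(g[which(g == "trnK") + 1L], "trnD")
  expect_identical(g[which(g == "trnA") + 1:2], c("trnR", "trnN"))
  expect_identical(orientations(anc)[match(c("trnQ", "trnE", "nad5", "cox1"), g)],
                   c("-", "+", "-", "+"))
})

test_that("gene orders derive from annotations and compare rotation-invariantly", {
  obs <- earwigOrder()
  expect_identical(orderGenes(obs)[1:5], c("trnM", "nad2", "trnI", "trnW", "cox1"))
  expect_identical(length(obs), 38L)                   # TRU dropped, CR kept
  # rotation does not change the circular order
  g <- orderGenes(obs); o <- orientations(obs)
  rot <- c(9:38, 1:8)
  expect_true(sameGeneOrder(obs, geneOrder(g[rot], o[rot])))
  expect_false(sameGeneOrder(obs, ancestralInsectOrder()))
  # a genome missing one tRNA still yields a (shorter) order
  ft <- featureTable(earwigGenome())
  g37 <- annotatedGenome(ft[ft$name != "trnI", ], genomeLength = 20456L)
  expect_identical(length(orderFromGenome(g37)), 37L)
})

test_that("comparing an order to itself reports no events", {
  rep <- compareOrders(ancestralInsectOrder(), ancestralInsectOrder())
  expect_identical(rep$summary$in_place, 38L)
  expect_identical(nrow(rep$events), 0L)
  expect_identical(rep$breakpoints, 0L)
})

test_that("the earwig order is classified exactly as the rearrangement map", {
  rep <- compareOrders(earwigOrder(), ancestralInsectOrder())
  cls <- split(rep$table$gene, rep$table$class)
  expect_setequal(cls$translocated, c("trnI", "trnN", "trnR"))
  expect_setequal(cls$local_inversion, "trnE")
  expect_setequal(cls$shuffle_with_remote_inversion, c("trnQ", "trnY", "trnC"))
  # every protein-coding and rRNA gene anchors the backbone
  pcgRrn <- rep$table$gene[rep$table$klass %in% c("PCG", "rRNA")]
  expect_true(all(rep$table$class[rep$table$gene %in% pcgRrn] == "in_place"))
  # trnN/trnR form one swap event: 3 translocated genes, 2 translocation events
  ev <- rep$events
  expect_identical(sum(ev$type %in% c("translocation", "translocation_swap")), 2L)
  expect_identical(rep$summary$translocated, 3L)
})

test_that("an adjacent swap is one translocation event affecting both genes", {
  swapped <- applyDupLoss(ancestralInsectOrder(), c("trnK", "trnD"),
                          loseFirst = "trnK", loseSecond = "trnD")
  rep <- compareOrders(swapped, ancestralInsectOrder())
  expect_setequal(rep$table$gene[rep$table$class == "translocated"],
                  c("trnK", "trnD"))
  expect_identical(rep$events$type, "translocation_swap")
  expect_identical(nrow(rep$events), 1L)
})

test_that("gene-set mismatches are reported as errors", {
  short <- geneOrder(orderGenes(ancestralInsectOrder())[-1L],
                     orientations(ancestralInsectOrder())[-1L])
  expect_error(compareOrders(short, ancestralInsectOrder()), "trnI")
  expect_error(breakpointCount(short, ancestralInsectOrder()), "gene sets differ")
})

test_that("duplication/random loss reproduces the documented local orders", {
  anc <- ancestralInsectOrder()
  # block trnI-trnQ-trnM-nad2: lose trnI from copy 1 and the rest from copy 2
  o1 <- applyDupLoss(anc, c("trnI", "trnQ", "trnM", "nad2"),
                     loseFirst = "trnI", loseSecond = c("trnQ", "trnM", "nad2"))
  expect_identical(nextGenes(o1, "trnQ", 3), c("trnM", "nad2", "trnI"))
  # block trnC-trnY -> intermediate trnY-trnC
  o2 <- applyDupLoss(anc, c("trnC", "trnY"), loseFirst = "trnC", loseSecond = "trnY")
  expect_identical(nextGenes(o2, "trnW", 2), c("trnY", "trnC"))
  # block trnR-trnN -> current trnN-trnR
  o3 <- applyDupLoss(anc, c("trnR", "trnN"), loseFirst = "trnR", loseSecond = "trnN")
  expect_identical(nextGenes(o3, "trnA", 2), c("trnN", "trnR"))
  # deleting the whole second copy restores the original order
  o4 <- applyDupLoss(anc, c("trnK", "trnD"), loseFirst = character(0),
                     loseSecond = c("trnK", "trnD"))
  expect_true(sameGeneOrder(o4, anc))
  expect_error(applyDupLoss(anc, c("trnK", "trnD"), loseFirst = "trnK",
                            loseSecond = "trnK"), "partition")
  expect_error(applyDupLoss(anc, c("trnK", "trnM"), "trnK", "trnM"),
               "not contiguous")
})

test_that("inversion flips orientation in place and is an involution", {
  anc <- ancestralInsectOrder()
  inv <- applyInversion(anc, "trnE")
  expect_identical(orientations(inv)[match("trnE", orderGenes(inv))], "-")
  expect_identical(match("trnE", orderGenes(inv)), match("trnE", orderGenes(anc)))
  expect_true(sameGeneOrder(applyInversion(inv, "trnE"), anc))
  # segment inversion reverses order and flips both orientations
  inv2 <- applyInversion(anc, c("trnC", "trnY"))
  i <- match("trnW", orderGenes(inv2))
  expect_identical(orderGenes(inv2)[i + 1:2], c("trnY", "trnC"))
  expect_identical(orientations(inv2)[i + 1:2], c("+", "+"))
  expect_true(sameGeneOrder(applyInversion(inv2, c("trnY", "trnC")), anc))
})

test_that("translocation moves segments intact, matching the dup-loss outcome", {
  anc <- ancestralInsectOrder()
  t1 <- applyTranslocation(anc, "trnI", after = "nad2")
  dl <- applyDupLoss(anc, c("trnI", "trnQ", "trnM", "nad2"),
                     loseFirst = "trnI", loseSecond = c("trnQ", "trnM", "nad2"))
  expect_true(sameGeneOrder(t1, dl))
  expect_error(applyTranslocation(anc, "trnI", after = "trnI"), "outside")
})

test_that("breakpoint counts match a brute-force adjacency oracle", {
  naiveBreakpoints <- function(a, b) {
    adj <- function(ord) {
      g <- orderGenes(ord); o <- orientations(ord); n <- length(g)
      out <- character(0)
      for (i in seq_len(n)) {
        j <- if (i == n) 1L else i + 1L
        f <- function(x) if (x == "+") "-" else "+"
        s1 <- paste0(o[i], g[i], ">", o[j], g[j])
        s2 <- paste0(f(o[j]), g[j], ">", f(o[i]), g[i])
        out <- c(out, min(s1, s2))
      }
      out
    }
    sum(!(adj(a) %in% adj(b)))
  }
  expect_identical(breakpointCount(earwigOrder(), ancestralInsectOrder()),
                   naiveBreakpoints(earwigOrder(), ancestralInsectOrder()))
  set.seed(33)
  genes <- letters[1:6]
  for (k in 1:40) {
    a <- geneOrder(sample(genes), sample(c("+", "-"), 6, TRUE))
    b <- geneOrder(sample(genes), sample(c("+", "-"), 6, TRUE))
    expect_identical(breakpointCount(a, b), naiveBreakpoints(a, b))
    # rotation invariance
    rot <- c(3:6, 1:2)
    a2 <- geneOrder(orderGenes(a)[rot], orientations(a)[rot])
    expect_identical(breakpointCount(a2, b), breakpointCount(a, b))
  }
})

test_that("classification is invariant under rotation of the observed order", {
  obs <- earwigOrder()
  base <- compareOrders(obs, ancestralInsectOrder())
  set.seed(34)
  for (r in sample(2:37, 5)) {
    g <- orderGenes(obs); o <- orientations(obs)
    rot <- c(r:38, 1:(r - 1))
    rep <- compareOrders(geneOrder(g[rot], o[rot]), ancestralInsectOrder())
    expect_identical(rep$summary, base$summary)
    expect_identical(sort(rep$table$gene[rep$table$class != "in_place"]),
                     sort(base$table$gene[base$table$class != "in_place"]))
  }
})

test_that("the documented event script transforms the ancestral into the observed order", {
  o <- ancestralInsectOrder()
  o <- applyDupLoss(o, c("trnI", "trnQ", "trnM", "nad2"),
                    loseFirst = "trnI", loseSecond = c("trnQ", "trnM", "nad2"))
  o <- applyDupLoss(o, c("trnC", "trnY"), loseFirst = "trnC", loseSecond = "trnY")
  o <- applyDupLoss(o, c("trnR", "trnN"), loseFirst = "trnR", loseSecond = "trnN")
  o <- applyInversion(o, "trnE")
  o <- applyInversion(o, "trnY")
  o <- applyInversion(o, "trnC")
  o <- applyTranslocation(o, c("trnY", "trnC"), after = "trnS(AGN)")
  o <- applyInversion(o, "trnQ")
  o <- applyTranslocation(o, "trnQ", after = "trnC")
  expect_true(sameGeneOrder(o, earwigOrder()))
})

test_that("random event scripts are recovered gene for gene", {
  set.seed(35)
  for (k in 1:60) {
    gt <- generateOrder(nEvents = sample(1:3, 1))
    rep <- compareOrders(gt$order, ancestralInsectOrder())
    expect_identical(rep$table$class[match(gt$truth$gene, rep$table$gene)],
                     gt$truth$class)
  }
})
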