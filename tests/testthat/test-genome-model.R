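# Circular genome model: parsing, lengths, spacers, extraction, validation.

test_that("the published feature table parses with the expected census", {
  g <- earwigGenome()
  expect_s4_class(g, "AnnotatedGenome")
  expect_identical(genomeLength(g), 20456L)
  ft <- featureTable(g)
  expect_identical(nrow(ft), 39L)
  counts <- table(ft$klass)
  expect_identical(as.integer(counts[c("PCG", "tRNA", "rRNA", "control_region",
                                       "repeat_region")]),
                   c(13L, 22L, 2L, 1L, 1L))
  expect_false(is.unsorted(ft$start))
  lens <- featureLengths(g)
  expect_identical(unname(lens[c("rrnL", "rrnS", "A+T-rich region", "TRU", "nad2")]),
                   c(1334L, 763L, 1816L, 2856L, 1017L))
  # anticodon metadata survives parsing
  trnM <- ft[ft$name == "trnM", ]
  expect_identical(trnM$anticodon, "CAT")
  expect_identical(c(trnM$anticodon_start, trnM$anticodon_end), c(31L, 33L))
})

test_that("single rows, dash dialects and degenerate tables parse as specified", {
  for (dash in c("-", "–", "—")) {
    g <- parseFeatureTable(c("gene\tdirection\tcoordinates",
                             sprintf("trnM\tF\t1%s68", dash)), text = TRUE)
    ft <- featureTable(g)
    expect_identical(ft$klass, "tRNA")
    expect_identical(unname(featureLengths(g)), 68L)
    expect_identical(ft$strand, "+")
  }
  # thousands separators in coordinates
  g <- parseFeatureTable(c("gene\tdirection\tcoordinates", "rrnL\tR\t16,455–1,7788"),
                         text = TRUE)
  expect_identical(featureTable(g)$start, 16455L)
  expect_error(parseFeatureTable("gene\tdirection\tcoordinates", text = TRUE),
               "no features")
  expect_error(parseFeatureTable(c("gene\tdirection\tcoordinates", "trnM\tF\toops"),
                                 text = TRUE), "malformed coordinate")
  expect_error(parseFeatureTable(c("gene\tdirection\tcoordinates",
                                   "trnM\tF\t1-68", "trnM\tF\t70-140"), text = TRUE),
               "duplicate")
})

test_that("featureLength handles plain, single-base and origin-wrapping features", {
  expect_identical(featureLength(16455, 17788), 1334L)
  expect_identical(featureLength(5, 5), 1L)
  expect_identical(featureLength(20450, 10, 20456), 17L)
  expect_error(featureLength(10, 5, circular = FALSE), "non-circular")
})

test_that("featureLength agrees with brute-force position enumeration", {
  set.seed(101)
  L <- 500L
  for (k in 1:1000) {
    s <- sample.int(L, 1L)
    e <- sample.int(L, 1L)
    expect_identical(featureLength(s, e, L),
                     length(mitoarch:::.featurePositions(s, e, L)))
  }
})

test_that("intergenic accounting reproduces the published spacer structure", {
  g <- earwigGenome()
  ir <- intergenicRegions(g)
  sp <- ir$spacers
  len <- function(up) sp$length[sp$upstream == up]
  expect_identical(len("trnI"), 2888L)       # longest, hosts the repeat region
  expect_identical(len("trnE"), 217L)        # second longest
  expect_identical(len("nad2"), 131L)        # the unassigned ORF spacer
  expect_identical(len("atp8"), -7L)         # atp8/atp6 overlap
  expect_identical(sp$contains[sp$upstream == "trnI"], "TRU")
  # the wrap record spans the A+T-rich region and is excluded from the summary
  wrap <- sp[sp$upstream == "rrnS", ]
  expect_identical(wrap$length, 1816L)
  expect_true(wrap$is_control_region)
  expect_identical(ir$summary$n_positive, 24L)
  expect_identical(ir$summary$total_positive, 3783L)
  expect_identical(ir$summary$min_positive, 1L)
  expect_identical(ir$summary$max_positive, 2888L)
})

test_that("abutting features yield a zero-length record that is not counted", {
  g <- annotatedGenome(data.frame(name = c("a", "b"), klass = "PCG",
                                  strand = "+", start = c(1L, 101L), end = c(100L, 200L)))
  ir <- intergenicRegions(g)
  expect_identical(ir$spacers$length[1L], 0L)
  expect_identical(ir$summary$n_positive, 0L)
  g1 <- annotatedGenome(data.frame(name = "a", klass = "PCG", strand = "+",
                                   start = 1L, end = 100L))
  expect_error(intergenicRegions(g1), "at least two")
})

test_that("coverage conservation: genes, positive spacers and the control region tile the circle", {
  g <- earwigGenome()
  L <- genomeLength(g)
  ft <- featureTable(g)
  covered <- logical(L)
  for (i in which(ft$klass %in% c("PCG", "tRNA", "rRNA", "control_region"))) {
    covered[mitoarch:::.featurePositions(ft$start[i], ft$end[i], L)] <- TRUE
  }
  chain <- ft[ft$klass %in% c("PCG", "tRNA", "rRNA"), ]
  sp <- intergenicRegions(g)$spacers
  for (i in which(sp$length > 0L & !sp$is_control_region)) {
    a <- chain$end[chain$name == sp$upstream[i]] + 1L
    covered[mitoarch:::.featurePositions(a, a + sp$length[i] - 1L, L)] <- TRUE
  }
  expect_true(all(covered))
})

test_that("spacer antisymmetry: chain lengths plus signed spacers close the circle", {
  g <- earwigGenome()
  chain <- featureTable(g)
  chain <- chain[chain$klass %in% c("PCG", "tRNA", "rRNA"), ]
  ir <- intergenicRegions(g)
  expect_identical(sum(chain$end - chain$start + 1L) + sum(ir$spacers$length),
                   genomeLength(g))
})

test_that("feature sequences are extracted strand- and wrap-aware", {
  g <- tinyGenome("ATGCATGC",
                  data.frame(name = c("p", "m", "w"), klass = "PCG",
                             strand = c("+", "-", "+"),
                             start = c(1L, 1L, 7L), end = c(3L, 3L, 10L)))
  expect_identical(extractFeatureSequence(g, "p"), "ATG")
  expect_identical(extractFeatureSequence(g, "m"), "CAT")
  # wrap (7,2) on the 8-bp circle: positions 7,8,1,2 -> "GCAT"
  expect_identical(extractFeatureSequence(g, "w"), "GCAT")
  gNoSeq <- annotatedGenome(featureTable(g), genomeLength = 8L)
  expect_error(extractFeatureSequence(gNoSeq, "p"), "sequence-free")
  expect_error(extractFeatureSequence(g, "absent"), "unknown feature")
})

test_that("validation flags inconsistencies without throwing", {
  # the published table carries an anticodon-coordinate typo in trnL(CUN)
  v <- validateAnnotation(earwigGenome())
  expect_identical(v$feature[v$rule == "anticodon_span"], "trnL(CUN)")
  expect_identical(v$severity[v$rule == "anticodon_span"], "error")
  # a clean tRNA row produces no finding
  g <- parseFeatureTable(c("gene\tdirection\tcoordinates\tanticodon",
                           "trnM\tF\t1-68\t31-33 CAT"), text = TRUE)
  expect_identical(nrow(validateAnnotation(g)), 0L)
  # incomplete stop codons warn, invalid ones error
  g2 <- annotatedGenome(data.frame(name = c("nad2", "cox1"), klass = "PCG",
                                   strand = "+", start = c(1L, 200L), end = c(99L, 400L),
                                   start_codon = c("ATT", "CCC"),
                                   stop_codon = c("TA", "AAA")))
  v2 <- validateAnnotation(g2)
  expect_identical(v2$severity[v2$feature == "nad2" & v2$rule == "stop_codon"], "warning")
  expect_setequal(v2$severity[v2$feature == "cox1"], c("warning", "error"))
})
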