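w <- wobbleThresholds(a = 50, m = 10, z = 50)

test_that("merging an annotation with itself is idempotent", {
  a <- mkAnn(list(id = "T1", gene = "GA", starts = c(101, 401), ends = c(200, 500)),
             list(id = "T2", gene = "GA", starts = c(101, 451), ends = c(200, 500)),
             list(id = "T3", gene = "GB", starts = 900, ends = 1500,
                  strand = "-"))
  mg <- mergeAnnotations(list(mergeSource(a, "self")), w = w)
  expect_equal(nTranscripts(mg$annotation), 3L)
  mg2 <- mergeAnnotations(list(mergeSource(a, "a"),
                               mergeSource(a, "b")), w = w)
  expect_equal(nTranscripts(mg2$annotation), 3L)
  expect_true(all(mg2$annotation@txData$sources == "a,b"))
})

test_that("a truncated no-cap model absorbs into the prioritised reference", {
  ref <- mkAnn(list(id = "R1", gene = "G", starts = c(1000, 2000, 3000),
                    ends = c(1200, 2200, 3200)))
  lr <- mkAnn(list(id = "L1", gene = "g", starts = c(2055, 3004),
                   ends = c(2204, 3195)))
  mg <- mergeAnnotations(list(
    mergeSource(lr, "long_read", mode = "no_cap", priority = c(2, 2, 2)),
    mergeSource(ref, "reference", mode = "capped", priority = c(1, 1, 1))),
    w = w)
  expect_equal(nTranscripts(mg$annotation), 1L)
  ex <- exonsBy(mg$annotation)[[1]]
  ## reference coordinates win everywhere
  expect_equal(GenomicRanges::start(ex), c(1000, 2000, 3000))
  expect_equal(GenomicRanges::end(ex), c(1200, 2200, 3200))
  expect_equal(sort(unique(mg$transReport$source)),
               c("long_read", "reference"))
})

test_that("junctions differing beyond the wobble stay distinct transcripts", {
  a <- mkAnn(list(id = "A1", gene = "GA", starts = c(1000, 2000),
                  ends = c(1200, 2200)))
  b <- mkAnn(list(id = "B1", gene = "GB", starts = c(1000, 2000),
                  ends = c(1211, 2200)))
  mg <- mergeAnnotations(list(mergeSource(a, "a"), mergeSource(b, "b")), w = w)
  expect_equal(nTranscripts(mg$annotation), 2L)
  ## but they share one gene locus (overlapping spans, same strand)
  expect_equal(nGenes(mg$annotation), 1L)
})

test_that("equal-priority merges are order-insensitive up to labelling", {
  set.seed(7)
  mk <- function(seedOffset) {
    chains <- randomInstance(4, w)
    specs <- lapply(seq_along(chains), function(i)
      list(id = sprintf("S%d.%d", seedOffset, i),
           starts = chains[[i]]$starts, ends = chains[[i]]$ends,
           strand = chains[[i]]$strand))
    do.call(mkAnn, specs)
  }
  a <- mk(1); b <- mk(2)
  sig <- function(ann) sort(vapply(IsoCollapse:::.chains(ann), function(c)
    paste(c$chrom, c$strand, paste(c$starts, collapse = ","),
          paste(c$ends, collapse = ",")), character(1)))
  m1 <- mergeAnnotations(list(mergeSource(a, "a"), mergeSource(b, "b")), w = w)
  m2 <- mergeAnnotations(list(mergeSource(b, "b"), mergeSource(a, "a")), w = w)
  expect_equal(sig(m1$annotation), sig(m2$annotation))
  ## merged count bounded by the sum of inputs
  expect_lte(nTranscripts(m1$annotation), nTranscripts(a) + nTranscripts(b))
})

test_that("every merged junction exists in a contributing source", {
  set.seed(8)
  chains <- randomInstance(6, w)
  a <- do.call(mkAnn, lapply(1:3, function(i)
    list(id = sprintf("A%d", i), starts = chains[[i]]$starts,
         ends = chains[[i]]$ends, strand = chains[[i]]$strand)))
  b <- do.call(mkAnn, lapply(4:6, function(i)
    list(id = sprintf("B%d", i), starts = chains[[i]]$starts,
         ends = chains[[i]]$ends, strand = chains[[i]]$strand)))
  mg <- mergeAnnotations(list(mergeSource(a, "a"), mergeSource(b, "b")), w = w)
  srcJn <- do.call(rbind, lapply(c(IsoCollapse:::.chains(a),
                                   IsoCollapse:::.chains(b)),
                                 IsoCollapse:::.junctions))
  for (mc in IsoCollapse:::.chains(mg$annotation)) {
    jn <- IsoCollapse:::.junctions(mc)
    for (r in seq_len(nrow(jn)))
      expect_true(any(srcJn[, 1] == jn[r, 1] & srcJn[, 2] == jn[r, 2]))
  }
})

test_that("duplicate source labels are rejected", {
  a <- mkAnn(list(id = "T1", starts = 100, ends = 200))
  expect_error(mergeAnnotations(list(
    mergeSource(a, "x"), mergeSource(a, "x"))), "unique")
})

test_that("locus overlap supports many-to-one and empty relations", {
  a <- mkAnn(list(id = "A1", gene = "GA1", starts = 1000, ends = 2000),
             list(id = "A2", gene = "GA2", starts = 5000, ends = 6000))
  b <- mkAnn(list(id = "B1", gene = "GB1", starts = 1500, ends = 5500))
  ov <- lociOverlap(a, b)
  expect_equal(nrow(ov), 2L)
  expect_setequal(ov$gene_a, c("GA1", "GA2"))
  ## identical annotations give the identity mapping
  ovSelf <- lociOverlap(a, a)
  expect_equal(sort(ovSelf$gene_a), sort(ovSelf$gene_b))
  ## disjoint and cross-strand pairs yield nothing
  c1 <- mkAnn(list(id = "C1", gene = "GC", starts = 9000, ends = 9500))
  expect_equal(nrow(lociOverlap(a, c1)), 0L)
  d1 <- mkAnn(list(id = "D1", gene = "GD", starts = 1000, ends = 2000,
                   strand = "-"))
  expect_equal(nrow(lociOverlap(a, d1)), 0L)
  ## brute-force O(n^2) span scan agrees on a random fixture
  set.seed(11)
  mkRand <- function(pfx, n) {
    specs <- lapply(seq_len(n), function(i) {
      s <- sample(1000:20000, 1)
      list(id = sprintf("%s%d", pfx, i), gene = sprintf("g%s%d", pfx, i),
           starts = s, ends = s + sample(500:3000, 1),
           strand = sample(c("+", "-"), 1))
    })
    do.call(mkAnn, specs)
  }
  ra <- mkRand("A", 8); rb <- mkRand("B", 8)
  ov2 <- lociOverlap(ra, rb)
  cha <- IsoCollapse:::.chains(ra); chb <- IsoCollapse:::.chains(rb)
  brute <- 0L
  for (i in seq_along(cha)) for (j in seq_along(chb)) {
    x <- cha[[i]]; y <- chb[[j]]
    if (x$strand == y$strand &&
        min(x$ends) >= min(y$starts) && min(x$starts) <= max(y$ends) &&
        max(pmin(max(x$ends), max(y$ends)) -
            pmax(min(x$starts), min(y$starts)) + 1, 0) >= 1)
      brute <- brute + 1L
  }
  expect_equal(nrow(ov2), brute)
})

test_that("3' structure matching classifies 5' completeness", {
  a <- mkAnn(list(id = "A1", starts = c(1000, 2000, 3000),
                  ends = c(1200, 2200, 3200)))
  sameB <- mkAnn(list(id = "B1", starts = c(1000, 2000, 3000),
                      ends = c(1200, 2200, 3200)))
  expect_equal(threePrimeMatchCompare(a, sameB)$classification, "equal")
  ## dropping the 5' exon: a is longer with an extra 5' exon
  truncB <- mkAnn(list(id = "B1", starts = c(2000, 3000),
                       ends = c(2200, 3200)))
  cmp <- threePrimeMatchCompare(a, truncB)
  expect_equal(cmp$classification, "a_longer_5prime")
  expect_true(cmp$extra_5prime_exons)
  ## same exon count, longer 5' extent without extra exons
  extB <- mkAnn(list(id = "B1", starts = c(900, 2000, 3000),
                     ends = c(1200, 2200, 3200)))
  cmp2 <- threePrimeMatchCompare(a, extB, wobbleThresholds(300, 10, 50))
  expect_equal(cmp2$classification, "b_longer_5prime")
  expect_false(cmp2$extra_5prime_exons)
  ## classification agrees with a matchNocap-based oracle on random pairs
  set.seed(13)
  for (rep in 1:20) {
    chains <- randomInstance(2, wobbleThresholds(300, 30, 300))
    x <- do.call(mkAnn, list(list(id = "X", starts = chains[[1]]$starts,
                                  ends = chains[[1]]$ends,
                                  strand = chains[[1]]$strand)))
    y <- do.call(mkAnn, list(list(id = "Y", starts = chains[[2]]$starts,
                                  ends = chains[[2]]$ends,
                                  strand = chains[[2]]$strand)))
    w3 <- wobbleThresholds(300, 30, 300)
    got <- threePrimeMatchCompare(x, y, w3)
    matches <- matchNocap(exonsBy(x)[[1]], exonsBy(y)[[1]], w3)
    expect_equal(nrow(got) == 1L, matches, info = sprintf("rep %d", rep))
  }
})
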