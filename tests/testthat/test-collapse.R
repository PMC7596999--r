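test_that("identical reads collapse into one model with their read count", {
  chains <- lapply(1:10, function(i)
    chain(sprintf("r%d", i), c(1000, 2000, 3000), c(1200, 2200, 3200)))
  res <- collapseReads(profilesFromChains(chains), NULL,
                       collapseConfig("capped"))
  expect_equal(nTranscripts(res$annotation), 1L)
  expect_equal(readCounts(res$annotation), 10L)
  expect_equal(nrow(res$transReads), 10L)
})

test_that("5' truncations split in capped mode and merge in no-cap mode", {
  full <- lapply(1:10, function(i)
    chain(sprintf("f%d", i), c(1000, 2000, 3000), c(1200, 2200, 3200)))
  trunc <- lapply(1:5, function(i)
    chain(sprintf("t%d", i), c(2050, 3000), c(2200, 3200)))
  prof <- profilesFromChains(c(full, trunc))
  capped <- collapseReads(prof, NULL, collapseConfig("capped"))
  nocap <- collapseReads(prof, NULL, collapseConfig("no_cap"))
  expect_equal(nTranscripts(capped$annotation), 2L)
  expect_equal(nTranscripts(nocap$annotation), 1L)
  expect_equal(readCounts(nocap$annotation), 15L)
  ## the merged model keeps the full-length 5' start
  expect_equal(GenomicRanges::start(exonsBy(nocap$annotation)[[1]])[1], 1000)
})

test_that("splice junction ranking prefers clean flanks, coverage when off", {
  ## candidate A: 1 read, clean flanks, junction (1200, 2000)
  ## candidate B: 3 reads, 2 flanking mismatches each, junction (1204, 2004)
  mkProf <- function(id, ends1, starts2, nErr) {
    ch <- chain(id, c(1000, starts2), c(ends1, 2200))
    ev <- if (nErr > 0)
      data.frame(kind = rep("substitution", nErr),
                 pos = ends1 - seq_len(nErr), len = 1L)
    else data.frame(kind = character(0), pos = integer(0), len = integer(0))
    list(read_id = id, chrom = ch$chrom, strand = ch$strand,
         starts = ch$starts, ends = ch$ends, events = ev,
         read_length = 400L, coverage = 1, identity = 1 - nErr / 400)
  }
  profs <- new("ReadProfiles", profiles = list(
    mkProf("clean", 1200L, 2000L, 0L),
    mkProf("err1", 1204L, 2004L, 2L),
    mkProf("err2", 1204L, 2004L, 2L),
    mkProf("err3", 1204L, 2004L, 2L)))
  chains <- IsoCollapse:::.chains(profs)
  flanks <- sjErrorProfile(profs, 20)
  on <- rankSpliceJunctions(chains, flanks, sjRanking = TRUE)
  expect_equal(unname(on[1, ]), c(1200, 2000))
  off <- rankSpliceJunctions(chains, flanks, sjRanking = FALSE)
  expect_equal(unname(off[1, ]), c(1204, 2004))
  ## end to end: the collapsed model carries the chosen junction
  resOn <- collapseReads(profs, NULL, collapseConfig("capped"))
  expect_equal(GenomicRanges::end(exonsBy(resOn$annotation)[[1]])[1], 1200)
  resOff <- collapseReads(profs, NULL, collapseConfig("capped",
                                                      sjRanking = FALSE))
  expect_equal(GenomicRanges::end(exonsBy(resOff$annotation)[[1]])[1], 1204)
})

test_that("genomic poly-A detection reads the strand-aware downstream window", {
  g <- Biostrings::DNAStringSet(c(chr1 = paste0(
    paste(rep("C", 100), collapse = ""),
    paste(rep("A", 20), collapse = ""),
    paste(rep("C", 100), collapse = ""))))
  expect_true(detectGenomicPolyA(g, "chr1", "+", tes = 100, window = 20,
                                 frac = 0.7))
  expect_false(detectGenomicPolyA(g, "chr1", "+", tes = 140, window = 20,
                                  frac = 0.7))
  ## minus strand: downstream is genomic-left, read as T on the plus strand
  g2 <- Biostrings::DNAStringSet(c(chr1 = paste0(
    paste(rep("C", 100), collapse = ""),
    paste(rep("T", 20), collapse = ""),
    paste(rep("C", 100), collapse = ""))))
  expect_true(detectGenomicPolyA(g2, "chr1", "-", tes = 121, window = 20,
                                 frac = 0.7))
  ## window truncates at the contig end without error
  expect_false(detectGenomicPolyA(g, "chr1", "+", tes = 219, window = 20,
                                  frac = 0.7))
})

test_that("planted genomic A-tracts are flagged on the right models", {
  sim <- simulateIsoSeq(simConfig(seed = 31, nGenes = 10,
                                  polyaPlantFraction = 0.5,
                                  degradationFraction = 0,
                                  sjFlankErrorRate = 0,
                                  backgroundErrorRate = 0))
  res <- collapseSim(sim, "capped")
  ## map collapsed genes back to truth genes via read ids
  truthGene <- stats::setNames(sim$readTruth$gene_id, sim$readTruth$read_id)
  planted <- stats::setNames(sim$polya$planted, sim$polya$gene_id)
  ch <- IsoCollapse:::.chains(res$annotation)
  for (i in seq_len(nTranscripts(res$annotation))) {
    tid <- transcriptIds(res$annotation)[i]
    rids <- res$transReads$read_id[res$transReads$transcript_id == tid]
    gene <- unique(truthGene[rids])
    expect_length(gene, 1L)
    ## only full-3'-length models inherit the planted tract verdict
    truthTes <- IsoCollapse:::.tes(
      IsoCollapse:::.chains(sim$truth)[[match(gene, geneIds(sim$truth))]])
    if (IsoCollapse:::.tes(ch[[i]]) == truthTes)
      expect_equal(res$polya$genomic_polya[res$polya$transcript_id == tid],
                   unname(planted[gene]), info = tid)
  }
})

test_that("LDE filtering keeps clean reads and preserves truth junctions", {
  ## plant a locus where half the reads carry junction-flank errors
  sim <- simulateIsoSeq(simConfig(seed = 32, nGenes = 6,
                                  exonsPerGene = c(3, 5),
                                  degradationFraction = 0,
                                  sjFlankErrorRate = 0.08,
                                  backgroundErrorRate = 0))
  samp <- tempfile(fileext = ".sam")
  writeLines(sim$samLines, samp)
  prof <- profileAlignments(readAlignments(samp), sim$genome)
  cfg <- collapseConfig("capped", ldeWindow = 20, ldeMax = 0)
  res <- collapseReads(prof, sim$genome, cfg)
  ## discarded = exactly the reads with planted events near a junction
  flaggedTruth <- vapply(seq_len(length(prof)), function(i) {
    p <- prof[[i]]
    ev <- sim$events[sim$events$read_id == p$read_id, ]
    if (length(p$starts) < 2 || nrow(ev) == 0) return(FALSE)
    any(vapply(seq_len(length(p$starts) - 1), function(j) {
      d <- p$ends[j]; a <- p$starts[j + 1]
      sum(ev$pos >= d - 19 & ev$pos <= d) +
        sum(ev$pos >= a & ev$pos <= a + 19) > 0
    }, logical(1)))
  }, logical(1))
  ids <- vapply(seq_len(length(prof)), function(i) prof[[i]]$read_id,
                character(1))
  expect_setequal(res$discarded, ids[flaggedTruth])
  ## surviving models carry exactly the truth junctions
  truthCh <- IsoCollapse:::.chains(sim$truth)
  truthJn <- lapply(truthCh, IsoCollapse:::.junctions)
  for (mc in IsoCollapse:::.chains(res$annotation)) {
    jn <- IsoCollapse:::.junctions(mc)
    if (nrow(jn) == 0) next
    hit <- any(vapply(truthJn, function(tj)
      nrow(tj) == nrow(jn) && all(tj == jn), logical(1)))
    expect_true(hit, info = mc$id)
  }
})

test_that("collapse invariants hold on simulated data", {
  for (seed in c(41, 42)) {
    sim <- simulateIsoSeq(simConfig(seed = seed, degradationFraction = 0.3))
    capped <- collapseSim(sim, "capped")
    nocap <- collapseSim(sim, "no_cap")
    ## no_cap only merges further
    expect_lte(nTranscripts(nocap$annotation), nTranscripts(capped$annotation))
    ## read count conservation
    nPassing <- sum(capped$readReport$accepted)
    expect_equal(sum(readCounts(capped$annotation)), nPassing)
    expect_equal(sum(readCounts(nocap$annotation)), nPassing)
    ## chosen junctions always come from at least one supporting read
    readJn <- unique(do.call(rbind, lapply(sim$readChains,
      IsoCollapse:::.junctions)))
    for (mc in IsoCollapse:::.chains(capped$annotation)) {
      jn <- IsoCollapse:::.junctions(mc)
      for (r in seq_len(nrow(jn)))
        expect_true(any(readJn[, 1] == jn[r, 1] & readJn[, 2] == jn[r, 2]))
    }
    ## idempotence: re-collapsing the models reproduces the same chains
    for (mode in c("capped", "no_cap")) {
      res <- if (mode == "capped") capped else nocap
      again <- collapseReads(
        profilesFromChains(IsoCollapse:::.chains(res$annotation)), NULL,
        collapseConfig(mode))
      expect_equal(nTranscripts(again$annotation),
                   nTranscripts(res$annotation))
      sig <- function(a) sort(vapply(IsoCollapse:::.chains(a), function(c)
        paste(c$chrom, c$strand, paste(c$starts, collapse = ","),
              paste(c$ends, collapse = ",")), character(1)))
      expect_equal(sig(again$annotation), sig(res$annotation))
    }
  }
})

test_that("gene and transcript ids are assigned in coordinate order", {
  chains <- c(
    lapply(1:3, function(i) chain(sprintf("a%d", i), 1000, 2000)),
    lapply(1:2, function(i) chain(sprintf("b%d", i), c(5000, 6000),
                                  c(5500, 6500))),
    list(chain("c1", c(5000, 6100), c(5500, 6500))))
  res <- collapseReads(profilesFromChains(chains), NULL,
                       collapseConfig("capped"))
  a <- res$annotation
  expect_equal(geneIds(a), c("G1", "G2", "G2"))
  ## within G2 the 2-read model is numbered before the 1-read model
  expect_equal(transcriptIds(a)[readCounts(a) == 3], "G1.1")
  expect_equal(transcriptIds(a)[readCounts(a) == 2], "G2.1")
  expect_equal(transcriptIds(a)[readCounts(a) == 1], "G2.2")
})
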