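genome1 <- Biostrings::DNAStringSet(c(chr1 = paste(
  rep("ACGT", 25000), collapse = "")))

test_that("substitutions are called against the genome with correct identity", {
  ## genome at chr1:101-110 is "ACGTACGTAC"; flip one base
  p <- writeSam(samLine("r1", "chr1", 101, "10M", "ACGTACGTAG"))
  prof <- profileAlignments(readAlignments(p), genome1)
  ev <- prof[[1]]$events
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "substitution")
  expect_equal(ev$pos, 110L)
  expect_equal(ev$len, 1L)
  expect_equal(prof[[1]]$identity, 0.9)
  expect_equal(prof[[1]]$coverage, 1)
})

test_that("soft clip 5'/3' classification is strand-aware", {
  seq15 <- paste0("TTTTT", "ACGTACGTAC")
  pPlus <- writeSam(samLine("r1", "chr1", 101, "5S10M", seq15))
  profP <- profileAlignments(readAlignments(pPlus), genome1)
  expect_equal(profP[[1]]$events$kind[1], "softclip5")
  expect_equal(profP[[1]]$coverage, 10 / 15)
  pMinus <- writeSam(samLine("r1", "chr1", 101, "5S10M", seq15, flag = 16L))
  profM <- profileAlignments(readAlignments(pMinus), genome1)
  expect_equal(profM[[1]]$events$kind[1], "softclip3")
})

test_that("planted event multisets are recovered exactly from simulated reads", {
  sim <- simulateIsoSeq(simConfig(seed = 21, nGenes = 6,
                                  sjFlankErrorRate = 0.05,
                                  backgroundErrorRate = 0.01))
  samp <- tempfile(fileext = ".sam")
  writeLines(sim$samLines, samp)
  prof <- profileAlignments(readAlignments(samp), sim$genome)
  expect_gt(nrow(sim$events), 0L)
  for (i in seq_len(length(prof))) {
    p <- prof[[i]]
    truth <- sim$events[sim$events$read_id == p$read_id, c("kind", "pos", "len")]
    got <- p$events[, c("kind", "pos", "len")]
    o1 <- order(truth$pos, truth$kind); o2 <- order(got$pos, got$kind)
    expect_equal(unname(as.list(got[o2, ])), unname(as.list(truth[o1, ])),
                 info = p$read_id)
  }
})

test_that("quality filter equals a per-read threshold scan and is monotone", {
  sim <- simulateIsoSeq(simConfig(seed = 22, nGenes = 8,
                                  backgroundErrorRate = 0.02))
  samp <- tempfile(fileext = ".sam")
  writeLines(sim$samLines, samp)
  prof <- profileAlignments(readAlignments(samp), sim$genome)
  for (minId in c(0, 0.97, 0.995, 1)) {
    got <- passQuality(prof, minCoverage = 0.5, minIdentity = minId)
    manual <- vapply(seq_len(length(prof)), function(i)
      prof[[i]]$coverage >= 0.5 && prof[[i]]$identity >= minId, logical(1))
    expect_equal(got, manual)
  }
  ## monotone: raising a threshold never flips FALSE -> TRUE
  loose <- passQuality(prof, 0, 0.97)
  tight <- passQuality(prof, 0, 0.995)
  expect_true(all(loose | !tight))
})

test_that("LDE counts flanking mismatches per junction with inclusive window", {
  ## two exons 101-200, 301-400; junction donor=200 acceptor=301
  ref <- function(from, to) as.character(Biostrings::subseq(genome1[["chr1"]], from, to))
  readSeq <- paste0(ref(101, 200), ref(301, 400))
  mutate <- function(s, at) {                       # at: read coordinate
    ch <- strsplit(s, "")[[1]]
    ch[at] <- setdiff(c("A", "C", "G", "T"), ch[at])[1]
    paste(ch, collapse = "")
  }
  ## two substitutions 3 bp from the junction (read coords 98 and 103)
  seq2 <- mutate(mutate(readSeq, 98), 103)
  p <- writeSam(samLine("r1", "chr1", 101, "100M100N100M", seq2))
  prof <- profileAlignments(readAlignments(p), genome1)
  expect_false(passLde(prof, window = 10, maxMismatch = 1))
  expect_true(passLde(prof, window = 10, maxMismatch = 2))
  ## window exactly reaching the event: substitution at distance 10 from donor
  seq3 <- mutate(readSeq, 91)                       # genomic pos 191 = donor-9
  p3 <- writeSam(samLine("r1", "chr1", 101, "100M100N100M", seq3))
  prof3 <- profileAlignments(readAlignments(p3), genome1)
  expect_false(passLde(prof3, window = 10, maxMismatch = 0))
  expect_true(passLde(prof3, window = 9, maxMismatch = 0))
  ## single-exon reads pass vacuously
  p4 <- writeSam(samLine("r1", "chr1", 101, "10M", "ACGTACGTAC"))
  prof4 <- profileAlignments(readAlignments(p4), genome1)
  expect_true(passLde(prof4, window = 20, maxMismatch = 0))
  expect_equal(nrow(sjErrorProfile(prof4, 20)[[1]]), 0L)
})

test_that("sj error profile equals a brute-force windowed scan", {
  sim <- simulateIsoSeq(simConfig(seed = 23, nGenes = 6,
                                  sjFlankErrorRate = 0.08))
  samp <- tempfile(fileext = ".sam")
  writeLines(sim$samLines, samp)
  prof <- profileAlignments(readAlignments(samp), sim$genome)
  win <- 20
  fl <- sjErrorProfile(prof, win)
  for (i in seq_len(length(prof))) {
    p <- prof[[i]]
    nj <- length(p$starts) - 1
    if (nj < 1) { expect_equal(nrow(fl[[i]]), 0L); next }
    ## naive scan: expand every event to base positions, count per window
    bases <- unlist(lapply(seq_len(nrow(p$events)), function(k)
      if (p$events$kind[k] == "deletion")
        seq(p$events$pos[k], length.out = p$events$len[k])
      else rep(p$events$pos[k], p$events$len[k])))
    for (j in seq_len(nj)) {
      d <- p$ends[j]; a <- p$starts[j + 1]
      expect_equal(unname(fl[[i]][j, "left"]),
                   sum(bases >= d - win + 1 & bases <= d))
      expect_equal(unname(fl[[i]][j, "right"]),
                   sum(bases >= a & bases <= a + win - 1))
    }
  }
})

test_that("LDE filter is monotone in window and allowance", {
  sim <- simulateIsoSeq(simConfig(seed = 24, nGenes = 6,
                                  sjFlankErrorRate = 0.06))
  samp <- tempfile(fileext = ".sam")
  writeLines(sim$samLines, samp)
  prof <- profileAlignments(readAlignments(samp), sim$genome)
  for (w in c(5, 10, 20)) {
    p1 <- passLde(prof, w, 1); p2 <- passLde(prof, w, 2)
    expect_true(all(p2 | !p1))        # raising the allowance keeps passers
  }
  w1 <- passLde(prof, 10, 1); w2 <- passLde(prof, 20, 1)
  expect_true(all(w1 | !w2))          # shrinking the window keeps passers
})

test_that("mismatch summary equals per-read arithmetic", {
  sim <- simulateIsoSeq(simConfig(seed = 25, nGenes = 5,
                                  backgroundErrorRate = 0.01))
  samp <- tempfile(fileext = ".sam")
  writeLines(sim$samLines, samp)
  prof <- profileAlignments(readAlignments(samp), sim$genome)
  ms <- mismatchSummary(prof)
  manual <- mean(vapply(seq_len(length(prof)), function(i)
    sum(prof[[i]]$events$len) / prof[[i]]$read_length, numeric(1)))
  expect_equal(ms$mean_rate[ms$kind == "total"], manual)
  subManual <- mean(vapply(seq_len(length(prof)), function(i)
    sum(prof[[i]]$events$len[prof[[i]]$events$kind == "substitution"]) /
      prof[[i]]$read_length, numeric(1)))
  expect_equal(ms$mean_rate[ms$kind == "substitution"], subManual)
  ## error-free reads give all-zero rates
  clean <- simulateIsoSeq(simConfig(seed = 26, nGenes = 3,
                                    sjFlankErrorRate = 0,
                                    backgroundErrorRate = 0))
  samc <- tempfile(fileext = ".sam")
  writeLines(clean$samLines, samc)
  profc <- profileAlignments(readAlignments(samc), clean$genome)
  expect_true(all(mismatchSummary(profc)$mean_rate == 0))
  expect_true(all(passQuality(profc, 1, 1)))
})
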