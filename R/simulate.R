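#' Simulation configuration
#'
#' Defines the conditions a simulated Iso-Seq experiment emulates: a toy
#' genome of spliced genes, full-length reads plus a controlled fraction of
#' 5'-truncated reads (degraded RNA), planted alignment errors with elevated
#' density within 20 bp of splice junctions, and genomic A-tracts planted
#' downstream of a fraction of loci (internal-priming artifacts). All
#' randomness derives from \code{seed}; the same seed yields byte-identical
#' outputs.
#'
#' @param seed Integer seed.
#' @param nGenes Number of gene loci (split across two chromosomes).
#' @param txPerGene Range \code{c(min, max)} of transcripts per gene
#'   (alternative transcripts are internal-exon-skipping variants).
#' @param exonsPerGene Range of exons in a gene's full-length transcript.
#' @param exonLength,intronLength Ranges in bases.
#' @param readsPerTx Range of reads per transcript.
#' @param degradationFraction Probability that a read of a multi-exon
#'   transcript is 5'-truncated at a random internal point.
#' @param sjFlankErrorRate Per-base error probability within 20 bp of a
#'   splice junction (exonic side).
#' @param backgroundErrorRate Per-base error probability elsewhere.
#' @param polyaPlantFraction Fraction of genes given a 20-base genomic
#'   A-tract immediately downstream of the transcript end.
#' @param paralogPairs Number of gene loci duplicated elsewhere in the
#'   genome at \code{paralogIdentity} sequence identity (no reads are drawn
#'   from the copies; they provide paralogous sequence context).
#' @param paralogIdentity Target identity of paralog copies.
#' @return A list of class \code{"SimConfig"}.
#' @export
simConfig <- function(seed = 1L, nGenes = 10, txPerGene = c(1, 2),
                      exonsPerGene = c(1, 6),
                      exonLength = c(80, 200), intronLength = c(100, 300),
                      readsPerTx = c(2, 5),
                      degradationFraction = 0.25,
                      sjFlankErrorRate = 0.02,
                      backgroundErrorRate = 0.002,
                      polyaPlantFraction = 0.25,
                      paralogPairs = 0, paralogIdentity = 0.8) {
  stopifnot(degradationFraction >= 0, degradationFraction <= 1,
            sjFlankErrorRate >= 0, sjFlankErrorRate <= 1,
            backgroundErrorRate >= 0, backgroundErrorRate <= 1,
            polyaPlantFraction >= 0, polyaPlantFraction <= 1,
            txPerGene[1] <= txPerGene[2],
            exonsPerGene[1] <= exonsPerGene[2],
            readsPerTx[1] <= readsPerTx[2])
  structure(list(seed = as.integer(seed), nGenes = nGenes,
                 txPerGene = txPerGene, exonsPerGene = exonsPerGene,
                 exonLength = exonLength, intronLength = intronLength,
                 readsPerTx = readsPerTx,
                 degradationFraction = degradationFraction,
                 sjFlankErrorRate = sjFlankErrorRate,
                 backgroundErrorRate = backgroundErrorRate,
                 polyaPlantFraction = polyaPlantFraction,
                 paralogPairs = paralogPairs,
                 paralogIdentity = paralogIdentity),
            class = "SimConfig")
}

.randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

#' Simulate a toy genome with mapped spliced long reads
#'
#' Generates a genome, a ground-truth annotation and pre-mapped reads (SAM
#' records constructed directly from truth coordinates plus planted errors,
#' so no external aligner enters the loop) together with truth tables that
#' record every planted event. See \code{\link{simConfig}} for the knobs.
#'
#' @param cfg A \code{\link{simConfig}}.
#' @param outdir If non-NULL, write \code{genome.fa}, \code{truth.bed},
#'   \code{reads.sam} and the truth tables there.
#' @return A list: \code{genome} (DNAStringSet), \code{truth}
#'   (\linkS4class{TranscriptAnnotation}), \code{readTruth} (data.frame:
#'   \code{read_id}, \code{transcript_id}, \code{gene_id}, \code{truncated},
#'   \code{n_events}), \code{events} (data.frame of planted events),
#'   \code{polya} (data.frame: \code{gene_id}, \code{planted}),
#'   \code{readChains} (error-free truth chains of every read, for oracle
#'   use), \code{paths} (written file paths, when \code{outdir} given).
#' @export
simulateIsoSeq <- function(cfg = simConfig(), outdir = NULL) {
  set.seed(cfg$seed)
  genes <- list()
  cursor <- c(chr1 = 1L, chr2 = 1L)
  for (g in seq_len(cfg$nGenes)) {
    chrom <- if (g %% 2L == 1L) "chr1" else "chr2"
    strand <- sample(c("+", "-"), 1)
    E <- sample(seq(cfg$exonsPerGene[1], cfg$exonsPerGene[2]), 1)
    exLen <- sample(seq(cfg$exonLength[1], cfg$exonLength[2]), E, replace = TRUE)
    inLen <- if (E > 1) sample(seq(cfg$intronLength[1], cfg$intronLength[2]),
                               E - 1, replace = TRUE) else integer(0)
    gap <- sample(300:600, 1)
    start <- cursor[[chrom]] + gap
    starts <- integer(E); ends <- integer(E)
    pos <- start
    for (k in seq_len(E)) {
      starts[k] <- pos; ends[k] <- pos + exLen[k] - 1L
      pos <- ends[k] + if (k < E) inLen[k] else 0L
      if (k < E) pos <- pos + 1L
    }
    cursor[[chrom]] <- ends[E] + 40L      # room for a planted poly-A tract
    full <- list(chrom = chrom, strand = strand, starts = starts, ends = ends)
    nTx <- sample(seq(cfg$txPerGene[1], cfg$txPerGene[2]), 1)
    txs <- list(full)
    if (E >= 3L && nTx > 1L) {
      ## internal exons only (sample() on a length-1 vector would permute 1:x)
      skippable <- (2:(E - 1L))[sample.int(E - 2L)]
      for (t in seq_len(min(nTx - 1L, length(skippable)))) {
        k <- skippable[t]
        txs[[t + 1L]] <- list(chrom = chrom, strand = strand,
                              starts = starts[-k], ends = ends[-k])
      }
    }
    genes[[g]] <- list(id = sprintf("SIM_G%d", g), chrom = chrom,
                       strand = strand, txs = txs)
  }
  ## genome sequences, then plant poly-A tracts downstream of chosen genes
  seqs <- lapply(cursor, function(n) strsplit(.randSeq(n + 200L), "")[[1]])
  polyaPlanted <- stats::runif(cfg$nGenes) < cfg$polyaPlantFraction
  for (g in seq_len(cfg$nGenes)) {
    if (!polyaPlanted[g]) next
    gene <- genes[[g]]
    full <- gene$txs[[1]]
    if (gene$strand == "+") {
      tes <- max(full$ends)
      seqs[[gene$chrom]][(tes + 1L):(tes + 20L)] <- "A"
    } else {
      tss <- min(full$starts)
      seqs[[gene$chrom]][(tss - 20L):(tss - 1L)] <- "T"
    }
  }
  ## paralog copies appended at the end of each chromosome
  if (cfg$paralogPairs > 0) {
    for (g in seq_len(min(cfg$paralogPairs, cfg$nGenes))) {
      gene <- genes[[g]]
      full <- gene$txs[[1]]
      span <- seqs[[gene$chrom]][min(full$starts):max(full$ends)]
      mut <- stats::runif(length(span)) > cfg$paralogIdentity
      span[mut] <- vapply(span[mut], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      seqs[[gene$chrom]] <- c(seqs[[gene$chrom]],
                              strsplit(.randSeq(200L), "")[[1]], span)
    }
  }
  genome <- Biostrings::DNAStringSet(vapply(seqs, paste, character(1),
                                            collapse = ""))
  names(genome) <- names(cursor)
  ## truth annotation
  truthChains <- list(); truthGene <- character(0)
  for (gene in genes) for (t in seq_along(gene$txs)) {
    ch <- gene$txs[[t]]
    ch$id <- sprintf("%s.%d", gene$id, t)
    truthChains[[length(truthChains) + 1L]] <- ch
    truthGene <- c(truthGene, gene$id)
  }
  truth <- .annotationFromChains(truthChains, geneId = truthGene)
  ## reads
  readChains <- list(); readTruth <- list(); events <- list(); sam <- list()
  ridN <- 0L
  for (ti in seq_along(truthChains)) {
    tch <- truthChains[[ti]]
    nr <- sample(seq(cfg$readsPerTx[1], cfg$readsPerTx[2]), 1)
    for (r in seq_len(nr)) {
      ridN <- ridN + 1L
      rid <- sprintf("read%05d", ridN)
      ch <- list(id = rid, chrom = tch$chrom, strand = tch$strand,
                 starts = tch$starts, ends = tch$ends)
      truncated <- FALSE
      nEx <- length(ch$starts)
      if (nEx > 1L && stats::runif(1) < cfg$degradationFraction) {
        truncated <- TRUE
        ## truncate on the 5' side at a random internal exon, either at its
        ## boundary or inside it (leaving >= 30 bases of that exon)
        if (ch$strand == "+") {
          k <- sample(2:nEx, 1)
          ch$starts <- ch$starts[k:nEx]; ch$ends <- ch$ends[k:nEx]
          len <- ch$ends[1] - ch$starts[1] + 1L
          if (stats::runif(1) < 0.5 && len > 60L)
            ch$starts[1] <- ch$starts[1] + sample.int(len - 30L, 1)
        } else {
          k <- sample(seq_len(nEx - 1L), 1)
          ch$starts <- ch$starts[1:k]; ch$ends <- ch$ends[1:k]
          len <- ch$ends[k] - ch$starts[k] + 1L
          if (stats::runif(1) < 0.5 && len > 60L)
            ch$ends[k] <- ch$ends[k] - sample.int(len - 30L, 1)
        }
      }
      ev <- .plantErrors(ch, cfg)
      if (nrow(ev) > 0L) ev$read_id <- rid
      readChains[[ridN]] <- ch
      readTruth[[ridN]] <- data.frame(
        read_id = rid, transcript_id = tch$id, gene_id = truthGene[ti],
        truncated = truncated, n_events = nrow(ev),
        stringsAsFactors = FALSE)
      events[[ridN]] <- ev
      sam[[ridN]] <- .samRecord(rid, ch, ev, seqs[[ch$chrom]])
    }
  }
  eventsDf <- do.call(rbind, events[vapply(events, nrow, integer(1)) > 0])
  if (is.null(eventsDf))
    eventsDf <- data.frame(kind = character(0), pos = integer(0),
                           len = integer(0), read_id = character(0))
  readTruthDf <- do.call(rbind, readTruth)
  polyaDf <- data.frame(gene_id = vapply(genes, `[[`, character(1), "id"),
                        planted = polyaPlanted, stringsAsFactors = FALSE)
  ## SAM, coordinate-sorted
  samDf <- do.call(rbind, sam)
  o <- order(samDf$chrom, samDf$pos)
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                      Biostrings::width(genome)))
  samLines <- c(header, samDf$line[o])
  out <- list(genome = genome, truth = truth, readTruth = readTruthDf,
              events = eventsDf, polya = polyaDf, readChains = readChains)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(genome = file.path(outdir, "genome.fa"),
                  truth = file.path(outdir, "truth.bed"),
                  sam = file.path(outdir, "reads.sam"),
                  readTruth = file.path(outdir, "read_truth.tsv"),
                  events = file.path(outdir, "events.tsv"),
                  polya = file.path(outdir, "polya.tsv"))
    Biostrings::writeXStringSet(genome, paths$genome)
    writeBed12(truth, paths$truth)
    writeLines(samLines, paths$sam)
    utils::write.table(readTruthDf, paths$readTruth, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(eventsDf, paths$events, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(polyaDf, paths$polya, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    out$paths <- paths
  } else {
    out$samLines <- samLines
  }
  out
}

## Sample planted errors for one read chain: elevated rate within 20 bp of a
## splice junction (exonic side), background elsewhere. Events never land on
## the first/last 2 bases of a block (keeps CIGAR construction canonical).
.plantErrors <- function(ch, cfg) {
  nEx <- length(ch$starts)
  jn <- if (nEx > 1) .junctions(ch) else NULL
  posAll <- integer(0); rate <- numeric(0)
  for (k in seq_len(nEx)) {
    if (ch$ends[k] - ch$starts[k] < 5L) next
    p <- (ch$starts[k] + 2L):(ch$ends[k] - 2L)
    r <- rep(cfg$backgroundErrorRate, length(p))
    if (!is.null(jn)) {
      nearSj <- rep(FALSE, length(p))
      for (j in seq_len(nrow(jn))) {
        nearSj <- nearSj |
          (p >= jn[j, "donor"] - 19L & p <= jn[j, "donor"]) |
          (p >= jn[j, "acceptor"] & p <= jn[j, "acceptor"] + 19L)
      }
      r[nearSj] <- cfg$sjFlankErrorRate
    }
    posAll <- c(posAll, p); rate <- c(rate, r)
  }
  hit <- stats::runif(length(posAll)) < rate
  pos <- posAll[hit]
  if (length(pos) == 0L)
    return(data.frame(kind = character(0), pos = integer(0),
                      len = integer(0), read_id = character(0)))
  kind <- sample(c("substitution", "insertion", "deletion"), length(pos),
                 replace = TRUE, prob = c(0.8, 0.1, 0.1))
  data.frame(kind = kind, pos = pos, len = 1L,
             read_id = NA_character_, stringsAsFactors = FALSE)
}

## Build one SAM line for a read chain with planted events.
.samRecord <- function(rid, ch, ev, chromChars) {
  cigar <- character(0); seqParts <- character(0)
  nEx <- length(ch$starts)
  for (k in seq_len(nEx)) {
    s <- ch$starts[k]; e <- ch$ends[k]
    evb <- ev[ev$pos >= s & ev$pos <= e, , drop = FALSE]
    evb <- evb[order(evb$pos), , drop = FALSE]
    cur <- s
    for (q in seq_len(nrow(evb))) {
      p <- evb$pos[q]; kind <- evb$kind[q]
      if (kind == "substitution") {
        seg <- chromChars[cur:p]
        orig <- seg[length(seg)]
        seg[length(seg)] <- sample(setdiff(c("A", "C", "G", "T"), orig), 1)
        seqParts <- c(seqParts, paste(seg, collapse = ""))
        cigar <- c(cigar, sprintf("%dM", p - cur + 1L))
        cur <- p + 1L
      } else if (kind == "insertion") {
        seqParts <- c(seqParts,
                      paste(chromChars[cur:p], collapse = ""),
                      sample(c("A", "C", "G", "T"), 1))
        cigar <- c(cigar, sprintf("%dM", p - cur + 1L), "1I")
        cur <- p + 1L
      } else {                                    # deletion
        if (p > cur)
          { seqParts <- c(seqParts, paste(chromChars[cur:(p - 1L)], collapse = ""))
            cigar <- c(cigar, sprintf("%dM", p - cur)) }
        cigar <- c(cigar, "1D")
        cur <- p + 1L
      }
    }
    if (cur <= e) {
      seqParts <- c(seqParts, paste(chromChars[cur:e], collapse = ""))
      cigar <- c(cigar, sprintf("%dM", e - cur + 1L))
    }
    if (k < nEx)
      cigar <- c(cigar, sprintf("%dN", ch$starts[k + 1L] - e - 1L))
  }
  ## merge adjacent M ops
  cigar <- .mergeCigar(cigar)
  flag <- if (ch$strand == "+") 0L else 16L
  line <- paste(rid, flag, ch$chrom, ch$starts[1], 60L,
                paste(cigar, collapse = ""),
                "*", 0L, 0L, paste(seqParts, collapse = ""), "*",
                sep = "\t")
  data.frame(chrom = ch$chrom, pos = ch$starts[1], line = line,
             stringsAsFactors = FALSE)
}

.mergeCigar <- function(ops) {
  if (length(ops) < 2L) return(ops)
  lens <- as.integer(sub("[A-Z]$", "", ops))
  kinds <- sub("^[0-9]+", "", ops)
  out <- character(0)
  i <- 1L
  while (i <= length(ops)) {
    j <- i
    while (j < length(ops) && kinds[j + 1L] == kinds[i]) j <- j + 1L
    out <- c(out, sprintf("%d%s", sum(lens[i:j]), kinds[i]))
    i <- j + 1L
  }
  out
}

#' Expected capped/no-cap model counts from simulation truth
#'
#' Computes, by brute-force grouping of the error-free truth read chains,
#' the exact capped- and no-cap-mode model counts a correct collapser must
#' produce, and the resulting expected Degradation Signature. The grouping
#' here is an independent naive implementation (full pairwise match matrix
#' plus iterated boolean closure), not the package's collapse path.
#'
#' @param sim The result of \code{\link{simulateIsoSeq}}.
#' @param w A \linkS4class{WobbleThresholds}.
#' @return A list with \code{CT}, \code{NT} and \code{degsig} (percent).
#' @export
degsigTruth <- function(sim, w = wobbleThresholds()) {
  chains <- sim$readChains
  geneOf <- stats::setNames(sim$readTruth$gene_id, sim$readTruth$read_id)
  count <- function(nocap) {
    grp <- .naiveComponents(chains, w, nocap)
    groups <- split(seq_along(chains), grp)
    nModels <- 0L
    for (ix in groups) {
      nEx <- max(vapply(chains[ix], function(c) length(c$starts), integer(1)))
      if (nEx < 2L) next
      gene <- geneOf[[chains[[ix[1]]]$id]]
      geneReads <- sum(vapply(chains, function(c)
        geneOf[[c$id]] == gene, logical(1)))
      if (geneReads > 1L) nModels <- nModels + 1L
    }
    nModels
  }
  CT <- count(nocap = FALSE)
  NT <- count(nocap = TRUE)
  list(CT = CT, NT = NT,
       degsig = if (CT > 0) 100 * (CT - NT) / CT else NA_real_)
}

## Naive pairwise matcher + boolean transitive closure (oracle-grade code,
## deliberately independent of the igraph-based grouping).
.naiveComponents <- function(chains, w, nocap) {
  n <- length(chains)
  M <- diag(TRUE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    x <- chains[[i]]; y <- chains[[j]]
    ok <- x$chrom == y$chrom && x$strand == y$strand &&
      (if (nocap) .naiveNocap(x, y, w) else .naiveCapped(x, y, w))
    M[i, j] <- M[j, i] <- ok
  }
  repeat {
    M2 <- (M %*% M) > 0
    if (identical(M2, M)) break
    M <- M2
  }
  match(apply(M, 1, function(r) paste(which(r), collapse = ",")),
        unique(apply(M, 1, function(r) paste(which(r), collapse = ","))))
}

.naiveCapped <- function(x, y, w) {
  if (length(x$starts) != length(y$starts)) return(FALSE)
  n <- length(x$starts)
  tssX <- if (x$strand == "+") x$starts[1] else x$ends[n]
  tssY <- if (x$strand == "+") y$starts[1] else y$ends[n]
  tesX <- if (x$strand == "+") x$ends[n] else x$starts[1]
  tesY <- if (x$strand == "+") y$ends[n] else y$starts[1]
  if (abs(tssX - tssY) > w@a || abs(tesX - tesY) > w@z) return(FALSE)
  if (n > 1) {
    for (k in seq_len(n - 1)) {
      if (abs(x$ends[k] - y$ends[k]) > w@m) return(FALSE)
      if (abs(x$starts[k + 1] - y$starts[k + 1]) > w@m) return(FALSE)
    }
  }
  TRUE
}

.naiveNocap <- function(x, y, w) {
  if (length(x$starts) == length(y$starts)) return(.naiveCapped(x, y, w))
  if (length(x$starts) > length(y$starts)) { L <- x; S <- y }
  else { L <- y; S <- x }
  nL <- length(L$starts); nS <- length(S$starts)
  tesL <- if (L$strand == "+") L$ends[nL] else L$starts[1]
  tesS <- if (L$strand == "+") S$ends[nS] else S$starts[1]
  if (abs(tesL - tesS) > w@z) return(FALSE)
  if (nS > 1) {
    for (k in seq_len(nS - 1)) {
      if (L$strand == "+") {
        kL <- nL - nS + k
        if (abs(L$ends[kL] - S$ends[k]) > w@m) return(FALSE)
        if (abs(L$starts[kL + 1] - S$starts[k + 1]) > w@m) return(FALSE)
      } else {
        if (abs(L$ends[k] - S$ends[k]) > w@m) return(FALSE)
        if (abs(L$starts[k + 1] - S$starts[k + 1]) > w@m) return(FALSE)
      }
    }
  }
  corr <- if (L$strand == "+") nL - nS + 1L else nS
  if (L$strand == "+") {
    s5 <- S$starts[1]
    s5 >= L$starts[corr] - w@a && s5 <= L$ends[corr]
  } else {
    s5 <- S$ends[nS]
    s5 <= L$ends[corr] + w@a && s5 >= L$starts[corr]
  }
}
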