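## Shared fixture builders and test-side oracles.  Everything here is
## deliberately naive (full pairwise scans, boolean closure) so it stays
## independent of the package's own algorithms.

mkGR <- function(starts, ends, chrom = "chr1", strand = "+") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends), strand = strand)
}

## Build a TranscriptAnnotation from compact per-transcript specs:
## list(id=, gene=, starts=, ends=, chrom=, strand=)
mkAnn <- function(...) {
  specs <- list(...)
  grl <- GenomicRanges::GRangesList(lapply(specs, function(s)
    mkGR(s$starts, s$ends,
         chrom = if (is.null(s$chrom)) "chr1" else s$chrom,
         strand = if (is.null(s$strand)) "+" else s$strand)))
  names(grl) <- vapply(specs, `[[`, character(1), "id")
  gid <- vapply(specs, function(s)
    if (is.null(s$gene)) s$id else s$gene, character(1))
  rc <- vapply(specs, function(s)
    if (is.null(s$reads)) 0L else as.integer(s$reads), integer(1))
  TranscriptAnnotation(grl, geneId = gid, readCount = rc)
}

## Wrap bare exon chains as a ReadProfiles with empty event lists
## (perfect-quality pseudo-reads).
profilesFromChains <- function(chains) {
  profs <- lapply(chains, function(ch) {
    len <- sum(ch$ends - ch$starts + 1)
    list(read_id = ch$id, chrom = ch$chrom, strand = ch$strand,
         starts = as.integer(ch$starts), ends = as.integer(ch$ends),
         events = data.frame(kind = character(0), pos = integer(0),
                             len = integer(0)),
         read_length = len, coverage = 1, identity = 1)
  })
  new("ReadProfiles", profiles = profs)
}

chain <- function(id, starts, ends, chrom = "chr1", strand = "+") {
  list(id = id, chrom = chrom, strand = strand,
       starts = as.integer(starts), ends = as.integer(ends))
}

## Write SAM lines (with a header) to a temp file.
writeSam <- function(records, seqlens = c(chr1 = 100000L), sorted = TRUE) {
  hd <- c(paste0("@HD\tVN:1.6\tSO:", if (sorted) "coordinate" else "unsorted"),
          sprintf("@SQ\tSN:%s\tLN:%d", names(seqlens), seqlens))
  path <- tempfile(fileext = ".sam")
  writeLines(c(hd, records), path)
  path
}

samLine <- function(qname, chrom, pos, cigar, seq, flag = 0L) {
  paste(qname, flag, chrom, pos, 60, cigar, "*", 0, 0, seq, "*", sep = "\t")
}

## Brute-force grouping oracle: full pairwise match matrix via the exported
## matchers, then iterated boolean closure.
oracleComponents <- function(chains, w, mode) {
  n <- length(chains)
  grs <- lapply(chains, function(ch) mkGR(ch$starts, ch$ends, ch$chrom, ch$strand))
  M <- matrix(FALSE, n, n); diag(M) <- TRUE
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    ok <- if (mode == "capped") matchCapped(grs[[i]], grs[[j]], w)
          else matchNocap(grs[[i]], grs[[j]], w)
    M[i, j] <- M[j, i] <- ok
  }
  repeat {
    M2 <- (M %*% M) > 0
    if (identical(M2, M)) break
    M <- M2
  }
  sig <- apply(M, 1, function(r) paste(which(r), collapse = ","))
  match(sig, unique(sig))
}

## Two partitions are the same up to relabelling?
samePartition <- function(a, b) {
  identical(match(a, unique(a)), match(b, unique(b)))
}

## Random read-chain instance on one locus: a base multi-exon chain plus
## jittered / truncated copies, for grouping-oracle comparisons.
randomInstance <- function(nReads, w, allowTrunc = TRUE) {
  E <- sample(2:4, 1)
  exLen <- sample(100:200, E, replace = TRUE)
  inLen <- sample(150:300, E - 1, replace = TRUE)
  strand <- sample(c("+", "-"), 1)
  starts <- integer(E); ends <- integer(E); pos <- 1000L
  for (k in seq_len(E)) {
    starts[k] <- pos; ends[k] <- pos + exLen[k] - 1L
    if (k < E) pos <- ends[k] + inLen[k] + 1L
  }
  jitter <- function(v, amt) v + sample(seq(-amt, amt), length(v), replace = TRUE)
  chains <- vector("list", nReads)
  for (r in seq_len(nReads)) {
    s <- starts; e <- ends
    ## jitter boundaries around the wobble threshold so both matches and
    ## non-matches occur
    amt <- sample(c(1, ceiling(w@m / 2), w@m + 3), 1)
    s[-1] <- jitter(s[-1], amt); e[-E] <- jitter(e[-E], amt)
    s[1] <- jitter(s[1], max(1, w@a)); e[E] <- jitter(e[E], max(1, w@z))
    keep <- seq_len(E)
    if (allowTrunc && E > 1 && stats::runif(1) < 0.4) {
      drop <- sample(seq_len(E - 1), 1)
      keep <- if (strand == "+") (drop + 1):E else seq_len(E - drop)
    }
    s <- s[keep]; e <- e[keep]
    if (any(e < s) || (length(s) > 1 && any(s[-1] <= e[-length(e)]))) {
      s <- starts[keep]; e <- ends[keep]      # fall back to clean copy
    }
    chains[[r]] <- chain(sprintf("r%d", r), s, e, strand = strand)
  }
  chains
}

## Collapse a simulation end-to-end (SAM -> profiles -> models).
collapseSim <- function(sim, mode, config = NULL) {
  samp <- tempfile(fileext = ".sam")
  writeLines(sim$samLines, samp)
  prof <- profileAlignments(readAlignments(samp), sim$genome)
  if (is.null(config)) config <- collapseConfig(mode)
  collapseReads(prof, sim$genome, config)
}
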