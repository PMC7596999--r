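#' Group reads by exon-intron structure under wobble
#'
#' Groups are the connected components of the pairwise match relation
#' (\code{\link{matchCapped}} or \code{\link{matchNocap}} per the config
#' mode). Because matching is pairwise and transitive, wobble walking is
#' permitted by construction: a staggered series of boundaries, each within
#' the threshold of its neighbour, groups together even when its extremes are
#' farther apart than the threshold.
#'
#' @param profiles A \linkS4class{ReadProfiles} of quality- and LDE-passing
#'   reads.
#' @param config A \linkS4class{CollapseConfig}.
#' @return Integer vector assigning each read to a group.
#' @export
groupReads <- function(profiles, config) {
  chains <- .chains(profiles)
  .matchComponents(chains, config@wobble,
                   modeOf = function(i, j) config@mode)
}

#' Rank and choose splice junctions for a read group
#'
#' For each splice-junction slot of the group's representative chain
#' (anchored at the 3' end so 5'-truncated members align to the right slots),
#' candidate coordinates are ranked by the lowest flanking mismatch count
#' among their supporting reads (a junction with zero flanking mismatches in
#' some read outranks all others), then by supporting-read count, then by
#' leftmost coordinate. With ranking off, candidates are ranked by read
#' support alone.
#'
#' @param chains List of member chains (internal representation) of one group.
#' @param flanks List of per-member junction flank-count matrices, parallel
#'   to \code{chains} (see \code{\link{sjErrorProfile}}).
#' @param sjRanking Logical; use the mismatch-profile ranking.
#' @return A matrix with columns \code{donor}, \code{acceptor}; one row per
#'   junction of the representative chain, ascending genomic order.
#' @export
rankSpliceJunctions <- function(chains, flanks, sjRanking = TRUE) {
  if (length(chains) == 0L) stop("empty read group")
  nEx <- vapply(chains, function(c) length(c$starts), integer(1))
  nRep <- max(nEx)
  strand <- chains[[1]]$strand
  if (nRep < 2L)
    return(cbind(donor = integer(0), acceptor = integer(0)))
  chosen <- matrix(NA_integer_, nrow = nRep - 1L, ncol = 2,
                   dimnames = list(NULL, c("donor", "acceptor")))
  for (slot in seq_len(nRep - 1L)) {
    cand <- list()
    for (mi in seq_along(chains)) {
      ch <- chains[[mi]]
      nj <- length(ch$starts) - 1L
      if (slot > nj) next
      g <- .gIdxOf(ch, slot)
      jn <- .junctions(ch)[g, ]
      fl <- flanks[[mi]]
      err <- if (nrow(fl) >= g) sum(fl[g, ]) else 0L
      key <- paste(jn["donor"], jn["acceptor"])
      if (is.null(cand[[key]]))
        cand[[key]] <- list(donor = jn[["donor"]], acceptor = jn[["acceptor"]],
                            support = 0L, minErr = Inf)
      cand[[key]]$support <- cand[[key]]$support + 1L
      cand[[key]]$minErr <- min(cand[[key]]$minErr, err)
    }
    don <- vapply(cand, `[[`, numeric(1), "donor")
    acc <- vapply(cand, `[[`, numeric(1), "acceptor")
    sup <- vapply(cand, `[[`, numeric(1), "support")
    err <- vapply(cand, `[[`, numeric(1), "minErr")
    o <- if (sjRanking) order(err, -sup, don) else order(-sup, err, don)
    best <- o[1]
    g <- nRep - slot; if (strand == "-") g <- slot
    chosen[g, "donor"] <- don[best]
    chosen[g, "acceptor"] <- acc[best]
  }
  chosen
}

#' Detect a genomic poly-A tract downstream of a model end
#'
#' Flags models whose genome sequence immediately 3' of the transcript end
#' (strand-aware) is A-rich: evidence of internal priming on unprocessed RNA
#' or of genomic DNA contamination rather than a real poly-A tail.
#'
#' @param genome A named \link[Biostrings]{DNAStringSet} or
#'   \link[Rsamtools]{FaFile}.
#' @param chrom Chromosome name.
#' @param strand \code{"+"} or \code{"-"}.
#' @param tes Transcript end coordinate (1-based, last transcribed base).
#' @param window Number of downstream bases to examine (truncated at contig
#'   ends).
#' @param frac Minimum fraction of A (on the transcript strand) to flag.
#' @return \code{TRUE} if the downstream window is A-rich.
#' @export
detectGenomicPolyA <- function(genome, chrom, strand, tes,
                               window = 20, frac = 0.7) {
  contigLen <- if (is(genome, "FaFile")) {
    idx <- Rsamtools::scanFaIndex(genome)
    GenomicRanges::width(idx)[match(chrom, as.character(GenomicRanges::seqnames(idx)))]
  } else length(genome[[chrom]])
  if (strand == "+") {
    from <- tes + 1L; to <- min(tes + window, contigLen)
    if (from > to) return(FALSE)
    s <- .genomeSeq(genome, chrom, from, to)
    base <- "A"
  } else {
    from <- max(1L, tes - window); to <- tes - 1L
    if (from > to) return(FALSE)
    s <- .genomeSeq(genome, chrom, from, to)
    base <- "T"   # A on the transcript strand
  }
  chars <- strsplit(toupper(s), "")[[1]]
  length(chars) > 0 && mean(chars == base) >= frac
}

#' Collapse mapped reads into transcript models
#'
#' The central assembly step: quality- and LDE-passing reads are grouped by
#' exon-intron structure under the configured wobble thresholds and collapse
#' mode; each group becomes one transcript model whose splice junctions are
#' chosen by rank among the member reads, whose start is the 5'-most start
#' among full-length members and whose end is the 3'-most member end. Gene
#' loci are connected components of same-strand >= 1 bp overlap among models,
#' labelled \code{G1, G2, ...} in coordinate order; transcripts within a
#' locus are numbered by descending read count then coordinate.
#'
#' @param profiles A \linkS4class{ReadProfiles} (all mapped primary reads;
#'   filtering happens inside).
#' @param genome Genome accessor for poly-A detection, or \code{NULL} to skip.
#' @param config A \linkS4class{CollapseConfig}.
#' @return A list with elements \code{annotation}
#'   (\linkS4class{TranscriptAnnotation}), \code{transReads} (data.frame
#'   \code{transcript_id}, \code{read_id}), \code{readReport} (per-read
#'   accept/discard report), \code{polya} (data.frame \code{transcript_id},
#'   \code{genomic_polya}) and \code{discarded} (read ids that failed
#'   filters).
#' @export
collapseReads <- function(profiles, genome = NULL,
                          config = collapseConfig()) {
  report <- readReport(profiles, config)
  keep <- report$accepted
  kept <- new("ReadProfiles", profiles = profiles@profiles[keep])
  if (length(kept) == 0L) {
    return(list(annotation = TranscriptAnnotation(GRangesList()),
                transReads = data.frame(transcript_id = character(0),
                                        read_id = character(0)),
                readReport = report,
                polya = data.frame(transcript_id = character(0),
                                   genomic_polya = logical(0)),
                discarded = report$read_id[!keep]))
  }
  chains <- .chains(kept)
  flanks <- sjErrorProfile(kept, config@ldeWindow)
  grp <- groupReads(kept, config)
  modelChains <- vector("list", max(grp))
  members <- split(seq_along(chains), grp)
  for (gi in seq_along(members)) {
    idx <- members[[gi]]
    modelChains[[gi]] <- .buildModel(chains[idx], flanks[idx], config)
  }
  ## gene loci + deterministic ids
  loci <- .lociClusters(modelChains)
  readCount <- vapply(members, length, integer(1))
  ord <- order(loci,
               -readCount,
               vapply(modelChains, function(c) min(c$starts), numeric(1)),
               vapply(modelChains, function(c) max(c$ends), numeric(1)))
  txNum <- stats::ave(seq_along(ord), loci[ord], FUN = seq_along)
  gid <- character(length(ord)); tid <- character(length(ord))
  gid[ord] <- sprintf("G%d", loci[ord])
  tid[ord] <- sprintf("G%d.%d", loci[ord], txNum)
  for (i in seq_along(modelChains)) modelChains[[i]]$id <- tid[i]
  ## store models in locus/transcript order
  modelChains <- modelChains[ord]; gid <- gid[ord]; tid <- tid[ord]
  readCount <- readCount[ord]; members <- members[ord]
  ann <- .annotationFromChains(modelChains, geneId = gid,
                               readCount = readCount)
  transReads <- data.frame(
    transcript_id = rep(tid, readCount),
    read_id = unlist(lapply(members, function(ix)
      vapply(chains[ix], `[[`, character(1), "id"))),
    stringsAsFactors = FALSE)
  polya <- data.frame(transcript_id = tid, genomic_polya = NA)
  if (!is.null(genome)) {
    polya$genomic_polya <- vapply(modelChains, function(c)
      detectGenomicPolyA(genome, c$chrom, c$strand, .tes(c),
                         config@polyaWindow, config@polyaFraction),
      logical(1))
  }
  list(annotation = ann, transReads = transReads, readReport = report,
       polya = polya, discarded = report$read_id[!keep])
}

## Build one model chain from a group's member chains + flank profiles.
.buildModel <- function(chains, flanks, config) {
  nEx <- vapply(chains, function(c) length(c$starts), integer(1))
  nRep <- max(nEx)
  strand <- chains[[1]]$strand
  full <- which(nEx == nRep)
  tssCand <- vapply(chains[full], .tss, numeric(1))
  tesCand <- vapply(chains, .tes, numeric(1))
  tss <- if (strand == "+") min(tssCand) else max(tssCand)
  tes <- if (strand == "+") max(tesCand) else min(tesCand)
  jn <- rankSpliceJunctions(chains, flanks, config@sjRanking)
  if (nRep == 1L) {
    starts <- min(tss, tes); ends <- max(tss, tes)
  } else if (strand == "+") {
    starts <- c(tss, jn[, "acceptor"])
    ends <- c(jn[, "donor"], tes)
  } else {
    starts <- c(tes, jn[, "acceptor"])
    ends <- c(jn[, "donor"], tss)
  }
  if (is.unsorted(starts, strictly = TRUE) || any(ends < starts) ||
      (length(starts) > 1L && any(starts[-1] <= ends[-length(ends)]))) {
    ## pathological wobble left inconsistent boundaries: fall back to the
    ## representative member's own chain with extreme outer ends
    rep1 <- chains[[which.max(nEx)]]
    starts <- rep1$starts; ends <- rep1$ends
    n <- length(starts)
    if (strand == "+") { starts[1] <- min(starts[1], tss); ends[n] <- max(ends[n], tes) }
    else { starts[1] <- min(starts[1], tes); ends[n] <- max(ends[n], tss) }
  }
  list(id = NA_character_, chrom = chains[[1]]$chrom, strand = strand,
       starts = as.integer(starts), ends = as.integer(ends))
}
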