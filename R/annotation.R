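#' Construct a TranscriptAnnotation
#'
#' @param exons A \link[GenomicRanges]{GRangesList} of exon chains, one element
#'   per transcript, named by transcript id. Exons may be given in any order;
#'   they are sorted into ascending genomic order.
#' @param geneId Character vector of gene ids, one per transcript. Defaults to
#'   the transcript ids (each transcript its own locus).
#' @param readCount Integer vector of supporting read counts (default 0).
#' @param sources Character vector of comma-separated source labels.
#' @return A \linkS4class{TranscriptAnnotation}.
#' @examples
#' ex <- GenomicRanges::GRangesList(
#'   T1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(c(101, 401), c(200, 500)), "+"))
#' TranscriptAnnotation(ex, geneId = "G1")
#' @export
TranscriptAnnotation <- function(exons, geneId = names(exons),
                                 readCount = rep(0L, length(exons)),
                                 sources = rep(NA_character_, length(exons))) {
  if (!is(exons, "GRangesList"))
    exons <- GRangesList(exons)
  exons <- endoapply(exons, function(g) g[order(GenomicRanges::start(g))])
  td <- DataFrame(transcript_id = names(exons),
                  gene_id = as.character(geneId),
                  read_count = as.integer(readCount),
                  sources = as.character(sources))
  rownames(td) <- NULL
  new("TranscriptAnnotation", exons = exons, txData = td)
}

#' @importFrom S4Vectors endoapply
NULL

#' Accessors for TranscriptAnnotation
#'
#' \code{transcriptIds}, \code{geneIds}, \code{readCounts} and
#' \code{txSources} return per-transcript metadata; \code{exonsBy} returns the
#' exon chains as a \code{GRangesList}; \code{nTranscripts} and \code{nGenes}
#' count models and loci.
#'
#' @param x A \linkS4class{TranscriptAnnotation}.
#' @return A vector with one entry per transcript model (or, for
#'   \code{exonsBy}, a \code{GRangesList}).
#' @name annotation-accessors
#' @examples
#' ex <- GenomicRanges::GRangesList(
#'   T1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200), "+"))
#' transcriptIds(TranscriptAnnotation(ex))
NULL

#' @rdname annotation-accessors
#' @export
transcriptIds <- function(x) as.character(x@txData$transcript_id)

#' @rdname annotation-accessors
#' @export
geneIds <- function(x) as.character(x@txData$gene_id)

#' @rdname annotation-accessors
#' @export
readCounts <- function(x) as.integer(x@txData$read_count)

#' @rdname annotation-accessors
#' @export
txSources <- function(x) as.character(x@txData$sources)

#' @rdname annotation-accessors
#' @export
exonsBy <- function(x) x@exons

#' @rdname annotation-accessors
#' @export
nTranscripts <- function(x) length(x@exons)

#' @rdname annotation-accessors
#' @export
nGenes <- function(x) length(unique(geneIds(x)))

#' @export
setMethod("length", "TranscriptAnnotation", function(x) length(x@exons))

#' @export
setMethod("show", "TranscriptAnnotation", function(object) {
  cat(sprintf("TranscriptAnnotation: %d transcript model(s), %d gene locus/loci\n",
              nTranscripts(object), nGenes(object)))
  if (length(object) > 0) {
    n <- min(5L, length(object))
    ch <- .chains(object)
    for (i in seq_len(n)) {
      c1 <- ch[[i]]
      cat(sprintf("  %s (%s) %s:%d-%d [%d exon(s)] reads=%d\n",
                  c1$id, object@txData$gene_id[i], c1$chrom,
                  min(c1$starts), max(c1$ends), length(c1$starts),
                  object@txData$read_count[i]))
    }
    if (length(object) > n) cat(sprintf("  ... and %d more\n", length(object) - n))
  }
})

#' @export
setMethod("[", "TranscriptAnnotation", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, transcriptIds(x))
  new("TranscriptAnnotation", exons = x@exons[i], txData = x@txData[i, , drop = FALSE])
})

## ---- internal chain representation -------------------------------------
## A "chain" is list(id, chrom, strand, starts, ends) with starts/ends the
## 1-based closed exon coordinates in ascending genomic order.

.chains <- function(x) {
  if (is(x, "TranscriptAnnotation")) {
    ids <- transcriptIds(x)
    lapply(seq_along(ids), function(i) {
      g <- x@exons[[i]]
      list(id = ids[i],
           chrom = as.character(GenomicRanges::seqnames(g))[1],
           strand = as.character(GenomicRanges::strand(g))[1],
           starts = GenomicRanges::start(g),
           ends = GenomicRanges::end(g))
    })
  } else if (is(x, "ReadProfiles")) {
    lapply(x@profiles, function(p)
      list(id = p$read_id, chrom = p$chrom, strand = p$strand,
           starts = p$starts, ends = p$ends))
  } else stop("cannot extract chains from ", class(x))
}

.chainToGRanges <- function(ch) {
  GRanges(ch$chrom, IRanges(ch$starts, ch$ends), strand = ch$strand)
}

.annotationFromChains <- function(chains, geneId, readCount = NULL,
                                  sources = NULL) {
  grl <- GRangesList(lapply(chains, .chainToGRanges))
  names(grl) <- vapply(chains, `[[`, character(1), "id")
  TranscriptAnnotation(grl, geneId = geneId,
    readCount = if (is.null(readCount)) rep(0L, length(chains)) else readCount,
    sources = if (is.null(sources)) rep(NA_character_, length(chains)) else sources)
}

## Strand-aware feature coordinates of a chain.
.tss <- function(ch) if (ch$strand == "+") ch$starts[1] else ch$ends[length(ch$ends)]
.tes <- function(ch) if (ch$strand == "+") ch$ends[length(ch$ends)] else ch$starts[1]

## Genomic junction list: (donor, acceptor) pairs in ascending genomic order;
## on "-" the biological donor/acceptor roles are swapped but coordinates are
## compared as plain genomic positions throughout.
.junctions <- function(ch) {
  n <- length(ch$starts)
  if (n < 2L) return(cbind(donor = integer(0), acceptor = integer(0)))
  cbind(donor = ch$ends[-n], acceptor = ch$starts[-1])
}

## Map a genomic junction index to its 3'-anchored slot (1 = 3'-most).
.slotOf <- function(ch, gIdx) {
  n <- length(ch$starts)
  if (ch$strand == "+") n - gIdx else gIdx
}

## Genomic junction index of a 3'-anchored slot for a chain with n exons.
.gIdxOf <- function(ch, slot) {
  n <- length(ch$starts)
  if (ch$strand == "+") n - slot else slot
}

## Locus assignment: connected components of same-strand >=1 bp span overlap.
## Returns an integer cluster id per chain, numbered in coordinate order.
.lociClusters <- function(chains) {
  if (length(chains) == 0L) return(integer(0))
  gr <- GRanges(
    vapply(chains, `[[`, character(1), "chrom"),
    IRanges(vapply(chains, function(c) min(c$starts), numeric(1)),
            vapply(chains, function(c) max(c$ends), numeric(1))),
    strand = vapply(chains, `[[`, character(1), "strand"))
  ## min.gapwidth = 0: merge only truly overlapping spans (adjacency is not
  ## >=1 bp overlap)
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  hit <- GenomicRanges::findOverlaps(gr, red)
  cl <- integer(length(gr))
  cl[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)
  ## renumber loci in (chrom, start) order
  o <- order(as.character(GenomicRanges::seqnames(red)),
             GenomicRanges::start(red))
  rank <- integer(length(red)); rank[o] <- seq_along(o)
  rank[cl]
}
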