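## Coerce a match argument to an internal chain.
.asChain <- function(x) {
  if (is.list(x) && !is.null(x$starts)) return(x)
  if (is(x, "GRanges")) {
    o <- order(GenomicRanges::start(x))
    return(list(id = NA_character_,
                chrom = as.character(GenomicRanges::seqnames(x))[1],
                strand = as.character(GenomicRanges::strand(x))[1],
                starts = GenomicRanges::start(x)[o],
                ends = GenomicRanges::end(x)[o]))
  }
  stop("cannot interpret exon chain of class ", class(x)[1])
}

## Core capped comparison on two chains known to share chrom+strand.
.matchCappedChains <- function(x, y, w) {
  nx <- length(x$starts)
  if (nx != length(y$starts)) return(FALSE)
  if (abs(.tss(x) - .tss(y)) > w@a) return(FALSE)
  if (abs(.tes(x) - .tes(y)) > w@z) return(FALSE)
  if (nx > 1L) {
    if (any(abs(x$ends[-nx] - y$ends[-nx]) > w@m)) return(FALSE)
    if (any(abs(x$starts[-1] - y$starts[-1]) > w@m)) return(FALSE)
  }
  TRUE
}

## Core no-cap comparison: the shorter model's splice-junction chain must
## match a 3'-terminal suffix of the longer model's chain (within m), the 3'
## ends must agree within z, and the shorter model's 5' end must lie within
## (or within a of the 5' boundary of) the longer model's corresponding exon.
.matchNocapChains <- function(x, y, w) {
  nx <- length(x$starts); ny <- length(y$starts)
  if (nx == ny) return(.matchCappedChains(x, y, w))
  if (nx > ny) { L <- x; S <- y } else { L <- y; S <- x }
  nL <- length(L$starts); nS <- length(S$starts)
  if (abs(.tes(L) - .tes(S)) > w@z) return(FALSE)
  jL <- .junctions(L); jS <- .junctions(S)
  ## 3'-terminal suffix of the longer chain, in genomic order:
  ## on "+" the 3' end is genomic right, so the suffix is the last nS-1
  ## junctions; on "-" it is the first nS-1.
  if (nS > 1L) {
    idx <- if (L$strand == "+") (nL - nS + 1L):(nL - 1L) else seq_len(nS - 1L)
    if (any(abs(jL[idx, "donor"] - jS[, "donor"]) > w@m) ||
        any(abs(jL[idx, "acceptor"] - jS[, "acceptor"]) > w@m))
      return(FALSE)
  }
  ## corresponding exon of the longer model for the shorter model's 5' exon
  corr <- if (L$strand == "+") nL - nS + 1L else nS
  if (L$strand == "+") {
    s5 <- S$starts[1]
    if (s5 < L$starts[corr] - w@a) return(FALSE)   # extends too far 5'
    if (s5 > L$ends[corr]) return(FALSE)           # outside the exon
  } else {
    s5 <- S$ends[nS]
    if (s5 > L$ends[corr] + w@a) return(FALSE)
    if (s5 < L$starts[corr]) return(FALSE)
  }
  TRUE
}

.matchChains <- function(x, y, w, mode) {
  if (x$chrom != y$chrom || x$strand != y$strand) return(FALSE)
  if (mode == "capped") .matchCappedChains(x, y, w)
  else .matchNocapChains(x, y, w)
}

#' Capped-mode exon chain match
#'
#' Two exon chains match in capped mode iff they have the same exon count,
#' their transcription start sites differ by at most \code{a}, their end sites
#' by at most \code{z}, and every internal exon boundary (all splice donors
#' and acceptors) differs by at most \code{m}. All thresholds are inclusive:
#' a boundary exactly at the threshold distance still matches.
#'
#' @param x,y Exon chains: \link[GenomicRanges]{GRanges} of exons (one
#'   transcript each) on the same chromosome and strand.
#' @param w A \linkS4class{WobbleThresholds}.
#' @return \code{TRUE} or \code{FALSE}.
#' @seealso \code{\link{matchNocap}}
#' @export
matchCapped <- function(x, y, w = wobbleThresholds()) {
  x <- .asChain(x); y <- .asChain(y)
  if (x$chrom != y$chrom || x$strand != y$strand) return(FALSE)
  .matchCappedChains(x, y, w)
}

#' No-cap-mode exon chain match
#'
#' Like \code{\link{matchCapped}}, but allows the two chains to differ in
#' exon count at the 5' end, so that reads from 5'-degraded RNA can merge
#' into the full-length model: the shorter chain's entire splice-junction
#' chain must match (within \code{m}) a 3'-terminal suffix of the longer
#' chain's junctions, the 3' ends must agree within \code{z}, and the shorter
#' chain's 5' end must fall within the longer chain's corresponding exon
#' (extension past that exon's 5' boundary is tolerated up to \code{a}).
#' With equal exon counts this degenerates to the capped match.
#'
#' @inheritParams matchCapped
#' @return \code{TRUE} or \code{FALSE}.
#' @export
matchNocap <- function(x, y, w = wobbleThresholds()) {
  x <- .asChain(x); y <- .asChain(y)
  if (x$chrom != y$chrom || x$strand != y$strand) return(FALSE)
  .matchNocapChains(x, y, w)
}

## Connected components of the pairwise match relation over a list of chains.
## Pruned by span overlap (padded by the largest threshold) before the exact
## pairwise test; components computed with igraph. Returns an integer
## membership vector.
#' @importFrom igraph graph_from_data_frame components vcount
.matchComponents <- function(chains, w, modeOf) {
  n <- length(chains)
  if (n == 0L) return(integer(0))
  pad <- max(w@a, w@m, w@z)
  gr <- GRanges(
    vapply(chains, `[[`, character(1), "chrom"),
    IRanges(pmax(1L, vapply(chains, function(c) min(c$starts), numeric(1)) - pad),
            vapply(chains, function(c) max(c$ends), numeric(1)) + pad),
    strand = vapply(chains, `[[`, character(1), "strand"))
  hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  keep <- logical(length(qh))
  for (k in seq_along(qh)) {
    i <- qh[k]; j <- sh[k]
    keep[k] <- .matchChains(chains[[i]], chains[[j]], w, modeOf(i, j))
  }
  edges <- cbind(qh[keep], sh[keep])
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  comp <- igraph::components(g)$membership
  as.integer(comp[as.character(seq_len(n))])
}
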