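#' Specify one merge input source
#'
#' @param annotation A \linkS4class{TranscriptAnnotation} (or a BED12 path,
#'   read with \code{\link{readBed12}}).
#' @param label Unique source label.
#' @param mode Collapse mode for this source: \code{"capped"} or
#'   \code{"no_cap"}. A pair of models is compared in no-cap mode when either
#'   member's source is no-cap, which lets 5'-truncated long-read models
#'   absorb into capped reference models.
#' @param priority Integer vector \code{c(tss, sj, tes)} of feature
#'   priorities; 1 is highest. The merged model's start, junctions and end
#'   are taken from the highest-priority source present in each group.
#' @return A list describing the source, for \code{\link{mergeAnnotations}}.
#' @export
mergeSource <- function(annotation, label, mode = c("capped", "no_cap"),
                        priority = c(1, 1, 1)) {
  mode <- match.arg(mode)
  if (is.character(annotation)) annotation <- readBed12(annotation)
  stopifnot(is(annotation, "TranscriptAnnotation"),
            length(priority) == 3, all(priority >= 1))
  list(annotation = annotation, label = label, mode = mode,
       tss_rank = as.integer(priority[1]), sj_rank = as.integer(priority[2]),
       tes_rank = as.integer(priority[3]))
}

#' Merge annotations into a non-redundant transcript set
#'
#' Combines one or more annotations by the same pairwise wobble matching used
#' for read collapsing. Each connected component of the match relation
#' becomes one merged transcript; its splice junctions come from the
#' highest-sj-priority source present in the component (ties broken by
#' contributor count, then leftmost coordinate), its start from the
#' highest-tss-priority full-length contributor (ties by most extreme 5' end)
#' and its end from the highest-tes-priority contributor (ties by most
#' extreme 3' end). Gene loci are re-derived from same-strand >= 1 bp
#' overlap. Merging an annotation with itself is idempotent.
#'
#' @param sources List of \code{\link{mergeSource}} specifications with
#'   unique labels.
#' @param w A \linkS4class{WobbleThresholds}.
#' @return A list with \code{annotation} (\linkS4class{TranscriptAnnotation};
#'   \code{sources} column lists contributing labels), \code{transReport}
#'   (data.frame: merged transcript, contributing label and transcript id,
#'   and signed per-boundary wobble offsets \code{final - contributor}) and
#'   \code{geneReport} (data.frame: merged gene, contributing labels).
#' @export
mergeAnnotations <- function(sources, w = wobbleThresholds()) {
  if (length(sources) < 1L) stop("need at least one source")
  labels <- vapply(sources, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("source labels must be unique")
  chains <- list(); meta <- list()
  for (s in sources) {
    ids <- transcriptIds(s$annotation)
    if (anyDuplicated(ids))
      stop("duplicate transcript ids within source ", s$label)
    ch <- .chains(s$annotation)
    for (k in seq_along(ch)) {
      chains[[length(chains) + 1L]] <- ch[[k]]
      meta[[length(meta) + 1L]] <- list(label = s$label, tx = ids[k],
        mode = s$mode, tss_rank = s$tss_rank, sj_rank = s$sj_rank,
        tes_rank = s$tes_rank)
    }
  }
  if (length(chains) == 0L)
    return(list(annotation = TranscriptAnnotation(GRangesList()),
                transReport = data.frame(), geneReport = data.frame()))
  modes <- vapply(meta, `[[`, character(1), "mode")
  grp <- .matchComponents(chains, w, modeOf = function(i, j)
    if (modes[i] == "no_cap" || modes[j] == "no_cap") "no_cap" else "capped")
  members <- split(seq_along(chains), grp)
  modelChains <- vector("list", length(members))
  contribs <- vector("list", length(members))
  for (gi in seq_along(members)) {
    idx <- members[[gi]]
    modelChains[[gi]] <- .buildMergedModel(chains[idx], meta[idx], w)
    contribs[[gi]] <- idx
  }
  loci <- .lociClusters(modelChains)
  nMem <- vapply(members, length, integer(1))
  ord <- order(loci, -nMem,
               vapply(modelChains, function(c) min(c$starts), numeric(1)),
               vapply(modelChains, function(c) max(c$ends), numeric(1)))
  txNum <- stats::ave(seq_along(ord), loci[ord], FUN = seq_along)
  gid <- character(length(ord)); tid <- character(length(ord))
  gid[ord] <- sprintf("G%d", loci[ord])
  tid[ord] <- sprintf("G%d.%d", loci[ord], txNum)
  for (i in seq_along(modelChains)) modelChains[[i]]$id <- tid[i]
  modelChains <- modelChains[ord]; gid <- gid[ord]; tid <- tid[ord]
  nMem <- nMem[ord]; contribs <- contribs[ord]
  srcLabels <- vapply(contribs, function(ix)
    paste(sort(unique(vapply(meta[ix], `[[`, character(1), "label"))),
          collapse = ","), character(1))
  ann <- .annotationFromChains(modelChains, geneId = gid,
                               readCount = nMem, sources = srcLabels)
  transReport <- do.call(rbind, lapply(seq_along(modelChains), function(gi) {
    idx <- contribs[[gi]]
    do.call(rbind, lapply(idx, function(i)
      data.frame(transcript_id = tid[gi],
                 source = meta[[i]]$label,
                 source_transcript_id = meta[[i]]$tx,
                 wobble = .boundaryWobble(modelChains[[gi]], chains[[i]]),
                 stringsAsFactors = FALSE)))
  }))
  geneReport <- do.call(rbind, lapply(split(seq_along(modelChains),
                                            gid), function(ix)
    data.frame(gene_id = gid[ix[1]],
               sources = paste(sort(unique(unlist(lapply(contribs[ix],
                 function(jx) vapply(meta[jx], `[[`, character(1), "label"))))),
                 collapse = ","),
               n_transcripts = length(ix), stringsAsFactors = FALSE)))
  rownames(transReport) <- rownames(geneReport) <- NULL
  list(annotation = ann, transReport = transReport, geneReport = geneReport)
}

## Signed offsets (final - contributor) over the contributor's boundaries,
## aligned at the 3' end, reported as a compact "s:e,s:e,..." string.
.boundaryWobble <- function(final, contrib) {
  nF <- length(final$starts); nC <- length(contrib$starts)
  if (final$strand == "+") {
    off <- nF - nC
    ds <- final$starts[seq_len(nC) + off] - contrib$starts
    de <- final$ends[seq_len(nC) + off] - contrib$ends
  } else {
    ds <- final$starts[seq_len(nC)] - contrib$starts
    de <- final$ends[seq_len(nC)] - contrib$ends
  }
  paste(paste0(ds, ":", de), collapse = ",")
}

## Merged model construction with per-source feature priorities.
.buildMergedModel <- function(chains, meta, w) {
  nEx <- vapply(chains, function(c) length(c$starts), integer(1))
  nRep <- max(nEx)
  strand <- chains[[1]]$strand
  ## TSS: full-length contributors only, best (lowest) tss_rank, most extreme
  full <- which(nEx == nRep)
  tssRank <- vapply(meta[full], `[[`, integer(1), "tss_rank")
  tssPool <- full[tssRank == min(tssRank)]
  tssCand <- vapply(chains[tssPool], .tss, numeric(1))
  tss <- if (strand == "+") min(tssCand) else max(tssCand)
  ## TES: all contributors, best tes_rank, most extreme
  tesRank <- vapply(meta, `[[`, integer(1), "tes_rank")
  tesPool <- which(tesRank == min(tesRank))
  tesCand <- vapply(chains[tesPool], .tes, numeric(1))
  tes <- if (strand == "+") max(tesCand) else min(tesCand)
  if (nRep == 1L)
    return(list(id = NA_character_, chrom = chains[[1]]$chrom,
                strand = strand, starts = as.integer(min(tss, tes)),
                ends = as.integer(max(tss, tes))))
  ## SJ slots (3'-anchored): candidate coordinate pairs ranked by best
  ## sj_rank among supporters, then contributor count, then leftmost
  jn <- matrix(NA_integer_, nrow = nRep - 1L, ncol = 2,
               dimnames = list(NULL, c("donor", "acceptor")))
  for (slot in seq_len(nRep - 1L)) {
    cand <- list()
    for (mi in seq_along(chains)) {
      ch <- chains[[mi]]
      if (slot > length(ch$starts) - 1L) next
      g <- .gIdxOf(ch, slot)
      j1 <- .junctions(ch)[g, ]
      key <- paste(j1["donor"], j1["acceptor"])
      if (is.null(cand[[key]]))
        cand[[key]] <- list(donor = j1[["donor"]], acceptor = j1[["acceptor"]],
                            support = 0L, rank = Inf)
      cand[[key]]$support <- cand[[key]]$support + 1L
      cand[[key]]$rank <- min(cand[[key]]$rank, meta[[mi]]$sj_rank)
    }
    don <- vapply(cand, `[[`, numeric(1), "donor")
    acc <- vapply(cand, `[[`, numeric(1), "acceptor")
    sup <- vapply(cand, `[[`, numeric(1), "support")
    rk <- vapply(cand, `[[`, numeric(1), "rank")
    best <- order(rk, -sup, don)[1]
    g <- if (strand == "+") nRep - slot else slot
    jn[g, "donor"] <- don[best]
    jn[g, "acceptor"] <- acc[best]
  }
  if (strand == "+") {
    starts <- c(tss, jn[, "acceptor"]); ends <- c(jn[, "donor"], tes)
  } else {
    starts <- c(tes, jn[, "acceptor"]); ends <- c(jn[, "donor"], tss)
  }
  if (is.unsorted(starts, strictly = TRUE) || any(ends < starts) ||
      any(starts[-1] <= ends[-length(ends)])) {
    rep1 <- chains[[which.max(nEx)]]
    starts <- rep1$starts; ends <- rep1$ends
    n <- length(starts)
    if (strand == "+") { starts[1] <- min(starts[1], tss); ends[n] <- max(ends[n], tes) }
    else { starts[1] <- min(starts[1], tes); ends[n] <- max(ends[n], tss) }
  }
  list(id = NA_character_, chrom = chains[[1]]$chrom, strand = strand,
       starts = as.integer(starts), ends = as.integer(ends))
}

#' Same-strand gene locus overlap between two annotations
#'
#' For each gene locus of \code{b}, lists the gene loci of \code{a} whose
#' exonic span overlaps it by at least 1 bp on the same strand. Supports
#' many-to-one relations (several loci of \code{a} overlapped by one locus of
#' \code{b}).
#'
#' @param a,b \linkS4class{TranscriptAnnotation} objects on the same genome.
#' @return A data.frame with columns \code{gene_b}, \code{gene_a}; zero rows
#'   when the annotations are disjoint.
#' @export
lociOverlap <- function(a, b) {
  spanOf <- function(ann) {
    ch <- .chains(ann); gid <- geneIds(ann)
    gs <- split(seq_along(ch), gid)
    GRanges(
      vapply(gs, function(ix) ch[[ix[1]]]$chrom, character(1)),
      IRanges(vapply(gs, function(ix)
                min(vapply(ch[ix], function(c) min(c$starts), numeric(1))),
                numeric(1)),
              vapply(gs, function(ix)
                max(vapply(ch[ix], function(c) max(c$ends), numeric(1))),
                numeric(1))),
      strand = vapply(gs, function(ix) ch[[ix[1]]]$strand, character(1)),
      gene = names(gs))
  }
  if (nTranscripts(a) == 0L || nTranscripts(b) == 0L)
    return(data.frame(gene_b = character(0), gene_a = character(0)))
  ga <- spanOf(a); gb <- spanOf(b)
  hits <- GenomicRanges::findOverlaps(gb, ga, minoverlap = 1L)
  data.frame(gene_b = gb$gene[S4Vectors::queryHits(hits)],
             gene_a = ga$gene[S4Vectors::subjectHits(hits)],
             stringsAsFactors = FALSE)
}

#' Compare 5' completeness of 3'-matching transcript pairs
#'
#' Finds pairs (one model from each annotation) whose splice-junction chains
#' match at the 3' end (the shorter chain's junctions are a 3'-terminal
#' suffix of the longer's, within \code{m}; ends within the \code{a}/\code{z}
#' allowances), then classifies which side has the longer 5' representation
#' and flags pairs where the longer member has additional 5' exons.
#'
#' @param a,b \linkS4class{TranscriptAnnotation} objects.
#' @param w A \linkS4class{WobbleThresholds} (typically generous ends, e.g.
#'   \code{wobbleThresholds(300, 30, 300)}).
#' @return A data.frame with columns \code{tx_a}, \code{tx_b},
#'   \code{classification} (\code{"a_longer_5prime"},
#'   \code{"b_longer_5prime"} or \code{"equal"}) and
#'   \code{extra_5prime_exons}.
#' @export
threePrimeMatchCompare <- function(a, b, w = wobbleThresholds(300, 30, 300)) {
  cha <- .chains(a); chb <- .chains(b)
  out <- list()
  for (i in seq_along(cha)) for (j in seq_along(chb)) {
    x <- cha[[i]]; y <- chb[[j]]
    if (x$chrom != y$chrom || x$strand != y$strand) next
    if (!.matchNocapChains(x, y, w)) next
    nx <- length(x$starts); ny <- length(y$starts)
    cls <- if (nx > ny) "a_longer_5prime"
           else if (ny > nx) "b_longer_5prime"
           else {
             dx <- .tss(x); dy <- .tss(y)
             if (dx == dy) "equal"
             else if ((x$strand == "+") == (dx < dy)) "a_longer_5prime"
             else "b_longer_5prime"
           }
    out[[length(out) + 1L]] <- data.frame(
      tx_a = x$id, tx_b = y$id, classification = cls,
      extra_5prime_exons = nx != ny, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(tx_a = character(0), tx_b = character(0),
                      classification = character(0),
                      extra_5prime_exons = logical(0)))
  do.call(rbind, out)
}
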