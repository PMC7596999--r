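#' Degradation Signature
#'
#' Estimates the proportion of reads originating from 5'-degraded RNA by
#' comparing a capped-mode collapse with a no-cap-mode collapse of the same
#' reads: DegSig = (CT - NT) / CT, where CT is the number of multi-exon
#' transcript models from genes with more than one supporting read in the
#' capped run, and NT the same count in the no-cap run. Because no-cap mode
#' lets 5'-truncated models merge into their full-length parents, the models
#' that disappear between the two runs are those explained by 5' truncation.
#'
#' @param capped,nocap Lists with elements \code{annotation}
#'   (\linkS4class{TranscriptAnnotation}) and \code{transReads} (data.frame
#'   \code{transcript_id}, \code{read_id}) from \code{\link{collapseReads}}
#'   run in capped and no-cap mode on the same reads.
#' @return A list with \code{CT}, \code{NT} and \code{degsig} (percent; one
#'   decimal is the conventional presentation; \code{NA} when CT = 0).
#' @examples
#' # DegSig for CT = 10, NT = 4 is (10 - 4) / 10 = 60%
#' @export
degradationSignature <- function(capped, nocap) {
  readsC <- unique(capped$transReads$read_id)
  readsN <- unique(nocap$transReads$read_id)
  dsym <- length(setdiff(readsC, readsN)) + length(setdiff(readsN, readsC))
  if (dsym > 0L)
    warning("capped and no_cap runs differ in ", dsym, " read(s)")
  CT <- .countMultiExonMultiRead(capped$annotation, capped$transReads)
  NT <- .countMultiExonMultiRead(nocap$annotation, nocap$transReads)
  degsig <- if (CT > 0) 100 * (CT - NT) / CT else NA_real_
  list(CT = CT, NT = NT, degsig = degsig)
}

## Multi-exon transcript models belonging to genes with total read support > 1.
.countMultiExonMultiRead <- function(ann, transReads) {
  if (nTranscripts(ann) == 0L) return(0L)
  ch <- .chains(ann)
  nEx <- vapply(ch, function(c) length(c$starts), integer(1))
  gid <- geneIds(ann)
  geneReads <- vapply(split(seq_along(ch), gid), function(ix) {
    ids <- transcriptIds(ann)[ix]
    length(unique(transReads$read_id[transReads$transcript_id %in% ids]))
  }, integer(1))
  sum(nEx > 1L & geneReads[gid] > 1L)
}

#' Splice-junction wobble against a reference annotation
#'
#' Matches each query transcript to a reference transcript with the same
#' exon count whose boundaries agree within \code{maxWobble} per splice
#' junction and \code{endsAllowance} at the transcript start/end, then
#' reports the signed offsets (query - reference) at every donor and
#' acceptor. Start/end offsets are excluded: transcript ends are naturally
#' variable and say nothing about splice-junction accuracy. When several
#' reference models match, the one with the smallest mean absolute offset is
#' used.
#'
#' @param query,reference \linkS4class{TranscriptAnnotation} objects on the
#'   same genome.
#' @param maxWobble Per-junction matching allowance in bases (default 30).
#' @param endsAllowance Start/end matching allowance in bases (default 300).
#' @return A list with \code{offsets} (data.frame: \code{query_id},
#'   \code{ref_id}, \code{junction}, \code{donor_offset},
#'   \code{acceptor_offset}) and \code{perTranscript} (data.frame:
#'   \code{query_id}, \code{ref_id}, \code{mean_abs_offset}).
#' @export
sjWobble <- function(query, reference, maxWobble = 30, endsAllowance = 300) {
  w <- wobbleThresholds(a = endsAllowance, m = maxWobble, z = endsAllowance)
  chq <- .chains(query); chr <- .chains(reference)
  offs <- list(); per <- list()
  for (i in seq_along(chq)) {
    x <- chq[[i]]
    if (length(x$starts) < 2L) next          # no junctions to assess
    bestJ <- NA_integer_; bestMean <- Inf
    for (j in seq_along(chr)) {
      y <- chr[[j]]
      if (x$chrom != y$chrom || x$strand != y$strand) next
      if (!.matchCappedChains(x, y, w)) next
      jx <- .junctions(x); jy <- .junctions(y)
      m1 <- mean(abs(c(jx[, "donor"] - jy[, "donor"],
                       jx[, "acceptor"] - jy[, "acceptor"])))
      if (m1 < bestMean) { bestMean <- m1; bestJ <- j }
    }
    if (is.na(bestJ)) next
    y <- chr[[bestJ]]
    jx <- .junctions(x); jy <- .junctions(y)
    offs[[length(offs) + 1L]] <- data.frame(
      query_id = x$id, ref_id = y$id, junction = seq_len(nrow(jx)),
      donor_offset = jx[, "donor"] - jy[, "donor"],
      acceptor_offset = jx[, "acceptor"] - jy[, "acceptor"],
      stringsAsFactors = FALSE)
    per[[length(per) + 1L]] <- data.frame(
      query_id = x$id, ref_id = y$id, mean_abs_offset = bestMean,
      stringsAsFactors = FALSE)
  }
  empty1 <- data.frame(query_id = character(0), ref_id = character(0),
                       junction = integer(0), donor_offset = numeric(0),
                       acceptor_offset = numeric(0))
  empty2 <- data.frame(query_id = character(0), ref_id = character(0),
                       mean_abs_offset = numeric(0))
  list(offsets = if (length(offs)) do.call(rbind, offs) else empty1,
       perTranscript = if (length(per)) do.call(rbind, per) else empty2)
}

#' Detect read-jumble events between two pipelines
#'
#' Given a merged annotation built from exactly two pipeline annotations and
#' the traced read support, any read supporting more than one merged
#' transcript model is a jumble event: the read was assigned to different
#' models by the two pipelines. Events are classified as gene-level when the
#' two models belong to different gene loci, transcript-level otherwise.
#'
#' @param merged The \code{annotation} from \code{\link{mergeAnnotations}} of
#'   the two pipelines.
#' @param support A read-support data.frame covering both pipelines
#'   (\code{\link{readSupportLevels}}).
#' @return A list with \code{events} (data.frame: \code{read_id},
#'   \code{model_before}, \code{model_after}, \code{gene_before},
#'   \code{gene_after}, \code{level}) and \code{summary} (counts by level).
#' @export
findModelChanges <- function(merged, support) {
  gid <- stats::setNames(geneIds(merged), transcriptIds(merged))
  byRead <- split(support$transcript_id, support$read_id)
  events <- list()
  for (rid in names(byRead)) {
    txs <- sort(unique(byRead[[rid]]))
    if (length(txs) < 2L) next
    ## one event per read: the pair of differing assignments (first two in
    ## deterministic order when a read touches more than two models)
    g1 <- unname(gid[txs[1]]); g2 <- unname(gid[txs[2]])
    events[[length(events) + 1L]] <- data.frame(
      read_id = rid, model_before = txs[1], model_after = txs[2],
      gene_before = g1, gene_after = g2,
      level = if (identical(g1, g2)) "transcript" else "gene",
      stringsAsFactors = FALSE)
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(read_id = character(0), model_before = character(0),
               model_after = character(0), gene_before = character(0),
               gene_after = character(0), level = character(0))
  list(events = ev,
       summary = c(gene = sum(ev$level == "gene"),
                   transcript = sum(ev$level == "transcript")))
}
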