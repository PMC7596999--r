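#' Trace read support through collapse/merge chains
#'
#' Builds the transitive mapping from final transcript ids down to the
#' original read ids, through arbitrarily many merge steps. A read-support
#' table is a data.frame with columns \code{transcript_id}, \code{source} and
#' \code{read_id}; the per-collapse \code{transReads} table (plus a label)
#' is the base case.
#'
#' @param transReport A merge \code{transReport} (columns
#'   \code{transcript_id}, \code{source}, \code{source_transcript_id}), or
#'   \code{NULL} to label a single collapse output.
#' @param upstream Named list (by source label) of upstream read-support
#'   tables, or, in the base case, a single \code{transReads} data.frame.
#' @param label Source label for the base case.
#' @return A read-support data.frame (one row per transcript/source/read).
#' @examples
#' tr <- data.frame(transcript_id = "G1.1", read_id = c("r1", "r2"))
#' rs <- readSupportLevels(NULL, tr, label = "cell1")
#' @export
readSupportLevels <- function(transReport, upstream, label = "reads") {
  if (is.null(transReport)) {
    stopifnot(is.data.frame(upstream),
              all(c("transcript_id", "read_id") %in% names(upstream)))
    return(data.frame(transcript_id = upstream$transcript_id,
                      source = label,
                      read_id = upstream$read_id,
                      stringsAsFactors = FALSE))
  }
  stopifnot(all(c("transcript_id", "source", "source_transcript_id") %in%
                names(transReport)))
  out <- list()
  for (k in seq_len(nrow(transReport))) {
    src <- transReport$source[k]
    stx <- transReport$source_transcript_id[k]
    up <- upstream[[src]]
    if (is.null(up))
      stop("no upstream support table for source '", src, "'")
    rows <- up[up$transcript_id == stx, , drop = FALSE]
    if (nrow(rows) == 0L)
      stop("dangling contributor id '", stx, "' from source '", src, "'")
    out[[k]] <- data.frame(transcript_id = transReport$transcript_id[k],
                           source = rows$source,
                           read_id = rows$read_id,
                           stringsAsFactors = FALSE)
  }
  res <- unique(do.call(rbind, out))
  rownames(res) <- NULL
  res
}

#' Per-transcript and per-gene support counts
#'
#' @param a A \linkS4class{TranscriptAnnotation}.
#' @param support A read-support data.frame from
#'   \code{\link{readSupportLevels}}.
#' @param unit Count distinct \code{"reads"} or distinct \code{"sources"}.
#' @return A list with \code{transcript} and \code{gene} named integer
#'   vectors of distinct-support counts (zero for models with no rows).
#' @export
supportCounts <- function(a, support, unit = c("reads", "sources")) {
  unit <- match.arg(unit)
  key <- if (unit == "reads") support$read_id else support$source
  byTx <- tapply(key, support$transcript_id,
                 function(v) length(unique(v)))
  tx <- stats::setNames(rep(0L, nTranscripts(a)), transcriptIds(a))
  common <- intersect(names(byTx), names(tx))
  tx[common] <- as.integer(byTx[common])
  gid <- geneIds(a)
  gene <- vapply(split(seq_along(tx), gid), function(ix) {
    ids <- names(tx)[ix]
    length(unique(key[support$transcript_id %in% ids]))
  }, integer(1))
  list(transcript = tx, gene = gene)
}

#' Remove fragment models
#'
#' A model is removed iff some other model's splice-junction chain contains
#' the model's full junction chain as a contiguous subchain (each boundary
#' within \code{m}) and that other model extends strictly beyond it on both
#' the 5' and 3' ends. A single-exon model is removed iff it lies strictly
#' inside a longer model's single exon span. Containment requires a
#' contiguous subchain, not a subsequence: the internal structure must be
#' identical.
#'
#' @param a A \linkS4class{TranscriptAnnotation}.
#' @param m Splice-junction wobble in bases.
#' @return The filtered \linkS4class{TranscriptAnnotation}.
#' @export
removeFragments <- function(a, m = 0) {
  ch <- .chains(a)
  n <- length(ch)
  if (n < 2L) return(a)
  isFrag <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (.isFragmentOf(ch[[i]], ch[[j]], m)) { isFrag[i] <- TRUE; break }
    }
  }
  a[which(!isFrag)]
}

## Is `frag` a fragment of `full`?  Both ends of `full` must extend strictly
## beyond `frag` (in genomic coordinates; strand-symmetric).
.isFragmentOf <- function(frag, full, m) {
  if (frag$chrom != full$chrom || frag$strand != full$strand) return(FALSE)
  fragSpan <- c(min(frag$starts), max(frag$ends))
  fullSpan <- c(min(full$starts), max(full$ends))
  if (!(fullSpan[1] < fragSpan[1] && fullSpan[2] > fragSpan[2])) return(FALSE)
  jF <- .junctions(frag); jL <- .junctions(full)
  nF <- nrow(jF); nL <- nrow(jL)
  if (nF == 0L) {
    ## single-exon fragment: both ends strictly inside one exon of the
    ## longer model
    return(any(full$starts < fragSpan[1] & full$ends > fragSpan[2]))
  }
  if (nL < nF) return(FALSE)
  for (off in 0:(nL - nF)) {
    idx <- seq_len(nF) + off
    if (all(abs(jL[idx, "donor"] - jF[, "donor"]) <= m) &&
        all(abs(jL[idx, "acceptor"] - jF[, "acceptor"]) <= m))
      return(TRUE)
  }
  FALSE
}

#' Filter models by read or source support
#'
#' Keeps a transcript (or a whole gene) iff its distinct supporting read
#' count, or distinct source-label count, reaches \code{minCount}. Removing
#' at gene level drops all the gene's transcripts. Monotone: raising
#' \code{minCount} never adds survivors.
#'
#' @param a A \linkS4class{TranscriptAnnotation}.
#' @param support A read-support data.frame
#'   (\code{\link{readSupportLevels}}).
#' @param level \code{"transcript"} or \code{"gene"}.
#' @param minCount Minimum distinct support count.
#' @param unit \code{"reads"} or \code{"sources"} (e.g. require models to be
#'   seen in at least two sequencing runs with \code{unit = "sources",
#'   minCount = 2}).
#' @return The filtered \linkS4class{TranscriptAnnotation}.
#' @export
filterBySupport <- function(a, support, level = c("transcript", "gene"),
                            minCount = 1, unit = c("reads", "sources")) {
  level <- match.arg(level); unit <- match.arg(unit)
  cnt <- supportCounts(a, support, unit)
  if (level == "transcript") {
    keep <- cnt$transcript[transcriptIds(a)] >= minCount
  } else {
    okGene <- names(cnt$gene)[cnt$gene >= minCount]
    keep <- geneIds(a) %in% okGene
  }
  a[which(keep)]
}

#' Reference-guided filtering of a long-read annotation
#'
#' Retains only long-read models matching the reference annotation, adopting
#' the reference's coordinates and splice junctions: the two annotations are
#' merged (long-read source in no-cap mode with priority 2,2,2; reference
#' capped with priority 1,1,1) and merged transcripts supported by both
#' sources are kept.
#'
#' @param longRead,reference \linkS4class{TranscriptAnnotation} objects.
#' @param w A \linkS4class{WobbleThresholds}.
#' @return The guided \linkS4class{TranscriptAnnotation} (reference-derived
#'   coordinates; \code{sources} lists both labels).
#' @export
guidedFilter <- function(longRead, reference, w = wobbleThresholds()) {
  mg <- mergeAnnotations(list(
    mergeSource(longRead, "long_read", mode = "no_cap", priority = c(2, 2, 2)),
    mergeSource(reference, "reference", mode = "capped", priority = c(1, 1, 1))),
    w = w)
  if (nTranscripts(mg$annotation) == 0L) return(mg$annotation)
  nsrc <- tapply(mg$transReport$source, mg$transReport$transcript_id,
                 function(v) length(unique(v)))
  keepIds <- names(nsrc)[nsrc >= 2L]
  mg$annotation[which(transcriptIds(mg$annotation) %in% keepIds)]
}
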