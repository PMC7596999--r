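#' Spliced transcript sequences
#'
#' Extracts the spliced, strand-corrected nucleotide sequence of every model
#' (exons concatenated 5' to 3'; reverse-complemented on the minus strand).
#'
#' @param a A \linkS4class{TranscriptAnnotation}.
#' @param genome A named \link[Biostrings]{DNAStringSet} or
#'   \link[Rsamtools]{FaFile}.
#' @return A \link[Biostrings]{DNAStringSet} named by transcript id.
#' @export
transcriptSeqs <- function(a, genome) {
  ch <- .chains(a)
  seqs <- vapply(ch, function(c1) {
    parts <- vapply(seq_along(c1$starts), function(k)
      .genomeSeq(genome, c1$chrom, c1$starts[k], c1$ends[k]), character(1))
    s <- paste(parts, collapse = "")
    if (c1$strand == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }, character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- transcriptIds(a)
  out
}

#' @importFrom Biostrings DNAString
NULL

#' Find the longest stop-terminated ORF in each forward frame
#'
#' For each of the three forward frames, reports the longest open stretch
#' that ends in a stop codon (the stretch runs from the frame start, or from
#' the codon after the previous stop, up to and including the stop codon).
#' Start codons are not required; \code{has_start} records whether the
#' stretch begins with ATG — its absence is evidence that the transcript may
#' come from degraded RNA. The reverse strand is never scanned: models are
#' already strand-corrected.
#'
#' @param seqs A named \link[Biostrings]{DNAStringSet} (or named character
#'   vector) of spliced transcript sequences.
#' @return A data.frame with one row per (transcript, frame) that has a
#'   stop-terminated ORF: \code{transcript_id}, \code{frame} (0/1/2),
#'   \code{orf_start}, \code{orf_stop} (0-based transcript coordinates, stop
#'   codon included, so \code{orf_stop - orf_start} is divisible by 3),
#'   \code{has_start}, \code{peptide} (stop excluded).
#' @examples
#' findOrfs(c(T1 = "ATGAAATAG"))   # peptide "MK", has_start TRUE
#' @export
findOrfs <- function(seqs) {
  if (is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  stopifnot(!is.null(names(seqs)))
  rows <- list()
  for (tx in names(seqs)) {
    s <- toupper(seqs[[tx]])
    n <- nchar(s)
    for (frame in 0:2) {
      ncod <- (n - frame) %/% 3
      if (ncod < 1L) next
      codons <- substring(s, frame + 1L + 3L * (seq_len(ncod) - 1L),
                          frame + 3L * seq_len(ncod))
      isStop <- codons %in% c("TAA", "TAG", "TGA")
      if (!any(isStop)) next
      stops <- which(isStop)
      segStart <- c(1L, stops[-length(stops)] + 1L)
      segLen <- stops - segStart + 1L          # codons incl. the stop
      best <- which.max(segLen)                # first maximum: 5'-most
      a <- segStart[best]; b <- stops[best]
      orfStart <- frame + 3L * (a - 1L)        # 0-based
      orfStop <- frame + 3L * b
      pep <- if (b > a)
        as.character(Biostrings::translate(
          Biostrings::DNAString(substring(s, orfStart + 1L, orfStop - 3L))))
      else ""
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = tx, frame = frame,
        orf_start = orfStart, orf_stop = orfStop,
        has_start = codons[a] == "ATG", peptide = pep,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(transcript_id = character(0), frame = integer(0),
                      orf_start = integer(0), orf_stop = integer(0),
                      has_start = logical(0), peptide = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Label a transcript as an NMD candidate
#'
#' Applies the canonical 50-nucleotide rule: a transcript is flagged for
#' nonsense-mediated decay when its stop codon lies at least 50 nt upstream
#' (in transcript coordinates) of the final exon-exon junction. Single-exon
#' transcripts are never NMD candidates.
#'
#' @param exons Exon chain of the model (\link[GenomicRanges]{GRanges} or
#'   internal chain).
#' @param orfStop The ORF's \code{orf_stop} (0-based transcript coordinate
#'   just past the stop codon, as reported by \code{\link{findOrfs}}).
#' @return \code{TRUE} or \code{FALSE}.
#' @export
labelNmd <- function(exons, orfStop) {
  ch <- .asChain(exons)
  n <- length(ch$starts)
  if (n < 2L) return(FALSE)
  lens <- ch$ends - ch$starts + 1L
  if (ch$strand == "-") lens <- rev(lens)      # 5'->3' order
  lastSJ <- sum(lens[-n])                      # transcript coord of final SJ
  (lastSJ - orfStop) >= 50L
}

#' Select the predicted true ORF per transcript
#'
#' With homology-search hits, the frame of the best hit wins (highest bit
#' score, ties by lowest E-value); without hits the longest ORF is kept and
#' the transcript is labelled a non-coding candidate.
#'
#' @param orfs The data.frame from \code{\link{findOrfs}}.
#' @param hits Parsed tabular homology results (outfmt-6 style) with at least
#'   columns \code{qseqid}, \code{bitscore}, \code{evalue}; \code{qseqid}
#'   must follow the \code{"<transcript_id>|F<frame>"} convention used by
#'   \code{\link{writePeptideFasta}}. May be \code{NULL} or empty.
#' @return One row per transcript: the selected ORF plus a logical
#'   \code{coding} column.
#' @export
selectBestOrf <- function(orfs, hits = NULL) {
  if (nrow(orfs) == 0L)
    return(cbind(orfs, coding = logical(0)))
  pick <- lapply(split(seq_len(nrow(orfs)), orfs$transcript_id), function(ix) {
    sub <- orfs[ix, , drop = FALSE]
    if (!is.null(hits) && nrow(hits) > 0L) {
      q <- paste0(sub$transcript_id, "|F", sub$frame)
      h <- hits[hits$qseqid %in% q, , drop = FALSE]
      if (nrow(h) > 0L) {
        h <- h[order(-h$bitscore, h$evalue), , drop = FALSE]
        best <- h$qseqid[1]
        row <- sub[q == best, , drop = FALSE][1, , drop = FALSE]
        row$coding <- TRUE
        return(row)
      }
    }
    len <- sub$orf_stop - sub$orf_start
    row <- sub[order(-len, sub$frame), , drop = FALSE][1, , drop = FALSE]
    row$coding <- FALSE
    row
  })
  out <- do.call(rbind, pick)
  rownames(out) <- NULL
  out
}

#' Write ORF peptides as FASTA for external homology search
#'
#' Peptides are named \code{"<transcript_id>|F<frame>"} so that tabular
#' search results can be keyed back to (transcript, frame) by
#' \code{\link{selectBestOrf}}.
#'
#' @param orfs The data.frame from \code{\link{findOrfs}}.
#' @param path Output FASTA path.
#' @return Invisibly, the path.
#' @export
writePeptideFasta <- function(orfs, path) {
  keep <- nchar(orfs$peptide) > 0L
  aa <- Biostrings::AAStringSet(orfs$peptide[keep])
  names(aa) <- paste0(orfs$transcript_id[keep], "|F", orfs$frame[keep])
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Full ORF/NMD annotation of a transcript set
#'
#' Runs \code{\link{findOrfs}} on every model, selects the best ORF
#' (optionally informed by homology hits) and applies the NMD and
#' degraded-evidence labels.
#'
#' @param a A \linkS4class{TranscriptAnnotation}.
#' @param genome Genome accessor.
#' @param hits Optional homology hit table (see \code{\link{selectBestOrf}}).
#' @return A data.frame, one row per transcript with an ORF: the selected
#'   ORF columns plus \code{nmd} and \code{degraded_evidence}
#'   (\code{!has_start}).
#' @export
orfPipeline <- function(a, genome, hits = NULL) {
  seqs <- transcriptSeqs(a, genome)
  orfs <- findOrfs(seqs)
  best <- selectBestOrf(orfs, hits)
  if (nrow(best) == 0L) {
    best$nmd <- logical(0); best$degraded_evidence <- logical(0)
    return(best)
  }
  ex <- exonsBy(a)
  best$nmd <- vapply(seq_len(nrow(best)), function(i)
    labelNmd(ex[[best$transcript_id[i]]], best$orf_stop[i]), logical(1))
  best$degraded_evidence <- !best$has_start
  best
}
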