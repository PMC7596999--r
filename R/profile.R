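#' @importFrom Biostrings DNAStringSet readDNAStringSet subseq
#'   reverseComplement translate AAStringSet writeXStringSet getSeq
NULL

## Fetch genome sequence [from, to] on chrom as a character scalar.
## `genome` is a named DNAStringSet or an Rsamtools::FaFile.
.genomeSeq <- function(genome, chrom, from, to) {
  if (from > to) return("")
  if (is(genome, "FaFile")) {
    as.character(Biostrings::getSeq(genome,
      GRanges(chrom, IRanges(from, to))))[1]
  } else {
    as.character(Biostrings::subseq(genome[[chrom]], from, to))
  }
}

#' Load a genome for sequence access
#'
#' @param path FASTA file path.
#' @return A named \link[Biostrings]{DNAStringSet}.
#' @export
readGenome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Profile spliced alignments into positioned mismatch events
#'
#' Converts each primary alignment into a mismatch-event profile: soft clips,
#' insertions, deletions (from the CIGAR) and per-base substitutions (from
#' comparing the read sequence with the genome). Substitution runs are split
#' into length-1 events so that windowed counts around splice junctions are
#' base-accurate. The per-read mismatch rate is the summed event length
#' (hard clips excluded) divided by the read length; identity is one minus
#' that rate, and coverage is the non-clipped fraction of the read.
#'
#' @param aln A \link[GenomicAlignments]{GAlignments} from
#'   \code{\link{readAlignments}} (must carry \code{qname}, \code{flag} and
#'   \code{seq} metadata columns).
#' @param genome A named \link[Biostrings]{DNAStringSet} or
#'   \link[Rsamtools]{FaFile} for the reference the reads were mapped to.
#' @return A \linkS4class{ReadProfiles} object.
#' @export
profileAlignments <- function(aln, genome) {
  n <- length(aln)
  profs <- vector("list", n)
  cig <- GenomicAlignments::cigar(aln)
  pos <- GenomicRanges::start(aln)
  chroms <- as.character(GenomicRanges::seqnames(aln))
  strands <- as.character(GenomicRanges::strand(aln))
  qn <- mcols(aln)$qname
  seqs <- as.character(mcols(aln)$seq)
  opsL <- GenomicAlignments::explodeCigarOps(cig)
  lensL <- GenomicAlignments::explodeCigarOpLengths(cig)
  for (i in seq_len(n)) {
    profs[[i]] <- .profileOne(qn[i], chroms[i], strands[i], pos[i],
                              opsL[[i]], lensL[[i]], seqs[i], genome)
  }
  new("ReadProfiles", profiles = profs)
}

.profileOne <- function(read_id, chrom, strand, pos, ops, lens, seq, genome) {
  if (length(ops) == 0L) stop("missing CIGAR for read ", read_id)
  if ((is.na(seq) || seq == "") && any(ops %in% c("M", "X")))
    stop("read ", read_id,
         ": no SEQ available for substitution calling")
  qpos <- 1L; rpos <- pos
  evKind <- character(0); evPos <- integer(0); evLen <- integer(0)
  bStarts <- integer(0); bEnds <- integer(0)
  curStart <- NA_integer_
  seenAligned <- FALSE
  for (k in seq_along(ops)) {
    op <- ops[k]; len <- lens[k]
    if (op == "H") next
    if (op == "S") {
      five <- xor(!seenAligned, strand == "-")  # leading clip is 5' on "+"
      evKind <- c(evKind, if (five) "softclip5" else "softclip3")
      evPos <- c(evPos, if (!seenAligned) pos - 1L else rpos)
      evLen <- c(evLen, len)
      qpos <- qpos + len
    } else if (op %in% c("M", "=", "X")) {
      if (is.na(curStart)) curStart <- rpos
      readPart <- substring(seq, qpos, qpos + len - 1L)
      refPart <- .genomeSeq(genome, chrom, rpos, rpos + len - 1L)
      mm <- which(strsplit(toupper(readPart), "")[[1]] !=
                  strsplit(toupper(refPart), "")[[1]])
      if (length(mm) > 0L) {
        evKind <- c(evKind, rep("substitution", length(mm)))
        evPos <- c(evPos, rpos + mm - 1L)
        evLen <- c(evLen, rep(1L, length(mm)))
      }
      qpos <- qpos + len; rpos <- rpos + len
      seenAligned <- TRUE
    } else if (op == "I") {
      evKind <- c(evKind, "insertion")
      evPos <- c(evPos, rpos - 1L)                 # anchored at left flank
      evLen <- c(evLen, len)
      qpos <- qpos + len
      seenAligned <- TRUE
    } else if (op == "D") {
      if (is.na(curStart)) curStart <- rpos
      evKind <- c(evKind, "deletion")
      evPos <- c(evPos, rpos)
      evLen <- c(evLen, len)
      rpos <- rpos + len
      seenAligned <- TRUE
    } else if (op == "N") {
      if (!is.na(curStart)) {
        bStarts <- c(bStarts, curStart); bEnds <- c(bEnds, rpos - 1L)
        curStart <- NA_integer_
      }
      rpos <- rpos + len
    } else stop("unsupported CIGAR op '", op, "' in read ", read_id)
  }
  if (!is.na(curStart)) {
    bStarts <- c(bStarts, curStart); bEnds <- c(bEnds, rpos - 1L)
  }
  readLen <- sum(lens[ops %in% c("S", "M", "I", "=", "X")])
  clipLen <- sum(lens[ops == "S"])
  mmBases <- sum(evLen)
  list(read_id = read_id, chrom = chrom, strand = strand,
       starts = bStarts, ends = bEnds,
       events = data.frame(kind = evKind, pos = evPos, len = evLen,
                           stringsAsFactors = FALSE),
       read_length = readLen,
       coverage = (readLen - clipLen) / readLen,
       identity = max(0, 1 - mmBases / readLen))
}

#' @export
setMethod("length", "ReadProfiles", function(x) length(x@profiles))

#' @export
setMethod("show", "ReadProfiles", function(object) {
  cat(sprintf("ReadProfiles: %d alignment(s)\n", length(object)))
  if (length(object) > 0) {
    p <- object@profiles[[1]]
    cat(sprintf("  e.g. %s %s:%d-%d (%s) identity=%.3f coverage=%.3f events=%d\n",
                p$read_id, p$chrom, min(p$starts), max(p$ends), p$strand,
                p$identity, p$coverage, nrow(p$events)))
  }
})

#' @export
setMethod("[", "ReadProfiles", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i))
    i <- match(i, vapply(x@profiles, `[[`, character(1), "read_id"))
  new("ReadProfiles", profiles = x@profiles[i])
})

#' @export
setMethod("[[", "ReadProfiles", function(x, i, ...) x@profiles[[i]])

#' Alignment quality filter
#'
#' A read passes iff its alignment coverage and identity both meet the
#' thresholds.
#'
#' @param profiles A \linkS4class{ReadProfiles}.
#' @param minCoverage,minIdentity Thresholds in [0,1].
#' @return Logical vector, one entry per read.
#' @export
passQuality <- function(profiles, minCoverage = 0, minIdentity = 0) {
  vapply(profiles@profiles, function(p)
    p$coverage >= minCoverage && p$identity >= minIdentity, logical(1))
}

## Per-junction flank mismatch counts for one profile.
## Returns a matrix with columns left,right; one row per junction
## (ascending genomic order).  Window is counted on the exonic side only:
## positions [donor-window+1, donor] and [acceptor, acceptor+window-1];
## a base exactly `window` away from the junction still counts (inclusive).
.sjFlankCounts <- function(p, window) {
  nj <- length(p$starts) - 1L
  if (nj < 1L)
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("left", "right"))))
  ev <- p$events
  out <- matrix(0L, nrow = nj, ncol = 2, dimnames = list(NULL, c("left", "right")))
  if (nrow(ev) == 0L || window <= 0) return(out)
  ## expand events into per-base positions (substitutions are length 1;
  ## deletions span; insertions/clips anchored at pos with len bases there)
  basePos <- unlist(lapply(seq_len(nrow(ev)), function(k) {
    if (ev$kind[k] == "deletion") seq(ev$pos[k], ev$pos[k] + ev$len[k] - 1L)
    else rep(ev$pos[k], ev$len[k])
  }))
  for (j in seq_len(nj)) {
    donor <- p$ends[j]; acceptor <- p$starts[j + 1L]
    out[j, "left"] <- sum(basePos >= donor - window + 1L & basePos <= donor)
    out[j, "right"] <- sum(basePos >= acceptor & basePos <= acceptor + window - 1L)
  }
  out
}

#' Per-junction splice-flank mismatch profile
#'
#' Counts mismatch-event bases within \code{window} bases of each splice
#' junction on its exonic side, for each junction of each read. These counts
#' drive both the LDE read filter (\code{\link{passLde}}) and splice-junction
#' ranking during collapsing.
#'
#' @param profiles A \linkS4class{ReadProfiles}.
#' @param window Flank window in bases.
#' @return A list (one element per read) of integer matrices with columns
#'   \code{left}, \code{right} and one row per splice junction in ascending
#'   genomic order; single-exon reads get a zero-row matrix.
#' @export
sjErrorProfile <- function(profiles, window) {
  lapply(profiles@profiles, .sjFlankCounts, window = window)
}

#' Local density error (LDE) filter
#'
#' A read passes iff, at every one of its splice junctions, the number of
#' mismatch bases within \code{window} bases of the junction (both exonic
#' flanks combined) is at most \code{maxMismatch}. Single-exon reads pass
#' vacuously. The stringent setting \code{window = 20, maxMismatch = 1}
#' discards any read with more than one error within 20 bp of a splice
#' junction.
#'
#' @param profiles A \linkS4class{ReadProfiles}.
#' @param window Flank window in bases.
#' @param maxMismatch Maximum tolerated mismatch bases per junction.
#' @return Logical vector, one entry per read.
#' @export
passLde <- function(profiles, window, maxMismatch) {
  vapply(profiles@profiles, function(p) {
    cnt <- .sjFlankCounts(p, window)
    nrow(cnt) == 0L || all(rowSums(cnt) <= maxMismatch)
  }, logical(1))
}

#' Mean mismatch rates by event kind
#'
#' For each mismatch kind, the mean over reads of (event bases of that kind /
#' read length), plus the overall mean mismatch rate.
#'
#' @param profiles A \linkS4class{ReadProfiles}.
#' @return A data.frame with columns \code{kind} and \code{mean_rate}; the
#'   final row (\code{kind == "total"}) is the overall mean mismatch rate.
#' @export
mismatchSummary <- function(profiles) {
  kinds <- c("softclip5", "softclip3", "insertion", "deletion", "substitution")
  rates <- vapply(profiles@profiles, function(p) {
    per <- vapply(kinds, function(k)
      sum(p$events$len[p$events$kind == k]), numeric(1))
    c(per, total = sum(per)) / p$read_length
  }, numeric(length(kinds) + 1L))
  means <- if (length(profiles) == 0L)
    stats::setNames(rep(NA_real_, length(kinds) + 1L), c(kinds, "total"))
  else rowMeans(rates)
  data.frame(kind = c(kinds, "total"), mean_rate = unname(means),
             stringsAsFactors = FALSE)
}

#' Per-read alignment report
#'
#' The read-level report emitted by collapsing: coordinates, quality metrics,
#' per-kind mismatch counts and the accept/discard decision with its reason.
#'
#' @param profiles A \linkS4class{ReadProfiles}.
#' @param config A \linkS4class{CollapseConfig}.
#' @return A data.frame with one row per read.
#' @export
readReport <- function(profiles, config) {
  qual <- passQuality(profiles, config@minCoverage, config@minIdentity)
  lde <- if (is.na(config@ldeMax)) rep(TRUE, length(profiles))
         else passLde(profiles, config@ldeWindow, config@ldeMax)
  kinds <- c("softclip5", "softclip3", "insertion", "deletion", "substitution")
  counts <- t(vapply(profiles@profiles, function(p)
    vapply(kinds, function(k) sum(p$events$len[p$events$kind == k]),
           numeric(1)), numeric(length(kinds))))
  df <- data.frame(
    read_id = vapply(profiles@profiles, `[[`, character(1), "read_id"),
    chrom = vapply(profiles@profiles, `[[`, character(1), "chrom"),
    start = vapply(profiles@profiles, function(p) min(p$starts), numeric(1)),
    end = vapply(profiles@profiles, function(p) max(p$ends), numeric(1)),
    strand = vapply(profiles@profiles, `[[`, character(1), "strand"),
    coverage = vapply(profiles@profiles, `[[`, numeric(1), "coverage"),
    identity = vapply(profiles@profiles, `[[`, numeric(1), "identity"),
    stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(counts))
  df$accepted <- qual & lde
  df$reason <- ifelse(!qual, "quality",
               ifelse(!lde, "lde", "accepted"))
  rownames(df) <- NULL
  df
}
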