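#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges GRangesList start end strand seqnames width
NULL

#' Transcript annotation container
#'
#' Holds a set of strand-aware transcript models, each an ordered chain of
#' exons on one chromosome, together with the gene locus each model belongs
#' to, its supporting read count and the source annotations it came from.
#' This is the unit that collapsing, merging, filtering and all diagnostic
#' statistics operate on.
#'
#' @slot exons A \link[GenomicRanges]{GRangesList}, one element per transcript
#'   (names are transcript ids); exons are sorted in ascending genomic order,
#'   are non-overlapping, and share one seqname and strand.
#' @slot txData A \link[S4Vectors]{DataFrame} with one row per transcript and
#'   columns \code{transcript_id}, \code{gene_id}, \code{read_count} and
#'   \code{sources} (comma-separated source labels).
#'
#' @aliases TranscriptAnnotation-class
#' @export
setClass("TranscriptAnnotation",
  representation(exons = "GRangesList", txData = "DataFrame"))

setValidity("TranscriptAnnotation", function(object) {
  ex <- object@exons
  td <- object@txData
  if (length(ex) != nrow(td))
    return("exons and txData lengths differ")
  if (length(ex) == 0L)
    return(TRUE)
  if (is.null(names(ex)) || anyDuplicated(names(ex)))
    return("transcript ids must be unique and non-empty")
  if (!identical(names(ex), as.character(td$transcript_id)))
    return("names(exons) must equal txData$transcript_id")
  ok <- vapply(seq_along(ex), function(i) {
    g <- ex[[i]]
    s <- GenomicRanges::start(g); e <- GenomicRanges::end(g)
    length(unique(as.character(GenomicRanges::seqnames(g)))) == 1L &&
      length(unique(as.character(GenomicRanges::strand(g)))) == 1L &&
      all(as.character(GenomicRanges::strand(g)) %in% c("+", "-")) &&
      !is.unsorted(s, strictly = TRUE) &&
      all(e >= s) &&
      (length(g) < 2L || all(s[-1] > e[-length(e)]))
  }, logical(1))
  if (!all(ok))
    return(sprintf("malformed exon chain for transcript(s): %s",
                   paste(names(ex)[!ok], collapse = ", ")))
  TRUE
})

#' Read profiles: spliced alignments with positioned mismatch events
#'
#' Each profile describes one primary spliced alignment: its aligned blocks
#' (introns are the gaps between blocks), a positioned mismatch-event list
#' (soft clips, insertions, deletions, single-base substitutions), and the
#' derived per-read coverage and identity fractions.
#'
#' @slot profiles A list; each element is a list with fields \code{read_id},
#'   \code{chrom}, \code{strand}, \code{starts}, \code{ends} (parallel integer
#'   vectors of aligned blocks, 1-based closed), \code{events} (data.frame with
#'   \code{kind}, \code{pos}, \code{len}), \code{read_length},
#'   \code{coverage}, \code{identity}.
#'
#' @aliases ReadProfiles-class
#' @export
setClass("ReadProfiles", representation(profiles = "list"))

#' Wobble thresholds for exon-boundary matching
#'
#' @slot a 5' start wobble in bases.
#' @slot m splice-junction wobble in bases.
#' @slot z 3' end wobble in bases.
#' @aliases WobbleThresholds-class
#' @export
setClass("WobbleThresholds",
  representation(a = "numeric", m = "numeric", z = "numeric"))

setValidity("WobbleThresholds", function(object) {
  if (any(c(object@a, object@m, object@z) < 0)) "thresholds must be >= 0" else TRUE
})

#' Collapse configuration
#'
#' @slot mode \code{"capped"} or \code{"no_cap"}.
#' @slot wobble A \linkS4class{WobbleThresholds}.
#' @slot ldeWindow LDE window in bases flanking each splice junction.
#' @slot ldeMax maximum allowed mismatch bases within the LDE window
#'   (a read exceeding this at any junction is discarded); \code{NA} disables
#'   the filter.
#' @slot minCoverage,minIdentity alignment quality thresholds in [0,1].
#' @slot sjRanking logical; rank splice junctions by flanking mismatch profile
#'   (\code{TRUE}) or by read coverage alone (\code{FALSE}).
#' @slot polyaWindow,polyaFraction genomic downstream poly-A detection: window
#'   length in bases and minimum A fraction.
#' @aliases CollapseConfig-class
#' @export
setClass("CollapseConfig",
  representation(mode = "character", wobble = "WobbleThresholds",
                 ldeWindow = "numeric", ldeMax = "numeric",
                 minCoverage = "numeric", minIdentity = "numeric",
                 sjRanking = "logical",
                 polyaWindow = "numeric", polyaFraction = "numeric"))

setValidity("CollapseConfig", function(object) {
  if (!object@mode %in% c("capped", "no_cap"))
    return("mode must be 'capped' or 'no_cap'")
  if (object@minCoverage < 0 || object@minCoverage > 1 ||
      object@minIdentity < 0 || object@minIdentity > 1)
    return("quality thresholds must lie in [0,1]")
  if (object@polyaFraction < 0 || object@polyaFraction > 1)
    return("polyaFraction must lie in [0,1]")
  TRUE
})

#' Construct wobble thresholds
#'
#' @param a 5' start wobble (bases).
#' @param m splice-junction wobble (bases).
#' @param z 3' end wobble (bases).
#' @return A \linkS4class{WobbleThresholds} object.
#' @examples
#' wobbleThresholds(a = 100, m = 10, z = 100)
#' @export
wobbleThresholds <- function(a = 100, m = 10, z = 100) {
  new("WobbleThresholds", a = as.numeric(a), m = as.numeric(m),
      z = as.numeric(z))
}

#' Construct a collapse configuration
#'
#' Defaults follow common long-read practice: 100 bp start/end wobble, 10 bp
#' splice-junction wobble, LDE window 20 bp, quality thresholds permissive.
#'
#' @param mode \code{"capped"} (grouped reads must share exon count and all
#'   boundaries) or \code{"no_cap"} (5'-truncated reads may merge into longer
#'   models sharing a 3' splice-junction suffix).
#' @param wobble A \linkS4class{WobbleThresholds}.
#' @param ldeWindow,ldeMax local density error filter: window (bases) around
#'   each splice junction and maximum tolerated mismatch bases within it;
#'   \code{ldeMax = NA} disables the filter.
#' @param minCoverage,minIdentity per-read alignment quality thresholds.
#' @param sjRanking rank splice junctions by flanking mismatch profile.
#' @param polyaWindow,polyaFraction genomic downstream poly-A call parameters.
#' @return A \linkS4class{CollapseConfig} object.
#' @examples
#' collapseConfig(mode = "no_cap", ldeMax = 1)
#' @export
collapseConfig <- function(mode = c("capped", "no_cap"),
                           wobble = wobbleThresholds(),
                           ldeWindow = 20, ldeMax = NA_real_,
                           minCoverage = 0, minIdentity = 0,
                           sjRanking = TRUE,
                           polyaWindow = 20, polyaFraction = 0.7) {
  mode <- match.arg(mode)
  new("CollapseConfig", mode = mode, wobble = wobble,
      ldeWindow = as.numeric(ldeWindow), ldeMax = as.numeric(ldeMax),
      minCoverage = as.numeric(minCoverage),
      minIdentity = as.numeric(minIdentity),
      sjRanking = isTRUE(sjRanking),
      polyaWindow = as.numeric(polyaWindow),
      polyaFraction = as.numeric(polyaFraction))
}

#' @export
setMethod("show", "WobbleThresholds", function(object) {
  cat(sprintf("WobbleThresholds: a=%g m=%g z=%g\n",
              object@a, object@m, object@z))
})

#' @export
setMethod("show", "CollapseConfig", function(object) {
  cat(sprintf(
    "CollapseConfig: mode=%s wobble(a=%g,m=%g,z=%g) lde(window=%g,max=%s)\n",
    object@mode, object@wobble@a, object@wobble@m, object@wobble@z,
    object@ldeWindow,
    if (is.na(object@ldeMax)) "off" else format(object@ldeMax)))
  cat(sprintf("  quality: coverage>=%g identity>=%g; sjRanking=%s; polyA(%g bp, %g)\n",
              object@minCoverage, object@minIdentity, object@sjRanking,
              object@polyaWindow, object@polyaFraction))
})
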