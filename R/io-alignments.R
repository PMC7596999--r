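#' @importFrom Rsamtools BamFile ScanBamParam scanBamFlag scanBamHeader
#'   asBam sortBam indexBam countBam filterBam idxstatsBam
#' @importFrom GenomicAlignments readGAlignments cigar qwidth
#'   explodeCigarOps explodeCigarOpLengths
NULL

## Accept SAM or BAM; return a BAM path (converted/indexed in tempdir when
## needed).  Sortedness is asserted from the @HD SO tag.
.asSortedBam <- function(path) {
  isSam <- grepl("\\.sam$", path, ignore.case = TRUE)
  bam <- if (isSam) {
    dest <- tempfile(fileext = "")
    suppressMessages(Rsamtools::asBam(path, dest, overwrite = TRUE,
                                      indexDestination = FALSE))
  } else path
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]
  txt <- hdr$text
  if (length(txt) == 0L || !"@HD" %in% names(txt))
    stop("missing or incomplete SAM/BAM header in ", path)
  hd <- unlist(txt[names(txt) == "@HD"])
  if (!any(grepl("^SO:coordinate$", hd)))
    stop("input is not coordinate-sorted: ", path)
  if (!file.exists(paste0(bam, ".bai")))
    Rsamtools::indexBam(bam)
  bam
}

#' Read primary spliced alignments from SAM/BAM
#'
#' Reads a coordinate-sorted SAM or BAM file and returns the primary
#' alignments (secondary, supplementary and unmapped records are excluded;
#' the number skipped is recorded in \code{S4Vectors::metadata(x)$skipped}).
#' SAM input is converted on the fly.
#'
#' @param path Path to a coordinate-sorted SAM/BAM file with a header.
#' @param region Optional chromosome name; restrict to that reference.
#' @return A \link[GenomicAlignments]{GAlignments} with metadata columns
#'   \code{qname}, \code{flag} and \code{seq}.
#' @export
readAlignments <- function(path, region = NULL) {
  bam <- .asSortedBam(path)
  flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isUnmappedQuery = FALSE)
  what <- c("qname", "flag", "seq")
  total <- Rsamtools::countBam(Rsamtools::BamFile(bam))$records
  if (is.null(region)) {
    param <- Rsamtools::ScanBamParam(flag = flag, what = what)
  } else {
    sl <- Rsamtools::scanBamHeader(bam)[[1]]$targets
    if (!region %in% names(sl))
      stop("region not present in header: ", region)
    param <- Rsamtools::ScanBamParam(flag = flag, what = what,
      which = GRanges(region, IRanges(1, sl[[region]])))
    total <- Rsamtools::countBam(Rsamtools::BamFile(bam),
      param = Rsamtools::ScanBamParam(
        which = GRanges(region, IRanges(1, sl[[region]]))))$records
  }
  aln <- GenomicAlignments::readGAlignments(bam, param = param)
  metadata(aln)$skipped <- total - length(aln)
  aln
}

#' Split a sorted BAM by chromosome into balanced parts
#'
#' Each chromosome's records land wholly in one output part (so reads from one
#' gene are never separated); chromosomes are assigned greedily to the
#' currently least-loaded part by mapped record count.
#'
#' @param path Sorted SAM/BAM file.
#' @param nParts Number of output files (>= 1). More parts than chromosomes
#'   leaves the tail parts empty (header-only).
#' @param outdir Directory for the output BAM files.
#' @return Character vector of output BAM paths, length \code{nParts}.
#' @export
splitByChrom <- function(path, nParts, outdir = tempdir()) {
  if (nParts < 1L) stop("nParts must be >= 1")
  bam <- .asSortedBam(path)
  stats <- Rsamtools::idxstatsBam(bam)
  stats <- stats[stats$seqnames != "*", , drop = FALSE]
  load <- numeric(nParts)
  assign <- integer(nrow(stats))
  for (i in order(stats$mapped, decreasing = TRUE)) {
    k <- which.min(load)
    assign[i] <- k
    load[k] <- load[k] + stats$mapped[i]
  }
  sl <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  out <- file.path(outdir, sprintf("part%02d.bam", seq_len(nParts)))
  for (k in seq_len(nParts)) {
    chroms <- as.character(stats$seqnames[assign == k & stats$mapped > 0])
    if (length(chroms) > 0L) {
      which <- GRanges(chroms, IRanges(1, unname(sl[chroms])))
      Rsamtools::filterBam(bam, out[k],
        param = Rsamtools::ScanBamParam(which = which, what = character(0)),
        indexDestination = FALSE)
    } else {
      ## header-only part
      hdrTxt <- .headerText(bam)
      samTmp <- tempfile(fileext = ".sam")
      writeLines(hdrTxt, samTmp)
      suppressMessages(Rsamtools::asBam(samTmp, sub("\\.bam$", "", out[k]),
                                        overwrite = TRUE,
                                        indexDestination = FALSE))
    }
  }
  out
}

.headerText <- function(bam) {
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$text
  vapply(seq_along(hdr), function(i)
    paste(c(names(hdr)[i], hdr[[i]]), collapse = "\t"), character(1))
}
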