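#' Read a BED12 transcript annotation
#'
#' Reads a BED12 file into a \linkS4class{TranscriptAnnotation}. The name
#' field is interpreted in the \code{"gene_id;transcript_id"} dialect used
#' throughout this package; a name without \code{";"} is treated as a
#' transcript id whose gene id equals the transcript id. Block sizes/starts
#' are converted to absolute exon intervals.
#'
#' @param path Path to a BED12 file.
#' @return A \linkS4class{TranscriptAnnotation}.
#' @details Strand \code{"."} is rejected: all grouping in this package is
#'   strand-aware. Malformed lines (wrong field count, non-numeric fields,
#'   blockCount disagreeing with blockSizes/blockStarts) raise an error naming
#'   the offending line number.
#' @seealso \code{\link{writeBed12}}
#' @export
readBed12 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  keep <- !grepl("^(track|browser|#)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(TranscriptAnnotation(GRangesList()))
  fields <- strsplit(lines, "[ \t]+")
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 12L)
      stop(sprintf("BED12 parse error at line %d: expected 12 fields, got %d",
                   lineno[i], length(f)))
    if (is.na(suppressWarnings(as.integer(f[2]))) ||
        is.na(suppressWarnings(as.integer(f[3]))) ||
        is.na(suppressWarnings(as.integer(f[10]))))
      stop(sprintf("BED12 parse error at line %d: non-numeric coordinate field",
                   lineno[i]))
    if (!f[6] %in% c("+", "-"))
      stop(sprintf("BED12 parse error at line %d: strand must be '+' or '-'",
                   lineno[i]))
    nb <- as.integer(f[10])
    sizes <- suppressWarnings(as.integer(strsplit(f[11], ",")[[1]]))
    offs <- suppressWarnings(as.integer(strsplit(f[12], ",")[[1]]))
    if (length(sizes) != nb || length(offs) != nb ||
        anyNA(sizes) || anyNA(offs))
      stop(sprintf("BED12 parse error at line %d: blockCount (%d) disagrees with blockSizes/blockStarts",
                   lineno[i], nb))
  }
  chains <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    chromStart <- as.integer(f[2])
    sizes <- as.integer(strsplit(f[11], ",")[[1]])
    offs <- as.integer(strsplit(f[12], ",")[[1]])
    nm <- strsplit(f[4], ";", fixed = TRUE)[[1]]
    if (length(nm) >= 2L) {
      gid <- nm[1]; tid <- nm[2]
    } else {
      gid <- tid <- f[4]
    }
    list(id = tid, gene = gid, chrom = f[1], strand = f[6],
         starts = chromStart + offs + 1L,          # BED 0-based -> 1-based
         ends = chromStart + offs + sizes)
  })
  ids <- vapply(chains, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate transcript ids in BED12: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  .annotationFromChains(chains,
                        geneId = vapply(chains, `[[`, character(1), "gene"))
}

#' Write a TranscriptAnnotation as BED12
#'
#' Writes models in the \code{"gene_id;transcript_id"} name dialect with
#' deterministic ordering (chrom, start, transcript_id), so repeated runs
#' produce byte-identical files. Score and RGB are fixed placeholders
#' (40 and 0); thickStart/thickEnd span the whole model.
#'
#' @param a A \linkS4class{TranscriptAnnotation}.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @seealso \code{\link{readBed12}}
#' @export
writeBed12 <- function(a, path) {
  ch <- .chains(a)
  if (length(ch) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  gid <- geneIds(a)
  rows <- vapply(seq_along(ch), function(i) {
    c1 <- ch[[i]]
    chromStart <- min(c1$starts) - 1L                # 1-based -> BED 0-based
    chromEnd <- max(c1$ends)
    sizes <- c1$ends - c1$starts + 1L
    offs <- c1$starts - 1L - chromStart
    paste(c1$chrom, chromStart, chromEnd,
          paste0(gid[i], ";", c1$id), 40, c1$strand,
          chromStart, chromEnd, 0, length(sizes),
          paste0(paste(sizes, collapse = ","), ","),
          paste0(paste(offs, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  o <- order(vapply(ch, `[[`, character(1), "chrom"),
             vapply(ch, function(c) min(c$starts), numeric(1)),
             vapply(ch, `[[`, character(1), "id"))
  writeLines(rows[o], path)
  invisible(path)
}

#' Read a GTF annotation
#'
#' Imports exon features from a GTF file (Ensembl dialect: \code{gene_id} and
#' \code{transcript_id} attributes) into a \linkS4class{TranscriptAnnotation}.
#' Exon order is normalised to ascending genomic coordinates regardless of
#' file order or strand. Transcripts that carry no exon feature are skipped
#' with a warning giving their count.
#'
#' @param path Path to a GTF file.
#' @return A \linkS4class{TranscriptAnnotation}.
#' @export
readGtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  allTx <- unique(stats::na.omit(gr$transcript_id))
  ex <- gr[gr$type == "exon" & !is.na(gr$transcript_id)]
  skipped <- setdiff(allTx, unique(ex$transcript_id))
  if (length(skipped) > 0L)
    warning(sprintf("skipped %d transcript(s) with no exon features",
                    length(skipped)))
  if (length(ex) == 0L)
    return(TranscriptAnnotation(GRangesList()))
  mcols(ex) <- mcols(ex)[, c("transcript_id", "gene_id")]
  grl <- GenomicRanges::split(GRanges(GenomicRanges::seqnames(ex),
                                      IRanges(GenomicRanges::start(ex),
                                              GenomicRanges::end(ex)),
                                      strand = GenomicRanges::strand(ex)),
                              ex$transcript_id)
  gid <- vapply(split(ex$gene_id, ex$transcript_id), `[`, character(1), 1)
  grl <- endoapply(grl, function(g) g[order(GenomicRanges::start(g))])
  TranscriptAnnotation(grl, geneId = gid[names(grl)])
}
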