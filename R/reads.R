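#' Load aligned small-RNA reads as genomic intervals
#'
#' Reads are reduced to their aligned reference span (for SAM/BAM, the
#' CIGAR-consumed reference length) in 0-based half-open coordinates, tagged
#' with a sample label. No uniqueness filter is applied: every reported
#' placement of a multi-mapped read is kept, and `mapping_count` records how
#' many placements each read name has (1 for BED input, where names are not
#' assumed unique identifiers of molecules).
#'
#' @param path SAM, BAM or BED6 file.
#' @param sample sample label attached to every read.
#' @param format `"auto"` (by extension), `"bed"`, `"sam"` or `"bam"`.
#' @param include_secondary keep secondary alignments (default TRUE, matching
#'   mapping without a uniqueness filter).
#' @return data frame of class `aligned_reads` with columns `read_id`,
#'   `contig`, `start`, `end`, `strand`, `sample`, `mapping_count`.
#' @export
read_alignments <- function(path, sample,
                            format = c("auto", "bed", "sam", "bam"),
                            include_secondary = TRUE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     sam = "sam", bam = "bam", "bed")
  if (format == "bed") {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE,
                            colClasses = c("character", "integer", "integer",
                                           "character", "character", "character"))
    reads <- data.frame(read_id = df[[4]], contig = df[[1]],
                        start = df[[2]], end = df[[3]], strand = df[[6]],
                        sample = sample, mapping_count = 1L)
  } else {
    bam <- if (format == "sam") {
      Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
    } else path
    flag <- Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE,
      isSecondaryAlignment = if (include_secondary) NA else FALSE)
    ga <- GenomicAlignments::readGAlignments(
      bam, use.names = TRUE, param = Rsamtools::ScanBamParam(flag = flag))
    nm <- names(ga)
    reads <- data.frame(
      read_id = nm,
      contig = as.character(GenomicAlignments::seqnames(ga)),
      start = GenomicAlignments::start(ga) - 1L,
      end = GenomicAlignments::end(ga),
      strand = as.character(GenomicAlignments::strand(ga)),
      sample = sample,
      mapping_count = as.integer(table(nm)[nm]))
  }
  as_aligned_reads(reads)
}

#' Validate an aligned-reads table
#'
#' @param df data frame with columns `read_id`, `contig`, `start`, `end`,
#'   `strand`, `sample`; `mapping_count` defaults to 1.
#' @return the data frame with class `aligned_reads`.
#' @export
as_aligned_reads <- function(df) {
  req <- c("read_id", "contig", "start", "end", "strand", "sample")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("reads are missing required column(s): ", paste(miss, collapse = ", "))
  if (!"mapping_count" %in% names(df)) df$mapping_count <- 1L
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(df$end <= df$start))
    stop("zero- or negative-length read interval for read ",
         paste(utils::head(df$read_id[df$end <= df$start], 3), collapse = ", "))
  if (any(df$mapping_count < 1L)) stop("mapping_count must be >= 1")
  rownames(df) <- NULL
  class(df) <- c("aligned_reads", "data.frame")
  df
}

#' Write aligned reads to BED6
#'
#' @param reads an `aligned_reads` table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignments_bed <- function(reads, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", reads$contig, reads$start,
                     reads$end, reads$read_id, reads$strand), path)
  invisible(path)
}
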