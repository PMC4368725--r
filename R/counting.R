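#' Fraction of a read covered by a feature
#'
#' Overlap is measured as the length of the intersection divided by the read
#' length (BEDtools `-f` semantics: the fraction of the *read*, the "A" file,
#' that must be covered). Strand is ignored; intervals on different contigs do
#' not overlap. All arguments are vectorised.
#'
#' @param read_start,read_end read interval, 0-based half-open.
#' @param feature_start,feature_end feature interval, 0-based half-open.
#' @param read_contig,feature_contig optional contig names; when supplied,
#'   pairs on different contigs get fraction 0.
#' @return numeric fraction(s) in \[0, 1\].
#' @export
overlap_fraction <- function(read_start, read_end, feature_start, feature_end,
                             read_contig = NULL, feature_contig = NULL) {
  rlen <- read_end - read_start
  if (any(rlen <= 0)) stop("zero-length read interval")
  ov <- pmax(0, pmin(read_end, feature_end) - pmax(read_start, feature_start))
  f <- ov / rlen
  if (!is.null(read_contig) && !is.null(feature_contig))
    f[read_contig != feature_contig] <- 0
  f
}

## features (mature loci + flank parts) as a single GRanges; flank parts keep
## locus_id + role so multi-part (wrapped) flanks can be re-aggregated per read
.feature_granges <- function(annotation, flanks) {
  mat <- data.frame(locus_id = annotation$locus_id, role = "mature",
                    contig = annotation$contig, start = annotation$start,
                    end = annotation$end, strand = annotation$strand)
  fl <- flanks[, c("locus_id", "role", "contig", "start", "end", "strand")]
  feat <- rbind(mat, fl)
  GenomicRanges::GRanges(
    feat$contig,
    IRanges::IRanges(feat$start + 1L, feat$end),  # to 1-based closed
    strand = feat$strand,
    locus_id = feat$locus_id, role = feat$role)
}

#' Count reads on mature tRNA regions and their flanks
#'
#' A read increments the `mature` count of a locus when the overlap fraction
#' (intersection length over read length) with the mature interval is at least
#' `f_mature`, and the `leader5p`/`trailer3p` count when the fraction over the
#' flank window is at least `f_flank`. The same read may increment both a
#' mature and a flank counter (unprocessed precursor reads spanning the
#' cleavage site do), and a read overlapping two distinct loci increments
#' both. Counts of duplicate-group members are summed into the group
#' representative, and only representatives are reported.
#'
#' @param reads an `aligned_reads` table (one or more samples).
#' @param annotation a `trna_annotation`.
#' @param flanks flanks from [derive_flanks()] on the same annotation.
#' @param f_mature,f_flank minimum overlap fractions (defaults 0.3 and 0.1);
#'   compared with `>=`, so ties count.
#' @param duplicate_map mapping from [collapse_duplicates()].
#' @param multimap_weight down-weight each placement of a multi-mapped read by
#'   1/`mapping_count` instead of counting every placement once (default
#'   FALSE: no uniqueness filtering or weighting).
#' @param stranded require read strand to match locus strand (default FALSE:
#'   intersection is strand-blind).
#' @return data frame of class `trna_counts` with columns `locus_id`,
#'   `sample`, `mature`, `leader5p`, `trailer3p`; one row per representative
#'   locus and sample, zero-filled.
#' @export
count_reads <- function(reads, annotation, flanks,
                        f_mature = 0.3, f_flank = 0.1,
                        duplicate_map = collapse_duplicates(annotation),
                        multimap_weight = FALSE, stranded = FALSE) {
  stopifnot(f_mature > 0, f_mature <= 1, f_flank > 0, f_flank <= 1)
  if (!all(annotation$locus_id %in% names(duplicate_map)))
    stop("duplicate_map is missing locus id(s): ",
         paste(setdiff(annotation$locus_id, names(duplicate_map)), collapse = ", "))
  samples <- unique(reads$sample)
  reps <- unique(unname(duplicate_map[annotation$locus_id]))
  grid <- expand.grid(locus_id = reps, sample = samples,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$mature <- grid$leader5p <- grid$trailer3p <- 0

  if (nrow(reads) > 0) {
    feat <- .feature_granges(annotation, flanks)
    rgr <- GenomicRanges::GRanges(
      reads$contig, IRanges::IRanges(reads$start + 1L, reads$end),
      strand = reads$strand)
    hits <- GenomicRanges::findOverlaps(rgr, feat, ignore.strand = !stranded)
    if (length(hits) > 0) {
      q <- S4Vectors::queryHits(hits)
      s <- S4Vectors::subjectHits(hits)
      ov <- pmax(0L, pmin(reads$end[q], GenomicRanges::end(feat)[s]) -
                      pmax(reads$start[q], GenomicRanges::start(feat)[s] - 1L))
      key <- paste(q, feat$locus_id[s], feat$role[s], sep = "\r")
      ovsum <- rowsum(ov, key)  # sum flank parts per (read, locus, role)
      parts <- strsplit(rownames(ovsum), "\r", fixed = TRUE)
      qi <- as.integer(vapply(parts, `[[`, "", 1L))
      lid <- vapply(parts, `[[`, "", 2L)
      role <- vapply(parts, `[[`, "", 3L)
      frac <- ovsum[, 1] / (reads$end[qi] - reads$start[qi])
      keep <- ifelse(role == "mature", frac >= f_mature, frac >= f_flank)
      if (any(keep)) {
        qi <- qi[keep]; lid <- lid[keep]; role <- role[keep]
        w <- if (multimap_weight) 1 / reads$mapping_count[qi] else rep(1, length(qi))
        tab <- rowsum(w, paste(unname(duplicate_map[lid]), reads$sample[qi],
                               role, sep = "\r"))
        parts <- strsplit(rownames(tab), "\r", fixed = TRUE)
        for (j in seq_len(nrow(tab))) {
          p <- parts[[j]]
          r <- grid$locus_id == p[1] & grid$sample == p[2]
          grid[[p[3]]][r] <- tab[j, 1]
        }
      }
    }
  }
  out <- grid[order(match(grid$sample, samples),
                    match(grid$locus_id, reps)),
              c("locus_id", "sample", "mature", "leader5p", "trailer3p")]
  rownames(out) <- NULL
  class(out) <- c("trna_counts", "data.frame")
  out
}

#' Priority-ordered read annotation statistics
#'
#' Each read is assigned to the first category (in the supplied order) whose
#' feature set it overlaps by at least one base; reads matching no category are
#' reported as `unassigned`. The default order used for genome-wide read
#' bookkeeping is exons, UTRs, repeats, tRNA flanks.
#'
#' @param reads an `aligned_reads` table.
#' @param feature_sets named, ordered list; each element a data frame with
#'   columns `contig`, `start`, `end` (0-based half-open).
#' @return data frame of class `category_stats` with columns `category` and
#'   `reads`, in priority order plus a final `unassigned` row; counts sum to
#'   `nrow(reads)`.
#' @export
annotate_by_priority <- function(reads, feature_sets) {
  if (length(feature_sets) == 0 || is.null(names(feature_sets)))
    stop("feature_sets must be a non-empty named list in priority order")
  rgr <- GenomicRanges::GRanges(
    reads$contig, IRanges::IRanges(reads$start + 1L, reads$end))
  unassigned <- rep(TRUE, nrow(reads))
  counts <- integer(length(feature_sets))
  for (k in seq_along(feature_sets)) {
    fs <- feature_sets[[k]]
    fgr <- GenomicRanges::GRanges(
      fs$contig, IRanges::IRanges(fs$start + 1L, fs$end))
    hit <- GenomicRanges::countOverlaps(rgr, fgr, ignore.strand = TRUE) > 0
    counts[k] <- sum(hit & unassigned)
    unassigned <- unassigned & !hit
  }
  out <- data.frame(category = c(names(feature_sets), "unassigned"),
                    reads = c(counts, sum(unassigned)))
  class(out) <- c("category_stats", "data.frame")
  out
}
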