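#' Validate and classify a tRNA annotation table
#'
#' Builds a `trna_annotation` data frame from per-locus fields. Coordinates are
#' 0-based half-open (BED convention) on the given contig. Duplicate loci
#' (exact copies of a gene, either an inverted-repeat pair or tandem identical
#' copies) are declared through `duplicate_group`/`group_kind`; the
#' representative member of each group is derived from the collapsing rules
#' (see [collapse_duplicates()]) and stored in `is_representative`.
#'
#' @param df data frame with columns `locus_id`, `amino_acid`, `anticodon`,
#'   `organelle` (one of `"plastid"`, `"mitochondrion"`, `"nucleus"`),
#'   `contig`, `start`, `end`, `strand` (`"+"`/`"-"`), `has_intron` (logical),
#'   and optionally `duplicate_group` (NA for singletons) and `group_kind`
#'   (`"inverted_repeat"` or `"tandem"` where `duplicate_group` is set).
#' @param length_bounds sanity bounds (nt) on locus length; tRNA genes are
#'   expected in roughly 50-120 nt.
#' @return the validated data frame with class `trna_annotation` and a
#'   logical `is_representative` column appended.
#' @export
as_trna_annotation <- function(df, length_bounds = c(50, 120)) {
  req <- c("locus_id", "amino_acid", "anticodon", "organelle",
           "contig", "start", "end", "strand", "has_intron")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("annotation is missing required column(s): ", paste(miss, collapse = ", "))
  if (!"duplicate_group" %in% names(df)) df$duplicate_group <- NA_character_
  if (!"group_kind" %in% names(df)) df$group_kind <- NA_character_
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$has_intron <- as.logical(df$has_intron)

  if (anyDuplicated(df$locus_id))
    stop("duplicated locus_id: ",
         paste(unique(df$locus_id[duplicated(df$locus_id)]), collapse = ", "))
  bad <- which(is.na(df$start) | is.na(df$end) | df$start < 0 | df$start >= df$end)
  if (length(bad) > 0)
    stop("invalid interval (need 0 <= start < end) for locus ",
         paste(df$locus_id[bad], collapse = ", "))
  len <- df$end - df$start
  bad <- which(len < length_bounds[1] | len > length_bounds[2])
  if (length(bad) > 0)
    stop("locus length outside sanity bounds [", length_bounds[1], ", ",
         length_bounds[2], "] for locus ", paste(df$locus_id[bad], collapse = ", "))
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-' for locus ",
         paste(df$locus_id[!df$strand %in% c("+", "-")], collapse = ", "))
  if (!all(df$organelle %in% c("plastid", "mitochondrion", "nucleus")))
    stop("organelle must be plastid, mitochondrion or nucleus for locus ",
         paste(df$locus_id[!df$organelle %in%
                             c("plastid", "mitochondrion", "nucleus")], collapse = ", "))
  if (!all(nchar(df$anticodon) == 3L))
    stop("anticodon must be a 3-letter code for locus ",
         paste(df$locus_id[nchar(df$anticodon) != 3L], collapse = ", "))
  grp <- df$duplicate_group[!is.na(df$duplicate_group)]
  if (length(grp) > 0) {
    sizes <- table(grp)
    if (any(sizes < 2))
      stop("duplicate_group with fewer than 2 members: ",
           paste(names(sizes)[sizes < 2], collapse = ", "))
    kinds <- df$group_kind[!is.na(df$duplicate_group)]
    if (any(is.na(kinds)) || !all(kinds %in% c("inverted_repeat", "tandem")))
      stop("every duplicate_group member needs group_kind 'inverted_repeat' or 'tandem'")
  }
  rownames(df) <- NULL
  class(df) <- c("trna_annotation", "data.frame")
  map <- collapse_duplicates(df)
  df$is_representative <- unname(map[df$locus_id]) == df$locus_id
  df
}

#' Map duplicate tRNA loci to their representative copy
#'
#' Exact duplicate tRNA genes are counted once: for an inverted-repeat pair the
#' forward-strand instance is the representative, and for tandem identical
#' copies (e.g. the duplicated mitochondrial tRNA-Lys/Tyr/Ser genes) the
#' instance listed first on the genome, i.e. with the smallest start
#' coordinate, is. Reads of all group members are later summed into the
#' representative and non-representatives are dropped from per-locus reporting.
#'
#' @param annotation a `trna_annotation` (the `is_representative` column, if
#'   present, is ignored and re-derived).
#' @return named character vector mapping every `locus_id` to the
#'   representative `locus_id` of its group (itself for singletons).
#' @export
collapse_duplicates <- function(annotation) {
  map <- stats::setNames(as.character(annotation$locus_id),
                         as.character(annotation$locus_id))
  grouped <- !is.na(annotation$duplicate_group)
  for (g in unique(annotation$duplicate_group[grouped])) {
    i <- which(!is.na(annotation$duplicate_group) & annotation$duplicate_group == g)
    kind <- annotation$group_kind[i[1]]
    if (kind == "inverted_repeat") {
      fwd <- i[annotation$strand[i] == "+"]
      if (length(fwd) != 1L)
        stop("inverted-repeat group '", g, "' must have exactly one ",
             "forward-strand member (found ", length(fwd), ")")
      rep_id <- annotation$locus_id[fwd]
    } else {
      rep_id <- annotation$locus_id[i[which.min(annotation$start[i])]]
    }
    map[annotation$locus_id[i]] <- rep_id
  }
  map
}

#' Which loci enter processing-efficiency reporting?
#'
#' Plastid tRNA genes harbouring introns are excluded (reads over spliced loci
#' cannot be assigned unambiguously on the genome), as are non-representative
#' members of duplicate groups. Nucleus-encoded tRNAs are carried through
#' accumulation analysis but by default left out of PER reporting.
#'
#' @param annotation a `trna_annotation`.
#' @param include_nuclear keep nucleus-encoded loci eligible?
#' @return logical vector along the annotation rows.
#' @export
per_eligible <- function(annotation, include_nuclear = FALSE) {
  ok <- annotation$is_representative &
    !(annotation$organelle == "plastid" & annotation$has_intron)
  if (!include_nuclear) ok <- ok & annotation$organelle != "nucleus"
  ok
}

#' Derive 5'-leader and 3'-trailer flank windows
#'
#' Precursor-specific leader/trailer regions are approximated by fixed windows
#' of `flank_size` nt on either side of the mature locus, strand-aware: on the
#' plus strand the leader is upstream (lower coordinates) and the trailer
#' downstream; on the minus strand the roles swap. Windows are clipped at
#' contig ends (a window clipped to nothing is omitted) or, for circular
#' organellar contigs with `circular = TRUE`, wrapped around the origin; a
#' wrapped window is returned as two parts sharing `locus_id` and `role`.
#'
#' @param annotation a `trna_annotation`.
#' @param flank_size window width in nt (default 50).
#' @param contig_lengths named integer vector of contig lengths; required for
#'   `circular = TRUE`, otherwise optional (without it only the left end is
#'   clipped).
#' @param circular treat contigs as circular and wrap windows.
#' @return data frame of class `trna_flanks` with columns `locus_id`, `role`
#'   (`"leader5p"`/`"trailer3p"`), `contig`, `start`, `end`, `strand`, `part`.
#' @export
derive_flanks <- function(annotation, flank_size = 50, contig_lengths = NULL,
                          circular = FALSE) {
  stopifnot(flank_size > 0)
  if (circular && is.null(contig_lengths))
    stop("circular = TRUE requires contig_lengths")
  out <- vector("list", nrow(annotation))
  for (i in seq_len(nrow(annotation))) {
    a <- annotation[i, ]
    clen <- if (!is.null(contig_lengths)) unname(contig_lengths[a$contig]) else NA_integer_
    up <- c(a$start - flank_size, a$start)      # genomically upstream window
    down <- c(a$end, a$end + flank_size)        # genomically downstream window
    if (a$strand == "+") {
      roles <- c("leader5p", "trailer3p")
    } else {
      roles <- c("trailer3p", "leader5p")
    }
    parts <- list()
    for (k in 1:2) {
      w <- if (k == 1) up else down
      role <- roles[k]
      if (circular) {
        L <- clen
        s <- w[1] %% L
        e <- s + (w[2] - w[1])
        if (e <= L) {
          parts[[length(parts) + 1]] <- data.frame(
            locus_id = a$locus_id, role = role, contig = a$contig,
            start = s, end = e, strand = a$strand, part = 1L)
        } else {
          parts[[length(parts) + 1]] <- data.frame(
            locus_id = a$locus_id, role = role, contig = a$contig,
            start = s, end = L, strand = a$strand, part = 1L)
          parts[[length(parts) + 1]] <- data.frame(
            locus_id = a$locus_id, role = role, contig = a$contig,
            start = 0L, end = e - L, strand = a$strand, part = 2L)
        }
      } else {
        s <- max(w[1], 0L)
        e <- if (is.na(clen)) w[2] else min(w[2], clen)
        if (e > s)
          parts[[length(parts) + 1]] <- data.frame(
            locus_id = a$locus_id, role = role, contig = a$contig,
            start = s, end = e, strand = a$strand, part = 1L)
      }
    }
    out[[i]] <- do.call(rbind, parts)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$start <- as.integer(res$start)
  res$end <- as.integer(res$end)
  attr(res, "flank_size") <- flank_size
  class(res) <- c("trna_flanks", "data.frame")
  res
}

## extended BED schema: BED6 + organelle, has_intron (0/1), duplicate_group
## ('.' = none), group_kind ('.'), amino_acid, anticodon
.bed_extra_cols <- c("organelle", "has_intron", "duplicate_group",
                     "group_kind", "amino_acid", "anticodon")

#' Read a tRNA annotation from BED or GTF
#'
#' The BED dialect is BED6 plus six documented extra columns (`organelle`,
#' `has_intron` as 0/1, `duplicate_group` with `.` for none, `group_kind`,
#' `amino_acid`, `anticodon`); the name field carries the locus id. The GTF
#' dialect carries the same fields as attributes (`gene_id` for the locus id)
#' and is converted from 1-based inclusive to the internal 0-based half-open
#' convention on load. Loci are returned in file order.
#'
#' @param path annotation file.
#' @param format `"auto"` (by extension), `"bed"` or `"gtf"`.
#' @param length_bounds passed to [as_trna_annotation()].
#' @return a `trna_annotation`.
#' @export
read_trna_annotation <- function(path, format = c("auto", "bed", "gtf"),
                                 length_bounds = c(50, 120)) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gtf", "gff")) "gtf" else "bed"
  }
  if (format == "bed") {
    lines <- readLines(path)
    lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 12L))
      stop("malformed BED line ", which(nf != 12L)[1],
           ": expected 12 tab-separated fields, found ", nf[nf != 12L][1])
    m <- do.call(rbind, fields)
    df <- data.frame(
      locus_id = m[, 4], amino_acid = m[, 11], anticodon = m[, 12],
      organelle = m[, 7], contig = m[, 1],
      start = suppressWarnings(as.integer(m[, 2])),
      end = suppressWarnings(as.integer(m[, 3])),
      strand = m[, 6],
      has_intron = m[, 8] == "1",
      duplicate_group = ifelse(m[, 9] == ".", NA_character_, m[, 9]),
      group_kind = ifelse(m[, 10] == ".", NA_character_, m[, 10]))
    bad <- which(is.na(df$start) | is.na(df$end))
    if (length(bad) > 0)
      stop("malformed BED line ", bad[1], ": non-numeric coordinates")
  } else {
    gr <- rtracklayer::import(path, format = "gtf")
    mc <- S4Vectors::mcols(gr)
    need <- c("gene_id", "organelle", "has_intron", "amino_acid", "anticodon")
    miss <- setdiff(need, names(mc))
    if (length(miss) > 0)
      stop("GTF is missing required attribute(s): ", paste(miss, collapse = ", "))
    df <- data.frame(
      locus_id = mc$gene_id, amino_acid = mc$amino_acid,
      anticodon = mc$anticodon, organelle = mc$organelle,
      contig = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,  # 1-based inclusive -> 0-based half-open
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      has_intron = mc$has_intron %in% c("1", "true", "TRUE"),
      duplicate_group = if ("duplicate_group" %in% names(mc))
        ifelse(mc$duplicate_group %in% c(".", ""), NA_character_,
               mc$duplicate_group) else NA_character_,
      group_kind = if ("group_kind" %in% names(mc))
        ifelse(mc$group_kind %in% c(".", ""), NA_character_,
               mc$group_kind) else NA_character_)
  }
  as_trna_annotation(df, length_bounds = length_bounds)
}

#' Write a tRNA annotation to BED or GTF
#'
#' Emits the normalised annotation in either dialect of the schema read by
#' [read_trna_annotation()], for audit and round-tripping.
#'
#' @param annotation a `trna_annotation`.
#' @param path output file.
#' @param format `"bed"` or `"gtf"`.
#' @return `path`, invisibly.
#' @export
write_trna_annotation <- function(annotation, path, format = c("bed", "gtf")) {
  format <- match.arg(format)
  a <- annotation
  if (format == "bed") {
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s\t%s\t%d\t%s\t%s\t%s\t%s",
                     a$contig, a$start, a$end, a$locus_id, a$strand,
                     a$organelle, as.integer(a$has_intron),
                     ifelse(is.na(a$duplicate_group), ".", a$duplicate_group),
                     ifelse(is.na(a$group_kind), ".", a$group_kind),
                     a$amino_acid, a$anticodon)
  } else {
    attrs <- sprintf(paste0('gene_id "%s"; organelle "%s"; has_intron "%d"; ',
                            'duplicate_group "%s"; group_kind "%s"; ',
                            'amino_acid "%s"; anticodon "%s";'),
                     a$locus_id, a$organelle, as.integer(a$has_intron),
                     ifelse(is.na(a$duplicate_group), ".", a$duplicate_group),
                     ifelse(is.na(a$group_kind), ".", a$group_kind),
                     a$amino_acid, a$anticodon)
    lines <- sprintf("%s\ttrnaproc\ttRNA\t%d\t%d\t.\t%s\t.\t%s",
                     a$contig, a$start + 1L, a$end, a$strand, attrs)
  }
  writeLines(lines, path)
  invisible(path)
}
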