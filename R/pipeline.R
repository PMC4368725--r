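#' Assemble and validate a pipeline configuration
#'
#' @param annotation a `trna_annotation` or path to an annotation file.
#' @param reads named list (sample label -> `aligned_reads` table or path to a
#'   SAM/BAM/BED file).
#' @param reference,contrast sample labels; must differ and be in `reads`.
#' @param genome optional FASTA path or `DNAStringSet` (used for contig
#'   lengths when clipping flanks).
#' @param output_dir optional directory; when set, [run_pipeline()] writes its
#'   result tables and run log there as TSV/text.
#' @param flank_size,f_mature,f_flank counting parameters (defaults 50 nt,
#'   0.3, 0.1).
#' @param alternative Fisher alternative (see [fisher_exact()]).
#' @param bh_family `"run"` (one BH family pooling the 5' and 3' tests of the
#'   run, the default) or `"per_end"` (adjust each end separately).
#' @param stranded,circular,include_nuclear,multimap_weight switches passed to
#'   the counting and eligibility stages.
#' @param library_sizes optional named vector of total mapped reads per sample
#'   for RPKM; defaults to the number of reads supplied per sample.
#' @param feature_sets optional ordered named list of interval sets for
#'   [annotate_by_priority()].
#' @param seed seed recorded in the log (the pipeline itself is
#'   deterministic).
#' @return a validated `run_config` list.
#' @export
run_config <- function(annotation, reads, reference, contrast,
                       genome = NULL, output_dir = NULL,
                       flank_size = 50, f_mature = 0.3, f_flank = 0.1,
                       alternative = c("greater", "two.sided", "less"),
                       bh_family = c("run", "per_end"),
                       stranded = FALSE, circular = FALSE,
                       include_nuclear = FALSE, multimap_weight = FALSE,
                       library_sizes = NULL, feature_sets = NULL,
                       seed = NULL) {
  alternative <- match.arg(alternative)
  bh_family <- match.arg(bh_family)
  stopifnot(flank_size > 0, f_mature > 0, f_mature <= 1,
            f_flank > 0, f_flank <= 1)
  if (identical(reference, contrast))
    stop("reference and contrast samples must differ")
  if (is.null(names(reads)) || any(!nzchar(names(reads))))
    stop("reads must be a named list (sample label -> table or path)")
  if (!all(c(reference, contrast) %in% names(reads)))
    stop("reference and contrast must name entries of reads")
  structure(list(annotation = annotation, reads = reads, genome = genome,
                 output_dir = output_dir, flank_size = flank_size,
                 f_mature = f_mature, f_flank = f_flank,
                 alternative = alternative, bh_family = bh_family,
                 stranded = stranded, circular = circular,
                 include_nuclear = include_nuclear,
                 multimap_weight = multimap_weight,
                 library_sizes = library_sizes, feature_sets = feature_sets,
                 reference = reference, contrast = contrast, seed = seed),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML keys mirror the arguments of [run_config()]; `reads` is a mapping
#' from sample label to alignment path.
#'
#' @param path YAML file.
#' @param ... overrides applied on top of the file values.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}

#' Run the tRNA end-processing pipeline end to end
#'
#' Annotation loading, flank derivation, duplicate collapsing, read counting,
#' differential PER testing at both ends, RPKM/MA accumulation analysis and
#' (optionally) priority-ordered annotation statistics, with a run log that
#' records every parameter, the BH family, and the excluded-locus accounting
#' (loci in = loci reported + intron-excluded + duplicate non-representatives
#' + nuclear loci when excluded). Deterministic given the configuration.
#'
#' @param config a `run_config`.
#' @return an object of class `trna_run`: a list with `counts`, `per_5p` and
#'   `per_3p` (`per_fit` objects), `per_locus` (combined report table),
#'   `accumulation`, `category_stats` (or NULL), `annotation`, `log` (character
#'   vector) and the echoed `config`. Tables are also written under
#'   `config$output_dir` when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  ann <- config$annotation
  if (is.character(ann)) ann <- read_trna_annotation(ann)
  log <- c(sprintf("trnaproc run: reference=%s contrast=%s", config$reference,
                   config$contrast),
           sprintf("parameters: flank_size=%d f_mature=%g f_flank=%g %s",
                   config$flank_size, config$f_mature, config$f_flank,
                   sprintf("alternative=%s bh_family=%s stranded=%s circular=%s",
                           config$alternative, config$bh_family,
                           config$stranded, config$circular)))

  contig_lengths <- NULL
  if (!is.null(config$genome)) {
    gen <- config$genome
    if (is.character(gen)) gen <- Biostrings::readDNAStringSet(gen)
    contig_lengths <- stats::setNames(Biostrings::width(gen), names(gen))
  }
  flanks <- derive_flanks(ann, flank_size = config$flank_size,
                          contig_lengths = contig_lengths,
                          circular = config$circular)

  reads <- lapply(names(config$reads), function(smp) {
    r <- config$reads[[smp]]
    if (is.character(r)) r <- read_alignments(r, sample = smp)
    if (nrow(r) == 0) stop("empty read set for sample ", smp)
    r$sample <- smp
    r
  })
  reads <- as_aligned_reads(do.call(rbind, reads))
  bad <- setdiff(unique(reads$contig), unique(ann$contig))
  if (length(bad) > 0)
    stop("read contig(s) absent from the annotation: ",
         paste(bad, collapse = ", "))

  dup_map <- collapse_duplicates(ann)
  counts <- count_reads(reads, ann, flanks,
                        f_mature = config$f_mature, f_flank = config$f_flank,
                        duplicate_map = dup_map,
                        multimap_weight = config$multimap_weight,
                        stranded = config$stranded)

  eligible <- per_eligible(ann, include_nuclear = config$include_nuclear)
  elig_ids <- ann$locus_id[eligible]
  n_nonrep <- sum(!ann$is_representative)
  n_intron <- sum(ann$is_representative & ann$organelle == "plastid" &
                    ann$has_intron)
  n_nuclear <- if (config$include_nuclear) 0 else
    sum(ann$is_representative & ann$organelle == "nucleus" &
          !(ann$organelle == "plastid" & ann$has_intron))
  log <- c(log, sprintf(
    "loci: %d in = %d reported + %d intron-excluded + %d duplicate non-representatives + %d nuclear-excluded",
    nrow(ann), length(elig_ids), n_intron, n_nonrep, n_nuclear))

  per5 <- per_test(counts, config$reference, config$contrast, end = "5p",
                   alternative = config$alternative, eligible_ids = elig_ids)
  per3 <- per_test(counts, config$reference, config$contrast, end = "3p",
                   alternative = config$alternative, eligible_ids = elig_ids)
  if (config$bh_family == "run") {
    pool <- bh_adjust(c(per5$table$p_value, per3$table$p_value))
    per5$table$adj_p <- pool[seq_len(nrow(per5$table))]
    per3$table$adj_p <- pool[-seq_len(nrow(per5$table))]
    fam <- sum(!is.na(pool))
    per5$family_size <- per3$family_size <- fam
    log <- c(log, sprintf("BH family: pooled 5'+3' tests, size %d", fam),
             paste("BH family members (5'):",
                   paste(per5$table$locus_id[!is.na(per5$table$p_value)],
                         collapse = ",")),
             paste("BH family members (3'):",
                   paste(per3$table$locus_id[!is.na(per3$table$p_value)],
                         collapse = ",")))
  } else {
    log <- c(log, sprintf("BH family: per end, sizes %d (5') and %d (3')",
                          per5$family_size, per3$family_size))
  }

  lib <- config$library_sizes
  if (is.null(lib)) lib <- tapply(rep(1L, nrow(reads)), reads$sample, sum)
  acc <- accumulation_ma(counts, ann, config$reference, config$contrast,
                         library_sizes = lib)
  log <- c(log, sprintf("library sizes: %s",
                        paste(names(lib), unname(lib), sep = "=", collapse = " ")))

  cat_stats <- NULL
  if (!is.null(config$feature_sets))
    cat_stats <- annotate_by_priority(reads, config$feature_sets)

  per_locus <- .per_report_table(per5, per3, ann)
  res <- structure(list(counts = counts, per_5p = per5, per_3p = per3,
                        per_locus = per_locus, accumulation = acc,
                        category_stats = cat_stats, annotation = ann,
                        log = log, config = config),
                   class = "trna_run")
  if (!is.null(config$output_dir)) .write_run(res, config$output_dir)
  res
}

## combined per-locus report in the layout of the published tables:
## per-sample mature/leader counts and log2 ratios (full precision plus a
## 2-decimal printed column), P and adjusted P for the 5' end, then 3' PERs
.per_report_table <- function(per5, per3, ann) {
  t5 <- per5$table
  t3 <- per3$table[, c("locus_id", "per_ref", "per_con", "M", "p_value", "adj_p")]
  names(t3) <- c("locus_id", "per3_ref", "per3_con", "M_3p", "p_value_3p",
                 "adj_p_3p")
  meta <- ann[match(t5$locus_id, ann$locus_id),
              c("locus_id", "amino_acid", "anticodon", "organelle")]
  out <- cbind(meta, t5[, setdiff(names(t5), "locus_id")])
  out$per_ref_printed <- round_half_up(out$per_ref, 2)
  out$per_con_printed <- round_half_up(out$per_con, 2)
  out <- merge(out, t3, by = "locus_id", sort = FALSE)
  rownames(out) <- NULL
  out
}

.fmt_dash <- function(x, digits = 6) ifelse(is.na(x), "-",
                                            formatC(x, digits = digits,
                                                    format = "g"))

.write_run <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    df2 <- df
    for (cn in names(df2)) if (is.numeric(df2[[cn]]))
      df2[[cn]] <- .fmt_dash(df2[[cn]])
    utils::write.table(df2, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wr(res$per_locus, "per_locus.tsv")
  ma5 <- res$per_5p$table[, c("locus_id", "A", "M", "p_value", "adj_p")]
  ma3 <- res$per_3p$table[, c("locus_id", "A", "M", "p_value", "adj_p")]
  wr(ma5[!is.na(ma5$M), ], "per_ma_5p.tsv")
  wr(ma3[!is.na(ma3$M), ], "per_ma_3p.tsv")
  wr(res$accumulation, "accumulation_ma.tsv")
  if (!is.null(res$category_stats)) wr(res$category_stats, "category_stats.tsv")
  writeLines(res$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' @export
print.trna_run <- function(x, ...) {
  cat("trnaproc pipeline run\n")
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}

#' Compare a result table against a reference fixture
#'
#' Cell-by-cell comparison of shared numeric columns between two tables keyed
#' by locus id. Differences exceeding `tolerance`, definedness mismatches
#' (value vs dash/NA) and key mismatches are reported; an empty report means
#' the tables agree.
#'
#' @param result,fixture data frames sharing a key column and some numeric
#'   columns.
#' @param tolerance absolute tolerance for numeric cells (default 0.005, i.e.
#'   2-decimal printed precision).
#' @param key key column name (default `"locus_id"`).
#' @return data frame with columns `locus_id`, `column`, `result`, `fixture`,
#'   `type` (`"value"`, `"definedness"` or `"missing_key"`); zero rows = pass.
#' @export
validate_against_fixture <- function(result, fixture, tolerance = 0.005,
                                     key = "locus_id") {
  rep0 <- data.frame(locus_id = character(), column = character(),
                     result = numeric(), fixture = numeric(),
                     type = character())
  out <- rep0
  only_r <- setdiff(result[[key]], fixture[[key]])
  only_f <- setdiff(fixture[[key]], result[[key]])
  for (k in c(only_r, only_f))
    out <- rbind(out, data.frame(locus_id = k, column = key, result = NA,
                                 fixture = NA, type = "missing_key"))
  shared <- intersect(result[[key]], fixture[[key]])
  cols <- intersect(names(result), names(fixture))
  cols <- cols[cols != key &
                 vapply(cols, function(cn) is.numeric(result[[cn]]) &&
                          is.numeric(fixture[[cn]]), logical(1))]
  ri <- match(shared, result[[key]])
  fi <- match(shared, fixture[[key]])
  for (cn in cols) {
    rv <- result[[cn]][ri]
    fv <- fixture[[cn]][fi]
    mism <- xor(is.na(rv), is.na(fv))
    if (any(mism))
      out <- rbind(out, data.frame(locus_id = shared[mism], column = cn,
                                   result = rv[mism], fixture = fv[mism],
                                   type = "definedness"))
    both <- !is.na(rv) & !is.na(fv)
    off <- both & abs(rv - fv) > tolerance
    if (any(off))
      out <- rbind(out, data.frame(locus_id = shared[off], column = cn,
                                   result = rv[off], fixture = fv[off],
                                   type = "value"))
  }
  rownames(out) <- NULL
  out
}

#' Parse a printed per-tRNA count table
#'
#' Reads a TSV in the layout of the published per-tRNA tables: one row per
#' locus with mature and 5'-leader counts for two samples, printed log2 ratios
#' and P values. Thousands separators (`"39,297"`) are parsed and dashes
#' (transcripts not detected, or values that could not be calculated) become
#' NA.
#'
#' @param path TSV file; the packaged fixtures live under
#'   `system.file("extdata", package = "trnaproc")`.
#' @return data frame with numeric count/ratio columns; see the fixture
#'   headers for the column set.
#' @export
read_printed_counts <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, colClasses = "character")
  num <- function(x) suppressWarnings(as.numeric(gsub(",", "", x, fixed = TRUE)))
  for (cn in setdiff(names(df), c("amino_acid", "anticodon", "locus_id",
                                  "organelle")))
    df[[cn]] <- num(df[[cn]])
  df
}

#' Long count table from a printed fixture
#'
#' Reshapes a [read_printed_counts()] table into the `trna_counts` layout
#' consumed by [per_test()], with the printed sample columns mapped to the
#' given labels.
#'
#' @param printed table from [read_printed_counts()].
#' @param reference,contrast sample labels for the printed WT / knock-down
#'   columns.
#' @return a `trna_counts` data frame (with `trailer3p` absent from print
#'   fixtures set to NA).
#' @export
printed_to_counts <- function(printed, reference = "WT", contrast = "RNAi-2") {
  long <- rbind(
    data.frame(locus_id = printed$locus_id, sample = reference,
               mature = printed$mature_wt, leader5p = printed$leader_wt,
               trailer3p = NA_real_),
    data.frame(locus_id = printed$locus_id, sample = contrast,
               mature = printed$mature_rnai, leader5p = printed$leader_rnai,
               trailer3p = NA_real_))
  ## a dash in a printed count cell means "not detected": zero reads
  long$mature[is.na(long$mature)] <- 0
  long$leader5p[is.na(long$leader5p)] <- 0
  class(long) <- c("trna_counts", "data.frame")
  long
}
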