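#' Differential tRNA end-processing analysis
#'
#' Fits the processing-efficiency contrast between two samples from a
#' mature/flank count table: computes the per-sample processing efficiency
#' rate (PER, log2 mature/flank), the difference M and average A of the two
#' PERs, a Fisher exact p value on the underlying 2x2 count table, and
#' Benjamini-Hochberg adjusted p values over the defined tests.
#'
#' PER and hence M, A and the p value are undefined (NA) for a locus whenever
#' the mature or flank count of either sample is zero; undefined rows are
#' reported with dashes and excluded from the BH family.
#'
#' @param counts a `trna_counts` table (from [count_reads()] or
#'   [read_printed_counts()]) holding both samples.
#' @param reference reference sample label (e.g. `"WT"`).
#' @param contrast contrast sample label (e.g. the knock-down line); defaults
#'   to the only other sample present.
#' @param end which flank to test: `"5p"` (leader) or `"3p"` (trailer).
#' @param alternative Fisher alternative, see [fisher_exact()].
#' @param eligible_ids optional locus ids to restrict the analysis (and the BH
#'   family) to, e.g. `annotation$locus_id[per_eligible(annotation)]`.
#' @return an object of class `per_fit`: a list with the per-locus `table`
#'   (columns `locus_id`, counts, `per_ref`, `per_con`, `M`, `A`, `p_value`,
#'   `adj_p`, `defined`), the sample labels, `end`, `alternative` and the BH
#'   `family_size`.
#' @seealso [plot.per_fit()] for the MA plot.
#' @export
per_test <- function(counts, reference, contrast = NULL,
                     end = c("5p", "3p"),
                     alternative = c("greater", "two.sided", "less"),
                     eligible_ids = NULL) {
  end <- match.arg(end)
  alternative <- match.arg(alternative)
  samples <- unique(counts$sample)
  if (!reference %in% samples) stop("reference sample '", reference, "' not in counts")
  if (is.null(contrast)) {
    others <- setdiff(samples, reference)
    if (length(others) != 1)
      stop("contrast must be given when counts hold more than two samples")
    contrast <- others
  }
  if (identical(reference, contrast)) stop("reference and contrast must differ")
  if (!contrast %in% samples) stop("contrast sample '", contrast, "' not in counts")
  fcol <- if (end == "5p") "leader5p" else "trailer3p"

  ref <- counts[counts$sample == reference, c("locus_id", "mature", fcol)]
  con <- counts[counts$sample == contrast, c("locus_id", "mature", fcol)]
  names(ref)[2:3] <- c("mature_ref", "flank_ref")
  names(con)[2:3] <- c("mature_con", "flank_con")
  tab <- merge(ref, con, by = "locus_id", sort = FALSE)
  if (!is.null(eligible_ids)) tab <- tab[tab$locus_id %in% eligible_ids, ]
  rownames(tab) <- NULL

  tab$per_ref <- compute_per(tab$mature_ref, tab$flank_ref)
  tab$per_con <- compute_per(tab$mature_con, tab$flank_con)
  tab$defined <- !is.na(tab$per_ref) & !is.na(tab$per_con)
  ma <- ma_transform(tab$per_ref, tab$per_con, scale = "identity")
  tab$M <- ifelse(tab$defined, ma$M, NA_real_)
  tab$A <- ifelse(tab$defined, ma$A, NA_real_)
  tab$p_value <- NA_real_
  if (any(tab$defined))
    tab$p_value[tab$defined] <- fisher_exact(
      tab$mature_ref[tab$defined], tab$flank_ref[tab$defined],
      tab$mature_con[tab$defined], tab$flank_con[tab$defined],
      alternative = alternative)
  tab$adj_p <- bh_adjust(tab$p_value)

  structure(list(table = tab, reference = reference, contrast = contrast,
                 end = end, alternative = alternative,
                 family_size = sum(tab$defined), call = match.call()),
            class = "per_fit")
}

#' @export
print.per_fit <- function(x, ...) {
  cat("Differential tRNA ", x$end, " end-processing (PER) analysis\n", sep = "")
  cat("  samples:     ", x$contrast, " vs ", x$reference, " (reference)\n", sep = "")
  cat("  loci:        ", nrow(x$table), " (", x$family_size,
      " with defined PER in both samples)\n", sep = "")
  cat("  Fisher test: alternative = '", x$alternative,
      "', BH family size = ", x$family_size, "\n", sep = "")
  nsig <- sum(x$table$adj_p < 0.05, na.rm = TRUE)
  cat("  significant: ", nsig, " loci at adjusted p < 0.05\n", sep = "")
  invisible(x)
}

#' @export
summary.per_fit <- function(object, ...) {
  tab <- object$table
  ord <- order(tab$adj_p, tab$p_value, na.last = TRUE)
  print(object)
  show <- tab[ord, c("locus_id", "per_ref", "per_con", "M", "p_value", "adj_p")]
  cat("\nTop loci by adjusted p value:\n")
  print(utils::head(show, 10), digits = 3, row.names = FALSE)
  invisible(tab[ord, ])
}

#' Per-locus PER differences
#'
#' @param object a `per_fit`.
#' @param ... unused.
#' @return named vector of M values (PER contrast minus PER reference).
#' @export
coef.per_fit <- function(object, ...) {
  stats::setNames(object$table$M, object$table$locus_id)
}

#' MA plot of processing efficiency
#'
#' Plots the PER difference M against the PER average A for every locus with
#' defined values; loci significant at `alpha` (BH-adjusted) are filled.
#'
#' @param x a `per_fit`.
#' @param alpha significance threshold on the adjusted p value.
#' @param ... passed to [graphics::plot()].
#' @export
plot.per_fit <- function(x, alpha = 0.05, ...) {
  tab <- x$table[x$table$defined, ]
  sig <- !is.na(tab$adj_p) & tab$adj_p < alpha
  graphics::plot(tab$A, tab$M, pch = ifelse(sig, 19, 1),
                 xlab = "A (mean PER)", ylab = "M (PER difference)",
                 main = paste0(x$end, " processing efficiency: ",
                               x$contrast, " vs ", x$reference), ...)
  graphics::abline(h = 0, lty = 2, col = "grey50")
  if (any(sig))
    graphics::text(tab$A[sig], tab$M[sig], tab$locus_id[sig],
                   pos = 4, cex = 0.7)
  invisible(x)
}

#' RPKM accumulation table and MA values
#'
#' Computes per-locus RPKM on the mature region for two samples and the
#' M/A transform of the two RPKM values (defined only where both are
#' positive).
#'
#' @param counts a `trna_counts` table.
#' @param annotation a `trna_annotation` (for mature region lengths).
#' @param reference,contrast sample labels.
#' @param library_sizes named vector of total mapped reads per sample.
#' @return data frame with columns `locus_id`, `rpkm_ref`, `rpkm_con`,
#'   `M`, `A`.
#' @export
accumulation_ma <- function(counts, annotation, reference, contrast,
                            library_sizes) {
  if (!all(c(reference, contrast) %in% names(library_sizes)))
    stop("library_sizes must be named with the sample labels")
  len <- stats::setNames(annotation$end - annotation$start, annotation$locus_id)
  ref <- counts[counts$sample == reference, c("locus_id", "mature")]
  con <- counts[counts$sample == contrast, c("locus_id", "mature")]
  tab <- merge(ref, con, by = "locus_id", suffixes = c("_ref", "_con"),
               sort = FALSE)
  tab$rpkm_ref <- compute_rpkm(tab$mature_ref, len[tab$locus_id],
                               library_sizes[[reference]])
  tab$rpkm_con <- compute_rpkm(tab$mature_con, len[tab$locus_id],
                               library_sizes[[contrast]])
  ok <- tab$rpkm_ref > 0 & tab$rpkm_con > 0
  tab$M <- tab$A <- NA_real_
  if (any(ok)) {
    ma <- ma_transform(tab$rpkm_ref[ok], tab$rpkm_con[ok], scale = "log2")
    tab$M[ok] <- ma$M
    tab$A[ok] <- ma$A
  }
  tab[, c("locus_id", "rpkm_ref", "rpkm_con", "M", "A")]
}
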