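#' Reads per kilobase per million mapped reads
#'
#' @param count read count(s) on the feature.
#' @param feature_length feature length(s) in nt, > 0.
#' @param library_size total mapped reads in the library, > 0.
#' @return RPKM value(s).
#' @export
compute_rpkm <- function(count, feature_length, library_size) {
  if (any(feature_length <= 0)) stop("feature_length must be > 0")
  if (any(library_size <= 0)) stop("library_size must be > 0")
  count / (feature_length / 1000) / (library_size / 1e6)
}

#' Processing efficiency rate (PER)
#'
#' PER is the log2 ratio of reads on the mature tRNA region to reads on its 5'
#' or 3' flanking region. It is undefined (NA, printed as a dash) whenever
#' either count is zero — no pseudocounts are applied, so non-detected
#' transcripts propagate as dashes rather than infinities.
#'
#' @param mature_count,flank_count non-negative read counts (vectorised).
#' @return log2 ratio(s); NA where undefined.
#' @export
compute_per <- function(mature_count, flank_count) {
  if (any(mature_count < 0, na.rm = TRUE) || any(flank_count < 0, na.rm = TRUE))
    stop("counts must be non-negative")
  ok <- !is.na(mature_count) & !is.na(flank_count) &
    mature_count > 0 & flank_count > 0
  out <- rep(NA_real_, length(ok))
  out[ok] <- log2(mature_count[ok] / flank_count[ok])
  out
}

#' MA transform of two paired quantities
#'
#' For accumulation values (RPKM), M is the log2 fold difference
#' `log2(contrast) - log2(reference)` and A the mean of the two log2 values.
#' PER values are already log2 ratios (and may be negative), so with
#' `scale = "identity"` M and A are computed on the values directly.
#'
#' @param value_ref reference-sample value(s) (e.g. wild type).
#' @param value_con contrast-sample value(s) (e.g. the knock-down line).
#' @param scale `"log2"` for positive accumulation values, `"identity"` for
#'   quantities already on a log scale.
#' @return data frame with columns `M` and `A`.
#' @export
ma_transform <- function(value_ref, value_con, scale = c("log2", "identity")) {
  scale <- match.arg(scale)
  if (scale == "log2") {
    if (any(value_ref <= 0, na.rm = TRUE) || any(value_con <= 0, na.rm = TRUE))
      stop("log2 MA transform requires positive values")
    value_ref <- log2(value_ref)
    value_con <- log2(value_con)
  }
  data.frame(M = value_con - value_ref, A = (value_con + value_ref) / 2)
}

#' Fisher's exact test on a mature/flank x sample contingency table
#'
#' Tests whether the mature:flank read ratio differs between the two samples,
#' on the 2x2 table `[[mature_ref, flank_ref], [mature_con, flank_con]]`. The
#' default alternative `"greater"` (odds ratio > 1, i.e. relatively more
#' flank/precursor reads in the contrast sample) asks specifically for a loss
#' of processing efficiency in the contrast line; `"two.sided"` uses the
#' point-probability rule. All count arguments are vectorised.
#'
#' @param mature_ref,flank_ref,mature_con,flank_con non-negative counts.
#' @param alternative `"greater"`, `"two.sided"` or `"less"`.
#' @return p value(s); NA where a margin is empty or a count is NA.
#' @export
fisher_exact <- function(mature_ref, flank_ref, mature_con, flank_con,
                         alternative = c("greater", "two.sided", "less")) {
  alternative <- match.arg(alternative)
  n <- max(length(mature_ref), length(flank_ref),
           length(mature_con), length(flank_con))
  a <- rep_len(mature_ref, n); b <- rep_len(flank_ref, n)
  c_ <- rep_len(mature_con, n); d <- rep_len(flank_con, n)
  if (any(c(a, b, c_, d) < 0, na.rm = TRUE)) stop("counts must be non-negative")
  vapply(seq_len(n), function(i) {
    x <- c(a[i], b[i], c_[i], d[i])
    if (anyNA(x)) return(NA_real_)
    m <- matrix(x, nrow = 2, byrow = TRUE)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(NA_real_)
    stats::fisher.test(m, alternative = alternative)$p.value
  }, numeric(1))
}

#' Benjamini-Hochberg adjustment over the defined tests
#'
#' Step-up FDR adjustment where the family is the set of *defined* (non-NA)
#' p values; undefined entries stay NA and do not inflate the family size.
#'
#' @param p p values, possibly with NAs for tests that could not be computed.
#' @return adjusted p values in input order, NA where input was NA.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' tRNA editing efficiency from chromatogram peak heights
#'
#' A-to-I editing at the anticodon wobble position is read as G by reverse
#' transcriptase, so the efficiency is the G peak height over the summed G and
#' A peak heights at the edited site, in percent.
#'
#' @param peak_g,peak_a non-negative peak heights (vectorised).
#' @return editing efficiency in percent, in \[0, 100\].
#' @export
editing_efficiency <- function(peak_g, peak_a) {
  if (any(peak_g < 0) || any(peak_a < 0)) stop("peak heights must be >= 0")
  if (any(peak_g + peak_a == 0)) stop("peak heights must not both be zero")
  100 * peak_g / (peak_g + peak_a)
}

#' Round half away from zero
#'
#' Table-style printing convention used for the "printed" columns of result
#' tables (R's `round()` rounds half to even).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded values.
#' @export
round_half_up <- function(x, digits = 2) {
  s <- 10^digits
  # pre-round far below the target precision to absorb binary representation
  # error (2.425 * 100 is stored as 242.4999...)
  sign(x) * floor(round(abs(x) * s, 9) + 0.5) / s
}
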