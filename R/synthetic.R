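## amino-acid / anticodon combinations cycled over simulated loci
.aa_table <- data.frame(
  amino_acid = c("Phe", "Arg", "Val", "Cys", "Tyr", "His", "Gly", "Pro",
                 "Ser", "Lys", "Asp", "Glu", "Asn", "Trp", "Gln", "Met",
                 "Thr", "Leu", "Ile", "Ala"),
  anticodon = c("GAA", "ACG", "GAC", "GCA", "GTA", "GTG", "GCC", "TGG",
                "GCT", "TTT", "GTC", "TTC", "GTT", "CCA", "TTG", "CAT",
                "GGT", "TAG", "CAT", "TGC"))

.rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

.revcomp <- function(s) as.character(Biostrings::reverseComplement(
  Biostrings::DNAString(s)))

#' Build a toy organellar genome with tRNA loci
#'
#' Generates two circularly inspired (but linearly represented) contigs,
#' `"pt"` (plastid) and `"mt"` (mitochondrion), with non-overlapping tRNA loci
#' of 70-90 nt placed at least 120 nt apart. The structural quirks of real
#' organellar annotations are reproduced on demand: `n_ir_pairs` plastid loci
#' are duplicated as exact reverse-complement copies (inverted-repeat pairs,
#' one `+` and one `-` member), `n_tandem_dups` mitochondrial loci are
#' duplicated with identical sequence *and* identical 50-nt flanks (tandem
#' pairs), and `n_intron_trnas` plastid loci are flagged as intron-containing.
#'
#' @param n_plastid_trnas,n_mito_trnas numbers of base loci per contig.
#' @param n_ir_pairs inverted-repeat duplications (adds one extra plastid
#'   copy each); drawn from intronless plastid loci.
#' @param n_tandem_dups tandem duplications (adds one extra mitochondrial
#'   copy each).
#' @param n_intron_trnas plastid loci flagged `has_intron`.
#' @param seed RNG seed; the output is reproducible byte for byte.
#' @return list with `genome` (a [Biostrings::DNAStringSet]) and `annotation`
#'   (a `trna_annotation`).
#' @export
build_genome <- function(n_plastid_trnas = 5, n_mito_trnas = 5,
                         n_ir_pairs = 1, n_tandem_dups = 1,
                         n_intron_trnas = 1, seed = 1L) {
  stopifnot(n_plastid_trnas >= 0, n_mito_trnas >= 0, n_ir_pairs >= 0,
            n_tandem_dups >= 0, n_intron_trnas >= 0)
  if (n_intron_trnas + n_ir_pairs > n_plastid_trnas)
    stop("need n_plastid_trnas >= n_intron_trnas + n_ir_pairs")
  if (n_tandem_dups > n_mito_trnas)
    stop("need n_mito_trnas >= n_tandem_dups")
  set.seed(seed)
  slot <- 400L

  place_contig <- function(contig, n_loci, prefix) {
    if (n_loci == 0)
      return(list(seq = .rand_dna(slot), ann = NULL))
    clen <- (n_loci + 1L) * slot
    seq <- .rand_dna(clen)
    len <- sample(70:90, n_loci, replace = TRUE)
    jit <- sample(0:50, n_loci, replace = TRUE)
    start <- 100L + (seq_len(n_loci) - 1L) * slot + jit
    aa <- .aa_table[((seq_len(n_loci) - 1L) %% nrow(.aa_table)) + 1L, ]
    ann <- data.frame(
      locus_id = sprintf("%s-trna-%02d", prefix, seq_len(n_loci)),
      amino_acid = aa$amino_acid, anticodon = aa$anticodon,
      organelle = if (prefix == "pt") "plastid" else "mitochondrion",
      contig = contig, start = start, end = start + len,
      strand = sample(c("+", "-"), n_loci, replace = TRUE),
      has_intron = FALSE,
      duplicate_group = NA_character_, group_kind = NA_character_)
    list(seq = seq, ann = ann)
  }

  pt <- place_contig("pt", n_plastid_trnas + n_ir_pairs, "pt")
  mt <- place_contig("mt", n_mito_trnas + n_tandem_dups, "mt")
  ann <- rbind(pt$ann, mt$ann)

  copy_region <- function(seq, src_start, src_end, dst_start, revcomp) {
    s <- substr(seq, src_start + 1L, src_end)
    if (revcomp) s <- .revcomp(s)
    paste0(substr(seq, 1, dst_start),
           s, substr(seq, dst_start + nchar(s) + 1L, nchar(seq)))
  }

  pt_idx <- which(ann$contig == "pt")
  if (n_intron_trnas > 0)
    ann$has_intron[pt_idx[seq_len(n_intron_trnas)]] <- TRUE
  if (n_ir_pairs > 0) {
    orig <- pt_idx[n_intron_trnas + seq_len(n_ir_pairs)]
    copy <- pt_idx[n_plastid_trnas + seq_len(n_ir_pairs)]
    for (k in seq_len(n_ir_pairs)) {
      o <- orig[k]; cpy <- copy[k]
      g <- sprintf("ir_%02d", k)
      ann$strand[o] <- "+"
      ann$strand[cpy] <- "-"
      ann$duplicate_group[c(o, cpy)] <- g
      ann$group_kind[c(o, cpy)] <- "inverted_repeat"
      ann[cpy, c("amino_acid", "anticodon", "has_intron")] <-
        ann[o, c("amino_acid", "anticodon", "has_intron")]
      # exact reverse-complement copy including 50-nt flanks
      ann$end[cpy] <- ann$start[cpy] + (ann$end[o] - ann$start[o])
      pt$seq <- copy_region(pt$seq, ann$start[o] - 50L, ann$end[o] + 50L,
                            ann$start[cpy] - 50L, revcomp = TRUE)
    }
  }
  mt_idx <- which(ann$contig == "mt")
  if (n_tandem_dups > 0) {
    orig <- mt_idx[seq_len(n_tandem_dups)]
    copy <- mt_idx[n_mito_trnas + seq_len(n_tandem_dups)]
    for (k in seq_len(n_tandem_dups)) {
      o <- orig[k]; cpy <- copy[k]
      g <- sprintf("td_%02d", k)
      ann$strand[cpy] <- ann$strand[o]
      ann$duplicate_group[c(o, cpy)] <- g
      ann$group_kind[c(o, cpy)] <- "tandem"
      ann[cpy, c("amino_acid", "anticodon")] <- ann[o, c("amino_acid", "anticodon")]
      # identical copy including identical 50-nt flanks
      ann$end[cpy] <- ann$start[cpy] + (ann$end[o] - ann$start[o])
      mt$seq <- copy_region(mt$seq, ann$start[o] - 50L, ann$end[o] + 50L,
                            ann$start[cpy] - 50L, revcomp = FALSE)
    }
  }
  genome <- Biostrings::DNAStringSet(c(pt = pt$seq, mt = mt$seq))
  list(genome = genome, annotation = as_trna_annotation(ann), seed = seed)
}

#' Generative parameters of a synthetic processing experiment
#'
#' Describes, per locus and sample, the expected number of tRNA molecules and
#' the probabilities that a molecule has been 5'-processed (`p5`, leader
#' removed) and 3'-processed (`p3`, trailer removed). The contrast sample
#' (every sample after the first) has its `p5` (and optionally `p3`)
#' multiplied by `knockdown_factor`, emulating a knock-down of the
#' 5'-processing enzyme.
#'
#' @param annotation a `trna_annotation` the truth applies to.
#' @param expression_level expected molecule count per locus (recycled).
#' @param p5,p3 processing probabilities in (0, 1] for the reference sample.
#' @param knockdown_factor multiplier on `p5` in non-reference samples, in
#'   (0, 1].
#' @param knockdown_3p also apply the factor to `p3`?
#' @param leader_len,trailer_len unprocessed extension lengths in nt, 1-50.
#' @param read_length_range inclusive range of read lengths; a read covers its
#'   molecule from the 5' end, truncated to the drawn length.
#' @param capture_efficiency per-locus multiplier on `expression_level`
#'   (recycled), mimicking modification-driven underrepresentation.
#' @param samples sample labels; the first is the reference.
#' @param seed RNG seed used by [simulate_reads()].
#' @return an object of class `sim_truth`.
#' @export
sim_truth <- function(annotation, expression_level = 500, p5 = 0.8, p3 = 0.9,
                      knockdown_factor = 0.5, knockdown_3p = FALSE,
                      leader_len = 20, trailer_len = 20,
                      read_length_range = c(70, 150),
                      capture_efficiency = 1,
                      samples = c("WT", "RNAi"), seed = 1L) {
  stopifnot(all(p5 > 0 & p5 <= 1), all(p3 > 0 & p3 <= 1),
            knockdown_factor > 0, knockdown_factor <= 1,
            leader_len >= 1, leader_len <= 50,
            trailer_len >= 1, trailer_len <= 50,
            length(read_length_range) == 2,
            read_length_range[1] > 0,
            read_length_range[1] <= read_length_range[2],
            all(expression_level > 0), length(samples) >= 2)
  n <- nrow(annotation)
  expr <- rep_len(expression_level, n) * rep_len(capture_efficiency, n)
  p5 <- rep_len(p5, n)
  p3 <- rep_len(p3, n)
  params <- do.call(rbind, lapply(seq_along(samples), function(si) {
    kd <- if (si == 1) 1 else knockdown_factor
    data.frame(locus_id = annotation$locus_id, sample = samples[si],
               expression = expr, p5 = p5 * kd,
               p3 = if (knockdown_3p && si > 1) p3 * kd else p3)
  }))
  structure(list(params = params, annotation = annotation,
                 leader_len = as.integer(leader_len),
                 trailer_len = as.integer(trailer_len),
                 read_length_range = as.integer(read_length_range),
                 samples = samples, seed = as.integer(seed)),
            class = "sim_truth")
}

#' Simulate aligned small-RNA reads from a processing truth
#'
#' For each locus and sample, a Poisson number of molecules (mean
#' `expression`) is drawn; each molecule is independently 5'-processed with
#' probability `p5` and 3'-processed with `p3`, an unprocessed end extending
#' the molecule by `leader_len`/`trailer_len` nt beyond the mature locus. Each
#' molecule yields one read spanning it from the biological 5' end, truncated
#' to a length drawn uniformly from `read_length_range`, and placed at the
#' locus's genomic coordinates. Reads are emitted directly as alignments
#' (mapping is out of scope); sequences can optionally be written as FASTQ.
#'
#' @param truth a `sim_truth`.
#' @param annotation annotation to simulate over (default: the truth's).
#' @param samples sample labels to emit (default: all in the truth).
#' @param fastq optional FASTQ output path; requires `genome`.
#' @param genome `DNAStringSet` for FASTQ sequence extraction.
#' @return an `aligned_reads` table covering all requested samples.
#' @export
simulate_reads <- function(truth, annotation = truth$annotation,
                           samples = truth$samples,
                           fastq = NULL, genome = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  if (!is.null(fastq) && is.null(genome))
    stop("fastq output requires the genome sequences")
  set.seed(truth$seed)
  lmin <- truth$read_length_range[1]
  lmax <- truth$read_length_range[2]
  out <- list()
  for (smp in samples) {
    for (i in seq_len(nrow(annotation))) {
      a <- annotation[i, ]
      p <- truth$params[truth$params$sample == smp &
                          truth$params$locus_id == a$locus_id, ]
      if (nrow(p) != 1) stop("truth does not cover locus ", a$locus_id)
      n <- stats::rpois(1, p$expression)
      if (n == 0) next
      u5 <- stats::runif(n) >= p$p5   # leader still attached
      u3 <- stats::runif(n) >= p$p3   # trailer still attached
      lead <- ifelse(u5, truth$leader_len, 0L)
      trail <- ifelse(u3, truth$trailer_len, 0L)
      if (a$strand == "+") {
        mstart <- a$start - lead
        mend <- a$end + trail
      } else {
        mstart <- a$start - trail
        mend <- a$end + lead
      }
      rl <- pmin(sample(lmin:lmax, n, replace = TRUE), mend - mstart)
      if (a$strand == "+") {
        rstart <- mstart
        rend <- mstart + rl
      } else {
        rstart <- mend - rl
        rend <- mend
      }
      out[[length(out) + 1]] <- data.frame(
        read_id = sprintf("%s_%s_%06d", smp, a$locus_id, seq_len(n)),
        contig = a$contig, start = rstart, end = rend, strand = a$strand,
        sample = smp, mapping_count = 1L)
    }
  }
  reads <- as_aligned_reads(do.call(rbind, out))
  if (!is.null(fastq)) {
    seqs <- character(nrow(reads))
    for (j in seq_len(nrow(reads))) {
      s <- as.character(Biostrings::subseq(genome[[reads$contig[j]]],
                                           reads$start[j] + 1L, reads$end[j]))
      if (reads$strand[j] == "-") s <- .revcomp(s)
      seqs[j] <- s
    }
    rec <- rbind(paste0("@", reads$read_id), seqs, "+",
                 vapply(nchar(seqs), function(n)
                   paste(rep("I", n), collapse = ""), ""))
    writeLines(as.vector(rec), fastq)
  }
  reads
}

#' Analytic PER expectation under the generative model
#'
#' Computes log2 of the expected mature-assigned count over the expected
#' flank-assigned count for one locus and sample, by enumerating the four
#' processing states and the (discrete uniform) read-length distribution and
#' applying the same overlap-fraction thresholds as the counting stage. Used
#' as the recovery target in simulation tests. Undefined (NA) when the
#' expected flank count is zero (fully processed end).
#'
#' @param truth a `sim_truth`.
#' @param locus_id locus to evaluate.
#' @param sample sample label.
#' @param end `"5p"` or `"3p"`.
#' @param f_mature,f_flank overlap-fraction thresholds used in counting.
#' @return expected PER (log2 ratio), or NA.
#' @export
expected_per <- function(truth, locus_id, sample, end = c("5p", "3p"),
                         f_mature = 0.3, f_flank = 0.1) {
  end <- match.arg(end)
  a <- truth$annotation[truth$annotation$locus_id == locus_id, ]
  p <- truth$params[truth$params$sample == sample &
                      truth$params$locus_id == locus_id, ]
  if (nrow(a) != 1 || nrow(p) != 1) stop("unknown locus or sample")
  trna <- a$end - a$start
  ll <- truth$leader_len
  tl <- truth$trailer_len
  lens <- truth$read_length_range[1]:truth$read_length_range[2]
  e_mature <- 0; e_flank <- 0
  for (u5 in c(0, 1)) for (u3 in c(0, 1)) {
    prob <- (if (u5) 1 - p$p5 else p$p5) * (if (u3) 1 - p$p3 else p$p3)
    if (prob == 0) next
    mol <- trna + u5 * ll + u3 * tl
    rl <- pmin(lens, mol)
    lead_ov <- u5 * pmin(rl, ll)
    mat_ov <- pmax(0, pmin(rl - u5 * ll, trna))
    trail_ov <- u3 * pmax(0, rl - u5 * ll - trna)
    e_mature <- e_mature + prob * mean(mat_ov / rl >= f_mature)
    fl_ov <- if (end == "5p") lead_ov else trail_ov
    e_flank <- e_flank + prob * mean(fl_ov / rl >= f_flank)
  }
  if (e_flank == 0) return(NA_real_)
  log2(e_mature / e_flank)
}
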