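# independent brute-force oracles and small fixture builders

# minimal annotation builder
make_ann <- function(start, end, strand = "+", contig = "pt",
                     organelle = "plastid", has_intron = FALSE,
                     duplicate_group = NA_character_,
                     group_kind = NA_character_,
                     locus_id = sprintf("L%02d", seq_along(start))) {
  as_trna_annotation(data.frame(
    locus_id = locus_id, amino_acid = "Phe", anticodon = "GAA",
    organelle = organelle, contig = contig, start = start, end = end,
    strand = strand, has_intron = has_intron,
    duplicate_group = duplicate_group, group_kind = group_kind))
}

make_reads <- function(start, end, contig = "pt", strand = "+",
                       sample = "WT", mapping_count = 1L,
                       read_id = sprintf("r%04d", seq_along(start))) {
  as_aligned_reads(data.frame(
    read_id = read_id, contig = contig, start = start, end = end,
    strand = strand, sample = sample, mapping_count = mapping_count))
}

# double-loop counting oracle: plain arithmetic, no interval machinery
brute_count <- function(reads, ann, flanks, f_mature = 0.3, f_flank = 0.1,
                        dup_map = collapse_duplicates(ann)) {
  reps <- unique(unname(dup_map[ann$locus_id]))
  samples <- unique(reads$sample)
  grid <- expand.grid(locus_id = reps, sample = samples,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$mature <- grid$leader5p <- grid$trailer3p <- 0
  ov <- function(rs, re, fs, fe) max(0, min(re, fe) - max(rs, fs))
  for (i in seq_len(nrow(reads))) {
    rlen <- reads$end[i] - reads$start[i]
    for (j in seq_len(nrow(ann))) {
      rep_id <- dup_map[[ann$locus_id[j]]]
      row <- which(grid$locus_id == rep_id & grid$sample == reads$sample[i])
      if (reads$contig[i] == ann$contig[j]) {
        f <- ov(reads$start[i], reads$end[i], ann$start[j], ann$end[j]) / rlen
        if (f >= f_mature) grid$mature[row] <- grid$mature[row] + 1
      }
      for (role in c("leader5p", "trailer3p")) {
        fl <- flanks[flanks$locus_id == ann$locus_id[j] & flanks$role == role, ]
        if (nrow(fl) == 0) next
        w <- 0
        for (k in seq_len(nrow(fl)))
          if (reads$contig[i] == fl$contig[k])
            w <- w + ov(reads$start[i], reads$end[i], fl$start[k], fl$end[k])
        if (w / rlen >= f_flank) grid[[role]][row] <- grid[[role]][row] + 1
      }
    }
  }
  grid
}

# hypergeometric enumeration oracle for a 2x2 table [[a,b],[c,d]]
fisher_oracle <- function(a, b, c, d, alternative = "two.sided") {
  m <- a + c; n <- b + d; k <- a + b
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  if (alternative == "two.sided") {
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  } else if (alternative == "greater") {
    sum(probs[support >= a])
  } else {
    sum(probs[support <= a])
  }
}

# hand step-up BH oracle
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# tiny SAM writer for round-trip tests
write_sam <- function(path, contigs, records) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), contigs))
  writeLines(c(hdr, records), path)
}

fixture_annotation <- function() {
  read_trna_annotation(system.file("extdata", "organelle_trna.synthetic.bed",
                                   package = "trnaproc"))
}

fixture_printed <- function(which = c("plastid", "mito")) {
  which <- match.arg(which)
  read_printed_counts(system.file(
    "extdata", paste0(which, "_trna_counts.tsv"), package = "trnaproc"))
}
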