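test_that("overlap_fraction is intersection over read length", {
  expect_equal(overlap_fraction(100, 180, 150, 220), 30 / 80)
  expect_equal(overlap_fraction(100, 180, 100, 180), 1)
  expect_equal(overlap_fraction(100, 180, 200, 300), 0)
  expect_equal(overlap_fraction(100, 180, 150, 220, "pt", "mt"), 0)
  expect_error(overlap_fraction(100, 100, 150, 220), "zero-length")
})

test_that("reads crossing the cleavage site count on mature and flank", {
  ann <- make_ann(1000, 1072)  # 72-nt locus
  fl <- derive_flanks(ann, 50, c(pt = 5000))
  # 80-nt read: 72 nt mature (0.9 >= 0.3) plus 8 nt leader (0.1 >= 0.1)
  r <- make_reads(992, 1072)
  cc <- count_reads(r, ann, fl)
  expect_equal(cc$mature, 1)
  expect_equal(cc$leader5p, 1)
  expect_equal(cc$trailer3p, 0)
  # read fully inside the mature interval: mature only
  cc <- count_reads(make_reads(1000, 1072), ann, fl)
  expect_equal(unlist(cc[, c("mature", "leader5p", "trailer3p")]),
               c(mature = 1, leader5p = 0, trailer3p = 0))
  # 7 nt of leader on an 80-nt read is below the 0.1 flank threshold
  cc <- count_reads(make_reads(993, 1073), ann, fl)
  expect_equal(cc$leader5p, 0)
})

test_that("duplicate-group counts are combined into the representative", {
  ann <- make_ann(c(1000, 3000), c(1072, 3072), c("+", "-"),
                  duplicate_group = "g1", group_kind = "inverted_repeat")
  fl <- derive_flanks(ann, 50, c(pt = 5000))
  r <- make_reads(c(rep(1000, 5), rep(3000, 7)), c(rep(1072, 5), rep(3072, 7)))
  cc <- count_reads(r, ann, fl)
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$locus_id, ann$locus_id[1])
  expect_equal(cc$mature, 12)
})

test_that("counting matches a brute-force pairwise oracle on random instances", {
  set.seed(2024)
  for (rep in 1:200) {
    n_loci <- sample(1:10, 1)
    starts <- sort(sample(seq(200, 9000, by = 250), n_loci))
    ann <- make_ann(starts, starts + sample(60:110, n_loci, replace = TRUE),
                    strand = sample(c("+", "-"), n_loci, replace = TRUE))
    fl <- derive_flanks(ann, 50, c(pt = 10000))
    n_reads <- sample(1:50, 1)
    rs <- sample(0:9800, n_reads, replace = TRUE)
    reads <- make_reads(rs, rs + sample(20:150, n_reads, replace = TRUE),
                        strand = sample(c("+", "-"), n_reads, replace = TRUE),
                        sample = sample(c("WT", "KD"), n_reads, replace = TRUE))
    got <- count_reads(reads, ann, fl)
    want <- brute_count(reads, ann, fl)
    key <- function(d) d[order(d$locus_id, d$sample),
                         c("locus_id", "sample", "mature", "leader5p", "trailer3p")]
    expect_equal(key(as.data.frame(got)), key(want), ignore_attr = TRUE)
  }
})

test_that("raising overlap thresholds never increases counts, and read order is irrelevant", {
  set.seed(7)
  starts <- c(500, 1500, 2500)
  ann <- make_ann(starts, starts + 72)
  fl <- derive_flanks(ann, 50, c(pt = 5000))
  rs <- sample(300:2700, 120, replace = TRUE)
  reads <- make_reads(rs, rs + sample(30:140, 120, replace = TRUE))
  lo <- count_reads(reads, ann, fl, f_mature = 0.2, f_flank = 0.05)
  hi <- count_reads(reads, ann, fl, f_mature = 0.6, f_flank = 0.3)
  expect_true(all(hi$mature <= lo$mature))
  expect_true(all(hi$leader5p <= lo$leader5p))
  expect_true(all(hi$trailer3p <= lo$trailer3p))

  shuf <- reads[sample(nrow(reads)), ]
  expect_equal(as.data.frame(count_reads(shuf, ann, fl)),
               as.data.frame(count_reads(reads, ann, fl)))
})

test_that("multimap down-weighting and strand-matched counting are available", {
  ann <- make_ann(1000, 1072, "+")
  fl <- derive_flanks(ann, 50, c(pt = 5000))
  r <- make_reads(c(1000, 1000), c(1072, 1072), mapping_count = c(2L, 2L),
                  read_id = c("r1", "r1"))
  expect_equal(count_reads(r, ann, fl)$mature, 2)
  expect_equal(count_reads(r, ann, fl, multimap_weight = TRUE)$mature, 1)

  r2 <- make_reads(c(1000, 1000), c(1072, 1072), strand = c("+", "-"))
  expect_equal(count_reads(r2, ann, fl)$mature, 2)
  expect_equal(count_reads(r2, ann, fl, stranded = TRUE)$mature, 1)
})

test_that("priority annotation assigns each read to its first matching category", {
  reads <- make_reads(c(100, 100, 500, 900), c(180, 180, 580, 980))
  fs <- list(exons = data.frame(contig = "pt", start = 150, end = 400),
             utrs = data.frame(contig = "pt", start = 90, end = 120),
             repeats = data.frame(contig = "pt", start = 480, end = 600))
  cs <- annotate_by_priority(reads, fs)
  expect_equal(cs$reads[cs$category == "exons"], 2L)  # exon beats UTR overlap
  expect_equal(cs$reads[cs$category == "utrs"], 0L)
  expect_equal(cs$reads[cs$category == "repeats"], 1L)
  expect_equal(cs$reads[cs$category == "unassigned"], 1L)
  expect_equal(sum(cs$reads), nrow(reads))
  expect_error(annotate_by_priority(reads, list()), "named list")

  # property: counts always sum to the number of reads
  set.seed(5)
  for (i in 1:20) {
    rs <- sample(0:2000, 30, replace = TRUE)
    rd <- make_reads(rs, rs + 50)
    fs <- lapply(1:3, function(k) {
      s <- sample(0:2000, 5)
      data.frame(contig = "pt", start = s, end = s + sample(20:200, 5))
    })
    names(fs) <- c("exons", "utrs", "repeats")
    expect_equal(sum(annotate_by_priority(rd, fs)$reads), 30L)
  }
})

test_that("SAM alignments load with CIGAR-consumed reference spans", {
  sam <- tempfile(fileext = ".sam")
  write_sam(sam, c(pt = 5000), c(
    # 30M: reference span 30
    paste("r1", 0, "pt", 1001, 60, "30M", "*", 0, 0,
          paste(rep("A", 30), collapse = ""), "*", sep = "\t"),
    # 10M5D10M: deletion consumes reference -> span 25
    paste("r2", 16, "pt", 2001, 60, "10M5D10M", "*", 0, 0,
          paste(rep("A", 20), collapse = ""), "*", sep = "\t"),
    # 10M5I10M: insertion does not consume reference -> span 20
    paste("r3", 0, "pt", 3001, 60, "10M5I10M", "*", 0, 0,
          paste(rep("A", 25), collapse = ""), "*", sep = "\t"),
    # secondary placement of r1
    paste("r1", 256, "pt", 4001, 0, "30M", "*", 0, 0, "*", "*", sep = "\t")))
  rd <- read_alignments(sam, sample = "WT")
  expect_equal(nrow(rd), 4L)
  expect_equal(rd$start[rd$read_id == "r2"], 2000L)
  expect_equal(rd$end[rd$read_id == "r2"], 2025L)
  expect_equal(rd$end[rd$read_id == "r3"], 3020L)
  expect_equal(rd$strand[rd$read_id == "r2"], "-")
  expect_equal(sort(unique(rd$mapping_count[rd$read_id == "r1"])), 2L)

  prim <- read_alignments(sam, sample = "WT", include_secondary = FALSE)
  expect_equal(nrow(prim), 3L)

  # BED round trip preserves intervals
  bed <- tempfile(fileext = ".bed")
  write_alignments_bed(rd, bed)
  back <- read_alignments(bed, sample = "WT")
  expect_equal(back[, c("contig", "start", "end", "strand")],
               rd[, c("contig", "start", "end", "strand")],
               ignore_attr = TRUE)
})
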