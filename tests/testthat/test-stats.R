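test_that("RPKM follows count / (kb) / (million mapped reads)", {
  expect_equal(compute_rpkm(10, 100, 1e6), 100)
  expect_equal(compute_rpkm(0, 100, 1e6), 0)
  expect_equal(compute_rpkm(1, 1000, 1e6), 1)
  expect_error(compute_rpkm(1, 0, 1e6), "feature_length")
  expect_error(compute_rpkm(1, 100, 0), "library_size")
})

test_that("PER reproduces published log2 ratios and dash semantics", {
  expect_equal(round(compute_per(953, 177), 2), 2.43)
  expect_equal(round(compute_per(5880, 1), 2), 12.52)
  expect_equal(round(compute_per(118, 1061), 2), -3.17)
  expect_equal(compute_per(7, 7), 0)
  expect_equal(compute_per(c(2, 4, 8), c(2, 4, 8)), c(0, 0, 0))
  expect_true(is.na(compute_per(5618, 0)))
  expect_true(is.na(compute_per(0, 10)))
  expect_error(compute_per(-1, 5), "non-negative")
  # scale invariance in the multiplier
  set.seed(3)
  m <- sample(1:500, 25); f <- sample(1:500, 25); k <- sample(1:9, 25, replace = TRUE)
  expect_equal(compute_per(k * m, k * f), compute_per(m, f))
})

test_that("MA transform handles log2 accumulation and identity PER scales", {
  ma <- ma_transform(4, 16, scale = "log2")
  expect_equal(ma$M, 2)
  expect_equal(ma$A, 3)
  ma <- ma_transform(2.43, -0.05, scale = "identity")
  expect_equal(ma$M, -2.48)
  expect_equal(ma$A, 1.19)
  expect_equal(ma_transform(5, 5, "log2")$M, 0)
  expect_error(ma_transform(0, 4, "log2"), "positive")
})

test_that("fisher_exact matches hypergeometric enumeration on all tables with margins <= 12", {
  grid <- expand.grid(a = 0:12, b = 0:12, c = 0:12, d = 0:12)
  grid <- grid[grid$a + grid$b <= 12 & grid$c + grid$d <= 12 &
                 grid$a + grid$c <= 12 & grid$b + grid$d <= 12 &
                 (grid$a + grid$b) > 0 & (grid$c + grid$d) > 0 &
                 (grid$a + grid$c) > 0 & (grid$b + grid$d) > 0, ]
  for (alt in c("two.sided", "greater")) {
    got <- fisher_exact(grid$a, grid$b, grid$c, grid$d, alternative = alt)
    want <- mapply(fisher_oracle, grid$a, grid$b, grid$c, grid$d,
                   MoreArgs = list(alternative = alt))
    expect_equal(got, want, tolerance = 1e-12)
    expect_true(all(got > 0 & got <= 1 + 1e-12))
  }
})

test_that("fisher_exact worked examples and symmetries", {
  expect_equal(fisher_exact(5, 5, 5, 5, alternative = "two.sided"), 1)
  expect_equal(fisher_exact(3, 1, 1, 3, alternative = "two.sided"),
               fisher_oracle(3, 1, 1, 3))
  # invariance under simultaneous swap of both rows and both columns
  set.seed(9)
  for (i in 1:25) {
    x <- sample(0:40, 4)
    if (sum(x[1:2]) == 0 || sum(x[3:4]) == 0 ||
        x[1] + x[3] == 0 || x[2] + x[4] == 0) next
    expect_equal(fisher_exact(x[1], x[2], x[3], x[4], "two.sided"),
                 fisher_exact(x[4], x[3], x[2], x[1], "two.sided"))
  }
  expect_true(is.na(fisher_exact(0, 0, 5, 5)))
  expect_error(fisher_exact(-1, 2, 3, 4), "non-negative")
})

test_that("BH adjustment is the NA-aware step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.5, 1.0)), c(1.0, 1.0))
  got <- bh_adjust(c(0.01, NA, 0.02, NA, 0.03))
  expect_equal(got, c(0.03, NA, 0.03, NA, 0.03))
  expect_error(bh_adjust(c(0.5, 1.5)), "\\[0, 1\\]")
  # properties against the hand step-up oracle
  set.seed(13)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p))
    expect_true(all(adj >= p & adj <= 1))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
  }
})

test_that("editing efficiency is the G peak share in percent", {
  expect_equal(editing_efficiency(95, 5), 95)
  expect_equal(editing_efficiency(0, 7), 0)
  expect_equal(editing_efficiency(3.2, 3.2), 50)
  expect_error(editing_efficiency(0, 0), "zero")
  expect_error(editing_efficiency(-1, 2), ">= 0")
})

test_that("per_test builds a per_fit with dash propagation and methods", {
  printed <- fixture_printed("mito")
  counts <- printed_to_counts(printed)
  fit <- per_test(counts, reference = "WT", contrast = "RNAi-2")
  expect_s3_class(fit, "per_fit")
  tab <- fit$table
  # undefined wherever a mature or leader count is zero in either sample
  lys <- tab[tab$locus_id == "ATMG00100", ]
  expect_true(is.na(lys$per_ref) && !is.na(lys$per_con) && is.na(lys$p_value))
  expect_false(lys$defined)
  # family excludes undefined tests
  expect_equal(fit$family_size, sum(tab$defined))
  expect_true(all(is.na(tab$adj_p) == is.na(tab$p_value)))
  expect_true(all(tab$adj_p >= tab$p_value, na.rm = TRUE))
  # M is the PER difference
  gly <- tab[tab$locus_id == "ATMG00190", ]
  expect_equal(gly$M, gly$per_con - gly$per_ref)

  expect_output(print(fit), "PER")
  expect_named(coef(fit))
  expect_silent({
    pdf(NULL)
    plot(fit)
    dev.off()
  })
  capture.output(s <- summary(fit))
  expect_true(is.data.frame(s))

  expect_error(per_test(counts, reference = "WT", contrast = "WT"), "differ")
  expect_error(per_test(counts, reference = "nope"), "not in counts")
})

test_that("accumulation MA uses RPKM on mature regions", {
  ann <- make_ann(c(100, 400), c(172, 472))
  counts <- data.frame(locus_id = rep(ann$locus_id, 2),
                       sample = rep(c("WT", "KD"), each = 2),
                       mature = c(10, 0, 40, 8),
                       leader5p = 0, trailer3p = 0)
  acc <- accumulation_ma(counts, ann, "WT", "KD",
                         library_sizes = c(WT = 1e6, KD = 2e6))
  expect_equal(acc$rpkm_ref[1], compute_rpkm(10, 72, 1e6))
  expect_equal(acc$M[1], log2(acc$rpkm_con[1]) - log2(acc$rpkm_ref[1]))
  expect_true(is.na(acc$M[2]))  # zero in one sample -> undefined
})
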