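test_that("read counting honours half-open bin boundaries", {
  g <- bin_grid(rep("chr1", 3), c(0, 100, 200), c(100, 200, 300))
  pos <- data.frame(chrom = "chr1", pos = c(0, 99, 100, 200, 299))
  bc <- count_reads_in_bins(pos, g)
  # bin start included, bin end belongs to the next bin
  expect_equal(bc$count, c(2, 1, 2))
  expect_equal(attr(bc, "dropped"), 0L)
})

test_that("reads outside the grid are dropped and reported", {
  g <- bin_grid("chr1", 0, 100)
  pos <- data.frame(chrom = c("chr1", "chr1", "chrUn"), pos = c(50, 150, 10))
  expect_warning(bc <- count_reads_in_bins(pos, g), "dropped")
  expect_equal(bc$count, 1)
  expect_equal(attr(bc, "dropped"), 2L)
})

test_that("uniform positions distribute multinomially across bins", {
  g <- bin_grid(rep("chr1", 10), seq(0, 900, 100), seq(100, 1000, 100))
  set.seed(99)
  pos <- data.frame(chrom = "chr1", pos = floor(runif(10000, 0, 1000)))
  bc <- count_reads_in_bins(pos, g)
  expect_equal(sum(bc$count), 10000)
  sd_bin <- sqrt(10000 * 0.1 * 0.9)
  expect_true(all(abs(bc$count - 1000) < 4 * sd_bin))
})

test_that("normalization produces mean-1 ratios and floors zero bins", {
  g3 <- make_grid(3)
  bc <- normalize_counts(bin_counts(g3, c(2, 4, 6)))
  expect_equal(bc$ratio, c(0.5, 1, 1.5))
  expect_equal(mean(bc$ratio), 1, tolerance = 1e-12)
  u <- normalize_counts(bin_counts(g3, c(5, 5, 5)))
  expect_equal(u$ratio, rep(1, 3))
  expect_equal(u$log2ratio, rep(0, 3))
  z <- normalize_counts(bin_counts(g3, c(0, 3, 3)))
  expect_equal(mean(z$ratio), 1, tolerance = 1e-12)
  expect_true(z$low_count[1])
  expect_equal(z$log2ratio[1], log2(1 / (2 * 2)))
  expect_error(normalize_counts(bin_counts(g3, c(0, 0, 0))), "zero")
})

test_that("constant profiles return a single segment", {
  bc <- normalize_counts(bin_counts(make_grid(200), rep(80, 200)))
  prof <- cbs_segment(bc, seed = 1)
  expect_equal(n_segments(prof), 1)
  expect_equal(prof$segments$n_bins, 200)
})

test_that("a planted step is localized like the exhaustive RSS oracle", {
  n <- 400
  for (seed in 1:5) {
    set.seed(seed)
    x <- c(rep(1, 250), rep(1.6, 150)) + rnorm(n, 0, 0.1)
    bc <- bin_counts(make_grid(n), round(pmax(x, 0.01) * 1000))
    bc <- normalize_counts(bc)
    prof <- cbs_segment(bc, seed = seed)
    expect_equal(n_segments(prof), 2)
    # oracle: exhaustive single-changepoint residual-sum-of-squares scan
    r <- bc$ratio
    rss <- vapply(1:(n - 1), function(k)
      sum((r[1:k] - mean(r[1:k]))^2) +
        sum((r[(k + 1):n] - mean(r[(k + 1):n]))^2), numeric(1))
    k_oracle <- which.min(rss)
    expect_lte(abs(prof$segments$end_bin[1] - k_oracle), 1)
  }
})

test_that("segment count is monotone in alpha", {
  set.seed(7)
  x <- c(rep(1, 200), rep(1.5, 200)) + rnorm(400, 0, 0.1)
  bc <- normalize_counts(bin_counts(make_grid(400),
                                    round(pmax(x, 0.01) * 1000)))
  n_strict <- n_segments(cbs_segment(bc, cbs_params(alpha = 1e-12),
                                     seed = 1))
  n_loose <- n_segments(cbs_segment(bc, cbs_params(alpha = 0.01),
                                    seed = 1))
  expect_lte(n_strict, n_loose)
})

test_that("segmentation partitions the bins and reconstructs segment means", {
  set.seed(12)
  x <- c(rep(1, 120), rep(1.7, 80), rep(0.6, 100)) + rnorm(300, 0, 0.1)
  bc <- normalize_counts(bin_counts(make_grid(300),
                                    round(pmax(x, 0.01) * 1000)))
  prof <- cbs_segment(bc, seed = 3)
  segs <- prof$segments
  expect_equal(sum(segs$n_bins), 300)
  expect_equal(segs$start_bin[1], 1)
  expect_equal(segs$end_bin[nrow(segs)], 300)
  if (nrow(segs) > 1)
    expect_true(all(segs$start_bin[-1] == head(segs$end_bin, -1) + 1))
  for (k in seq_len(nrow(segs))) {
    idx <- segs$start_bin[k]:segs$end_bin[k]
    expect_equal(unique(prof$segvalue[idx]), segs$mean_ratio[k])
    expect_equal(segs$mean_ratio[k], mean(bc$ratio[idx]))
  }
})

test_that("merge_levels joins equal-level neighbours and stops", {
  # two adjacent segments with identical bin values must merge
  bc <- normalize_counts(bin_counts(make_grid(100), rep(50, 100)))
  prof <- make_profile(c(1, 1), c(50, 50), bin_bp = 220000)
  merged <- merge_levels(prof, bc)
  expect_equal(n_segments(merged), 1)
  # strongly separated segments must not merge
  set.seed(5)
  x <- c(rnorm(50, 0.5, 0.05), rnorm(50, 1.5, 0.05))
  bc2 <- bin_counts(make_grid(100), round(x * 1000))
  bc2 <- normalize_counts(bc2)
  prof2 <- plasmaTrace:::.profile_from_ends(bc2, bc2$ratio,
                                            list(chr1 = c(50L, 100L)))
  merged2 <- merge_levels(prof2, bc2)
  expect_equal(n_segments(merged2), 2)
})

test_that("merge decisions equal the direct rank-sum computation", {
  for (seed in 1:6) {
    set.seed(seed)
    delta <- runif(1, 0, 0.05)
    x <- c(rnorm(40, 1, 0.05), rnorm(40, 1 + delta, 0.05))
    bc <- normalize_counts(bin_counts(make_grid(80), round(x * 1e4)))
    prof <- plasmaTrace:::.profile_from_ends(bc, bc$ratio,
                                             list(chr1 = c(40L, 80L)))
    merged <- merge_levels(prof, bc, merge_p_threshold = 0.05)
    p_oracle <- suppressWarnings(
      wilcox.test(bc$ratio[1:40], bc$ratio[41:80], exact = FALSE)$p.value)
    expect_equal(n_segments(merged) == 1, p_oracle >= 0.05)
  }
})

test_that("merge_levels is idempotent and never increases segment count", {
  set.seed(21)
  x <- c(rep(1, 60), rep(1.03, 60), rep(1.5, 60)) + rnorm(180, 0, 0.08)
  bc <- normalize_counts(bin_counts(make_grid(180),
                                    round(pmax(x, 0.01) * 1000)))
  prof <- cbs_segment(bc, cbs_params(alpha = 0.01), seed = 2)
  m1 <- merge_levels(prof, bc)
  expect_lte(n_segments(m1), n_segments(prof))
  m2 <- merge_levels(m1, bc)
  expect_equal(m1$segments, m2$segments)
})

test_that("exome depth ratios are centered library-size ratios", {
  d <- rep(100, 50)
  r0 <- exome_cn_ratio(d, d)
  expect_equal(r0$log2ratio, rep(0, 50))
  # doubling a minority block gives log2 ratio 1 after centering
  t2 <- d; t2[11:20] <- 200
  r2 <- exome_cn_ratio(t2, d)
  expect_equal(r2$log2ratio[11:20], rep(1, 10), tolerance = 1e-9)
  expect_equal(r2$log2ratio[1], 0, tolerance = 1e-9)
  # single target centers to zero
  expect_equal(exome_cn_ratio(37, 12)$log2ratio, 0)
  # zero-normal targets are excluded and reported
  rz <- exome_cn_ratio(c(10, 10, 10), c(10, 0, 10))
  expect_equal(attr(rz, "excluded"), 2L)
  expect_equal(nrow(rz), 2)
})
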