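test_that("the neutral level is the median segmentation value", {
  expect_equal(neutral_level(make_profile(1, 10)), 1)
  # 60% of bins at 1.0, 40% at 1.5 -> median 1.0
  expect_equal(neutral_level(make_profile(c(1, 1.5), c(60, 40))), 1)
  # even split: midpoint convention
  expect_equal(neutral_level(make_profile(c(0.8, 1.2), c(50, 50))), 1)
})

test_that("CNA calls are maximal altered runs with bp lengths", {
  expect_equal(nrow(call_cnas(make_profile(1, 50))), 0)
  # bins 10-19 of a 220 kb grid at ratio 1.5: one amplification of 2.2 Mb
  prof <- make_profile(c(1, 1.5, 1), c(9, 10, 31), bin_bp = 220000)
  calls <- call_cnas(prof)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$direction, "amplification")
  expect_equal(calls$length_bp, 10 * 220000)
  expect_equal(calls$start_bp, 9 * 220000)
  # two non-adjacent altered runs give two calls
  prof2 <- make_profile(c(1, 0.6, 1, 1.4, 1), c(10, 5, 10, 5, 10))
  calls2 <- call_cnas(prof2)
  expect_equal(nrow(calls2), 2)
  expect_equal(calls2$direction, c("deletion", "amplification"))
})

test_that("CNA calls cover exactly the deviating bins, disjointly", {
  set.seed(31)
  means <- round(sample(c(1, 1, 1, 0.7, 1.3, 1.6), 12, replace = TRUE), 3)
  nb <- sample(3:8, 12, replace = TRUE)
  prof <- make_profile(means, nb)
  neutral <- neutral_level(prof)
  calls <- call_cnas(prof, neutral)
  covered <- rep(FALSE, nrow(prof$grid))
  for (k in seq_len(nrow(calls))) {
    idx <- which(prof$grid$start >= calls$start_bp[k] &
                   prof$grid$end <= calls$end_bp[k])
    expect_false(any(covered[idx]))   # disjoint
    covered[idx] <- TRUE
  }
  expect_equal(covered, abs(prof$segvalue - neutral) > 1e-9)
})

test_that("CNA burden counts calls above the deviation baseline", {
  prof <- make_profile(c(1, 1.02, 1, 1.05, 1, 1.4), c(30, 4, 10, 4, 10, 4))
  calls <- call_cnas(prof)
  expect_equal(cna_burden(calls, baseline = 0), nrow(calls))
  expect_equal(cna_burden(calls, baseline = 0.03), 2)
  expect_equal(cna_burden(calls[0, ], 0.03), 0L)
})

test_that("ploidy classification follows the segment-count rules", {
  # flat single segment -> diploid
  p1 <- classify_ploidy(make_profile(1, 100))
  expect_equal(p1$label, "diploid")
  expect_equal(p1$supporting_rule, "diploid_default")
  # > 45 segments with > 0.03 deviation -> aneuploid outright
  means <- rep(c(1, 1.05), 25); means[2] <- 1  # keep median at 1
  nb <- rep(c(10, 3), 25)
  p2 <- classify_ploidy(make_profile(means, nb))
  expect_equal(p2$label, "aneuploid")
  expect_equal(p2$supporting_rule, "high_seg_count")
  # intermediate count with a large deviating segment -> aneuploid
  means3 <- c(rep(1, 10), 1.05, rep(1, 19))
  nb3 <- c(rep(5, 10), 20, rep(5, 19))   # 20 x 1 Mb = 20 Mb deviating
  p3 <- classify_ploidy(make_profile(means3, nb3))
  expect_equal(p3$label, "aneuploid")
  expect_equal(p3$supporting_rule, "intermediate_with_support")
  # intermediate count, deviation below the gate -> diploid
  means4 <- c(rep(1, 15), 1.01, rep(1, 14))
  p4 <- classify_ploidy(make_profile(means4, rep(5, 30)))
  expect_equal(p4$label, "diploid")
})

test_that("gene annotation respects half-open intersection", {
  prof <- make_profile(c(1, 1.5, 1), c(10, 10, 10), bin_bp = 1e6)
  calls <- call_cnas(prof)   # one amplification on [1e7, 2e7)
  genes <- data.frame(
    chrom = "chr1",
    start = c(1.2e7, 2e7, 0.95e7, 5e6),
    end = c(1.3e7, 2.1e7, 1.05e7, 6e6),
    name = c("INSIDE", "ABUTTING", "SPANNING", "OUTSIDE"))
  ann <- annotate_genes(calls, genes)
  expect_setequal(ann$genes[[1]], c("INSIDE", "SPANNING"))
})

test_that("gene annotation matches a brute-force all-pairs oracle", {
  set.seed(17)
  prof <- make_profile(rep(c(1, 1.4), 10), sample(2:6, 20, replace = TRUE))
  calls <- call_cnas(prof)
  genes <- data.frame(chrom = "chr1",
                      start = floor(runif(100, 0, 8e7)))
  genes$end <- genes$start + floor(runif(100, 1e4, 5e6))
  genes$name <- paste0("g", seq_len(100))
  ann <- annotate_genes(calls, genes)
  for (k in seq_len(nrow(calls))) {
    oracle <- genes$name[genes$start < calls$end_bp[k] &
                           calls$start_bp[k] < genes$end]
    expect_setequal(ann$genes[[k]], oracle)
  }
})

test_that("profile correlation matches the textbook formula", {
  a <- make_profile(c(1, 1.4, 0.8), c(10, 10, 10))
  expect_equal(plasma_tissue_correlation(a, a), 1)
  b <- a
  b$segvalue <- 2 - a$segvalue
  b$segments$mean_ratio <- 2 - a$segments$mean_ratio
  expect_equal(plasma_tissue_correlation(a, b), -1)
  set.seed(13)
  c2 <- make_profile(runif(3, 0.5, 1.5), c(10, 10, 10))
  r <- plasma_tissue_correlation(a, c2)
  x <- a$segvalue; y <- c2$segvalue
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r, r_oracle)
  # zero variance -> NA with warning
  flat <- make_profile(1, 30)
  expect_warning(rna <- plasma_tissue_correlation(a, flat), "variance")
  expect_true(is.na(rna))
  # grid mismatch -> error
  expect_error(plasma_tissue_correlation(a, make_profile(1, 10)), "grid")
})

test_that("mutation concordance is the shared fraction of the union", {
  expect_equal(mutation_concordance(c("a", "b"), c("a", "b")), 100)
  expect_equal(mutation_concordance(c("a", "b"), c("c", "d")), 0)
  expect_equal(mutation_concordance(c("a", "b", "c"), c("b", "c", "d")), 50)
  expect_true(is.na(mutation_concordance(character(0), character(0))))
  # symmetric, bounded, and data-frame keyed
  set.seed(3)
  A <- data.frame(chrom = "chr1", pos = sample(100, 20), ref = "A",
                  alt = "T")
  B <- data.frame(chrom = "chr1", pos = sample(100, 20), ref = "A",
                  alt = "T")
  ab <- mutation_concordance(A, B)
  expect_equal(ab, mutation_concordance(B, A))
  expect_gte(ab, 0); expect_lte(ab, 100)
})
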