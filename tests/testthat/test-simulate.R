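test_that("clone trees obey the sum and perfect-phylogeny invariants", {
  for (seed in 1:8) {
    K <- 2 + (seed %% 5)
    tr <- simulate_clone_tree(K, 3, "stable_dominant", seed = seed)
    phi <- tr$prevalence
    expect_true(all(phi[1, ] <= 1))
    parents <- match(tr$clones$parent_id, tr$clones$clone_id)
    for (i in seq_len(K)) {
      ch <- which(parents == i)
      if (length(ch))
        expect_true(all(phi[i, ] >= colSums(phi[ch, , drop = FALSE]) - 1e-9))
    }
    # perfect phylogeny: child payload contains every ancestral mutation
    for (i in seq_len(K)) {
      p <- parents[i]
      if (is.na(p)) next
      child <- with(tr$snv_payload[[i]], paste(chrom, pos))
      parent <- with(tr$snv_payload[[p]], paste(chrom, pos))
      expect_true(all(parent %in% child))
    }
  }
})

test_that("a single-clone tree is degenerate at frequency 1", {
  tr <- simulate_clone_tree(1, 2, "stable_dominant", seed = 7)
  expect_equal(unname(tr$prevalence[1, ]), c(1, 1))
  expect_equal(tr$clones$parent_id, "root")
})

test_that("expanding_minor plants a minor clone that expands", {
  tr <- simulate_clone_tree(3, 4, "expanding_minor", seed = 1)
  phi <- tr$prevalence
  grew <- phi[, 4] > phi[, 1] & phi[, 1] >= 0.01 & phi[, 1] <= 0.21
  expect_true(any(grew[-1]))
})

test_that("stable_dominant keeps the largest clone within a 0.05 band", {
  for (seed in 1:5) {
    tr <- simulate_clone_tree(4, 4, "stable_dominant", seed = seed)
    top <- which.max(rowMeans(tr$prevalence))
    expect_lt(diff(range(tr$prevalence[top, ])), 0.05)
  }
})

test_that("simulators are deterministic given the seed", {
  a <- simulate_clone_tree(4, 3, "expanding_minor", seed = 11)
  b <- simulate_clone_tree(4, 3, "expanding_minor", seed = 11)
  expect_identical(a, b)
  expect_identical(simulate_cohort_clinical(50, 2, seed = 3),
                   simulate_cohort_clinical(50, 2, seed = 3))
  expect_identical(simulate_fragment_sizes(0.3, 1000, seed = 4),
                   simulate_fragment_sizes(0.3, 1000, seed = 4))
  g <- make_grid(50)
  tr <- simulate_clone_tree(2, 2, "stable_dominant", seed = 2)
  expect_identical(simulate_bin_counts(tr, 0.5, g, 50, seed = 9),
                   simulate_bin_counts(tr, 0.5, g, 50, seed = 9))
})

test_that("argument validation rejects degenerate simulator inputs", {
  expect_error(simulate_clone_tree(0, 3, seed = 1), "invalid")
  expect_error(simulate_clone_tree(3, 1, seed = 1), "invalid")
  expect_error(simulate_fragment_sizes(0.5, 0, seed = 1), "invalid")
  tr <- simulate_clone_tree(2, 2, "stable_dominant", seed = 1)
  expect_error(simulate_bin_counts(tr, 0.5, make_grid(10), -5), "invalid")
  expect_error(simulate_variants(tr, 0.5, 0, 10), "invalid")
})

test_that("bin-count mixture arithmetic matches its closed form", {
  grid <- make_grid(30)
  # single clone at frequency 1 carrying CN 4 over bins 10-19
  payload <- data.frame(chrom = "chr1", start = grid$start[10],
                        end = grid$end[19], cn = 4L)
  tr <- make_truth(matrix(1, 1, 2), parents = 0,
                   cna_payload = list(C1 = payload))
  # purity 0: all-normal, expected ratio 1 everywhere
  bc0 <- simulate_bin_counts(tr, 0, grid, 100, seed = 1)
  expect_equal(bc0$truth_ratio, rep(1, 30))
  # purity 1: ratio = CN/2 = 2 on the altered bins
  bc1 <- simulate_bin_counts(tr, 1, grid, 100, seed = 1)
  expect_equal(bc1$truth_ratio[10:19], rep(2, 10))
  expect_equal(bc1$truth_ratio[c(1:9, 20:30)], rep(1, 20))
  # purity 0.4: 0.4*2 + 0.6*1 = 1.4; empirical mean within 3 SE
  big <- make_grid(10000)
  payload_all <- data.frame(chrom = "chr1", start = 0,
                            end = max(big$end), cn = 4L)
  tr2 <- make_truth(matrix(1, 1, 2), parents = 0,
                    cna_payload = list(C1 = payload_all))
  bc <- simulate_bin_counts(tr2, 0.4, big, 100, overdispersion = 0.05,
                            seed = 42)
  expect_equal(unique(bc$truth_ratio), 1.4)
  mu <- 100 * 1.4
  se <- sqrt(mu + 0.05 * mu^2) / sqrt(10000)
  expect_lt(abs(mean(bc$count) - mu), 3 * se)
})

test_that("variant VAFs follow the purity/prevalence formula", {
  tr <- make_truth(matrix(1, 1, 2), parents = 0)
  v1 <- simulate_variants(tr, 1, 100, 100, seed = 1)
  expect_equal(v1$true_vaf_T1, 0.5)  # clonal heterozygote
  v2 <- simulate_variants(tr, 0.5, 10000, 100, seed = 2)
  expect_equal(v2$true_vaf_T1, 0.25)
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_lt(abs(v2$alt_T1 / v2$dep_T1 - 0.25), 3 * se)
  v0 <- simulate_variants(tr, 0, 100, 100, seed = 3)
  expect_equal(v0$true_vaf_T1, 0)
  expect_equal(v0$alt_T1, 0L)
})

test_that("fragment-size components are calibrated to the 142/154 bp means", {
  n <- 1e5
  fn <- simulate_fragment_sizes(0, n, seed = 1, harmonic_weights = c(0, 0))
  expect_lt(abs(mean(fn$sizes) - 154), 3 * 20 / sqrt(n))
  ft <- simulate_fragment_sizes(1, n, seed = 2, harmonic_weights = c(0, 0))
  expect_lt(abs(mean(ft$sizes) - 142), 3 * 20 / sqrt(n))
  expect_true(all(fn$sizes > 0))
  expect_gt(fn$total_mass_ng, 0)
})

test_that("clinical cohorts carry the planted ploidy hazard structure", {
  cl <- simulate_cohort_clinical(300, ploidy_effect = 3, seed = 5)
  expect_true(all(cl$months > 0))
  expect_true(all(cl$event %in% 0:1))
  expect_setequal(unique(cl$ploidy), c("diploid", "aneuploid"))
  # higher hazard => shorter observed survival for aneuploid patients
  expect_lt(median(cl$months[cl$ploidy == "aneuploid"]),
            median(cl$months[cl$ploidy == "diploid"]))
  expect_gt(median(cl$cfdna_ng[cl$ploidy == "aneuploid"]),
            median(cl$cfdna_ng[cl$ploidy == "diploid"]))
})

test_that("simulated segment profiles realize their planted ploidy label", {
  pa <- simulate_segment_profile("aneuploid", seed = 1)
  pd <- simulate_segment_profile("diploid", seed = 2)
  expect_gt(n_segments(pa), 45)
  expect_gt(max(abs(pa$segments$mean_ratio - median(pa$segvalue))), 0.03)
  expect_lt(max(abs(pd$segments$mean_ratio - median(pd$segvalue))), 0.03)
})
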