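test_that("cellular prevalence follows the normalization formula", {
  expect_equal(cellular_prevalence(0.5, 1, 2, 1), 1, ignore_attr = TRUE)
  expect_equal(cellular_prevalence(0.25, 1, 2, 1), 0.5, ignore_attr = TRUE)
  expect_equal(cellular_prevalence(0.1, 0.5, 2, 1), 0.4, ignore_attr = TRUE)
  expect_warning(cp <- cellular_prevalence(0.9, 0.5, 2, 1), "clipped")
  expect_equal(cp, 1, ignore_attr = TRUE)
  expect_error(cellular_prevalence(0.1, 0, 2, 1), "purity 0")
  # linear in VAF before clipping
  v <- seq(0.01, 0.2, by = 0.01)
  cp <- cellular_prevalence(v, 0.5, 2, 1)
  expect_equal(as.numeric(cp), v * 4, ignore_attr = TRUE)
})

test_that("the crude purity estimator inverts clonal VAFs", {
  expect_equal(as.numeric(estimate_purity_simple(rep(0.25, 10))), 0.5)
  expect_equal(as.numeric(estimate_purity_simple(rep(0.5, 10))), 1)
  low <- estimate_purity_simple(rep(0.005, 10))
  expect_false(attr(low, "usable"))
  expect_error(estimate_purity_simple(rep(0.2, 6), cn = rep(3, 6)),
               "no CN-2")
})

test_that("clustering collapses a single shared trajectory to K = 1", {
  set.seed(2)
  phi <- c(0.8, 0.5, 0.3)
  conv <- 0.5   # purity 1, CN 2
  alt <- t(replicate(30, rbinom(3, 500, conv * phi)))
  depth <- matrix(500, 30, 3)
  cl <- cluster_mutations(alt, depth, purity = 1, k_max = 4, seed = 5)
  expect_equal(cl$K, 1)
  expect_equal(as.numeric(cl$centers), phi, tolerance = 0.05)
  expect_equal(min(cl$bic, na.rm = TRUE), cl$bic[cl$K])
})

test_that("well-separated trajectories are recovered with high accuracy", {
  phi <- rbind(c(0.9, 0.9, 0.9), c(0.6, 0.35, 0.15), c(0.1, 0.35, 0.65))
  correct <- 0
  for (seed in 1:6) {
    set.seed(100 + seed)
    lab <- rep(1:3, each = 20)
    alt <- t(vapply(lab, function(k) rbinom(3, 500, 0.5 * phi[k, ]),
                    numeric(3)))
    depth <- matrix(500, 60, 3)
    cl <- cluster_mutations(alt, depth, purity = 1, k_max = 5,
                            seed = seed)
    if (cl$K == 3) {
      perm <- match_clones(phi, cl$centers)
      acc <- mean(perm[lab] == cl$assignment)
      if (acc >= 0.95) correct <- correct + 1
    }
  }
  expect_gte(correct, 5)
})

test_that("tree inference recovers a constraint-binding chain exactly", {
  m <- infer_tree(matrix(1, 1, 2))
  expect_equal(m$K, 1)
  expect_equal(m$fit_error, 0, tolerance = 1e-9)
  centers <- matrix(c(0.9, 0.6, 0.5), 3, 2)   # chain: star infeasible
  fit <- infer_tree(centers)
  expect_equal(fit$parents, c(0L, 1L, 2L))
  expect_lt(fit$fit_error, 1e-6)
  expect_equal(unname(fit$prevalence), unname(centers), tolerance = 1e-4)
})

test_that("a larger clone is absorbed as the ancestor when feasible", {
  # (0.5, 0.6) fits exactly with clone 2 ancestral to clone 1
  fit <- infer_tree(matrix(c(0.5, 0.6), 2, 1))
  expect_equal(fit$parents, c(2L, 0L))
  expect_equal(fit$fit_error, 0, tolerance = 1e-9)
})

test_that("infeasible centers are projected onto the constraint set", {
  # crossing, over-committed trajectories: no 2-clone topology can fit
  # exactly.  Oracle: grid projection over every topology's feasible set
  # (f >= 0, sum <= 1), minimizing the squared center misfit.
  centers <- rbind(c(0.7, 0.3), c(0.5, 0.9))
  fs <- seq(0, 1, by = 0.002)
  grid <- expand.grid(f1 = fs, f2 = fs)
  grid <- grid[grid$f1 + grid$f2 <= 1, ]
  proj_err <- function(B) {
    phi1 <- B[1, 1] * grid$f1 + B[1, 2] * grid$f2
    phi2 <- B[2, 1] * grid$f1 + B[2, 2] * grid$f2
    sum(vapply(1:2, function(t)
      min((phi1 - centers[1, t])^2 + (phi2 - centers[2, t])^2),
      numeric(1)))
  }
  topologies <- list(diag(2),                      # siblings
                     rbind(c(1, 1), c(0, 1)),      # 1 ancestral to 2
                     rbind(c(1, 0), c(1, 1)))      # 2 ancestral to 1
  oracle <- min(vapply(topologies, proj_err, numeric(1)))
  fit <- infer_tree(centers)
  expect_gt(fit$fit_error, 0)
  expect_equal(fit$fit_error, oracle, tolerance = 1e-4)
  # the returned model is feasible for its own topology
  for (t in 1:2) {
    expect_lte(sum(fit$clone_freq[, t]), 1 + 1e-9)
    for (i in 1:2) {
      ch <- which(fit$parents == i)
      if (length(ch))
        expect_lte(sum(fit$prevalence[ch, t]),
                   fit$prevalence[i, t] + 1e-6)
    }
  }
})

test_that("every fitted model satisfies the frequency-sum constraint", {
  set.seed(44)
  for (rep in 1:10) {
    K <- sample(2:4, 1)
    centers <- matrix(runif(K * 3, 0, 1), K, 3)
    fit <- infer_tree(centers)
    for (i in seq_len(K)) {
      ch <- which(fit$parents == i)
      if (length(ch))
        expect_true(all(fit$prevalence[i, ] >=
                          colSums(fit$prevalence[ch, , drop = FALSE]) - 1e-6))
    }
    expect_true(all(colSums(fit$clone_freq) <= 1 + 1e-6))
    expect_true(all(fit$clone_freq >= -1e-9))
  }
})

test_that("tree sizes beyond the enumeration bound are refused", {
  expect_error(infer_tree(matrix(0.1, 7, 2)), "unsupported")
})

test_that("clone frequencies are prevalences minus children", {
  centers <- matrix(c(0.9, 0.5), 2, 1)
  fit <- infer_tree(centers)
  # chain is forced here: 0.5+0.9 > 1 rules out two top-level clones
  expect_equal(fit$parents, c(0L, 1L))
  expect_equal(as.numeric(clone_frequencies(fit)), c(0.4, 0.5),
               tolerance = 1e-4)
  star <- infer_tree(matrix(c(0.9, 0.3, 0.3), 3, 1))
  expect_equal(sort(as.numeric(clone_frequencies(star))),
               c(0.3, 0.3, 0.3), tolerance = 1e-4)
})

test_that("expanding minor clones are flagged; stable ones are not", {
  freq <- rbind(c(0.07, 0.10, 0.75), c(0.80, 0.75, 0.15))
  model <- structure(list(K = 2, parents = c(0L, 0L),
                          prevalence = freq, clone_freq = freq,
                          fit_error = 0, centers = freq),
                     class = "clone_model")
  calls <- detect_expanding_clones(model)
  expect_true(calls$flagged[1])
  expect_false(calls$flagged[2])
  # raising expansion_min never adds flags
  stricter <- detect_expanding_clones(model, expansion_min = 0.8)
  expect_true(all(stricter$flagged <= calls$flagged))
  # significant mutations of flagged clones are attached
  muts <- data.frame(gene = c("CAPN2", "MRPL47", "OTHER"),
                     clone = c(1, 1, 2),
                     significant = c(TRUE, TRUE, TRUE))
  calls2 <- detect_expanding_clones(model, mutations = muts)
  expect_equal(attr(calls2, "significant_mutations")$gene,
               c("CAPN2", "MRPL47"))
})
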