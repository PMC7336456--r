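# Purity/copy-number-normalized cellular prevalence, multi-timepoint
# mutation clustering, clone-tree inference under frequency-sum
# constraints, and expanding-clone detection.

#' Cellular prevalence of a mutation
#'
#' Normalizes a variant allele frequency for tumor purity and local copy
#' number: `CP = vaf * (purity * cn_total + (1 - purity) * 2) /
#' (purity * multiplicity)`, clipped to \[0, 1\].  The result is the
#' fraction of tumor cells carrying the mutation, invariant to
#' sequencing depth given the VAF and linear in the VAF before clipping.
#' Clipping events are reported with a warning and in the `clipped`
#' attribute.
#'
#' @param vaf Variant allele frequency (vectorized).
#' @param purity Tumor purity in (0, 1\]; prevalence is undefined at
#'   purity 0.
#' @param cn_total Total tumor copy number at the site (>= 1).
#' @param multiplicity Mutation copies per tumor cell (1..cn_total).
#' @return Cellular prevalence in \[0, 1\].
#' @export
cellular_prevalence <- function(vaf, purity, cn_total = 2L,
                                multiplicity = 1L) {
  if (any(purity <= 0))
    stop("invalid argument: prevalence undefined at purity 0", call. = FALSE)
  .assert(all(purity <= 1), "purity must be in (0,1]")
  .assert(all(cn_total >= 1), "cn_total must be >= 1")
  .assert(all(multiplicity >= 1 & multiplicity <= cn_total),
          "multiplicity must be in [1, cn_total]")
  cp <- vaf * (purity * cn_total + (1 - purity) * 2) /
    (purity * multiplicity)
  clipped <- cp < 0 | cp > 1
  if (any(clipped))
    warning(sprintf("%d prevalence value(s) clipped to [0,1]", sum(clipped)))
  out <- pmin(pmax(cp, 0), 1)
  attr(out, "clipped") <- clipped
  out
}

#' Crude purity estimate from copy-neutral VAFs
#'
#' When no external purity estimate is supplied, purity can be
#' approximated as twice an upper quantile of the VAFs at copy-number-2
#' sites (inverting the prevalence formula at full prevalence,
#' multiplicity 1), capped at 1.  Estimates below `floor` are flagged as
#' unusable.
#'
#' @param vafs Variant allele frequencies.
#' @param cn Total copy number per site (only CN-2 sites are used).
#' @param quantile_used Upper quantile (default 0.9).
#' @param floor Usability floor (default 0.05).
#' @return Purity estimate with attribute `usable`.
#' @export
estimate_purity_simple <- function(vafs, cn = rep(2L, length(vafs)),
                                   quantile_used = 0.9, floor = 0.05) {
  .assert(length(vafs) >= 5, "need at least 5 mutations")
  cn2 <- which(cn == 2)
  if (!length(cn2))
    stop("estimation unavailable: no CN-2 sites", call. = FALSE)
  est <- min(1, 2 * quantile(vafs[cn2], quantile_used, names = FALSE))
  attr(est, "usable") <- est >= floor
  est
}

# expected VAF for prevalence phi given the per-cell conversion factors
.cp_to_vaf <- function(phi, conv) pmin(pmax(conv * phi, 1e-9), 1 - 1e-9)

# one EM run for fixed K; alt/depth/conv are N x T matrices
.em_binom <- function(alt, depth, conv, K, init_centers, max_iter = 200,
                      tol = 1e-8) {
  N <- nrow(alt); T_ <- ncol(alt)
  phi <- init_centers                       # K x T
  pi_k <- rep(1 / K, K)
  ll_old <- -Inf
  resp <- matrix(1 / K, N, K)
  for (iter in seq_len(max_iter)) {
    # E-step: binomial log-likelihood per mutation and cluster
    logl <- matrix(0, N, K)
    for (k in seq_len(K)) {
      p <- .cp_to_vaf(matrix(phi[k, ], N, T_, byrow = TRUE), conv)
      logl[, k] <- rowSums(dbinom(alt, depth, p, log = TRUE)) + log(pi_k[k])
    }
    m <- apply(logl, 1, max)
    w <- exp(logl - m)
    ll <- sum(m + log(rowSums(w)))
    resp <- w / rowSums(w)
    # M-step: weighted binomial MLE (exact when conv is shared across
    # mutations, quasi-likelihood moment update otherwise)
    pi_k <- pmax(colMeans(resp), 1e-12)
    for (k in seq_len(K)) {
      num <- colSums(resp[, k] * alt)
      den <- colSums(resp[, k] * depth * conv)
      phi[k, ] <- pmin(pmax(num / pmax(den, 1e-12), 0), 1)
    }
    if (abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  assign <- max.col(resp)
  list(phi = phi, pi = pi_k, loglik = ll, assignment = assign, resp = resp)
}

#' Cluster mutations on their prevalence trajectories
#'
#' Finite binomial mixture over per-timepoint cellular prevalences: each
#' cluster has a prevalence per timepoint, each mutation's alt counts
#' are binomial at the cluster prevalence mapped back to VAF space
#' through purity and local copy number (so low-depth sites carry less
#' weight).  The number of clusters is chosen by BIC over `1..k_max`,
#' with seeded multi-restart initialization (k-means on the observed
#' prevalence matrix plus random restarts).
#'
#' @param alt,depth Mutation x timepoint matrices of alt and total read
#'   counts.
#' @param purity Purity per timepoint (recycled if scalar).
#' @param cn_total Total tumor copy number per mutation (default 2).
#' @param multiplicity Mutation multiplicity per mutation (default 1).
#' @param k_max Largest cluster number considered (default 8).
#' @param n_restarts EM restarts per K (default 20).
#' @param seed Integer seed.
#' @return List of class `mutation_clusters`: `K`, `centers`
#'   (K x timepoints prevalences), `assignment`, `bic` (per candidate K),
#'   `loglik`, `cp` (observed prevalence matrix).
#' @export
cluster_mutations <- function(alt, depth, purity, cn_total = 2L,
                              multiplicity = 1L, k_max = 8L,
                              n_restarts = 20L, seed = NULL) {
  alt <- as.matrix(alt); depth <- as.matrix(depth)
  N <- nrow(alt); T_ <- ncol(alt)
  .assert(N >= 1, "need at least one mutation")
  .assert(T_ >= 1, "need at least one timepoint")
  .assert(k_max >= 1 && k_max <= 8, "k_max must be in 1..8")
  purity <- rep_len(purity, T_)
  .assert(all(purity > 0 & purity <= 1), "purity must be in (0,1]")
  cn_total <- rep_len(cn_total, N)
  multiplicity <- rep_len(multiplicity, N)
  conv <- outer(seq_len(N), seq_len(T_), function(i, t)
    purity[t] * multiplicity[i] / (purity[t] * cn_total[i] +
                                     (1 - purity[t]) * 2))
  cp_obs <- pmin(pmax((alt / pmax(depth, 1)) / conv, 0), 1)

  .with_seed(seed, {
    fits <- vector("list", k_max)
    bic <- rep(NA_real_, k_max)
    for (K in seq_len(min(k_max, N))) {
      best <- NULL
      for (r in seq_len(n_restarts)) {
        init <- if (r == 1 && K > 1 && N > K) {
          tryCatch(suppressWarnings(kmeans(cp_obs, K, nstart = 1))$centers,
                   error = function(e)
                     cp_obs[sample(N, K), , drop = FALSE])
        } else {
          cp_obs[sample(N, K, replace = N < K), , drop = FALSE]
        }
        init <- matrix(pmin(pmax(init, 0.01), 0.99), K, T_)
        fit <- .em_binom(alt, depth, conv, K, init)
        if (is.null(best) || fit$loglik > best$loglik) best <- fit
      }
      fits[[K]] <- best
      n_par <- K * T_ + (K - 1)
      bic[K] <- -2 * best$loglik + n_par * log(N)
    }
    K_star <- which.min(bic)
    best <- fits[[K_star]]
    centers <- best$phi
    rownames(centers) <- paste0("clone", seq_len(K_star))
    structure(list(K = K_star, centers = centers,
                   assignment = best$assignment, bic = bic,
                   loglik = best$loglik, cp = cp_obs),
              class = "mutation_clusters")
  })
}

# all parent vectors (0 = root) of rooted labelled forests on K nodes
.enumerate_parent_vectors <- function(K) {
  if (K == 1) return(list(0L))
  choices <- lapply(seq_len(K), function(i) 0:K)
  grids <- as.matrix(do.call(expand.grid, choices))
  out <- list()
  for (r in seq_len(nrow(grids))) {
    p <- as.integer(grids[r, ])
    if (any(p == seq_len(K))) next
    # acyclic iff every node reaches the root
    ok <- TRUE
    for (i in seq_len(K)) {
      j <- i; steps <- 0L
      while (j != 0L) {
        j <- p[j]; steps <- steps + 1L
        if (steps > K) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) out[[length(out) + 1L]] <- p
  }
  out
}

# Lawson-Hanson active-set non-negative least squares; the design
# matrices here are tiny (<= 7 full-rank columns), so the plain normal
# equations are safe
.nnls <- function(A, b, tol = 1e-10) {
  n <- ncol(A)
  passive <- logical(n)
  x <- numeric(n)
  w <- as.numeric(crossprod(A, b))
  for (outer in seq_len(10 * n + 20)) {
    cand <- which(!passive & w > tol)
    if (!length(cand)) break
    passive[cand[which.max(w[cand])]] <- TRUE
    repeat {
      Ap <- A[, passive, drop = FALSE]
      s <- numeric(n)
      s[passive] <- solve(crossprod(Ap), crossprod(Ap, b))
      if (all(s[passive] > tol)) { x <- s; break }
      viol <- passive & s <= tol
      alpha <- min(x[viol] / (x[viol] - s[viol]))
      x <- x + alpha * (s - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
    w <- as.numeric(crossprod(A, b - A %*% x))
  }
  x
}

.subtree_matrix <- function(parents) {
  K <- length(parents)
  B <- diag(K)
  for (j in seq_len(K)) {
    i <- parents[j]
    while (i != 0L) { B[i, j] <- 1; i <- parents[i] }
  }
  B
}

.node_depths <- function(parents) {
  vapply(seq_along(parents), function(i) {
    d <- 1L; j <- parents[i]
    while (j != 0L) { d <- d + 1L; j <- parents[j] }
    d
  }, integer(1))
}

#' Infer the clone tree from cluster prevalences
#'
#' Exhaustive enumeration of rooted trees on the clusters (with an
#' implicit root of prevalence at most 1).  For each candidate tree the
#' cluster prevalences are projected, per timepoint, onto the feasible
#' set where every parent's prevalence is at least the sum of its
#' children's: with clone frequencies `f >= 0` as variables the
#' prevalences are `B f` (B the subtree indicator), so the projection is
#' a non-negative least squares problem; the total-frequency <= 1
#' constraint is enforced through a heavily weighted slack row.  The
#' tree minimizing the squared projection error wins; ties are broken by
#' fewer total edges from the root (shallower trees), then by lexical
#' parent order.
#'
#' @param centers K x timepoints matrix of cluster prevalences (K <=
#'   `max_clones`).
#' @param max_clones Enumeration bound (default 6; above it the tree
#'   space is too large for exhaustive search and an unsupported-size
#'   error is raised).
#' @return List of class `clone_model`: `K`, `parents` (0 = root),
#'   `prevalence` (fitted K x T), `clone_freq` (own frequencies, K x T),
#'   `fit_error` (squared projection error on the data rows), `centers`.
#' @export
infer_tree <- function(centers, max_clones = 6L) {
  centers <- as.matrix(centers)
  K <- nrow(centers); T_ <- ncol(centers)
  if (K > max_clones)
    stop(sprintf("unsupported size: %d clones exceeds enumeration bound %d",
                 K, max_clones), call. = FALSE)
  .assert(all(centers >= 0 & centers <= 1 + 1e-9),
          "centers must be prevalences in [0,1]")
  trees <- .enumerate_parent_vectors(K)
  w_slack <- 1e4
  best <- NULL
  for (p in trees) {
    B <- .subtree_matrix(p)
    A <- rbind(cbind(B, 0), sqrt(w_slack) * rep(1, K + 1))
    f <- matrix(0, K, T_)
    err <- 0
    for (t in seq_len(T_)) {
      b <- c(centers[, t], sqrt(w_slack))
      ft <- .nnls(A, b)[seq_len(K)]
      tot <- sum(ft)
      if (tot > 1) ft <- ft / tot   # exact total-frequency bound
      f[, t] <- ft
      err <- err + sum((B %*% ft - centers[, t])^2)
    }
    depth_sum <- sum(.node_depths(p))
    key <- list(err = err, depth = depth_sum, p = p, f = f)
    tie_tol <- 1e-7 * (1 + if (is.null(best)) 0 else best$err)
    if (is.null(best) || err < best$err - tie_tol ||
        (abs(err - best$err) <= tie_tol &&
         (depth_sum < best$depth ||
          (depth_sum == best$depth &&
           paste(p, collapse = ",") < paste(best$p, collapse = ","))))) {
      best <- key
    }
  }
  prevalence <- .subtree_matrix(best$p) %*% best$f
  dimnames(prevalence) <- dimnames(centers)
  clone_freq <- best$f
  dimnames(clone_freq) <- dimnames(centers)
  structure(list(K = K, parents = best$p, prevalence = prevalence,
                 clone_freq = clone_freq, fit_error = best$err,
                 centers = centers),
            class = "clone_model")
}

#' Clone (non-lineage) frequencies of a fitted clone model
#'
#' Each clone's own frequency: its prevalence minus the sum of its
#' children's prevalences, non-negative, summing to at most 1 per
#' timepoint.
#'
#' @param model A `clone_model`.
#' @return K x timepoints matrix.
#' @export
clone_frequencies <- function(model) {
  .assert(inherits(model, "clone_model"), "need a clone_model")
  pmax(model$clone_freq, 0)
}

#' Detect expanding (resistance-associated) minor clones
#'
#' Flags clones whose first-timepoint clone frequency is at most
#' `minor_max` (default 0.21, the upper end of the minor-subclone range)
#' and whose final-minus-first frequency change is at least
#' `expansion_min` (default 0.20).  When a mutation table with cluster
#' assignments and `significant` flags is supplied, each flagged clone's
#' functionally significant mutations are attached.
#'
#' @param model A `clone_model`.
#' @param minor_max Largest first-timepoint frequency of a "minor" clone.
#' @param expansion_min Smallest qualifying frequency gain.
#' @param mutations Optional `data.frame` with columns `clone`
#'   (cluster index) and `significant` plus identifying columns.
#' @return `data.frame` of class `expansion_calls`: one row per clone
#'   with initial/final frequencies and the flag; attribute
#'   `significant_mutations` lists flagged clones' significant
#'   mutations.
#' @export
detect_expanding_clones <- function(model, minor_max = 0.21,
                                    expansion_min = 0.20,
                                    mutations = NULL) {
  freq <- clone_frequencies(model)
  .assert(ncol(freq) >= 2, "need at least 2 timepoints")
  first <- freq[, 1]
  final <- freq[, ncol(freq)]
  flagged <- first <= minor_max & (final - first) >= expansion_min
  out <- data.frame(clone = seq_len(model$K),
                    initial_frequency = first, final_frequency = final,
                    flagged = flagged)
  sig <- NULL
  if (!is.null(mutations) && any(flagged)) {
    .assert(all(c("clone", "significant") %in% names(mutations)),
            "mutations needs clone/significant columns")
    sig <- mutations[mutations$clone %in% which(flagged) &
                       mutations$significant, , drop = FALSE]
  }
  attr(out, "significant_mutations") <- sig
  class(out) <- c("expansion_calls", "data.frame")
  out
}

#' Full clonal inference from variant read counts
#'
#' Convenience pipeline: cluster mutations on their prevalence
#' trajectories, infer the clone tree from the cluster centers, and
#' return the model together with per-mutation cluster assignments.
#'
#' @inheritParams cluster_mutations
#' @param max_clones Tree enumeration bound passed to [infer_tree()].
#' @return List: `model` (a `clone_model`), `clusters`
#'   (a `mutation_clusters`).
#' @export
infer_clones <- function(alt, depth, purity, cn_total = 2L,
                         multiplicity = 1L, k_max = 8L, n_restarts = 20L,
                         max_clones = 6L, seed = NULL) {
  cl <- cluster_mutations(alt, depth, purity, cn_total, multiplicity,
                          k_max, n_restarts, seed)
  model <- infer_tree(cl$centers, max_clones = max_clones)
  list(model = model, clusters = cl)
}

#' Match estimated clones to true clones by trajectory distance
#'
#' Exhaustive assignment (K <= 6) minimizing the total absolute
#' difference between matched prevalence trajectories; used by recovery
#' analyses to compare a fitted `clone_model` against simulator truth.
#'
#' @param true_prev,est_prev K x timepoints prevalence matrices with the
#'   same dimensions.
#' @return Integer permutation `perm` such that `est_prev[perm[i], ]`
#'   matches `true_prev[i, ]`, with attribute `total_abs_error`.
#' @export
match_clones <- function(true_prev, est_prev) {
  K <- nrow(true_prev)
  .assert(nrow(est_prev) == K && ncol(est_prev) == ncol(true_prev),
          "prevalence matrices must have identical dimensions")
  .assert(K <= 6, "exhaustive matching supports K <= 6")
  perms <- .permutations(K)
  best <- NULL
  for (p in perms) {
    err <- sum(abs(true_prev - est_prev[p, , drop = FALSE]))
    if (is.null(best) || err < best$err) best <- list(err = err, p = p)
  }
  structure(best$p, total_abs_error = best$err)
}

.permutations <- function(K) {
  if (K == 1) return(list(1L))
  out <- list()
  rec <- function(prefix, rest) {
    if (!length(rest)) { out[[length(out) + 1L]] <<- prefix; return() }
    for (r in rest) rec(c(prefix, r), setdiff(rest, r))
  }
  rec(integer(0), seq_len(K))
  out
}
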