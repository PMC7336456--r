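# Synthetic-cohort simulator: clone trees with CNA/SNV payloads,
# purity-diluted bin counts and VAFs over serial timepoints, bimodal
# fragment-size mixtures, segment profiles, and ploidy-correlated
# survival data.  Every generator is fully determined by its `seed`.

.rand_interval <- function(genome, min_len = 5e6, max_len = 4e7) {
  cc <- sample(names(genome), 1, prob = genome / sum(genome))
  len <- runif(1, min_len, min(max_len, genome[[cc]] / 2))
  start <- floor(runif(1, 0, genome[[cc]] - len))
  data.frame(chrom = cc, start = start, end = floor(start + len),
             stringsAsFactors = FALSE)
}

.overlaps_any <- function(iv, table) {
  if (is.null(table) || nrow(table) == 0) return(FALSE)
  same <- table$chrom == iv$chrom
  any(same & table$start < iv$end & iv$start < table$end)
}

.children_of <- function(parents) {
  lapply(seq_along(parents), function(i) which(parents == i))
}

#' Simulate a clone tree with per-timepoint frequencies
#'
#' Generates a rooted clone tree (perfect phylogeny: every clone carries
#' all of its ancestors' alterations plus private ones) with per-clone
#' lineage frequencies at each timepoint obeying the sum constraint
#' (a clone's frequency is at least the sum of its children's at every
#' timepoint; the founder's is at most 1).  Two expansion scenarios are
#' available: under `expanding_minor` one leaf clone starts as a minor
#' subclone (frequency 0.05-0.18 at the first timepoint, within the
#' 1-21% range typical of therapy-resistant minor subclones) and rises
#' monotonically to ~0.55-0.75 by the last timepoint, with the remaining
#' lineages rescaled to respect the sum constraint; under
#' `stable_dominant` the founder clone's frequency stays within a 0.02
#' band across timepoints.
#'
#' Clone trajectories are rejection-sampled so that every pair of clones
#' is separated by at least `min_separation` at some timepoint: clones
#' closer than the per-mutation prevalence noise are not distinguishable
#' subpopulations for any deconvolution method.
#'
#' @param n_clones Number of clones (1-8).
#' @param n_timepoints Number of serial timepoints (2-6).
#' @param expansion_scenario `"stable_dominant"` or `"expanding_minor"`.
#' @param seed Integer seed; fully determines the output.
#' @param n_snv_per_clone Private point mutations per clone (default 20).
#' @param n_cna_root,n_cna_per_clone Copy number alterations private to
#'   the founder (default 8) and to each further clone (default 2).
#' @param min_separation Minimum pairwise max-timepoint frequency
#'   separation (default 0.15).
#' @param genome Named chromosome lengths (default [default_genome()]).
#' @return List of class `clone_truth`: `clones` (clone_id, parent_id),
#'   `prevalence` (clone x timepoint lineage frequencies),
#'   `cna_payload` / `snv_payload` (per-clone full payloads, ancestors
#'   included), `snv_table` (one row per distinct mutation with its
#'   introducing clone and functional annotations), `scenario`, `seed`.
#' @export
simulate_clone_tree <- function(n_clones, n_timepoints,
                                expansion_scenario = c("stable_dominant",
                                                       "expanding_minor"),
                                seed,
                                n_snv_per_clone = 20L,
                                n_cna_root = 8L, n_cna_per_clone = 2L,
                                min_separation = 0.15,
                                genome = default_genome()) {
  expansion_scenario <- match.arg(expansion_scenario)
  if (!is.numeric(n_clones) || n_clones < 1)
    stop("invalid argument: n_clones must be >= 1", call. = FALSE)
  if (!is.numeric(n_timepoints) || n_timepoints < 2)
    stop("invalid argument: n_timepoints must be >= 2", call. = FALSE)
  .assert(n_clones <= 8, "n_clones must be <= 8")
  .assert(n_timepoints <= 6, "n_timepoints must be <= 6")
  if (expansion_scenario == "expanding_minor" && n_clones < 2)
    stop("invalid argument: expanding_minor needs >= 2 clones",
         call. = FALSE)
  K <- as.integer(n_clones); T_ <- as.integer(n_timepoints)

  .with_seed(seed, {
    gen_once <- function() {
      parents <- integer(K)
      parents[1] <- 0L
      if (K > 1) for (i in 2:K)
        parents[i] <- if (i == 2) 1L else sample(seq_len(i - 1L), 1L)
      if (expansion_scenario == "expanding_minor") parents[K] <- 1L

      phi <- matrix(0, K, T_)
      if (K == 1) {
        # degenerate tree: one clone, no subclonal structure
        phi[1, ] <- 1
        return(list(parents = parents, phi = phi))
      }
      if (expansion_scenario == "stable_dominant") {
        c0 <- runif(1, 0.92, 0.99)
        phi[1, ] <- c0 + runif(T_, -0.01, 0.01)
      } else phi[1, ] <- runif(T_, 0.9, 1.0)

      kids <- .children_of(parents)
      stable <- expansion_scenario == "stable_dominant"
      for (i in seq_len(K)) {
        ch <- kids[[i]]
        if (!length(ch)) next
        # stable scenario: allocations fixed over time (small jitter);
        # expanding scenario: allocations redrawn per timepoint
        u0 <- runif(1, 0.5, 1.0)
        w0 <- rexp(length(ch)); w0 <- w0 / sum(w0)
        for (t in seq_len(T_)) {
          if (stable) {
            u <- min(max(u0 + runif(1, -0.02, 0.02), 0), 1)
            w <- w0
          } else {
            u <- runif(1, 0.5, 1.0)
            w <- rexp(length(ch)); w <- w / sum(w)
          }
          phi[ch, t] <- phi[i, t] * u * w
        }
      }

      if (expansion_scenario == "expanding_minor") {
        e <- K
        f1 <- runif(1, 0.05, 0.18)
        fT <- runif(1, 0.55, 0.75)
        traj <- f1 + (fT - f1) * (seq_len(T_) - 1) / (T_ - 1)
        if (T_ > 2) {
          mid <- 2:(T_ - 1)
          traj[mid] <- pmin(pmax(traj[mid] + runif(length(mid), -0.03, 0.03),
                                 f1 + 1e-3), fT - 1e-3)
          traj <- cummax(traj)
        }
        phi[e, ] <- traj
        sibs <- setdiff(kids[[1]], e)
        if (length(sibs)) {
          desc <- function(i) {
            out <- i
            for (c_ in kids[[i]]) out <- c(out, desc(c_))
            out
          }
          for (t in seq_len(T_)) {
            tot <- sum(phi[sibs, t])
            cap <- phi[1, t] - phi[e, t]
            if (tot > cap && tot > 0) {
              s <- max(cap, 0) / tot
              for (sb in sibs) phi[desc(sb), t] <- phi[desc(sb), t] * s
            }
          }
        }
      }
      list(parents = parents, phi = phi)
    }

    sep_ok <- function(phi) {
      if (K == 1) return(TRUE)
      for (a in seq_len(K - 1)) for (b in (a + 1):K)
        if (max(abs(phi[a, ] - phi[b, ])) < min_separation) return(FALSE)
      TRUE
    }
    cand <- gen_once()
    tries <- 1L
    while (!sep_ok(cand$phi) && tries < 200L) {
      cand <- gen_once()
      tries <- tries + 1L
    }
    parents <- cand$parents; phi <- cand$phi

    # CNA payloads: private intervals avoiding ancestors', then unions
    private_cna <- vector("list", K)
    for (i in seq_len(K)) {
      n_iv <- if (i == 1) n_cna_root else n_cna_per_clone
      anc <- NULL
      j <- parents[i]
      while (j > 0) { anc <- rbind(anc, private_cna[[j]]); j <- parents[j] }
      ivs <- NULL
      for (k in seq_len(n_iv)) {
        for (try in 1:50) {
          iv <- .rand_interval(genome)
          if (!.overlaps_any(iv, rbind(anc, ivs))) break
        }
        iv$cn <- sample(c(0L, 1L, 1L, 3L, 3L, 4L), 1L)
        ivs <- rbind(ivs, iv)
      }
      private_cna[[i]] <- ivs
    }
    all_cna <- do.call(rbind, private_cna)

    # SNVs outside every CNA interval, so each site sits at tumor CN 2
    bases <- c("A", "C", "G", "T")
    snv_rows <- list()
    for (i in seq_len(K)) {
      for (k in seq_len(n_snv_per_clone)) {
        for (try in 1:50) {
          cc <- sample(names(genome), 1, prob = genome / sum(genome))
          pos <- floor(runif(1, 1, genome[[cc]]))
          iv <- data.frame(chrom = cc, start = pos - 1, end = pos)
          if (!.overlaps_any(iv, all_cna)) break
        }
        ref <- sample(bases, 1)
        snv_rows[[length(snv_rows) + 1L]] <- data.frame(
          chrom = cc, pos = pos, ref = ref,
          alt = sample(setdiff(bases, ref), 1), multiplicity = 1L,
          clone_id = paste0("C", i), stringsAsFactors = FALSE)
      }
    }
    snv <- do.call(rbind, snv_rows)
    n_mut <- nrow(snv)
    snv$gene <- paste0("GENE", seq_len(n_mut))
    snv$sift <- runif(n_mut)
    snv$polyphen <- runif(n_mut)
    snv$exonic_class <- sample(c("non-synonymous", "synonymous"), n_mut,
                               replace = TRUE, prob = c(0.7, 0.3))
    # guarantee functionally significant mutations on every subclone
    for (i in seq_len(K)) {
      idx <- which(snv$clone_id == paste0("C", i))
      pick <- idx[seq_len(min(2L, length(idx)))]
      snv$sift[pick] <- runif(length(pick), 0, 0.049)
      snv$polyphen[pick] <- runif(length(pick), 0.86, 1)
      snv$exonic_class[pick] <- "non-synonymous"
    }

    ids <- paste0("C", seq_len(K))
    lineage <- function(i) {
      out <- i
      j <- parents[i]
      while (j > 0) { out <- c(j, out); j <- parents[j] }
      out
    }
    cna_payload <- setNames(lapply(seq_len(K), function(i)
      do.call(rbind, private_cna[lineage(i)])), ids)
    snv_payload <- setNames(lapply(seq_len(K), function(i) {
      keep <- snv$clone_id %in% ids[lineage(i)]
      snv[keep, c("chrom", "pos", "multiplicity")]
    }), ids)

    rownames(phi) <- ids
    colnames(phi) <- paste0("T", seq_len(T_))
    structure(list(
      clones = data.frame(clone_id = ids,
                          parent_id = vapply(parents, function(p)
                            if (p == 0L) "root" else ids[p], character(1)),
                          stringsAsFactors = FALSE),
      prevalence = phi, cna_payload = cna_payload,
      snv_payload = snv_payload, snv_table = snv,
      scenario = expansion_scenario, seed = seed, genome = genome),
      class = "clone_truth")
  })
}

#' Clone (non-lineage) frequencies of a simulated tree
#'
#' Own frequency of each clone: its lineage frequency minus the sum of
#' its children's, i.e. the fraction of tumor cells belonging to exactly
#' that clone.
#'
#' @param truth A `clone_truth`.
#' @return Clone x timepoint matrix of own frequencies.
#' @export
clone_truth_frequencies <- function(truth) {
  phi <- truth$prevalence
  parents <- match(truth$clones$parent_id, truth$clones$clone_id)
  parents[is.na(parents)] <- 0L
  own <- phi
  for (i in seq_len(nrow(phi))) {
    ch <- which(parents == i)
    if (length(ch)) own[i, ] <- phi[i, ] - colSums(phi[ch, , drop = FALSE])
  }
  pmax(own, 0)
}

# tumor copy number per bin for one clone (fraction-weighted by overlap)
.clone_cn_per_bin <- function(grid, payload) {
  cn <- rep(2, nrow(grid))
  if (is.null(payload) || nrow(payload) == 0) return(cn)
  for (k in seq_len(nrow(payload))) {
    iv <- payload[k, ]
    idx <- which(grid$chrom == iv$chrom & grid$start < iv$end &
                   iv$start < grid$end)
    if (!length(idx)) next
    ov <- pmin(grid$end[idx], iv$end) - pmax(grid$start[idx], iv$start)
    frac <- ov / (grid$end[idx] - grid$start[idx])
    cn[idx] <- cn[idx] + (iv$cn - 2) * frac
  }
  cn
}

#' Simulate sparse WGS bin counts for a clone mixture
#'
#' Expected count per bin is proportional to the purity-weighted mixture
#' copy ratio: tumor cells contribute each clone's local copy number at
#' its clone frequency, normal cells contribute copy number 2.  Counts
#' are drawn from a gamma-mixed Poisson (negative binomial) with a single
#' dispersion parameter, matching sparse-WGS overdispersion without
#' per-bin GC modeling.
#'
#' @param truth A `clone_truth`.
#' @param purity Tumor-DNA fraction in \[0, 1\].
#' @param grid A [bin_grid()].
#' @param mean_depth_per_bin Expected reads per copy-neutral bin.
#' @param overdispersion Gamma-mixing dispersion (default 0.05; 0 gives
#'   pure Poisson counts).
#' @param timepoint Which timepoint's clone frequencies to use.
#' @param seed Integer seed.
#' @return `bin_counts` with raw `count` and the ground-truth mixture
#'   ratio in `truth_ratio`.
#' @export
simulate_bin_counts <- function(truth, purity, grid, mean_depth_per_bin,
                                overdispersion = 0.05, timepoint = 1L,
                                seed = NULL) {
  if (mean_depth_per_bin < 0)
    stop("invalid argument: negative depth", call. = FALSE)
  .assert(purity >= 0 && purity <= 1, "purity must be in [0,1]")
  grid <- .as_grid(grid)
  own <- clone_truth_frequencies(truth)[, timepoint]
  tumor_ratio <- rep(1, nrow(grid))   # in units of CN/2
  if (sum(own) > 0) {
    acc <- rep(0, nrow(grid))
    for (i in seq_along(own)) {
      id <- rownames(truth$prevalence)[i]
      acc <- acc + own[i] * .clone_cn_per_bin(grid, truth$cna_payload[[id]]) / 2
    }
    tumor_ratio <- acc + (1 - sum(own)) * 1
  }
  ratio <- (1 - purity) + purity * tumor_ratio
  .with_seed(seed, {
    mu <- mean_depth_per_bin * ratio
    count <- if (overdispersion > 0)
      rnbinom(length(mu), mu = mu, size = 1 / overdispersion)
    else rpois(length(mu), mu)
    out <- bin_counts(grid, count)
    out$truth_ratio <- ratio
    out
  })
}

#' Simulate per-timepoint somatic variant read counts
#'
#' For each mutation in the clone tree, the expected plasma VAF at
#' timepoint t is `purity_t * clone_freq * multiplicity /
#' (purity_t * cn_t + (1 - purity_t) * 2)` with `clone_freq` the lineage
#' frequency of the introducing clone (the simulator places mutations at
#' tumor copy number 2).  Plasma alt reads are binomial at
#' `depth_plasma`; matched-normal alt reads are binomial at
#' `contamination` times the plasma VAF (default 0).
#'
#' @param truth A `clone_truth`.
#' @param purity_by_timepoint Tumor purity per timepoint (recycled if
#'   scalar).
#' @param depth_plasma,depth_normal Sequencing depths (> 0).
#' @param contamination Fraction of the plasma VAF seen in the normal
#'   (default 0).
#' @param seed Integer seed.
#' @return `data.frame` of class `variant_timecourse`: variant identity,
#'   annotations, `clone_id`, `cn_total`, expected VAFs
#'   (`true_vaf_T*`), and per-timepoint `alt_T*` / `dep_T*` counts plus
#'   `normal_alt` / `normal_depth`.
#' @export
simulate_variants <- function(truth, purity_by_timepoint,
                              depth_plasma, depth_normal,
                              contamination = 0, seed = NULL) {
  if (depth_plasma <= 0 || depth_normal <= 0)
    stop("invalid argument: depths must be > 0", call. = FALSE)
  T_ <- ncol(truth$prevalence)
  purity <- rep_len(purity_by_timepoint, T_)
  .assert(all(purity >= 0 & purity <= 1), "purity must be in [0,1]")
  snv <- truth$snv_table
  phi <- truth$prevalence[snv$clone_id, , drop = FALSE]
  cn <- 2
  .with_seed(seed, {
    out <- snv
    out$cn_total <- cn
    for (t in seq_len(T_)) {
      vaf <- purity[t] * phi[, t] * snv$multiplicity /
        (purity[t] * cn + (1 - purity[t]) * 2)
      out[[paste0("true_vaf_T", t)]] <- vaf
      out[[paste0("alt_T", t)]] <- rbinom(nrow(snv), depth_plasma, vaf)
      out[[paste0("dep_T", t)]] <- depth_plasma
    }
    nvaf <- contamination * out$true_vaf_T1
    out$normal_alt <- rbinom(nrow(snv), depth_normal, pmin(nvaf, 1))
    out$normal_depth <- depth_normal
    class(out) <- c("variant_timecourse", "data.frame")
    out
  })
}

#' Extract alt/depth matrices from a simulated variant table
#' @param variants A `variant_timecourse`.
#' @return List with `alt` and `depth` (mutations x timepoints) matrices.
#' @export
variant_matrices <- function(variants) {
  ac <- grep("^alt_T", names(variants), value = TRUE)
  dc <- grep("^dep_T", names(variants), value = TRUE)
  list(alt = as.matrix(variants[ac]), depth = as.matrix(variants[dc]))
}

#' Simulate a bimodal cfDNA fragment-size sample
#'
#' Mixture of a tumor component (mean 142 bp) and a normal component
#' (mean 154 bp), each drawn as a near-symmetric shifted gamma (shape 36;
#' the component mean sits at the stated location, the mode ~3 bp below)
#' so sizes stay positive.  Each component carries di- and tri-nucleosome
#' harmonics at twice and three times its mean with minor weights
#' (defaults 0.15 / 0.05) and the mononucleosome spread.
#'
#' @param tumor_fraction Fraction of tumor-derived fragments in \[0, 1\].
#' @param n_fragments Number of fragments (> 0).
#' @param seed Integer seed.
#' @param tumor_mean_bp,normal_mean_bp Component means (defaults 142 and
#'   154 bp).
#' @param sd_bp Component spread (default 20 bp; no published value pins
#'   the per-mode spread down, so this is a free parameter).
#' @param harmonic_weights Weights of the di- and tri-nucleosome
#'   harmonics (default `c(0.15, 0.05)`; `c(0, 0)` gives unimodal
#'   components).
#' @param shape Gamma shape of each component (default 36).
#' @param mass_scale See [fragment_mass_ng()].
#' @return List of class `fragment_sample`: `sizes` (bp), `total_mass_ng`,
#'   `tumor` (logical per fragment).
#' @export
simulate_fragment_sizes <- function(tumor_fraction, n_fragments, seed = NULL,
                                    tumor_mean_bp = 142,
                                    normal_mean_bp = 154, sd_bp = 20,
                                    harmonic_weights = c(0.15, 0.05),
                                    shape = 36, mass_scale = 2e5) {
  if (n_fragments <= 0)
    stop("invalid argument: n_fragments must be > 0", call. = FALSE)
  .assert(tumor_fraction >= 0 && tumor_fraction <= 1,
          "tumor_fraction must be in [0,1]")
  .assert(all(harmonic_weights >= 0) && sum(harmonic_weights) < 1,
          "harmonic weights must be >= 0 and sum to < 1")
  .with_seed(seed, {
    tumor <- runif(n_fragments) < tumor_fraction
    base_mean <- ifelse(tumor, tumor_mean_bp, normal_mean_bp)
    h <- sample(1:3, n_fragments, replace = TRUE,
                prob = c(1 - sum(harmonic_weights), harmonic_weights))
    mean_i <- base_mean * h
    theta <- sd_bp / sqrt(shape)
    shift <- mean_i - shape * theta
    sizes <- shift + rgamma(n_fragments, shape = shape, scale = theta)
    structure(list(sizes = sizes,
                   total_mass_ng = sum(fragment_mass_ng(sizes, mass_scale)),
                   tumor = tumor),
              class = "fragment_sample")
  })
}

#' Simulate a clinical cohort with ploidy-linked survival
#'
#' Exponential survival with the aneuploid group's hazard multiplied by
#' `ploidy_effect`; censoring is administrative at a uniform follow-up
#' horizon.  Total cfDNA mass is drawn log-normally with a higher
#' location for aneuploid patients, reflecting the higher plasma DNA
#' concentrations seen with aneuploid profiles.
#'
#' @param n_patients Cohort size (>= 2).
#' @param ploidy_effect Hazard ratio of aneuploid vs diploid (1 = null).
#' @param seed Integer seed.
#' @param aneuploid_frac Expected aneuploid fraction (default 0.45).
#' @param median_os_diploid Baseline median overall survival in months
#'   (default 22).
#' @param followup_months Range of administrative censoring times
#'   (default 12-60 months).
#' @return `data.frame`: `patient_id`, `months` (> 0), `event` (1 =
#'   death observed), `ploidy` ("diploid"/"aneuploid"), `cfdna_ng`,
#'   `psa`.
#' @export
simulate_cohort_clinical <- function(n_patients, ploidy_effect = 2.0,
                                     seed = NULL, aneuploid_frac = 0.45,
                                     median_os_diploid = 22,
                                     followup_months = c(12, 60)) {
  .assert(n_patients >= 2, "n_patients must be >= 2")
  .assert(ploidy_effect > 0, "ploidy_effect must be > 0")
  .with_seed(seed, {
    aneu <- runif(n_patients) < aneuploid_frac
    rate <- log(2) / median_os_diploid * ifelse(aneu, ploidy_effect, 1)
    t_event <- rexp(n_patients, rate)
    t_cens <- runif(n_patients, followup_months[1], followup_months[2])
    months <- pmax(pmin(t_event, t_cens), 1e-3)
    data.frame(
      patient_id = paste0("P", seq_len(n_patients)),
      months = months,
      event = as.integer(t_event <= t_cens),
      ploidy = ifelse(aneu, "aneuploid", "diploid"),
      cfdna_ng = stats::rlnorm(n_patients,
                               meanlog = log(3) + aneu * log(8 / 3),
                               sdlog = 0.8),
      psa = stats::rlnorm(n_patients, meanlog = log(10), sdlog = 1),
      stringsAsFactors = FALSE)
  })
}

#' Simulate a segmented copy number profile with a planted ploidy label
#'
#' Draws a `segment_profile` directly in segment space: diploid profiles
#' get few segments with small level jitter (per-segment means wobble by
#' ~0.005, the scale expected when averaging noisy bins over large
#' segments); aneuploid profiles get many segments (> 45) about half of
#' which deviate by 0.05-0.4 from the neutral level.  Useful for testing
#' ploidy classification without running segmentation.
#'
#' @param label Planted label, `"diploid"` or `"aneuploid"`.
#' @param seed Integer seed.
#' @param n_chrom Chromosomes in the synthetic genome (default 22).
#' @param bins_per_chrom Bins per chromosome (default 100, 1 Mb each).
#' @param noise_sd Additional per-segment measurement noise (default
#'   0.005).
#' @return A `segment_profile` with attribute `true_label`.
#' @export
simulate_segment_profile <- function(label = c("diploid", "aneuploid"),
                                     seed = NULL, n_chrom = 22L,
                                     bins_per_chrom = 100L,
                                     noise_sd = 0.005) {
  label <- match.arg(label)
  .with_seed(seed, {
    n_bins <- n_chrom * bins_per_chrom
    grid <- bin_grid(rep(paste0("chr", seq_len(n_chrom)),
                         each = bins_per_chrom),
                     rep(seq(0, by = 1e6, length.out = bins_per_chrom),
                         n_chrom),
                     rep(seq(1e6, by = 1e6, length.out = bins_per_chrom),
                         n_chrom))
    n_seg <- if (label == "diploid") 5L + rpois(1, 10) else 50L + rpois(1, 25)
    n_seg <- min(n_seg, n_bins %/% 2L)
    # distribute breakpoints over the genome, then split at chromosome ends
    cuts <- sort(sample(seq_len(n_bins - 1L), n_seg - 1L))
    cuts <- sort(unique(c(cuts, seq_len(n_chrom - 1L) * bins_per_chrom)))
    ends_global <- c(cuts, n_bins)
    dev <- if (label == "diploid") rnorm(length(ends_global), 0, 0.005)
    else {
      big <- runif(length(ends_global)) < 0.5
      ifelse(big, sample(c(-1, 1), length(ends_global), TRUE) *
               runif(length(ends_global), 0.05, 0.4),
             rnorm(length(ends_global), 0, 0.005))
    }
    means <- 1 + dev + rnorm(length(ends_global), 0, noise_sd)
    segval <- rep(means, diff(c(0L, ends_global)))
    chrom_ends <- lapply(seq_len(n_chrom), function(ci) {
      lo <- (ci - 1L) * bins_per_chrom
      e <- ends_global[ends_global > lo & ends_global <= lo + bins_per_chrom]
      as.integer(e - lo)
    })
    names(chrom_ends) <- paste0("chr", seq_len(n_chrom))
    counts <- grid
    counts$count <- 1
    prof <- .profile_from_ends(counts, segval, chrom_ends)
    attr(prof, "true_label") <- label
    prof
  })
}
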