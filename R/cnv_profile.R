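# Bin grids, read counting, normalization, circular binary segmentation
# and MergeLevels for sparse whole-genome plasma sequencing.

#' Construct a genomic bin grid
#'
#' A bin grid is an ordered set of non-overlapping genomic intervals in
#' 0-based half-open coordinates (BED convention): a position `p` belongs
#' to bin `[start, end)` iff `start <= p < end`.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors of 0-based half-open bin boundaries.
#' @return A `data.frame` of class `bin_grid` with columns
#'   `chrom`, `start`, `end`, sorted by (chrom, start).
#' @export
bin_grid <- function(chrom, start, end) {
  .assert(length(chrom) == length(start) && length(start) == length(end),
          "chrom/start/end must have equal length")
  .assert(length(chrom) > 0, "grid must be non-empty")
  .assert(all(end > start), "all bins must satisfy end > start")
  g <- data.frame(chrom = as.character(chrom),
                  start = as.numeric(start), end = as.numeric(end),
                  stringsAsFactors = FALSE)
  g <- g[order(factor(g$chrom, levels = unique(g$chrom)), g$start), ,
         drop = FALSE]
  for (cc in unique(g$chrom)) {
    gc <- g[g$chrom == cc, ]
    if (nrow(gc) > 1)
      .assert(all(gc$start[-1] >= gc$end[-nrow(gc)]),
              sprintf("bins overlap on %s", cc))
  }
  rownames(g) <- NULL
  class(g) <- c("bin_grid", "data.frame")
  g
}

#' Equal-width bin grid over a genome
#'
#' Tiles each chromosome with fixed-width bins (default width matches the
#' ~220 kb mean resolution used for sparse plasma WGS); the last bin of a
#' chromosome is truncated at the chromosome end.
#'
#' @param bin_size Bin width in bp.
#' @param genome Named vector of chromosome lengths (default
#'   [default_genome()]).
#' @return A [bin_grid()].
#' @export
uniform_bin_grid <- function(bin_size = 220000, genome = default_genome()) {
  .assert(bin_size > 0, "bin_size must be positive")
  pieces <- lapply(names(genome), function(cc) {
    len <- genome[[cc]]
    s <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = cc, start = s, end = pmin(s + bin_size, len),
               stringsAsFactors = FALSE)
  })
  g <- do.call(rbind, pieces)
  bin_grid(g$chrom, g$start, g$end)
}

.as_grid <- function(x) {
  if (inherits(x, "bin_grid")) return(x)
  .assert(all(c("chrom", "start", "end") %in% names(x)),
          "grid needs chrom/start/end columns")
  bin_grid(x$chrom, x$start, x$end)
}

#' Count read start positions into a bin grid
#'
#' Each read is assigned to the unique bin whose half-open interval
#' contains its start position; reads on unknown chromosomes or outside
#' all bins are dropped and reported via the `"dropped"` attribute.
#'
#' @param positions `data.frame` with columns `chrom` and `pos`
#'   (0-based positions).
#' @param grid A [bin_grid()].
#' @return A `data.frame` of class `bin_counts`: the grid columns plus a
#'   raw `count` per bin; attribute `dropped` gives the number of unbinned
#'   reads.
#' @export
count_reads_in_bins <- function(positions, grid) {
  grid <- .as_grid(grid)
  .assert(all(c("chrom", "pos") %in% names(positions)),
          "positions needs chrom/pos columns")
  counts <- numeric(nrow(grid))
  dropped <- 0L
  bad <- !positions$chrom %in% unique(grid$chrom)
  if (any(bad)) {
    warning(sprintf("%d read(s) on chromosomes absent from the grid dropped",
                    sum(bad)))
    dropped <- dropped + sum(bad)
    positions <- positions[!bad, , drop = FALSE]
  }
  for (cc in unique(positions$chrom)) {
    idx <- which(grid$chrom == cc)
    pos <- positions$pos[positions$chrom == cc]
    # half-open bins: pos in [start, end) ; findInterval on starts, then
    # reject positions at/after the bin end (gaps between bins)
    k <- findInterval(pos, grid$start[idx])
    inside <- k >= 1 & pos < grid$end[idx][pmax(k, 1)]
    dropped <- dropped + sum(!inside)
    tab <- tabulate(k[inside], nbins = length(idx))
    counts[idx] <- counts[idx] + tab
  }
  out <- grid
  out$count <- counts
  attr(out, "dropped") <- dropped
  class(out) <- c("bin_counts", "data.frame")
  out
}

#' Assemble bin counts from a grid and a raw count vector
#' @param grid A [bin_grid()].
#' @param count Non-negative counts, one per bin.
#' @return A `bin_counts` data frame.
#' @export
bin_counts <- function(grid, count) {
  grid <- .as_grid(grid)
  .assert(length(count) == nrow(grid), "one count per bin required")
  .assert(all(count >= 0), "counts must be non-negative")
  out <- grid
  out$count <- as.numeric(count)
  class(out) <- c("bin_counts", "data.frame")
  out
}

#' Normalize bin counts to copy ratios
#'
#' `ratio = count / mean(count)` so that `mean(ratio) == 1` exactly;
#' `log2ratio = log2(ratio)` with zero-count bins floored at
#' `1 / (2 * mean(count))` in the log transform only (flagged in
#' `low_count`), which avoids -Inf log ratios in sparse data without
#' disturbing the mean-1 normalization.
#'
#' @param counts A `bin_counts` object with a raw `count` column.
#' @return The same object with `ratio`, `log2ratio` and `low_count`
#'   columns filled.
#' @export
normalize_counts <- function(counts) {
  .assert(inherits(counts, "bin_counts") || "count" %in% names(counts),
          "counts must carry a `count` column")
  raw <- counts$count
  .assert(sum(raw) > 0, "all-zero counts cannot be normalized")
  mu <- mean(raw)
  counts$ratio <- raw / mu
  floor_ratio <- 1 / (2 * mu)
  counts$low_count <- counts$ratio < floor_ratio
  counts$log2ratio <- log2(pmax(counts$ratio, floor_ratio))
  if (!inherits(counts, "bin_counts"))
    class(counts) <- c("bin_counts", class(counts))
  counts
}

#' Circular binary segmentation parameters
#'
#' @param alpha Permutation significance level for accepting a split
#'   (default 0.0001).
#' @param undo_prune Relative residual-sum-of-squares increase below which
#'   a changepoint is undone after segmentation (default 0.05).
#' @param n_permutations Permutation cap per split test (default 10000).
#' @param min_seg_bins Minimum bins on either side of a cut (default 2).
#' @param tail_fit_n Number of permutation maxima used for the tail
#'   approximation that resolves p-values below the permutation
#'   resolution (default 500).
#' @return A list of class `cbs_params`.
#' @export
cbs_params <- function(alpha = 1e-4, undo_prune = 0.05,
                       n_permutations = 10000L, min_seg_bins = 2L,
                       tail_fit_n = 500L) {
  .assert(alpha > 0 && alpha < 1, "alpha must be in (0,1)")
  .assert(undo_prune >= 0, "undo_prune must be >= 0")
  .assert(n_permutations >= 10, "n_permutations too small")
  .assert(min_seg_bins >= 1, "min_seg_bins must be >= 1")
  structure(list(alpha = alpha, undo_prune = undo_prune,
                 n_permutations = as.integer(n_permutations),
                 min_seg_bins = as.integer(min_seg_bins),
                 tail_fit_n = as.integer(tail_fit_n)),
            class = "cbs_params")
}

# recursive CBS on one chromosome; returns integer vector of segment
# boundaries (last bin index of each segment, 1-based, local)
.cbs_chrom <- function(x, params) {
  n <- length(x)
  if (n < 2 * params$min_seg_bins || sd(x) == 0) return(n)
  res <- .cbs_perm_test(x, params$alpha, params$n_permutations,
                        params$tail_fit_n, params$min_seg_bins)
  if (res$p >= params$alpha) return(n)
  cps <- sort(setdiff(c(res$i, res$j), c(0L, n)))
  if (length(cps) == 0) return(n)
  bounds <- c(0L, cps, n)
  out <- integer(0)
  for (k in seq_len(length(bounds) - 1)) {
    lo <- bounds[k] + 1L
    hi <- bounds[k + 1L]
    out <- c(out, bounds[k] + .cbs_chrom(x[lo:hi], params))
  }
  out
}

# undo-pruning: repeatedly remove the changepoint whose removal increases
# the residual sum of squares by less than undo_prune * total SSR
.undo_prune_chrom <- function(x, ends, undo_prune) {
  repeat {
    if (length(ends) < 2 || undo_prune <= 0) return(ends)
    starts <- c(1L, head(ends, -1) + 1L)
    ssr_seg <- mapply(function(s, e) sum((x[s:e] - mean(x[s:e]))^2),
                      starts, ends)
    ssr_tot <- sum(ssr_seg)
    if (ssr_tot == 0) return(ends)
    k <- length(ends)
    delta <- vapply(seq_len(k - 1), function(b) {
      s <- starts[b]; e <- ends[b + 1L]
      sum((x[s:e] - mean(x[s:e]))^2) - ssr_seg[b] - ssr_seg[b + 1L]
    }, numeric(1))
    if (min(delta) < undo_prune * ssr_tot) {
      ends <- ends[-which.min(delta)]
    } else return(ends)
  }
}

.profile_from_ends <- function(counts, values, chrom_ends) {
  segs <- list()
  segval <- numeric(nrow(counts))
  for (cc in names(chrom_ends)) {
    idx <- which(counts$chrom == cc)
    ends <- chrom_ends[[cc]]
    starts <- c(1L, head(ends, -1) + 1L)
    for (k in seq_along(ends)) {
      gi <- idx[starts[k]:ends[k]]
      m <- mean(values[gi])
      segval[gi] <- m
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = cc, start_bin = gi[1], end_bin = gi[length(gi)],
        start_bp = counts$start[gi[1]], end_bp = counts$end[gi[length(gi)]],
        n_bins = length(gi), mean_ratio = m, stringsAsFactors = FALSE)
    }
  }
  structure(list(segments = do.call(rbind, segs), segvalue = segval,
                 grid = .as_grid(counts[c("chrom", "start", "end")])),
            class = "segment_profile")
}

#' Circular binary segmentation of normalized bin counts
#'
#' Recursive changepoint detection per chromosome: at each step the arc
#' maximizing the standardized mean difference between in-arc and
#' out-of-arc bins is found; the split is accepted when its permutation
#' p-value falls below `alpha` (within-chromosome label permutations with
#' sequential early stopping; see [cbs_params()]).  Accepted cuts are then
#' subject to undo-pruning: a changepoint is removed when undoing it
#' increases the residual sum of squares by less than
#' `undo_prune` times the profile's total within-segment sum of squares.
#'
#' @param counts Normalized `bin_counts` (see [normalize_counts()]).
#' @param params A [cbs_params()] object.
#' @param space Segment the `"ratio"` (default) or `"log2"` values.
#' @param seed Optional seed for the permutation stream (restored on
#'   exit).
#' @return A `segment_profile`: `$segments` (one row per segment with
#'   chrom, bin span, bp span, `n_bins`, `mean_ratio`) and `$segvalue`
#'   (the per-bin segmented value).
#' @export
cbs_segment <- function(counts, params = cbs_params(),
                        space = c("ratio", "log2"), seed = NULL) {
  space <- match.arg(space)
  if (!"ratio" %in% names(counts)) counts <- normalize_counts(counts)
  values <- if (space == "ratio") counts$ratio else counts$log2ratio
  .with_seed(seed, {
    chrom_ends <- list()
    for (cc in unique(counts$chrom)) {
      x <- values[counts$chrom == cc]
      ends <- .cbs_chrom(x, params)
      chrom_ends[[cc]] <- .undo_prune_chrom(x, ends, params$undo_prune)
    }
    .profile_from_ends(counts, values, chrom_ends)
  })
}

#' Merge adjacent segments with indistinguishable levels (MergeLevels)
#'
#' Iteratively merges, within each chromosome, the adjacent segment pair
#' whose member-bin ratios have the largest Wilcoxon rank-sum p-value, as
#' long as that p-value is at or above `merge_p_threshold`; merged means
#' are recomputed and the procedure runs to a fixed point.  This removes
#' erroneous breakpoints left by segmentation.
#'
#' @param profile A `segment_profile` from [cbs_segment()].
#' @param counts The `bin_counts` the profile was fitted to.
#' @param merge_p_threshold Minimum rank-sum p-value for merging
#'   (default 0.05).
#' @return A `segment_profile` with (possibly) fewer segments.
#' @export
merge_levels <- function(profile, counts, merge_p_threshold = 0.05) {
  .assert(inherits(profile, "segment_profile"), "profile must be segmented")
  .assert(nrow(profile$grid) == nrow(counts),
          "profile and counts disagree on bin number")
  if (!"ratio" %in% names(counts)) counts <- normalize_counts(counts)
  values <- counts$ratio
  chrom_ends <- list()
  for (cc in unique(profile$segments$chrom)) {
    segs <- profile$segments[profile$segments$chrom == cc, ]
    idx0 <- which(counts$chrom == cc)[1] - 1L
    ends <- segs$end_bin - idx0
    x <- values[counts$chrom == cc]
    repeat {
      if (length(ends) < 2) break
      starts <- c(1L, head(ends, -1) + 1L)
      pvals <- vapply(seq_len(length(ends) - 1), function(b) {
        a <- x[starts[b]:ends[b]]
        bb <- x[starts[b + 1L]:ends[b + 1L]]
        if (length(unique(c(a, bb))) == 1) return(1)
        suppressWarnings(wilcox.test(a, bb, exact = FALSE)$p.value)
      }, numeric(1))
      if (max(pvals) >= merge_p_threshold) {
        ends <- ends[-which.max(pvals)]
      } else break
    }
    chrom_ends[[cc]] <- ends
  }
  .profile_from_ends(counts, values, chrom_ends)
}

#' Tumor/normal exome depth-ratio profile
#'
#' Library-size-normalized depth ratio per capture target,
#' `ratio_t = (tumor_t / sum(tumor)) / (normal_t / sum(normal))`, reported
#' as median-centered log2 ratios.  Targets with zero normal depth are
#' excluded and reported via the `excluded` attribute.  The result is
#' segmentable with [cbs_segment()] on target order.
#'
#' @param tumor_depth,normal_depth Equal-length per-target depth vectors.
#' @param targets Optional `data.frame` of target intervals
#'   (chrom/start/end) carried through to the output.
#' @return `data.frame` with the retained targets and `log2ratio`;
#'   attribute `excluded` holds the indices of zero-normal-depth targets.
#' @export
exome_cn_ratio <- function(tumor_depth, normal_depth, targets = NULL) {
  .assert(length(tumor_depth) == length(normal_depth),
          "depth vectors must have equal length")
  excl <- which(normal_depth <= 0)
  keep <- setdiff(seq_along(tumor_depth), excl)
  .assert(length(keep) > 0, "no targets with positive normal depth")
  td <- tumor_depth[keep]; nd <- normal_depth[keep]
  ratio <- (td / sum(td)) / (nd / sum(nd))
  l2 <- log2(pmax(ratio, 1e-6))
  l2 <- l2 - median(l2)
  out <- if (!is.null(targets)) targets[keep, , drop = FALSE]
         else data.frame(target = keep)
  out$log2ratio <- l2
  attr(out, "excluded") <- excl
  out
}

#' Number of segments in a profile
#' @param profile A `segment_profile`.
#' @return Integer segment count.
#' @export
n_segments <- function(profile) nrow(profile$segments)

#' @export
print.segment_profile <- function(x, ...) {
  cat(sprintf("segment_profile: %d segments over %d bins (%d chromosomes)\n",
              nrow(x$segments), nrow(x$grid), length(unique(x$grid$chrom))))
  print(head(x$segments, 10), ...)
  invisible(x)
}
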