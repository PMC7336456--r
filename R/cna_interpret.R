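# CNA calling, burden, aneuploidy classification, gene annotation and
# plasma--tissue concordance on segmented copy number profiles.

#' Copy-neutral level of a segment profile
#'
#' The neutral copy number state is the median of the per-bin segmented
#' values over all genomic bins (even bin counts use the midpoint of the
#' two central order statistics, the standard median convention).
#'
#' @param profile A `segment_profile`.
#' @return The neutral segmentation level.
#' @export
neutral_level <- function(profile) {
  .assert(inherits(profile, "segment_profile"), "need a segment_profile")
  .assert(length(profile$segvalue) > 0, "empty profile")
  median(profile$segvalue)
}

#' Call copy number alterations from a segment profile
#'
#' Any maximal run of consecutive bins within one chromosome sharing a
#' segmentation value that deviates from the neutral state by more than
#' `tol` becomes one CNA call; its length is the difference between the
#' run's first bin start and last bin end.  The default `tol` treats
#' post-MergeLevels segment values as exact levels (strict inequality up
#' to floating point); raise it for noisy inputs.
#'
#' @param profile A `segment_profile` (ideally after [merge_levels()]).
#' @param neutral Neutral level, default [neutral_level()] of the profile.
#' @param tol Absolute deviation below which a value counts as neutral.
#' @return `data.frame` of class `cna_calls`: chrom, start_bp, end_bp,
#'   length_bp, direction (amplification/deletion), seg_ratio, deviation,
#'   n_bins.
#' @export
call_cnas <- function(profile, neutral = neutral_level(profile),
                      tol = 1e-9) {
  .assert(inherits(profile, "segment_profile"), "need a segment_profile")
  g <- profile$grid
  v <- profile$segvalue
  out <- list()
  for (cc in unique(g$chrom)) {
    idx <- which(g$chrom == cc)
    dev <- v[idx] - neutral
    altered <- abs(dev) > tol
    if (!any(altered)) next
    # maximal runs of identical altered values
    r <- rle(paste0(altered, "|", v[idx]))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$lengths)) {
      if (!altered[starts[k]]) next
      gi <- idx[starts[k]:ends[k]]
      val <- v[gi[1]]
      out[[length(out) + 1L]] <- data.frame(
        chrom = cc, start_bp = g$start[gi[1]], end_bp = g$end[gi[length(gi)]],
        length_bp = g$end[gi[length(gi)]] - g$start[gi[1]],
        direction = if (val > neutral) "amplification" else "deletion",
        seg_ratio = val, deviation = val - neutral,
        n_bins = length(gi), stringsAsFactors = FALSE)
    }
  }
  calls <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start_bp = numeric(),
               end_bp = numeric(), length_bp = numeric(),
               direction = character(), seg_ratio = numeric(),
               deviation = numeric(), n_bins = integer(),
               stringsAsFactors = FALSE)
  class(calls) <- c("cna_calls", "data.frame")
  calls
}

#' Count CNAs above a deviation baseline
#'
#' @param calls Output of [call_cnas()].
#' @param baseline Minimum absolute deviation from the neutral level for a
#'   call to count (default 0.03, the aneuploidy deviation gate).
#' @return Integer CNA burden.
#' @export
cna_burden <- function(calls, baseline = 0.03) {
  .assert(baseline >= 0, "baseline must be >= 0")
  if (nrow(calls) == 0) return(0L)
  sum(abs(calls$deviation) >= baseline)
}

#' Thresholds for aneuploid/diploid classification
#'
#' @param seg_high Segment count above which a deviating profile is
#'   aneuploid outright (default 45).
#' @param seg_low Lower bound of the intermediate segment-count band
#'   (default 25).
#' @param deviation_min Minimum absolute deviation of any segment mean
#'   from the median segmentation value (default 0.03).
#' @param large_segment_bp Span qualifying as a "large segment" in the
#'   intermediate band (default 10 Mb).
#' @param high_value_dev Deviation qualifying as a "high segmentation
#'   value" in the intermediate band (default 0.10).
#' @return List of class `ploidy_thresholds`.
#' @export
ploidy_thresholds <- function(seg_high = 45L, seg_low = 25L,
                              deviation_min = 0.03,
                              large_segment_bp = 1e7,
                              high_value_dev = 0.10) {
  .assert(seg_low < seg_high, "seg_low must be < seg_high")
  .assert(deviation_min > 0, "deviation_min must be > 0")
  structure(list(seg_high = seg_high, seg_low = seg_low,
                 deviation_min = deviation_min,
                 large_segment_bp = large_segment_bp,
                 high_value_dev = high_value_dev),
            class = "ploidy_thresholds")
}

#' Classify a copy number profile as aneuploid or diploid
#'
#' A profile is aneuploid when it contains a large number of segments
#' (more than `seg_high`) together with a deviation from the median
#' segmentation value above `deviation_min`; a profile with an
#' intermediate segment count (`seg_low` to `seg_high` inclusive) is
#' aneuploid when it additionally shows a deviating segment of large span
#' (at least `large_segment_bp`) or a high segmentation deviation (at
#' least `high_value_dev`).  All other profiles are diploid.  The
#' deviation statistic is the maximum absolute difference between a
#' segment mean and the median per-bin segmentation value.
#'
#' @param profile A `segment_profile`.
#' @param thresholds A [ploidy_thresholds()] object.
#' @return List of class `ploidy_call`: `label` ("aneuploid"/"diploid"),
#'   `n_segments`, `max_abs_deviation`, `supporting_rule` (one of
#'   `high_seg_count`, `intermediate_with_support`, `diploid_default`).
#' @export
classify_ploidy <- function(profile, thresholds = ploidy_thresholds()) {
  .assert(inherits(profile, "segment_profile"), "need a segment_profile")
  segs <- profile$segments
  med <- median(profile$segvalue)
  dev <- abs(segs$mean_ratio - med)
  nseg <- nrow(segs)
  maxdev <- max(dev)
  deviating <- dev > thresholds$deviation_min
  label <- "diploid"; rule <- "diploid_default"
  if (nseg > thresholds$seg_high && maxdev > thresholds$deviation_min) {
    label <- "aneuploid"; rule <- "high_seg_count"
  } else if (nseg >= thresholds$seg_low && nseg <= thresholds$seg_high &&
             maxdev > thresholds$deviation_min) {
    span <- segs$end_bp - segs$start_bp
    support <- any(deviating & span >= thresholds$large_segment_bp) ||
      any(dev >= thresholds$high_value_dev)
    if (support) { label <- "aneuploid"; rule <- "intermediate_with_support" }
  }
  structure(list(label = label, n_segments = nseg,
                 max_abs_deviation = maxdev, supporting_rule = rule),
            class = "ploidy_call")
}

#' Annotate CNA calls with overlapping genes
#'
#' Interval intersection under 0-based half-open (BED) semantics; a gene
#' is reported for a call when they share at least 1 bp, so a gene whose
#' start equals the call end does not overlap.
#'
#' @param calls Output of [call_cnas()].
#' @param genes `data.frame` with columns chrom, start, end, name
#'   (BED-style half-open coordinates).
#' @return The calls with a `genes` list-column (character vector of
#'   overlapping gene names per call).
#' @export
annotate_genes <- function(calls, genes) {
  .assert(all(c("chrom", "start", "end", "name") %in% names(genes)),
          "genes needs chrom/start/end/name columns")
  .assert(all(genes$end > genes$start), "malformed gene interval(s)")
  hits <- vector("list", nrow(calls))
  for (i in seq_len(nrow(calls))) hits[[i]] <- character(0)
  if (nrow(calls) > 0 && nrow(genes) > 0) {
    for (cc in unique(calls$chrom)) {
      ci <- which(calls$chrom == cc)
      gi <- which(genes$chrom == cc)
      if (!length(gi)) next
      # half-open -> 1-based closed for IRanges
      qr <- IRanges::IRanges(start = calls$start_bp[ci] + 1L,
                             end = calls$end_bp[ci])
      sr <- IRanges::IRanges(start = genes$start[gi] + 1L,
                             end = genes$end[gi])
      ov <- IRanges::findOverlaps(qr, sr, minoverlap = 1L)
      for (k in seq_along(ov)) {
        q <- ci[S4Vectors::queryHits(ov)[k]]
        s <- gi[S4Vectors::subjectHits(ov)[k]]
        hits[[q]] <- c(hits[[q]], genes$name[s])
      }
    }
  }
  calls$genes <- hits
  calls
}

#' Pearson correlation of two segment profiles on a shared bin grid
#'
#' @param profileA,profileB `segment_profile`s with identical bin grids.
#' @return Pearson correlation of the per-bin segmentation values, or
#'   `NA` (with a warning) when either profile has zero variance.
#' @export
plasma_tissue_correlation <- function(profileA, profileB) {
  .assert(inherits(profileA, "segment_profile") &&
            inherits(profileB, "segment_profile"),
          "need two segment_profiles")
  ga <- profileA$grid; gb <- profileB$grid
  .assert(nrow(ga) == nrow(gb) && all(ga$chrom == gb$chrom) &&
            all(ga$start == gb$start) && all(ga$end == gb$end),
          "profiles are on different bin grids")
  a <- profileA$segvalue; b <- profileB$segvalue
  if (sd(a) == 0 || sd(b) == 0) {
    warning("zero variance in a profile; correlation undefined")
    return(NA_real_)
  }
  cor(a, b)
}

#' Mutation concordance between two samples
#'
#' Percentage of shared mutations among all mutations seen in either
#' sample: `100 * |A intersect B| / |A union B|`.
#'
#' @param setA,setB Mutation keys: character vectors, or data frames with
#'   chrom/pos/ref/alt columns (keys are built from those four fields).
#' @return Concordance percentage in \[0, 100\], or `NA` when both sets
#'   are empty.
#' @export
mutation_concordance <- function(setA, setB) {
  key <- function(x) {
    if (is.data.frame(x)) {
      .assert(all(c("chrom", "pos", "ref", "alt") %in% names(x)),
              "mutation keys need chrom/pos/ref/alt")
      paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
    } else as.character(x)
  }
  a <- unique(key(setA)); b <- unique(key(setB))
  u <- union(a, b)
  if (length(u) == 0) return(NA_real_)
  100 * length(intersect(a, b)) / length(u)
}
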