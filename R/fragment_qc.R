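# cfDNA fragment-size quality control: size-gated concentration,
# pass/fail, and nucleosome-peak detection.

#' Fragment QC configuration
#'
#' Concentration and size statistics are gated on fragments within
#' `[gate_low_bp, gate_high_bp]` (inclusive on both ends) to exclude
#' contaminating high molecular weight DNA; a sample passes QC when its
#' gated mass is at least `qc_threshold_ng`.  `size_select_max_bp`
#' records the upstream size-selection cutoff.
#'
#' @param gate_low_bp,gate_high_bp QC gate in bp (defaults 100 and 700).
#' @param qc_threshold_ng Minimum gated mass in ng (default 2.0,
#'   inclusive).
#' @param size_select_max_bp Library size-selection limit (default 1000).
#' @return List of class `qc_config`.
#' @export
qc_config <- function(gate_low_bp = 100L, gate_high_bp = 700L,
                      qc_threshold_ng = 2.0, size_select_max_bp = 1000L) {
  .assert(gate_low_bp < gate_high_bp, "gate_low must be < gate_high")
  .assert(gate_high_bp <= size_select_max_bp,
          "gate_high must be <= size_select_max")
  .assert(qc_threshold_ng >= 0, "qc_threshold_ng must be >= 0")
  structure(list(gate_low_bp = gate_low_bp, gate_high_bp = gate_high_bp,
                 qc_threshold_ng = qc_threshold_ng,
                 size_select_max_bp = size_select_max_bp),
            class = "qc_config")
}

#' Compute cfDNA quality-control metrics
#'
#' Mass and size statistics are computed only over fragments inside the
#' QC gate; a sample with no gated fragments gets zero metrics and fails
#' QC.
#'
#' @param sizes Fragment lengths in bp (non-empty).
#' @param per_fragment_mass Mass in ng per fragment; a scalar is
#'   recycled, `NULL` derives mass from fragment length via
#'   [fragment_mass_ng()].
#' @param config A [qc_config()].
#' @return List of class `qc_metrics`: `total_mass_ng`, `mean_size_bp`,
#'   `mode_size_bp`, `peaks` (from [detect_peaks()] on the gated sizes,
#'   `NULL` if too few fragments), `pass_qc`, `n_gated`.
#' @export
compute_qc <- function(sizes, per_fragment_mass = NULL,
                       config = qc_config()) {
  .assert(length(sizes) > 0, "sizes must be non-empty")
  if (is.null(per_fragment_mass)) per_fragment_mass <- fragment_mass_ng(sizes)
  mass <- rep_len(per_fragment_mass, length(sizes))
  gated <- sizes >= config$gate_low_bp & sizes <= config$gate_high_bp
  if (!any(gated)) {
    return(structure(list(total_mass_ng = 0, mean_size_bp = 0,
                          mode_size_bp = 0, peaks = NULL, pass_qc = FALSE,
                          n_gated = 0L), class = "qc_metrics"))
  }
  gs <- sizes[gated]
  total <- sum(mass[gated])
  peaks <- if (length(gs) >= 100) detect_peaks(gs) else NULL
  mode_bp <- if (!is.null(peaks) && nrow(peaks) > 0)
    peaks$location[which.max(peaks$height)]
  else as.numeric(names(which.max(table(round(gs)))))
  structure(list(total_mass_ng = total, mean_size_bp = mean(gs),
                 mode_size_bp = mode_bp, peaks = peaks,
                 pass_qc = total >= config$qc_threshold_ng,
                 n_gated = sum(gated)),
            class = "qc_metrics")
}

#' Mass of DNA fragments in nanograms
#'
#' `size_bp * 1.096e-12 ng/bp * mass_scale`, where `mass_scale` is the
#' number of physical fragments each observation stands for (simulated
#' samples subsample the real fragment population; only relative masses
#' matter for QC thresholds).
#'
#' @param sizes Fragment lengths (bp).
#' @param mass_scale Physical fragments per observation (default 2e5).
#' @return Vector of per-fragment masses (ng).
#' @export
fragment_mass_ng <- function(sizes, mass_scale = 2e5) {
  sizes * 1.096e-12 * mass_scale
}

#' Detect peaks in a fragment-size distribution
#'
#' Builds a fixed-width histogram and reports local maxima whose
#' prominence (height above the deepest flanking valley inside a local
#' window) exceeds `min_prominence` of the tallest bin.  Mono-nucleosomal
#' cfDNA yields a single peak; DNA protected by two or three nucleosomes
#' adds peaks near twice and three times the primary mode, which are
#' flagged in the `harmonics` attribute when they fall within
#' `harmonic_tol_bp` of those positions.
#'
#' @param sizes Fragment lengths in bp (at least 100 fragments).
#' @param bin_width_bp Histogram bin width (default 5 bp).
#' @param min_prominence Minimum prominence as a fraction of the maximum
#'   bin height (default 0.05).
#' @param window_bins Half-width (in bins) of the neighbourhood used for
#'   the local-maximum and prominence checks (default 10).
#' @param harmonic_tol_bp Tolerance for di-/tri-nucleosome annotation
#'   (default 15 bp).
#' @return `data.frame` with `location` (bin center, bp) and `height`
#'   (bin count), sorted by location; attribute `harmonics` is a logical
#'   pair (di, tri).
#' @export
detect_peaks <- function(sizes, bin_width_bp = 5L, min_prominence = 0.05,
                         window_bins = 10L, harmonic_tol_bp = 15) {
  if (length(sizes) < 100)
    stop("insufficient data: need >= 100 fragments", call. = FALSE)
  .assert(bin_width_bp > 0, "bin_width_bp must be positive")
  breaks <- seq(floor(min(sizes) / bin_width_bp) * bin_width_bp,
                max(sizes) + bin_width_bp, by = bin_width_bp)
  h <- graphics::hist(sizes, breaks = breaks, plot = FALSE, right = FALSE)
  counts <- h$counts
  mids <- h$mids
  nmax <- max(counts)
  peaks <- integer(0)
  n <- length(counts)
  for (i in seq_len(n)) {
    lo <- max(1L, i - window_bins); hi <- min(n, i + window_bins)
    win <- counts[lo:hi]
    if (counts[i] < max(win)) next
    if (counts[i] == max(win) && i > lo &&
        which.max(win) != (i - lo + 1L)) next  # plateau: keep first bin
    prom <- counts[i] - min(win)
    if (prom >= min_prominence * nmax) peaks <- c(peaks, i)
  }
  out <- data.frame(location = mids[peaks], height = counts[peaks])
  out <- out[order(out$location), , drop = FALSE]
  rownames(out) <- NULL
  harmonics <- c(di = FALSE, tri = FALSE)
  if (nrow(out) >= 2) {
    primary <- out$location[which.max(out$height)]
    others <- setdiff(out$location, primary)
    harmonics["di"] <- any(abs(others - 2 * primary) <= harmonic_tol_bp)
    harmonics["tri"] <- any(abs(others - 3 * primary) <= harmonic_tol_bp)
  }
  attr(out, "harmonics") <- harmonics
  out
}

#' @export
print.qc_metrics <- function(x, ...) {
  cat(sprintf(paste0("cfDNA QC: %.3g ng gated mass, mean size %.1f bp, ",
                     "mode %.0f bp, %s\n"),
              x$total_mass_ng, x$mean_size_bp, x$mode_size_bp,
              if (x$pass_qc) "PASS" else "FAIL"))
  invisible(x)
}
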