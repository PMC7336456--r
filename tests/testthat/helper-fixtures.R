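# Fixtures are built in code; nothing is stored on disk.

# simple single-chromosome grid with equal-width bins
make_grid <- function(n_bins, bin_bp = 220000, chrom = "chr1") {
  s <- seq(0, by = bin_bp, length.out = n_bins)
  bin_grid(rep(chrom, n_bins), s, s + bin_bp)
}

# a segment_profile built directly from per-segment (mean, n_bins) specs,
# optionally spread over several chromosomes
make_profile <- function(means, n_bins_each, bin_bp = 1e6,
                         chrom = rep("chr1", length(means))) {
  stopifnot(length(means) == length(n_bins_each),
            length(chrom) == length(means))
  segval <- rep(means, n_bins_each)
  cc <- rep(chrom, n_bins_each)
  start <- unlist(lapply(unique(cc), function(c_)
    seq(0, by = bin_bp, length.out = sum(cc == c_))))
  counts <- bin_grid(cc, start, start + bin_bp)
  counts$count <- 1
  ends_local <- lapply(unique(cc), function(c_) {
    n_by_seg <- n_bins_each[chrom == c_]
    as.integer(cumsum(n_by_seg))
  })
  names(ends_local) <- unique(cc)
  plasmaTrace:::.profile_from_ends(counts, segval, ends_local)
}

# minimal hand-built clone truth: one clone tree with explicit payloads
make_truth <- function(prevalence, parents, cna_payload = NULL,
                       snv = NULL) {
  K <- nrow(prevalence)
  ids <- paste0("C", seq_len(K))
  rownames(prevalence) <- ids
  if (is.null(cna_payload))
    cna_payload <- setNames(rep(list(NULL), K), ids)
  if (is.null(snv))
    snv <- data.frame(chrom = "chr1", pos = 1e6, ref = "A", alt = "T",
                      multiplicity = 1L, clone_id = "C1",
                      gene = "GENE1", sift = 0.5, polyphen = 0.5,
                      exonic_class = "non-synonymous",
                      stringsAsFactors = FALSE)
  structure(list(
    clones = data.frame(clone_id = ids,
                        parent_id = vapply(parents, function(p)
                          if (p == 0) "root" else ids[p], character(1)),
                        stringsAsFactors = FALSE),
    prevalence = prevalence, cna_payload = cna_payload,
    snv_payload = NULL, snv_table = snv,
    scenario = "fixture", seed = NA, genome = default_genome()),
    class = "clone_truth")
}

# engineered 20-record table exercising every branch of the filter
# cascade (status tags, the 0.06/0.07 VAF boundary, the normal-depth
# 80 vs 200 branches, annotation combinations)
make_filter_fixture <- function() {
  variant_records(
    chrom = rep("chr1", 20), pos = seq(1000, by = 1000, length.out = 20),
    ref = c(rep("A", 15), "AT", "G", "AT", "C", "T"),
    alt = c(rep("G", 15), "A", "GT", "GC", "T", "A"),
    filter_status = c("PASS", "germline_risk", "clustered_events",
                      "PASS;clustered_events", "", rep("PASS", 15)),
    plasma_depth = rep(100L, 20),
    plasma_alt = c(10L, 10L, 10L, 10L, 10L,
                   6L, 7L, 8L, 0L, 50L,       # VAF 0.06 / 0.07 boundary
                   rep(20L, 10)),
    normal_depth = c(rep(120L, 10),
                     80L, 80L, 80L, 200L, 200L, 200L,
                     rep(150L, 4)),
    normal_alt = c(rep(0L, 10),
                   3L, 2L, 0L,                # lowdepth: >2 removed
                   3L, 2L, 0L,                # highdepth: VAF .015/.01/0
                   rep(0L, 4)),
    gene = paste0("G", 1:20),
    sift = c(rep(0.5, 16), 0.01, 0.01, 0.05, NA),
    polyphen = c(rep(0.5, 16), 0.95, 0.5, 0.95, 0.95),
    exonic_class = c(rep("non-synonymous", 12), rep("synonymous", 5),
                     rep("intronic", 3)))
}

# independent brute-force evaluation of the three filter rules
brute_force_filter <- function(rec, cfg = filter_config()) {
  status_ok <- vapply(strsplit(rec$filter_status, ";", fixed = TRUE),
                      function(s) any(s %in% c("PASS", cfg$germline_tag)),
                      logical(1))
  status_ok[is.na(rec$filter_status) | !nzchar(trimws(rec$filter_status))] <-
    FALSE
  vaf_ok <- rec$plasma_depth > 0 &
    rec$plasma_alt / rec$plasma_depth >= cfg$vaf_min_plasma
  norm_ok <- ifelse(rec$normal_depth < cfg$normal_depth_cut,
                    rec$normal_alt <= cfg$normal_alt_max_lowdepth,
                    rec$normal_alt / rec$normal_depth <=
                      cfg$normal_vaf_max_highdepth)
  status_ok & vaf_ok & norm_ok
}

mut_key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
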