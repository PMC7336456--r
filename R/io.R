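# Readers and writers for the plain-text formats the pipeline consumes
# and produces: BED bin grids and gene lists, TSV bin counts, SEG
# segment tables (IGV dialect), VCF variant tables, and simulator
# sidecars.

#' Read a BED file (bin grid or gene list)
#'
#' 0-based half-open intervals; a 4th column, when present, is taken as
#' the feature name.  Malformed lines raise an error carrying the line
#' number.
#'
#' @param path BED file path.
#' @return `data.frame` with chrom/start/end (and `name` if present).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 3)
  if (length(bad))
    stop(sprintf("malformed BED line %d: fewer than 3 fields", bad[1]),
         call. = FALSE)
  start <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3)))
  bad <- which(is.na(start) | is.na(end) | end <= start)
  if (length(bad))
    stop(sprintf("malformed BED line %d: bad coordinates", bad[1]),
         call. = FALSE)
  out <- data.frame(chrom = vapply(parts, `[`, "", 1),
                    start = start, end = end, stringsAsFactors = FALSE)
  if (all(vapply(parts, length, integer(1)) >= 4))
    out$name <- vapply(parts, `[`, "", 4)
  out
}

#' Write bin counts as TSV (chrom, start, end, count, ...)
#' @param counts A `bin_counts` object.
#' @param path Output path.
#' @export
write_bin_tsv <- function(counts, path) {
  write.table(as.data.frame(counts), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read bin counts from TSV
#' @param path TSV with chrom/start/end/count columns.
#' @return A `bin_counts` object.
#' @export
read_bin_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  .assert(all(c("chrom", "start", "end", "count") %in% names(df)),
          "bin TSV needs chrom/start/end/count columns")
  out <- bin_counts(bin_grid(df$chrom, df$start, df$end), df$count)
  for (extra in setdiff(names(df), names(out))) out[[extra]] <- df[[extra]]
  out
}

#' Write a segment profile as a SEG file
#'
#' IGV SEG dialect: 1-based inclusive coordinates (internal processing
#' is 0-based half-open; the conversion happens here).
#'
#' @param profile A `segment_profile`.
#' @param path Output path.
#' @param sample_id Sample name for the first column.
#' @export
write_seg <- function(profile, path, sample_id = "sample") {
  s <- profile$segments
  out <- data.frame(ID = sample_id, chrom = s$chrom,
                    loc.start = s$start_bp + 1, loc.end = s$end_bp,
                    num.mark = s$n_bins, seg.mean = s$mean_ratio)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SEG file back into segment form
#' @param path SEG file (as written by [write_seg()]).
#' @return `data.frame` with chrom, start_bp, end_bp (0-based half-open),
#'   n_bins, mean_ratio, sample.
#' @export
read_seg <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  data.frame(sample = df$ID, chrom = df$chrom, start_bp = df$loc.start - 1,
             end_bp = df$loc.end, n_bins = df$num.mark,
             mean_ratio = df$seg.mean, stringsAsFactors = FALSE)
}

#' Write a variant table as VCF
#'
#' Minimal VCFv4.2 writer with plasma and matched-normal sample columns
#' (GT:AD:DP) and annotation INFO keys (GENE, SIFT, POLYPHEN,
#' EXONIC_CLASS).
#'
#' @param records A `variant_records` table.
#' @param path Output path.
#' @param plasma_name,normal_name Sample column names.
#' @export
write_variant_vcf <- function(records, path, plasma_name = "PLASMA",
                              normal_name = "NORMAL") {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene\">",
           "##INFO=<ID=SIFT,Number=1,Type=Float,Description=\"SIFT score\">",
           paste0("##INFO=<ID=POLYPHEN,Number=1,Type=Float,",
                  "Description=\"POLYPHEN score\">"),
           paste0("##INFO=<ID=EXONIC_CLASS,Number=1,Type=String,",
                  "Description=\"Exonic class\">"),
           paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                  "Description=\"Genotype\">"),
           paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
                  "Description=\"Allelic depths\">"),
           paste0("##FORMAT=<ID=DP,Number=1,Type=Integer,",
                  "Description=\"Read depth\">"),
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", plasma_name, normal_name, sep = "\t"))
  info <- sprintf("GENE=%s;SIFT=%s;POLYPHEN=%s;EXONIC_CLASS=%s",
                  ifelse(is.na(records$gene), ".", records$gene),
                  ifelse(is.na(records$sift), ".", records$sift),
                  ifelse(is.na(records$polyphen), ".", records$polyphen),
                  ifelse(is.na(records$exonic_class), ".",
                         records$exonic_class))
  fmt <- function(alt, depth)
    sprintf("0/1:%d,%d:%d", depth - alt, alt, depth)
  filt <- ifelse(is.na(records$filter_status) |
                   !nzchar(records$filter_status), ".",
                 records$filter_status)
  rows <- paste(records$chrom, records$pos, ".", records$ref, records$alt,
                ".", filt, info, "GT:AD:DP",
                fmt(records$plasma_alt, records$plasma_depth),
                fmt(records$normal_alt, records$normal_depth), sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a somatic VCF into a variant record table
#'
#' Parses plasma and matched-normal genotype columns (allelic depths
#' from AD, total depth from DP or the AD sum) and annotation INFO keys.
#' Multi-allelic records are decomposed into one row per alt allele
#' before filtering.
#'
#' @param path VCF path.
#' @param plasma_name,normal_name Sample column names in the VCF.
#' @param info_keys Named list mapping record fields to INFO keys.
#' @return A `variant_records` table.
#' @export
read_variant_vcf <- function(path, plasma_name = "PLASMA",
                             normal_name = "NORMAL",
                             info_keys = list(gene = "GENE", sift = "SIFT",
                                              polyphen = "POLYPHEN",
                                              exonic_class = "EXONIC_CLASS")) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  .assert(all(c(plasma_name, normal_name) %in% colnames(vcf@gt)),
          "plasma/normal sample columns not found in VCF")
  ad_p <- vcfR::extract.gt(vcf, "AD")[, plasma_name]
  ad_n <- vcfR::extract.gt(vcf, "AD")[, normal_name]
  info_get <- function(key) {
    v <- vcfR::extract.info(vcf, key)
    if (is.null(v)) rep(NA_character_, nrow(fix)) else v
  }
  gene <- info_get(info_keys$gene)
  sift <- suppressWarnings(as.numeric(info_get(info_keys$sift)))
  polyphen <- suppressWarnings(as.numeric(info_get(info_keys$polyphen)))
  excl <- info_get(info_keys$exonic_class)

  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    adp <- suppressWarnings(as.integer(
      strsplit(ad_p[i], ",", fixed = TRUE)[[1]]))
    adn <- suppressWarnings(as.integer(
      strsplit(ad_n[i], ",", fixed = TRUE)[[1]]))
    for (a in seq_along(alts)) {
      pa <- if (length(adp) > a) adp[a + 1] else NA_integer_
      na_ <- if (length(adn) > a) adn[a + 1] else NA_integer_
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[a],
        filter_status = ifelse(is.na(fix$FILTER[i]) | fix$FILTER[i] == ".",
                               "", fix$FILTER[i]),
        plasma_depth = sum(adp, na.rm = TRUE), plasma_alt = pa,
        normal_depth = sum(adn, na.rm = TRUE), normal_alt = na_,
        gene = gene[i], sift = sift[i], polyphen = polyphen[i],
        exonic_class = excl[i], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("variant_records", "data.frame")
  out
}

#' Write simulator ground truth as a JSON sidecar
#' @param truth A `clone_truth`.
#' @param path Output path.
#' @export
write_truth_json <- function(truth, path) {
  prev <- as.data.frame(truth$prevalence)
  prev <- cbind(clone_id = rownames(prev), prev)
  rownames(prev) <- NULL
  obj <- list(clones = truth$clones,
              prevalence = prev,
              snv_table = truth$snv_table,
              cna_payload = lapply(truth$cna_payload, as.data.frame),
              scenario = truth$scenario, seed = truth$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
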