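# Post-caller somatic variant filter cascade, SNV/indel split,
# functional-significance flagging and mutation-burden summaries.

#' Somatic filter cascade configuration
#'
#' Thresholds of the post-caller filter cascade: plasma variants below
#' `vaf_min_plasma` allele frequency are removed; variants are removed
#' when the matched normal shows more than `normal_alt_max_lowdepth`
#' variant reads at below `normal_depth_cut` coverage, or more than
#' `normal_vaf_max_highdepth` allele frequency at or above that coverage
#' (depth exactly at the cut uses the high-depth VAF rule).  SIFT and
#' POLYPHEN thresholds flag functionally significant mutations.
#'
#' @param vaf_min_plasma Minimum retained plasma VAF (default 0.07;
#'   strictly lower VAFs are removed, the boundary is retained).
#' @param normal_depth_cut Depth separating the normal-filter branches
#'   (default 100).
#' @param normal_alt_max_lowdepth Maximum tolerated normal alt reads
#'   below the depth cut (default 2).
#' @param normal_vaf_max_highdepth Maximum tolerated normal VAF at/above
#'   the depth cut (default 0.01).
#' @param sift_max SIFT score strictly below which (default 0.05) and
#' @param polyphen_min POLYPHEN score strictly above which (default 0.85)
#'   a mutation is flagged functionally significant.
#' @param germline_tag Caller status string retained alongside `PASS`
#'   (default `"germline_risk"`).
#' @return List of class `filter_config`.
#' @export
filter_config <- function(vaf_min_plasma = 0.07, normal_depth_cut = 100L,
                          normal_alt_max_lowdepth = 2L,
                          normal_vaf_max_highdepth = 0.01,
                          sift_max = 0.05, polyphen_min = 0.85,
                          germline_tag = "germline_risk") {
  .assert(vaf_min_plasma >= 0 && vaf_min_plasma <= 1, "bad vaf_min_plasma")
  .assert(normal_vaf_max_highdepth >= 0 && normal_vaf_max_highdepth <= 1,
          "bad normal_vaf_max_highdepth")
  .assert(normal_alt_max_lowdepth >= 0, "bad normal_alt_max_lowdepth")
  structure(list(vaf_min_plasma = vaf_min_plasma,
                 normal_depth_cut = as.integer(normal_depth_cut),
                 normal_alt_max_lowdepth = as.integer(normal_alt_max_lowdepth),
                 normal_vaf_max_highdepth = normal_vaf_max_highdepth,
                 sift_max = sift_max, polyphen_min = polyphen_min,
                 germline_tag = germline_tag),
            class = "filter_config")
}

#' Construct a variant record table
#'
#' Canonical in-memory form of somatic variant calls: one row per
#' (position, alt allele) with plasma/normal allelic depths, the caller's
#' filter status, and annotation columns.
#'
#' @param chrom,pos,ref,alt Variant identity (`pos` 1-based, VCF
#'   convention).
#' @param filter_status Caller status string(s), `;`-separated sets
#'   allowed.
#' @param plasma_depth,plasma_alt,normal_depth,normal_alt Read counts.
#' @param gene,sift,polyphen,exonic_class Annotations (may be `NA`).
#' @return `data.frame` of class `variant_records`.
#' @export
variant_records <- function(chrom, pos, ref, alt, filter_status,
                            plasma_depth, plasma_alt,
                            normal_depth, normal_alt,
                            gene = NA_character_, sift = NA_real_,
                            polyphen = NA_real_,
                            exonic_class = NA_character_) {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   filter_status = as.character(filter_status),
                   plasma_depth = as.integer(plasma_depth),
                   plasma_alt = as.integer(plasma_alt),
                   normal_depth = as.integer(normal_depth),
                   normal_alt = as.integer(normal_alt),
                   gene = as.character(gene), sift = as.numeric(sift),
                   polyphen = as.numeric(polyphen),
                   exonic_class = as.character(exonic_class),
                   stringsAsFactors = FALSE)
  ok <- (df$plasma_alt <= df$plasma_depth) & (df$normal_alt <= df$normal_depth)
  .assert(all(ok | is.na(ok)), "alt counts exceed depths")
  class(df) <- c("variant_records", "data.frame")
  df
}

.vaf <- function(alt, depth) ifelse(depth > 0, alt / depth, NA_real_)

#' Retain caller-confident somatic calls
#'
#' Keeps records whose caller status set contains `PASS` (high
#' confidence) or the germline-risk tag (borderline somatic); everything
#' else is dropped with a reason code.
#'
#' @param records A `variant_records` table.
#' @param config A [filter_config()].
#' @return Surviving records; dropped rows (with `drop_reason`) in the
#'   `dropped` attribute.
#' @export
retain_caller_status <- function(records, config = filter_config()) {
  status <- strsplit(records$filter_status, ";", fixed = TRUE)
  missing_status <- is.na(records$filter_status) |
    !nzchar(trimws(records$filter_status))
  keep <- vapply(status, function(s)
    any(s %in% c("PASS", config$germline_tag)), logical(1))
  keep[missing_status] <- FALSE
  reason <- ifelse(missing_status, "missing_caller_status",
                   "caller_status_not_retained")
  .split_records(records, keep, reason)
}

#' Plasma variant-allele-frequency filter
#'
#' Removes variants whose plasma VAF is strictly below
#' `vaf_min_plasma` (default 0.07); the boundary VAF is retained.
#' Zero-plasma-depth records are dropped with their own reason code.
#'
#' @inheritParams retain_caller_status
#' @return Surviving records (dropped rows in the `dropped` attribute).
#' @export
apply_plasma_vaf_filter <- function(records, config = filter_config()) {
  vaf <- .vaf(records$plasma_alt, records$plasma_depth)
  no_depth <- records$plasma_depth <= 0
  keep <- !no_depth & vaf >= config$vaf_min_plasma
  reason <- ifelse(no_depth, "zero_plasma_depth", "plasma_vaf_below_min")
  .split_records(records, keep, reason)
}

#' Matched-normal contamination filter
#'
#' At normal depth below `normal_depth_cut`, removes records with more
#' than `normal_alt_max_lowdepth` variant reads in the normal; at or
#' above the cut, removes records whose normal VAF exceeds
#' `normal_vaf_max_highdepth`.
#'
#' @inheritParams retain_caller_status
#' @return Surviving records (dropped rows in the `dropped` attribute).
#' @export
apply_normal_filter <- function(records, config = filter_config()) {
  low <- records$normal_depth < config$normal_depth_cut
  nvaf <- .vaf(records$normal_alt, records$normal_depth)
  remove <- ifelse(low,
                   records$normal_alt > config$normal_alt_max_lowdepth,
                   nvaf > config$normal_vaf_max_highdepth)
  remove[is.na(remove)] <- FALSE
  reason <- ifelse(low, "normal_alt_reads_lowdepth", "normal_vaf_highdepth")
  .split_records(records, !remove, reason)
}

.split_records <- function(records, keep, reason) {
  dropped <- records[!keep, , drop = FALSE]
  if (nrow(dropped)) dropped$drop_reason <- reason[!keep]
  out <- records[keep, , drop = FALSE]
  attr(out, "dropped") <- dropped
  class(out) <- c("variant_records", "data.frame")
  out
}

#' Split variants into SNVs and indels
#'
#' A variant is an SNV iff both alleles are single bases; all other
#' variants (insertions, deletions, and equal-length multi-nucleotide
#' substitutions) fall in the indel bucket, since only two classes are
#' distinguished downstream.
#'
#' @param records A `variant_records` table.
#' @return List with elements `snvs` and `indels`.
#' @export
split_variant_classes <- function(records) {
  is_snv <- nchar(records$ref) == 1L & nchar(records$alt) == 1L
  list(snvs = records[is_snv, , drop = FALSE],
       indels = records[!is_snv, , drop = FALSE])
}

#' Flag functionally significant mutations
#'
#' A mutation is significant for impacting gene function iff
#' `sift < sift_max` (strict) and `polyphen > polyphen_min` (strict);
#' records missing either score are not flagged.
#'
#' @inheritParams retain_caller_status
#' @return The records with a logical `significant` column.
#' @export
flag_functional <- function(records, config = filter_config()) {
  sig <- !is.na(records$sift) & !is.na(records$polyphen) &
    records$sift < config$sift_max & records$polyphen > config$polyphen_min
  records$significant <- sig
  records
}

#' Exonic mutation burden
#'
#' @param records A `variant_records` table with `exonic_class`
#'   annotation (`synonymous`, `non-synonymous`, or other; records with
#'   other/missing classes are outside the exome scope).
#' @param scope `"all_exonic"` counts synonymous plus non-synonymous;
#'   `"nonsyn_only"` counts non-synonymous only.
#' @return Integer count.
#' @export
mutation_burden <- function(records, scope = c("all_exonic", "nonsyn_only")) {
  scope <- match.arg(scope)
  cls <- records$exonic_class
  if (scope == "all_exonic")
    sum(cls %in% c("synonymous", "non-synonymous"))
  else sum(cls %in% "non-synonymous")
}

#' Run the full somatic filter cascade
#'
#' Applies, in order: caller-status retention, the plasma VAF filter, and
#' the matched-normal filter.  Each rule depends only on the record's own
#' fields, so the survivor set is invariant under stage permutation; the
#' staged order fixes which reason a doubly-failing record is attributed
#' to (its first failure).
#'
#' @inheritParams retain_caller_status
#' @return List: `records` (survivors, with `significant` flags),
#'   `dropped` (with one `drop_reason` each) and `attrition`
#'   (`data.frame` of per-stage input/surviving counts).
#' @export
run_filter_cascade <- function(records, config = filter_config()) {
  stages <- list(caller_status = retain_caller_status,
                 plasma_vaf = apply_plasma_vaf_filter,
                 normal_reads = apply_normal_filter)
  dropped <- list()
  att <- data.frame(stage = character(), n_in = integer(),
                    n_out = integer(), stringsAsFactors = FALSE)
  cur <- records
  for (nm in names(stages)) {
    n_in <- nrow(cur)
    cur <- stages[[nm]](cur, config)
    dropped[[nm]] <- attr(cur, "dropped")
    att <- rbind(att, data.frame(stage = nm, n_in = n_in, n_out = nrow(cur),
                                 stringsAsFactors = FALSE))
  }
  attr(cur, "dropped") <- NULL
  list(records = flag_functional(cur, config),
       dropped = do.call(rbind, dropped),
       attrition = att)
}
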