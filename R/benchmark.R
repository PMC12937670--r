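#' Long-read-validated e-tSNV reference set parameters
#'
#' @param min_depth minimum long-read site depth (default 100).
#' @param min_variant_reads minimum main-variant reads (default 30).
#' @return list of class `tscs_refset_params`.
#' @export
reference_set_params <- function(min_depth = 100, min_variant_reads = 30) {
  stopifnot(min_depth > 0, min_variant_reads > 0)
  structure(list(min_depth = min_depth,
                 min_variant_reads = min_variant_reads),
            class = "tscs_refset_params")
}

benchmark_result <- function(metric, numerator, denominator) {
  data.frame(metric = metric, numerator = numerator,
             denominator = denominator,
             value = if (denominator > 0) numerator / denominator
                     else NA_real_,
             stringsAsFactors = FALSE)
}

#' Recognition sensitivity for g-tSNVs
#'
#' The ratio of transcript-detected g-tSNVs to the expressed genomic SNVs:
#' genomic calls inside the coding mask that are covered by both the
#' genomic and the transcriptomic sequencing data. Matching is
#' allele-exact.
#'
#' @param transcript_g_calls transcript-level g-class calls (table or key
#'   vector).
#' @param genomic_calls genomic call table.
#' @param coding_mask interval table (`chrom`, `start`, `end`) of coding
#'   regions.
#' @param dna_track,rna_track depth tracks; a position is covered when its
#'   depth is at least `min_cov`. `NULL` means unconditionally covered.
#' @param min_cov coverage threshold (default 1).
#' @return one-row data frame (`metric`, `numerator`, `denominator`,
#'   `value`).
#' @export
rs_g <- function(transcript_g_calls, genomic_calls, coding_mask,
                 dna_track = NULL, rna_track = NULL, min_cov = 1) {
  in_mask <- in_intervals(genomic_calls, coding_mask)
  covered <- rep(TRUE, nrow(genomic_calls))
  if (!is.null(dna_track)) {
    covered <- covered & depth_at(dna_track, genomic_calls$chrom,
                                  genomic_calls$pos) >= min_cov
  }
  if (!is.null(rna_track)) {
    covered <- covered & depth_at(rna_track, genomic_calls$chrom,
                                  genomic_calls$pos) >= min_cov
  }
  expressed <- genomic_calls[in_mask & covered, , drop = FALSE]
  tkeys <- if (is.character(transcript_g_calls)) transcript_g_calls
           else variant_key_df(transcript_g_calls)
  detected <- sum(variant_key_df(expressed) %in% tkeys)
  benchmark_result("rs_g", detected, nrow(expressed))
}

in_intervals <- function(calls, intervals) {
  count_in_intervals_membership(calls, intervals)
}

count_in_intervals_membership <- function(calls, intervals) {
  if (nrow(calls) == 0) return(logical(0))
  if (nrow(intervals) == 0) return(rep(FALSE, nrow(calls)))
  q <- IRanges::IRanges(calls$pos + 1L, calls$pos + 1L)
  s <- IRanges::IRanges(intervals$start + 1L, intervals$end)
  hits <- IRanges::findOverlaps(q, s)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ok <- unique(qh[calls$chrom[qh] == intervals$chrom[sh]])
  seq_len(nrow(calls)) %in% ok
}

#' Long-read-validated e-tSNV reference set
#'
#' Sites whose long-read pileup reaches the depth and main-variant read
#' thresholds and whose allele-exact key is absent from the genomic call
#' set.
#'
#' @param lrs_pileup long-read pileup table.
#' @param genomic_calls genomic call table or key vector.
#' @param params [reference_set_params()].
#' @return character vector of reference keys.
#' @export
build_e_reference <- function(lrs_pileup, genomic_calls,
                              params = reference_set_params()) {
  if (nrow(lrs_pileup) == 0) return(character(0))
  pm <- pileup_site_metrics(lrs_pileup)
  keep <- !is.na(pm$main_alt) & pm$total >= params$min_depth &
    pm$alt_reads >= params$min_variant_reads
  keys <- variant_key(pm$chrom[keep], pm$pos[keep], pm$ref[keep],
                      pm$main_alt[keep])
  gkeys <- if (is.character(genomic_calls)) genomic_calls
           else variant_key_df(genomic_calls)
  setdiff(keys, gkeys)
}

#' Recognition sensitivity for e-tSNVs
#'
#' Recall of the long-read-validated reference set: the proportion of
#' reference e-tSNVs detected (allele-exact) by a tool's e-class calls.
#'
#' @param tool_e_calls e-class call table or key vector.
#' @param reference_keys keys from [build_e_reference()].
#' @return one-row benchmark data frame.
#' @export
rs_e <- function(tool_e_calls, reference_keys) {
  tkeys <- if (is.character(tool_e_calls)) tool_e_calls
           else variant_key_df(tool_e_calls)
  benchmark_result("rs_e", sum(reference_keys %in% tkeys),
                   length(reference_keys))
}

#' Directional overlap and Jaccard index of two call sets
#'
#' @param a,b call tables or key vectors.
#' @return data frame with `overlap_a_in_b` (|A∩B|/|A|), `overlap_b_in_a`,
#'   and `jaccard`.
#' @export
overlap_rate <- function(a, b) {
  ka <- unique(if (is.character(a)) a else variant_key_df(a))
  kb <- unique(if (is.character(b)) b else variant_key_df(b))
  inter <- length(intersect(ka, kb))
  uni <- length(union(ka, kb))
  data.frame(
    overlap_a_in_b = if (length(ka) > 0) inter / length(ka) else NA_real_,
    overlap_b_in_a = if (length(kb) > 0) inter / length(kb) else NA_real_,
    jaccard = if (uni > 0) inter / uni else NA_real_)
}

#' Spearman correlation of VAFs across platforms
#'
#' Standard rank correlation with average ranks for ties, for co-detected
#' sites measured on two platforms.
#'
#' @param vaf_a,vaf_b numeric VAF vectors of equal length.
#' @return Spearman's rho in `[-1, 1]`.
#' @export
vaf_spearman <- function(vaf_a, vaf_b) {
  stopifnot(length(vaf_a) == length(vaf_b))
  cor(vaf_a, vaf_b, method = "spearman")
}

#' VAF group tabulation
#'
#' Counts calls per VAF group. Default boundaries follow the five-group
#' convention `[0,0.1) [0.1,0.3) [0.3,0.5) [0.5,0.9) [0.9,1]`: half-open
#' bins with the last bin closed.
#'
#' @param vaf numeric VAF vector (or a call table with a `vaf` column).
#' @param boundaries increasing break points from 0 to 1.
#' @return data frame with `bin` and `count`.
#' @export
vaf_group_table <- function(vaf, boundaries = c(0, 0.1, 0.3, 0.5, 0.9, 1)) {
  if (is.data.frame(vaf)) vaf <- vaf$vaf
  vaf <- vaf[!is.na(vaf)]
  # right = FALSE gives half-open bins; include.lowest closes the last one
  cuts <- cut(vaf, breaks = boundaries, right = FALSE,
              include.lowest = TRUE)
  tab <- table(cuts)
  data.frame(bin = names(tab), count = as.integer(tab),
             stringsAsFactors = FALSE)
}
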