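#' Truth-set construction parameters
#'
#' Thresholds for the two long-read-anchored phases: candidate SNVs are
#' long-read calls in regions of long-read depth at least
#' `lrs_region_min_reads` with at least `lrs_site_min_reads` supporting
#' reads; short-read calls in regions of long-read depth at least
#' `lrs_false_min_coverage` that the long-read caller did not call at all
#' are labelled false.
#'
#' @param lrs_region_min_reads minimum long-read depth defining a
#'   high-confidence region (default 10).
#' @param lrs_site_min_reads minimum supporting reads per candidate site
#'   (default 5).
#' @param lrs_false_min_coverage minimum long-read depth for the false
#'   label (default 100).
#' @param site_reads_mode whether `lrs_site_min_reads` counts
#'   alternate-supporting reads (`"alt"`, default) or total site depth
#'   (`"total"`).
#' @return list of class `tscs_truthset_params`.
#' @export
truthset_params <- function(lrs_region_min_reads = 10,
                            lrs_site_min_reads = 5,
                            lrs_false_min_coverage = 100,
                            site_reads_mode = c("alt", "total")) {
  stopifnot(lrs_region_min_reads > 0, lrs_site_min_reads > 0,
            lrs_false_min_coverage > lrs_region_min_reads)
  structure(list(lrs_region_min_reads = lrs_region_min_reads,
                 lrs_site_min_reads = lrs_site_min_reads,
                 lrs_false_min_coverage = lrs_false_min_coverage,
                 site_reads_mode = match.arg(site_reads_mode)),
            class = "tscs_truthset_params")
}

# Alternate-supporting reads of each record, from its allele depths.
alt_reads_of <- function(records) {
  ad <- as.matrix(records[, paste0("ad_", BASES)])
  ad[cbind(seq_len(nrow(records)), match(records$alt, BASES))]
}

#' Select long-read-anchored candidate SNVs
#'
#' Phase 1 of truth-set construction: a long-read call is a candidate when
#' it lies in a high-confidence region (long-read depth from the track, not
#' the VCF DP, at or above `lrs_region_min_reads`) and its supporting reads
#' reach `lrs_site_min_reads`.
#'
#' @param lrs_calls long-read variant table.
#' @param lrs_track long-read depth track.
#' @param params [truthset_params()].
#' @return character vector of allele-exact candidate keys
#'   (see [variant_key()]).
#' @export
select_candidates <- function(lrs_calls, lrs_track,
                              params = truthset_params()) {
  if (nrow(lrs_calls) == 0) return(character(0))
  region_depth <- depth_at(lrs_track, lrs_calls$chrom, lrs_calls$pos)
  support <- if (params$site_reads_mode == "alt") {
    alt_reads_of(lrs_calls)
  } else {
    lrs_calls$depth
  }
  keep <- region_depth >= params$lrs_region_min_reads &
    !is.na(support) & support >= params$lrs_site_min_reads
  unique(variant_key_df(lrs_calls[keep, , drop = FALSE]))
}

#' Label short-read calls as true, false or unlabeled
#'
#' Phase 2: a short-read call is `true` when its allele-exact key is among
#' the long-read candidates; `false` when the long-read platform covers its
#' position at or above `lrs_false_min_coverage` yet called no variant
#' there (any long-read call at the position, even with a different
#' alternate allele, blocks the false label); `unlabeled` otherwise. A
#' candidate match always wins over the false rule.
#'
#' @param srs_calls short-read variant table.
#' @param candidates candidate key vector from [select_candidates()].
#' @param lrs_track long-read depth track.
#' @param lrs_call_positions data frame with `chrom`, `pos` of all long-read
#'   calls (pre-filter), used position-wise.
#' @param params [truthset_params()].
#' @return the `srs_calls` table with an added `label` column
#'   (`"true"`/`"false"`/`"unlabeled"`); the three labels partition the
#'   input.
#' @export
label_calls <- function(srs_calls, candidates, lrs_track,
                        lrs_call_positions, params = truthset_params()) {
  out <- srs_calls
  if (nrow(out) == 0) { out$label <- character(0); return(out) }
  key <- variant_key_df(out)
  lrs_depth <- depth_at(lrs_track, out$chrom, out$pos)
  pos_key <- paste0(out$chrom, ":", out$pos)
  lrs_pos_key <- character(0)
  if (!is.null(lrs_call_positions) && nrow(lrs_call_positions) > 0) {
    lrs_pos_key <- paste0(lrs_call_positions$chrom, ":",
                          lrs_call_positions$pos)
  }
  is_true <- key %in% candidates
  is_false <- !is_true & lrs_depth >= params$lrs_false_min_coverage &
    !(pos_key %in% lrs_pos_key)
  out$label <- ifelse(is_true, "true", ifelse(is_false, "false",
                                              "unlabeled"))
  out
}

#' Truth-set composition report
#'
#' @param labeled output of [label_calls()].
#' @return one-row data frame with counts per label and the true/(true +
#'   false) class balance.
#' @export
truthset_report <- function(labeled) {
  n_true <- sum(labeled$label == "true")
  n_false <- sum(labeled$label == "false")
  n_unlab <- sum(labeled$label == "unlabeled")
  data.frame(n = nrow(labeled), n_true = n_true, n_false = n_false,
             n_unlabeled = n_unlab,
             balance = if (n_true + n_false > 0)
               n_true / (n_true + n_false) else NA_real_)
}
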