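#' Feature vector definition
#'
#' The fixed, ordered 21-feature layout: 12 VCF-level features describing
#' call confidence, allele evidence and site-level alignment-bias
#' annotations, plus 9 exon-context features describing the uniformity and
#' call context of the harboring exon. Trained model bundles embed this
#' list, so models are self-describing.
#'
#' @return character vector of the 21 feature names, in column order.
#' @export
feature_names <- function() {
  c("qual", "depth", "vaf", "cps", "alt_reads", "ref_reads",
    "mapping_quality", "mq0_fraction", "variant_distance_bias",
    "read_position_bias_z", "base_quality_bias_z",
    "mapping_quality_bias_z",
    "exon_rsd", "exon_snv_count", "exon_rank_top", "exon_mean_depth",
    "exon_coverage_fraction", "exon_length", "exon_snv_density",
    "site_depth_ratio", "exon_cps_mean")
}

#' VCF-level features
#'
#' The 12 per-site features taken from a variant record: QUAL, depth, VAF
#' and CPS (computed from the four-base allele depths through the same code
#' path as [site_vaf()]/[site_cps()]), alternate/reference read counts, and
#' the six alignment annotations (MQ, MQ0 fraction, variant distance bias,
#' read-position/base-quality/mapping-quality bias z-scores). Absent inputs
#' yield `NA` — an explicit imputation marker resolved by
#' [build_matrix()], never a silent zero.
#'
#' @param records variant table.
#' @param pileup optional pileup table; its counts are used for records
#'   whose own allele depths are absent.
#' @return data frame with the 12 VCF-level feature columns, one row per
#'   record.
#' @export
vcf_features <- function(records, pileup = NULL) {
  n <- nrow(records)
  ad <- as.matrix(records[, paste0("ad_", BASES)])
  colnames(ad) <- BASES
  if (!is.null(pileup) && nrow(pileup) > 0) {
    absent <- rowSums(!is.na(ad)) == 0
    if (any(absent)) {
      m <- match(paste0(records$chrom, ":", records$pos),
                 paste0(pileup$chrom, ":", pileup$pos))
      fill <- which(absent & !is.na(m))
      ad[fill, ] <- as.matrix(pileup[m[fill], BASES])
    }
  }
  have_ad <- rowSums(!is.na(ad)) > 0
  ad0 <- ad
  ad0[is.na(ad0)] <- 0
  st <- allele_stats(ad0, records$ref)
  alt_idx <- match(records$alt, BASES)
  ref_idx <- match(records$ref, BASES)
  out <- data.frame(
    qual = records$qual,
    depth = as.numeric(records$depth),
    vaf = ifelse(have_ad, st$vaf, NA_real_),
    cps = ifelse(have_ad, st$cps, NA_real_),
    alt_reads = ifelse(have_ad, ad0[cbind(seq_len(n), alt_idx)], NA_real_),
    ref_reads = ifelse(have_ad, ad0[cbind(seq_len(n), ref_idx)], NA_real_),
    mapping_quality = records$mq,
    mq0_fraction = records$mq0f,
    variant_distance_bias = records$vdb,
    read_position_bias_z = records$rpbz,
    base_quality_bias_z = records$bqbz,
    mapping_quality_bias_z = records$mqbz)
  rownames(out) <- NULL
  out
}

#' Exon-context index
#'
#' Precomputes per-exon statistics used by [exon_context_features()]:
#' depth statistics and RSD from the platform's depth track, call counts
#' and mean CPS of calls per exon, and top-decile-by-mean-depth membership.
#'
#' @param track depth track of the calling platform.
#' @param exons structural exon table ([structural_exons()]).
#' @param calls full variant call table of the platform (used for per-exon
#'   call counts and CPS context).
#' @param top_quantile quantile of mean depth above which `rank_top` is 1
#'   (default 0.9, i.e. top decile).
#' @return [exon_depth_stats()] output extended with `cps_mean` and
#'   `rank_top`.
#' @export
build_exon_index <- function(track, exons, calls, top_quantile = 0.9) {
  st <- exon_depth_stats(track, exons, calls = calls)
  cps_mean <- rep(NA_real_, nrow(st))
  if (nrow(calls) > 0) {
    ad <- as.matrix(calls[, paste0("ad_", BASES)])
    ad[is.na(ad)] <- 0
    call_cps <- allele_stats(ad, calls$ref)$cps
    idx <- assign_interval(calls, st)
    ok <- !is.na(idx) & !is.na(call_cps)
    if (any(ok)) {
      agg <- tapply(call_cps[ok], idx[ok], mean)
      cps_mean[as.integer(names(agg))] <- as.numeric(agg)
    }
  }
  st$cps_mean <- cps_mean
  thr <- quantile(st$mean_depth, top_quantile, na.rm = TRUE,
                  names = FALSE, type = 7)
  st$rank_top <- as.integer(!is.na(st$mean_depth) & st$mean_depth >= thr)
  st
}

# Map call positions to a single interval row; among overlapping intervals
# the one with the highest mean depth wins (deterministic, best-measured
# context). Returns NA for positions outside all intervals.
assign_interval <- function(calls, intervals) {
  out <- rep(NA_integer_, nrow(calls))
  if (nrow(calls) == 0 || nrow(intervals) == 0) return(out)
  q <- IRanges::IRanges(calls$pos + 1L, calls$pos + 1L)
  s <- IRanges::IRanges(intervals$start + 1L, intervals$end)
  hits <- IRanges::findOverlaps(q, s)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  same <- calls$chrom[qh] == intervals$chrom[sh]
  qh <- qh[same]; sh <- sh[same]
  if (length(qh) == 0) return(out)
  depth_rank <- intervals$mean_depth[sh]
  depth_rank[is.na(depth_rank)] <- -Inf
  ord <- order(qh, -depth_rank, sh)
  qh <- qh[ord]; sh <- sh[ord]
  first <- !duplicated(qh)
  out[qh[first]] <- sh[first]
  out
}

#' Exon-context features
#'
#' The 9 features describing the exon harboring each call: RSD, call count,
#' top-decile membership, mean depth, coverage fraction, length, call
#' density, the site's depth relative to the exon mean, and the mean CPS of
#' calls in the exon. Calls outside every exon get all nine features `NA`
#' and are flagged `intergenic`.
#'
#' @param records variant table.
#' @param exon_index output of [build_exon_index()].
#' @return data frame with the 9 exon-context feature columns plus a
#'   logical `intergenic` flag column (not part of the feature vector).
#' @export
exon_context_features <- function(records, exon_index) {
  idx <- assign_interval(records, exon_index)
  ex <- exon_index[ifelse(is.na(idx), 1L, idx), , drop = FALSE]
  na_row <- is.na(idx)
  out <- data.frame(
    exon_rsd = ifelse(na_row, NA_real_, ex$rsd),
    exon_snv_count = ifelse(na_row, NA_real_, as.numeric(ex$snv_count)),
    exon_rank_top = ifelse(na_row, NA_real_, as.numeric(ex$rank_top)),
    exon_mean_depth = ifelse(na_row, NA_real_, ex$mean_depth),
    exon_coverage_fraction = ifelse(na_row, NA_real_,
                                    ex$coverage_fraction),
    exon_length = ifelse(na_row, NA_real_, as.numeric(ex$length)),
    exon_snv_density = ifelse(na_row, NA_real_,
                              ex$snv_count / ex$length),
    site_depth_ratio = ifelse(na_row | is.na(ex$mean_depth) |
                                ex$mean_depth == 0, NA_real_,
                              records$depth / ex$mean_depth),
    exon_cps_mean = ifelse(na_row, NA_real_, ex$cps_mean))
  out$intergenic <- na_row
  rownames(out) <- NULL
  out
}

#' Assemble the full 21-column feature table
#'
#' @param records variant table.
#' @param exon_index [build_exon_index()] output.
#' @param pileup optional pileup for allele-depth fallback.
#' @return data frame with columns `key` (allele-exact variant key) then
#'   the 21 features of [feature_names()], plus `intergenic`.
#' @export
assemble_features <- function(records, exon_index, pileup = NULL) {
  vf <- vcf_features(records, pileup)
  ef <- exon_context_features(records, exon_index)
  out <- cbind(data.frame(key = variant_key_df(records),
                          stringsAsFactors = FALSE), vf,
               ef[, setdiff(names(ef), "intergenic")])
  names(out) <- c("key", feature_names())
  out$intergenic <- ef$intergenic
  out
}

#' Build the numeric training matrix
#'
#' Converts a feature table to a numeric matrix, replacing every `NA`
#' imputation marker by the per-feature median over non-missing values
#' (deterministic given the input; a feature with no observed value falls
#' back to 0). Imputation is idempotent: a matrix with no markers passes
#' through unchanged.
#'
#' @param features feature table from [assemble_features()] (any extra
#'   non-feature columns are ignored).
#' @param labels optional label vector aligned with rows (e.g. the `label`
#'   column of [label_calls()]).
#' @return list with `x` (numeric matrix, columns = [feature_names()]),
#'   `y` (labels or `NULL`), `keys`, and `medians` used for imputation.
#' @export
build_matrix <- function(features, labels = NULL) {
  x <- as.matrix(features[, feature_names()])
  mode(x) <- "numeric"
  medians <- apply(x, 2, function(col) {
    m <- median(col, na.rm = TRUE)
    if (is.na(m)) 0 else m
  })
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- medians[j]
  }
  keys <- if ("key" %in% names(features)) features$key else NULL
  rownames(x) <- NULL
  list(x = x, y = labels, keys = keys, medians = medians)
}
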