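#' Variant allele frequency and per-site consistency
#'
#' `site_vaf()` is the ratio of reads supporting the main variant (the
#' best-supported non-reference base, ties broken in A<C<G<T order) to the
#' total reads at the site. `site_cps()` — consistency of primary SNVs at a
#' site — is the ratio of main-variant reads to all variant-supporting
#' (non-reference) reads, so 1 means every variant read agrees on one
#' allele. Both are `NA` when undefined (no reads / no variant reads).
#'
#' @param counts named numeric vector of read counts with names among
#'   `A`, `C`, `G`, `T`.
#' @param ref reference base at the site.
#' @return a single value in `[0, 1]`, or `NA`.
#' @examples
#' site_vaf(c(A = 6, G = 4), "A")  # 0.4
#' site_cps(c(A = 10, G = 3, T = 1), "A")  # 0.75
#' @export
site_vaf <- function(counts, ref) {
  allele_stats(matrix(counts_vec(counts), nrow = 1,
                      dimnames = list(NULL, BASES)), ref)$vaf
}

#' @rdname site_vaf
#' @export
site_cps <- function(counts, ref) {
  allele_stats(matrix(counts_vec(counts), nrow = 1,
                      dimnames = list(NULL, BASES)), ref)$cps
}

counts_vec <- function(counts) {
  out <- setNames(numeric(4), BASES)
  out[names(counts)] <- counts
  out
}

# Vectorized core shared by coverage metrics and feature assembly.
# `mat` is an n x 4 matrix of counts in A,C,G,T order; `ref` a base vector.
allele_stats <- function(mat, ref) {
  stopifnot(ncol(mat) == 4)
  n <- nrow(mat)
  ref_idx <- match(ref, BASES)
  nonref <- mat
  nonref[cbind(seq_len(n), ref_idx)] <- -Inf
  main_idx <- max.col(nonref, ties.method = "first")  # A<C<G<T tie order
  main <- mat[cbind(seq_len(n), main_idx)]
  total <- rowSums(mat)
  nonref[nonref == -Inf] <- 0
  var_reads <- rowSums(nonref)
  vaf <- ifelse(total > 0 & var_reads > 0, main / total, NA_real_)
  cps <- ifelse(var_reads > 0, main / var_reads, NA_real_)
  list(main_alt = ifelse(var_reads > 0, BASES[main_idx], NA_character_),
       main_reads = main, ref_reads = mat[cbind(seq_len(n), ref_idx)],
       var_reads = var_reads, total = total, vaf = vaf, cps = cps)
}

#' Per-site VAF/CPS over a pileup table
#'
#' @param pileup data frame with columns `chrom`, `pos`, `ref` and count
#'   columns `A`, `C`, `G`, `T` (one row per site).
#' @return the pileup with added columns `main_alt`, `vaf`, `cps`,
#'   `alt_reads`, `total`.
#' @export
pileup_site_metrics <- function(pileup) {
  stopifnot_cols(pileup, c("ref", BASES), "pileup")
  st <- allele_stats(as.matrix(pileup[, BASES]), pileup$ref)
  pileup$main_alt <- st$main_alt
  pileup$vaf <- st$vaf
  pileup$cps <- st$cps
  pileup$alt_reads <- st$main_reads
  pileup$total <- st$total
  pileup
}

#' Per-exon depth statistics
#'
#' Computes, for each exon interval, the mean and population standard
#' deviation of depth over covered positions, the relative standard
#' deviation (RSD = sd/mean, the exon-level coverage-uniformity metric),
#' the coverage fraction (covered positions / exon length), and optionally
#' the number of variant calls falling in the exon.
#'
#' Positions absent from the track count against `coverage_fraction` but are
#' excluded from the mean/sd, so partial short-read coverage is not
#' conflated with low depth. Exons with no covered position get
#' `coverage_fraction = 0` and `NA` mean/sd/RSD.
#'
#' @param track depth track ([read_depth_track()]).
#' @param exons interval table with columns `chrom`, `start`, `end` (e.g.
#'   [structural_exons()] output); extra columns are carried through.
#' @param calls optional variant table; adds per-exon `snv_count`.
#' @return data frame: the exon columns plus `length`, `covered_positions`,
#'   `mean_depth`, `sd_depth`, `rsd`, `coverage_fraction`, `snv_count`.
#' @export
exon_depth_stats <- function(track, exons, calls = NULL) {
  stopifnot_cols(exons, c("chrom", "start", "end"), "exon table")
  n <- nrow(exons)
  mean_depth <- sd_depth <- rep(NA_real_, n)
  covered <- integer(n)
  for (ch in unique(exons$chrom)) {
    tr <- track[track$chrom == ch, , drop = FALSE]
    for (i in which(exons$chrom == ch)) {
      sel <- tr[tr$end > exons$start[i] & tr$start < exons$end[i], ,
                drop = FALSE]
      if (nrow(sel) == 0) next
      len <- pmin(sel$end, exons$end[i]) - pmax(sel$start, exons$start[i])
      npos <- sum(len)
      s1 <- sum(sel$depth * len)
      s2 <- sum(sel$depth^2 * len)
      covered[i] <- npos
      mean_depth[i] <- s1 / npos
      sd_depth[i] <- sqrt(pmax(s2 / npos - (s1 / npos)^2, 0))
    }
  }
  out <- exons
  out$length <- exons$end - exons$start
  out$covered_positions <- covered
  out$mean_depth <- mean_depth
  out$sd_depth <- sd_depth
  out$rsd <- ifelse(!is.na(mean_depth) & mean_depth > 0,
                    sd_depth / mean_depth, NA_real_)
  out$coverage_fraction <- covered / out$length
  if (!is.null(calls)) {
    out$snv_count <- count_in_intervals(calls, exons)
  }
  out
}

# Number of call positions falling in each interval (0-based half-open).
count_in_intervals <- function(calls, intervals) {
  out <- integer(nrow(intervals))
  if (nrow(calls) == 0 || nrow(intervals) == 0) return(out)
  q <- IRanges::IRanges(calls$pos + 1L, calls$pos + 1L)
  s <- IRanges::IRanges(intervals$start + 1L, intervals$end)
  hits <- IRanges::findOverlaps(q, s)
  same_chrom <- calls$chrom[S4Vectors::queryHits(hits)] ==
    intervals$chrom[S4Vectors::subjectHits(hits)]
  tab <- table(S4Vectors::subjectHits(hits)[same_chrom])
  out[as.integer(names(tab))] <- as.integer(tab)
  out
}

#' Platform contrast summary
#'
#' Bins per-exon statistics from two (or more) platforms into depth,
#' coverage-fraction and RSD classes for side-by-side comparison of
#' short-read versus long-read behaviour.
#'
#' @param stats_list named list of [exon_depth_stats()] outputs, one per
#'   platform.
#' @param depth_breaks,coverage_breaks,rsd_breaks bin edges (right-open,
#'   last bin closed).
#' @return data frame with columns `platform`, `metric`, `bin`, `count`,
#'   `fraction`; deterministic given inputs and invariant to row order.
#' @export
platform_contrast_summary <- function(stats_list,
                                      depth_breaks = c(0, 10, 50, 100, Inf),
                                      coverage_breaks = c(0, 0.5, 0.9,
                                                          0.999, 1),
                                      rsd_breaks = c(0, 0.1, 0.25, 0.5, Inf)) {
  stopifnot(is.list(stats_list), length(names(stats_list)) ==
              length(stats_list))
  one <- function(platform, st) {
    if (nrow(st) == 0) return(NULL)
    bin_tab <- function(metric, x, breaks) {
      x <- x[!is.na(x)]
      cuts <- cut(x, breaks = breaks, right = FALSE, include.lowest = TRUE)
      tab <- table(cuts)
      data.frame(platform = platform, metric = metric,
                 bin = names(tab), count = as.integer(tab),
                 fraction = if (sum(tab) > 0) as.numeric(tab) / sum(tab)
                            else 0,
                 stringsAsFactors = FALSE)
    }
    rbind(bin_tab("mean_depth", st$mean_depth, depth_breaks),
          bin_tab("coverage_fraction", st$coverage_fraction,
                  coverage_breaks),
          bin_tab("rsd", st$rsd, rsd_breaks))
  }
  out <- do.call(rbind, Map(one, names(stats_list), stats_list))
  if (is.null(out)) {
    out <- empty_df(list(platform = character(), metric = character(),
                         bin = character(), count = integer(),
                         fraction = numeric()))
  }
  rownames(out) <- NULL
  out
}
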