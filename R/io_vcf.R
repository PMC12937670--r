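#' Read SNVs from a VCF file
#'
#' Parses a VCF 4.x file into the package's variant table. Only single-base
#' substitutions are retained; multi-allelic rows are decomposed into one
#' record per alternate allele (sharing the site depth), and non-SNV rows
#' (indels, symbolic alleles) are skipped and counted.
#'
#' Coordinates are converted to the internal 0-based convention on read
#' (`pos = POS - 1`) and back on write. Per-allele read counts are taken from
#' the `AD4` INFO tag (counts for A,C,G,T as written by [write_vcf()]) when
#' present, else from the first sample's `AD` FORMAT field; records lacking
#' both carry `NA` allele depths (an explicit "absent" marker, imputed later
#' by [build_matrix()], never silently zero-filled).
#'
#' @param path VCF file (plain or gzipped).
#' @param platform platform tag stored on every record: `"SRS"`, `"LRS"` or
#'   `"DNA"` (or `NA`).
#' @param sample_id sample identifier stored on every record.
#' @param filters optional [quality_filter_params()]; when supplied, records
#'   are passed through [filter_records()] and only the kept set is returned.
#' @return data frame of variant records with columns `chrom`, `pos`
#'   (0-based), `ref`, `alt`, `qual`, `depth`, `ad_A`..`ad_T`, the numeric
#'   annotation columns `mq`, `mq0f`, `vdb`, `rpbz`, `bqbz`, `mqbz`,
#'   `sample_id` and `platform`. The number of skipped non-SNV rows is
#'   attached as `attr(, "skipped")`.
#' @seealso [write_vcf()], [filter_records()]
#' @export
read_vcf <- function(path, platform = NA_character_, sample_id = NA_character_,
                     filters = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path, call. = FALSE)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("failed to parse VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0) {
    out <- empty_variants()
    attr(out, "skipped") <- 0L
    return(out)
  }
  n_header <- length(vcf@meta) + 1L  # meta lines + #CHROM line

  pos_num <- suppressWarnings(as.numeric(fix[, "POS"]))
  bad <- which(is.na(pos_num) | is.na(fix[, "REF"]) | is.na(fix[, "ALT"]))
  if (length(bad) > 0) {
    stop(sprintf("malformed VCF row at line %d of '%s'",
                 n_header + bad[1], path), call. = FALSE)
  }

  info <- fix[, "INFO"]
  ref <- toupper(fix[, "REF"])
  alts <- strsplit(toupper(fix[, "ALT"]), ",", fixed = TRUE)

  # FORMAT AD fallback (first sample).
  ad_fmt <- rep(NA_character_, nrow(fix))
  if (ncol(vcf@gt) >= 2) {
    ad_fmt <- vcfR::extract.gt(vcf, element = "AD")[, 1]
  }

  rows <- vector("list", nrow(fix))
  skipped <- 0L
  for (i in seq_len(nrow(fix))) {
    if (!(ref[i] %in% BASES)) { skipped <- skipped + 1L; next }
    snv_alts <- alts[[i]][alts[[i]] %in% BASES & alts[[i]] != ref[i]]
    if (length(snv_alts) == 0) { skipped <- skipped + 1L; next }

    dp <- info_value(info[i], "DP")
    ad4 <- info_vector(info[i], "AD4", 4L)
    if (all(is.na(ad4)) && !is.na(ad_fmt[i]) && ad_fmt[i] != ".") {
      # FORMAT AD lists depths in REF,ALT order.
      vals <- suppressWarnings(as.numeric(strsplit(ad_fmt[i], ",")[[1]]))
      ad4 <- rep(NA_real_, 4)
      names(ad4) <- BASES
      all_alleles <- c(ref[i], alts[[i]])
      for (j in seq_along(all_alleles)) {
        if (all_alleles[j] %in% BASES && j <= length(vals)) {
          ad4[all_alleles[j]] <- vals[j]
        }
      }
    } else {
      names(ad4) <- BASES
    }
    qual <- suppressWarnings(as.numeric(fix[i, "QUAL"]))
    rows[[i]] <- data.frame(
      chrom = unname(fix[i, "CHROM"]), pos = as.integer(pos_num[i]) - 1L,
      ref = ref[i], alt = snv_alts,
      qual = if (is.na(qual)) NA_real_ else qual,
      depth = if (is.na(dp)) NA_integer_ else as.integer(dp),
      ad_A = unname(ad4[["A"]]), ad_C = unname(ad4[["C"]]),
      ad_G = unname(ad4[["G"]]), ad_T = unname(ad4[["T"]]),
      mq = info_value(info[i], "MQ"), mq0f = info_value(info[i], "MQ0F"),
      vdb = info_value(info[i], "VDB"), rpbz = info_value(info[i], "RPBZ"),
      bqbz = info_value(info[i], "BQBZ"), mqbz = info_value(info[i], "MQBZ"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- empty_variants()
  out$sample_id <- sample_id
  out$platform <- platform
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  if (!is.null(filters)) out <- filter_records(out, filters)$kept
  out
}

empty_variants <- function() {
  empty_df(list(chrom = character(), pos = integer(), ref = character(),
                alt = character(), qual = numeric(), depth = integer(),
                ad_A = numeric(), ad_C = numeric(), ad_G = numeric(),
                ad_T = numeric(), mq = numeric(), mq0f = numeric(),
                vdb = numeric(), rpbz = numeric(), bqbz = numeric(),
                mqbz = numeric(), sample_id = character(),
                platform = character()))
}

info_value <- function(info, key) {
  m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]+"), info))
  if (length(m) == 0) return(NA_real_)
  suppressWarnings(as.numeric(sub(paste0("^;?", key, "="), "", m)))
}

info_vector <- function(info, key, n) {
  m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]+"), info))
  if (length(m) == 0) return(rep(NA_real_, n))
  vals <- suppressWarnings(
    as.numeric(strsplit(sub(paste0("^;?", key, "="), "", m), ",")[[1]]))
  length(vals) <- n
  vals
}

#' Write a variant table as VCF 4.2
#'
#' Inverse of [read_vcf()] for canonical single-sample SNV tables: internal
#' 0-based positions become 1-based `POS`, full four-base allele depths are
#' written to the `AD4` INFO tag (so write-then-read is lossless), and the
#' standard annotation columns are emitted when non-missing.
#'
#' @param records variant table as produced by [read_vcf()] or
#'   [naive_primary_call()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_vcf <- function(records, path) {
  stopifnot_cols(records, c("chrom", "pos", "ref", "alt", "qual", "depth"),
                 "variant table")
  sample_name <- "SAMPLE"
  if (nrow(records) > 0 && !is.na(records$sample_id[1])) {
    sample_name <- records$sample_id[1]
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=tscs",
    paste0("##contig=<ID=", unique(records$chrom), ">"),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##INFO=<ID=AD4,Number=4,Type=Integer,Description=\"Read counts for A,C,G,T\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mean mapping quality\">",
    "##INFO=<ID=MQ0F,Number=1,Type=Float,Description=\"Fraction of MQ0 reads\">",
    "##INFO=<ID=VDB,Number=1,Type=Float,Description=\"Variant distance bias\">",
    "##INFO=<ID=RPBZ,Number=1,Type=Float,Description=\"Read position bias (z)\">",
    "##INFO=<ID=BQBZ,Number=1,Type=Float,Description=\"Base quality bias (z)\">",
    "##INFO=<ID=MQBZ,Number=1,Type=Float,Description=\"Mapping quality bias (z)\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths (ref,alt)\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t"))
  body <- character(0)
  if (nrow(records) > 0) {
    ad_mat <- as.matrix(records[, paste0("ad_", BASES)])
    info <- vapply(seq_len(nrow(records)), function(i) {
      parts <- c(
        if (!is.na(records$depth[i])) paste0("DP=", records$depth[i]),
        if (!all(is.na(ad_mat[i, ]))) {
          paste0("AD4=", paste(ifelse(is.na(ad_mat[i, ]), 0,
                                      as.integer(ad_mat[i, ])),
                               collapse = ","))
        },
        info_kv("MQ", records$mq[i]), info_kv("MQ0F", records$mq0f[i]),
        info_kv("VDB", records$vdb[i]), info_kv("RPBZ", records$rpbz[i]),
        info_kv("BQBZ", records$bqbz[i]), info_kv("MQBZ", records$mqbz[i]))
      if (length(parts) == 0) "." else paste(parts, collapse = ";")
    }, character(1))
    ref_ad <- ad_mat[cbind(seq_len(nrow(records)),
                           match(records$ref, BASES))]
    alt_ad <- ad_mat[cbind(seq_len(nrow(records)),
                           match(records$alt, BASES))]
    fmt <- ifelse(is.na(ref_ad) & is.na(alt_ad),
                  paste0("./.:", ifelse(is.na(records$depth), ".",
                                        records$depth), ":."),
                  paste0("./.:", ifelse(is.na(records$depth), ".",
                                        records$depth), ":",
                         ifelse(is.na(ref_ad), 0, as.integer(ref_ad)), ",",
                         ifelse(is.na(alt_ad), 0, as.integer(alt_ad))))
    body <- paste(records$chrom, records$pos + 1L, ".", records$ref,
                  records$alt,
                  ifelse(is.na(records$qual), ".",
                         format(records$qual, trim = TRUE, scientific = FALSE)),
                  "PASS", info, "GT:DP:AD", fmt, sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

info_kv <- function(key, val) {
  if (is.na(val)) NULL else paste0(key, "=",
                                   format(val, trim = TRUE, scientific = FALSE))
}

#' Quality filter parameters
#'
#' Rule-based re-implementation of the common bcftools-style low-quality site
#' exclusion: sites with `QUAL < min_qual` or depth `< min_depth`, or within
#' `snp_gap` bases of an indel, are removed. The thresholds are exclusive
#' (strictly-less-than removal), so `qual = 10` and `depth = 5` survive the
#' defaults.
#'
#' @param min_qual,min_depth,snp_gap numeric thresholds.
#' @return a list of class `tscs_filter_params`.
#' @export
quality_filter_params <- function(min_qual = 10, min_depth = 5, snp_gap = 5) {
  stopifnot(min_qual >= 0, min_depth >= 0, snp_gap >= 0)
  structure(list(min_qual = min_qual, min_depth = min_depth,
                 snp_gap = snp_gap),
            class = "tscs_filter_params")
}

#' Filter variant records on quality, depth and indel proximity
#'
#' @param records variant table sorted by `chrom`, `pos`.
#' @param params a [quality_filter_params()] object.
#' @param indels optional data frame with columns `chrom`, `pos` (0-based)
#'   giving indel positions for the SnpGap rule; a record at absolute
#'   distance `<= snp_gap` from any indel on the same chromosome is removed.
#'   `NULL` or empty disables the gap rule.
#' @return list with elements `kept` and `removed` (the `removed` table gains
#'   a `reason` column); `kept` and `removed` partition the input.
#' @export
filter_records <- function(records, params = quality_filter_params(),
                           indels = NULL) {
  stopifnot(inherits(params, "tscs_filter_params"))
  if (nrow(records) == 0) {
    removed <- records
    removed$reason <- character(0)
    return(list(kept = records, removed = removed))
  }
  ord <- order(records$chrom, records$pos)
  if (!identical(ord, seq_len(nrow(records)))) {
    stop("records must be sorted by chrom, pos", call. = FALSE)
  }
  low_qual <- !is.na(records$qual) & records$qual < params$min_qual
  low_qual[is.na(records$qual)] <- TRUE
  low_dp <- is.na(records$depth) | records$depth < params$min_depth
  near_indel <- rep(FALSE, nrow(records))
  if (!is.null(indels) && nrow(indels) > 0) {
    for (ch in unique(records$chrom)) {
      ip <- sort(indels$pos[indels$chrom == ch])
      if (length(ip) == 0) next
      sel <- which(records$chrom == ch)
      idx <- findInterval(records$pos[sel], ip)
      d_lo <- ifelse(idx >= 1, records$pos[sel] - ip[pmax(idx, 1)], Inf)
      d_hi <- ifelse(idx < length(ip), ip[pmin(idx + 1, length(ip))] -
                       records$pos[sel], Inf)
      near_indel[sel] <- pmin(abs(d_lo), abs(d_hi)) <= params$snp_gap
    }
  }
  drop <- low_qual | low_dp | near_indel
  reason <- rep("", nrow(records))
  reason[near_indel] <- "snp_gap"
  reason[low_dp] <- "low_depth"
  reason[low_qual] <- "low_qual"
  removed <- records[drop, , drop = FALSE]
  removed$reason <- reason[drop]
  kept <- records[!drop, , drop = FALSE]
  rownames(kept) <- rownames(removed) <- NULL
  list(kept = kept, removed = removed)
}
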