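#' Read exon annotation from BED6 or GTF
#'
#' Normalizes exon/feature annotation to the internal 0-based half-open
#' convention. BED input is taken as-is; GTF (1-based inclusive) has its
#' start decremented by one.
#'
#' BED6 name fields written by [write_exons()] carry
#' `gene|transcript|feature_class|frame`; plain BED names become both
#' `gene_id` and `transcript_id` with `feature_class = "exon_nc"`. In GTF
#' input the feature type column is mapped to `CDS`, `UTR5`, `UTR3` and
#' `exon_nc` (anything else), with CDS frame taken from the phase column.
#'
#' @param path annotation file.
#' @param dialect `"BED6"` or `"GTF"`; default guesses from the file
#'   extension.
#' @return data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `gene_id`, `transcript_id`, `feature_class`
#'   (`CDS`, `UTR5`, `UTR3`, `exon_nc`) and `frame` (0/1/2 for CDS, else
#'   `NA`).
#' @export
read_exons <- function(path, dialect = c("auto", "BED6", "GTF")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    dialect <- switch(ext, bed = "BED6", gtf = "GTF", gff = "GTF",
                      stop("cannot guess annotation dialect from '", path,
                           "'; pass dialect explicitly", call. = FALSE))
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = if (dialect == "BED6") "BED" else "GTF"),
    error = function(e) stop("failed to parse ", dialect, " '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (length(gr) == 0) return(empty_exons())
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  if (any(start0 >= end0)) {
    stop("zero- or negative-length interval in '", path, "'", call. = FALSE)
  }
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  if (dialect == "BED6") {
    nm <- as.character(S4Vectors::mcols(gr)$name %||%
                         rep(NA_character_, length(gr)))
    parts <- strsplit(ifelse(is.na(nm), "", nm), "|", fixed = TRUE)
    four <- lengths(parts) == 4
    gene_id <- ifelse(four, vapply(parts, `[`, "", 1), nm)
    transcript_id <- ifelse(four, vapply(parts, `[`, "", 2), nm)
    feature_class <- ifelse(four, vapply(parts, `[`, "", 3), "exon_nc")
    frame_chr <- ifelse(four, vapply(parts, `[`, "", 4), ".")
    frame <- suppressWarnings(as.integer(frame_chr))
  } else {
    mc <- S4Vectors::mcols(gr)
    type <- as.character(mc$type)
    feature_class <- ifelse(
      type == "CDS", "CDS",
      ifelse(grepl("five_prime|5UTR|UTR5", type, ignore.case = TRUE), "UTR5",
             ifelse(grepl("three_prime|3UTR|UTR3", type, ignore.case = TRUE),
                    "UTR3", "exon_nc")))
    gene_id <- as.character(mc$gene_id %||% rep(NA_character_, length(gr)))
    transcript_id <- as.character(mc$transcript_id %||% gene_id)
    frame <- suppressWarnings(as.integer(as.character(mc$phase %||%
                                                        rep(NA, length(gr)))))
    frame[feature_class != "CDS"] <- NA_integer_
  }
  bad <- !feature_class %in% c("CDS", "UTR5", "UTR3", "exon_nc")
  if (any(bad)) {
    stop("unknown feature class in '", path, "': ",
         paste(unique(feature_class[bad]), collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = start0, end = end0, strand = strand,
    gene_id = gene_id, transcript_id = transcript_id,
    feature_class = feature_class, frame = frame,
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_exons <- function() {
  empty_df(list(chrom = character(), start = integer(), end = integer(),
                strand = character(), gene_id = character(),
                transcript_id = character(), feature_class = character(),
                frame = integer()))
}

#' Write exon annotation as BED6
#'
#' The BED name field encodes `gene|transcript|feature_class|frame` so that
#' [read_exons()] round-trips all fields.
#'
#' @param exons exon table as returned by [read_exons()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_exons <- function(exons, path) {
  stopifnot_cols(exons, c("chrom", "start", "end", "strand", "gene_id",
                          "transcript_id", "feature_class"), "exon table")
  nm <- paste(exons$gene_id, exons$transcript_id, exons$feature_class,
              ifelse(is.na(exons$frame), ".", exons$frame), sep = "|")
  lines <- paste(exons$chrom, exons$start, exons$end, nm, 0L,
                 ifelse(exons$strand == ".", ".", exons$strand), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Merge feature segments into structural exons
#'
#' Feature-class segments (UTR5/CDS/UTR3 pieces of the same exon) are merged
#' per transcript into the structural exon intervals used for depth and
#' uniformity statistics.
#'
#' @param exons exon/feature table from [read_exons()].
#' @return data frame with columns `chrom`, `start`, `end`, `strand`,
#'   `gene_id`, `transcript_id`, `exon_id`.
#' @export
structural_exons <- function(exons) {
  if (nrow(exons) == 0) {
    return(empty_df(list(chrom = character(), start = integer(),
                         end = integer(), strand = character(),
                         gene_id = character(), transcript_id = character(),
                         exon_id = character())))
  }
  pieces <- split(exons, exons$transcript_id)
  out <- lapply(pieces, function(df) {
    ir <- IRanges::reduce(IRanges::IRanges(df$start + 1L, df$end))
    data.frame(chrom = df$chrom[1], start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir), strand = df$strand[1],
               gene_id = df$gene_id[1], transcript_id = df$transcript_id[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$exon_id <- paste0(out$transcript_id, ":e",
                        stats::ave(seq_len(nrow(out)), out$transcript_id,
                                   FUN = seq_along))
  rownames(out) <- NULL
  out
}

#' Tab-separated table helpers
#'
#' Plain TSV (header row, UTF-8, no quoting) used for truth tables, feature
#' matrices, classified SNVs and metric reports.
#'
#' @param path file path.
#' @param df data frame to write.
#' @return `read_tsv_table()` returns a data frame; `write_tsv_table()`
#'   returns `path` invisibly.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' @rdname read_tsv_table
#' @export
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a known-variant catalog
#'
#' Position-allele tables in the style of public genomic-variant (dbSNP,
#' COSMIC) or RNA-editing (REDIportal, DARNED) catalogs: a TSV with columns
#' `chrom`, `pos` (0-based), `ref`, `alt`.
#'
#' @param path TSV file.
#' @param kind `"g"` (genomic) or `"e"` (editing).
#' @return data frame of unique entries with attribute `kind`.
#' @export
read_catalog <- function(path, kind = c("g", "e")) {
  kind <- match.arg(kind)
  df <- read_tsv_table(path)
  stopifnot_cols(df, c("chrom", "pos", "ref", "alt"), "catalog")
  df <- unique(df[, c("chrom", "pos", "ref", "alt")])
  rownames(df) <- NULL
  attr(df, "kind") <- kind
  df
}
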