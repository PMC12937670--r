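#' Strand assignment and biological base change
#'
#' Locates each variant in the exon annotation, assigns the transcriptional
#' strand of the harboring gene, and converts the alignment-based base
#' change to the biological (sense-strand) change: unchanged on "+" genes,
#' both bases complemented on "-" genes. Positions overlapped by genes on
#' both strands are tagged `ambiguous` (their change is reported on the "+"
#' orientation but they are excluded from substitution spectra by default);
#' intergenic positions are split off with a reason code.
#'
#' When a position carries several feature classes (different transcripts),
#' the region tag follows the priority `CDS > UTR3 > UTR5 > exon_nc`.
#'
#' @param records variant table.
#' @param exons feature-segment annotation ([read_exons()]).
#' @param region_priority region precedence, highest first.
#' @return list with `snvs` (records plus `strand`, `bio_ref`, `bio_alt`,
#'   `region`, `gene_id`) and `excluded` (intergenic records with a
#'   `reason` column).
#' @export
assign_strand_and_change <- function(records, exons,
                                     region_priority = c("CDS", "UTR3",
                                                         "UTR5",
                                                         "exon_nc")) {
  n <- nrow(records)
  strand <- gene_id <- rep(NA_character_, n)
  region <- rep(NA_character_, n)
  if (n > 0 && nrow(exons) > 0) {
    q <- IRanges::IRanges(records$pos + 1L, records$pos + 1L)
    s <- IRanges::IRanges(exons$start + 1L, exons$end)
    hits <- IRanges::findOverlaps(q, s)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    same <- records$chrom[qh] == exons$chrom[sh]
    qh <- qh[same]; sh <- sh[same]
    if (length(qh) > 0) {
      prio <- match(exons$feature_class[sh], region_priority)
      for (i in unique(qh)) {
        rows <- sh[qh == i]
        p <- prio[qh == i]
        strands <- unique(exons$strand[rows])
        best <- rows[order(p)][1]
        gene_id[i] <- exons$gene_id[best]
        if (length(setdiff(strands, ".")) > 1) {
          strand[i] <- "."
          region[i] <- "ambiguous"
        } else {
          strand[i] <- exons$strand[best]
          region[i] <- exons$feature_class[best]
        }
      }
    }
  }
  out <- records
  out$strand <- strand
  minus <- !is.na(strand) & strand == "-"
  out$bio_ref <- ifelse(minus, complement_base(records$ref), records$ref)
  out$bio_alt <- ifelse(minus, complement_base(records$alt), records$alt)
  out$region <- region
  out$gene_id <- gene_id
  intergenic <- is.na(region)
  excluded <- out[intergenic, , drop = FALSE]
  if (nrow(excluded) > 0) excluded$reason <- "intergenic"
  else excluded$reason <- character(0)
  snvs <- out[!intergenic, , drop = FALSE]
  rownames(snvs) <- rownames(excluded) <- NULL
  list(snvs = snvs, excluded = excluded)
}

#' Split transcript SNVs into genome-derived and editing-derived classes
#'
#' A confirmed transcript SNV is a g-tSNV when its allele-exact key
#' (chrom, pos, ref, alt on the alignment strand) is present in the
#' genomic call set, else an e-tSNV. The partition is exhaustive and
#' disjoint.
#'
#' @param snvs classified variant table (from
#'   [assign_strand_and_change()]).
#' @param genomic_calls genomic (DNA) variant table, or a character vector
#'   of keys.
#' @return `snvs` with an added `snv_class` column (`"g"`/`"e"`).
#' @export
split_g_e <- function(snvs, genomic_calls) {
  gkeys <- if (is.character(genomic_calls)) genomic_calls
           else variant_key_df(genomic_calls)
  snvs$snv_class <- ifelse(variant_key_df(snvs) %in% gkeys, "g", "e")
  snvs
}

#' Flag known versus new SNVs against public-style catalogs
#'
#' A variant is `known` when its allele-exact key appears in the catalog
#' matching its class (genomic catalog for g-tSNVs, editing catalog for
#' e-tSNVs), `new` otherwise, and `no_catalog` when no catalog of the
#' matching kind was supplied. Keys are matched on the alignment strand.
#'
#' @param snvs classified table with `snv_class`.
#' @param g_catalog,e_catalog catalogs from [read_catalog()] (or `NULL`).
#' @return `snvs` with an added `known` column.
#' @export
known_new <- function(snvs, g_catalog = NULL, e_catalog = NULL) {
  key <- variant_key_df(snvs)
  known <- rep("no_catalog", nrow(snvs))
  if (!is.null(g_catalog)) {
    is_g <- snvs$snv_class == "g"
    known[is_g] <- ifelse(key[is_g] %in% variant_key_df(g_catalog),
                          "known", "new")
  }
  if (!is.null(e_catalog)) {
    is_e <- snvs$snv_class == "e"
    known[is_e] <- ifelse(key[is_e] %in% variant_key_df(e_catalog),
                          "known", "new")
  }
  snvs$known <- known
  snvs
}

#' Expression mask
#'
#' Retains SNVs whose gene reaches the FPKM threshold; genes absent from
#' the table are dropped.
#'
#' @param snvs classified table with `gene_id`.
#' @param fpkm data frame with columns `gene_id`, `fpkm`.
#' @param min_fpkm inclusive threshold (default 1).
#' @return filtered table; dropped rows are attached as
#'   `attr(, "dropped")` with a `reason` column.
#' @export
expression_mask <- function(snvs, fpkm, min_fpkm = 1) {
  stopifnot_cols(fpkm, c("gene_id", "fpkm"), "FPKM table")
  val <- fpkm$fpkm[match(snvs$gene_id, fpkm$gene_id)]
  keep <- !is.na(val) & val >= min_fpkm
  dropped <- snvs[!keep, , drop = FALSE]
  if (nrow(dropped) > 0) {
    dropped$reason <- ifelse(is.na(val[!keep]), "gene_absent", "low_fpkm")
  }
  out <- snvs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Categorize confirmed transcript SNVs
#'
#' Convenience wrapper chaining [assign_strand_and_change()],
#' [split_g_e()] and optionally [known_new()] and [expression_mask()].
#'
#' @param records confirmed variant table.
#' @param exons feature annotation.
#' @param genomic_calls genomic call table or key vector.
#' @param g_catalog,e_catalog optional catalogs.
#' @param fpkm optional FPKM table.
#' @param min_fpkm FPKM threshold.
#' @return classified SNV table.
#' @export
categorize_calls <- function(records, exons, genomic_calls,
                             g_catalog = NULL, e_catalog = NULL,
                             fpkm = NULL, min_fpkm = 1) {
  asgn <- assign_strand_and_change(records, exons)
  out <- split_g_e(asgn$snvs, genomic_calls)
  out <- known_new(out, g_catalog, e_catalog)
  if (!is.null(fpkm)) out <- expression_mask(out, fpkm, min_fpkm)
  out
}
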