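#' Substitution-type spectrum
#'
#' Counts classified SNVs over the 12 sense-strand substitutions.
#' Ambiguous-strand sites (overlapping genes on both strands) are excluded,
#' since their biological orientation is undefined.
#'
#' @param snvs classified table with `bio_ref`, `bio_alt`, `region`.
#' @return data frame with `change` (all 12 substitutions, fixed order),
#'   `count` and `fraction`.
#' @export
type_spectrum <- function(snvs) {
  keep <- snvs$region != "ambiguous"
  change <- paste0(snvs$bio_ref[keep], ">", snvs$bio_alt[keep])
  tab <- table(factor(change, levels = SUBSTITUTIONS))
  data.frame(change = SUBSTITUTIONS, count = as.integer(tab),
             fraction = if (sum(tab) > 0) as.integer(tab) / sum(tab)
                        else rep(0, 12),
             stringsAsFactors = FALSE)
}

#' Genomic-region distribution
#'
#' @param snvs classified table with a `region` column.
#' @return data frame with `region` (UTR3, UTR5, CDS, exon_nc, ambiguous),
#'   `count`, `fraction`.
#' @export
region_distribution <- function(snvs) {
  lev <- c("UTR3", "UTR5", "CDS", "exon_nc", "ambiguous")
  tab <- table(factor(snvs$region, levels = lev))
  data.frame(region = lev, count = as.integer(tab),
             fraction = if (sum(tab) > 0) as.integer(tab) / sum(tab)
                        else rep(0, length(lev)),
             stringsAsFactors = FALSE)
}

#' Seven-category amino-acid property scheme
#'
#' Chemistry-based grouping of the 20 standard residues: aliphatic
#' (A,G,I,L,P,V), aromatic (F,W,Y), sulfur-containing (C,M), basic
#' (H,K,R), acidic (D,E), amide (N,Q) and hydroxyl (S,T). Every residue
#' belongs to exactly one category; the mapping is user-overridable.
#'
#' @return named character vector residue -> category.
#' @export
aa_property_scheme <- function() {
  c(A = "aliphatic", G = "aliphatic", I = "aliphatic", L = "aliphatic",
    P = "aliphatic", V = "aliphatic",
    F = "aromatic", W = "aromatic", Y = "aromatic",
    C = "sulfur", M = "sulfur",
    H = "basic", K = "basic", R = "basic",
    D = "acidic", E = "acidic",
    N = "amide", Q = "amide",
    S = "hydroxyl", T = "hydroxyl")
}

#' Amino-acid property change
#'
#' @param aa_ref,aa_alt single-letter residues.
#' @param scheme category mapping ([aa_property_scheme()]).
#' @return list with `changed` (logical) and `category_ref`,
#'   `category_alt`.
#' @export
property_change <- function(aa_ref, aa_alt, scheme = aa_property_scheme()) {
  cr <- unname(scheme[aa_ref])
  ca <- unname(scheme[aa_alt])
  list(changed = !is.na(cr) & !is.na(ca) & cr != ca,
       category_ref = cr, category_alt = ca)
}

#' Build the codon model from annotation and reference bases
#'
#' For each transcript with CDS segments, concatenates the CDS on the
#' sense strand (segments and positions reversed, bases complemented, for
#' "-" genes) and records the genomic position of every CDS base, so a
#' variant position maps straight to its codon.
#'
#' @param exons feature annotation with CDS segments.
#' @param ref reference bases: character vector over the chromosome (as in
#'   the simulator's gene model) or a `Biostrings::DNAStringSet` read from
#'   FASTA.
#' @return named list per transcript: `gene_id`, `strand`, `chrom`,
#'   `pos` (genomic 0-based positions in CDS order), `seq` (sense-strand
#'   bases), `cds_len`.
#' @export
codon_model <- function(exons, ref) {
  cds <- exons[exons$feature_class == "CDS", , drop = FALSE]
  if (nrow(cds) == 0) return(list())
  base_at <- make_base_lookup(ref)
  out <- list()
  for (tx in unique(cds$transcript_id)) {
    seg <- cds[cds$transcript_id == tx, , drop = FALSE]
    seg <- seg[order(seg$start), , drop = FALSE]
    strand <- seg$strand[1]
    if (strand == "-") seg <- seg[rev(seq_len(nrow(seg))), , drop = FALSE]
    pos <- unlist(lapply(seq_len(nrow(seg)), function(i) {
      p <- seq.int(seg$start[i], seg$end[i] - 1L)
      if (strand == "-") rev(p) else p
    }))
    bases <- base_at(seg$chrom[1], pos)
    if (strand == "-") bases <- complement_base(bases)
    out[[tx]] <- list(gene_id = seg$gene_id[1], strand = strand,
                      chrom = seg$chrom[1], pos = pos, seq = bases,
                      cds_len = length(pos))
  }
  out
}

make_base_lookup <- function(ref) {
  if (is.character(ref) && length(ref) > 1) {
    function(chrom, pos) ref[pos + 1L]
  } else if (methods::is(ref, "DNAStringSet")) {
    function(chrom, pos) {
      s <- ref[[chrom]]
      vapply(pos, function(p) as.character(s[(p + 1):(p + 1)]), "")
    }
  } else {
    stop("unsupported reference representation", call. = FALSE)
  }
}

#' Coding consequence of classified SNVs
#'
#' Maps each CDS variant to its codon on the sense strand, applies the
#' single-base substitution, and translates with the standard genetic
#' code. Non-CDS variants are `noncoding`. When a position lies in several
#' transcripts' CDS, the transcript with the longest CDS is used.
#'
#' @param snvs classified table (`pos`, `bio_ref`, `bio_alt`, `region`).
#' @param cmodel [codon_model()] output.
#' @param scheme property scheme for the `property_changed` column.
#' @return `snvs` with added columns `consequence` (`synonymous`,
#'   `nonsynonymous`, `stop_gain`, `stop_loss`, `noncoding`), `aa_ref`,
#'   `aa_alt`, `property_changed`.
#' @export
consequence <- function(snvs, cmodel, scheme = aa_property_scheme()) {
  n <- nrow(snvs)
  cons <- rep("noncoding", n)
  aa_ref <- aa_alt <- rep(NA_character_, n)
  if (length(cmodel) > 0) {
    cds_len <- vapply(cmodel, `[[`, 0, "cds_len")
    # per-transcript position lookup tables
    lookups <- lapply(cmodel, function(m) {
      setNames(seq_along(m$pos), paste0(m$chrom, ":", m$pos))
    })
    code <- Biostrings::GENETIC_CODE
    for (i in seq_len(n)) {
      if (is.na(snvs$region[i]) || snvs$region[i] != "CDS") next
      key <- paste0(snvs$chrom[i], ":", snvs$pos[i])
      hit_tx <- names(cmodel)[vapply(lookups,
                                     function(lk) !is.na(lk[key]),
                                     logical(1))]
      if (length(hit_tx) == 0) next
      tx <- hit_tx[which.max(cds_len[hit_tx])]
      m <- cmodel[[tx]]
      ci <- unname(lookups[[tx]][key])
      if (ci %% 3 != 0 && (ci + (3 - ci %% 3)) > m$cds_len) {
        stop("incomplete terminal codon in transcript ", tx, call. = FALSE)
      }
      codon_start <- ci - (ci - 1L) %% 3L
      ref_codon <- m$seq[codon_start:(codon_start + 2L)]
      offset <- ci - codon_start + 1L
      if (!is.na(snvs$bio_ref[i]) &&
          ref_codon[offset] != snvs$bio_ref[i]) {
        stop("reference mismatch at ", key, " in transcript ", tx,
             ": expected ", ref_codon[offset], call. = FALSE)
      }
      alt_codon <- ref_codon
      alt_codon[offset] <- snvs$bio_alt[i]
      a_ref <- unname(code[paste(ref_codon, collapse = "")])
      a_alt <- unname(code[paste(alt_codon, collapse = "")])
      aa_ref[i] <- a_ref
      aa_alt[i] <- a_alt
      cons[i] <- if (a_ref == a_alt) "synonymous"
        else if (a_alt == "*") "stop_gain"
        else if (a_ref == "*") "stop_loss"
        else "nonsynonymous"
    }
  }
  snvs$consequence <- cons
  snvs$aa_ref <- aa_ref
  snvs$aa_alt <- aa_alt
  pc <- property_change(aa_ref, aa_alt, scheme)
  snvs$property_changed <- ifelse(cons == "nonsynonymous", pc$changed, NA)
  snvs
}

#' Per-gene clustering of nonsynonymous SNVs
#'
#' @param snvs table with `gene_id` and `consequence` columns (from
#'   [consequence()]).
#' @return list with `per_gene` (gene_id, nonsynonymous count) and `bins`
#'   (histogram over `1`, `2-5`, `>5` SNVs/gene).
#' @export
per_gene_clustering <- function(snvs) {
  ns <- snvs[snvs$consequence == "nonsynonymous", , drop = FALSE]
  if (nrow(ns) == 0) {
    per_gene <- empty_df(list(gene_id = character(), n = integer()))
  } else {
    tab <- table(ns$gene_id)
    per_gene <- data.frame(gene_id = names(tab), n = as.integer(tab),
                           stringsAsFactors = FALSE)
  }
  bins <- c(`1` = sum(per_gene$n == 1),
            `2-5` = sum(per_gene$n >= 2 & per_gene$n <= 5),
            `>5` = sum(per_gene$n > 5))
  list(per_gene = per_gene,
       bins = data.frame(bin = names(bins), count = as.integer(bins),
                         stringsAsFactors = FALSE))
}
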