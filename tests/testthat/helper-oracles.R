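# Independent brute-force oracles, kept deliberately naive and separate
# from the implementation paths they check.

oracle_vaf <- function(counts, ref) {
  total <- sum(unlist(counts))
  best <- -1; main <- NA
  for (b in BASES_T) {
    if (b == ref) next
    cnt <- if (b %in% names(counts)) counts[[b]] else 0
    if (cnt > best) { best <- cnt; main <- b }
  }
  if (total == 0 || best <= 0) return(NA_real_)
  best / total
}

oracle_cps <- function(counts, ref) {
  var_total <- 0; best <- -1
  for (b in BASES_T) {
    if (b == ref) next
    cnt <- if (b %in% names(counts)) counts[[b]] else 0
    var_total <- var_total + cnt
    if (cnt > best) best <- cnt
  }
  if (var_total == 0) return(NA_real_)
  best / var_total
}

oracle_rsd <- function(depths) {
  m <- mean(depths)
  s <- sqrt(mean((depths - m)^2))  # population sd
  s / m
}

oracle_auroc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  wins / (length(pos) * length(neg))
}

# average ranks by hand, then the Pearson product-moment of the ranks
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Exhaustive re-statement of the labeling rules.
oracle_labels <- function(srs_calls, lrs_calls, lrs_track, params) {
  cand <- character(0)
  for (i in seq_len(nrow(lrs_calls))) {
    d <- depth_at(lrs_track, lrs_calls$chrom[i], lrs_calls$pos[i])
    ad <- unlist(lrs_calls[i, paste0("ad_", BASES_T)])
    alt_reads <- ad[match(lrs_calls$alt[i], BASES_T)]
    if (d >= params$lrs_region_min_reads &&
        !is.na(alt_reads) && alt_reads >= params$lrs_site_min_reads) {
      cand <- c(cand, paste(lrs_calls$chrom[i], lrs_calls$pos[i],
                            lrs_calls$ref[i], lrs_calls$alt[i]))
    }
  }
  lrs_pos <- paste(lrs_calls$chrom, lrs_calls$pos)
  out <- character(nrow(srs_calls))
  for (i in seq_len(nrow(srs_calls))) {
    k <- paste(srs_calls$chrom[i], srs_calls$pos[i], srs_calls$ref[i],
               srs_calls$alt[i])
    pk <- paste(srs_calls$chrom[i], srs_calls$pos[i])
    d <- depth_at(lrs_track, srs_calls$chrom[i], srs_calls$pos[i])
    out[i] <- if (k %in% cand) "true"
      else if (d >= params$lrs_false_min_coverage && !(pk %in% lrs_pos))
        "false"
      else "unlabeled"
  }
  out
}

# Consequence oracle: translate the full reference and mutated CDS.
oracle_consequence <- function(m, cds_index, alt_base) {
  translate_vec <- function(bases) {
    s <- Biostrings::DNAString(paste(bases, collapse = ""))
    as.character(Biostrings::translate(s, no.init.codon = TRUE,
                                       if.fuzzy.codon = "X"))
  }
  ref_aa <- strsplit(translate_vec(m$seq), "")[[1]]
  mut <- m$seq
  mut[cds_index] <- alt_base
  alt_aa <- strsplit(translate_vec(mut), "")[[1]]
  ai <- (cds_index - 1) %/% 3 + 1
  a_ref <- ref_aa[ai]; a_alt <- alt_aa[ai]
  if (a_ref == a_alt) "synonymous"
  else if (a_alt == "*") "stop_gain"
  else if (a_ref == "*") "stop_loss"
  else "nonsynonymous"
}
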