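#' Simulation configuration
#'
#' Parameters of the synthetic dual-platform dataset: a gene model on one
#' synthetic chromosome, planted genomic variants (high VAF: heterozygous
#' mass near 0.5 plus homozygous mass at 1.0) and editing-derived variants
#' (low VAF, A>G- and 3'UTR-enriched), and per-platform pileup profiles.
#' The short-read (SRS) profile is deep, overdispersed and covers a random
#' contiguous subfraction of each exon; the long-read (LRS) profile is
#' shallower but uniform with complete exon coverage — the platform
#' contrasts the truth-set construction relies on.
#'
#' Sites whose variant reads arise purely from sequencing error carry
#' alignment-artifact annotation signatures (lower mapping quality, skewed
#' position/quality bias statistics), emulating how misalignment-driven
#' false calls look in caller annotations; planted variants draw these
#' annotations from clean null distributions.
#'
#' @param n_genes number of genes.
#' @param exons_per_gene,exon_length integer ranges `c(min, max)`.
#' @param fraction_minus_strand fraction of genes on the minus strand.
#' @param fraction_noncoding fraction of genes without a CDS.
#' @param n_g_variants,n_e_variants planted genomic / editing variant counts
#'   (default ratio 60:40).
#' @param g_vaf_mixture list with `means`, `sds`, `weights` of the genomic
#'   VAF mixture (defaults: near-0.5 heterozygous and exactly-1 homozygous).
#' @param e_vaf_beta Beta shape parameters of the editing VAF distribution
#'   (mass concentrated below 0.5).
#' @param e_type_weights named weights over the 12 sense-strand
#'   substitutions (default: A>G 0.8, remainder uniform).
#' @param e_region_weights named weights over region classes (default:
#'   UTR3 0.6).
#' @param srs_profile,lrs_profile,dna_profile platform profiles: lists with
#'   `mean_depth`, `depth_dispersion` (negative-binomial size; smaller =
#'   noisier), `coverage_fraction` (Beta shapes `c(a, b)` for SRS, `1` for
#'   full coverage), `per_read_error`.
#' @param expression_sdlog log-sd of the per-gene expression factor shared
#'   by both RNA platforms.
#' @param caller_params defaults for [naive_primary_call()].
#' @param utr5_frac,utr3_frac fraction of a coding gene's exonic length
#'   assigned to the 5'/3' UTR.
#' @param intron_length,intergenic_length integer ranges.
#' @param chrom synthetic chromosome name.
#' @param seed integer seed fixing the full bundle.
#' @return a list of class `tscs_sim_config`.
#' @export
sim_config <- function(n_genes = 240,
                       exons_per_gene = c(3, 7),
                       exon_length = c(120, 400),
                       fraction_minus_strand = 0.4,
                       fraction_noncoding = 0.1,
                       n_g_variants = 4500,
                       n_e_variants = 3000,
                       g_vaf_mixture = list(means = c(0.5, 1.0),
                                            sds = c(0.04, 0.0),
                                            weights = c(0.6, 0.4)),
                       e_vaf_beta = c(1.2, 4.0),
                       e_type_weights = NULL,
                       e_region_weights = c(UTR3 = 0.6, CDS = 0.2,
                                            UTR5 = 0.1, exon_nc = 0.1),
                       srs_profile = list(mean_depth = 300,
                                          depth_dispersion = 3,
                                          coverage_fraction = c(5, 2),
                                          per_read_error = 0.0027),
                       lrs_profile = list(mean_depth = 150,
                                          depth_dispersion = 12,
                                          coverage_fraction = 1,
                                          per_read_error = 0.002),
                       dna_profile = list(mean_depth = 60,
                                          depth_dispersion = 8,
                                          coverage_fraction = 1,
                                          per_read_error = 0.002),
                       expression_sdlog = 0.5,
                       caller_params = list(min_alt_reads = 3, min_depth = 5),
                       utr5_frac = 0.15, utr3_frac = 0.30,
                       intron_length = c(50, 300),
                       intergenic_length = c(200, 500),
                       chrom = "chrS",
                       seed = 1L) {
  if (is.null(e_type_weights)) {
    e_type_weights <- setNames(rep(0.2 / 11, 12), SUBSTITUTIONS)
    e_type_weights["A>G"] <- 0.8
  }
  stopifnot(all(sort(names(e_type_weights)) == sort(SUBSTITUTIONS)),
            all(e_type_weights >= 0), all(e_region_weights >= 0),
            n_genes >= 1, n_g_variants >= 0, n_e_variants >= 0,
            srs_profile$mean_depth > 0, lrs_profile$mean_depth > 0,
            abs(sum(g_vaf_mixture$weights) - 1) < 1e-9)
  e_type_weights <- e_type_weights / sum(e_type_weights)
  e_region_weights <- e_region_weights / sum(e_region_weights)
  structure(list(
    n_genes = n_genes, exons_per_gene = exons_per_gene,
    exon_length = exon_length,
    fraction_minus_strand = fraction_minus_strand,
    fraction_noncoding = fraction_noncoding,
    n_g_variants = n_g_variants, n_e_variants = n_e_variants,
    g_vaf_mixture = g_vaf_mixture, e_vaf_beta = e_vaf_beta,
    e_type_weights = e_type_weights, e_region_weights = e_region_weights,
    srs_profile = srs_profile, lrs_profile = lrs_profile,
    dna_profile = dna_profile, expression_sdlog = expression_sdlog,
    caller_params = caller_params,
    utr5_frac = utr5_frac, utr3_frac = utr3_frac,
    intron_length = intron_length, intergenic_length = intergenic_length,
    chrom = chrom, seed = as.integer(seed)), class = "tscs_sim_config")
}

rint <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq.int(range[1], range[2]), n, replace = TRUE)
}

#' Build the synthetic gene model
#'
#' Lays out non-overlapping genes along the synthetic chromosome, partitions
#' each coding gene's exonic sequence into UTR5/CDS/UTR3 in transcription
#' order (CDS trimmed to a codon multiple), assigns i.i.d. uniform reference
#' bases, and draws a per-gene expression factor shared by both RNA
#' platforms.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (defaults to the config seed).
#' @return list with `exons` (feature segments, see [read_exons()]),
#'   `structural` (merged exons), `genes`, `ref` (character vector of
#'   reference bases), `chrom`, `chrom_len`, `config`.
#' @export
build_gene_model <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "tscs_sim_config"))
  set.seed(derive_seed(seed, "gene_model"))
  cursor <- 0L
  seg_list <- vector("list", config$n_genes)
  gene_rows <- vector("list", config$n_genes)
  for (g in seq_len(config$n_genes)) {
    cursor <- cursor + rint(1, config$intergenic_length)
    gene_id <- sprintf("gene%03d", g)
    tx_id <- paste0(gene_id, ".t1")
    strand <- if (runif(1) < config$fraction_minus_strand) "-" else "+"
    coding <- runif(1) >= config$fraction_noncoding
    n_ex <- rint(1, config$exons_per_gene)
    ex_len <- rint(n_ex, config$exon_length)
    starts <- integer(n_ex)
    for (e in seq_len(n_ex)) {
      starts[e] <- cursor
      cursor <- cursor + ex_len[e]
      if (e < n_ex) cursor <- cursor + rint(1, config$intron_length)
    }
    ends <- starts + ex_len
    segs <- gene_segments(gene_id, tx_id, config$chrom, starts, ends,
                          strand, coding, config)
    seg_list[[g]] <- segs
    gene_rows[[g]] <- data.frame(gene_id = gene_id, transcript_id = tx_id,
                                 strand = strand, coding = coding,
                                 stringsAsFactors = FALSE)
  }
  exons <- do.call(rbind, seg_list)
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  genes <- do.call(rbind, gene_rows)
  genes$expression <- exp(rnorm(nrow(genes), 0, config$expression_sdlog))
  chrom_len <- cursor + rint(1, config$intergenic_length)
  ref <- sample(BASES, chrom_len, replace = TRUE)
  list(exons = exons, structural = structural_exons(exons), genes = genes,
       ref = ref, chrom = config$chrom, chrom_len = chrom_len,
       config = config)
}

# Split one gene's exons into feature-class segments in transcription order.
gene_segments <- function(gene_id, tx_id, chrom, starts, ends, strand,
                          coding, config) {
  total <- sum(ends - starts)
  base <- data.frame(chrom = chrom, start = starts, end = ends,
                     strand = strand, gene_id = gene_id,
                     transcript_id = tx_id, stringsAsFactors = FALSE)
  if (!coding || total < 30) {
    base$feature_class <- "exon_nc"
    base$frame <- NA_integer_
    return(base)
  }
  u5 <- max(3L, round(config$utr5_frac * total))
  u3 <- max(3L, round(config$utr3_frac * total))
  cds <- total - u5 - u3
  u3 <- u3 + cds %% 3  # trim CDS to a codon multiple
  cds <- cds - cds %% 3
  # walk exonic positions in transcription order
  class_seq <- rep(c("UTR5", "CDS", "UTR3"), times = c(u5, cds, u3))
  cds_off <- cumsum(class_seq == "CDS") - 1L  # 0-based CDS offset
  out <- list()
  off <- 0L
  ex_order <- if (strand == "+") seq_along(starts) else rev(seq_along(starts))
  for (e in ex_order) {
    len <- ends[e] - starts[e]
    cls <- class_seq[(off + 1):(off + len)]
    cdo <- cds_off[(off + 1):(off + len)]
    runs <- rle(cls)
    run_end <- cumsum(runs$lengths)
    run_start <- run_end - runs$lengths + 1L
    for (r in seq_along(runs$values)) {
      # positions within the exon in transcription order
      if (strand == "+") {
        s <- starts[e] + run_start[r] - 1L
        en <- starts[e] + run_end[r]
      } else {
        s <- ends[e] - run_end[r]
        en <- ends[e] - run_start[r] + 1L
      }
      fr <- NA_integer_
      if (runs$values[r] == "CDS") {
        off0 <- cdo[run_start[r]]  # CDS offset of segment's first sense base
        fr <- (3L - off0 %% 3L) %% 3L
      }
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom, start = s, end = en, strand = strand,
        gene_id = gene_id, transcript_id = tx_id,
        feature_class = runs$values[r], frame = fr,
        stringsAsFactors = FALSE)
    }
    off <- off + len
  }
  do.call(rbind, out)
}

# Expand the model's feature segments into one row per exonic position.
exonic_positions <- function(model) {
  ex <- model$exons
  len <- ex$end - ex$start
  pos <- unlist(lapply(seq_len(nrow(ex)),
                       function(i) seq.int(ex$start[i], ex$end[i] - 1L)))
  idx <- rep(seq_len(nrow(ex)), len)
  base <- model$ref[pos + 1L]
  strand <- ex$strand[idx]
  data.frame(pos = pos, gene_id = ex$gene_id[idx], strand = strand,
             region = ex$feature_class[idx], base = base,
             sense_base = ifelse(strand == "-", complement_base(base), base),
             stringsAsFactors = FALSE)
}

#' Plant genomic and editing variants
#'
#' Genomic (class g) variants get positions uniform over exonic space, a
#' uniform alternate base and VAF from the configured heterozygous/
#' homozygous mixture; they are mirrored into a genomic (DNA) call table
#' with VAF-consistent allele depths. Editing (class e) variants draw a
#' sense-strand substitution type and a region class from the configured
#' weights, then a compatible position, with Beta-distributed VAF.
#'
#' @param model output of [build_gene_model()].
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return list with `truth` (one row per planted variant: sense-strand
#'   `ref`/`alt`, alignment-strand `ref_aln`/`alt_aln`, `class`, `true_vaf`,
#'   `region`, `gene_id`, `strand`) and `dna_calls` (variant table for the
#'   class-g entries).
#' @export
plant_variants <- function(model, config = model$config,
                           seed = config$seed) {
  set.seed(derive_seed(seed, "plant"))
  pool <- exonic_positions(model)
  n_g <- config$n_g_variants
  n_e <- config$n_e_variants
  if (n_g + n_e > nrow(pool)) {
    stop("requested ", n_g + n_e, " variants but only ", nrow(pool),
         " exonic positions are available", call. = FALSE)
  }
  take <- sample.int(nrow(pool), n_g)
  g_rows <- pool[take, , drop = FALSE]
  pool <- pool[-take, , drop = FALSE]

  g_alt_aln <- vapply(g_rows$base,
                      function(b) sample(setdiff(BASES, b), 1), "")
  mix <- config$g_vaf_mixture
  comp <- sample.int(length(mix$weights), n_g, replace = TRUE,
                     prob = mix$weights)
  g_vaf <- pmin(pmax(rnorm(n_g, mix$means[comp], mix$sds[comp]), 0.05), 1)

  minus_g <- g_rows$strand == "-"
  g_truth <- data.frame(
    chrom = model$chrom, pos = g_rows$pos,
    ref = ifelse(minus_g, complement_base(g_rows$base), g_rows$base),
    alt = ifelse(minus_g, complement_base(g_alt_aln), g_alt_aln),
    ref_aln = g_rows$base, alt_aln = g_alt_aln,
    class = "g", true_vaf = g_vaf, region = g_rows$region,
    gene_id = g_rows$gene_id, strand = g_rows$strand,
    stringsAsFactors = FALSE)

  e_truth <- NULL
  if (n_e > 0) {
    types <- sample(names(config$e_type_weights), n_e, replace = TRUE,
                    prob = config$e_type_weights)
    regions <- sample(names(config$e_region_weights), n_e, replace = TRUE,
                      prob = config$e_region_weights)
    sense_ref <- sub(">.*", "", types)
    sense_alt <- sub(".*>", "", types)
    picked <- rep(NA_integer_, n_e)
    # pool row indices grouped by (region, sense base), consumed as drawn
    grp_of <- paste0(pool$region, "/", pool$sense_base)
    avail <- split(seq_len(nrow(pool)), grp_of)
    avail <- lapply(avail, sample)  # pre-shuffle; take from the front
    taken <- setNames(integer(length(avail)), names(avail))
    for (round in 1:60) {
      open <- which(is.na(picked))
      if (length(open) == 0) break
      want <- paste0(regions[open], "/", sense_ref[open])
      for (g in unique(want)) {
        rows <- open[want == g]
        pool_g <- avail[[g]]
        free <- length(pool_g %||% integer(0)) - taken[g]
        if (is.na(free) || free <= 0) next
        use <- rows[seq_len(min(length(rows), free))]
        picked[use] <- pool_g[taken[g] + seq_along(use)]
        taken[g] <- taken[g] + length(use)
      }
      open <- which(is.na(picked))
      if (length(open) == 0) break
      # group exhausted: redraw the region, and late on the type too
      regions[open] <- sample(names(config$e_region_weights), length(open),
                              replace = TRUE,
                              prob = config$e_region_weights)
      if (round > 30) {
        t2 <- sample(names(config$e_type_weights), length(open),
                     replace = TRUE, prob = config$e_type_weights)
        sense_ref[open] <- sub(">.*", "", t2)
        sense_alt[open] <- sub(".*>", "", t2)
      }
    }
    if (anyNA(picked)) {
      stop("could not place all editing variants: exonic positions ",
           "exhausted", call. = FALSE)
    }
    e_rows <- pool[picked, , drop = FALSE]
    minus_e <- e_rows$strand == "-"
    e_vaf <- pmin(pmax(rbeta(n_e, config$e_vaf_beta[1],
                             config$e_vaf_beta[2]), 0.02), 0.98)
    e_truth <- data.frame(
      chrom = model$chrom, pos = e_rows$pos,
      ref = sense_ref, alt = sense_alt,
      ref_aln = ifelse(minus_e, complement_base(sense_ref), sense_ref),
      alt_aln = ifelse(minus_e, complement_base(sense_alt), sense_alt),
      class = "e", true_vaf = e_vaf, region = e_rows$region,
      gene_id = e_rows$gene_id, strand = e_rows$strand,
      stringsAsFactors = FALSE)
  }
  truth <- rbind(g_truth, e_truth)
  truth <- truth[order(truth$pos), , drop = FALSE]
  rownames(truth) <- NULL

  dna_calls <- dna_calls_from_truth(truth[truth$class == "g", , drop = FALSE],
                                    config)
  list(truth = truth, dna_calls = dna_calls)
}

dna_calls_from_truth <- function(g_truth, config) {
  n <- nrow(g_truth)
  if (n == 0) return(empty_variants())
  prof <- config$dna_profile
  depth <- pmax(rnbinom(n, mu = prof$mean_depth,
                        size = prof$depth_dispersion), 10L)
  alt <- pmax(rbinom(n, depth, g_truth$true_vaf), 1L)
  ad <- matrix(0, n, 4, dimnames = list(NULL, BASES))
  ad[cbind(seq_len(n), match(g_truth$ref_aln, BASES))] <- depth - alt
  ad[cbind(seq_len(n), match(g_truth$alt_aln, BASES))] <- alt
  out <- data.frame(
    chrom = g_truth$chrom, pos = g_truth$pos,
    ref = g_truth$ref_aln, alt = g_truth$alt_aln,
    qual = round(100 * alt / depth, 2), depth = as.integer(depth),
    ad_A = ad[, "A"], ad_C = ad[, "C"], ad_G = ad[, "G"], ad_T = ad[, "T"],
    mq = NA_real_, mq0f = NA_real_, vdb = NA_real_, rpbz = NA_real_,
    bqbz = NA_real_, mqbz = NA_real_,
    sample_id = "sim", platform = "DNA", stringsAsFactors = FALSE)
  out[order(out$pos), , drop = FALSE]
}

# Annotation signature profiles for clean (planted) vs artifact (pure
# sequencing-error) variant sites.
aux_clean <- list(mq = c(58, 2), mq0f = c(1, 60), vdb_unif = c(0.05, 1),
                  z = c(0, 1))
aux_artifact <- list(mq = c(44, 8), mq0f = c(2, 10), vdb_beta = c(1, 8),
                     z = c(-2, 1.2))

draw_aux <- function(n, planted) {
  mq <- ifelse(planted, pmin(rnorm(n, aux_clean$mq[1], aux_clean$mq[2]), 60),
               pmin(rnorm(n, aux_artifact$mq[1], aux_artifact$mq[2]), 60))
  mq0f <- ifelse(planted, rbeta(n, aux_clean$mq0f[1], aux_clean$mq0f[2]),
                 rbeta(n, aux_artifact$mq0f[1], aux_artifact$mq0f[2]))
  vdb <- ifelse(planted, runif(n, aux_clean$vdb_unif[1],
                               aux_clean$vdb_unif[2]),
                rbeta(n, aux_artifact$vdb_beta[1], aux_artifact$vdb_beta[2]))
  z <- function() ifelse(planted, rnorm(n, aux_clean$z[1], aux_clean$z[2]),
                         rnorm(n, aux_artifact$z[1], aux_artifact$z[2]))
  data.frame(mq = round(mq, 2), mq0f = round(mq0f, 4), vdb = round(vdb, 4),
             rpbz = round(z(), 3), bqbz = round(z(), 3),
             mqbz = round(z(), 3))
}

#' Simulate one platform's pileups and depth track
#'
#' Per structural exon, the covered interval is the whole exon (profile
#' `coverage_fraction = 1`, long-read behaviour) or a random contiguous
#' subinterval with Beta-distributed fraction (short-read behaviour);
#' per-position depth is negative-binomial around the profile mean scaled by
#' the gene's expression factor. At planted sites alternate reads are
#' binomial in the true VAF; sequencing errors scatter uniformly over the
#' remaining non-reference bases at the profile's per-read error rate.
#'
#' @param truth truth table from [plant_variants()].
#' @param model gene model.
#' @param profile one of the config's platform profiles.
#' @param seed RNG seed.
#' @param platform label stored on the outputs.
#' @return list with `pileup` (sites with at least one non-reference read:
#'   `chrom`, `pos`, `ref`, counts `A`..`T`, annotation columns) and
#'   `track` (run-length depth track).
#' @export
simulate_platform_pileups <- function(truth, model, profile, seed,
                                      platform = "SRS") {
  set.seed(derive_seed(seed, paste0("pileup_", platform)))
  st <- model$structural
  expr <- model$genes$expression[match(st$gene_id, model$genes$gene_id)]
  pos_list <- vector("list", nrow(st))
  for (i in seq_len(nrow(st))) {
    len <- st$end[i] - st$start[i]
    if (identical(profile$coverage_fraction, 1) ||
        length(profile$coverage_fraction) == 1) {
      cov_s <- st$start[i]; cov_e <- st$end[i]
    } else {
      f <- rbeta(1, profile$coverage_fraction[1],
                 profile$coverage_fraction[2])
      clen <- max(1L, round(f * len))
      cov_s <- st$start[i] + sample.int(len - clen + 1L, 1) - 1L
      cov_e <- cov_s + clen
    }
    pos_list[[i]] <- seq.int(cov_s, cov_e - 1L)
  }
  pos <- unlist(pos_list)
  mu <- rep(profile$mean_depth * expr, lengths(pos_list))
  depth <- rnbinom(length(pos), mu = mu, size = profile$depth_dispersion)

  track <- track_from_depths(rep(model$chrom, length(pos)), pos, depth)

  keep <- depth > 0
  pos <- pos[keep]; depth <- depth[keep]
  ref <- model$ref[pos + 1L]
  n <- length(pos)
  ti <- match(pos, truth$pos)
  planted <- !is.na(ti)
  vaf <- ifelse(planted, truth$true_vaf[ti], 0)
  alt_base <- ifelse(planted, truth$alt_aln[ti], NA_character_)
  alt <- integer(n)
  alt[planted] <- rbinom(sum(planted), depth[planted], vaf[planted])
  err <- rbinom(n, depth - alt, profile$per_read_error)

  counts <- matrix(0L, n, 4, dimnames = list(NULL, BASES))
  ref_idx <- match(ref, BASES)
  counts[cbind(seq_len(n), ref_idx)] <- depth - alt - err
  if (any(planted)) {
    counts[cbind(which(planted), match(alt_base[planted], BASES))] <-
      counts[cbind(which(planted), match(alt_base[planted], BASES))] + alt[planted]
  }
  # scatter errors uniformly over the non-ref (and non-alt, at planted
  # sites) bases via sequential binomial splits, vectorized across sites
  others <- rbind(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L),
                  c(1L, 2L, 3L))  # non-ref base indices per ref index
  tgt <- others[ref_idx, , drop = FALSE]
  three <- rep(TRUE, n)
  if (any(planted)) {
    pi_ <- which(planted)
    alt_idx <- match(alt_base[pi_], BASES)
    eq_col <- (tgt[pi_, 1] == alt_idx) * 1L + (tgt[pi_, 2] == alt_idx) *
      2L + (tgt[pi_, 3] == alt_idx) * 3L
    keep2 <- rbind(c(2L, 3L), c(1L, 3L), c(1L, 2L))[eq_col, , drop = FALSE]
    tgt[pi_, 1:2] <- cbind(tgt[cbind(pi_, keep2[, 1])],
                           tgt[cbind(pi_, keep2[, 2])])
    three[pi_] <- FALSE
  }
  n1 <- rbinom(n, err, ifelse(three, 1 / 3, 1 / 2))
  n2 <- rbinom(n, err - n1, ifelse(three, 1 / 2, 1))
  n3 <- ifelse(three, err - n1 - n2, 0L)
  counts[cbind(seq_len(n), tgt[, 1])] <-
    counts[cbind(seq_len(n), tgt[, 1])] + n1
  counts[cbind(seq_len(n), tgt[, 2])] <-
    counts[cbind(seq_len(n), tgt[, 2])] + n2
  idx3 <- which(three & n3 > 0)
  counts[cbind(idx3, tgt[idx3, 3])] <-
    counts[cbind(idx3, tgt[idx3, 3])] + n3[idx3]
  nonref <- rowSums(counts) - counts[cbind(seq_len(n), ref_idx)]
  keep2 <- nonref > 0
  aux <- draw_aux(sum(keep2), planted[keep2])
  pileup <- cbind(
    data.frame(chrom = model$chrom, pos = pos[keep2], ref = ref[keep2],
               stringsAsFactors = FALSE),
    as.data.frame(counts[keep2, , drop = FALSE]), aux)
  pileup <- pileup[order(pileup$pos), , drop = FALSE]
  rownames(pileup) <- NULL
  attr(pileup, "platform") <- platform
  list(pileup = pileup, track = track)
}

#' Naive primary variant caller over simulated pileups
#'
#' Stand-in for an external primary caller: emits a record wherever the
#' best-supported non-reference allele (ties broken in A<C<G<T order)
#' reaches `min_alt_reads` supporting reads at a site of depth at least
#' `min_depth`. QUAL is a monotone function of alternate-allele evidence,
#' `100 * alt_reads / depth` (so low-VAF sites score low, the behaviour
#' that makes a plain QUAL cutoff discard low-frequency variants).
#'
#' @param pileup pileup table from [simulate_platform_pileups()].
#' @param params list with `min_alt_reads`, `min_depth`.
#' @param sample_id,platform labels stored on the records.
#' @return variant table (see [read_vcf()] for columns).
#' @export
naive_primary_call <- function(pileup,
                               params = list(min_alt_reads = 3,
                                             min_depth = 5),
                               sample_id = "sim",
                               platform = attr(pileup, "platform") %||%
                                 NA_character_) {
  if (nrow(pileup) == 0) return(empty_variants())
  pm <- pileup_site_metrics(pileup)
  keep <- !is.na(pm$main_alt) & pm$alt_reads >= params$min_alt_reads &
    pm$total >= params$min_depth
  pm <- pm[keep, , drop = FALSE]
  if (nrow(pm) == 0) return(empty_variants())
  out <- data.frame(
    chrom = pm$chrom, pos = pm$pos, ref = pm$ref, alt = pm$main_alt,
    qual = round(100 * pm$alt_reads / pm$total, 2),
    depth = as.integer(pm$total),
    ad_A = as.numeric(pm$A), ad_C = as.numeric(pm$C),
    ad_G = as.numeric(pm$G), ad_T = as.numeric(pm$T),
    mq = pm$mq %||% NA_real_, mq0f = pm$mq0f %||% NA_real_,
    vdb = pm$vdb %||% NA_real_, rpbz = pm$rpbz %||% NA_real_,
    bqbz = pm$bqbz %||% NA_real_, mqbz = pm$mqbz %||% NA_real_,
    sample_id = sample_id, platform = platform, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate a full dual-platform bundle in memory
#'
#' Chains [build_gene_model()], [plant_variants()],
#' [simulate_platform_pileups()] for both RNA platforms and
#' [naive_primary_call()].
#'
#' @param config a [sim_config()].
#' @return list with `model`, `truth`, `dna_calls`, `srs`/`lrs`
#'   (each `pileup`, `track`, `calls`), `config`.
#' @export
simulate_bundle <- function(config = sim_config()) {
  model <- build_gene_model(config)
  planted <- plant_variants(model, config)
  srs <- simulate_platform_pileups(planted$truth, model,
                                   config$srs_profile, config$seed, "SRS")
  lrs <- simulate_platform_pileups(planted$truth, model,
                                   config$lrs_profile, config$seed, "LRS")
  srs$calls <- naive_primary_call(srs$pileup, config$caller_params,
                                  platform = "SRS")
  lrs$calls <- naive_primary_call(lrs$pileup, config$caller_params,
                                  platform = "LRS")
  list(model = model, truth = planted$truth, dna_calls = planted$dna_calls,
       srs = srs, lrs = lrs, config = config)
}

#' Write a simulated dataset to disk
#'
#' Emits the file bundle consumed by the rest of the workflow:
#' `annotation.bed`, `reference.fa`, `srs.vcf`, `lrs.vcf`, `dna.vcf`,
#' `srs.bedgraph`, `lrs.bedgraph`, `truth.tsv` and `config.json`. The
#' bundle is deterministic: identical (config, seed) give byte-identical
#' files.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the in-memory bundle with a `paths` element added.
#' @export
emit_dataset <- function(config = sim_config(), outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  b <- simulate_bundle(config)
  p <- list(
    annotation = file.path(outdir, "annotation.bed"),
    reference = file.path(outdir, "reference.fa"),
    srs_vcf = file.path(outdir, "srs.vcf"),
    lrs_vcf = file.path(outdir, "lrs.vcf"),
    dna_vcf = file.path(outdir, "dna.vcf"),
    srs_bedgraph = file.path(outdir, "srs.bedgraph"),
    lrs_bedgraph = file.path(outdir, "lrs.bedgraph"),
    truth = file.path(outdir, "truth.tsv"),
    config = file.path(outdir, "config.json"))
  write_exons(b$model$exons, p$annotation)
  write_fasta(b$model$ref, b$model$chrom, p$reference)
  write_vcf(b$srs$calls, p$srs_vcf)
  write_vcf(b$lrs$calls, p$lrs_vcf)
  write_vcf(b$dna_calls, p$dna_vcf)
  write_depth_track(b$srs$track, p$srs_bedgraph)
  write_depth_track(b$lrs$track, p$lrs_bedgraph)
  write_tsv_table(b$truth, p$truth)
  cfg <- unclass(config)
  jsonlite::write_json(cfg, p$config, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  b$paths <- p
  invisible(b)
}

write_fasta <- function(bases, chrom, path) {
  seq <- paste(bases, collapse = "")
  lines <- substring(seq, seq(1, nchar(seq), 70),
                     pmin(seq(1, nchar(seq), 70) + 69, nchar(seq)))
  writeLines(c(paste0(">", chrom), lines), path)
  invisible(path)
}
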