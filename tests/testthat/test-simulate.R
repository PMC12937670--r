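test_that("the gene model is deterministic and respects strand/structure settings", {
  cfg <- small_config()
  m1 <- build_gene_model(cfg)
  m2 <- build_gene_model(cfg)
  expect_identical(m1$exons, m2$exons)
  expect_identical(m1$ref, m2$ref)

  cfg_minus <- sim_config(n_genes = 5, fraction_minus_strand = 1,
                          n_g_variants = 10, n_e_variants = 0, seed = 3)
  m3 <- build_gene_model(cfg_minus)
  expect_true(all(m3$exons$strand == "-"))

  cfg_1ex <- sim_config(n_genes = 2, exons_per_gene = c(1, 1),
                        fraction_noncoding = 1, n_g_variants = 5,
                        n_e_variants = 0, seed = 4)
  m4 <- build_gene_model(cfg_1ex)
  expect_equal(nrow(m4$structural), 2)
  # genes do not overlap
  expect_true(all(m4$structural$start[-1] >= m4$structural$end[-2]))
})

test_that("CDS frames are codon-consistent in transcription order", {
  m <- build_gene_model(small_config())
  cds <- m$exons[m$exons$feature_class == "CDS", ]
  expect_true(all(cds$frame %in% 0:2))
  for (tx in unique(cds$transcript_id)) {
    seg <- cds[cds$transcript_id == tx, ]
    seg <- seg[order(seg$start), ]
    if (seg$strand[1] == "-") seg <- seg[rev(seq_len(nrow(seg))), ]
    # first CDS segment starts in frame 0; total length is a codon multiple
    expect_equal(seg$frame[1], 0L)
    expect_equal(sum(seg$end - seg$start) %% 3, 0)
  }
})

test_that("planted variants honor class counts, uniqueness and class-g mirroring", {
  b <- small_bundle()
  cfg <- b$config
  expect_equal(sum(b$truth$class == "g"), cfg$n_g_variants)
  expect_equal(sum(b$truth$class == "e"), cfg$n_e_variants)
  expect_false(any(duplicated(b$truth$pos)))
  gk <- variant_key(b$truth$chrom[b$truth$class == "g"],
                    b$truth$pos[b$truth$class == "g"],
                    b$truth$ref_aln[b$truth$class == "g"],
                    b$truth$alt_aln[b$truth$class == "g"])
  dk <- variant_key_df(b$dna_calls)
  expect_setequal(gk, dk)
  ek <- b$truth$pos[b$truth$class == "e"]
  expect_false(any(ek %in% b$dna_calls$pos))
})

test_that("degenerate planting configurations behave as specified", {
  m <- build_gene_model(sim_config(n_genes = 10, seed = 5,
                                   n_g_variants = 20, n_e_variants = 30))
  w <- setNames(rep(0, 12), SUBSTITUTIONS); w["A>G"] <- 1
  cfg_ag <- sim_config(n_genes = 10, seed = 5, n_g_variants = 20,
                       n_e_variants = 30, e_type_weights = w)
  pv <- plant_variants(m, cfg_ag, seed = 5)
  e <- pv$truth[pv$truth$class == "e", ]
  expect_true(all(e$ref == "A" & e$alt == "G"))

  cfg_noe <- sim_config(n_genes = 10, seed = 5, n_g_variants = 20,
                        n_e_variants = 0)
  pv2 <- plant_variants(m, cfg_noe, seed = 5)
  expect_true(all(pv2$truth$class == "g"))

  cfg_over <- sim_config(n_genes = 2, exons_per_gene = c(1, 1),
                         exon_length = c(50, 50), n_g_variants = 500,
                         n_e_variants = 500, seed = 5)
  m_small <- build_gene_model(cfg_over)
  expect_error(plant_variants(m_small, cfg_over, seed = 5), "available")
})

test_that("pileups are exact at error-free sites and LRS covers exons fully", {
  cfg <- sim_config(n_genes = 8, n_g_variants = 40, n_e_variants = 0,
                    g_vaf_mixture = list(means = 1, sds = 0, weights = 1),
                    srs_profile = list(mean_depth = 50,
                                       depth_dispersion = 5,
                                       coverage_fraction = 1,
                                       per_read_error = 0),
                    seed = 9)
  m <- build_gene_model(cfg)
  pv <- plant_variants(m, cfg, seed = 9)
  sim <- simulate_platform_pileups(pv$truth, m, cfg$srs_profile, 9, "SRS")
  pm <- pileup_site_metrics(sim$pileup)
  # vaf 1, no errors: every read at a planted site is the alternate
  expect_true(all(pm$vaf == 1))
  expect_true(all(pm$pos %in% pv$truth$pos))

  b <- small_bundle()
  st <- exon_depth_stats(b$lrs$track, b$model$structural)
  deep <- st[!is.na(st$mean_depth) & st$mean_depth >= 20, ]
  expect_true(mean(deep$coverage_fraction > 0.95) > 0.95)
})

test_that("empirical VAF at a planted site is binomial around the true VAF", {
  cfg <- sim_config(n_genes = 2, exons_per_gene = c(1, 1),
                    exon_length = c(60, 60), n_g_variants = 1,
                    n_e_variants = 0,
                    g_vaf_mixture = list(means = 0.3, sds = 0, weights = 1),
                    srs_profile = list(mean_depth = 80,
                                       depth_dispersion = 50,
                                       coverage_fraction = 1,
                                       per_read_error = 0),
                    seed = 21)
  m <- build_gene_model(cfg)
  pv <- plant_variants(m, cfg, seed = 21)
  alt <- 0; tot <- 0
  for (s in 1:200) {
    sim <- simulate_platform_pileups(pv$truth, m, cfg$srs_profile, s, "SRS")
    pm <- pileup_site_metrics(sim$pileup)
    hit <- pm[pm$pos == pv$truth$pos, ]
    if (nrow(hit) == 1) { alt <- alt + hit$alt_reads; tot <- tot + hit$total }
  }
  p_hat <- alt / tot
  se <- sqrt(0.3 * 0.7 / tot)
  expect_lt(abs(p_hat - 0.3), 3 * se)
})

test_that("naive caller applies thresholds at the boundary with fixed tie order", {
  pu <- data.frame(chrom = "chrS", pos = c(1L, 2L, 3L), ref = "A",
                   A = c(20, 20, 20), C = 0, G = c(5, 4, 5),
                   T = c(0, 0, 5), stringsAsFactors = FALSE)
  calls <- naive_primary_call(pu, list(min_alt_reads = 5, min_depth = 5))
  expect_equal(calls$pos, c(1L, 3L))
  expect_equal(calls$alt, c("G", "G"))  # tie at pos 3 resolves to G
  # qual is monotone in alternate evidence at fixed depth
  pu2 <- data.frame(chrom = "chrS", pos = 1:3, ref = "A",
                    A = c(27, 24, 21), C = 0, G = c(3, 6, 9), T = 0)
  q <- naive_primary_call(pu2, list(min_alt_reads = 1, min_depth = 1))$qual
  expect_true(all(diff(q) > 0))
})

test_that("emitted bundles are byte-identical under a fixed config and parseable", {
  cfg <- small_config(seed = 31)
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  b1 <- emit_dataset(cfg, d1)
  b2 <- emit_dataset(cfg, d2)
  for (k in names(b1$paths)) {
    expect_identical(readLines(b1$paths[[k]]), readLines(b2$paths[[k]]),
                     label = k)
  }
  expect_gt(nrow(read_vcf(b1$paths$srs_vcf)), 0)
  expect_gt(nrow(read_exons(b1$paths$annotation)), 0)
  expect_gt(nrow(read_depth_track(b1$paths$lrs_bedgraph)), 0)
  truth <- read_tsv_table(b1$paths$truth)
  dna <- read_vcf(b1$paths$dna_vcf)
  gk <- variant_key(truth$chrom[truth$class == "g"],
                    truth$pos[truth$class == "g"],
                    truth$ref_aln[truth$class == "g"],
                    truth$alt_aln[truth$class == "g"])
  expect_true(all(gk %in% variant_key_df(dna)))
})
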