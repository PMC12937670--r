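plus_minus_exons <- function() {
  data.frame(chrom = "chrS",
             start = c(0L, 200L, 400L, 450L),
             end = c(100L, 300L, 500L, 550L),
             strand = c("+", "-", "+", "-"),
             gene_id = c("gp", "gm", "ga", "gb"),
             transcript_id = c("gp.t", "gm.t", "ga.t", "gb.t"),
             feature_class = c("CDS", "UTR3", "UTR3", "CDS"),
             frame = c(0L, NA, NA, 0L), stringsAsFactors = FALSE)
}

test_that("biological change is identity on plus genes and complemented on minus genes", {
  ex <- plus_minus_exons()
  rec <- make_records(c(10, 210), ref = c("A", "T"), alt = c("G", "C"))
  out <- assign_strand_and_change(rec, ex)
  expect_equal(out$snvs$bio_ref, c("A", "A"))
  expect_equal(out$snvs$bio_alt, c("G", "G"))
  expect_equal(out$snvs$strand, c("+", "-"))
  expect_equal(out$snvs$region, c("CDS", "UTR3"))
  expect_equal(nrow(out$excluded), 0)
})

test_that("strand conversion is an involution over all 12 substitutions", {
  for (s in SUBSTITUTIONS) {
    r <- sub(">.*", "", s); a <- sub(".*>", "", s)
    cc <- tscs:::complement_change(r, a)
    back <- tscs:::complement_change(cc$ref, cc$alt)
    expect_equal(paste0(back$ref, ">", back$alt), s)
  }
})

test_that("intergenic sites are excluded with a reason; dual-strand overlap is ambiguous", {
  ex <- plus_minus_exons()
  rec <- make_records(150)  # between genes
  out <- assign_strand_and_change(rec, ex)
  expect_equal(nrow(out$snvs), 0)
  expect_equal(out$excluded$reason, "intergenic")
  # overlap both strands -> ambiguous
  rec2 <- make_records(470)  # inside ga (+ UTR3) and gb (- CDS)
  out2 <- assign_strand_and_change(rec2, ex)
  expect_equal(out2$snvs$region, "ambiguous")
  expect_equal(out2$snvs$strand, ".")
})

test_that("region priority resolves multi-transcript positions as CDS first", {
  ex <- data.frame(chrom = "chrS", start = c(0L, 0L), end = c(100L, 100L),
                   strand = "+", gene_id = "g",
                   transcript_id = c("t1", "t2"),
                   feature_class = c("UTR3", "CDS"), frame = c(NA, 0L))
  out <- assign_strand_and_change(make_records(10), ex)
  expect_equal(out$snvs$region, "CDS")
})

test_that("g/e splitting is allele-exact, exhaustive and disjoint", {
  ex <- plus_minus_exons()
  rec <- make_records(c(10, 20, 30), ref = "A", alt = "G")
  snvs <- assign_strand_and_change(rec, ex)$snvs
  genomic <- make_records(c(10, 20), ref = "A", alt = c("G", "T"))
  out <- split_g_e(snvs, genomic)
  expect_equal(out$snv_class, c("g", "e", "e"))  # pos 20 alt mismatch -> e
  expect_equal(sum(out$snv_class == "g") + sum(out$snv_class == "e"),
               nrow(snvs))
  out2 <- split_g_e(snvs, character(0))
  expect_true(all(out2$snv_class == "e"))
})

test_that("known/new flags use the class-matched catalog only", {
  ex <- plus_minus_exons()
  rec <- make_records(c(10, 20), ref = "A", alt = "G")
  snvs <- split_g_e(assign_strand_and_change(rec, ex)$snvs,
                    make_records(10, ref = "A", alt = "G"))
  e_cat <- data.frame(chrom = "chrS", pos = 20L, ref = "A", alt = "G")
  g_cat <- data.frame(chrom = "chrS", pos = 20L, ref = "A", alt = "G")
  # e-SNV present in the e catalog -> known
  out <- known_new(snvs, g_catalog = NULL, e_catalog = e_cat)
  expect_equal(out$known, c("no_catalog", "known"))
  # e-SNV present only in the g catalog -> new
  out2 <- known_new(snvs, g_catalog = g_cat, e_catalog = e_cat[0, ])
  expect_equal(out2$known[2], "new")
  out3 <- known_new(snvs)
  expect_true(all(out3$known == "no_catalog"))
  # idempotent and catalog-order independent
  expect_equal(known_new(out, g_catalog = NULL, e_catalog = e_cat), out)
})

test_that("expression mask keeps FPKM >= threshold and drops absent genes", {
  ex <- plus_minus_exons()
  rec <- make_records(c(10, 210, 520), ref = c("A", "T", "T"),
                      alt = c("G", "C", "C"))
  snvs <- assign_strand_and_change(rec, ex)$snvs
  fpkm <- data.frame(gene_id = c("gp", "gm"), fpkm = c(1, 0.99))
  out <- expression_mask(snvs, fpkm)
  expect_equal(out$gene_id, "gp")  # 1 kept, 0.99 dropped, absent dropped
  dropped <- attr(out, "dropped")
  expect_setequal(dropped$reason, c("low_fpkm", "gene_absent"))
  out2 <- expression_mask(snvs, fpkm[0, ])
  expect_equal(nrow(out2), 0)
})

test_that("simulated g/e classes are recovered through the caller outputs", {
  b <- default_bundle()
  res <- default_pipeline()
  cl <- res$classified
  tk <- variant_key(b$truth$chrom, b$truth$pos, b$truth$ref_aln,
                    b$truth$alt_aln)
  m <- match(variant_key_df(cl), tk)
  agree <- cl$snv_class[!is.na(m)] == b$truth$class[m[!is.na(m)]]
  expect_gte(mean(agree), 0.99)
  # the recovered biological changes match the planted sense-strand ones
  mm <- which(!is.na(m) & cl$region != "ambiguous")
  expect_true(all(cl$bio_ref[mm] == b$truth$ref[m[mm]]))
  expect_true(all(cl$bio_alt[mm] == b$truth$alt[m[mm]]))
})
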