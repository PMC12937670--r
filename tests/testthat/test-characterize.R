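classified_stub <- function(bio_ref, bio_alt, region = "CDS",
                            gene_id = "g1") {
  n <- length(bio_ref)
  data.frame(chrom = "chrS", pos = seq_len(n), ref = bio_ref,
             alt = bio_alt, bio_ref = bio_ref, bio_alt = bio_alt,
             region = rep_len(region, n), gene_id = rep_len(gene_id, n),
             strand = "+", stringsAsFactors = FALSE)
}

test_that("the substitution spectrum counts sense-strand changes and excludes ambiguous sites", {
  cl <- classified_stub(rep("A", 5), rep("G", 5))
  sp <- type_spectrum(cl)
  expect_equal(sp$count[sp$change == "A>G"], 5)
  expect_equal(sum(sp$count), 5)
  expect_equal(sp$fraction[sp$change == "A>G"], 1)
  expect_equal(sum(type_spectrum(cl[0, ])$count), 0)
  cl2 <- rbind(cl, classified_stub("C", "T", region = "ambiguous"))
  expect_equal(sum(type_spectrum(cl2)$count), 5)
})

test_that("flipping every gene strand complements the spectrum", {
  b <- small_bundle()
  res <- assign_strand_and_change(b$srs$calls, b$model$exons)
  sp <- type_spectrum(res$snvs)
  flipped <- b$model$exons
  flipped$strand <- ifelse(flipped$strand == "+", "-", "+")
  sp_f <- type_spectrum(assign_strand_and_change(b$srs$calls,
                                                 flipped)$snvs)
  comp <- vapply(sp$change, function(s) {
    cc <- tscs:::complement_change(sub(">.*", "", s), sub(".*>", "", s))
    paste0(cc$ref, ">", cc$alt)
  }, "")
  expect_equal(sp_f$count[match(comp, sp_f$change)], sp$count)
})

test_that("region distributions count and normalize per region class", {
  cl <- classified_stub(rep("A", 4), rep("G", 4), region = "UTR3")
  rd <- region_distribution(cl)
  expect_equal(rd$fraction[rd$region == "UTR3"], 1)
  expect_equal(sum(region_distribution(cl[0, ])$count), 0)
  expect_equal(region_distribution(cl[sample(4), ]), rd)
})

test_that("coding consequences follow the genetic code on worked examples", {
  # gene: + strand, CDS = ATG AAA GCT TAA at positions 0..11
  ref <- strsplit("ATGAAAGCTTAA", "")[[1]]
  ex <- data.frame(chrom = "chrS", start = 0L, end = 12L, strand = "+",
                   gene_id = "g1", transcript_id = "t1",
                   feature_class = "CDS", frame = 0L)
  cm <- codon_model(ex, ref)
  expect_equal(length(cm$t1$pos), 12)
  # GCT -> GCC : synonymous (Ala)
  syn <- classified_stub("T", "C")
  syn$pos <- 8L
  out <- consequence(syn, cm)
  expect_equal(out$consequence, "synonymous")
  # AAA -> GAA : Lys -> Glu
  ns <- classified_stub("A", "G")
  ns$pos <- 3L
  out2 <- consequence(ns, cm)
  expect_equal(out2$consequence, "nonsynonymous")
  expect_equal(out2$aa_ref, "K")
  expect_equal(out2$aa_alt, "E")
  expect_true(out2$property_changed)  # basic -> acidic
  # AAA -> TAA : stop gain
  sg <- classified_stub("A", "T"); sg$pos <- 3L
  expect_equal(consequence(sg, cm)$consequence, "stop_gain")
  # TAA -> CAA : stop loss
  sl <- classified_stub("T", "C"); sl$pos <- 9L
  expect_equal(consequence(sl, cm)$consequence, "stop_loss")
  # non-CDS variant
  nc <- classified_stub("A", "G", region = "UTR3"); nc$pos <- 3L
  expect_equal(consequence(nc, cm)$consequence, "noncoding")
  # reference mismatch is an error naming the transcript
  bad <- classified_stub("G", "C"); bad$pos <- 3L
  expect_error(consequence(bad, cm), "t1")
})

test_that("consequences agree with full-CDS translation on simulated variants", {
  b <- small_bundle()
  cm <- codon_model(b$model$exons, b$model$ref)
  cds_truth <- b$truth[b$truth$region == "CDS", ]
  set.seed(17)
  cds_truth <- cds_truth[sample(nrow(cds_truth), min(500, nrow(cds_truth))), ]
  cl <- data.frame(chrom = cds_truth$chrom, pos = cds_truth$pos,
                   ref = cds_truth$ref_aln, alt = cds_truth$alt_aln,
                   bio_ref = cds_truth$ref, bio_alt = cds_truth$alt,
                   region = "CDS", gene_id = cds_truth$gene_id,
                   strand = cds_truth$strand, stringsAsFactors = FALSE)
  out <- consequence(cl, cm)
  for (i in seq_len(nrow(out))) {
    tx <- paste0(out$gene_id[i], ".t1")
    m <- cm[[tx]]
    ci <- match(out$pos[i], m$pos)
    expect_equal(out$consequence[i],
                 oracle_consequence(m, ci, out$bio_alt[i]),
                 label = paste("site", out$pos[i]))
  }
})

test_that("property categories partition the 20 residues and compare symmetrically", {
  scheme <- aa_property_scheme()
  expect_length(scheme, 20)
  expect_equal(sort(unique(scheme)),
               sort(c("aliphatic", "aromatic", "sulfur", "basic", "acidic",
                      "amide", "hydroxyl")))
  expect_false(property_change("K", "R")$changed)  # both basic
  pc <- property_change("K", "E")
  expect_true(pc$changed)
  expect_equal(c(pc$category_ref, pc$category_alt), c("basic", "acidic"))
  expect_false(property_change("A", "A")$changed)
  for (a in names(scheme)) for (b_ in names(scheme)) {
    expect_equal(property_change(a, b_)$changed,
                 property_change(b_, a)$changed)
  }
})

test_that("per-gene clustering bins nonsynonymous counts as 1 / 2-5 / >5", {
  cl <- classified_stub(rep("A", 16), rep("G", 16))
  cl$gene_id <- c(paste0("g", 1:10), rep("gBig", 6))
  cl$consequence <- "nonsynonymous"
  out <- per_gene_clustering(cl)
  expect_equal(out$bins$count[out$bins$bin == "1"], 10)
  expect_equal(out$bins$count[out$bins$bin == ">5"], 1)
  empty <- cl[0, ]
  expect_equal(sum(per_gene_clustering(empty)$bins$count), 0)
})
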