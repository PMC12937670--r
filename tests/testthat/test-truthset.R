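lrs_call_at <- function(pos, depth_track_depth, alt_reads, ref = "A",
                        alt = "G") {
  ad <- matrix(0, length(pos), 4, dimnames = list(NULL, BASES_T))
  ad[, match(ref, BASES_T)] <- 50
  ad[, match(alt, BASES_T)] <- alt_reads
  make_records(pos, ref = ref, alt = alt, depth = 50 + alt_reads, ad = ad)
}

test_that("candidate selection applies both long-read thresholds at the boundary", {
  track <- make_track(c(0, 100, 200), c(50, 150, 250), c(12, 9, 50))
  calls <- lrs_call_at(c(10, 110, 210), alt_reads = c(5, 7, 4))
  cand <- select_candidates(calls, track, truthset_params())
  # depth 12 & alt 5 -> in; depth 9 -> out; alt 4 -> out
  expect_equal(cand, variant_key("chrS", 10, "A", "G"))
})

test_that("total-depth candidate mode is switchable", {
  track <- make_track(0, 50, 12)
  calls <- lrs_call_at(10, alt_reads = 4)
  expect_length(select_candidates(calls, track, truthset_params()), 0)
  cand <- select_candidates(calls, track,
                            truthset_params(site_reads_mode = "total"))
  expect_length(cand, 1)
})

test_that("labels follow the precedence rules on enumerated boundary cases", {
  # lrs covers [0,1000) at depth 150 and [1000,2000) at depth 40
  track <- make_track(c(0, 1000), c(1000, 2000), c(150, 40))
  cand <- variant_key("chrS", 10, "A", "G")
  lrs_pos <- data.frame(chrom = "chrS", pos = c(10L, 500L))
  srs <- make_records(c(10, 20, 500, 1500), ref = "A", alt = "G")
  lab <- label_calls(srs, cand, track, lrs_pos, truthset_params())
  expect_equal(lab$label, c("true",       # candidate match
                            "false",      # deep, uncalled by LRS
                            "unlabeled",  # LRS called this position
                            "unlabeled")) # depth 40 < 100
  # allele-exact: same position, different alt is not true
  srs2 <- make_records(10, ref = "A", alt = "T")
  lab2 <- label_calls(srs2, cand, track, lrs_pos, truthset_params())
  expect_equal(lab2$label, "unlabeled")  # position called by LRS blocks false
})

test_that("labels equal exhaustive rule evaluation on boundary grids", {
  params <- truthset_params()
  grid <- expand.grid(depth = c(9, 10, 99, 100), alt = c(4, 5))
  pos <- seq_len(nrow(grid)) * 10L
  track <- make_track(pos, pos + 1L, grid$depth)
  lrs <- lrs_call_at(pos, alt_reads = grid$alt)
  cand <- select_candidates(lrs, track, params)
  srs <- make_records(pos, ref = "A", alt = "G")
  lab <- label_calls(srs, cand, track, lrs[, c("chrom", "pos")], params)
  expect_equal(lab$label, oracle_labels(srs, lrs, track, params))
})

test_that("labels equal the brute-force classifier on random instances", {
  set.seed(77)
  params <- truthset_params()
  for (rep in 1:3) {
    n <- 400
    pos <- sort(sample.int(5000, n))
    track <- make_track(pos, pos + 1L,
                        sample(c(0, 5, 50, 100, 120, 200), n, TRUE))
    lrs_rows <- sort(sample.int(n, n %/% 3))
    lrs <- lrs_call_at(pos[lrs_rows],
                       alt_reads = sample(3:40, length(lrs_rows), TRUE))
    cand <- select_candidates(lrs, track, params)
    srs <- make_records(pos, ref = "A",
                        alt = sample(c("G", "T"), n, TRUE, c(0.8, 0.2)))
    lab <- label_calls(srs, cand, track, lrs[, c("chrom", "pos")], params)
    expect_equal(lab$label, oracle_labels(srs, lrs, track, params))
    # partition property
    expect_equal(sum(table(lab$label)), n)
  }
})

test_that("false labels shrink as the coverage bar rises; true labels grow as the site bar drops", {
  b <- small_bundle()
  base <- truthset_params()
  lab0 <- label_calls(b$srs$calls,
                      select_candidates(b$lrs$calls, b$lrs$track, base),
                      b$lrs$track, b$lrs$calls[, c("chrom", "pos")], base)
  hi <- truthset_params(lrs_false_min_coverage = 200)
  lab1 <- label_calls(b$srs$calls,
                      select_candidates(b$lrs$calls, b$lrs$track, hi),
                      b$lrs$track, b$lrs$calls[, c("chrom", "pos")], hi)
  expect_lte(sum(lab1$label == "false"), sum(lab0$label == "false"))
  lo <- truthset_params(lrs_site_min_reads = 2)
  lab2 <- label_calls(b$srs$calls,
                      select_candidates(b$lrs$calls, b$lrs$track, lo),
                      b$lrs$track, b$lrs$calls[, c("chrom", "pos")], lo)
  expect_gte(sum(lab2$label == "true"), sum(lab0$label == "true"))
})

test_that("true-labeled sites coincide with planted variants on simulated data", {
  b <- default_bundle()
  res <- default_pipeline()
  lab <- res$labeled
  tk <- variant_key(b$truth$chrom, b$truth$pos, b$truth$ref_aln,
                    b$truth$alt_aln)
  true_keys <- variant_key_df(lab[lab$label == "true", ])
  expect_gte(mean(true_keys %in% tk), 0.95)
})

test_that("truthset report counts and balance are consistent", {
  empty <- make_records(integer(0))
  empty$label <- character(0)
  r0 <- truthset_report(empty)
  expect_equal(r0$n, 0)
  lab <- make_records(1:4)
  lab$label <- c("true", "true", "false", "unlabeled")
  r <- truthset_report(lab)
  expect_equal(c(r$n_true, r$n_false, r$n_unlabeled), c(2, 1, 1))
  expect_equal(r$balance, 2 / 3)
  expect_equal(truthset_report(lab[sample(4), ]), r)
})
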