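# Shared fixtures, built lazily once per test run.

fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, builder(), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

# Small bundle: fast, used by most module tests.
small_config <- function(seed = 11) {
  sim_config(n_genes = 40, n_g_variants = 360, n_e_variants = 240,
             seed = seed)
}

small_bundle <- function() memo("small_bundle", function() {
  simulate_bundle(small_config())
})

# The default study-condition bundle (seed 1) and the pipeline run on it;
# shared between the end-to-end tests.
default_bundle <- function() memo("default_bundle", function() {
  simulate_bundle(sim_config(seed = 1))
})

default_pipeline <- function() memo("default_pipeline", function() {
  b <- default_bundle()
  tscs_pipeline(b$srs$calls, b$lrs$calls, b$srs$track, b$lrs$track,
                b$model$exons, b$dna_calls,
                tconfig = train_config(iterations = 10, seed = 1))
})

# Minimal variant-table constructor for rule-level tests.
make_records <- function(pos, ref = "A", alt = "G", qual = 50, depth = 30,
                         chrom = "chrS", ad = NULL) {
  n <- length(pos)
  rec <- data.frame(
    chrom = rep_len(chrom, n), pos = as.integer(pos),
    ref = rep_len(ref, n), alt = rep_len(alt, n),
    qual = rep_len(qual, n), depth = as.integer(rep_len(depth, n)),
    ad_A = rep(NA_real_, n), ad_C = rep(NA_real_, n),
    ad_G = rep(NA_real_, n), ad_T = rep(NA_real_, n),
    mq = rep(NA_real_, n), mq0f = rep(NA_real_, n),
    vdb = rep(NA_real_, n), rpbz = rep(NA_real_, n),
    bqbz = rep(NA_real_, n), mqbz = rep(NA_real_, n),
    sample_id = rep_len("t", n), platform = rep_len("SRS", n),
    stringsAsFactors = FALSE)
  if (!is.null(ad)) {
    rec$ad_A <- ad[, "A"]; rec$ad_C <- ad[, "C"]
    rec$ad_G <- ad[, "G"]; rec$ad_T <- ad[, "T"]
  } else {
    idx_r <- match(rec$ref, c("A", "C", "G", "T"))
    idx_a <- match(rec$alt, c("A", "C", "G", "T"))
    admat <- matrix(0, n, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
    admat[cbind(seq_len(n), idx_r)] <- rec$depth - pmax(1, rec$depth %/% 3)
    admat[cbind(seq_len(n), idx_a)] <- pmax(1, rec$depth %/% 3)
    rec$ad_A <- admat[, "A"]; rec$ad_C <- admat[, "C"]
    rec$ad_G <- admat[, "G"]; rec$ad_T <- admat[, "T"]
  }
  rec
}

make_track <- function(start, end, depth, chrom = "chrS") {
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(end), depth = depth,
             stringsAsFactors = FALSE)
}

random_pileup <- function(n, seed) {
  set.seed(seed)
  counts <- matrix(rpois(4 * n, lambda = sample(0:20, 1)), n, 4,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  data.frame(chrom = "chrS", pos = seq_len(n), ref = sample(BASES_T, n,
                                                            replace = TRUE),
             A = counts[, 1], C = counts[, 2], G = counts[, 3],
             T = counts[, 4], stringsAsFactors = FALSE)
}

BASES_T <- c("A", "C", "G", "T")
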