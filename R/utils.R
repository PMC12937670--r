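#' Variant key strings
#'
#' Builds the allele-exact key `chrom:pos:ref>alt` used for all set
#' operations (truth-set overlap, g/e splitting, catalog lookup). Positions
#' are the package-internal 0-based coordinates.
#'
#' @param chrom,pos,ref,alt vectors of equal length (or length 1, recycled).
#' @return character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  if (length(pos) == 0) return(character(0))
  paste0(chrom, ":", pos, ":", ref, ">", alt)
}

#' @rdname variant_key
#' @param df data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @export
variant_key_df <- function(df) {
  variant_key(df$chrom, df$pos, df$ref, df$alt)
}

# Deterministic child seed: keeps every stage's RNG stream independent of the
# others while being fully determined by (seed, label). Stays below 2^31.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) %% 1000003L) * 2017L + as.integer(h %% 100003L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Complement of bases / substitution strings ("A>G" -> "T>C").
complement_base <- function(b) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  unname(map[b])
}

complement_change <- function(ref, alt) {
  list(ref = complement_base(ref), alt = complement_base(alt))
}

stopifnot_cols <- function(df, cols, what = "input") {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
}

# Consistent empty data frame with given column names/prototypes.
empty_df <- function(proto) {
  as.data.frame(lapply(proto, function(x) x[0]), stringsAsFactors = FALSE)
}
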