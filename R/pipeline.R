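#' Run the full discrimination workflow in memory
#'
#' Chains the four phases over parsed inputs: long-read candidate
#' selection, true/false labeling of short-read calls, 21-feature
#' assembly, five-algorithm training with AUROC selection, scoring of all
#' short-read calls, and g/e categorization of the confirmed set.
#'
#' @param srs_calls,lrs_calls short-/long-read variant tables.
#' @param srs_track,lrs_track matching depth tracks.
#' @param exons feature annotation ([read_exons()]).
#' @param genomic_calls genomic (DNA) variant table.
#' @param tparams [truthset_params()].
#' @param tconfig [train_config()].
#' @param g_catalog,e_catalog,fpkm optional catalog/expression inputs
#'   passed to [categorize_calls()].
#' @return list with `candidates`, `labeled`, `features`, `bundle`,
#'   `scores` (per short-read call), `confirmed` (calls at or above the
#'   decision threshold), `classified`.
#' @export
tscs_pipeline <- function(srs_calls, lrs_calls, srs_track, lrs_track,
                          exons, genomic_calls,
                          tparams = truthset_params(),
                          tconfig = train_config(),
                          g_catalog = NULL, e_catalog = NULL,
                          fpkm = NULL) {
  candidates <- select_candidates(lrs_calls, lrs_track, tparams)
  labeled <- label_calls(srs_calls, candidates, lrs_track,
                         lrs_calls[, c("chrom", "pos")], tparams)
  exon_index <- build_exon_index(srs_track, structural_exons(exons),
                                 srs_calls)
  feats <- assemble_features(labeled, exon_index)
  train_rows <- labeled$label %in% c("true", "false")
  mat_train <- build_matrix(feats[train_rows, , drop = FALSE],
                            labeled$label[train_rows])
  bundle <- train_select(mat_train$x, mat_train$y, tconfig)
  mat_all <- build_matrix(feats)
  scores <- predict_snv(bundle, mat_all$x)
  confirmed <- labeled[scores$call, , drop = FALSE]
  classified <- categorize_calls(confirmed, exons, genomic_calls,
                                 g_catalog, e_catalog, fpkm)
  list(candidates = candidates, labeled = labeled, features = feats,
       bundle = bundle, scores = cbind(key = feats$key, scores),
       confirmed = confirmed, classified = classified)
}

# Reconstruct a pileup-shaped table from call records' AD4 allele depths,
# for reference-set construction from a VCF rather than raw pileups.
pileup_from_calls <- function(calls) {
  out <- data.frame(chrom = calls$chrom, pos = calls$pos, ref = calls$ref,
                    A = calls$ad_A, C = calls$ad_C, G = calls$ad_G,
                    T = calls$ad_T, stringsAsFactors = FALSE)
  out[stats::complete.cases(out[, BASES]), , drop = FALSE]
}

#' Run one workflow subcommand
#'
#' Single programmatic entry point behind the command-line tool. Each
#' subcommand reads its inputs from paths in `config`, writes its
#' artifacts under `config$out`, and snapshots the effective configuration
#' to `config.json` in the output directory. Outputs are deterministic
#' given (inputs, config, seed); on error, files created during the failed
#' run are removed.
#'
#' Subcommands and their main `config` entries:
#' \describe{
#'   \item{simulate}{`sim` (overrides for [sim_config()])}
#'   \item{coverage}{`bedgraph`, `annotation`}
#'   \item{label}{`srs_vcf`, `lrs_vcf`, `lrs_bedgraph`}
#'   \item{features}{`srs_vcf`, `srs_bedgraph`, `annotation`,
#'     `labels` (optional labeled TSV)}
#'   \item{train}{`features` (TSV with a label column), `train`
#'     (overrides for [train_config()])}
#'   \item{predict}{`model`, `features`}
#'   \item{categorize}{`vcf`, `annotation`, `dna_vcf`, optional
#'     `g_catalog`, `e_catalog`, `fpkm`}
#'   \item{benchmark}{`classified`, `dna_vcf`, `lrs_vcf`, `annotation`}
#'   \item{characterize}{`classified`, `annotation`, `reference`}
#'   \item{pipeline}{`bundle` (a simulated bundle directory), optional
#'     `train` overrides}
#' }
#'
#' @param name subcommand name.
#' @param config named list of paths and parameter overrides; must contain
#'   `out` (output directory) and may contain `seed`.
#' @return invisibly, a list of written file paths.
#' @export
run_subcommand <- function(name = c("simulate", "coverage", "label",
                                    "features", "train", "predict",
                                    "categorize", "benchmark",
                                    "characterize", "pipeline"),
                           config = list()) {
  name <- match.arg(name)
  if (is.null(config$out)) stop("config$out (output directory) is required",
                                call. = FALSE)
  known <- c("out", "seed", "sim", "train", "bedgraph", "annotation",
             "srs_vcf", "lrs_vcf", "dna_vcf", "srs_bedgraph",
             "lrs_bedgraph", "labels", "features", "model", "vcf",
             "g_catalog", "e_catalog", "fpkm", "classified", "reference",
             "bundle", "truthset")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (key in intersect(names(config), c("bedgraph", "annotation",
                                         "srs_vcf", "lrs_vcf", "dna_vcf",
                                         "srs_bedgraph", "lrs_bedgraph",
                                         "labels", "features", "model",
                                         "vcf", "g_catalog", "e_catalog",
                                         "fpkm", "classified", "reference",
                                         "bundle"))) {
    if (!file.exists(config[[key]])) {
      stop("input not found: ", config[[key]], call. = FALSE)
    }
  }
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  written <- character(0)
  emit <- function(obj, file) {
    path <- file.path(config$out, file)
    if (is.data.frame(obj)) write_tsv_table(obj, path)
    else if (inherits(obj, "tscs_model")) save_model(obj, path)
    written <<- c(written, path)
    path
  }
  on_fail <- function(e) {
    unlink(written)
    stop("subcommand '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    result <- switch(name,
      simulate = {
        cfg <- do.call(sim_config, modifyList(config$sim %||% list(),
                                              list(seed = seed)))
        b <- emit_dataset(cfg, config$out)
        written <- c(written, unlist(b$paths))
        unlist(b$paths)
      },
      coverage = {
        track <- read_depth_track(config$bedgraph)
        exons <- read_exons(config$annotation)
        st <- exon_depth_stats(track, structural_exons(exons))
        emit(st, "exon_stats.tsv")
      },
      label = {
        srs <- read_vcf(config$srs_vcf, platform = "SRS")
        lrs <- read_vcf(config$lrs_vcf, platform = "LRS")
        track <- read_depth_track(config$lrs_bedgraph)
        tp <- do.call(truthset_params, config$truthset %||% list())
        cand <- select_candidates(lrs, track, tp)
        labeled <- label_calls(srs, cand, track,
                               lrs[, c("chrom", "pos")], tp)
        out <- labeled[, c("chrom", "pos", "ref", "alt", "label")]
        out$key <- variant_key_df(labeled)
        emit(out, "labeled.tsv")
      },
      features = {
        srs <- read_vcf(config$srs_vcf, platform = "SRS")
        track <- read_depth_track(config$srs_bedgraph)
        exons <- read_exons(config$annotation)
        idx <- build_exon_index(track, structural_exons(exons), srs)
        feats <- assemble_features(srs, idx)
        if (!is.null(config$labels)) {
          lab <- read_tsv_table(config$labels)
          feats$label <- lab$label[match(feats$key, lab$key)]
        }
        emit(feats, "features.tsv")
      },
      train = {
        feats <- read_tsv_table(config$features)
        if (is.null(feats$label)) {
          stop("features table has no label column", call. = FALSE)
        }
        rows <- feats$label %in% c("true", "false")
        m <- build_matrix(feats[rows, , drop = FALSE],
                          feats$label[rows])
        tc <- do.call(train_config,
                      modifyList(config$train %||% list(),
                                 list(seed = seed)))
        bundle <- train_select(m$x, m$y, tc)
        emit(bundle, "model.rds")
        emit(bundle$auroc, "model_auroc.tsv")
      },
      predict = {
        bundle <- load_model(config$model)
        feats <- read_tsv_table(config$features)
        m <- build_matrix(feats)
        sc <- predict_snv(bundle, m$x)
        emit(cbind(key = feats$key, sc), "scores.tsv")
      },
      categorize = {
        calls <- read_vcf(config$vcf, platform = "SRS")
        exons <- read_exons(config$annotation)
        dna <- read_vcf(config$dna_vcf, platform = "DNA")
        g_cat <- if (!is.null(config$g_catalog))
          read_catalog(config$g_catalog, "g")
        e_cat <- if (!is.null(config$e_catalog))
          read_catalog(config$e_catalog, "e")
        fpkm <- if (!is.null(config$fpkm)) read_tsv_table(config$fpkm)
        cl <- categorize_calls(calls, exons, dna, g_cat, e_cat, fpkm)
        emit(cl, "classified.tsv")
      },
      benchmark = {
        cl <- read_tsv_table(config$classified)
        dna <- read_vcf(config$dna_vcf, platform = "DNA")
        lrs <- read_vcf(config$lrs_vcf, platform = "LRS")
        exons <- read_exons(config$annotation)
        coding <- exons[exons$feature_class == "CDS", , drop = FALSE]
        g_res <- rs_g(cl[cl$snv_class == "g", , drop = FALSE], dna, coding)
        ref_keys <- build_e_reference(pileup_from_calls(lrs), dna)
        e_res <- rs_e(cl[cl$snv_class == "e", , drop = FALSE], ref_keys)
        emit(rbind(g_res, e_res), "benchmark.tsv")
      },
      characterize = {
        cl <- read_tsv_table(config$classified)
        exons <- read_exons(config$annotation)
        ref <- Biostrings::readDNAStringSet(config$reference)
        names(ref) <- sub(" .*", "", names(ref))
        cm <- codon_model(exons, ref)
        cons <- consequence(cl, cm)
        emit(type_spectrum(cl), "type_spectrum.tsv")
        emit(region_distribution(cl), "region_distribution.tsv")
        emit(cons, "consequence.tsv")
        emit(per_gene_clustering(cons)$bins, "per_gene_bins.tsv")
      },
      pipeline = {
        bd <- config$bundle
        srs <- read_vcf(file.path(bd, "srs.vcf"), platform = "SRS")
        lrs <- read_vcf(file.path(bd, "lrs.vcf"), platform = "LRS")
        dna <- read_vcf(file.path(bd, "dna.vcf"), platform = "DNA")
        srs_track <- read_depth_track(file.path(bd, "srs.bedgraph"))
        lrs_track <- read_depth_track(file.path(bd, "lrs.bedgraph"))
        exons <- read_exons(file.path(bd, "annotation.bed"))
        tc <- do.call(train_config,
                      modifyList(config$train %||% list(),
                                 list(seed = seed)))
        res <- tscs_pipeline(srs, lrs, srs_track, lrs_track, exons, dna,
                             tconfig = tc)
        emit(res$classified, "classified.tsv")
        emit(res$scores, "scores.tsv")
        emit(res$bundle$auroc, "model_auroc.tsv")
        emit(truthset_report(res$labeled), "truthset_report.tsv")
      })
    snap <- file.path(config$out, "config.json")
    jsonlite::write_json(
      list(subcommand = name, seed = seed,
           config = config[setdiff(names(config), "out")]),
      snap, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, snap)
    invisible(written)
  }, error = on_fail)
}
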