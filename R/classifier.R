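#' Area under the ROC curve
#'
#' Rank-based AUROC, equal to the Mann-Whitney U statistic normalized by
#' the product of class sizes; tied scores contribute one half.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels: logical, 0/1, or `"true"`/`"false"`.
#' @return AUROC in `[0, 1]`.
#' @export
compute_auroc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(y) != length(scores)) stop("scores/labels length mismatch")
  n1 <- sum(y)
  n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present to compute AUROC", call. = FALSE)
  }
  r <- rank(scores)  # average ranks for ties
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels > 0)
  l <- tolower(as.character(labels))
  if (!all(l %in% c("true", "false"))) {
    stop("labels must be logical, 0/1, or 'true'/'false'", call. = FALSE)
  }
  l == "true"
}

#' Training configuration
#'
#' Five algorithm families — random forest (`rf`), support-vector machine
#' (`svm`), logistic regression (`lr`), extreme gradient boosting (`xgb`)
#' and gradient-boosted decision trees (`gbdt`) — are each evaluated over
#' `iterations` random stratified train/test splits, and the family with
#' the highest mean held-out AUROC is selected and refit on all data.
#'
#' @param algorithms subset of the five family ids.
#' @param train_fraction training fraction of each split (default 0.8).
#' @param iterations number of random stratified resplits per algorithm
#'   (default 100).
#' @param decision_threshold score threshold for calls (default 0.5).
#' @param seed integer seed; all splits and fits derive from it.
#' @return list of class `tscs_train_config`.
#' @export
train_config <- function(algorithms = c("rf", "svm", "lr", "xgb", "gbdt"),
                         train_fraction = 0.8, iterations = 100,
                         decision_threshold = 0.5, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1, iterations >= 1,
            all(algorithms %in% c("rf", "svm", "lr", "xgb", "gbdt")))
  structure(list(algorithms = algorithms, train_fraction = train_fraction,
                 iterations = as.integer(iterations),
                 decision_threshold = decision_threshold,
                 seed = as.integer(seed)),
            class = "tscs_train_config")
}

fit_algorithm <- function(alg, x, y, seed) {
  set.seed(seed)
  yf <- factor(y, levels = c(FALSE, TRUE))
  switch(alg,
    rf = randomForest::randomForest(x, yf, ntree = 200),
    svm = e1071::svm(x, yf, kernel = "radial", scale = TRUE),
    lr = {
      fit <- suppressWarnings(stats::glm.fit(cbind(1, x), as.numeric(y),
                                             family = binomial()))
      coefs <- fit$coefficients
      coefs[is.na(coefs)] <- 0
      list(coef = coefs)
    },
    xgb = xgboost::xgb.train(
      params = list(objective = "binary:logistic", nthread = 1,
                    max_depth = 6, eta = 0.3, seed = seed),
      data = xgboost::xgb.DMatrix(x, label = as.numeric(y)), nrounds = 100),
    gbdt = xgboost::xgb.train(
      params = list(objective = "binary:logistic", nthread = 1,
                    max_depth = 3, eta = 0.1, subsample = 0.8,
                    seed = seed),
      data = xgboost::xgb.DMatrix(x, label = as.numeric(y)), nrounds = 200),
    stop("unknown algorithm: ", alg))
}

score_algorithm <- function(alg, model, x) {
  switch(alg,
    rf = unname(predict(model, x, type = "prob")[, "TRUE"]),
    svm = {
      pr <- predict(model, x, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      pos_first <- startsWith(colnames(dv)[1], "TRUE")
      unname(plogis(if (pos_first) dv[, 1] else -dv[, 1]))
    },
    lr = unname(plogis(drop(cbind(1, x) %*% model$coef))),
    xgb = ,
    gbdt = unname(predict(model, xgboost::xgb.DMatrix(x))),
    stop("unknown algorithm: ", alg))
}

#' Train five candidate classifiers and select the best by AUROC
#'
#' For each algorithm family, `iterations` random stratified splits
#' (identical splits across families, derived from the seed) are fitted and
#' scored on the held-out portion; the family with the highest mean AUROC
#' is refit on all rows and returned with the per-family AUROC summaries.
#'
#' @param x numeric feature matrix (columns in [feature_names()] order for
#'   workflow use; any fixed column set works).
#' @param labels binary labels (see [compute_auroc()]).
#' @param config a [train_config()].
#' @return a model bundle (class `tscs_model`): `algorithm`, `model`,
#'   `feature_names`, `auroc` (per-family mean/sd data frame),
#'   `threshold`, `config`.
#' @export
train_select <- function(x, labels, config = train_config()) {
  y <- as_binary_labels(labels)
  stopifnot(nrow(x) == length(y))
  if (nrow(x) < 50) stop("need at least 50 labeled rows", call. = FALSE)
  if (sum(y) == 0 || sum(!y) == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  if (all(apply(x, 2, function(col) length(unique(col)) == 1))) {
    stop("degenerate feature matrix: every column is constant",
         call. = FALSE)
  }
  splits <- lapply(seq_len(config$iterations), function(k) {
    set.seed(derive_seed(config$seed, paste0("split", k)))
    idx_pos <- which(y)
    idx_neg <- which(!y)
    train <- c(sample(idx_pos, max(1, round(config$train_fraction *
                                              length(idx_pos)))),
               sample(idx_neg, max(1, round(config$train_fraction *
                                              length(idx_neg)))))
    sort(train)
  })
  res <- lapply(config$algorithms, function(alg) {
    aucs <- vapply(seq_along(splits), function(k) {
      tr <- splits[[k]]
      te <- setdiff(seq_len(nrow(x)), tr)
      fit <- fit_algorithm(alg, x[tr, , drop = FALSE], y[tr],
                           derive_seed(config$seed,
                                       paste0(alg, "_fit", k)))
      compute_auroc(score_algorithm(alg, fit, x[te, , drop = FALSE]),
                    y[te])
    }, numeric(1))
    c(mean = mean(aucs), sd = if (length(aucs) > 1) sd(aucs) else 0)
  })
  summary <- data.frame(algorithm = config$algorithms,
                        mean_auroc = vapply(res, `[[`, 0, "mean"),
                        sd_auroc = vapply(res, `[[`, 0, "sd"),
                        stringsAsFactors = FALSE)
  winner <- summary$algorithm[which.max(summary$mean_auroc)]
  final <- fit_algorithm(winner, x, y,
                         derive_seed(config$seed, paste0(winner, "_final")))
  structure(list(algorithm = winner, model = final,
                 feature_names = colnames(x), auroc = summary,
                 threshold = config$decision_threshold, config = config),
            class = "tscs_model")
}

#' Score and call sites with a trained bundle
#'
#' @param bundle a `tscs_model` from [train_select()].
#' @param x feature matrix with the bundle's columns.
#' @param threshold decision threshold (default: the bundle's).
#' @return data frame with `score` in `[0, 1]` and logical `call`
#'   (`score >= threshold`).
#' @export
predict_snv <- function(bundle, x, threshold = bundle$threshold) {
  stopifnot(inherits(bundle, "tscs_model"))
  if (!is.null(colnames(x)) &&
      !identical(colnames(x), bundle$feature_names)) {
    stop("feature columns do not match the model bundle", call. = FALSE)
  }
  score <- score_algorithm(bundle$algorithm, bundle$model, x)
  data.frame(score = score, call = score >= threshold)
}

#' Evaluate a trained bundle on other labeled samples
#'
#' @param bundle a `tscs_model`.
#' @param samples named list; each element a list with `x` (matrix) and
#'   `labels`.
#' @return data frame with columns `sample`, `auroc`, `n`.
#' @export
cross_sample_evaluate <- function(bundle, samples) {
  if (length(samples) == 0) {
    return(empty_df(list(sample = character(), auroc = numeric(),
                         n = integer())))
  }
  out <- lapply(names(samples), function(nm) {
    s <- samples[[nm]]
    sc <- predict_snv(bundle, s$x)$score
    data.frame(sample = nm, auroc = compute_auroc(sc, s$labels),
               n = nrow(s$x), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Save / load a model bundle
#'
#' The bundle is serialized natively (RDS) next to a portable JSON envelope
#' (`<path>.json`) holding the algorithm id, feature list, per-family AUROC
#' summary and training configuration, so stored models are
#' self-describing.
#'
#' @param bundle a `tscs_model`.
#' @param path file path for the native blob.
#' @return `save_model()` returns `path` invisibly; `load_model()` the
#'   bundle.
#' @export
save_model <- function(bundle, path) {
  stopifnot(inherits(bundle, "tscs_model"))
  saveRDS(bundle, path)
  meta <- list(algorithm = bundle$algorithm,
               feature_names = bundle$feature_names,
               auroc = bundle$auroc, threshold = bundle$threshold,
               config = unclass(bundle$config))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  bundle <- readRDS(path)
  stopifnot(inherits(bundle, "tscs_model"))
  bundle
}
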