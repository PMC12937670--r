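test_that("AUROC matches hand-computed cases including ties", {
  expect_equal(compute_auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(compute_auroc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(compute_auroc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0)), 0.75)
  expect_error(compute_auroc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("AUROC equals the brute-force pairwise oracle with ties at one half", {
  set.seed(19)
  for (rep in 1:50) {
    n <- sample(10:60, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # many ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (sum(labels) == 0 || sum(!labels) == 0) next
    expect_equal(compute_auroc(scores, labels),
                 oracle_auroc(scores, labels), tolerance = 1e-12)
  }
})

sep_matrix <- function(n = 120, p = 5, shift = 4, seed = 1) {
  set.seed(seed)
  y <- rep(c(FALSE, TRUE), each = n / 2)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  x[y, 1] <- x[y, 1] + shift
  list(x = x, y = y)
}

test_that("training selects a perfect model on a separable problem", {
  d <- sep_matrix()
  cfg <- train_config(algorithms = c("lr", "xgb"), iterations = 3,
                      seed = 1)
  bundle <- train_select(d$x, d$y, cfg)
  expect_gte(max(bundle$auroc$mean_auroc), 0.999)
  expect_equal(sort(bundle$auroc$algorithm), sort(c("lr", "xgb")))
})

test_that("each of the five algorithm families separates an easy problem", {
  d <- sep_matrix(n = 100)
  for (alg in c("rf", "svm", "lr", "xgb", "gbdt")) {
    fit <- tscs:::fit_algorithm(alg, d$x, d$y, seed = 2)
    sc <- tscs:::score_algorithm(alg, fit, d$x)
    expect_true(all(sc >= 0 & sc <= 1), label = alg)
    expect_gte(compute_auroc(sc, d$y), 0.99)
  }
})

test_that("permuted labels give chance-level selection AUROC", {
  set.seed(33)
  n <- 300
  x <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- sample(rep(c(TRUE, FALSE), each = n / 2))  # independent of x
  cfg <- train_config(algorithms = "lr", iterations = 100, seed = 7)
  bundle <- train_select(x, y, cfg)
  expect_gte(bundle$auroc$mean_auroc, 0.45)
  expect_lte(bundle$auroc$mean_auroc, 0.55)
})

test_that("training is deterministic under a fixed seed", {
  d <- sep_matrix(n = 100, shift = 1.5, seed = 4)
  cfg <- train_config(algorithms = c("rf", "xgb"), iterations = 3,
                      seed = 11)
  b1 <- train_select(d$x, d$y, cfg)
  b2 <- train_select(d$x, d$y, cfg)
  expect_equal(b1$auroc, b2$auroc)
  expect_equal(b1$algorithm, b2$algorithm)
  expect_equal(predict_snv(b1, d$x), predict_snv(b2, d$x))
})

test_that("degenerate matrices and tiny inputs are rejected", {
  x <- matrix(1, 60, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- rep(c(TRUE, FALSE), 30)
  expect_error(train_select(x, y), "degenerate|constant")
  d <- sep_matrix(n = 20)
  expect_error(train_select(d$x, d$y), "50")
})

test_that("predictions respect the decision threshold monotonically", {
  d <- sep_matrix()
  bundle <- train_select(d$x, d$y,
                         train_config(algorithms = "lr", iterations = 2,
                                      seed = 3))
  expect_true(all(predict_snv(bundle, d$x, threshold = 0)$call))
  expect_false(any(predict_snv(bundle, d$x, threshold = 1 + 1e-9)$call))
  p <- predict_snv(bundle, d$x, threshold = 0.5)
  expect_equal(p$call, p$score >= 0.5)
})

test_that("cross-sample evaluation composes predict and AUROC", {
  d <- sep_matrix()
  bundle <- train_select(d$x, d$y,
                         train_config(algorithms = "lr", iterations = 2,
                                      seed = 3))
  expect_equal(nrow(cross_sample_evaluate(bundle, list())), 0)
  d2 <- sep_matrix(seed = 9)
  samples <- list(train = list(x = d$x, labels = d$y),
                  other = list(x = d2$x, labels = d2$y))
  ev <- cross_sample_evaluate(bundle, samples)
  expect_equal(ev$sample, c("train", "other"))
  expect_gte(min(ev$auroc), 0.99)
  expect_equal(ev, cross_sample_evaluate(bundle, samples))
})

test_that("model bundles round-trip through serialization", {
  d <- sep_matrix()
  bundle <- train_select(d$x, d$y,
                         train_config(algorithms = "lr", iterations = 2,
                                      seed = 3))
  path <- tempfile(fileext = ".rds")
  save_model(bundle, path)
  back <- load_model(path)
  expect_equal(back$feature_names, bundle$feature_names)
  expect_equal(predict_snv(back, d$x), predict_snv(bundle, d$x))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(meta$algorithm, bundle$algorithm)
  expect_equal(meta$feature_names, bundle$feature_names)
})

test_that("the winner is robust to halving the majority class", {
  res <- default_pipeline()
  b <- default_bundle()
  lab <- res$labeled
  rows <- lab$label %in% c("true", "false")
  m <- build_matrix(res$features[rows, ], lab$label[rows])
  y <- tscs:::as_binary_labels(m$y)
  set.seed(3)
  maj <- if (sum(y) > sum(!y)) which(y) else which(!y)
  drop <- sample(maj, length(maj) %/% 2)
  keep <- setdiff(seq_along(y), drop)
  cfg <- train_config(algorithms = "xgb", iterations = 3, seed = 5)
  full <- train_select(m$x, y, cfg)
  half <- train_select(m$x[keep, ], y[keep], cfg)
  expect_lt(abs(full$auroc$mean_auroc - half$auroc$mean_auroc), 0.05)
})
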