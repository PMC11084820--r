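# Confusion accounting, macro metrics, splitting and cross-validation.

test_that("confusion counts match a hand count on the toy case", {
  cc <- confusion_counts(c(1, 1, 2, 3), c(1, 2, 2, 3))
  expect_equal(cc$class, c(1, 2, 3))
  expect_equal(cc$tp, c(1, 1, 1))
  expect_equal(cc$fn, c(1, 0, 0))
  expect_equal(cc$fp, c(0, 1, 0))
  expect_equal(cc$tn, c(2, 2, 3))
})

test_that("confusion invariants hold on random label pairs", {
  set.seed(77)
  for (rep in 1:25) {
    n_cls <- sample(2:6, 1)
    lp <- random_label_pair(sample(5:40, 1), n_cls)
    cc <- confusion_counts(lp$truth, lp$pred, labels = lp$labels)
    total <- attr(cc, "total")
    # per class the four cells tile the sample
    expect_true(all(cc$tp + cc$tn + cc$fp + cc$fn == total))
    expect_equal(sum(cc$tp), sum(lp$truth == lp$pred))
    expect_equal(sum(cc$fp), sum(lp$truth != lp$pred))
    expect_equal(sum(cc$fn), sum(lp$truth != lp$pred))
  }
})

test_that("counts are stable under consistent relabeling", {
  truth <- c(1, 1, 2, 2, 3, 3, 3)
  pred <- c(1, 2, 2, 3, 3, 1, 3)
  cc <- confusion_counts(truth, pred, labels = 1:3)
  # permute labels 1->3, 2->1, 3->2 on both vectors
  perm <- c(3, 1, 2)
  cc2 <- confusion_counts(perm[truth], perm[pred], labels = 1:3)
  reorder <- match(perm, cc2$class)
  expect_equal(cc2$tp[reorder], cc$tp)
  expect_equal(cc2$fp[reorder], cc$fp)
  expect_equal(cc2$fn[reorder], cc$fn)
})

test_that("unknown labels outside the map are rejected", {
  expect_error(confusion_counts(c(1, 5), c(1, 1), labels = 1:3), "unknown label")
})

test_that("a perfect classifier scores 1 on all four macro metrics", {
  cc <- confusion_counts(rep(1:3, each = 3), rep(1:3, each = 3))
  mm <- macro_metrics(cc)
  expect_equal(mm$mACC, 1)
  expect_equal(mm$mPrecision, 1)
  expect_equal(mm$mRecall, 1)
  expect_equal(mm$mF1, 1)
})

test_that("the harmonic mF1 reproduces the reference fold values", {
  harmonic <- function(p, r) 2 * p * r / (p + r)
  # published per-fold macro precision/recall pairs whose printed mF1 is
  # consistent with the harmonic combination
  expect_equal(round(harmonic(0.882, 0.861), 3), 0.871)
  expect_equal(round(harmonic(0.883, 0.857), 3), 0.870)
  expect_equal(round(harmonic(0.8795, 0.870), 3), 0.875)
  expect_equal(round(harmonic(0.876, 0.862), 3), 0.869)
  expect_equal(round(harmonic(0.879, 0.856), 3), 0.867)
})

test_that("macro metrics agree with a brute-force oracle on random tables", {
  set.seed(123)
  for (rep in 1:200) {
    lp <- random_label_pair(sample(4:50, 1), sample(2:8, 1))
    cc <- confusion_counts(lp$truth, lp$pred, labels = lp$labels)
    mm <- macro_metrics(cc)
    bf <- brute_macro_metrics(cc)
    for (k in c("mACC", "mPrecision", "mRecall", "mF1")) {
      expect_equal(mm[[k]], bf[[k]], tolerance = 1e-12)
    }
    # the one-vs-rest identity: mACC = 1 - 2 (1 - accuracy) / N
    acc <- mean(lp$truth == lp$pred)
    expect_equal(mm$mACC, 1 - 2 * (1 - acc) / length(lp$labels),
                 tolerance = 1e-12)
    # mF1 lies between the two macro averages it combines
    expect_gte(mm$mF1 + 1e-12, min(mm$mPrecision, mm$mRecall))
    expect_lte(mm$mF1 - 1e-12, max(mm$mPrecision, mm$mRecall))
  }
})

test_that("zero-denominator classes contribute zero but stay averaged", {
  # class 3 never occurs and is never predicted: precision = recall = 0
  cc <- confusion_counts(c(1, 1, 2), c(1, 1, 2), labels = 1:3)
  mm <- macro_metrics(cc)
  expect_equal(mm$per_class$precision, c(1, 1, 0))
  expect_equal(mm$mPrecision, 2 / 3)
  expect_equal(mm$mRecall, 2 / 3)
})

test_that("train/test split is disjoint, exhaustive and seed-stable", {
  sp <- train_test_split(10, ratio = 0.8, seed = 1)
  expect_length(sp$train, 8L)
  expect_length(sp$test, 2L)
  expect_identical(train_test_split(10, ratio = 0.8, seed = 1), sp)
  for (seed in 1:100) {
    s <- train_test_split(37, ratio = 0.8, seed = seed)
    expect_equal(sort(c(s$train, s$test)), 1:37)
    expect_length(intersect(s$train, s$test), 0L)
    expect_lte(abs(length(s$train) - 0.8 * 37), 1)
  }
  expect_error(train_test_split(1), "at least 2")
  expect_error(train_test_split(10, ratio = 1.2), "ratio")
})

test_that("cross-validation partitions samples and summarizes folds", {
  spec <- fixture_spec(n_per_class = 4, width = 12, seed = 9)
  emb <- make_synthetic_embeddings(spec)
  cfg <- ns_config(gru_hidden = 4, attention_heads = 2, epochs = 40,
                   batch_size = 64, seed = 2)
  # classes with fewer samples than folds are flagged
  expect_warning(
    cv <- cross_validate(emb$x, emb$labels, k = 5, config = cfg),
    "fewer than k")
  test_sets <- lapply(cv$folds, `[[`, "test_idx")
  expect_equal(sort(unlist(test_sets)), seq_len(nrow(emb$x)))
  expect_equal(sum(lengths(test_sets)), nrow(emb$x))
  # summary mean equals the hand-computed mean of the fold values
  fold_macc <- vapply(cv$folds, function(f) f$metrics$mACC, numeric(1))
  expect_equal(cv$summary$mean[cv$summary$metric == "mACC"], mean(fold_macc))
  expect_equal(cv$summary$sd[cv$summary$metric == "mACC"], sd(fold_macc))
  expect_equal(cv$table$fold[nrow(cv$table)], "Average")
  expect_error(cross_validate(emb$x, emb$labels, k = 1000, config = cfg),
               "k must not exceed")
})

test_that("the cross-validation report mirrors the fold-table layout", {
  spec <- fixture_spec(n_per_class = 8, width = 10, seed = 14, ns_labels = c(1, 2, 4))
  emb <- make_synthetic_embeddings(spec)
  cfg <- ns_config(gru_hidden = 2, attention_heads = 1, epochs = 20,
                   batch_size = 32, seed = 6, ns_labels = c(1, 2, 4))
  cv <- suppressWarnings(cross_validate(emb$x, emb$labels, k = 3, config = cfg))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cv_report(cv, path)
  rep <- read.delim(path, stringsAsFactors = FALSE)
  expect_equal(names(rep), c("fold", "mPrecision", "mRecall", "mACC", "mF1"))
  expect_equal(nrow(rep), 4L)  # 3 folds + Average
  expect_match(rep$mPrecision[4], "^\\d\\.\\d{3} ± \\d\\.\\d{3}$")
})
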