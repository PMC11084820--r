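# Multi-class evaluation: one-vs-rest confusion accounting, macro-averaged
# metrics, train/test splitting and k-fold cross-validation.

#' One-vs-rest confusion counts
#'
#' For each class i of the label map, counts true positives, true
#' negatives, false positives and false negatives of the prediction vector
#' treated as a one-vs-rest problem. For every class
#' `TP + TN + FP + FN = total`; summed over classes, TP gives the number of
#' correct predictions and FP and FN each give the number of errors.
#'
#' @param truth,predicted Equal-length label vectors.
#' @param labels Label map; defaults to the sorted union of the inputs.
#'   Values outside the map raise an error.
#' @return A data frame of class `confusion_counts` with columns `class`,
#'   `tp`, `tn`, `fp`, `fn`, and attribute `total`.
#' @export
confusion_counts <- function(truth, predicted, labels = NULL) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have the same length")
  }
  if (is.null(labels)) labels <- sort(unique(c(truth, predicted)))
  if (!all(truth %in% labels) || !all(predicted %in% labels)) {
    stop("unknown label outside the label map")
  }
  total <- length(truth)
  rows <- lapply(labels, function(cl) {
    tp <- sum(truth == cl & predicted == cl)
    fp <- sum(truth != cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    data.frame(class = cl, tp = tp, tn = total - tp - fp - fn,
               fp = fp, fn = fn)
  })
  out <- do.call(rbind, rows)
  attr(out, "total") <- total
  class(out) <- c("confusion_counts", "data.frame")
  out
}

#' Macro-averaged classification metrics
#'
#' Computes the four macro metrics from one-vs-rest confusion counts:
#'
#' * `mACC`: mean over classes of `(TP_i + TN_i) / total`;
#' * `mPrecision`: mean of `TP_i / (TP_i + FP_i)`;
#' * `mRecall`: mean of `TP_i / (TP_i + FN_i)`;
#' * `mF1`: the harmonic combination
#'   `2 * mPrecision * mRecall / (mPrecision + mRecall)`.
#'
#' A per-class precision or recall with a zero denominator contributes 0 to
#' its macro average and the class stays in the average — a class the model
#' never predicts correctly (e.g. a rare stoichiometry) must drag the score
#' down rather than silently vanish. Because the two mF1 conventions in use
#' differ, the macro average of per-class F1 scores is also reported as
#' `mF1_per_class`.
#'
#' @param counts A `confusion_counts` object.
#' @return A list of class `metrics_report`: `mACC`, `mPrecision`,
#'   `mRecall`, `mF1`, `mF1_per_class`, and `per_class` (data frame with
#'   per-class precision/recall/F1).
#' @examples
#' cc <- confusion_counts(c(1, 1, 2, 3), c(1, 2, 2, 3))
#' macro_metrics(cc)$mACC
#' @export
macro_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- attr(counts, "total")
  if (total == 0L) stop("cannot compute metrics for zero samples")
  safe_div <- function(a, b) ifelse(b == 0, 0, a / b)
  prec <- safe_div(counts$tp, counts$tp + counts$fp)
  rec <- safe_div(counts$tp, counts$tp + counts$fn)
  acc <- (counts$tp + counts$tn) / total
  f1 <- safe_div(2 * prec * rec, prec + rec)
  mPrecision <- mean(prec)
  mRecall <- mean(rec)
  mF1 <- if (mPrecision + mRecall == 0) 0 else {
    2 * mPrecision * mRecall / (mPrecision + mRecall)
  }
  structure(list(
    mACC = mean(acc), mPrecision = mPrecision, mRecall = mRecall,
    mF1 = mF1, mF1_per_class = mean(f1),
    per_class = data.frame(class = counts$class, precision = prec,
                           recall = rec, f1 = f1)),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("mACC %.3f  mPrecision %.3f  mRecall %.3f  mF1 %.3f\n",
              x$mACC, x$mPrecision, x$mRecall, x$mF1))
  invisible(x)
}

#' Seeded train/test split
#'
#' Randomly partitions `n` samples into disjoint, exhaustive train and test
#' index sets whose sizes respect `ratio` to within one sample. The default
#' 8:2 split matches the reference protocol.
#'
#' @param n Number of samples (at least 2).
#' @param ratio Training fraction, strictly between 0 and 1.
#' @param seed Integer seed; the same seed reproduces the same partition.
#' @return List with integer index vectors `train` and `test`.
#' @export
train_test_split <- function(n, ratio = 0.8, seed = 1L) {
  if (n < 2L) stop("need at least 2 samples to split")
  if (ratio <= 0 || ratio >= 1) stop("ratio must lie strictly in (0, 1)")
  with_seed(seed, {
    train <- sort(sample.int(n, round(ratio * n)))
    list(train = train, test = setdiff(seq_len(n), train))
  })
}

#' k-fold cross-validation of the NS classifier
#'
#' Randomly divides the dataset into `k` parts; each round trains on
#' `k - 1` parts and evaluates on the held-out part, so every sample
#' appears in exactly one test fold. Folds are random by default
#' (`stratified = TRUE` balances class proportions across folds). The
#' summary row reports the arithmetic mean and the sample standard
#' deviation (n − 1) of each macro metric across folds.
#'
#' @param x Pooled-embedding matrix.
#' @param labels NS labels.
#' @param k Number of folds.
#' @param config An [ns_config()]; fold f trains with seed
#'   `config$seed + f` so folds are independent but reproducible.
#' @param stratified Balance class counts across folds.
#' @param seed Seed for the fold assignment.
#' @return A list of class `ns_cv`: `folds` (per-fold list with `fold`,
#'   `metrics`, `train_idx`, `test_idx`), `table` (data frame mirroring the
#'   per-fold metric table with an `Average` row), and `summary` (mean and
#'   sd per metric).
#' @export
cross_validate <- function(x, labels, k = 10L, config = ns_config(),
                           stratified = FALSE, seed = config$seed) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k > n) stop("k must not exceed the number of samples")
  class_sizes <- table(labels)
  if (any(class_sizes < k)) {
    warning(sprintf("class(es) %s have fewer than k = %d samples",
                    paste(names(class_sizes)[class_sizes < k], collapse = ", "),
                    k), call. = FALSE)
  }
  fold_id <- with_seed(seed, {
    if (stratified) {
      id <- integer(n)
      for (cl in names(class_sizes)) {
        idx <- which(labels == cl)
        id[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
      id
    } else {
      sample(rep_len(seq_len(k), n))
    }
  })
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(fold_id == f)
    train_idx <- which(fold_id != f)
    cfg <- config
    cfg$seed <- config$seed + f
    model <- train_ns_classifier(x[train_idx, , drop = FALSE],
                                 labels[train_idx], cfg)
    pred <- predict(model, x[test_idx, , drop = FALSE])
    cc <- confusion_counts(labels[test_idx], pred, labels = config$ns_labels)
    folds[[f]] <- list(fold = f, metrics = macro_metrics(cc),
                       train_idx = train_idx, test_idx = test_idx)
  }
  per_fold <- do.call(rbind, lapply(folds, function(fr) {
    data.frame(fold = as.character(fr$fold),
               mPrecision = fr$metrics$mPrecision,
               mRecall = fr$metrics$mRecall,
               mACC = fr$metrics$mACC,
               mF1 = fr$metrics$mF1,
               stringsAsFactors = FALSE)
  }))
  metric_cols <- c("mPrecision", "mRecall", "mACC", "mF1")
  means <- vapply(per_fold[metric_cols], mean, numeric(1L))
  sds <- vapply(per_fold[metric_cols], stats::sd, numeric(1L))
  table <- rbind(per_fold,
                 data.frame(fold = "Average", t(means), stringsAsFactors = FALSE))
  structure(list(folds = folds, table = table,
                 summary = data.frame(metric = metric_cols, mean = unname(means),
                                      sd = unname(sds))),
            class = "ns_cv")
}

#' @export
print.ns_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation\n", length(x$folds)))
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write a cross-validation report as TSV
#'
#' One row per fold plus an `Average` row with `mean +/- sd` cells.
#'
#' @param cv An `ns_cv` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(cv, path) {
  tab <- cv$table[cv$table$fold != "Average", ]
  avg <- vapply(seq_len(nrow(cv$summary)), function(i) {
    sprintf("%.3f ± %.3f", cv$summary$mean[i], cv$summary$sd[i])
  }, character(1L))
  out <- rbind(
    data.frame(fold = tab$fold,
               mPrecision = sprintf("%.3f", tab$mPrecision),
               mRecall = sprintf("%.3f", tab$mRecall),
               mACC = sprintf("%.3f", tab$mACC),
               mF1 = sprintf("%.3f", tab$mF1), stringsAsFactors = FALSE),
    data.frame(fold = "Average", mPrecision = avg[1L], mRecall = avg[2L],
               mACC = avg[3L], mF1 = avg[4L], stringsAsFactors = FALSE))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
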