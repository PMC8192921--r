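#' Confusion counts for a binary prediction
#'
#' @param truth Integer vector of true labels (1 = driver, 0 = passenger).
#' @param predicted Integer vector of predicted labels.
#' @return Object of class `confusion_counts`: list with `pos_total` (P+),
#'   `neg_total` (P-), `fn` (drivers predicted passenger), `fp` (passengers
#'   predicted driver).
#' @export
confusion_counts <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  structure(list(pos_total = sum(truth == 1L),
                 neg_total = sum(truth == 0L),
                 fn = sum(truth == 1L & predicted == 0L),
                 fp = sum(truth == 0L & predicted == 1L)),
            class = "confusion_counts")
}

#' Sensitivity, specificity, accuracy and MCC from confusion counts
#'
#' The four metrics in their count-ratio formulation: Sn = 1 - fn/P+,
#' Sp = 1 - fp/P-, Acc = 1 - (fn + fp)/(P+ + P-), and
#' MCC = (1 - (fn/P+ + fp/P-)) / sqrt((1 + (fp - fn)/P+)(1 + (fn - fp)/P-)),
#' which is algebraically identical to the familiar TP/TN/FP/FN product form.
#' A zero MCC denominator (every prediction in one class) returns 0 by
#' convention, flagged via `mcc_degenerate`.
#'
#' @param counts A [confusion_counts] (or list with the same fields).
#' @param protocol Label of the producing validation protocol.
#' @return Object of class `metrics_report`: list with `sn`, `sp`, `acc`,
#'   `mcc` (all on the 0-1 / -1..1 scale), `counts`, `protocol`,
#'   `mcc_degenerate`.
#' @export
classification_metrics <- function(counts, protocol = "custom") {
  pp <- counts$pos_total; pn <- counts$neg_total
  fn <- counts$fn; fp <- counts$fp
  if (pp < 1L || pn < 1L) stop("both classes must be non-empty", call. = FALSE)
  if (fn < 0L || fn > pp || fp < 0L || fp > pn) {
    stop("confusion counts out of range", call. = FALSE)
  }
  sn <- 1 - fn / pp
  sp <- 1 - fp / pn
  acc <- 1 - (fn + fp) / (pp + pn)
  den2 <- (1 + (fp - fn) / pp) * (1 + (fn - fp) / pn)
  degenerate <- den2 <= 0
  mcc <- if (degenerate) 0 else (1 - (fn / pp + fp / pn)) / sqrt(den2)
  structure(list(sn = sn, sp = sp, acc = acc, mcc = mcc,
                 counts = counts, protocol = protocol,
                 mcc_degenerate = degenerate),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %s\n  Sn = %.4f  Sp = %.4f  Acc = %.4f  MCC = %.4f%s\n",
              x$protocol, x$sn, x$sp, x$acc, x$mcc,
              if (isTRUE(x$mcc_degenerate)) " (MCC degenerate, set to 0)" else ""))
  invisible(x)
}

metrics_from_predictions <- function(truth, predicted, protocol) {
  classification_metrics(confusion_counts(truth, predicted), protocol = protocol)
}

#' ROC curve and trapezoidal AUC
#'
#' Sweeps the decision threshold over the unique scores (ties grouped into
#' one step) from +Inf downward; AUC is computed by the trapezoidal rule and
#' equals the Mann-Whitney pair statistic with ties counted one half.
#'
#' @param labels Binary truth vector (both classes present).
#' @param scores Finite class-1 scores.
#' @return Object of class `roc_curve`: list with `thresholds`, `fpr`, `tpr`
#'   (non-decreasing sweeps), and `auc`.
#' @export
roc_curve <- function(labels, scores) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores), all(is.finite(scores)))
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) stop("ROC requires both classes", call. = FALSE)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & labels == 1L), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & labels == 0L), numeric(1))
  tpr <- c(0, tp / np, 1)
  fpr <- c(0, fp / nn, 1)
  thresholds <- c(Inf, thr, -Inf)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = thresholds, fpr = fpr, tpr = tpr, auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, AUC = %.4f\n", length(x$fpr), x$auc))
  invisible(x)
}

average_reports <- function(reports, protocol, pooled = FALSE) {
  if (pooled) {
    tot <- list(pos_total = sum(vapply(reports, function(r) r$counts$pos_total, 0)),
                neg_total = sum(vapply(reports, function(r) r$counts$neg_total, 0)),
                fn = sum(vapply(reports, function(r) r$counts$fn, 0)),
                fp = sum(vapply(reports, function(r) r$counts$fp, 0)))
    out <- classification_metrics(tot, protocol = protocol)
  } else {
    pick <- function(f) vapply(reports, `[[`, 0, f)
    out <- structure(list(sn = mean(pick("sn")), sp = mean(pick("sp")),
                          acc = mean(pick("acc")), mcc = mean(pick("mcc")),
                          counts = NULL, protocol = protocol,
                          mcc_degenerate = any(vapply(reports, `[[`, TRUE, "mcc_degenerate"))),
                     class = "metrics_report")
  }
  out$sd <- list(sn = stats::sd(vapply(reports, `[[`, 0, "sn")),
                 sp = stats::sd(vapply(reports, `[[`, 0, "sp")),
                 acc = stats::sd(vapply(reports, `[[`, 0, "acc")),
                 mcc = stats::sd(vapply(reports, `[[`, 0, "mcc")))
  out$per_run <- reports
  out
}

#' Self-consistency validation
#'
#' Trains on all rows and evaluates on those same rows: the most basic check
#' that the model can represent its own training data.
#'
#' @param fm A `feature_matrix`.
#' @param config A [model_config].
#' @return List with `metrics` (a `metrics_report`, protocol
#'   `"self-consistency"`) and `roc` (a `roc_curve`).
#' @export
self_consistency <- function(fm, config = model_config()) {
  model <- train_model(fm, config)
  pred <- predict(model, fm)
  list(metrics = metrics_from_predictions(fm$labels, pred$labels, "self-consistency"),
       roc = roc_curve(fm$labels, pred$scores))
}

stratified_split <- function(labels, train_fraction, stratify = TRUE) {
  n <- length(labels)
  if (!stratify) {
    train <- sample.int(n, size = round(train_fraction * n))
    return(sort(train))
  }
  train <- integer(0)
  for (cls in c(0L, 1L)) {
    idx <- which(labels == cls)
    take <- round(train_fraction * length(idx))
    take <- min(max(take, 1L), length(idx) - 1L)
    train <- c(train, sample(idx, take))
  }
  sort(train)
}

stratified_folds <- function(labels, k, stratify = TRUE) {
  n <- length(labels)
  fold <- integer(n)
  if (!stratify) {
    fold <- sample(rep_len(seq_len(k), n))
    return(fold)
  }
  for (cls in c(0L, 1L)) {
    idx <- sample(which(labels == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Repeated independent-split testing
#'
#' Repeated stratified random train/test partitions (default 70% train),
#' with per-repeat metrics on the held-out fraction and a headline report
#' that macro-averages the four metrics over the repeats (per-repeat standard
#' deviations attached as `$sd`; `pooled = TRUE` recomputes the headline from
#' summed confusion counts instead).
#'
#' @param fm A `feature_matrix`.
#' @param config A [model_config].
#' @param train_fraction Fraction of each class used for training.
#' @param repeats Number of random partitions.
#' @param seed Integer seed for the partition sequence.
#' @param stratify Preserve the class ratio in each partition?
#' @param pooled Average by pooling confusion counts instead of macro-average.
#' @return A `metrics_report` (protocol `"independent-split"`) with `per_run`.
#' @export
independent_split_test <- function(fm, config = model_config(),
                                   train_fraction = 0.7, repeats = 10L,
                                   seed = 1L, stratify = TRUE, pooled = FALSE) {
  if (min(sum(fm$labels == 1L), sum(fm$labels == 0L)) < 2L) {
    stop("each class needs at least 2 samples to stratify a split", call. = FALSE)
  }
  reports <- with_seed(seed, {
    lapply(seq_len(repeats), function(r) {
      train <- stratified_split(fm$labels, train_fraction, stratify)
      test <- setdiff(seq_along(fm$labels), train)
      model <- train_model(subset_feature_matrix(fm, train), config)
      pred <- predict(model, subset_feature_matrix(fm, test))
      metrics_from_predictions(fm$labels[test], pred$labels,
                               sprintf("independent-split repeat %d", r))
    })
  })
  average_reports(reports, "independent-split", pooled = pooled)
}

#' Stratified k-fold cross-validation
#'
#' Seeded partition into k disjoint folds covering every sample exactly once
#' (stratified by class); each fold is tested on a model trained on the other
#' k-1 folds and the four metrics are macro-averaged over folds.
#'
#' @param fm A `feature_matrix`.
#' @param config A [model_config].
#' @param k Number of folds (at most the smaller class size).
#' @param seed Integer seed for the fold assignment.
#' @param stratify Preserve the class ratio across folds?
#' @param pooled Average by pooling confusion counts instead of macro-average.
#' @return A `metrics_report` (protocol `"cross-validation"`) with `per_run`
#'   and the fold assignment as `$folds`.
#' @export
kfold_cv <- function(fm, config = model_config(), k = 10L, seed = 1L,
                     stratify = TRUE, pooled = FALSE) {
  smallest <- min(sum(fm$labels == 1L), sum(fm$labels == 0L))
  if (k > smallest && stratify) {
    stop(sprintf("k = %d exceeds the smaller class size %d", k, smallest),
         call. = FALSE)
  }
  if (k < 2L || k > length(fm$labels)) stop("k must be in 2..n", call. = FALSE)
  fold <- with_seed(seed, stratified_folds(fm$labels, k, stratify))
  reports <- lapply(seq_len(k), function(f) {
    test <- which(fold == f)
    train <- which(fold != f)
    model <- train_model(subset_feature_matrix(fm, train), config)
    pred <- predict(model, subset_feature_matrix(fm, test))
    if (min(sum(fm$labels[test] == 1L), sum(fm$labels[test] == 0L)) == 0L) {
      # unstratified folds can be single-class; score them on accuracy only
      cc <- confusion_counts(fm$labels[test], pred$labels)
      cc$pos_total <- max(cc$pos_total, 1L); cc$neg_total <- max(cc$neg_total, 1L)
      return(classification_metrics(cc, protocol = sprintf("cv fold %d", f)))
    }
    metrics_from_predictions(fm$labels[test], pred$labels, sprintf("cv fold %d", f))
  })
  out <- average_reports(reports, "cross-validation", pooled = pooled)
  out$folds <- fold
  out
}

#' Run the full validation battery
#'
#' Self-consistency, repeated independent split, and k-fold cross-validation
#' for one backend configuration, as a named list of reports.
#'
#' @inheritParams kfold_cv
#' @inheritParams independent_split_test
#' @return List with elements `self`, `independent`, `cv`.
#' @export
evaluate_all_protocols <- function(fm, config = model_config(), k = 10L,
                                   train_fraction = 0.7, repeats = 10L,
                                   seed = 1L) {
  list(self = self_consistency(fm, config),
       independent = independent_split_test(fm, config,
                                            train_fraction = train_fraction,
                                            repeats = repeats, seed = seed),
       cv = kfold_cv(fm, config, k = k, seed = seed))
}
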