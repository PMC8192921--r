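test_that("metric formulas reproduce the analytic identities", {
  # balanced predictor wrong on half of each class: Acc = 0.5, MCC = 0
  half <- classification_metrics(list(pos_total = 100, neg_total = 100,
                                      fn = 50, fp = 50))
  expect_equal(half$acc, 0.5)
  expect_equal(half$mcc, 0)

  # perfect predictor: Sn = Sp = Acc = MCC = 1
  perfect <- classification_metrics(list(pos_total = 30, neg_total = 70,
                                         fn = 0, fp = 0))
  expect_equal(perfect$sn, 1)
  expect_equal(perfect$sp, 1)
  expect_equal(perfect$acc, 1)
  expect_equal(perfect$mcc, 1)

  # everything wrong: Acc = 0, MCC = -1
  worst <- classification_metrics(list(pos_total = 40, neg_total = 60,
                                       fn = 40, fp = 60))
  expect_equal(worst$acc, 0)
  expect_equal(worst$mcc, -1)

  expect_error(classification_metrics(list(pos_total = 0, neg_total = 5,
                                           fn = 0, fp = 0)), "non-empty")
  expect_error(classification_metrics(list(pos_total = 5, neg_total = 5,
                                           fn = 6, fp = 0)), "range")
})

test_that("readable MCC form equals product-form MCC on random tables", {
  set.seed(50)
  for (i in 1:200) {
    pp <- sample(1:200, 1); pn <- sample(1:200, 1)
    fn <- sample(0:pp, 1); fp <- sample(0:pn, 1)
    rep_ <- classification_metrics(list(pos_total = pp, neg_total = pn,
                                        fn = fn, fp = fp))
    expect_equal(rep_$mcc, oracle_mcc_product(pp, pn, fn, fp),
                 tolerance = 1e-12)
  }
})

test_that("degenerate all-one-class predictions give MCC 0, flagged", {
  rep_ <- classification_metrics(list(pos_total = 10, neg_total = 10,
                                      fn = 10, fp = 0))  # everything passenger
  expect_equal(rep_$mcc, 0)
  expect_true(rep_$mcc_degenerate)
})

test_that("Sn/Sp/Acc are monotone in the error counts", {
  for (pp in c(3, 11, 20)) {
    for (pn in c(4, 20)) {
      sn <- vapply(0:pp, function(fn) {
        classification_metrics(list(pos_total = pp, neg_total = pn,
                                    fn = fn, fp = 0))$sn
      }, numeric(1))
      expect_true(all(diff(sn) < 0))
      sp <- vapply(0:pn, function(fp) {
        classification_metrics(list(pos_total = pp, neg_total = pn,
                                    fn = 0, fp = fp))$sp
      }, numeric(1))
      expect_true(all(diff(sp) < 0))
      acc <- vapply(0:min(pp, pn), function(e) {
        classification_metrics(list(pos_total = pp, neg_total = pn,
                                    fn = e, fp = e))$acc
      }, numeric(1))
      expect_true(all(diff(acc) < 0))
    }
  }
})

test_that("roc_curve handles perfect, chance, and the hand-worked 6-point set", {
  labels <- c(1, 1, 1, 0, 0, 0)
  expect_equal(roc_curve(labels, labels)$auc, 1)
  expect_equal(roc_curve(labels, rep(0.3, 6))$auc, 0.5)
  r <- roc_curve(labels, c(.9, .8, .4, .6, .3, .1))
  expect_equal(r$auc, 8 / 9, tolerance = 1e-12)
  expect_true(all(diff(r$tpr) >= 0))
  expect_true(all(diff(r$fpr) >= 0))
  expect_error(roc_curve(c(1, 1), c(.2, .3)), "both classes")
})

test_that("trapezoidal AUC equals the Mann-Whitney pair statistic", {
  set.seed(51)
  for (i in 1:60) {
    n <- sample(6:40, 1)
    labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), sample(1:3, 1))  # coarse rounding forces ties
    expect_equal(roc_curve(labels, scores)$auc,
                 oracle_auc_pairs(labels, scores), tolerance = 1e-12)
  }
})

fm_eval <- tiny_feature_matrix(n_pos = 20, n_neg = 24, length = 80,
                               separation = 1, seed = 52)

test_that("self-consistency wires train-set predictions into the report", {
  out <- self_consistency(fm_eval, model_config("rf", seed = 1))
  expect_equal(out$metrics$protocol, "self-consistency")
  cc <- out$metrics$counts
  expect_equal(cc$pos_total + cc$neg_total, length(fm_eval$labels))
  expect_gte(out$metrics$acc, 0.99)
  model <- train_model(fm_eval, model_config("rf", seed = 1))
  pred <- predict(model, fm_eval)
  manual <- classification_metrics(confusion_counts(fm_eval$labels, pred$labels))
  expect_equal(out$metrics$acc, manual$acc)
})

test_that("kfold_cv partitions every sample exactly once, stratified", {
  cv <- kfold_cv(fm_eval, model_config("rf", seed = 1), k = 4, seed = 9)
  fold <- cv$folds
  expect_equal(sort(unique(fold)), 1:4)
  expect_length(fold, length(fm_eval$labels))
  # stratification: positive count per fold within 1 of the ideal share
  pos_per_fold <- tapply(fm_eval$labels, fold, sum)
  expect_true(all(abs(pos_per_fold - sum(fm_eval$labels) / 4) <= 1))
  expect_length(cv$per_run, 4L)
  expect_error(kfold_cv(fm_eval, k = 21), "class size")
})

test_that("leave-one-out (k = n, unstratified) runs without error", {
  fm_small <- tiny_feature_matrix(n_pos = 4, n_neg = 4, length = 40, seed = 53)
  expect_no_error(kfold_cv(fm_small, model_config("svm", seed = 1),
                           k = 8, seed = 1, stratify = FALSE))
})

test_that("independent_split_test is seed-deterministic and averages repeats", {
  cfg <- model_config("rf", seed = 2)
  r1 <- independent_split_test(fm_eval, cfg, repeats = 3, seed = 7)
  r2 <- independent_split_test(fm_eval, cfg, repeats = 3, seed = 7)
  expect_equal(r1$acc, r2$acc)
  expect_length(r1$per_run, 3L)
  expect_equal(r1$acc, mean(vapply(r1$per_run, `[[`, 0, "acc")))
  expect_false(is.null(r1$sd))
  # pooled mode recomputes from summed counts
  rp <- independent_split_test(fm_eval, cfg, repeats = 3, seed = 7, pooled = TRUE)
  expect_equal(rp$counts$pos_total,
               sum(vapply(r1$per_run, function(r) r$counts$pos_total, 0)))
})

test_that("evaluate_all_protocols returns the three reports", {
  out <- evaluate_all_protocols(fm_eval, model_config("svm", seed = 1),
                                k = 4, repeats = 2, seed = 1)
  expect_named(out, c("self", "independent", "cv"))
  expect_s3_class(out$cv, "metrics_report")
  expect_s3_class(out$self$roc, "roc_curve")
})
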