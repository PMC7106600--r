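test_that("the reconstructed confusion matrix reproduces all printed metrics", {
  m <- metrics(list(tp = 223, fp = 89, fn = 103, tn = 235))
  expect_equal(round(m$sensitivity, 4), 0.6840)
  expect_equal(round(m$specificity, 4), 0.7253)
  expect_equal(round(m$pos_pred_value, 4), 0.7147)
  expect_equal(round(m$neg_pred_value, 4), 0.6953)
  expect_equal(round(m$precision, 4), 0.7147)
  expect_equal(round(m$recall, 4), 0.6840)
  expect_equal(round(m$f1, 4), 0.6991)
  expect_equal(round(m$prevalence, 4), 0.5015)
  expect_equal(round(m$detection_rate, 4), 0.3431)
  expect_equal(round(m$detection_prevalence, 4), 0.4800)
  expect_equal(round(m$balanced_accuracy, 4), 0.7047)
  expect_equal(m$n, 650)
})

test_that("metric identities hold on random confusion matrices", {
  set.seed(71)
  for (rep in 1:50) {
    cm <- list(tp = sample(1:200, 1), fp = sample(1:200, 1),
               fn = sample(1:200, 1), tn = sample(1:200, 1))
    m <- metrics(cm)
    n <- with(cm, tp + fp + fn + tn)
    expect_equal(m$precision, m$pos_pred_value, tolerance = 1e-12)
    expect_equal(m$recall, m$sensitivity, tolerance = 1e-12)
    expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall),
                 tolerance = 1e-12)
    expect_equal(m$balanced_accuracy, (m$sensitivity + m$specificity) / 2,
                 tolerance = 1e-12)
    expect_equal(m$detection_rate, cm$tp / n, tolerance = 1e-12)
    expect_equal(m$detection_prevalence, (cm$tp + cm$fp) / n, tolerance = 1e-12)
    expect_equal(m$prevalence, (cm$tp + cm$fn) / n, tolerance = 1e-12)
  }
})

test_that("metrics agree with caret's confusionMatrix on a sampled case", {
  skip_if_not_installed("caret")
  set.seed(72)
  truth <- sample(c("with_sb", "without_sb"), 300, TRUE)
  pred <- ifelse(stats::runif(300) < 0.7, truth,
                 sample(c("with_sb", "without_sb"), 300, TRUE))
  m <- metrics(confusion_matrix(truth, pred))
  cc <- caret::confusionMatrix(
    factor(pred, levels = c("with_sb", "without_sb")),
    factor(truth, levels = c("with_sb", "without_sb")),
    positive = "with_sb"
  )
  expect_equal(m$sensitivity, unname(cc$byClass["Sensitivity"]), tolerance = 1e-12)
  expect_equal(m$specificity, unname(cc$byClass["Specificity"]), tolerance = 1e-12)
  expect_equal(m$f1, unname(cc$byClass["F1"]), tolerance = 1e-12)
  expect_equal(m$balanced_accuracy, unname(cc$byClass["Balanced Accuracy"]),
               tolerance = 1e-12)
  expect_equal(m$detection_rate, unname(cc$byClass["Detection Rate"]),
               tolerance = 1e-12)
})

test_that("degenerate confusion matrices warn rather than silently zero", {
  m <- suppressWarnings(metrics(list(tp = 0, fp = 0, fn = 5, tn = 5)))
  expect_true(is.nan(m$pos_pred_value))
  w <- capture_warnings(metrics(list(tp = 0, fp = 0, fn = 5, tn = 5)))
  expect_true(any(grepl("pos_pred_value", w)))
  expect_true(any(grepl("f1", w)))
  expect_error(metrics(list(tp = 0, fp = 0, fn = 0, tn = 0)),
               class = "pvq_metric_error")
  perfect <- metrics(list(tp = 30, fp = 0, fn = 0, tn = 70))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$prevalence, 0.3)
  expect_equal(perfect$detection_rate, 0.3)
})

test_that("LOOCV is deterministic and hygienic on a small cohort", {
  sch <- pvq_schema("table3")
  co <- generate_cohort(generator_config(n = 36), seed = 73)
  cfg <- pipeline_config(nodes = c("oq_level", "rfl_level", "oq8"),
                         schema = sch, max_iter = 30)
  cv1 <- suppressWarnings(loocv(co$records, cfg))
  cv2 <- suppressWarnings(loocv(co$records, cfg))
  expect_identical(cv1$predictions, cv2$predictions)
  expect_equal(nrow(cv1$predictions), 36L)
  with(cv1$confusion, expect_equal(tp + fp + fn + tn, 36))
  expect_error(loocv(co$records[1:5, ], cfg), class = "pvq_cv_error")
})

test_that("repeated k-fold is seed-reproducible and pools accuracy per repeat", {
  co <- generate_cohort(generator_config(n = 60), seed = 74)
  cfg <- pipeline_config(nodes = c("oq_level", "rfl_level"),
                         schema = pvq_schema("table3"), max_iter = 20)
  r1 <- suppressWarnings(repeated_kfold(co$records, k = 5, repeats = 3,
                                        seed = 99, config = cfg))
  r2 <- suppressWarnings(repeated_kfold(co$records, k = 5, repeats = 3,
                                        seed = 99, config = cfg))
  expect_equal(r1$per_repeat, r2$per_repeat)
  expect_equal(nrow(r1$per_repeat), 3L)
  expect_true(all(r1$per_repeat$accuracy >= 0 & r1$per_repeat$accuracy <= 1))
  expect_error(repeated_kfold(co$records, k = 100, config = cfg),
               class = "pvq_cv_error")
})

test_that("algorithm selection ranks by error and reports unsupported names", {
  co <- generate_cohort(generator_config(n = 50), seed = 75)
  cfg <- pipeline_config(nodes = c("oq_level", "rfl_level"),
                         schema = pvq_schema("table3"), max_iter = 20)
  res <- suppressWarnings(
    select_algorithm(co$records, c("tabu", "grow_shrink"), config = cfg,
                     k = 5, repeats = 2, seed = 4)
  )
  expect_equal(nrow(res), 2L)
  expect_true(res$supported[res$algorithm == "tabu"])
  expect_false(res$supported[res$algorithm == "grow_shrink"])
  expect_equal(res$rank[res$algorithm == "tabu"], 1L)
  expect_true(is.na(res$rank[res$algorithm == "grow_shrink"]))
  expect_error(
    select_algorithm(co$records, c("grow_shrink", "mmpc"), config = cfg),
    class = "pvq_unsupported_algorithm"
  )
})

test_that("tidy/glance accessors expose predictions and the metric row", {
  co <- generate_cohort(generator_config(n = 30), seed = 76)
  cfg <- pipeline_config(nodes = c("oq_level",  "oq8"),
                         schema = pvq_schema("table3"), max_iter = 20)
  cv <- suppressWarnings(loocv(co$records, cfg))
  expect_identical(tidy(cv), cv$predictions)
  expect_identical(glance(cv), cv$metrics)
  expect_true(all(c("patient_id", "truth", "probability", "predicted") %in%
                    names(tidy(cv))))
})
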