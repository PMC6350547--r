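test_that("the confusion matrix uses columns for the actual class", {
  pred <- c("graves", "normal", "normal")
  act <- c("graves", "graves", "normal")
  cm <- confusion_matrix(pred, act)
  # hand tally: actual graves column holds 1 graves + 1 normal prediction
  expect_equal(cm["graves", "graves"], 1L)
  expect_equal(cm["normal", "graves"], 1L)
  expect_equal(cm["normal", "normal"], 1L)
  expect_equal(sum(cm), 3L)
  # column sums are the per-class actual counts
  expect_equal(unname(colSums(cm)), c(2L, 0L, 0L, 1L))

  expect_equal(sum(diag(confusion_matrix(act, act))), 3L)
  expect_equal(sum(confusion_matrix(character(0), character(0))), 0L)
  expect_error(confusion_matrix(pred, act[1:2]), "equal length")
  expect_error(confusion_matrix(c("cyst"), c("graves")), "unknown")
})

test_that("class_report reproduces the one-vs-rest formulas", {
  # perfect one-vs-rest
  cm <- diag(c(50L, 50L, 50L, 50L))
  dimnames(cm) <- list(predicted = spect_classes(),
                       actual = spect_classes())
  r <- class_report(cm, "graves")
  expect_equal(c(r$recall, r$precision, r$accuracy, r$specificity, r$f1),
               rep(1, 5))

  # frozen hand computation: TP=95, FN=5, FP=2, TN=98
  cm <- matrix(0L, 4, 4, dimnames = list(predicted = spect_classes(),
                                         actual = spect_classes()))
  cm["graves", "graves"] <- 95L
  cm["normal", "graves"] <- 5L
  cm["graves", "normal"] <- 2L
  cm["normal", "normal"] <- 98L
  r <- class_report(cm, "graves")
  expect_equal(r$TP, 95L); expect_equal(r$FN, 5L)
  expect_equal(r$FP, 2L); expect_equal(r$TN, 98L)
  expect_equal(r$recall, 0.95)
  expect_equal(r$precision, 95 / 97)
  expect_equal(r$accuracy, 0.965)
  expect_equal(r$specificity, 0.98)
  expect_equal(r$f1, 190 / 197)

  # zero denominator: undefined, not zero
  r <- class_report(cm, "hashimoto")
  expect_equal(r$TP, 0L)
  expect_true(is.na(r$precision))
  expect_true(is.na(r$recall))
  expect_false(is.na(r$specificity))
})

test_that("macro precision averages defined classes only", {
  cm <- diag(c(10L, 10L, 10L, 10L))
  dimnames(cm) <- list(predicted = spect_classes(), actual = spect_classes())
  expect_equal(macro_precision(cm)$value, 1)

  # nothing ever predicted as subacute: excluded from the mean
  cm2 <- cm
  cm2["subacute", "subacute"] <- 0L
  cm2["normal", "subacute"] <- 10L
  mp <- macro_precision(cm2)
  expect_equal(mp$n_undefined, 1L)
  expect_equal(mp$value, mean(c(1, 1, 10 / 20)))
})

test_that("random predictions on a balanced set give chance-level precision", {
  set.seed(111)
  act <- rep(spect_classes(), each = 600)
  pred <- sample(spect_classes(), 2400, replace = TRUE)
  mp <- macro_precision(confusion_matrix(pred, act))$value
  expect_gt(mp, 0.22)
  expect_lt(mp, 0.28)
})

test_that("metric identities hold on random confusion matrices", {
  set.seed(112)
  for (rep in 1:100) {
    n <- sample(20:200, 1)
    pred <- sample(spect_classes(), n, replace = TRUE)
    act <- sample(spect_classes(), n, replace = TRUE)
    cm <- confusion_matrix(pred, act)
    expect_equal(sum(cm), n)
    micro_acc <- sum(diag(cm)) / n
    expect_equal(micro_acc, mean(pred == act), tolerance = 1e-12)
    for (cl in spect_classes()) {
      r <- class_report(cm, cl)
      i <- match(cl, spect_classes())
      expect_equal(r$TP + r$FN, sum(cm[, i]))
      expect_equal(r$TP + r$FP, sum(cm[i, ]))
      expect_equal(r$TP + r$TN + r$FP + r$FN, n)
      if (!is.na(r$precision) && !is.na(r$recall) &&
          (r$precision + r$recall) > 0) {
        expect_equal(r$f1,
                     2 * r$precision * r$recall / (r$precision + r$recall),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("metrics agree with an independent reference implementation", {
  skip_if_not_installed("caret")
  set.seed(113)
  for (rep in 1:20) {
    n <- 150
    pred <- sample(spect_classes(), n, replace = TRUE)
    act <- sample(spect_classes(), n, replace = TRUE)
    cm <- confusion_matrix(pred, act)
    ref <- caret::confusionMatrix(factor(pred, levels = spect_classes()),
                                  factor(act, levels = spect_classes()))
    for (cl in spect_classes()) {
      r <- class_report(cm, cl)
      row <- paste("Class:", cl)
      expect_equal(r$recall, unname(ref$byClass[row, "Sensitivity"]),
                   tolerance = 1e-12)
      expect_equal(r$specificity, unname(ref$byClass[row, "Specificity"]),
                   tolerance = 1e-12)
      if (!is.na(r$precision)) {
        expect_equal(r$precision, unname(ref$byClass[row, "Precision"]),
                     tolerance = 1e-12)
      }
      if (!is.na(r$f1) && !is.na(ref$byClass[row, "F1"])) {
        expect_equal(r$f1, unname(ref$byClass[row, "F1"]),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("evaluate_model + write_report produce a consistent artifact", {
  m <- build_network(tiny_net_config(), seed = 114)
  set.seed(115)
  samples <- unlist(lapply(spect_classes(), function(cl) {
    lapply(1:6, function(i) {
      lv <- numeric(4); lv[match(cl, spect_classes())] <- 1
      list(pixels = matrix(runif(16 * 16), 16, 16), label_vec = lv,
           class_group = cl, origin = "real",
           id = paste0(cl, i))
    })
  }), recursive = FALSE)
  ev <- evaluate_model(m, samples)
  expect_equal(sum(ev$cm), 24)
  expect_equal(unname(colSums(ev$cm)), rep(6L, 4))
  expect_length(ev$reports, 4)

  dir <- withr::local_tempdir()
  write_report(ev, dir)
  expect_true(file.exists(file.path(dir, "report.json")))
  tab <- utils::read.csv(file.path(dir, "metrics.csv"), check.names = FALSE)
  expect_equal(tab$Metric,
               c("Recall", "Precision", "Accuracy", "Specificity",
                 "F1 score"))
  expect_equal(colnames(tab), c("Metric", spect_classes()))
  # determinism: same evaluation, byte-identical report
  dir2 <- withr::local_tempdir()
  write_report(evaluate_model(m, samples), dir2)
  expect_identical(readLines(file.path(dir, "report.json")),
                   readLines(file.path(dir2, "report.json")))

  expect_error(evaluate_model(m, list()), "empty")
})

test_that("a perfect classifier reports 100.00 in every table cell", {
  # identity "model": fabricate evaluation output via an exact cm
  pred <- rep(spect_classes(), each = 5)
  cm <- confusion_matrix(pred, pred)
  for (cl in spect_classes()) {
    r <- class_report(cm, cl)
    for (mtr in c("recall", "precision", "accuracy", "specificity", "f1")) {
      expect_identical(pollentrain:::fmt_pc(r[[mtr]]), "100.00")
    }
  }
})
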