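# Binary metrics, ROC/AUC, PR/AP, confusion matrices.

test_that("binary_metrics evaluates the four formulas exactly", {
  m <- binary_metrics(tp = 5, fp = 0, tn = 5, fn = 0)
  expect_equal(unlist(m), c(accuracy = 1, precision = 1, recall = 1, f1 = 1))

  m2 <- binary_metrics(tp = 3, fp = 1, tn = 5, fn = 1)
  expect_equal(m2$accuracy, 0.8)
  expect_equal(m2$precision, 0.75)
  expect_equal(m2$recall, 0.75)
  expect_equal(m2$f1, 0.75)

  # precision/recall swap under fp <-> fn
  a <- suppressWarnings(binary_metrics(tp = 4, fp = 2, tn = 3, fn = 1))
  b <- suppressWarnings(binary_metrics(tp = 4, fp = 1, tn = 3, fn = 2))
  expect_equal(a$precision, b$recall)
  expect_equal(a$recall, b$precision)

  # metrics from counts equal metrics from the generating labels
  withr::with_seed(1, {
    truth <- runif(200) < 0.4
    pred <- xor(truth, runif(200) < 0.2)
  })
  cc <- confusion_counts(truth, pred)
  expect_equal(binary_metrics(cc)$accuracy, mean(truth == pred))

  # undefined metrics are NaN with a warning, never zero
  expect_warning(m3 <- binary_metrics(tp = 0, fp = 0, tn = 5, fn = 2),
                 "precision")
  expect_true(is.nan(m3$precision))
  w <- capture_warnings(m4 <- binary_metrics(0, 0, 0, 0))
  expect_true(all(is.nan(unlist(m4))))
})

test_that("roc_curve separates, nulls, and matches Mann-Whitney", {
  # perfect separation
  r <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 1)

  # labels independent of scores -> AUC near 1/2
  withr::with_seed(0, {
    s <- runif(1e4)
    l <- runif(1e4) < 0.5
  })
  expect_gte(roc_curve(s, l)$auc, 0.48)
  expect_lte(roc_curve(s, l)$auc, 0.52)

  # closed-form equivalence on random instances, with and without ties
  withr::with_seed(5, {
    for (i in 1:50) {
      n <- sample(10:60, 1)
      sc <- if (i %% 2) runif(n) else sample(seq(0, 1, 0.1), n, replace = TRUE)
      lb <- runif(n) < 0.5
      if (!any(lb) || all(lb)) next
      expect_equal(roc_curve(sc, lb)$auc, auc_mann_whitney(sc, lb),
                   tolerance = 1e-12)
    }
  })

  # invariant under strictly monotone score transforms
  withr::with_seed(8, {
    sc <- rnorm(100)
    lb <- runif(100) < 0.4
  })
  expect_equal(roc_curve(sc, lb)$auc, roc_curve(exp(sc), lb)$auc)

  expect_error(roc_curve(1:5, rep(TRUE, 5)), "both classes")
})

test_that("roc and pr agree with pROC on a shared instance", {
  withr::with_seed(21, {
    sc <- runif(300)
    lb <- runif(300) < plogis(4 * (sc - 0.5))
  })
  ours <- roc_curve(sc, lb)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("pr_curve handles perfect, degenerate, and random cases", {
  p <- pr_curve(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(p$ap, 1)

  # single shared score: AP equals prevalence
  p2 <- pr_curve(rep(0.7, 10), c(rep(TRUE, 3), rep(FALSE, 7)))
  expect_equal(p2$ap, 0.3)

  withr::with_seed(9, {
    for (i in 1:50) {
      n <- sample(10:50, 1)
      sc <- if (i %% 2) runif(n) else sample(seq(0, 1, 0.2), n, replace = TRUE)
      lb <- runif(n) < 0.4
      if (!any(lb) || all(lb)) next
      expect_equal(pr_curve(sc, lb)$ap, ap_brute(sc, lb), tolerance = 1e-12)
    }
  })
})

test_that("confusion_matrix counts conserve and accuracy is exact-match", {
  truth <- c("0", "1+", "2+", "3+", "0", "1+", "2+", "3+")
  pred <- c("0", "1+", "2+", "3+", "0", "2+", "2+", "2+")
  cm <- confusion_matrix(truth, pred, classes = c("0", "1+", "2+", "3+"))
  expect_equal(cm$accuracy, 0.75)
  expect_equal(unname(rowSums(cm$table)), unname(table(factor(truth, cm$classes)))[1:4],
               ignore_attr = TRUE)
  expect_equal(cm$accuracy, mean(truth == pred))

  perfect <- confusion_matrix(truth, truth)
  expect_equal(perfect$accuracy, 1)
  expect_true(all(perfect$table[upper.tri(perfect$table)] == 0))

  expect_error(confusion_matrix(c("a"), c("b"), classes = "a"), "unknown class")

  td <- tidy(cm)
  expect_equal(sum(td$n), 8)
  expect_equal(glance(cm)$accuracy, 0.75)
})

test_that("curves and matrices serialize to CSV/JSON", {
  dir <- withr::local_tempdir()
  r <- roc_curve(c(0.9, 0.4, 0.2), c(TRUE, FALSE, TRUE))
  write_curve_csv(r, file.path(dir, "roc.csv"))
  back <- utils::read.csv(file.path(dir, "roc.csv"))
  expect_equal(back$tpr, r$points$tpr)
  cm <- confusion_matrix(c("0", "1+"), c("0", "0"), c("0", "1+"))
  write_confusion_csv(cm, file.path(dir, "cm.csv"))
  expect_true(file.exists(file.path(dir, "cm.csv")))
  write_metrics_json(binary_metrics(tp = 1, fp = 0, tn = 1, fn = 0),
                     file.path(dir, "m.json"))
  expect_equal(jsonlite::read_json(file.path(dir, "m.json"))$accuracy, 1)
})
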