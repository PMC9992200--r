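test_that("confusion counts match definitions and a loop oracle", {
  cm <- confusion(c(1, 0, 1), c(1, 0, 1))
  expect_equal(unlist(cm[c("tp", "fp", "fn", "tn")]),
               c(tp = 2L, fp = 0L, fn = 0L, tn = 1L))
  cm <- confusion(c(1, 0), c(0, 1))
  expect_equal(cm$tp + cm$tn, 0L)
  expect_error(confusion(c(1, 0), c(1)), "length")
  # loop oracle on random pairs
  cxrnlp:::with_seed(31, {
    for (i in 1:50) {
      pred <- sample(0:1, 50, TRUE)
      truth <- sample(0:1, 50, TRUE)
      cm <- confusion(pred, truth)
      tp <- fp <- fn <- tn <- 0L
      for (j in 1:50) {
        if (pred[j] == 1 && truth[j] == 1) tp <- tp + 1L
        else if (pred[j] == 1 && truth[j] == 0) fp <- fp + 1L
        else if (pred[j] == 0 && truth[j] == 1) fn <- fn + 1L
        else tn <- tn + 1L
      }
      expect_equal(unlist(cm[c("tp", "fp", "fn", "tn")]),
                   c(tp = tp, fp = fp, fn = fn, tn = tn))
    }
  })
})

test_that("metrics reproduce published-style rows and flag undefined cells", {
  ms <- metrics(confusion_matrix(113, 14, 72, 1151))
  expect_equal(cxrnlp:::round_half_up(100 * ms$accuracy, 1), 93.6)
  expect_equal(cxrnlp:::round_half_up(100 * ms$f1, 1), 72.4)
  ms <- metrics(confusion_matrix(173, 300, 12, 865))
  expect_equal(cxrnlp:::round_half_up(100 * ms$sensitivity, 1), 93.5)
  expect_equal(cxrnlp:::round_half_up(100 * ms$f1, 1), 52.6)
  # zero-denominator policy: NA, not 0
  ms <- metrics(confusion_matrix(0, 0, 5, 5))
  expect_true(is.na(ms$ppv))
  expect_equal(ms$sensitivity, 0)
  expect_error(metrics(confusion_matrix(0, 0, 0, 0)), "all zero")
})

test_that("Clopper-Pearson intervals hit their boundary and oracle values", {
  expect_equal(unname(proportion_ci(0, 10)["lo"]), 0)
  expect_equal(unname(proportion_ci(10, 10)["hi"]), 1)
  ci <- proportion_ci(113, 185)
  expect_equal(round(ci, 3), c(lo = 0.537, hi = 0.681), tolerance = 1e-3)
  # independent oracle: stats::binom.test implements the exact interval
  cxrnlp:::with_seed(7, {
    for (i in 1:200) {
      n <- sample(1:400, 1)
      k <- sample(0:n, 1)
      got <- proportion_ci(k, n)
      want <- stats::binom.test(k, n)$conf.int
      expect_equal(unname(got), as.numeric(want), tolerance = 1e-9)
    }
  })
  expect_error(proportion_ci(11, 10), "k must lie")
})

test_that("interval width shrinks as n grows at fixed k/n", {
  widths <- vapply(c(20, 80, 320, 1280), function(n) {
    ci <- proportion_ci(round(0.3 * n), n)
    unname(ci["hi"] - ci["lo"])
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("likelihood ratios and their log-method intervals are coherent", {
  cm <- confusion_matrix(113, 14, 72, 1151)
  lr <- likelihood_ratio_ci(cm)
  expect_equal(round(unname(lr$lr_pos["est"]), 1), 50.8)
  expect_false(any(lr$corrected))
  expect_lt(lr$lr_pos["lo"], lr$lr_pos["est"])
  expect_gt(lr$lr_pos["hi"], lr$lr_pos["est"])
  # uninformative test: sens = spec = 0.5 gives LR+ = LR- = 1
  cm5 <- confusion_matrix(50, 50, 50, 50)
  lr5 <- likelihood_ratio_ci(cm5)
  expect_equal(unname(lr5$lr_pos["est"]), 1)
  expect_equal(unname(lr5$lr_neg["est"]), 1)
  # zero cell triggers the documented continuity correction
  lr0 <- likelihood_ratio_ci(confusion_matrix(10, 0, 5, 100))
  expect_true(lr0$corrected["lr_pos"])
  expect_true(is.finite(lr0$lr_pos["hi"]))
})

test_that("cohens_kappa matches hand arithmetic and is symmetric", {
  r <- c(rep(1, 5), rep(0, 5))
  expect_equal(cohens_kappa(r, r)$kappa, 1)
  # table a=40 b=10 c=10 d=40: po=0.8, pe=0.5, kappa=0.6
  r1 <- rep(c(1, 1, 0, 0), c(40, 10, 10, 40))
  r2 <- rep(c(1, 0, 1, 0), c(40, 10, 10, 40))
  k <- cohens_kappa(r1, r2)
  expect_equal(k$observed_agreement, 0.8)
  expect_equal(k$expected_agreement, 0.5)
  expect_equal(k$kappa, 0.6)
  expect_equal(cohens_kappa(r2, r1)$kappa, k$kappa)
  # both raters constant and identical: undefined, flagged
  und <- cohens_kappa(rep(1, 4), rep(1, 4))
  expect_false(und$defined)
  expect_true(is.na(und$kappa))
})

test_that("F1 identity and accuracy bounds hold on random matrices", {
  cxrnlp:::with_seed(17, {
    for (i in 1:300) {
      cells <- as.integer(sample(0:40, 4, replace = TRUE))
      if (sum(cells) == 0L || cells[1] == 0L) next
      cm <- confusion_matrix(cells[1], cells[2], cells[3], cells[4])
      ms <- metrics(cm)
      expect_equal(ms$f1, 2 * cm$tp / (2 * cm$tp + cm$fp + cm$fn),
                   tolerance = 1e-12)
      if ((cm$tp + cm$fn) > 0 && (cm$fp + cm$tn) > 0) {
        expect_gte(ms$accuracy, min(ms$sensitivity, ms$specificity) - 1e-12)
        expect_lte(ms$accuracy, max(ms$sensitivity, ms$specificity) + 1e-12)
      }
    }
  })
})

test_that("reconstruct_confusion recovers consistent integer matrices", {
  # validation size 1350 with 185 reference positives; printed
  # sens/spec/PPV rows from the published table
  rows <- list(
    word_embedding = list(in_ = c(19.5, 95.1, 38.7),
                          out = c(36, 57, 149, 1108)),
    xgboost = list(in_ = c(61.1, 98.8, 89.0), out = c(113, 14, 72, 1151)),
    svm = list(in_ = c(56.2, 98.1, 82.5), out = c(104, 22, 81, 1143)),
    naive_bayes = list(in_ = c(93.5, 74.2, 36.6), out = c(173, 300, 12, 865)),
    logistic = list(in_ = c(5.4, 95.5, 16.1), out = c(10, 52, 175, 1113)),
    lightgbm = list(in_ = c(26.5, 99.8, 96.1), out = c(49, 2, 136, 1163)))
  for (nm in names(rows)) {
    r <- rows[[nm]]
    cm <- reconstruct_confusion(1350, 185, r$in_[1], r$in_[2], r$in_[3])
    expect_equal(unlist(cm[c("tp", "fp", "fn", "tn")]),
                 setNames(as.integer(r$out), c("tp", "fp", "fn", "tn")),
                 label = nm)
  }
  expect_error(reconstruct_confusion(100, 10, 99.9, 50, 50),
               "no integer confusion matrix")
})
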