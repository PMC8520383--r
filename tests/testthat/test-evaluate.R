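test_that("confusion counts follow the hand-placed 4x4 fixture", {
  truth <- matrix(FALSE, 4, 4); truth[1, 1:4] <- TRUE          # 4 vessel px
  pred <- matrix(FALSE, 4, 4); pred[1, 1:3] <- TRUE            # 3 of them
  pred[2, 1:2] <- TRUE                                         # 2 spurious
  cc <- confusion_counts(pred, truth)
  expect_equal(unclass(cc), list(tp = 3L, fp = 2L, tn = 10L, fn = 1L))
})

test_that("perfect agreement and perfect disagreement are degenerate", {
  set.seed(17)
  truth <- matrix(runif(100) > 0.5, 10, 10)
  agree <- confusion_counts(truth, truth)
  expect_equal(agree$fp + agree$fn, 0L)
  flip <- confusion_counts(!truth, truth)
  expect_equal(flip$tp + flip$tn, 0L)
})

test_that("counts restricted to the FOV equal the per-pixel loop", {
  set.seed(23)
  for (i in 1:5) {
    pred <- matrix(runif(400) > 0.6, 20, 20)
    truth <- matrix(runif(400) > 0.7, 20, 20)
    fov <- matrix(runif(400) > 0.2, 20, 20)
    expect_equal(unclass(confusion_counts(pred, truth, fov)),
                 o_confusion(pred, truth, fov))
  }
  expect_error(confusion_counts(matrix(TRUE, 2, 2), matrix(TRUE, 3, 3)),
               "shape")
})

test_that("metrics reproduce the hand-derived ratios", {
  m <- segmentation_metrics(list(tp = 90, fp = 20, tn = 880, fn = 10))
  expect_equal(m$acc, 0.97)
  expect_equal(m$tpr, 0.9)
  expect_equal(m$fpr, 20 / 900)
  expect_equal(m$precision, 90 / 110)
  expect_equal(m$f_measure, 2 * (90 / 110) * 0.9 / (90 / 110 + 0.9))

  perfect <- segmentation_metrics(list(tp = 123, fp = 0, tn = 456, fn = 0))
  expect_equal(c(perfect$acc, perfect$tpr, perfect$fpr), c(1, 1, 0))

  half <- segmentation_metrics(list(tp = 7, fp = 7, tn = 5, fn = 1))
  expect_equal(half$precision, 0.5)
})

test_that("undefined ratios are NA, all-zero counts are an error", {
  m <- segmentation_metrics(list(tp = 0, fp = 0, tn = 50, fn = 0))
  expect_true(is.na(m$tpr))
  expect_equal(m$fpr, 0)
  expect_error(segmentation_metrics(list(tp = 0, fp = 0, tn = 0, fn = 0)),
               "zero")
})

test_that("accuracy is the prevalence-weighted mix of TPR and 1 - FPR", {
  set.seed(31)
  for (i in 1:20) {
    cc <- as.list(rpois(4, 40) + 1)
    names(cc) <- c("tp", "fp", "tn", "fn")
    m <- segmentation_metrics(cc)
    p <- cc$tp + cc$fn; n <- cc$fp + cc$tn
    expect_equal(m$acc, (p * m$tpr + n * (1 - m$fpr)) / (p + n))
  }
})

test_that("tpr_at_fpr matches the requested background operating point", {
  ph <- phantom_suite(12)$thin
  igc <- inverted_green(ph$image)
  fused <- vessel_response(igc, ph$fov, "split")
  t0 <- stats::quantile(fused[ph$fov & !ph$truth], 0.95, names = FALSE)
  manual <- mean(fused[ph$fov & ph$truth] >= t0)
  expect_equal(tpr_at_fpr(fused, ph$truth, ph$fov, 0.05), manual)
  sweep <- threshold_sweep(fused, ph$truth, ph$fov, quantiles = c(0.05, 0.104, 0.2))
  expect_equal(nrow(sweep), 3L)
  expect_false(is.unsorted(sweep$tpr))   # looser thresholds recall more
  expect_false(is.unsorted(sweep$fpr))
})
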