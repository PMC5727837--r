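test_that("ground-truth mask combination is a pixel-wise AND", {
  a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  b <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  expect_identical(combine_gt_masks(a, a), a)
  expect_identical(combine_gt_masks(a, b), a & b)
  disj <- combine_gt_masks(a, !a)
  expect_false(any(disj))
  full <- matrix(TRUE, 2, 2)
  expect_identical(combine_gt_masks(a, full), a)
  expect_error(combine_gt_masks(a, matrix(TRUE, 3, 3)), "shape")
})

test_that("confusion counts match the double-loop oracle", {
  gt <- matrix(FALSE, 10, 10); gt[1:5, 1:6] <- TRUE
  cm <- confusion(gt, gt)
  expect_equal(cm$tp, 30); expect_equal(cm$tn, 70)
  expect_equal(cm$fp, 0); expect_equal(cm$fn, 0)

  cm2 <- confusion(!gt, gt)
  expect_equal(cm2$tp, 0); expect_equal(cm2$tn, 0)

  set.seed(0)
  for (rep in 1:3) {
    pred <- matrix(runif(32 * 32) < 0.4, 32, 32)
    gtr <- matrix(runif(32 * 32) < 0.2, 32, 32)
    expect_identical(unclass(confusion(pred, gtr)),
                     confusion_loop_oracle(pred, gtr))
  }
})

test_that("metrics compute the three ratios with NaN for empty denominators", {
  ev <- metrics(list(tp = 90, fn = 10, tn = 0, fp = 0))
  expect_equal(ev$sensitivity, 0.9)
  expect_true(is.nan(ev$specificity))

  ev2 <- metrics(list(tp = 5, tn = 90, fp = 3, fn = 2))
  expect_equal(ev2$accuracy, 0.95)
  expect_equal(ev2$sensitivity, 5 / 7)
  expect_equal(ev2$specificity, 90 / 93)

  ev3 <- metrics(list(tp = 0, fn = 0, tn = 5, fp = 5))
  expect_true(is.nan(ev3$sensitivity))
  td <- tidy(ev2)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$accuracy, 0.95)
})

test_that("accuracy lies between sensitivity and specificity", {
  set.seed(1)
  for (rep in 1:20) {
    cnt <- list(tp = sample(0:50, 1), fp = sample(0:50, 1),
                tn = sample(1:50, 1), fn = sample(1:50, 1))
    ev <- metrics(cnt)
    if (!is.nan(ev$sensitivity) && !is.nan(ev$specificity)) {
      expect_gte(ev$accuracy, min(ev$sensitivity, ev$specificity) - 1e-12)
      expect_lte(ev$accuracy, max(ev$sensitivity, ev$specificity) + 1e-12)
    }
  }
})

test_that("ROC handles perfect, constant, and random maps", {
  gt <- matrix(FALSE, 16, 16); gt[4:8, 4:8] <- TRUE
  perfect <- ifelse(gt, 1, 0); dim(perfect) <- dim(gt)
  expect_equal(roc_curve(perfect, gt)$auc, 1)

  const <- matrix(0.4, 16, 16)
  expect_equal(roc_curve(const, gt)$auc, 0.5)

  set.seed(0)
  v <- matrix(runif(64 * 64), 64, 64)
  gtr <- matrix(runif(64 * 64) < 0.3, 64, 64)
  rc <- roc_curve(v, gtr, n_thresholds = 201)
  expect_equal(rc$auc, auc_rank_oracle(v, gtr), tolerance = 1 / 201)
  # monotone coordinates as threshold increases
  expect_true(all(diff(rc$points$tpr) <= 1e-12))
  expect_true(all(diff(rc$points$fpr) <= 1e-12))
  # single-class ground truth
  expect_true(is.nan(roc_curve(v, matrix(FALSE, 64, 64))$auc))
})

test_that("ablation table has the seven combinations and is self-consistent", {
  fx <- generate_fixture(fixture_spec(height = 128, width = 128, seed = 0))
  ab <- ablation_table(fx$image, fx$gt_mask)
  expect_equal(ab$combination,
               c("edge", "intensity", "color", "edge+intensity",
                 "edge+color", "intensity+color", "fused"))
  expect_equal(nrow(ab), 7)
  # fused row reproduces the end-to-end pipeline
  loc <- localize_bleeding(fx$image)
  ev <- metrics(confusion(loc$mask, fx$gt_mask))
  frow <- ab[ab$combination == "fused", ]
  expect_equal(frow$accuracy, ev$accuracy)
  expect_equal(frow$threshold, loc$threshold)
})

test_that("noise sweep reports the clean reference and the six settings", {
  fx <- generate_fixture(fixture_spec(height = 96, width = 96, seed = 1))
  ns <- noise_sweep(fx$image, fx$gt_mask, seed = 1)
  expect_equal(nrow(ns), 7)
  expect_equal(ns$kind[1], "none")
  expect_equal(ns$level[ns$kind == "salt_pepper"], c(0.02, 0.04, 0.06))
  expect_equal(ns$level[ns$kind == "gaussian"], c(0.005, 0.01, 0.015))
  loc <- localize_bleeding(fx$image)
  ev <- metrics(confusion(loc$mask, fx$gt_mask))
  expect_equal(ns$accuracy[1], ev$accuracy)
})
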