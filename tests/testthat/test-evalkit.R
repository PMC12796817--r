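test_that("iou_matrix counts pixel overlaps exactly", {
  # renumbered identity: every pair has IoU 1
  gt <- rect_mask(32, 32, list(c(2, 6, 2, 6), c(10, 20, 10, 15)))
  pred <- gt * 10
  tab <- iou_matrix(gt, pred)
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$iou == 1))

  # 10x10 square shifted right by 2: intersection 80, union 120
  gt2 <- rect_mask(30, 30, list(c(1, 10, 1, 10)))
  pr2 <- rect_mask(30, 30, list(c(1, 10, 3, 12)))
  tab2 <- iou_matrix(gt2, pr2)
  expect_equal(tab2$intersection_px, 80)
  expect_equal(tab2$union_px, 120)
  expect_equal(tab2$iou, 80 / 120)

  # disjoint masks: empty table
  pr3 <- rect_mask(30, 30, list(c(20, 25, 20, 25)))
  expect_equal(nrow(iou_matrix(gt2, pr3)), 0)

  expect_error(iou_matrix(gt2, matrix(0, 5, 5)), "shapes differ")
})

test_that("match_instances is one-to-one and counts TP/FP/FN per totals", {
  gt <- rect_mask(30, 30, list(c(1, 10, 1, 10), c(20, 28, 20, 28)))
  pr <- rect_mask(30, 30, list(c(1, 10, 3, 12), c(2, 5, 20, 24), c(15, 18, 2, 6)))
  counts <- match_instances(iou_matrix(gt, pr), n_gt = 2, n_pred = 3)
  expect_equal(counts$tp, 1)
  expect_equal(counts$fp, 2)
  expect_equal(counts$fn, 1)
  expect_equal(nrow(counts$matches), 1)
  expect_true(all(counts$matches$iou >= 0.5))

  empty <- match_instances(iou_matrix(gt, matrix(0, 30, 30)), n_gt = 2, n_pred = 0)
  expect_equal(c(empty$tp, empty$fp, empty$fn), c(0, 0, 2))

  expect_error(match_instances(data.frame(), 1, 1, threshold = 0), "threshold")
})

test_that("compute_metrics reproduces the five formulas and degenerate policies", {
  r <- compute_metrics(list(tp = 1, fp = 2, fn = 1))
  expect_equal(r$precision, 1 / 3)
  expect_equal(r$recall, 1 / 2)
  expect_equal(r$f1, 0.4)
  expect_equal(r$jaccard, 0.25)
  expect_equal(r$dice, 0.4)

  perfect <- compute_metrics(list(tp = 7, fp = 0, fn = 0))
  expect_true(all(unlist(perfect[, c("precision", "recall", "f1", "jaccard", "dice")]) == 1))

  both_empty <- compute_metrics(list(tp = 0, fp = 0, fn = 0))
  expect_true(all(unlist(both_empty[, c("precision", "recall", "f1", "jaccard", "dice")]) == 1))

  no_pred <- compute_metrics(list(tp = 0, fp = 0, fn = 5))
  expect_equal(c(no_pred$precision, no_pred$recall), c(0, 0))
  no_gt <- compute_metrics(list(tp = 0, fp = 5, fn = 0))
  expect_equal(c(no_gt$precision, no_gt$recall), c(0, 0))
})

test_that("F1 equals Dice and Jaccard equals Dice/(2-Dice) on the full count grid", {
  grid <- expand.grid(tp = 0:20, fp = 0:20, fn = 0:20)
  grid <- grid[grid$tp + grid$fp + grid$fn > 0, ]
  err_f1 <- err_jac <- 0
  for (i in seq_len(nrow(grid))) {
    m <- compute_metrics(list(tp = grid$tp[i], fp = grid$fp[i], fn = grid$fn[i]))
    err_f1 <- max(err_f1, abs(m$f1 - m$dice))
    err_jac <- max(err_jac, abs(m$jaccard - m$dice / (2 - m$dice)))
  }
  expect_lt(err_f1, 1e-12)
  expect_lt(err_jac, 1e-12)
})

test_that("unmatched additions never increase precision/recall (monotonicity)", {
  set.seed(5)
  for (i in 1:50) {
    tp <- sample(0:10, 1); fp <- sample(0:10, 1); fn <- sample(0:10, 1)
    if (tp + fp + fn == 0) next
    base <- compute_metrics(list(tp = tp, fp = fp, fn = fn))
    more_fp <- compute_metrics(list(tp = tp, fp = fp + 1, fn = fn))
    more_fn <- compute_metrics(list(tp = tp, fp = fp, fn = fn + 1))
    expect_lte(more_fp$precision, base$precision)
    expect_lte(more_fn$recall, base$recall)
  }
})

test_that("greedy matching equals optimal assignment above IoU 0.5 on random pairs", {
  for (s in 1:200) {
    p <- synth_params(height = 64, width = 64, n_cells = 8,
                      radius_range = c(2, 4), seed = s)
    mask <- generate_tissue(p)$mask
    pert <- perturb_mask(mask, drop_fraction = 0.2, split_fraction = 0.2,
                         shift_px = 2, seed = s + 1000)$mask
    pairs <- iou_matrix(mask, pert)
    n_gt <- length(setdiff(unique(as.vector(mask)), 0))
    n_pred <- length(setdiff(unique(as.vector(pert)), 0))
    thr <- 0.5 + 1e-9
    greedy <- match_instances(pairs, n_gt, n_pred, threshold = thr)
    expect_equal(greedy$tp, optimal_match_tp(pairs, thr))
  }
})

test_that("evaluate_batch aggregates per-image reports and survives bad files", {
  dir <- withr::local_tempdir()
  gt <- rect_mask(30, 30, list(c(1, 10, 1, 10), c(20, 28, 20, 28)))
  pr_half <- rect_mask(30, 30, list(c(1, 10, 3, 12), c(2, 5, 20, 24), c(15, 18, 2, 6)))
  write_mask(gt, file.path(dir, "gt1.tif"))
  write_mask(gt, file.path(dir, "pred1.tif"))    # perfect -> f1 = 1
  write_mask(gt, file.path(dir, "gt2.tif"))
  write_mask(pr_half, file.path(dir, "pred2.tif"))  # f1 = 0.4
  res <- evaluate_batch(file.path(dir, c("gt1.tif", "gt2.tif")),
                        file.path(dir, c("pred1.tif", "pred2.tif")),
                        out_csv = file.path(dir, "metrics.csv"))
  expect_equal(nrow(res$per_image), 2)
  expect_equal(res$summary$f1[res$summary$stat == "mean"], 0.7)
  expect_true(file.exists(file.path(dir, "metrics.csv")))
  expect_true(file.exists(file.path(dir, "metrics_summary.csv")))

  # singleton batch: aggregate equals the single report
  res1 <- evaluate_batch(file.path(dir, "gt2.tif"), file.path(dir, "pred2.tif"))
  expect_equal(res1$summary$f1[res1$summary$stat == "mean"], res1$per_image$f1)

  # corrupt file: batch continues, failure recorded
  writeLines("not a tiff", file.path(dir, "bad.tif"))
  expect_warning(
    res2 <- evaluate_batch(file.path(dir, c("gt1.tif", "bad.tif")),
                           file.path(dir, c("pred1.tif", "pred2.tif"))),
    "failed")
  expect_equal(nrow(res2$per_image), 1)
  expect_equal(res2$failures, "bad.tif")
})
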