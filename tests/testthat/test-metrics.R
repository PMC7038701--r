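# Segmentation metrics: confusion accumulation and the four aggregates.

# direct per-pixel/per-class oracle, no shared code with the implementation
metrics_oracle <- function(pred, gt, n_cl) {
  cm <- matrix(0, n_cl, n_cl)
  for (i in seq_along(gt))
    cm[gt[i] + 1, pred[i] + 1] <- cm[gt[i] + 1, pred[i] + 1] + 1
  ti <- rowSums(cm); nii <- diag(cm); present <- which(ti > 0)
  iou <- sapply(present, function(i) nii[i] / (ti[i] + sum(cm[, i]) - nii[i]))
  list(pa = sum(nii) / sum(ti),
       ma = mean(sapply(present, function(i) nii[i] / ti[i])),
       miou = mean(iou),
       fwiou = sum(ti[present] * iou) / sum(ti))
}

test_that("confusion counts true-class rows against predicted-class columns", {
  gt <- matrix(c(0L, 0L, 1L, 1L), 2)
  pr <- matrix(c(0L, 1L, 1L, 1L), 2)
  cm <- seg_confusion(pr, gt, 2)
  expect_equal(unclass(cm), matrix(c(1L, 0L, 1L, 2L), 2),
               ignore_attr = TRUE)
  # perfect prediction: diagonal with trace = pixel count
  cmp <- seg_confusion(gt, gt, 2)
  expect_equal(sum(diag(cmp)), 4)
  expect_equal(sum(cmp) - sum(diag(cmp)), 0)
  # total confusion
  cmt <- seg_confusion(matrix(1L, 2, 2), matrix(0L, 2, 2), 2)
  expect_equal(cmt[1, 2], 4)
  expect_equal(sum(cmt), 4)
  expect_error(seg_confusion(pr, matrix(0L, 3, 3), 2), "dimensions")
  expect_error(seg_confusion(pr, gt, 1), ">= 2")
  expect_error(seg_confusion(matrix(5L, 2, 2), gt, 2), "out of range")
})

test_that("the four metrics reproduce the hand-worked 2x2 table", {
  m <- seg_evaluate(matrix(c(3, 2, 1, 4), 2))
  expect_equal(m$pa, 0.7)
  expect_equal(m$ma, 17 / 24, tolerance = 1e-12)       # (3/4 + 4/6) / 2
  expect_equal(m$miou, 0.5357143, tolerance = 1e-6)    # (1/2 + 4/7) / 2
  expect_equal(m$fwiou, 0.5428571, tolerance = 1e-6)   # (4*.5 + 6*4/7) / 10
  expect_equal(m$per_class_iou, c(0.5, 4 / 7), ignore_attr = TRUE)
})

test_that("perfect segmentation scores 1 on every metric", {
  set.seed(71)
  gt <- matrix(sample(0:3, 64, replace = TRUE), 8, 8)
  m <- seg_metrics(gt, gt, 4)
  expect_equal(c(m$pa, m$ma, m$miou, m$fwiou), rep(1, 4))
})

test_that("metrics are scale-free and permutation-equivariant", {
  cm <- matrix(c(5, 2, 0, 1, 7, 3, 2, 2, 9), 3)
  a <- seg_evaluate(cm)
  b <- seg_evaluate(7 * cm)
  expect_equal(a[c("pa", "ma", "miou", "fwiou")],
               b[c("pa", "ma", "miou", "fwiou")])
  # consistent relabelling permutes per-class IoU, fixes the aggregates
  p <- c(3, 1, 2)
  cp <- cm[p, p]
  ap <- seg_evaluate(cp)
  expect_equal(ap$per_class_iou, a$per_class_iou[p], ignore_attr = TRUE)
  expect_equal(ap$miou, a$miou)
  expect_equal(ap$fwiou, a$fwiou)
})

test_that("metrics agree with a direct per-pixel oracle on random masks", {
  set.seed(81)
  for (rep in 1:5) {
    n_cl <- sample(2:4, 1)
    gt <- matrix(sample(0:(n_cl - 1), 64, replace = TRUE), 8, 8)
    pr <- matrix(sample(0:(n_cl - 1), 64, replace = TRUE), 8, 8)
    m <- seg_metrics(pr, gt, n_cl)
    o <- metrics_oracle(pr, gt, n_cl)
    expect_equal(m$pa, o$pa)
    expect_equal(m$ma, o$ma)
    expect_equal(m$miou, o$miou)
    expect_equal(m$fwiou, o$fwiou)
    # structure: all in [0,1], fwiou a convex combination of per-class IoU
    vals <- c(m$pa, m$ma, m$miou, m$fwiou)
    expect_true(all(vals >= 0 & vals <= 1))
    expect_lte(m$miou, max(m$per_class_iou, na.rm = TRUE))
  }
})

test_that("classes absent from the ground truth are excluded from averages", {
  # class 2 never occurs in gt: row of zeros
  cm <- matrix(0, 3, 3)
  cm[1, 1] <- 8; cm[2, 2] <- 6; cm[2, 3] <- 2
  m <- seg_evaluate(cm)
  expect_true(is.na(m$per_class_iou[3]))
  expect_equal(m$ma, mean(c(1, 6 / 8)))
  expect_equal(m$miou, mean(c(1, 6 / 8)))  # both IoUs: 8/8 and 6/8
  expect_error(seg_evaluate(matrix(0, 2, 2)), "no counts")
})

test_that("pooled confusion over a set equals the confusion of the union", {
  set.seed(91)
  gts <- replicate(3, matrix(sample(0:1, 36, TRUE), 6, 6), simplify = FALSE)
  prs <- replicate(3, matrix(sample(0:1, 36, TRUE), 6, 6), simplify = FALSE)
  pooled <- seg_metrics(prs, gts, 2)
  big <- seg_metrics(do.call(rbind, prs), do.call(rbind, gts), 2)
  expect_equal(pooled$pa, big$pa)
  expect_equal(pooled$fwiou, big$fwiou)
})
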