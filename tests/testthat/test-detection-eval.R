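# detection metrics: IoU, matching, confusion-derived metrics, AP, YOLO I/O

box <- function(class_id, cx, cy, w, h, conf = NULL) {
  yolo_boxes(class_id, cx, cy, w, h, conf)
}

test_that("iou covers identity, disjoint and the half-offset case", {
  a <- c(0.5, 0.5, 0.2, 0.2)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, c(0.9, 0.9, 0.1, 0.1)), 0)
  # two equal squares offset by half a side: inter 1/2, union 3/2
  expect_equal(iou(c(0.4, 0.5, 0.2, 0.2), c(0.5, 0.5, 0.2, 0.2)), 1 / 3)
  expect_equal(iou(a, c(0.45, 0.5, 0.2, 0.2)),
               iou(c(0.45, 0.5, 0.2, 0.2), a))
  expect_error(iou(a, c(0.5, 0.5, 0, 0.2)), "degenerate")
})

test_that("match_detections implements the background bookkeeping", {
  truths <- box(c(0, 1), c(0.3, 0.7), c(0.3, 0.7), c(0.2, 0.2), c(0.2, 0.2))
  # perfect predictions -> purely diagonal
  cm <- match_detections(box(c(0, 1), c(0.3, 0.7), c(0.3, 0.7),
                             c(0.2, 0.2), c(0.2, 0.2), conf = c(0.9, 0.8)),
                         truths)
  expect_equal(unname(diag(cm)[1:2]), c(1L, 1L))
  expect_equal(sum(cm), 2)
  # no predictions -> all truths in the background row
  cm0 <- match_detections(empty_boxes(), truths)
  expect_equal(unname(cm0[4, 1:2]), c(1L, 1L))
  expect_equal(sum(cm0), 2)
  # IoU 0.4 < 0.5 threshold -> one background-column FP + one background-row FN
  p <- box(0, 0.3, 0.3, 0.2, 0.2, conf = 0.9)
  t1 <- box(0, 0.3, 0.3 + 0.2 * 3 / 7, 0.2, 0.2)  # IoU = (4/7)/(10/7) = 0.4
  expect_equal(iou(p, t1), 0.4, tolerance = 1e-12)
  cm2 <- match_detections(p, t1)
  expect_equal(unname(cm2[1, 4]), 1L)
  expect_equal(unname(cm2[4, 1]), 1L)
  expect_equal(sum(cm2), 2)
  # cross-class match lands off-diagonal
  cm3 <- match_detections(box(1, 0.3, 0.3, 0.2, 0.2, conf = 0.9),
                          box(0, 0.3, 0.3, 0.2, 0.2))
  expect_equal(unname(cm3[2, 1]), 1L)
})

test_that("greedy matching prefers higher confidence and higher IoU", {
  t1 <- box(0, 0.5, 0.5, 0.2, 0.2)
  # two predictions overlap the same truth: the confident one wins,
  # the other becomes a background FP
  p <- box(c(0, 0), c(0.5, 0.52), c(0.5, 0.5), c(0.2, 0.2), c(0.2, 0.2),
           conf = c(0.6, 0.95))
  cm <- match_detections(p, t1)
  expect_equal(unname(cm[1, 1]), 1L)
  expect_equal(unname(cm[1, 4]), 1L)
  # one prediction, two truths: picks the higher-IoU one
  t2 <- box(c(0, 0), c(0.5, 0.58), c(0.5, 0.5), c(0.2, 0.2), c(0.2, 0.2))
  cm2 <- match_detections(box(0, 0.51, 0.5, 0.2, 0.2, conf = 1), t2)
  expect_equal(unname(cm2[1, 1]), 1L)
  expect_equal(unname(cm2[4, 1]), 1L)
})

test_that("metrics_from_confusion matches a brute-force tally", {
  set.seed(23)
  for (rep in 1:5) {
    cm <- matrix(rpois(16, 40), 4, 4)
    cm[4, 4] <- 0
    met <- metrics_from_confusion(cm, classes = c("a", "b", "c"))
    for (c in 1:3) {
      TP <- cm[c, c]
      FN <- sum(cm[, c]) - TP
      FP <- sum(cm[c, ]) - TP
      expect_equal(met$per_class$sensitivity[c], TP / (TP + FN))
      expect_equal(met$per_class$precision[c], TP / (TP + FP))
    }
    expect_equal(met$accuracy, sum(diag(cm)[1:3]) / sum(cm[, 1:3]))
  }
  # perfect diagonal
  perfect <- diag(c(5, 5, 5, 0))
  mp <- metrics_from_confusion(perfect)
  expect_equal(mp$per_class$sensitivity, rep(1, 3))
  expect_equal(mp$per_class$precision, rep(1, 3))
  expect_equal(mp$per_class$f1, rep(1, 3))
  expect_equal(mp$accuracy, 1)
  expect_equal(mp$kappa, 1)
  # zero denominators are undefined, not 0
  z <- matrix(0L, 4, 4); z[1, 1] <- 3
  mz <- metrics_from_confusion(z)
  expect_true(is.na(mz$per_class$sensitivity[2]))
  expect_true(is.na(mz$per_class$precision[2]))
})

test_that("printed-table fixtures reproduce the published metric table", {
  # worked-example confusion matrices shipped as CSV fixtures
  expected <- list(
    rgb_wli = list(acc = 0.78, sens = c(0.78, 0.75, 0.80),
                   prec = c(0.93, 0.88, 0.89), f1 = c(0.85, 0.81, 0.84)),
    hsi_wli = list(acc = 0.86, sens = c(0.88, 0.86, 0.83),
                   prec = c(0.95, 0.93, 0.92), f1 = c(0.92, 0.89, 0.87)),
    rgb_nbi = list(acc = 0.86, sens = c(0.89, 0.84, 0.86),
                   prec = c(0.93, 0.93, 0.88), f1 = c(0.91, 0.88, 0.87)),
    hsi_nbi = list(acc = 0.90, sens = c(0.92, 0.88, 0.89),
                   prec = c(0.92, 0.92, 0.90), f1 = c(0.92, 0.90, 0.89)))
  for (nm in names(expected)) {
    cm <- read_confusion_csv(table1_csv(nm))
    met <- metrics_from_confusion(cm)
    e <- expected[[nm]]
    expect_equal(round_half_up(met$accuracy), e$acc, info = nm)
    expect_equal(round_half_up(met$per_class$sensitivity), e$sens, info = nm)
    expect_equal(round_half_up(met$per_class$precision), e$prec, info = nm)
    expect_equal(round_half_up(met$per_class$f1), e$f1, info = nm)
  }
})

test_that("average_precision matches the brute-force PR oracle", {
  # 3-detection toy: confidences 0.9 TP, 0.8 FP, 0.7 TP on 2 truths
  truths <- box(c(0, 0), c(0.2, 0.8), c(0.2, 0.8), c(0.2, 0.2), c(0.2, 0.2))
  preds <- box(c(0, 0, 0), c(0.2, 0.5, 0.8), c(0.2, 0.5, 0.8),
               c(0.2, 0.2, 0.2), c(0.2, 0.2, 0.2), conf = c(0.9, 0.8, 0.7))
  res <- average_precision(preds, truths, classes = "SCC")
  oracle <- brute_force_ap(c(0.9, 0.8, 0.7), c(TRUE, FALSE, TRUE), 2)
  expect_equal(unname(res$per_class["SCC"]), oracle)
  expect_equal(res$map, oracle)
  # single perfect confident prediction
  r1 <- average_precision(box(0, 0.2, 0.2, 0.2, 0.2, conf = 0.99),
                          box(0, 0.2, 0.2, 0.2, 0.2), classes = "SCC")
  expect_equal(unname(r1$per_class), 1)
  # all predictions wrong class -> AP 0 for the truth class
  r0 <- suppressWarnings(
    average_precision(box(1, 0.2, 0.2, 0.2, 0.2, conf = 0.9),
                      box(0, 0.2, 0.2, 0.2, 0.2),
                      classes = c("SCC", "dysplasia")))
  expect_equal(unname(r0$per_class["SCC"]), 0)
  expect_true(is.na(r0$per_class["dysplasia"]))
  # invariance to confidence-preserving reordering
  perm <- preds[c(3, 1, 2), ]
  expect_equal(average_precision(perm, truths, classes = "SCC")$map, oracle)
  expect_error(average_precision(box(0, 0.2, 0.2, 0.1, 0.1), truths),
               "confidences")
})

test_that("YOLO files round trip and reject malformed rows", {
  b <- box(c(0, 2), c(0.5, 0.25), c(0.5, 0.75), c(0.2, 0.1), c(0.1, 0.3),
           conf = c(0.93, 0.4))
  f <- tempfile(fileext = ".txt")
  write_yolo_annotations(b, f)
  back <- read_yolo_annotations(f)
  expect_equal(back, b, tolerance = 1e-6)
  expect_equal(back$class_id, c(0L, 2L))
  expect_equal(back$conf[1], 0.93)
  # ground truth without confidence
  g <- box(1, 0.5, 0.5, 0.2, 0.2)
  write_yolo_annotations(g, f)
  expect_null(read_yolo_annotations(f)$conf)
  # malformed rows name the line
  writeLines(c("0 0.5 0.5 0.2 0.1 0.9", "1 0.5 0.5 0.2"), f)
  expect_error(read_yolo_annotations(f), "line 2")
  writeLines("0 0.5 x 0.2 0.1", f)
  expect_error(read_yolo_annotations(f), "non-numeric")
  expect_equal(nrow(read_yolo_annotations(tempfile())), 0)
})

test_that("confusion CSV I/O mirrors the printed layout", {
  cm <- read_confusion_csv(table1_csv("rgb_wli"))
  expect_equal(rownames(cm), c("SCC", "dysplasia", "normal", "background"))
  expect_equal(unname(cm[1, 1]), 521L)
  expect_equal(unname(cm[4, 4]), 0L)
  f <- tempfile(fileext = ".csv")
  write_confusion_csv(cm, f)
  expect_equal(unclass(read_confusion_csv(f)), unclass(cm), ignore_attr = TRUE)
})

test_that("dedup_boxes suppresses same-class duplicates only", {
  b <- box(c(0, 0, 1), c(0.5, 0.51, 0.5), c(0.5, 0.5, 0.5),
           c(0.2, 0.2, 0.2), c(0.2, 0.2, 0.2), conf = c(0.9, 0.8, 0.7))
  kept <- dedup_boxes(b)
  expect_equal(nrow(kept), 2)              # duplicate SCC box dropped
  expect_equal(kept$class_id, c(0L, 1L))   # cross-class overlap survives
})

test_that("multi-image matching aligns by stem names", {
  preds <- list(img1 = box(0, 0.3, 0.3, 0.2, 0.2, conf = 0.9),
                img2 = empty_boxes())
  truths <- list(img2 = box(1, 0.7, 0.7, 0.2, 0.2),
                 img1 = box(0, 0.3, 0.3, 0.2, 0.2))
  cm <- match_detections(preds, truths)
  expect_equal(unname(cm[1, 1]), 1L)   # img1 TP despite list-order mismatch
  expect_equal(unname(cm[4, 2]), 1L)   # img2 missed dysplasia
})
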