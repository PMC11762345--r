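# Detection-output evaluation: IoU matching with a background class,
# confusion matrices in the rows-predicted / columns-true convention, the
# derived metric set, average precision, and YOLO text I/O.

#' Default detection class labels
#'
#' The three tissue classes scored by the evaluation layer, in YOLO id order
#' (0, 1, 2): squamous cell carcinoma, dysplasia, normal mucosa.
#' @return Character vector of length 3.
#' @export
detection_classes <- function() c("SCC", "dysplasia", "normal")

#' Construct a bounding-box table
#'
#' Boxes use normalised YOLO geometry: centre x/y, width and height as
#' fractions of the image.
#'
#' @param class_id Integer class ids (0-based, as in YOLO files).
#' @param cx,cy,w,h Normalised centre and size, in \eqn{[0, 1]}, `w`, `h` > 0.
#' @param conf Optional confidences in \eqn{[0, 1]} (predictions only).
#' @return A data.frame with those columns.
#' @export
yolo_boxes <- function(class_id, cx, cy, w, h, conf = NULL) {
  df <- data.frame(class_id = as.integer(class_id), cx = cx, cy = cy,
                   w = w, h = h)
  if (!is.null(conf)) df$conf <- conf
  validate_boxes(df)
  df
}

validate_boxes <- function(df, what = "boxes") {
  if (nrow(df) == 0L) return(invisible(df))
  need <- c("class_id", "cx", "cy", "w", "h")
  if (!all(need %in% names(df))) {
    stop_input("%s must have columns %s", what, paste(need, collapse = ", "))
  }
  if (any(df$w <= 0 | df$h <= 0)) stop_input("%s: width and height must be positive", what)
  if (any(df$cx < 0 | df$cx > 1 | df$cy < 0 | df$cy > 1)) {
    stop_input("%s: centres must lie in [0, 1]", what)
  }
  if (!is.null(df$conf) && any(df$conf < 0 | df$conf > 1, na.rm = TRUE)) {
    stop_input("%s: confidences must lie in [0, 1]", what)
  }
  invisible(df)
}

empty_boxes <- function() {
  data.frame(class_id = integer(), cx = numeric(), cy = numeric(),
             w = numeric(), h = numeric(), conf = numeric())
}

#' Intersection over union of two boxes
#'
#' @param a,b Boxes as length-4+ numeric vectors `(cx, cy, w, h)` or
#'   single-row data.frames with those columns.
#' @return Scalar IoU in \eqn{[0, 1]}.
#' @export
iou <- function(a, b) {
  geom <- function(x) {
    if (is.data.frame(x)) x <- c(x$cx[1], x$cy[1], x$w[1], x$h[1])
    x <- as.numeric(x)
    if (length(x) < 4L || any(!is.finite(x[1:4]))) stop_input("invalid box")
    if (x[3] <= 0 || x[4] <= 0) stop_input("degenerate box: width/height must be positive")
    c(x[1] - x[3] / 2, x[2] - x[4] / 2, x[1] + x[3] / 2, x[2] + x[4] / 2)
  }
  iou_corners(geom(a), geom(b))
}

iou_corners <- function(a, b) {
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (union <= 0) 0 else inter / union
}

# pairwise IoU matrix between two box tables
iou_matrix <- function(p, t) {
  out <- matrix(0, nrow(p), nrow(t))
  if (nrow(p) == 0L || nrow(t) == 0L) return(out)
  pc <- cbind(p$cx - p$w / 2, p$cy - p$h / 2, p$cx + p$w / 2, p$cy + p$h / 2)
  tc <- cbind(t$cx - t$w / 2, t$cy - t$h / 2, t$cx + t$w / 2, t$cy + t$h / 2)
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(nrow(t))) out[i, j] <- iou_corners(pc[i, ], tc[j, ])
  }
  out
}

#' Match detections against ground truth into a confusion matrix
#'
#' Greedy matching in descending prediction confidence: each prediction
#' claims the unmatched truth box with the highest IoU at or above the
#' threshold (regardless of class); the matched pair increments cell
#' (predicted class, true class). Unmatched predictions count against the
#' background column; unmatched truths against the background row. The
#' background/background cell is structurally zero. Ties in confidence are
#' broken by input order; if no `conf` column is present input order is
#' used directly.
#'
#' @param preds,truths Box tables ([yolo_boxes()]) for one image, or lists
#'   of per-image tables (aligned by name if both are named, else by
#'   position) whose matrices are summed.
#' @param iou_threshold Minimum IoU for a match (default 0.5).
#' @param classes Class labels indexed by `class_id + 1`.
#' @return A `detection_confusion` matrix, (K+1) x (K+1), rows = predicted,
#'   columns = true, background last.
#' @export
match_detections <- function(preds, truths, iou_threshold = 0.5,
                             classes = detection_classes()) {
  if (is.data.frame(preds)) preds <- list(preds)
  if (is.data.frame(truths)) truths <- list(truths)
  if (!is.null(names(preds)) && !is.null(names(truths))) {
    stems <- union(names(preds), names(truths))
    preds <- lapply(stems, function(s) if (s %in% names(preds)) preds[[s]] else empty_boxes())
    truths <- lapply(stems, function(s) if (s %in% names(truths)) truths[[s]] else empty_boxes())
  }
  if (length(preds) != length(truths)) {
    stop_input("preds and truths must cover the same images (%d vs %d)",
               length(preds), length(truths))
  }
  K <- length(classes)
  cm <- matrix(0L, K + 1L, K + 1L,
               dimnames = list(predicted = c(classes, "background"),
                               true = c(classes, "background")))
  for (i in seq_along(preds)) {
    p <- validate_boxes(as.data.frame(preds[[i]]), "preds")
    t <- validate_boxes(as.data.frame(truths[[i]]), "truths")
    if (any(p$class_id >= K) || any(t$class_id >= K)) {
      stop_input("class_id outside 0..%d", K - 1L)
    }
    ord <- if (!is.null(p$conf) && nrow(p) > 0L) {
      order(-p$conf)   # stable: ties keep input order
    } else seq_len(nrow(p))
    M <- iou_matrix(p, t)
    t_free <- rep(TRUE, nrow(t))
    for (pi in ord) {
      cand <- which(t_free & M[pi, ] >= iou_threshold)
      if (length(cand) > 0L) {
        j <- cand[which.max(M[pi, cand])]
        t_free[j] <- FALSE
        cm[p$class_id[pi] + 1L, t$class_id[j] + 1L] <-
          cm[p$class_id[pi] + 1L, t$class_id[j] + 1L] + 1L
      } else {
        cm[p$class_id[pi] + 1L, K + 1L] <- cm[p$class_id[pi] + 1L, K + 1L] + 1L
      }
    }
    for (j in which(t_free)) {
      cm[K + 1L, t$class_id[j] + 1L] <- cm[K + 1L, t$class_id[j] + 1L] + 1L
    }
  }
  structure(cm, class = c("detection_confusion", "matrix", "array"))
}

as_confusion <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm) || nrow(cm) < 2L) {
    stop_input("confusion matrix must be square, (K+1) x (K+1)")
  }
  if (any(cm < 0) || any(cm != round(cm))) {
    stop_input("confusion matrix entries must be nonnegative integers")
  }
  cm
}

#' Metrics derived from a background-aware confusion matrix
#'
#' With rows = predicted and columns = true (background last), computes per
#' real class: sensitivity (recall) `diag/column total`, precision
#' `diag/row total`, F1, and one-vs-rest specificity over the full table
#' (an approximation in the detection setting, since the background cell is
#' structurally zero); plus overall accuracy
#' \eqn{\sum_c diag_c / \sum_c colsum_c} over the real classes only
#' (background ground truth excluded from the denominator -- the convention
#' under which published detector tables are self-consistent), and Cohen's
#' kappa on the full (K+1)-square table. Zero denominators yield `NA`.
#'
#' @param cm A [match_detections()] result, or any (K+1) x (K+1) count
#'   matrix in the same convention.
#' @param classes Optional class labels (defaults to the matrix dimnames).
#' @return A list with `per_class` (data.frame: sensitivity, precision,
#'   specificity, f1), `accuracy`, `kappa`, `mean_f1`, `mean_sensitivity`,
#'   `mean_precision`.
#' @export
metrics_from_confusion <- function(cm, classes = NULL) {
  cm <- as_confusion(cm)
  K <- nrow(cm) - 1L
  if (is.null(classes)) {
    classes <- if (!is.null(rownames(cm))) rownames(cm)[seq_len(K)]
               else paste0("class", seq_len(K))
  }
  dg <- diag(cm)[seq_len(K)]
  col_tot <- colSums(cm)[seq_len(K)]
  row_tot <- rowSums(cm)[seq_len(K)]
  total <- sum(cm)
  safe_div <- function(a, b) ifelse(b == 0, NA_real_, a / b)
  sens <- safe_div(dg, col_tot)
  prec <- safe_div(dg, row_tot)
  f1 <- ifelse(is.na(sens) | is.na(prec) | (sens + prec) == 0, NA_real_,
               2 * sens * prec / (sens + prec))
  spec <- vapply(seq_len(K), function(c) {
    TN <- total - sum(cm[c, ]) - sum(cm[, c]) + cm[c, c]
    FP <- sum(cm[c, ]) - cm[c, c]
    safe_div(TN, TN + FP)
  }, numeric(1))
  accuracy <- safe_div(sum(dg), sum(col_tot))
  po <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  kappa <- if (pe == 1) NA_real_ else (po - pe) / (1 - pe)
  list(per_class = data.frame(class = classes, sensitivity = sens,
                              precision = prec, specificity = spec, f1 = f1,
                              row.names = NULL),
       accuracy = accuracy, kappa = kappa,
       mean_f1 = mean(f1), mean_sensitivity = mean(sens),
       mean_precision = mean(prec))
}

#' Average precision and mAP
#'
#' Per class: predictions of that class are pooled across images, sorted by
#' descending confidence, and greedily matched to unmatched same-class
#' truths at the IoU threshold; precision-recall points are then summarised
#' by 101-point interpolated average precision
#' \eqn{AP = \frac{1}{101}\sum_{r \in \{0, 0.01, \dots, 1\}} \max_{\tilde r \ge r} p(\tilde r)}.
#' mAP is the unweighted mean over classes that have ground truth; classes
#' without any truth get `NA` and are excluded with a warning.
#'
#' @param preds,truths Per-image box tables or lists thereof (aligned like
#'   [match_detections()]); predictions must carry `conf`.
#' @param iou_threshold Minimum IoU for a true positive (default 0.5).
#' @param classes Class labels indexed by `class_id + 1`.
#' @return List with `per_class` (named AP vector) and `map`.
#' @export
average_precision <- function(preds, truths, iou_threshold = 0.5,
                              classes = detection_classes()) {
  if (is.data.frame(preds)) preds <- list(preds)
  if (is.data.frame(truths)) truths <- list(truths)
  if (length(preds) != length(truths)) {
    stop_input("preds and truths must cover the same images")
  }
  for (p in preds) {
    p <- as.data.frame(p)
    if (nrow(p) > 0L && is.null(p$conf)) {
      stop_input("average_precision requires prediction confidences")
    }
  }
  K <- length(classes)
  ap <- stats::setNames(rep(NA_real_, K), classes)
  for (c in seq_len(K) - 1L) {
    n_truth <- 0L
    recs <- list()
    matched <- list()
    for (i in seq_along(preds)) {
      t <- as.data.frame(truths[[i]])
      t <- t[t$class_id == c, , drop = FALSE]
      matched[[i]] <- rep(FALSE, nrow(t))
      n_truth <- n_truth + nrow(t)
      p <- as.data.frame(preds[[i]])
      p <- p[p$class_id == c, , drop = FALSE]
      if (nrow(p) > 0L) {
        recs[[length(recs) + 1L]] <- data.frame(img = i, conf = p$conf,
                                                cx = p$cx, cy = p$cy,
                                                w = p$w, h = p$h)
      }
    }
    if (n_truth == 0L) next
    if (length(recs) == 0L) { ap[c + 1L] <- 0; next }
    allp <- do.call(rbind, recs)
    allp <- allp[order(-allp$conf), , drop = FALSE]
    tp <- logical(nrow(allp))
    for (r in seq_len(nrow(allp))) {
      i <- allp$img[r]
      t <- as.data.frame(truths[[i]])
      t <- t[t$class_id == c, , drop = FALSE]
      if (nrow(t) == 0L) next
      M <- iou_matrix(allp[r, , drop = FALSE], t)
      cand <- which(!matched[[i]] & M[1, ] >= iou_threshold)
      if (length(cand) > 0L) {
        j <- cand[which.max(M[1, cand])]
        matched[[i]][j] <- TRUE
        tp[r] <- TRUE
      }
    }
    cum_tp <- cumsum(tp)
    recall <- cum_tp / n_truth
    precision <- cum_tp / seq_along(tp)
    grid <- seq(0, 1, by = 0.01)
    ap[c + 1L] <- mean(vapply(grid, function(r) {
      ok <- recall >= r
      if (!any(ok)) 0 else max(precision[ok])
    }, numeric(1)))
  }
  if (anyNA(ap)) {
    warning(sprintf("no ground truth for class(es) %s; excluded from mAP",
                    paste(classes[is.na(ap)], collapse = ", ")), call. = FALSE)
  }
  list(per_class = ap, map = mean(ap, na.rm = TRUE))
}

#' Read / write YOLO annotation text files
#'
#' One text file per image; each row is `class cx cy w h` for ground truth
#' or `class cx cy w h conf` for predictions, whitespace separated,
#' normalised coordinates. Values round-trip at six-decimal precision.
#'
#' @param path Annotation file path (may be empty or absent: no boxes).
#' @param boxes A [yolo_boxes()] table.
#' @return `read_yolo_annotations()` returns a box table.
#' @export
read_yolo_annotations <- function(path) {
  if (!file.exists(path)) return(empty_boxes())
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_boxes())
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (!length(f) %in% c(5L, 6L)) {
      stop_input("%s line %d: expected 5 or 6 fields, got %d", path, i, length(f))
    }
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v)) stop_input("%s line %d: non-numeric field", path, i)
    if (v[1] != round(v[1]) || v[1] < 0) {
      stop_input("%s line %d: class id must be a nonnegative integer", path, i)
    }
    v
  })
  has_conf <- lengths(rows) == 6L
  if (any(has_conf) && !all(has_conf)) {
    stop_input("%s mixes rows with and without confidence", path)
  }
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- c("class_id", "cx", "cy", "w", "h", if (all(has_conf)) "conf")
  df$class_id <- as.integer(df$class_id)
  validate_boxes(df, what = path)
  df
}

#' @rdname read_yolo_annotations
#' @export
write_yolo_annotations <- function(boxes, path) {
  boxes <- validate_boxes(as.data.frame(boxes))
  fmt <- function(x) sprintf("%.6f", x)
  lines <- if (nrow(boxes) == 0L) character() else if (!is.null(boxes$conf)) {
    sprintf("%d %s %s %s %s %s", boxes$class_id, fmt(boxes$cx), fmt(boxes$cy),
            fmt(boxes$w), fmt(boxes$h), fmt(boxes$conf))
  } else {
    sprintf("%d %s %s %s %s", boxes$class_id, fmt(boxes$cx), fmt(boxes$cy),
            fmt(boxes$w), fmt(boxes$h))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a confusion matrix as labelled CSV
#'
#' Mirrors the printed-table layout: rows are predicted classes, columns are
#' true classes, background last; the first CSV column holds the predicted
#' labels.
#'
#' @param path CSV path.
#' @param cm A confusion matrix in the package convention.
#' @return `read_confusion_csv()` returns a `detection_confusion` matrix.
#' @export
read_confusion_csv <- function(path) {
  if (!file.exists(path)) stop_input("confusion CSV not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  structure(as_confusion(m), class = c("detection_confusion", "matrix", "array"))
}

#' @rdname read_confusion_csv
#' @export
write_confusion_csv <- function(cm, path) {
  cm <- as_confusion(cm)
  df <- data.frame(predicted = rownames(cm), as.data.frame(unclass(cm)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Remove duplicate overlapping predictions
#'
#' Optional IoU dedup for raw prediction files (detectors normally apply
#' non-maximum suppression themselves): keeps boxes in descending confidence
#' order, dropping any same-class box overlapping a kept box at or above the
#' threshold.
#'
#' @param boxes Prediction table with `conf`.
#' @param iou_threshold Overlap threshold (default 0.5).
#' @return The filtered table.
#' @export
dedup_boxes <- function(boxes, iou_threshold = 0.5) {
  boxes <- validate_boxes(as.data.frame(boxes))
  if (nrow(boxes) <= 1L) return(boxes)
  if (is.null(boxes$conf)) stop_input("dedup_boxes requires confidences")
  ord <- order(-boxes$conf)
  keep <- logical(nrow(boxes))
  M <- iou_matrix(boxes, boxes)
  for (i in ord) {
    rivals <- which(keep & boxes$class_id == boxes$class_id[i])
    if (!any(M[i, rivals] >= iou_threshold)) keep[i] <- TRUE
  }
  boxes[sort(which(keep)), , drop = FALSE]
}
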